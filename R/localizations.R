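LOC_COLUMNS <- c("frame", "x_nm", "y_nm", "photons", "psf_sigma_nm",
                 "background", "precision_nm")

#' Localization table
#'
#' One row per fitted single-molecule event: position (nm), photon count N,
#' PSF width s (nm), fitted background b (photons/px), estimated
#' localization precision sigma_loc (nm) and the 0-based frame index the
#' event was detected in. The table carries its bounding region (nm) and
#' provenance metadata as attributes.
#'
#' @param df Data frame with columns \code{frame, x_nm, y_nm, photons,
#'   psf_sigma_nm, background, precision_nm} (an optional \code{cell_id} is
#'   kept). A zero-row data frame is legal.
#' @param bounds Numeric \code{c(xmin, ymin, xmax, ymax)} in nm; defaults to
#'   the data range (0-sized for an empty table).
#' @param provenance Named list of metadata (source stack, parameters).
#' @return A data frame of class \code{localization_table}.
#' @export
localization_table <- function(df = NULL, bounds = NULL, provenance = list()) {
  if (is.null(df))
    df <- as.data.frame(setNames(rep(list(numeric(0)), length(LOC_COLUMNS)),
                                 LOC_COLUMNS))
  missing_cols <- setdiff(LOC_COLUMNS, names(df))
  if (length(missing_cols) > 0)
    stop("missing localization columns: ", paste(missing_cols, collapse = ", "))
  keep <- c(LOC_COLUMNS, intersect("cell_id", names(df)))
  df <- as.data.frame(df)[, keep, drop = FALSE]
  if (nrow(df) > 0) {
    if (any(df$photons <= 0)) stop("photons must be > 0")
    if (any(df$precision_nm <= 0)) stop("precision_nm must be > 0")
    if (any(df$frame < 0)) stop("frame indices must be >= 0")
  }
  if (is.null(bounds)) {
    bounds <- if (nrow(df) > 0)
      c(min(df$x_nm), min(df$y_nm), max(df$x_nm), max(df$y_nm))
    else c(0, 0, 0, 0)
  }
  stopifnot(length(bounds) == 4)
  if (nrow(df) > 0 &&
      (any(df$x_nm < bounds[1] - 1e-9) || any(df$x_nm > bounds[3] + 1e-9) ||
       any(df$y_nm < bounds[2] - 1e-9) || any(df$y_nm > bounds[4] + 1e-9)))
    stop("localizations outside the stated bounding region")
  structure(df,
            bounds = as.numeric(bounds),
            provenance = provenance,
            class = c("localization_table", "data.frame"))
}

#' @rdname localization_table
#' @param table A \code{localization_table}.
#' @export
loc_bounds <- function(table) attr(table, "bounds")

#' Write a localization table as CSV
#'
#' Columns \code{frame,x_nm,y_nm,photons,psf_sigma_nm,background,precision_nm}
#' (plus \code{cell_id} when present), one row per event, full double
#' precision so that read(write(t)) round-trips to below 1e-6 nm.
#'
#' @param table A \code{\link{localization_table}}.
#' @param path Output CSV path.
#' @export
write_localizations <- function(table, path) {
  stopifnot(inherits(table, "localization_table"))
  df <- as.data.frame(table)
  cols <- names(df)
  lines <- paste(cols, collapse = ",")
  if (nrow(df) > 0) {
    fmt <- vapply(seq_len(nrow(df)), function(r) {
      paste(vapply(cols, function(cl) {
        v <- df[[cl]][r]
        if (cl == "frame") sprintf("%d", as.integer(v))
        else sprintf("%.17g", v)
      }, character(1)), collapse = ",")
    }, character(1))
    lines <- c(lines, fmt)
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_localizations
#' @return \code{read_localizations} returns a \code{localization_table};
#'   malformed headers or non-numeric rows raise an error naming the line.
#' @export
read_localizations <- function(path) {
  if (!file.exists(path))
    stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) == 0)
    stop("empty localization file: ", path)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (!all(LOC_COLUMNS %in% header))
    stop("malformed header (line 1): expected columns ",
         paste(LOC_COLUMNS, collapse = ","))
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0)
    return(localization_table())
  parts <- strsplit(body, ",", fixed = TRUE)
  ncol_ok <- lengths(parts) == length(header)
  if (any(!ncol_ok))
    stop("malformed row at line ", which(!ncol_ok)[1] + 1L)
  vals <- suppressWarnings(
    vapply(parts, function(p) as.numeric(p), numeric(length(header))))
  if (length(header) == 1L) vals <- matrix(vals, nrow = 1)
  bad <- which(apply(is.na(vals), 2, any))
  if (length(bad) > 0)
    stop("non-numeric value at line ", bad[1] + 1L)
  df <- as.data.frame(t(vals))
  names(df) <- header
  localization_table(df)
}

#' Summary statistics of a localization table
#'
#' Number of localizations plus mean and median localization precision, the
#' per-cell headline numbers of an SMLM acquisition report.
#'
#' @param table A \code{\link{localization_table}}.
#' @return List with \code{n}, \code{mean_precision_nm},
#'   \code{median_precision_nm} (the last two \code{NA} when \code{n} = 0).
#' @export
summarize_localizations <- function(table) {
  stopifnot(inherits(table, "localization_table"))
  n <- nrow(table)
  if (n == 0)
    return(list(n = 0L, mean_precision_nm = NA_real_,
                median_precision_nm = NA_real_))
  list(n = n,
       mean_precision_nm = mean(table$precision_nm),
       median_precision_nm = median(table$precision_nm))
}
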