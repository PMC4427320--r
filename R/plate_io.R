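# Plate-grid container, raw plate preprocessing, and CSV readers/writers.

#' Well-plate luminescence grid
#'
#' Container for one plate of specific luminescence measured over a factorial
#' C8-HSL x 3OC6-HSL concentration design.  Missing wells are `NA` in `L`.
#'
#' @param c8_levels strictly ascending C8-HSL concentrations (nM), one per row.
#' @param c6_levels strictly ascending 3OC6-HSL concentrations (nM), one per
#'   column.
#' @param L matrix of specific luminescence (counts normalized to
#'   path-corrected OD600 of 1.0); `NA` marks missing wells.
#' @param meta named list of labels (strain, replicate, ...).
#' @return An object of class `"plate_grid"`.
#' @export
plate_grid <- function(c8_levels, c6_levels, L, meta = list()) {
  L <- as.matrix(L)
  storage.mode(L) <- "double"
  if (nrow(L) != length(c8_levels) || ncol(L) != length(c6_levels))
    stop("matrix shape does not match concentration axes", call. = FALSE)
  if (any(diff(c8_levels) <= 0) || any(diff(c6_levels) <= 0))
    stop("concentration levels must be strictly ascending", call. = FALSE)
  if (any(c8_levels < 0) || any(c6_levels < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  if (any(L < 0, na.rm = TRUE))
    stop("specific luminescence must be non-negative", call. = FALSE)
  dimnames(L) <- list(format(c8_levels, trim = TRUE),
                      format(c6_levels, trim = TRUE))
  structure(list(c8_levels = as.numeric(c8_levels),
                 c6_levels = as.numeric(c6_levels),
                 L = L, meta = meta),
            class = "plate_grid")
}

#' @export
print.plate_grid <- function(x, ...) {
  cat(sprintf("Plate grid: %d C8-HSL x %d 3OC6-HSL levels (nM), %d missing well(s)\n",
              length(x$c8_levels), length(x$c6_levels), sum(is.na(x$L))))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  }
  print(x$L)
  invisible(x)
}

#' Raw plate-reader measurements
#'
#' Holds raw OD600 and luminescence count matrices over the concentration
#' design, prior to normalization to specific luminescence.
#'
#' @param od600 matrix of raw OD600 readings (microplate path length).
#' @param lum matrix of raw luminescence counts, same shape.
#' @inheritParams plate_grid
#' @return An object of class `"raw_plate"`.
#' @export
raw_plate <- function(od600, lum, c8_levels, c6_levels, meta = list()) {
  od600 <- as.matrix(od600); lum <- as.matrix(lum)
  if (!all(dim(od600) == dim(lum)))
    stop("od600 and lum must have the same shape", call. = FALSE)
  if (nrow(lum) != length(c8_levels) || ncol(lum) != length(c6_levels))
    stop("matrix shape does not match concentration axes", call. = FALSE)
  structure(list(od600 = od600, lum = lum,
                 c8_levels = as.numeric(c8_levels),
                 c6_levels = as.numeric(c6_levels), meta = meta),
            class = "raw_plate")
}

#' Convert raw plate-reader readings to specific luminescence
#'
#' OD600 readings from the microplate are divided by 0.46 to correspond to a
#' 1-cm path length, and luminescence is normalized to the path-corrected
#' OD600 of 1.0: `specific L = lum / (od600 / 0.46)`.  Wells with
#' non-positive OD600 are flagged missing with a warning.
#'
#' @param raw a [raw_plate()] object.
#' @param od_path_factor microplate-to-1-cm path-length conversion divisor.
#' @return A [plate_grid()] of specific luminescence.
#' @export
preprocess_raw <- function(raw, od_path_factor = 0.46) {
  stopifnot(inherits(raw, "raw_plate"))
  bad <- !is.finite(raw$od600) | raw$od600 <= 0
  if (any(bad))
    warning(sprintf("%d well(s) with non-positive OD600 flagged missing",
                    sum(bad)), call. = FALSE)
  L <- raw$lum / (raw$od600 / od_path_factor)
  L[bad] <- NA_real_
  plate_grid(raw$c8_levels, raw$c6_levels, L, raw$meta)
}

#' Write a plate grid as a matrix-layout CSV
#'
#' Canonical layout mirrors the physical plate: the first header cell is
#' `c8_nM`, the remaining header cells are the 3OC6-HSL levels (nM), each
#' subsequent row starts with its C8-HSL level followed by the specific
#' luminescence of that row.  Missing wells are written as empty cells.
#'
#' @param plate a [plate_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_plate <- function(plate, path) {
  stopifnot(inherits(plate, "plate_grid"))
  df <- data.frame(c8_nM = plate$c8_levels, plate$L, check.names = FALSE)
  names(df) <- c("c8_nM", format(plate$c6_levels, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a plate grid from CSV
#'
#' Two dialects are supported.  `"matrix"`: the layout written by
#' [write_plate()] (first column C8-HSL levels, header row 3OC6-HSL levels).
#' `"long"`: one row per well with columns `c8_nM`, `c6_nM`, `luminescence`,
#' in any row order.  `"auto"` picks long format when those three columns are
#' present.  Axes are sorted ascending with the matrix permuted to match;
#' non-numeric or empty cells become missing wells.
#'
#' @param path CSV file path.
#' @param format `"auto"`, `"matrix"`, or `"long"`.
#' @param meta named list attached to the result.
#' @return A [plate_grid()].
#' @export
read_plate <- function(path, format = c("auto", "matrix", "long"),
                       meta = list()) {
  format <- match.arg(format)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character", strip.white = TRUE)
  if (format == "auto") {
    format <- if (all(c("c8_nM", "c6_nM", "luminescence") %in% names(df)))
      "long" else "matrix"
  }
  if (format == "long") {
    need <- c("c8_nM", "c6_nM", "luminescence")
    if (!all(need %in% names(df)))
      stop("long-format CSV needs columns c8_nM, c6_nM, luminescence",
           call. = FALSE)
    c8v <- as.numeric(df$c8_nM)
    c6v <- as.numeric(df$c6_nM)
    if (any(is.na(c8v)) || any(is.na(c6v)))
      stop("non-numeric concentration labels", call. = FALSE)
    if (anyDuplicated(paste(c8v, c6v)))
      stop("duplicate (c8, c6) well labels", call. = FALSE)
    c8_levels <- sort(unique(c8v))
    c6_levels <- sort(unique(c6v))
    L <- matrix(NA_real_, length(c8_levels), length(c6_levels))
    L[cbind(match(c8v, c8_levels), match(c6v, c6_levels))] <-
      suppressWarnings(as.numeric(df$luminescence))
    return(plate_grid(c8_levels, c6_levels, L, meta))
  }
  # matrix dialect
  if (ncol(df) < 2L)
    stop("matrix-format CSV needs a C8 column plus at least one 3OC6 column",
         call. = FALSE)
  c6_levels <- as.numeric(names(df)[-1L])
  c8_levels <- as.numeric(df[[1L]])
  if (any(is.na(c6_levels)) || any(is.na(c8_levels)))
    stop("non-numeric concentration labels", call. = FALSE)
  if (anyDuplicated(c6_levels) || anyDuplicated(c8_levels))
    stop("duplicate concentration labels", call. = FALSE)
  L <- suppressWarnings(
    apply(as.matrix(df[, -1L, drop = FALSE]), 2L, as.numeric))
  L <- matrix(L, nrow = length(c8_levels))
  oi <- order(c8_levels); oj <- order(c6_levels)
  plate_grid(c8_levels[oi], c6_levels[oj], L[oi, oj, drop = FALSE], meta)
}
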