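#' Norm tables of crown mesiodistal diameter
#'
#' A norm table gives, per jaw, tooth position (FDI second digit 1-8) and sex,
#' the population mean and SD of the crown mesiodistal diameter in mm, for
#' z-score analysis of measured teeth. CSV format: header
#' `jaw,position,sex,mean_mm,sd_mm`.
#'
#' Published population norms are not redistributed with the package;
#' [default_norm_table()] returns a clearly *synthetic* table derived from
#' the package's own tooth archetypes (the sizes the synthetic generator
#' plants), which makes generator output score near z = 0 by construction.
#' Supply your own table for real data.
#'
#' @param path CSV file path.
#' @return data.frame with columns `jaw`, `position`, `sex`, `mean_mm`,
#'   `sd_mm`.
#' @export
read_norm_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("jaw", "position", "sex", "mean_mm", "sd_mm")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("norm table '", path, "': missing columns ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(x$sd_mm)) || any(x$sd_mm <= 0)) {
    stop("norm table '", path, "': sd_mm must be > 0 in every row", call. = FALSE)
  }
  x
}

#' @param d a norm table data.frame.
#' @rdname read_norm_table
#' @export
write_norm_table <- function(d, path) {
  stopifnot(all(c("jaw", "position", "sex", "mean_mm", "sd_mm") %in% names(d)))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_norm_table
#' @export
default_norm_table <- function() {
  arch <- .tooth_archetypes()
  rows <- expand.grid(jaw = .jaws, sex = c("M", "F"),
                      position = arch$position, stringsAsFactors = FALSE)
  rows$mean_mm <- arch$md[match(rows$position, arch$position)]
  rows$sd_mm <- 0.45
  rows[, c("jaw", "position", "sex", "mean_mm", "sd_mm")]
}

#' Look up one norm row
#'
#' @param norms a norm table data.frame.
#' @param jaw,position,sex row key; `position` is the FDI second digit.
#' @return one-row data.frame with `mean_mm` and `sd_mm`.
#' @export
norm_lookup <- function(norms, jaw, position, sex) {
  i <- which(norms$jaw == jaw & norms$position == position & norms$sex == sex)
  if (length(i) == 0L) {
    stop("no norm row for jaw=", jaw, " position=", position, " sex=", sex,
         call. = FALSE)
  }
  norms[i[1], ]
}
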