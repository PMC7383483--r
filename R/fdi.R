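#' FDI tooth-code helpers
#'
#' Two-digit FDI codes: first digit is the quadrant (1 upper right, 2 upper
#' left, 3 lower left, 4 lower right), second the position (1 central incisor
#' ... 8 third molar). A supernumerary tooth is labelled with its adjacent
#' permanent tooth's code plus a trailing comma (e.g. `"33,"`), the convention
#' used on tooth formulas of supernumeraries in impacted-pair labelling.
#'
#' @param tooth_id character tooth label, FDI code optionally with trailing
#'   comma.
#' @return `fdi_parse()` returns a list with `quadrant`, `position`,
#'   `supernumerary`; the others return character scalars.
#' @examples
#' fdi_parse("35")
#' fdi_region("33,")   # supernumerary adjacent to the mandibular left canine
#' @export
fdi_parse <- function(tooth_id) {
  stopifnot(is.character(tooth_id), length(tooth_id) == 1L)
  supernum <- grepl(",$", tooth_id)
  code <- sub(",$", "", tooth_id)
  if (!grepl("^[1-4][1-8]$", code)) {
    stop("not an FDI permanent-tooth code: '", tooth_id, "'", call. = FALSE)
  }
  list(quadrant = as.integer(substr(code, 1, 1)),
       position = as.integer(substr(code, 2, 2)),
       supernumerary = supernum)
}

.is_fdi <- function(tooth_id) {
  grepl("^[1-4][1-8],?$", tooth_id)
}

#' @rdname fdi_parse
#' @export
fdi_jaw <- function(tooth_id) {
  q <- fdi_parse(tooth_id)$quadrant
  if (q %in% c(1L, 2L)) "maxilla" else "mandible"
}

#' @rdname fdi_parse
#' @export
fdi_region <- function(tooth_id) {
  p <- fdi_parse(tooth_id)$position
  if (p <= 2L) "anterior" else if (p == 3L) "canine" else if (p <= 5L) "premolar" else "molar"
}

.jaws <- c("maxilla", "mandible")
.regions <- c("anterior", "canine", "premolar", "molar")
.statuses <- c("primary", "erupted_permanent", "unerupted_permanent",
               "supernumerary", "impacted_unresolved")

#' The eight jaw-by-region location bins
#'
#' @return character vector of the eight bins, maxilla first.
#' @export
region_bins <- function() {
  as.vector(outer(c("maxillary", "mandibular"), .regions, paste))
}

#' @param jaw `"maxilla"` or `"mandible"`.
#' @param region one of `"anterior"`, `"canine"`, `"premolar"`, `"molar"`.
#' @rdname region_bins
#' @export
region_bin <- function(jaw, region) {
  jaw <- match.arg(jaw, .jaws)
  region <- match.arg(region, .regions)
  paste(if (jaw == "maxilla") "maxillary" else "mandibular", region)
}
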