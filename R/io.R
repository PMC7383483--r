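# Landmark file schema (version 1)
#
# JSON: one object per case:
#   {"schema": "supradent3d-landmarks-1",
#    "coordinate_frame": "right-handed mm; +x patient left; +y anterior; +z cranial",
#    "case_id": "...", "metadata": {...},
#    "volume_bounds": {"min": [x,y,z], "max": [x,y,z]},
#    "teeth": [{"tooth_id": "35", "jaw": "mandible", "region": "premolar",
#               "status": "unerupted_permanent", "apex_in_volume": true,
#               "landmarks": {"occlusal_center": [x,y,z], ... },
#               "cusp_tips": [[x,y,z], ...],
#               "accessory_apices": [[x,y,z], ...],   # optional
#               "metadata": {...}}, ...]}
#
# CSV alternative: one row per landmark with columns
#   case_id,tooth_id,jaw,region,status,apex_in_volume,landmark,x,y,z
# where `landmark` is one of the eight named points, or cusp_tip_<i> /
# accessory_apex_<i>.

.SCHEMA_ID <- "supradent3d-landmarks-1"
.FRAME_DOC <- "right-handed mm; +x patient left; +y anterior; +z cranial"

#' Read and write dentition landmark files
#'
#' `write_dentition()` refuses to write a dentition that fails
#' [validate_dentition()] (non-finite coordinates etc.); field order in the
#' output is deterministic so files diff cleanly. Coordinates are serialized
#' at 17 significant digits, so a write/read round trip reproduces every
#' coordinate bit-identically. Unknown per-tooth or per-case JSON fields are
#' preserved in the respective `metadata`.
#'
#' @param path file path; format from extension (`.json` or `.csv`) unless
#'   `format` is given.
#' @param format `"json"` or `"csv"`.
#' @return `read_dentition()` returns a [dentition()]; `write_dentition()`
#'   returns `path` invisibly.
#' @export
read_dentition <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "json") .read_dentition_json(path) else .read_dentition_csv(path)
}

.tooth_from_parts <- function(id, jaw, region, status, apex_in_volume,
                              landmarks, cusp_tips, accessory_apices, meta) {
  for (nm in .landmark_names) {
    if (is.null(landmarks[[nm]])) {
      stop("tooth '", id, "': missing landmark '", nm, "'", call. = FALSE)
    }
  }
  if (length(cusp_tips) < 1L) {
    stop("tooth '", id, "': missing cusp_tips", call. = FALSE)
  }
  tooth_landmarks(
    tooth_id = id, jaw = jaw, region = region, status = status,
    occlusal_center = landmarks$occlusal_center, apex = landmarks$apex,
    cej_labial = landmarks$cej_labial, cej_lingual = landmarks$cej_lingual,
    cusp_tips = cusp_tips,
    crown_mesial = landmarks$crown_mesial, crown_distal = landmarks$crown_distal,
    crown_buccal = landmarks$crown_buccal, crown_lingual = landmarks$crown_lingual,
    apex_in_volume = apex_in_volume, accessory_apices = accessory_apices,
    metadata = meta)
}

.read_dentition_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(x$schema, .SCHEMA_ID)) {
    stop("file '", path, "': unknown or missing schema id (expected '",
         .SCHEMA_ID, "')", call. = FALSE)
  }
  known <- c("schema", "coordinate_frame", "case_id", "metadata",
             "volume_bounds", "teeth")
  meta <- c(x$metadata %||% list(), x[setdiff(names(x), known)])
  teeth <- lapply(x$teeth %||% list(), function(tx) {
    id <- tx$tooth_id %||% "<missing tooth_id>"
    lk <- lapply(tx$landmarks %||% list(), unlist)
    tips <- lapply(tx$cusp_tips %||% list(), unlist)
    acc <- lapply(tx$accessory_apices %||% list(), unlist)
    tknown <- c("tooth_id", "jaw", "region", "status", "apex_in_volume",
                "landmarks", "cusp_tips", "accessory_apices", "metadata")
    tmeta <- c(tx$metadata %||% list(), tx[setdiff(names(tx), tknown)])
    .tooth_from_parts(id, tx$jaw, tx$region %||% NA_character_, tx$status,
                      isTRUE(tx$apex_in_volume %||% TRUE), lk, tips, acc, tmeta)
  })
  vb <- if (!is.null(x$volume_bounds)) {
    list(min = unlist(x$volume_bounds$min), max = unlist(x$volume_bounds$max))
  } else NULL
  d <- dentition(case_id = x$case_id %||% "<unknown>", teeth = teeth,
                 volume_bounds = vb, metadata = meta)
  dup <- unique(grep("^duplicate tooth_id", validate_dentition(d), value = TRUE))
  if (length(dup)) stop("file '", path, "': ", paste(dup, collapse = "; "), call. = FALSE)
  d
}

.read_dentition_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("case_id", "tooth_id", "jaw", "region", "status",
            "apex_in_volume", "landmark", "x", "y", "z")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("file '", path, "': missing columns ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  teeth <- lapply(split(x, factor(x$tooth_id, levels = unique(x$tooth_id))),
                  function(tx) {
    id <- tx$tooth_id[1]
    pts <- lapply(seq_len(nrow(tx)), function(i) c(tx$x[i], tx$y[i], tx$z[i]))
    names(pts) <- tx$landmark
    lk <- pts[intersect(.landmark_names, names(pts))]
    tips <- unname(pts[grep("^cusp_tip_", names(pts))])
    acc <- unname(pts[grep("^accessory_apex_", names(pts))])
    .tooth_from_parts(id, tx$jaw[1],
                      if (is.na(tx$region[1]) || tx$region[1] == "") NA_character_ else tx$region[1],
                      tx$status[1], isTRUE(as.logical(tx$apex_in_volume[1])),
                      lk, tips, acc, list())
  })
  dentition(case_id = as.character(x$case_id[1]), teeth = unname(teeth))
}

#' @param d a [dentition()].
#' @rdname read_dentition
#' @export
write_dentition <- function(d, path, format = c("auto", "json", "csv")) {
  stopifnot(inherits(d, "dentition"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  bad <- validate_dentition(d)
  if (length(bad)) {
    stop("refusing to write invalid dentition '", d$case_id, "': ",
         paste(bad, collapse = "; "), call. = FALSE)
  }
  if (format == "json") .write_dentition_json(d, path) else .write_dentition_csv(d, path)
  invisible(path)
}

.write_dentition_json <- function(d, path) {
  teeth <- lapply(d$teeth, function(t) {
    out <- list(tooth_id = t$tooth_id, jaw = t$jaw, region = t$region,
                status = t$status, apex_in_volume = t$apex_in_volume,
                landmarks = t[.landmark_names],
                cusp_tips = t$cusp_tips)
    if (length(t$accessory_apices)) out$accessory_apices <- t$accessory_apices
    if (length(t$metadata)) out$metadata <- t$metadata
    out
  })
  x <- list(schema = .SCHEMA_ID, coordinate_frame = .FRAME_DOC,
            case_id = d$case_id, metadata = d$metadata,
            volume_bounds = d$volume_bounds, teeth = teeth)
  # digits = I(17): exact decimal representation of doubles, so round trips
  # are bit-identical.
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, null = "null", na = "null")
}

.write_dentition_csv <- function(d, path) {
  rows <- lapply(d$teeth, function(t) {
    pts <- tooth_points(t)
    data.frame(case_id = d$case_id, tooth_id = t$tooth_id, jaw = t$jaw,
               region = ifelse(is.na(t$region), "", t$region),
               status = t$status, apex_in_volume = t$apex_in_volume,
               landmark = rownames(pts),
               x = pts[, 1], y = pts[, 2], z = pts[, 3],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(case_id = character(), tooth_id = character(), jaw = character(),
               region = character(), status = character(),
               apex_in_volume = logical(), landmark = character(),
               x = numeric(), y = numeric(), z = numeric())
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", .SCHEMA_ID, "; ", .FRAME_DOC), con)
  utils::write.csv(format(tab, digits = 17, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = TRUE)
}
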