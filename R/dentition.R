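#' Named dental landmarks for one tooth
#'
#' A `tooth_landmarks` object holds the named 3D anatomical points from which
#' every measurement in the pipeline is derived: the occlusal-surface centre
#' (incisal centre for anterior teeth, pointed cusp tip for canines, central
#' groove centre for premolars/molars), the root apex, the labial and lingual
#' cementoenamel-junction (CEJ) points defining the cervical reference line,
#' one or more cusp tips, and the mesial/distal/buccal/lingual crown extremes.
#' Coordinates are millimetres in a right-handed patient frame (+x patient
#' left, +y anterior, +z cranial).
#'
#' The constructor checks structure (numeric length-3 points); semantic
#' invariants (finiteness, non-empty cusp tips, distinct crown extremes,
#' jaw/region consistency with an FDI code) are collected by
#' [validate_dentition()] so that invalid data can be represented and
#' reported rather than crashing on construction.
#'
#' @param tooth_id FDI two-digit code, or the adjacent tooth's code plus a
#'   trailing comma for a supernumerary tooth, or any other label for teeth of
#'   unknown identity (e.g. from segmentation).
#' @param jaw `"maxilla"` or `"mandible"`.
#' @param region `"anterior"`, `"canine"`, `"premolar"`, `"molar"`, or `NA`
#'   when unknown.
#' @param status one of `"primary"`, `"erupted_permanent"`,
#'   `"unerupted_permanent"`, `"supernumerary"`, `"impacted_unresolved"`.
#' @param occlusal_center,apex,cej_labial,cej_lingual,crown_mesial,crown_distal,crown_buccal,crown_lingual
#'   numeric length-3 points (mm).
#' @param cusp_tips list of numeric length-3 points, at least one.
#' @param apex_in_volume logical; `FALSE` when the root extends out of the
#'   imaging range, in which case root length is not measurable and the tooth
#'   is excluded from root-length comparisons.
#' @param accessory_apices optional list of additional root-branch apex
#'   points for multi-rooted teeth.
#' @param metadata named list of free-form extra fields, preserved by I/O.
#' @return an object of class `tooth_landmarks`.
#' @export
tooth_landmarks <- function(tooth_id, jaw, region, status,
                            occlusal_center, apex, cej_labial, cej_lingual,
                            cusp_tips,
                            crown_mesial, crown_distal,
                            crown_buccal, crown_lingual,
                            apex_in_volume = TRUE,
                            accessory_apices = list(),
                            metadata = list()) {
  stopifnot(is.character(tooth_id), length(tooth_id) == 1L, nzchar(tooth_id))
  jaw <- match.arg(jaw, .jaws)
  if (!is.na(region)) region <- match.arg(region, .regions)
  status <- match.arg(status, .statuses)
  pts <- list(occlusal_center = occlusal_center, apex = apex,
              cej_labial = cej_labial, cej_lingual = cej_lingual,
              crown_mesial = crown_mesial, crown_distal = crown_distal,
              crown_buccal = crown_buccal, crown_lingual = crown_lingual)
  for (nm in names(pts)) {
    if (!.is_point3(pts[[nm]])) {
      stop("tooth '", tooth_id, "': landmark '", nm,
           "' must be a numeric length-3 point", call. = FALSE)
    }
    pts[[nm]] <- as.numeric(pts[[nm]])
  }
  if (!is.list(cusp_tips)) cusp_tips <- list(cusp_tips)
  cusp_tips <- lapply(cusp_tips, function(p) {
    if (!.is_point3(p)) {
      stop("tooth '", tooth_id, "': every cusp tip must be a numeric length-3 point",
           call. = FALSE)
    }
    as.numeric(p)
  })
  structure(c(list(tooth_id = tooth_id, jaw = jaw, region = region,
                   status = status),
              pts,
              list(cusp_tips = cusp_tips,
                   apex_in_volume = isTRUE(apex_in_volume),
                   accessory_apices = accessory_apices,
                   metadata = metadata)),
            class = "tooth_landmarks")
}

.landmark_names <- c("occlusal_center", "apex", "cej_labial", "cej_lingual",
                     "crown_mesial", "crown_distal", "crown_buccal",
                     "crown_lingual")

#' @export
print.tooth_landmarks <- function(x, ...) {
  cat(sprintf("<tooth %s: %s %s, %s, %d cusp tip(s)>\n",
              x$tooth_id, x$jaw, ifelse(is.na(x$region), "?", x$region),
              x$status, length(x$cusp_tips)))
  invisible(x)
}

#' All landmark points of a tooth as a matrix
#'
#' @param t a [tooth_landmarks()] object.
#' @return numeric matrix, one landmark per row (named rows; cusp tips and
#'   accessory apices included).
#' @export
tooth_points <- function(t) {
  stopifnot(inherits(t, "tooth_landmarks"))
  pts <- do.call(rbind, t[.landmark_names])
  out <- pts
  if (length(t$cusp_tips)) {
    tips <- do.call(rbind, t$cusp_tips)
    rownames(tips) <- paste0("cusp_tip_", seq_len(nrow(tips)))
    out <- rbind(pts, tips)
  }
  if (length(t$accessory_apices)) {
    acc <- do.call(rbind, t$accessory_apices)
    rownames(acc) <- paste0("accessory_apex_", seq_len(nrow(acc)))
    out <- rbind(out, acc)
  }
  out
}

#' One case's dentition: a collection of teeth plus imaging bounds
#'
#' @param case_id character case label.
#' @param teeth list of [tooth_landmarks()] objects.
#' @param volume_bounds imaging range as a list with numeric length-3 `min`
#'   and `max` (mm); defaults to the landmark bounding box plus a 6 mm margin.
#' @param metadata named list (e.g. sex, age), preserved by I/O.
#' @return an object of class `dentition`.
#' @export
dentition <- function(case_id, teeth, volume_bounds = NULL, metadata = list()) {
  stopifnot(is.character(case_id), length(case_id) == 1L, is.list(teeth))
  for (t in teeth) stopifnot(inherits(t, "tooth_landmarks"))
  if (is.null(volume_bounds)) {
    if (length(teeth)) {
      all_pts <- do.call(rbind, lapply(teeth, tooth_points))
      volume_bounds <- list(min = apply(all_pts, 2, min) - 6,
                            max = apply(all_pts, 2, max) + 6)
    } else {
      volume_bounds <- list(min = c(0, 0, 0), max = c(1, 1, 1))
    }
  }
  volume_bounds$min <- as.numeric(volume_bounds$min)
  volume_bounds$max <- as.numeric(volume_bounds$max)
  structure(list(case_id = case_id, teeth = teeth,
                 volume_bounds = volume_bounds, metadata = metadata),
            class = "dentition")
}

#' @export
print.dentition <- function(x, ...) {
  st <- table(vapply(x$teeth, `[[`, "", "status"))
  cat(sprintf("<dentition %s: %d teeth (%s)>\n", x$case_id, length(x$teeth),
              paste(sprintf("%s=%d", names(st), st), collapse = ", ")))
  invisible(x)
}

.tooth_by_id <- function(d, id) {
  ids <- vapply(d$teeth, `[[`, "", "tooth_id")
  i <- match(id, ids)
  if (is.na(i)) stop("no tooth '", id, "' in case '", d$case_id, "'", call. = FALSE)
  d$teeth[[i]]
}

.teeth_with_status <- function(d, statuses) {
  keep <- vapply(d$teeth, function(t) t$status %in% statuses, logical(1))
  d$teeth[keep]
}

#' Validate a dentition against the type invariants
#'
#' Violations are returned as data, not raised as errors, so that a whole
#' file can be audited in one pass. Checks: unique tooth ids, finite
#' coordinates, non-empty cusp tips, distinct mesial/distal crown extremes,
#' jaw/region consistency with FDI codes, valid status, and non-degenerate
#' volume bounds.
#'
#' @param d a [dentition()].
#' @return character vector of human-readable violations; empty when valid.
#' @export
validate_dentition <- function(d) {
  stopifnot(inherits(d, "dentition"))
  v <- character()
  ids <- vapply(d$teeth, `[[`, "", "tooth_id")
  dup <- unique(ids[duplicated(ids)])
  for (id in dup) v <- c(v, sprintf("duplicate tooth_id '%s'", id))
  if (!all(is.finite(d$volume_bounds$min)) || !all(is.finite(d$volume_bounds$max)) ||
      any(d$volume_bounds$max <= d$volume_bounds$min)) {
    v <- c(v, "degenerate volume_bounds")
  }
  for (t in d$teeth) {
    id <- t$tooth_id
    pts <- tooth_points(t)
    if (!all(is.finite(pts))) {
      bad <- unique(rownames(pts)[!apply(is.finite(pts), 1, all)])
      v <- c(v, sprintf("tooth '%s': non-finite coordinates in %s", id,
                        paste(bad, collapse = ", ")))
    }
    if (length(t$cusp_tips) < 1L) {
      v <- c(v, sprintf("tooth '%s': cusp_tips is empty", id))
    }
    if (isTRUE(all(t$crown_mesial == t$crown_distal))) {
      v <- c(v, sprintf("tooth '%s': crown_mesial equals crown_distal", id))
    }
    if (.is_fdi(id)) {
      if (t$jaw != fdi_jaw(id)) {
        v <- c(v, sprintf("tooth '%s': jaw '%s' inconsistent with FDI code", id, t$jaw))
      }
      if (!is.na(t$region) && t$region != fdi_region(id)) {
        v <- c(v, sprintf("tooth '%s': region '%s' inconsistent with FDI code", id, t$region))
      }
    }
  }
  v
}
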