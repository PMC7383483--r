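#' Resolve supernumerary vs permanent status within impacted pairs
#'
#' Impacted teeth in close proximity are clustered (single linkage on
#' occlusal-centre distance, cut at `proximity_radius`); within each cluster
#' of two, the tooth with the longer dental root is the unerupted permanent
#' tooth and the shorter-rooted one the supernumerary (root length tracks the
#' stage of odontogenesis). Equal root lengths are broken toward the larger
#' crown length and flagged. Clusters of three or more unresolved teeth are
#' not decidable by this rule and raise an error demanding manual status.
#'
#' @param d a [dentition()] containing teeth with status
#'   `"impacted_unresolved"`.
#' @param proximity_radius mm; default 6 (well under typical inter-tooth
#'   spacing, so clusters are unambiguous).
#' @return the dentition with statuses resolved; attribute `"pair_flags"`
#'   carries a data.frame of tie flags and unpaired leftovers.
#' @export
resolve_pair_status <- function(d, proximity_radius = 6) {
  stopifnot(inherits(d, "dentition"))
  idx <- which(vapply(d$teeth, function(t) t$status == "impacted_unresolved", logical(1)))
  flags <- data.frame(tooth_id = character(), flag = character(),
                      stringsAsFactors = FALSE)
  if (length(idx) == 0L) {
    attr(d, "pair_flags") <- flags
    return(d)
  }
  oc <- do.call(rbind, lapply(d$teeth[idx], `[[`, "occlusal_center"))
  cl <- if (length(idx) == 1L) {
    1L
  } else {
    stats::cutree(stats::hclust(stats::dist(oc), method = "single"),
                  h = proximity_radius)
  }
  for (g in unique(cl)) {
    members <- idx[cl == g]
    if (length(members) == 1L) {
      flags <- rbind(flags, data.frame(
        tooth_id = d$teeth[[members]]$tooth_id,
        flag = "unpaired_impacted_unresolved", stringsAsFactors = FALSE))
      next
    }
    if (length(members) > 2L) {
      stop("proximity cluster of ", length(members),
           " unresolved impacted teeth (",
           paste(vapply(d$teeth[members], `[[`, "", "tooth_id"), collapse = ", "),
           "): manual status assignment required", call. = FALSE)
    }
    rl <- vapply(d$teeth[members], root_length, numeric(1))
    if (any(is.na(rl))) {
      stop("cannot resolve pair (",
           paste(vapply(d$teeth[members], `[[`, "", "tooth_id"), collapse = ", "),
           "): root length not measurable", call. = FALSE)
    }
    if (rl[1] == rl[2]) {
      cw <- vapply(d$teeth[members], crown_length, numeric(1))
      longer <- if (cw[1] >= cw[2]) 1L else 2L
      flags <- rbind(flags, data.frame(
        tooth_id = d$teeth[[members[longer]]]$tooth_id,
        flag = "equal_root_length_tie", stringsAsFactors = FALSE))
    } else {
      longer <- which.max(rl)
    }
    d$teeth[[members[longer]]]$status <- "unerupted_permanent"
    d$teeth[[members[-longer]]]$status <- "supernumerary"
  }
  attr(d, "pair_flags") <- flags
  d
}

#' Assign the adjacent permanent tooth of a supernumerary
#'
#' The adjacent permanent tooth is the permanent tooth (erupted or unerupted)
#' of the same jaw minimizing the 3D Euclidean distance between occlusal
#' centres. Exact ties are broken by tooth-id order and flagged.
#'
#' @param s a supernumerary [tooth_landmarks()] object.
#' @param d the [dentition()] it belongs to.
#' @return list with `adjacent_id`, `distance_mm`, `tie` flag.
#' @export
assign_adjacent <- function(s, d) {
  stopifnot(inherits(s, "tooth_landmarks"), inherits(d, "dentition"))
  perm <- .teeth_with_status(d, c("erupted_permanent", "unerupted_permanent"))
  perm <- perm[vapply(perm, function(t) t$jaw == s$jaw, logical(1))]
  if (!length(perm)) {
    stop("no permanent tooth available in the ", s$jaw,
         " to pair with '", s$tooth_id, "'", call. = FALSE)
  }
  dst <- vapply(perm, function(t) .vnorm(t$occlusal_center - s$occlusal_center),
                numeric(1))
  ids <- vapply(perm, `[[`, "", "tooth_id")
  best <- which(dst <= min(dst) + 1e-9)
  tie <- length(best) > 1L
  pick <- best[order(ids[best])][1]
  list(adjacent_id = ids[pick], distance_mm = dst[pick], tie = tie)
}

#' Classify a supernumerary tooth's position relative to its adjacent tooth
#'
#' The displacement between occlusal-surface centres (supernumerary minus
#' adjacent) is expressed in the adjacent tooth's arch-local axes and each
#' component is read by sign: positive coronal component means coronal,
#' positive mesial component mesial (negative distal), positive lingual
#' component lingual (negative labial). Components smaller in magnitude than
#' `tie_epsilon` are below measurement precision; the call is then made
#' deterministically toward apical/mesial/labial and flagged.
#'
#' @param s supernumerary [tooth_landmarks()].
#' @param adjacent adjacent permanent [tooth_landmarks()].
#' @param axes the adjacent tooth's [local_axes()].
#' @param tie_epsilon mm; default 0.01 (the order of the smallest reported
#'   duplicate-measurement error).
#' @return one-row data.frame: ids, region bin, the three calls, displacement
#'   components (mm) and tie flags.
#' @export
classify_position <- function(s, adjacent, axes, tie_epsilon = 0.01) {
  stopifnot(inherits(s, "tooth_landmarks"), inherits(adjacent, "tooth_landmarks"),
            inherits(axes, "local_axes"))
  if (identical(s$tooth_id, adjacent$tooth_id)) {
    stop("supernumerary and adjacent tooth must differ", call. = FALSE)
  }
  disp <- s$occlusal_center - adjacent$occlusal_center
  comp <- c(coronal = .dot(disp, axes$coronal),
            mesial = .dot(disp, axes$mesial),
            lingual = .dot(disp, axes$lingual))
  tie <- abs(comp) < tie_epsilon
  vertical <- if (tie["coronal"]) "apical" else if (comp["coronal"] > 0) "coronal" else "apical"
  mesiodistal <- if (tie["mesial"]) "mesial" else if (comp["mesial"] > 0) "mesial" else "distal"
  labiolingual <- if (tie["lingual"]) "labial" else if (comp["lingual"] > 0) "lingual" else "labial"
  data.frame(supernumerary_id = s$tooth_id, adjacent_id = adjacent$tooth_id,
             region = assign_region(adjacent$tooth_id),
             vertical = vertical, mesiodistal = mesiodistal,
             labiolingual = labiolingual,
             disp_coronal = unname(comp["coronal"]),
             disp_mesial = unname(comp["mesial"]),
             disp_lingual = unname(comp["lingual"]),
             tie_vertical = unname(tie["coronal"]),
             tie_mesiodistal = unname(tie["mesial"]),
             tie_labiolingual = unname(tie["lingual"]),
             stringsAsFactors = FALSE)
}

#' Region bin of a tooth
#'
#' From its FDI code; a supernumerary label (`"33,"`) inherits the region of
#' its adjacent permanent tooth's code, matching the comma labelling scheme.
#'
#' @param tooth_id FDI code, optionally with trailing comma.
#' @return one of the eight [region_bins()].
#' @export
assign_region <- function(tooth_id) {
  region_bin(fdi_jaw(tooth_id), fdi_region(tooth_id))
}

#' Full pairing + classification of one dentition
#'
#' Resolves any `impacted_unresolved` statuses by root length, builds the
#' reference frame and per-jaw arch curves, assigns each supernumerary its
#' adjacent permanent tooth, and classifies position (in the adjacent tooth's
#' local axes), region, and axial direction (signed inclination of the
#' supernumerary's tooth axis against the occlusal plane).
#'
#' @param d a [dentition()].
#' @param frame optional [build_frame()] result.
#' @param tie_epsilon passed to [classify_position()].
#' @param proximity_radius passed to [resolve_pair_status()].
#' @return data.frame with one row per supernumerary tooth: the positional
#'   calls, displacement components, adjacency distance, inclination and
#'   direction, and flags.
#' @export
classify_dentition <- function(d, frame = NULL, tie_epsilon = 0.01,
                               proximity_radius = 6) {
  stopifnot(inherits(d, "dentition"))
  d <- resolve_pair_status(d, proximity_radius)
  if (is.null(frame)) frame <- frame_from_dentition(d)
  sup <- .teeth_with_status(d, "supernumerary")
  if (!length(sup)) {
    return(data.frame(supernumerary_id = character(), adjacent_id = character(),
                      region = character(), vertical = character(),
                      mesiodistal = character(), labiolingual = character(),
                      disp_coronal = numeric(), disp_mesial = numeric(),
                      disp_lingual = numeric(), tie_vertical = logical(),
                      tie_mesiodistal = logical(), tie_labiolingual = logical(),
                      adjacent_distance_mm = numeric(), adjacent_tie = logical(),
                      inclination_deg = numeric(), direction = character(),
                      near_horizontal = logical(), stringsAsFactors = FALSE))
  }
  arches <- list()
  for (jaw in unique(vapply(sup, `[[`, "", "jaw"))) {
    arches[[jaw]] <- fit_arch_curve(d, jaw, frame)
  }
  rows <- lapply(sup, function(s) {
    adj <- assign_adjacent(s, d)
    adjacent <- .tooth_by_id(d, adj$adjacent_id)
    axes <- local_axes(frame, arches[[s$jaw]], adjacent)
    row <- classify_position(s, adjacent, axes, tie_epsilon)
    inc <- inclination(s, frame)
    row$adjacent_distance_mm <- adj$distance_mm
    row$adjacent_tie <- adj$tie
    row$inclination_deg <- inc$angle_deg
    row$direction <- inc$direction
    row$near_horizontal <- inc$near_horizontal
    row
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
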