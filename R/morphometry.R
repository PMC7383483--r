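#' Per-tooth morphometry
#'
#' The size measures follow the standard cervical-reference-line definitions:
#' crown length runs from the midpoint of the cervical reference line (which
#' joins the labial and lingual CEJ points) to the highest point of the crown
#' (the cusp tip or incisal edge), root length from the same midpoint to the
#' root apex, and the crown diameters are the mesiodistal and buccolingual
#' extreme-to-extreme distances. "Highest point of the crown" is realized as
#' the cusp tip maximizing the distance from the cervical midpoint, which is
#' robust for tilted and inverted teeth and coincides with the intended
#' meaning for upright ones.
#'
#' @param t a [tooth_landmarks()] object.
#' @return `cervical_midpoint()`: numeric length-3 point.
#' @export
cervical_midpoint <- function(t) {
  stopifnot(inherits(t, "tooth_landmarks"))
  if (!.finite_point3(t$cej_labial) || !.finite_point3(t$cej_lingual)) {
    stop("tooth '", t$tooth_id, "': missing or non-finite CEJ landmarks",
         call. = FALSE)
  }
  if (all(t$cej_labial == t$cej_lingual)) {
    warning("tooth '", t$tooth_id, "': coincident CEJ points (degenerate cervical line)",
            call. = FALSE)
  }
  (t$cej_labial + t$cej_lingual) / 2
}

#' @rdname cervical_midpoint
#' @return `crown_length()`: mm, the maximum distance from the cervical
#'   midpoint to a cusp tip.
#' @export
crown_length <- function(t) {
  cm <- cervical_midpoint(t)
  max(vapply(t$cusp_tips, function(p) .vnorm(p - cm), numeric(1)))
}

#' @rdname cervical_midpoint
#' @return `root_length()`: mm, or `NA` when the apex lies outside the
#'   imaging range (`apex_in_volume = FALSE`); such teeth are excluded from
#'   root-length comparisons.
#' @export
root_length <- function(t) {
  if (!isTRUE(t$apex_in_volume)) return(NA_real_)
  .vnorm(t$apex - cervical_midpoint(t))
}

#' @rdname cervical_midpoint
#' @return `crown_diameters()`: named numeric `c(md, bl)` in mm.
#' @export
crown_diameters <- function(t) {
  stopifnot(inherits(t, "tooth_landmarks"))
  md <- .vnorm(t$crown_mesial - t$crown_distal)
  bl <- .vnorm(t$crown_buccal - t$crown_lingual)
  if (md == 0 || bl == 0) {
    warning("tooth '", t$tooth_id, "': coincident crown extremes (zero diameter)",
            call. = FALSE)
  }
  c(md = md, bl = bl)
}

#' Tooth axis and its inclination against the occlusal plane
#'
#' The tooth axis is the straight line connecting the central part of the
#' occlusal surface and the root apex, here as the unit vector from apex to
#' occlusal centre. Its signed inclination against the occlusal plane is
#' measured with respect to the jaw-specific coronal direction, so a positive
#' angle means "pointing toward the occlusal plane" (normal eruption
#' direction) in both jaws, and a negative angle means the inverse direction.
#' Teeth with `|inclination| < 1` degree are flagged near-horizontal: the
#' direction call is reported but is within measurement noise of the plane.
#'
#' @param t a [tooth_landmarks()] object.
#' @param frame a [build_frame()] result.
#' @return `tooth_axis()`: unit length-3 vector. `inclination()`: list with
#'   `angle_deg` in `[-90, 90]`, `direction` (`"normal"`/`"inverse"`), and
#'   `near_horizontal` flag.
#' @export
tooth_axis <- function(t) {
  stopifnot(inherits(t, "tooth_landmarks"))
  v <- t$occlusal_center - t$apex
  if (.vnorm(v) < 1e-9) {
    stop("tooth '", t$tooth_id, "': occlusal centre coincides with apex (zero-length axis)",
         call. = FALSE)
  }
  .unit(v)
}

#' @rdname tooth_axis
#' @export
inclination <- function(t, frame) {
  stopifnot(inherits(frame, "reference_frame"))
  ax <- tooth_axis(t)
  coronal <- if (t$jaw == "mandible") frame$occlusal$normal else -frame$occlusal$normal
  # atan2 formulation: well-conditioned at 0 and 180 degrees, unlike acos
  ang <- atan2(.vnorm(.cross(ax, coronal)), .dot(ax, coronal)) * 180 / pi
  incl <- 90 - ang
  list(angle_deg = incl,
       direction = if (incl > 0) "normal" else "inverse",
       near_horizontal = abs(incl) < 1)
}

#' Cusp counting and crown typing
#'
#' Digitized cusp tips closer than `merge_radius` are merged (single-linkage)
#' into one cusp; an incisal edge digitized as a row of closely spaced tips
#' therefore counts as a single cusp whose width is the largest within-cusp
#' tip span. A tooth with two cusps is bicuspid; with one cusp it is
#' incisal-edge type when the edge width is at least `edge_ratio_threshold`
#' of the mesiodistal diameter and cuspid (pointed cusp) type otherwise.
#' Microdont crowns (mesiodistal diameter below `microdont_floor`) are typed
#' `"obscure"`: too small for the morphology to be read. More than two cusps
#' is recorded as-is with `multi_cusped = TRUE` (typing of supernumerary
#' crowns only distinguishes up to two cusps).
#'
#' @param t a [tooth_landmarks()] object.
#' @param merge_radius mm; tips closer than this are one cusp. Default 0.5.
#' @param edge_ratio_threshold edge width / mesiodistal diameter cut-off
#'   between incisal-edge and cuspid type. Default 0.5.
#' @param microdont_floor mm of mesiodistal diameter below which the crown
#'   type is `"obscure"`. Default 2.
#' @return list with `n_cusps`, `crown_type` (`"incisal_edge"`, `"cuspid"`,
#'   `"bicuspid"`, `"obscure"`, or `NA` when multi-cusped), and
#'   `multi_cusped` flag.
#' @export
cusp_classification <- function(t, merge_radius = 0.5,
                                edge_ratio_threshold = 0.5,
                                microdont_floor = 2) {
  stopifnot(inherits(t, "tooth_landmarks"))
  tips <- do.call(rbind, t$cusp_tips)
  if (is.null(tips) || nrow(tips) == 0L) {
    stop("tooth '", t$tooth_id, "': no cusp tips", call. = FALSE)
  }
  if (nrow(tips) == 1L) {
    cl <- rep(1L, 1L)
  } else {
    hc <- stats::hclust(stats::dist(tips), method = "single")
    cl <- stats::cutree(hc, h = merge_radius)
  }
  n_cusps <- length(unique(cl))
  md <- unname(crown_diameters(t)["md"])
  multi <- n_cusps > 2L
  crown_type <- if (md < microdont_floor) {
    "obscure"
  } else if (multi) {
    NA_character_
  } else if (n_cusps == 2L) {
    "bicuspid"
  } else {
    members <- tips[cl == cl[1], , drop = FALSE]
    edge_width <- if (nrow(members) > 1L) max(stats::dist(members)) else 0
    if (edge_width / md >= edge_ratio_threshold) "incisal_edge" else "cuspid"
  }
  list(n_cusps = n_cusps, crown_type = crown_type, multi_cusped = multi)
}

#' Root count
#'
#' One root per apex landmark (the main apex plus any accessory apices).
#' When the root is shorter than `root_floor` (or not measurable) it is too
#' short and small for branches to be distinguished and the count is
#' indeterminate (`NA`).
#'
#' @param t a [tooth_landmarks()] object.
#' @param root_floor mm; default 1.
#' @return list with integer `n_roots` (`NA` when indeterminate) and
#'   `indeterminate` flag.
#' @export
root_count <- function(t, root_floor = 1) {
  rl <- root_length(t)
  if (is.na(rl) || rl < root_floor) {
    return(list(n_roots = NA_integer_, indeterminate = TRUE))
  }
  list(n_roots = 1L + length(t$accessory_apices), indeterminate = FALSE)
}

#' Full morphometric record for every tooth of a dentition
#'
#' @param d a [dentition()].
#' @param frame a [build_frame()] result (default: from the dentition).
#' @param ... threshold arguments passed to [cusp_classification()] and
#'   [root_count()].
#' @return data.frame with one row per tooth: id, jaw, region, status, the
#'   four size measures, signed inclination and direction, cusp count and
#'   crown type, root count and flags.
#' @export
measurement_table <- function(d, frame = frame_from_dentition(d), ...) {
  stopifnot(inherits(d, "dentition"))
  rows <- lapply(d$teeth, function(t) {
    dia <- crown_diameters(t)
    inc <- inclination(t, frame)
    cu <- cusp_classification(t, ...)
    rc <- root_count(t)
    data.frame(tooth_id = t$tooth_id, jaw = t$jaw,
               region = ifelse(is.na(t$region), NA_character_, t$region),
               status = t$status,
               crown_length = crown_length(t), root_length = root_length(t),
               md_diameter = unname(dia["md"]), bl_diameter = unname(dia["bl"]),
               inclination_deg = inc$angle_deg, direction = inc$direction,
               near_horizontal = inc$near_horizontal,
               n_cusps = cu$n_cusps, crown_type = cu$crown_type,
               multi_cusped = cu$multi_cusped,
               n_roots = rc$n_roots, roots_indeterminate = rc$indeterminate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) out <- data.frame()
  out
}
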