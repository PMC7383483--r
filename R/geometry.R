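#' Planes and the occlusal/sagittal/frontal reference frame
#'
#' A plane is stored as a unit normal and a scalar offset; a point `x` lies on
#' the plane iff `dot(normal, x) == offset`. The reference frame follows the
#' standard cephalometric construction for the dentition: the *occlusal*
#' plane passes through the central fossae of the right and left first molars
#' and the incisal midline point; the *sagittal* plane is perpendicular to it
#' through the fossa midpoint and the incisal midline point; the *frontal*
#' plane is perpendicular to the sagittal plane through the central incisal
#' edge midpoint. Orientation conventions (fixed because every downstream
#' binary call depends on them): occlusal normal cranial, sagittal normal
#' toward the patient's left, frontal normal anterior. The orientation rule
#' is intrinsic to the four input points, so the construction is equivariant
#' under rigid motions.
#'
#' @param normal numeric length-3 normal vector (normalized internally).
#' @param offset signed distance from the origin to the plane, mm.
#' @return `plane()` returns an object of class `plane`.
#' @export
plane <- function(normal, offset) {
  n <- .unit(as.numeric(normal), "plane normal")
  structure(list(normal = n, offset = as.numeric(offset)), class = "plane")
}

#' @export
print.plane <- function(x, ...) {
  cat(sprintf("<plane n=(%.4f, %.4f, %.4f) offset=%.4f mm>\n",
              x$normal[1], x$normal[2], x$normal[3], x$offset))
  invisible(x)
}

#' Signed distance from a plane to a point
#'
#' `dot(normal, x) - offset`: zero iff `x` is on the plane, positive on the
#' side the normal points to.
#'
#' @param p a [plane()].
#' @param x numeric length-3 point, or an n-by-3 matrix of points.
#' @return numeric scalar or vector of signed distances in mm.
#' @export
signed_distance <- function(p, x) {
  stopifnot(inherits(p, "plane"))
  if (is.matrix(x)) {
    as.numeric(x %*% p$normal) - p$offset
  } else {
    .dot(p$normal, x) - p$offset
  }
}

#' Build the occlusal/sagittal/frontal reference frame
#'
#' @param fossa_R,fossa_L central fossa of the occlusal surface of the right
#'   and left first molars (numeric length-3, mm).
#' @param incisal_mid incisal midline point of the central incisors.
#' @param incisal_edge_mid central incisal edge midpoint; defaults to
#'   `incisal_mid` when not separately digitized.
#' @return an object of class `reference_frame` with elements `occlusal`,
#'   `sagittal`, `frontal` (planes) and `points` (the inputs, for audit).
#' @export
build_frame <- function(fossa_R, fossa_L, incisal_mid,
                        incisal_edge_mid = incisal_mid) {
  pts <- list(fossa_R = fossa_R, fossa_L = fossa_L, incisal_mid = incisal_mid,
              incisal_edge_mid = incisal_edge_mid)
  for (nm in names(pts)) {
    if (!.finite_point3(pts[[nm]])) {
      stop("frame point '", nm, "' must be a finite length-3 point", call. = FALSE)
    }
  }
  scale <- max(.vnorm(fossa_L - fossa_R), .vnorm(incisal_mid - fossa_R))
  if (scale < 1e-9) stop("frame points are coincident", call. = FALSE)
  fossa_mid <- (fossa_R + fossa_L) / 2
  n_raw <- .cross(fossa_L - fossa_R, incisal_mid - fossa_mid)
  if (.vnorm(n_raw) < 1e-9 * scale^2) {
    stop("occlusal-plane points are collinear", call. = FALSE)
  }
  # With fossa_R on the patient's right (-x) and the incisal point anterior,
  # this cross-product order orients the occlusal normal cranially.
  occ_n <- .unit(n_raw)
  occ <- plane(occ_n, .dot(occ_n, fossa_R))
  ap <- incisal_mid - fossa_mid       # antero-posterior, lies in the plane
  sag_n <- .unit(.cross(ap, occ_n))   # toward patient left
  sag <- plane(sag_n, .dot(sag_n, fossa_mid))
  fro_n <- .unit(.cross(occ_n, sag_n)) # anterior
  fro <- plane(fro_n, .dot(fro_n, incisal_edge_mid))
  structure(list(occlusal = occ, sagittal = sag, frontal = fro, points = pts),
            class = "reference_frame")
}

#' @export
print.reference_frame <- function(x, ...) {
  cat("<reference_frame>\n  occlusal "); print(x$occlusal)
  cat("  sagittal "); print(x$sagittal)
  cat("  frontal  "); print(x$frontal)
  invisible(x)
}

#' Export a reference frame as JSON for audit
#'
#' @param frame a [build_frame()] result.
#' @param path output path.
#' @export
write_frame <- function(frame, path) {
  stopifnot(inherits(frame, "reference_frame"))
  x <- list(
    occlusal = list(normal = frame$occlusal$normal, offset = frame$occlusal$offset),
    sagittal = list(normal = frame$sagittal$normal, offset = frame$sagittal$offset),
    frontal = list(normal = frame$frontal$normal, offset = frame$frontal$offset),
    points = frame$points)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Build the reference frame from a dentition's own landmarks
#'
#' Uses the occlusal centres of the first molars and the midpoint of the
#' central incisors' occlusal centres of one jaw (mandible preferred, falling
#' back to maxilla when the mandibular teeth are absent).
#'
#' @param d a [dentition()].
#' @return a `reference_frame`.
#' @export
frame_from_dentition <- function(d) {
  stopifnot(inherits(d, "dentition"))
  ids <- vapply(d$teeth, `[[`, "", "tooth_id")
  pick <- function(want) {
    i <- match(want, ids)
    if (any(is.na(i))) NULL else lapply(d$teeth[i], `[[`, "occlusal_center")
  }
  # (right first molar, left first molar, right central incisor, left central)
  sets <- list(mandible = c("46", "36", "41", "31"),
               maxilla = c("16", "26", "11", "21"))
  for (jaw in names(sets)) {
    oc <- pick(sets[[jaw]])
    if (!is.null(oc)) {
      return(build_frame(fossa_R = oc[[1]], fossa_L = oc[[2]],
                         incisal_mid = (oc[[3]] + oc[[4]]) / 2))
    }
  }
  stop("dentition '", d$case_id,
       "' lacks the first molars and central incisors needed for the frame",
       call. = FALSE)
}

#' Fit the dental arch curve of one jaw
#'
#' Least-squares parabola through the occlusal centres of the jaw's permanent
#' teeth, in occlusal-plane coordinates `u` (signed distance to the sagittal
#' plane) and `v` (signed distance to the frontal plane):
#' `v = c0 + c1 u + c2 u^2`. The curve realizes the per-tooth mesiodistal and
#' labiolingual directions: its tangent gives the mesiodistal axis, its
#' in-plane normal the labiolingual axis.
#'
#' @param d a [dentition()].
#' @param jaw `"maxilla"` or `"mandible"`.
#' @param frame a [build_frame()] result (default: from the dentition).
#' @return object of class `arch_curve` with the coefficients, the frame,
#'   and the arch-interior point used to orient lingual axes.
#' @export
fit_arch_curve <- function(d, jaw, frame = frame_from_dentition(d)) {
  jaw <- match.arg(jaw, .jaws)
  perm <- .teeth_with_status(d, c("erupted_permanent", "unerupted_permanent"))
  perm <- perm[vapply(perm, function(t) t$jaw == jaw, logical(1))]
  if (length(perm) < 4L) {
    stop("arch fit for ", jaw, " needs >= 4 permanent teeth, have ",
         length(perm), call. = FALSE)
  }
  oc <- do.call(rbind, lapply(perm, `[[`, "occlusal_center"))
  u <- signed_distance(frame$sagittal, oc)
  v <- signed_distance(frame$frontal, oc)
  fit <- stats::lm.fit(cbind(1, u, u^2), v)
  structure(list(coef = unname(fit$coefficients), frame = frame, jaw = jaw,
                 interior = c(mean(u), mean(v)),
                 u_range = range(u), residuals = unname(fit$residuals)),
            class = "arch_curve")
}

.arch_v <- function(arch, u) {
  arch$coef[1] + arch$coef[2] * u + arch$coef[3] * u^2
}

.arch_slope <- function(arch, u) {
  arch$coef[2] + 2 * arch$coef[3] * u
}

# Nearest parameter on the arch parabola to the in-plane point (u0, v0).
# Stationarity of the squared distance is a cubic in u; real roots are
# compared and ties broken deterministically toward the smaller parameter.
.arch_project <- function(arch, u0, v0) {
  c0 <- arch$coef[1]; c1 <- arch$coef[2]; c2 <- arch$coef[3]
  # d/du [ (u-u0)^2 + (q(u)-v0)^2 ] / 2 = (u-u0) + (q(u)-v0) q'(u)
  k <- c0 - v0
  # stationarity: 2 c2^2 u^3 + 3 c1 c2 u^2 + (1 + c1^2 + 2 c2 k) u + (k c1 - u0) = 0
  roots <- polyroot(c(k * c1 - u0, 1 + c1^2 + 2 * c2 * k, 3 * c1 * c2, 2 * c2^2))
  re <- Re(roots[abs(Im(roots)) < 1e-7 * (1 + abs(Re(roots)))])
  if (!length(re)) re <- Re(roots)   # numerically safest fallback
  d2 <- (re - u0)^2 + (.arch_v(arch, re) - v0)^2
  best <- which(d2 < min(d2) + 1e-12)
  tie <- length(best) > 1L
  u_star <- min(re[best])
  list(u = u_star, v = .arch_v(arch, u_star), tie = tie)
}

#' Arch-local anatomical axes of one tooth
#'
#' Returns the orthonormal triad used for positional and directional calls:
#' `mesial` (arch tangent, oriented toward the midline / sagittal plane),
#' `lingual` (in-occlusal-plane arch normal, oriented toward the arch
#' interior) and `coronal` (occlusal-plane normal, flipped per jaw so it
#' points *toward* the occlusal plane: cranial for mandibular teeth, caudal
#' for maxillary teeth). The triad is orthonormal to machine precision; its
#' handedness necessarily differs between the left and right sides of the
#' arch (mirror anatomy).
#'
#' @param frame a [build_frame()] result.
#' @param arch a [fit_arch_curve()] result for the tooth's jaw.
#' @param tooth a [tooth_landmarks()] object.
#' @return object of class `local_axes`: list with unit vectors `coronal`,
#'   `mesial`, `lingual`, the arch parameter `u`, and `ambiguous_projection`
#'   flag (equidistant curve points; deterministic smaller-parameter choice).
#' @export
local_axes <- function(frame, arch, tooth) {
  stopifnot(inherits(frame, "reference_frame"), inherits(arch, "arch_curve"),
            inherits(tooth, "tooth_landmarks"))
  oc <- tooth$occlusal_center
  u0 <- signed_distance(frame$sagittal, oc)
  v0 <- signed_distance(frame$frontal, oc)
  pr <- .arch_project(arch, u0, v0)
  e_u <- frame$sagittal$normal
  e_v <- frame$frontal$normal
  slope <- .arch_slope(arch, pr$u)
  tangent2 <- c(1, slope) / sqrt(1 + slope^2)
  normal2 <- c(-slope, 1) / sqrt(1 + slope^2)
  # mesial: along the tangent, toward the midline (decreasing |u|)
  msign <- if (abs(pr$u) > 1e-9) -sign(pr$u) else if (abs(u0) > 1e-9) -sign(u0) else 1
  mesial <- msign * (tangent2[1] * e_u + tangent2[2] * e_v)
  # lingual: in-plane normal toward the arch interior
  to_int <- arch$interior - c(pr$u, pr$v)
  lsign <- if (abs(.dot(normal2, to_int)) > 1e-12) sign(.dot(normal2, to_int)) else 1
  lingual <- lsign * (normal2[1] * e_u + normal2[2] * e_v)
  coronal <- if (tooth$jaw == "mandible") frame$occlusal$normal else -frame$occlusal$normal
  structure(list(coronal = coronal, mesial = mesial, lingual = lingual,
                 u = pr$u, ambiguous_projection = pr$tie),
            class = "local_axes")
}

#' Apply a rigid motion to a dentition
#'
#' Rotates and translates every landmark: `x -> R x + t`. Used to verify that
#' all measurements and classification calls are invariant under rigid
#' motion of the whole dentition.
#'
#' @param d a [dentition()].
#' @param rotation 3x3 rotation matrix.
#' @param translation numeric length-3 vector, mm.
#' @return the transformed [dentition()].
#' @export
transform_dentition <- function(d, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(d, "dentition"), all(dim(rotation) == c(3, 3)))
  tf <- function(p) as.numeric(rotation %*% p + translation)
  teeth <- lapply(d$teeth, function(t) {
    for (nm in .landmark_names) t[[nm]] <- tf(t[[nm]])
    t$cusp_tips <- lapply(t$cusp_tips, tf)
    t$accessory_apices <- lapply(t$accessory_apices, tf)
    t
  })
  corners <- as.matrix(expand.grid(x = c(d$volume_bounds$min[1], d$volume_bounds$max[1]),
                                   y = c(d$volume_bounds$min[2], d$volume_bounds$max[2]),
                                   z = c(d$volume_bounds$min[3], d$volume_bounds$max[3])))
  tc <- t(apply(corners, 1, tf))
  dentition(case_id = d$case_id, teeth = teeth,
            volume_bounds = list(min = apply(tc, 2, min), max = apply(tc, 2, max)),
            metadata = d$metadata)
}
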