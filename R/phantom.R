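#' CBCT-like voxel volumes
#'
#' A `voxel_volume` is a 3D intensity array with per-axis voxel spacing (mm)
#' and a world origin: the world position of the low corner of the array, so
#' voxel `(i, j, k)` is centred at `origin + (c(i, j, k) - 0.5) * spacing`.
#' A `label_volume` is an aligned integer array (0 = background, labels
#' contiguous from 1, largest component first).
#'
#' @param intensity numeric 3D array.
#' @param spacing numeric length-3 voxel spacing in mm (all > 0).
#' @param origin numeric length-3 world position of the array's low corner.
#' @return an object of class `voxel_volume`.
#' @export
voxel_volume <- function(intensity, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(intensity), length(dim(intensity)) == 3L,
            all(dim(intensity) >= 1L))
  spacing <- rep_len(as.numeric(spacing), 3L)
  stopifnot(all(spacing > 0))
  structure(list(intensity = intensity, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("<voxel_volume %s; spacing %s mm; origin (%s)>\n",
              paste(dim(x$intensity), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = ", "),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' Render a CBCT-like phantom of a dentition
#'
#' Each tooth is rasterized as the union of two capsules sharing the
#' cervical midpoint: a crown capsule from the occlusal centre to the
#' cervical midpoint and a root capsule from the cervical midpoint to the
#' apex. The crown capsule radius is half the mean crown semidiameter,
#' `(md + bl) / 8` (full semidiameters of neighbouring teeth touch, as real
#' crowns do, which would merge their components under threshold
#' segmentation); the root radius is half the crown radius. An alveolar bone
#' slab of lower intensity surrounds the root region of each jaw, and
#' optional additive Gaussian noise models detector noise. Teeth are
#' rasterized brighter than bone, which is brighter than background,
#' mirroring the difference in X-ray permeability that threshold
#' segmentation exploits.
#'
#' @param d a [dentition()]; teeth must fit inside `bounds`.
#' @param spacing_mm voxel spacing, scalar or length-3, each in (0.05, 1).
#' @param intensities named numeric: `background`, `bone`, `tooth`
#'   (strictly increasing).
#' @param noise_sd SD of additive Gaussian noise; 0 = noise-free.
#' @param bounds imaging range (list with `min`, `max`); default the
#'   dentition's `volume_bounds`.
#' @param bone whether to draw the bone slabs.
#' @return a [voxel_volume()].
#' @export
render_phantom <- function(d, spacing_mm = 0.5,
                           intensities = c(background = 0, bone = 400, tooth = 1200),
                           noise_sd = 0, bounds = d$volume_bounds, bone = TRUE) {
  stopifnot(inherits(d, "dentition"))
  spacing <- rep_len(as.numeric(spacing_mm), 3L)
  if (any(spacing <= 0.05) || any(spacing >= 1)) {
    stop("spacing must lie in (0.05, 1) mm per axis", call. = FALSE)
  }
  if (!(intensities["tooth"] > intensities["bone"] &&
        intensities["bone"] > intensities["background"])) {
    stop("need tooth > bone > background intensities", call. = FALSE)
  }
  lo <- as.numeric(bounds$min); hi <- as.numeric(bounds$max)
  if (length(d$teeth)) {
    all_pts <- do.call(rbind, lapply(d$teeth, tooth_points))
    if (any(apply(all_pts, 2, min) < lo) || any(apply(all_pts, 2, max) > hi)) {
      stop("dentition extends outside the requested volume bounds", call. = FALSE)
    }
  }
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)))
  vol <- array(intensities[["background"]], dim = dims)
  ax <- lapply(1:3, function(i) lo[i] + (seq_len(dims[i]) - 0.5) * spacing[i])

  if (bone && length(d$teeth)) {
    # bone slabs span each jaw's root region (beyond 4 mm from the occlusal
    # surface) over the xy extent of that jaw's teeth
    for (jaw in .jaws) {
      teeth <- d$teeth[vapply(d$teeth, function(t) t$jaw == jaw, logical(1))]
      if (!length(teeth)) next
      pts <- do.call(rbind, lapply(teeth, tooth_points))
      oc_z <- mean(vapply(teeth, function(t) t$occlusal_center[3], numeric(1)))
      zr <- if (jaw == "mandible") c(min(pts[, 3]) - 1, oc_z - 4) else c(oc_z + 4, max(pts[, 3]) + 1)
      ii <- which(ax[[1]] >= min(pts[, 1]) - 2 & ax[[1]] <= max(pts[, 1]) + 2)
      jj <- which(ax[[2]] >= min(pts[, 2]) - 2 & ax[[2]] <= max(pts[, 2]) + 2)
      kk <- which(ax[[3]] >= zr[1] & ax[[3]] <= zr[2])
      if (length(ii) && length(jj) && length(kk)) {
        vol[ii, jj, kk] <- intensities[["bone"]]
      }
    }
  }

  for (t in d$teeth) {
    cm <- cervical_midpoint(t)
    dia <- crown_diameters(t)
    r_crown <- (dia[["md"]] + dia[["bl"]]) / 8
    r_root <- r_crown / 2
    segs <- list(list(a = t$occlusal_center, b = cm, r = r_crown),
                 list(a = cm, b = t$apex, r = r_root))
    for (s in segs) {
      rpad <- s$r + max(spacing)
      blo <- pmin(s$a, s$b) - rpad; bhi <- pmax(s$a, s$b) + rpad
      ii <- which(ax[[1]] >= blo[1] & ax[[1]] <= bhi[1])
      jj <- which(ax[[2]] >= blo[2] & ax[[2]] <= bhi[2])
      kk <- which(ax[[3]] >= blo[3] & ax[[3]] <= bhi[3])
      if (!length(ii) || !length(jj) || !length(kk)) next
      g <- expand.grid(x = ax[[1]][ii], y = ax[[2]][jj], z = ax[[3]][kk])
      ab <- s$b - s$a
      len2 <- sum(ab^2)
      px <- g$x - s$a[1]; py <- g$y - s$a[2]; pz <- g$z - s$a[3]
      tt <- if (len2 > 0) .clamp((px * ab[1] + py * ab[2] + pz * ab[3]) / len2, 0, 1) else 0
      d2 <- (px - tt * ab[1])^2 + (py - tt * ab[2])^2 + (pz - tt * ab[3])^2
      inside <- d2 <= s$r^2
      if (any(inside)) {
        idx <- as.matrix(expand.grid(i = ii, j = jj, k = kk))[inside, , drop = FALSE]
        vol[idx] <- intensities[["tooth"]]
      }
    }
  }
  if (noise_sd > 0) {
    vol <- vol + array(stats::rnorm(length(vol), 0, noise_sd), dim = dims)
  }
  voxel_volume(vol, spacing, lo)
}

# 26-connected component labelling by breadth-first flood fill over the
# foreground mask. Returns an integer array; components numbered in
# discovery order (relabelled by size by the caller).
.label_components26 <- function(mask) {
  dims <- dim(mask)
  labels <- array(0L, dim = dims)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  fg <- which(mask)
  if (!length(fg)) return(labels)
  nlab <- 0L
  for (seed in fg) {
    if (labels[seed] != 0L) next
    nlab <- nlab + 1L
    labels[seed] <- nlab
    frontier <- matrix(arrayInd(seed, dims), ncol = 3)
    while (nrow(frontier)) {
      nb <- frontier[rep(seq_len(nrow(frontier)), each = nrow(offs)), , drop = FALSE] +
        offs[rep(seq_len(nrow(offs)), times = nrow(frontier)), , drop = FALSE]
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
            nb[, 2] >= 1 & nb[, 2] <= dims[2] &
            nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      if (!nrow(nb)) break
      lin <- nb[, 1] + dims[1] * (nb[, 2] - 1L) + dims[1] * dims[2] * (nb[, 3] - 1L)
      keep <- mask[lin] & labels[lin] == 0L
      lin <- unique(lin[keep])
      if (!length(lin)) break
      labels[lin] <- nlab
      frontier <- arrayInd(lin, dims)
    }
  }
  labels
}

#' Threshold segmentation of a voxel volume
#'
#' Voxels at or above `threshold` are foreground; 26-connected components
#' are labelled, components smaller than `min_voxels` are despeckled, and the
#' remaining labels are renumbered contiguously from 1 in decreasing size
#' order. Teeth whose capsules touch or overlap are, by the definition of
#' connectivity, returned as a single merged component.
#'
#' @param v a [voxel_volume()].
#' @param threshold intensity threshold; must lie within the volume's
#'   intensity range (between bone and tooth intensity to pick out teeth).
#' @param min_voxels minimum component size kept; default 10.
#' @return object of class `label_volume`: integer `labels` array plus
#'   `spacing`, `origin` and `n_labels`.
#' @export
threshold_segment <- function(v, threshold, min_voxels = 10) {
  stopifnot(inherits(v, "voxel_volume"))
  rng <- range(v$intensity)
  if (threshold < rng[1] || threshold > rng[2] + 1e-9) {
    if (threshold > rng[2]) {
      # everything background: legal degenerate call
      labels <- array(0L, dim = dim(v$intensity))
      return(structure(list(labels = labels, spacing = v$spacing,
                            origin = v$origin, n_labels = 0L),
                       class = "label_volume"))
    }
    stop("threshold outside intensity range [", rng[1], ", ", rng[2], "]",
         call. = FALSE)
  }
  labels <- .label_components26(v$intensity >= threshold)
  if (max(labels) > 0L) {
    sizes <- tabulate(labels[labels > 0L])
    keep <- which(sizes >= min_voxels)
    remap <- integer(length(sizes))
    remap[keep[order(sizes[keep], decreasing = TRUE)]] <- seq_along(keep)
    labels[labels > 0L] <- remap[labels[labels > 0L]]
  }
  structure(list(labels = labels, spacing = v$spacing, origin = v$origin,
                 n_labels = max(labels)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume %s; %d labels>\n",
              paste(dim(x$labels), collapse = "x"), x$n_labels))
  invisible(x)
}

#' Approximate tooth landmarks from a segmented component
#'
#' Bridges segmentation to landmark-based morphometry: the component's
#' principal axis (from the voxel-coordinate SVD) is oriented so its
#' occlusal end faces the opposing jaw; the occlusal centre and apex are the
#' extreme voxels along it. The crown/root junction is estimated from the
#' radial profile along the axis (where the cross-section falls below 70% of
#' the crown's maximum radius), and the CEJ points are the cross-section
#' extremes of that junction slab along the second principal axis. The crown
#' extremes are the crown-half extreme voxels along the two transverse
#' principal axes. `apex_in_volume` is set `FALSE` when the apex voxel
#' touches a volume face. Deliberately coarse: the phantom path demonstrates
#' robustness; precise analysis runs on digitized landmarks.
#'
#' @param lbl a [threshold_segment()] result.
#' @param label_id which component.
#' @param jaw `"maxilla"` or `"mandible"`: which jaw the tooth belongs to
#'   (sets the occlusal orientation).
#' @return a [tooth_landmarks()] object (tooth_id `"seg<label_id>"`, status
#'   `"impacted_unresolved"`, region unknown).
#' @export
estimate_landmarks <- function(lbl, label_id, jaw) {
  stopifnot(inherits(lbl, "label_volume"))
  jaw <- match.arg(jaw, .jaws)
  sel <- which(lbl$labels == label_id)
  if (!length(sel)) stop("label ", label_id, " not present", call. = FALSE)
  if (length(sel) < 10L) {
    stop("label ", label_id, " has fewer than 10 voxels: too small to orient",
         call. = FALSE)
  }
  ijk <- arrayInd(sel, dim(lbl$labels))
  xyz <- sweep(sweep(ijk - 0.5, 2, lbl$spacing, `*`), 2, lbl$origin, `+`)
  ctr <- colMeans(xyz)
  cxyz <- sweep(xyz, 2, ctr)
  sv <- svd(cxyz, nu = 0, nv = 3)
  if (sv$d[1] < 1.2 * sv$d[2]) {
    stop("label ", label_id,
         " has no dominant elongation axis: orientation ambiguous", call. = FALSE)
  }
  axis <- sv$v[, 1]
  occl_dir <- if (jaw == "mandible") c(0, 0, 1) else c(0, 0, -1)
  if (.dot(axis, occl_dir) < 0) axis <- -axis
  proj <- as.numeric(cxyz %*% axis)
  i_occ <- which.max(proj); i_apex <- which.min(proj)

  # radial profile along the axis in ~0.5 mm slabs
  radial <- sqrt(rowSums((cxyz - outer(proj, axis))^2))
  brk <- seq(min(proj) - 1e-9, max(proj) + 1e-9,
             length.out = max(5L, ceiling(diff(range(proj)) / 0.5)))
  slab <- cut(proj, brk, labels = FALSE)
  agg <- tapply(radial, slab, max)
  slab_max_r <- rep(NA_real_, length(brk) - 1L)
  slab_max_r[as.integer(names(agg))] <- agg
  slab_mid <- (brk[-1] + brk[-length(brk)]) / 2
  ord <- order(slab_mid, decreasing = TRUE)   # occlusal end first
  top <- slab_max_r[ord][seq_len(max(1L, ceiling(length(ord) * 0.4)))]
  crown_max_r <- max(top, na.rm = TRUE)
  bottom <- slab_max_r[rev(ord)][seq_len(max(1L, ceiling(length(ord) * 0.2)))]
  apex_r <- max(bottom, na.rm = TRUE)
  prof <- slab_max_r[ord]
  start <- which(!is.na(prof) & prof >= 0.95 * crown_max_r)[1]   # past the rounded tip
  if (is.na(start)) start <- 1L
  below <- which(!is.na(prof) & prof < 0.7 * crown_max_r & seq_along(prof) > start)
  junction_raw <- if (length(below)) slab_mid[ord[below[1]]] else stats::median(proj)
  # a rounded crown end falls below 70% of its own radius only ~0.71 radii
  # past the true cervix; likewise the rounded ends extend one local radius
  # past the true occlusal centre and apex — correct all three from the
  # measured profile
  junction_proj <- junction_raw + 0.71 * crown_max_r
  occ_proj <- max(proj) - crown_max_r
  apex_proj <- min(proj) + apex_r
  occlusal_center <- ctr + occ_proj * axis
  apex <- ctr + apex_proj * axis
  cerv_pt <- ctr + junction_proj * axis

  v2 <- sv$v[, 2]; v3 <- sv$v[, 3]
  near_junction <- abs(proj - junction_proj) <= 1
  if (!any(near_junction)) near_junction <- rank(abs(proj - junction_proj)) <= 10
  jslab <- xyz[near_junction, , drop = FALSE]
  jproj2 <- as.numeric(sweep(jslab, 2, cerv_pt) %*% v2)
  cej_labial <- jslab[which.max(jproj2), ]
  cej_lingual <- jslab[which.min(jproj2), ]

  crown_half <- proj >= junction_proj
  if (sum(crown_half) < 4L) crown_half <- proj >= stats::median(proj)
  cr <- xyz[crown_half, , drop = FALSE]
  cr2 <- as.numeric(sweep(cr, 2, ctr) %*% v2)
  cr3 <- as.numeric(sweep(cr, 2, ctr) %*% v3)
  crown_buccal <- cr[which.max(cr2), ]
  crown_lingual <- cr[which.min(cr2), ]
  crown_mesial <- cr[which.max(cr3), ]
  crown_distal <- cr[which.min(cr3), ]

  apex_ijk <- ijk[i_apex, ]
  on_face <- any(apex_ijk == 1L) || any(apex_ijk == dim(lbl$labels))
  tooth_landmarks(
    tooth_id = paste0("seg", label_id), jaw = jaw, region = NA_character_,
    status = "impacted_unresolved",
    occlusal_center = occlusal_center, apex = apex,
    cej_labial = cej_labial, cej_lingual = cej_lingual,
    cusp_tips = list(occlusal_center),
    crown_mesial = crown_mesial, crown_distal = crown_distal,
    crown_buccal = crown_buccal, crown_lingual = crown_lingual,
    apex_in_volume = !on_face)
}

#' Read and write voxel volumes as NIfTI
#'
#' Spacing is carried in the NIfTI pixdim and the world origin in the
#' sform/qform translation.
#'
#' @param v a [voxel_volume()].
#' @param path `.nii` or `.nii.gz` path.
#' @return `read_volume()` returns a [voxel_volume()].
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "voxel_volume"))
  img <- RNifti::asNifti(v$intensity)
  RNifti::pixdim(img) <- v$spacing
  xform <- diag(c(v$spacing, 1))
  xform[1:3, 4] <- v$origin + v$spacing / 2   # world centre of voxel (1,1,1)
  RNifti::qform(img) <- structure(xform, code = 2L)
  RNifti::sform(img) <- structure(xform, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  spacing <- sqrt(colSums(xf[1:3, 1:3]^2))
  origin <- xf[1:3, 4] - spacing / 2
  voxel_volume(array(as.numeric(img), dim = dim(img)), spacing, origin)
}
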