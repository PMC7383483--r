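#' Tooth archetype dimensions used by the synthetic generator
#'
#' Typical adult crown/root lengths and crown diameters (mm) by tooth
#' position 1-7 (central incisor through second molar), and the cusp layout
#' used to plant cusp-tip landmarks: incisors carry an incisal edge (a row of
#' closely spaced tips), canines a single pointed cusp, premolars two cusps
#' (buccal + lingual), molars four.
#'
#' @return data.frame with columns `position`, `crown`, `root`, `md`, `bl`,
#'   `cusp_kind`.
#' @keywords internal
.tooth_archetypes <- function() {
  data.frame(
    position = 1:7,
    crown = c(10.5, 9.0, 10.0, 8.0, 7.5, 7.5, 7.0),
    root  = c(12.5, 13.0, 16.5, 13.5, 14.0, 13.0, 12.0),
    md    = c(8.5, 6.5, 7.5, 7.0, 6.8, 9.5, 9.0),
    bl    = c(7.0, 6.0, 8.0, 8.5, 8.5, 10.0, 10.0),
    cusp_kind = c("edge", "edge", "cusp", "bicusp", "bicusp", "molar", "molar"),
    stringsAsFactors = FALSE)
}

#' Default generator configuration
#'
#' The defaults encode the cohort structure this generator emulates: five-case
#' cohorts with 1-15 impacted supernumerary teeth per case, each paired with
#' one adjacent permanent tooth. Region probabilities follow the reported
#' per-region frequencies (mandibular premolar 14/39, mandibular canine 7/39,
#' maxillary canine 6/39, maxillary premolar 6/39, maxillary molar 3/39, no
#' mandibular molar supernumeraries; the remaining 3/39 are split 2/39
#' maxillary and 1/39 mandibular anterior). The placement probabilities are
#' the overall positional tendencies: coronal 26/39, distal 25/39, lingual
#' 35/39, inverse axial direction 5/39. Supernumerary linear size ratio
#' ~ Normal(0.7, 0.1) truncated to (0.3, 0.95) (supernumeraries are uniformly
#' smaller than their adjacent teeth; molar-region ones are microdont, ratio
#' further scaled by 0.4 with a single cusp tip). Per-axis displacement
#' magnitudes ~ |Normal(2, 0.5)| mm truncated to [0.5, 3.2] mm, which keeps
#' every pair closer than half the 8 mm inter-tooth spacing so pairing is
#' unambiguous yet non-degenerate.
#'
#' @return a `generator_config` list; see fields in the source. `seed`
#'   controls all randomness: identical configs give bit-identical output.
#' @export
default_config <- function() {
  rp <- c(2, 6, 6, 3, 1, 7, 14, 0) / 39
  names(rp) <- c("maxillary anterior", "maxillary canine", "maxillary premolar",
                 "maxillary molar", "mandibular anterior", "mandibular canine",
                 "mandibular premolar", "mandibular molar")
  structure(list(
    n_supernumerary = c(1L, 15L),     # scalar or [min,max] range per case
    n_unerupted = c(10L, 21L),        # unerupted permanent teeth per case
    region_probs = rp,
    p_coronal = 26 / 39,
    p_distal = 25 / 39,
    p_lingual = 35 / 39,
    p_inverse = 5 / 39,
    size_ratio_mean = 0.7,
    size_ratio_sd = 0.1,
    size_ratio_range = c(0.3, 0.95),
    microdont_factor = 0.4,           # extra shrink for molar-region supernumeraries
    offset_magnitude_mm = 2,
    offset_sd_mm = 0.5,
    offset_range_mm = c(0.5, 3.2),
    size_jitter_sd = 0.04,            # lognormal per-tooth size jitter
    arch = list(spacing = 8,          # arc-length tooth spacing, mm
                depth_mandible = 45, depth_maxilla = 47,
                a_mandible = 0.050, a_maxilla = 0.045,
                interocclusal_gap = 8),  # jaws scanned in open relation, mm
    seed = 1L), class = "generator_config")
}

.validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config") || is.list(cfg))
  pr <- cfg$region_probs
  if (any(pr < 0) || abs(sum(pr) - 1) > 1e-9) {
    stop("region_probs must be non-negative and sum to 1", call. = FALSE)
  }
  for (p in c(cfg$p_coronal, cfg$p_distal, cfg$p_lingual, cfg$p_inverse)) {
    if (p < 0 || p > 1) stop("placement probabilities must lie in [0,1]", call. = FALSE)
  }
  if (cfg$size_ratio_mean <= 0 || cfg$size_ratio_mean > 1) {
    stop("size_ratio_mean must lie in (0, 1]", call. = FALSE)
  }
  invisible(cfg)
}

# Arc-length placement on the arch parabola y = depth - a x^2 (occlusal
# plane z = 0). Returns x >= 0 at arc distance s from the apex.
.arch_x_at_arc <- function(a, s) {
  f <- function(x) {
    # closed-form arc length of y = -a x^2 from 0 to x
    t <- 2 * a * x
    (x * sqrt(1 + t^2) + asinh(t) / (2 * a)) / 2 - s
  }
  stats::uniroot(f, c(0, s + 1), tol = 1e-10)$root
}

# Analytic arch-local axes at a tooth placed at signed x on the parabola.
.gen_axes <- function(x, a, depth, jaw, interior_y) {
  slope <- -2 * a * x                       # dy/dx
  tangent <- .unit(c(1, slope, 0))
  mesial <- if (x > 0) -tangent else tangent
  normal <- .unit(c(-slope, 1, 0))
  pos_y <- depth - a * x^2
  lingual <- if (.dot(normal, c(0 - x, interior_y - pos_y, 0)) >= 0) normal else -normal
  coronal <- if (jaw == "mandible") c(0, 0, 1) else c(0, 0, -1)
  list(mesial = mesial, lingual = lingual, coronal = coronal)
}

# Build one permanent tooth's landmark set from archetype dims and axes.
.make_tooth <- function(tooth_id, jaw, region, status, oc, axes, dims, cusp_kind) {
  apical <- -axes$coronal
  labial <- -axes$lingual
  apex <- oc + apical * (dims$crown + dims$root)
  cerv <- oc + apical * dims$crown
  cej_labial <- cerv + labial * (0.4 * dims$bl)
  cej_lingual <- cerv + axes$lingual * (0.4 * dims$bl)
  mid_crown <- oc + apical * (0.3 * dims$crown)
  crown_mesial <- mid_crown + axes$mesial * (dims$md / 2)
  crown_distal <- mid_crown - axes$mesial * (dims$md / 2)
  crown_buccal <- mid_crown + labial * (dims$bl / 2)
  crown_lingual <- mid_crown + axes$lingual * (dims$bl / 2)
  tips <- switch(cusp_kind,
    edge = {
      # incisal edge: a row of tips 0.4 mm apart spanning 0.7 * md
      half <- 0.35 * dims$md
      offs <- seq(-half, half, by = 0.4)
      lapply(offs, function(o) oc + axes$mesial * o)
    },
    cusp = list(oc),
    bicusp = list(oc + labial * (0.25 * dims$bl), oc + axes$lingual * (0.25 * dims$bl)),
    molar = list(oc + labial * (0.22 * dims$bl) + axes$mesial * (0.22 * dims$md),
                 oc + labial * (0.22 * dims$bl) - axes$mesial * (0.22 * dims$md),
                 oc + axes$lingual * (0.22 * dims$bl) + axes$mesial * (0.22 * dims$md),
                 oc + axes$lingual * (0.22 * dims$bl) - axes$mesial * (0.22 * dims$md)),
    single = list(oc),
    stop("unknown cusp kind ", cusp_kind))
  tooth_landmarks(tooth_id = tooth_id, jaw = jaw, region = region,
                  status = status, occlusal_center = oc, apex = apex,
                  cej_labial = cej_labial, cej_lingual = cej_lingual,
                  cusp_tips = tips,
                  crown_mesial = crown_mesial, crown_distal = crown_distal,
                  crown_buccal = crown_buccal, crown_lingual = crown_lingual)
}

.rtrunc_norm <- function(n, mean, sd, range) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- stats::rnorm(1, mean, sd)
      if (x >= range[1] && x <= range[2]) break
    }
    out[i] <- x
  }
  out
}

# Scale a tooth's landmarks about its occlusal centre by `ratio`, then
# optionally point-reflect every landmark through the landmark centroid
# (flips the tooth axis while preserving all distances), then translate so
# the occlusal centre lands on `target_oc`.
.derive_supernumerary <- function(parent, sup_id, ratio, inverse, target_oc,
                                  microdont = FALSE) {
  t <- parent
  t$tooth_id <- sup_id
  t$status <- "supernumerary"
  oc0 <- parent$occlusal_center
  sc <- function(p) oc0 + ratio * (p - oc0)
  for (nm in .landmark_names) t[[nm]] <- sc(t[[nm]])
  t$cusp_tips <- lapply(t$cusp_tips, sc)
  t$accessory_apices <- lapply(t$accessory_apices, sc)
  if (microdont) t$cusp_tips <- list(t$occlusal_center)
  if (inverse) {
    pts <- rbind(do.call(rbind, t[.landmark_names]), do.call(rbind, t$cusp_tips))
    ctr <- colMeans(pts)
    rf <- function(p) 2 * ctr - p
    for (nm in .landmark_names) t[[nm]] <- rf(t[[nm]])
    t$cusp_tips <- lapply(t$cusp_tips, rf)
    t$accessory_apices <- lapply(t$accessory_apices, rf)
  }
  shift <- target_oc - t$occlusal_center
  tr <- function(p) p + shift
  for (nm in .landmark_names) t[[nm]] <- tr(t[[nm]])
  t$cusp_tips <- lapply(t$cusp_tips, tr)
  t$accessory_apices <- lapply(t$accessory_apices, tr)
  t
}

#' Generate one synthetic dentition with ground truth
#'
#' Places 28 permanent teeth (positions 1-7, four quadrants) on two parabolic
#' arches: the mandibular occlusal centres span the z = 0 occlusal plane and
#' the maxillary arch sits above an interocclusal gap (the jaws imaged in
#' open relation, which keeps the two arches spatially disjoint). It then
#' plants the configured number of supernumerary teeth: each is a scaled-down
#' clone of a randomly chosen adjacent permanent tooth (region drawn from
#' `region_probs`; no permanent tooth receives two supernumeraries),
#' displaced along the adjacent tooth's arch-local coronal/mesial/lingual
#' axes with per-axis signs drawn from `p_coronal`/`p_distal`/`p_lingual`,
#' and point-reflected through its own centroid (inverse axial direction)
#' with probability `p_inverse`. The supernumerary's root is strictly
#' shorter than its adjacent tooth's by construction (size ratio < 1).
#'
#' @param cfg a [default_config()]-style list.
#' @param case_id case label.
#' @return list with elements `dentition` (a [dentition()]) and `truth`
#'   (data.frame: one row per supernumerary with the planted adjacent id,
#'   positional calls, direction, region and size ratio).
#' @export
generate_dentition <- function(cfg = default_config(), case_id = "synthetic-1") {
  .validate_config(cfg)
  set.seed(cfg$seed %% .Machine$integer.max, kind = "Mersenne-Twister")
  arch_cfg <- cfg$arch
  archetypes <- .tooth_archetypes()
  teeth <- list()
  placements <- list()   # per permanent tooth: x, jaw, axes, dims, region bin
  for (jaw in .jaws) {
    a <- if (jaw == "mandible") arch_cfg$a_mandible else arch_cfg$a_maxilla
    depth <- if (jaw == "mandible") arch_cfg$depth_mandible else arch_cfg$depth_maxilla
    xs <- vapply(archetypes$position,
                 function(p) .arch_x_at_arc(a, arch_cfg$spacing * (p - 0.5)),
                 numeric(1))
    interior_y <- mean(depth - a * xs^2) - 4   # a point inside the arch U
    for (side in c("left", "right")) {
      quadrant <- if (jaw == "maxilla") {
        if (side == "right") 1L else 2L
      } else {
        if (side == "left") 3L else 4L
      }
      z_occ <- if (jaw == "mandible") 0 else arch_cfg$interocclusal_gap
      for (k in seq_len(nrow(archetypes))) {
        p <- archetypes$position[k]
        x <- if (side == "left") xs[k] else -xs[k]
        oc <- c(x, depth - a * x^2, z_occ)
        axes <- .gen_axes(x, a, depth, jaw, interior_y)
        jit <- exp(stats::rnorm(1, 0, cfg$size_jitter_sd))
        dims <- list(crown = archetypes$crown[k] * jit,
                     root = archetypes$root[k] * jit,
                     md = archetypes$md[k] * jit,
                     bl = archetypes$bl[k] * jit)
        id <- sprintf("%d%d", quadrant, p)
        teeth[[id]] <- .make_tooth(id, jaw, fdi_region(id), "erupted_permanent",
                                   oc, axes, dims, archetypes$cusp_kind[k])
        placements[[id]] <- list(axes = axes, bin = region_bin(jaw, fdi_region(id)))
      }
    }
  }
  ids <- names(teeth)
  # unerupted permanent teeth
  n_uner <- cfg$n_unerupted
  if (length(n_uner) == 2L) n_uner <- sample(n_uner[1]:n_uner[2], 1L)
  n_uner <- min(n_uner, length(ids))
  for (id in sample(ids, n_uner)) teeth[[id]]$status <- "unerupted_permanent"

  # supernumerary teeth
  n_sup <- cfg$n_supernumerary
  if (length(n_sup) == 2L) n_sup <- sample(n_sup[1]:n_sup[2], 1L)
  if (n_sup > length(ids)) {
    stop("infeasible config: ", n_sup, " supernumeraries for ", length(ids),
         " permanent teeth", call. = FALSE)
  }
  bins <- vapply(placements, `[[`, "", "bin")
  taken <- character()
  truth <- list()
  sup_teeth <- list()
  for (i in seq_len(n_sup)) {
    free <- setdiff(ids, taken)
    avail_bins <- unique(bins[free])
    pr <- cfg$region_probs[names(cfg$region_probs) %in% avail_bins]
    pr <- pr[pr > 0]
    if (!length(pr)) {
      # all positive-probability bins exhausted: fall back to any free tooth
      pr <- table(bins[free]) / length(free)
    }
    bin <- sample(names(pr), 1L, prob = pr)
    cand <- free[bins[free] == bin]
    adj_id <- if (length(cand) == 1L) cand else sample(cand, 1L)
    taken <- c(taken, adj_id)
    parent <- teeth[[adj_id]]
    axes <- placements[[adj_id]]$axes
    microdont <- grepl(" molar$", bin)   # molar region only; not premolar
    ratio <- .rtrunc_norm(1, cfg$size_ratio_mean, cfg$size_ratio_sd,
                          cfg$size_ratio_range)
    if (microdont) ratio <- ratio * cfg$microdont_factor
    s_cor <- if (stats::runif(1) < cfg$p_coronal) 1 else -1
    s_dis <- if (stats::runif(1) < cfg$p_distal) -1 else 1   # distal = -mesial
    s_lin <- if (stats::runif(1) < cfg$p_lingual) 1 else -1
    mags <- .clamp(abs(stats::rnorm(3, cfg$offset_magnitude_mm, cfg$offset_sd_mm)),
                   cfg$offset_range_mm[1], cfg$offset_range_mm[2])
    disp <- s_cor * mags[1] * axes$coronal +
            s_dis * mags[2] * axes$mesial +
            s_lin * mags[3] * axes$lingual
    inverse <- stats::runif(1) < cfg$p_inverse
    sup_id <- paste0(adj_id, ",")
    sup <- .derive_supernumerary(parent, sup_id, ratio, inverse,
                                 parent$occlusal_center + disp, microdont)
    sup_teeth[[sup_id]] <- sup
    truth[[sup_id]] <- data.frame(
      supernumerary_id = sup_id, adjacent_id = adj_id, region = bin,
      vertical = if (s_cor > 0) "coronal" else "apical",
      mesiodistal = if (s_dis < 0) "distal" else "mesial",
      labiolingual = if (s_lin > 0) "lingual" else "labial",
      direction = if (inverse) "inverse" else "normal",
      size_ratio = ratio, stringsAsFactors = FALSE)
  }
  truth_df <- if (length(truth)) {
    do.call(rbind, c(unname(truth), list(make.row.names = FALSE)))
  } else {
    data.frame(supernumerary_id = character(), adjacent_id = character(),
               region = character(), vertical = character(),
               mesiodistal = character(), labiolingual = character(),
               direction = character(), size_ratio = numeric(),
               stringsAsFactors = FALSE)
  }
  d <- dentition(case_id = case_id, teeth = c(unname(teeth), unname(sup_teeth)),
                 metadata = list(sex = sample(c("M", "F"), 1), generator_seed = cfg$seed))
  list(dentition = d, truth = truth_df)
}

#' Generate a cohort of synthetic cases
#'
#' Case `i` uses the derived seed `cfg$seed + i - 1`, so the whole cohort is
#' reproducible from one seed and individual cases can be regenerated in
#' isolation.
#'
#' @param cfg a [default_config()]-style list.
#' @param n_cases number of cases.
#' @param counts optional integer vector (length `n_cases`) fixing the
#'   supernumerary count of each case, e.g. `c(15, 10, 7, 6, 1)`.
#' @param unerupted_counts optional integer vector fixing unerupted
#'   permanent-tooth counts per case.
#' @return list of `list(dentition, truth)` per case.
#' @export
generate_cohort <- function(cfg = default_config(), n_cases = 5,
                            counts = NULL, unerupted_counts = NULL) {
  stopifnot(n_cases >= 1)
  if (!is.null(counts)) stopifnot(length(counts) == n_cases)
  if (!is.null(unerupted_counts)) stopifnot(length(unerupted_counts) == n_cases)
  lapply(seq_len(n_cases), function(i) {
    ci <- cfg
    ci$seed <- cfg$seed + i - 1L
    if (!is.null(counts)) ci$n_supernumerary <- counts[i]
    if (!is.null(unerupted_counts)) ci$n_unerupted <- unerupted_counts[i]
    generate_dentition(ci, case_id = sprintf("case-%03d", i))
  })
}

#' Mask planted statuses for pair-resolution testing
#'
#' Sets every supernumerary tooth and its planted adjacent permanent tooth to
#' `impacted_unresolved`, so that [resolve_pair_status()] has to recover the
#' assignment from root lengths.
#'
#' @param gen a `generate_dentition()` result.
#' @return the masked [dentition()].
#' @export
mask_pair_status <- function(gen) {
  d <- gen$dentition
  mask_ids <- c(gen$truth$supernumerary_id, gen$truth$adjacent_id)
  d$teeth <- lapply(d$teeth, function(t) {
    if (t$tooth_id %in% mask_ids) t$status <- "impacted_unresolved"
    t
  })
  d
}
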