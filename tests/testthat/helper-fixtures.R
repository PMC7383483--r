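# Shared fixtures: a hand-built minimal tooth, random rigid motions, and a
# small cached generator dentition.

make_simple_tooth <- function(tooth_id = "41", jaw = "mandible",
                              region = "anterior",
                              status = "unerupted_permanent",
                              oc = c(0, 0, 0),
                              crown = 8, root = 12, md = 6, bl = 5,
                              axis_dir = c(0, 0, -1),   # occlusal -> apical
                              cusp_tips = NULL,
                              apex_in_volume = TRUE) {
  cerv <- oc + axis_dir * crown
  apex <- oc + axis_dir * (crown + root)
  if (is.null(cusp_tips)) cusp_tips <- list(oc)
  tooth_landmarks(
    tooth_id = tooth_id, jaw = jaw, region = region, status = status,
    occlusal_center = oc, apex = apex,
    cej_labial = cerv + c(0, -bl / 2, 0), cej_lingual = cerv + c(0, bl / 2, 0),
    cusp_tips = cusp_tips,
    crown_mesial = oc + c(-md / 2, 0, 0), crown_distal = oc + c(md / 2, 0, 0),
    crown_buccal = oc + c(0, -bl / 2, 0), crown_lingual = oc + c(0, bl / 2, 0),
    apex_in_volume = apex_in_volume)
}

# independent oracle: two-sided exact signed-rank p by enumerating all 2^n
# sign patterns
brute_force_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  wps <- vapply(0:(2^n - 1), function(m) {
    sum(r[bitwAnd(m, 2^(0:(n - 1))) > 0])
  }, numeric(1))
  min(1, 2 * min(mean(wps <= obs), mean(wps >= obs)))
}

random_rotation <- function() {
  m <- matrix(rnorm(9), 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# canonical reference frame: occlusal z=0, sagittal x=0, frontal y=30
canonical_frame <- function() {
  build_frame(fossa_R = c(-20, 0, 0), fossa_L = c(20, 0, 0),
              incisal_mid = c(0, 30, 0))
}

# one cached default-generator case, reused across tests
cached_gen <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      cfg <- default_config()
      cfg$seed <- 42L
      cfg$n_supernumerary <- 8L
      val <<- generate_dentition(cfg, case_id = "fixture")
    }
    val
  }
})
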