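test_that("canonical frame has axis-aligned planes through the input points", {
  fr <- canonical_frame()
  expect_equal(fr$occlusal$normal, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(fr$sagittal$normal, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(fr$frontal$normal, c(0, 1, 0), tolerance = 1e-12)
  for (p in list(c(-20, 0, 0), c(20, 0, 0), c(0, 30, 0))) {
    expect_equal(signed_distance(fr$occlusal, p), 0, tolerance = 1e-12)
  }
  expect_equal(signed_distance(fr$sagittal, c(0, 0, 0)), 0, tolerance = 1e-12)
  expect_equal(signed_distance(fr$frontal, c(0, 30, 0)), 0, tolerance = 1e-12)
})

test_that("frame planes are mutually orthogonal to 1e-9", {
  set.seed(101)
  for (i in 1:50) {
    r <- random_rotation(); tr <- rnorm(3, 0, 40)
    fr <- build_frame(as.numeric(r %*% c(-20, 0, 0) + tr),
                      as.numeric(r %*% c(20, 1, -2) + tr),
                      as.numeric(r %*% c(1, 31, 1) + tr),
                      as.numeric(r %*% c(0, 33, 0) + tr))
    expect_lt(abs(sum(fr$occlusal$normal * fr$sagittal$normal)), 1e-9)
    expect_lt(abs(sum(fr$sagittal$normal * fr$frontal$normal)), 1e-9)
    expect_lt(abs(sum(fr$occlusal$normal * fr$frontal$normal)), 1e-9)
  }
})

test_that("build_frame is equivariant under rigid motions", {
  set.seed(7)
  pts <- list(fossa_R = c(-21, 1, 0.5), fossa_L = c(19, -1, -0.5),
              incisal_mid = c(0.3, 29, 0.2), incisal_edge_mid = c(0.1, 31, 0))
  fr0 <- do.call(build_frame, pts)
  for (i in 1:20) {
    r <- random_rotation(); tr <- rnorm(3, 0, 25)
    fr1 <- do.call(build_frame, lapply(pts, function(p) as.numeric(r %*% p + tr)))
    probe <- matrix(rnorm(30, 0, 20), ncol = 3)
    probe_t <- t(apply(probe, 1, function(p) as.numeric(r %*% p + tr)))
    for (pl in c("occlusal", "sagittal", "frontal")) {
      expect_equal(signed_distance(fr1[[pl]], probe_t),
                   signed_distance(fr0[[pl]], probe), tolerance = 1e-9)
    }
  }
})

test_that("degenerate frame inputs error", {
  expect_error(build_frame(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0)), "collinear")
  expect_error(build_frame(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)), "coincident")
})

test_that("signed_distance matches the independent point-plane formula", {
  p <- plane(c(0, 0, 2), 0)     # normal normalized internally
  expect_equal(signed_distance(p, c(5, 5, 3)), 3)
  expect_equal(signed_distance(p, c(1, -4, 0)), 0)
  set.seed(11)
  for (i in 1:10) {
    n <- rnorm(3); pt0 <- rnorm(3, 0, 10)
    nu <- n / sqrt(sum(n^2))
    pl <- plane(n, sum(nu * pt0))
    x <- matrix(rnorm(300, 0, 50), ncol = 3)
    # brute-force: distance along the unit normal from the plane point
    brute <- as.numeric((x - matrix(pt0, nrow(x), 3, byrow = TRUE)) %*% nu)
    expect_equal(signed_distance(pl, x), brute, tolerance = 1e-12)
  }
})

test_that("the three plane distances reconstruct a point in the frame basis", {
  fr <- canonical_frame()
  set.seed(5)
  x <- rnorm(3, 0, 30)
  u <- signed_distance(fr$sagittal, x)
  v <- signed_distance(fr$frontal, x)
  w <- signed_distance(fr$occlusal, x)
  origin_contrib <- fr$sagittal$offset * fr$sagittal$normal +
    fr$frontal$offset * fr$frontal$normal + fr$occlusal$offset * fr$occlusal$normal
  rec <- origin_contrib + u * fr$sagittal$normal + v * fr$frontal$normal +
    w * fr$occlusal$normal
  expect_equal(rec, x, tolerance = 1e-12)
})

test_that("arch fit recovers an exact parabola and symmetric apex", {
  fr <- build_frame(c(-20, 0, 0), c(20, 0, 0), c(0, 30, 0),
                    incisal_edge_mid = c(0, 0, 0))  # frontal through y=0: v = y
  a <- 0.04; cc <- 38
  xs <- seq(-24, 24, length.out = 10)
  teeth <- lapply(seq_along(xs), function(i) {
    make_simple_tooth(tooth_id = sprintf("t%02d", i), oc = c(xs[i], cc - a * xs[i]^2, 0))
  })
  arch <- fit_arch_curve(dentition("arch", teeth), "mandible", fr)
  expect_equal(arch$coef[3], -a, tolerance = 1e-9)
  expect_equal(arch$coef[2], 0, tolerance = 1e-9)
  expect_equal(arch$coef[1], cc, tolerance = 1e-9)
  # symmetric arch: vertex (zero tangent slope) on the sagittal plane
  expect_equal(-arch$coef[2] / (2 * arch$coef[3]), 0, tolerance = 1e-9)
  expect_error(fit_arch_curve(dentition("few", teeth[1:3]), "mandible", fr),
               ">= 4 permanent teeth")
})

test_that("generator arches are reproduced by the least-squares fit", {
  gen <- cached_gen()
  fr <- frame_from_dentition(gen$dentition)
  for (jaw in c("mandible", "maxilla")) {
    arch <- fit_arch_curve(gen$dentition, jaw, fr)
    expect_lt(max(abs(arch$residuals)), 1)
  }
})

test_that("local axes are orthonormal and anatomically oriented", {
  gen <- cached_gen()
  d <- gen$dentition
  fr <- frame_from_dentition(d)
  perm <- Filter(function(t) t$status != "supernumerary", d$teeth)
  centroids <- list(
    mandible = colMeans(do.call(rbind, lapply(
      Filter(function(t) t$jaw == "mandible", perm), `[[`, "occlusal_center"))),
    maxilla = colMeans(do.call(rbind, lapply(
      Filter(function(t) t$jaw == "maxilla", perm), `[[`, "occlusal_center"))))
  for (jaw in c("mandible", "maxilla")) {
    arch <- fit_arch_curve(d, jaw, fr)
    for (t in Filter(function(t) t$jaw == jaw, perm)) {
      ax <- local_axes(fr, arch, t)
      m <- cbind(ax$coronal, ax$mesial, ax$lingual)
      expect_lt(max(abs(crossprod(m) - diag(3))), 1e-9)
      # mesial points toward the midline
      u <- signed_distance(fr$sagittal, t$occlusal_center)
      expect_lt(sum(ax$mesial * fr$sagittal$normal) * sign(u), 0)
      # lingual points toward the arch interior
      expect_gt(sum(ax$lingual * (centroids[[jaw]] - t$occlusal_center)), 0)
    }
  }
})

test_that("coronal axes of opposing jaws are antiparallel", {
  gen <- cached_gen()
  d <- gen$dentition
  fr <- frame_from_dentition(d)
  arch_mn <- fit_arch_curve(d, "mandible", fr)
  arch_mx <- fit_arch_curve(d, "maxilla", fr)
  t_mn <- Filter(function(t) t$jaw == "mandible" && t$status != "supernumerary", d$teeth)[[1]]
  t_mx <- Filter(function(t) t$jaw == "maxilla" && t$status != "supernumerary", d$teeth)[[1]]
  ax_mn <- local_axes(fr, arch_mn, t_mn)
  ax_mx <- local_axes(fr, arch_mx, t_mx)
  expect_equal(sum(ax_mn$coronal * ax_mx$coronal), -1, tolerance = 1e-9)
})
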