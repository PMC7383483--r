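test_that("cervical midpoint is the CEJ midpoint and warns when degenerate", {
  t <- make_simple_tooth()
  t$cej_labial <- c(0, 0, 0); t$cej_lingual <- c(2, 0, 0)
  expect_equal(cervical_midpoint(t), c(1, 0, 0))
  t$cej_lingual <- t$cej_labial
  expect_warning(cm <- cervical_midpoint(t), "degenerate cervical line")
  expect_equal(cm, c(0, 0, 0))
  set.seed(2)
  for (i in 1:20) {
    t$cej_labial <- rnorm(3); t$cej_lingual <- rnorm(3)
    expect_equal(cervical_midpoint(t), colMeans(rbind(t$cej_labial, t$cej_lingual)))
  }
})

test_that("crown and root lengths follow the cervical-line definitions", {
  t <- make_simple_tooth()
  t$cej_labial <- c(-1, 0, 0); t$cej_lingual <- c(1, 0, 0)  # midpoint origin
  t$cusp_tips <- list(c(0, 0, 8), c(0, 0, 5))
  expect_equal(crown_length(t), 8)   # highest crown point = farthest cusp tip
  t$apex <- c(0, 0, -12)
  expect_equal(root_length(t), 12)
  t$apex_in_volume <- FALSE
  expect_true(is.na(root_length(t)))  # root out of imaging range: excluded
})

test_that("crown diameters are extreme-to-extreme distances, degree-1 homogeneous", {
  t <- make_simple_tooth()
  t$crown_mesial <- c(-3.5, 0, 0); t$crown_distal <- c(3.5, 0, 0)
  t$crown_buccal <- c(0, -4, 0); t$crown_lingual <- c(0, 4, 0)
  expect_equal(unname(crown_diameters(t)), c(7, 8))
  k <- 2.5
  for (nm in c("crown_mesial", "crown_distal", "crown_buccal", "crown_lingual")) {
    t[[nm]] <- k * t[[nm]]
  }
  expect_equal(unname(crown_diameters(t)), k * c(7, 8))
  t$crown_distal <- t$crown_mesial
  expect_warning(crown_diameters(t), "coincident crown extremes")
})

test_that("inclination is +90 for an upright tooth and flips with the axis", {
  fr <- canonical_frame()
  t <- make_simple_tooth()                   # mandibular, apex below crown
  inc <- inclination(t, fr)
  expect_equal(inc$angle_deg, 90)
  expect_equal(inc$direction, "normal")
  # swapping occlusal centre and apex reflects the axis
  t2 <- t
  tmp <- t2$occlusal_center; t2$occlusal_center <- t2$apex; t2$apex <- tmp
  inc2 <- inclination(t2, fr)
  expect_equal(inc2$angle_deg, -90)
  expect_equal(inc2$direction, "inverse")
  # maxillary upright tooth (apex cranial) is also +90 via the jaw flip
  t3 <- make_simple_tooth(tooth_id = "11", jaw = "maxilla", axis_dir = c(0, 0, 1))
  expect_equal(inclination(t3, fr)$angle_deg, 90)
  t4 <- t; t4$apex <- t4$occlusal_center
  expect_error(tooth_axis(t4), "zero-length axis")
})

test_that("direction flips and |inclination| is preserved under point reflection", {
  fr <- canonical_frame()
  gen <- cached_gen()
  sup <- Filter(function(t) t$status == "supernumerary", gen$dentition$teeth)
  fr_gen <- frame_from_dentition(gen$dentition)
  for (t in sup[1:4]) {
    pts <- tooth_points(t)
    ctr <- colMeans(pts)
    t2 <- t
    for (nm in c("occlusal_center", "apex", "cej_labial", "cej_lingual",
                 "crown_mesial", "crown_distal", "crown_buccal", "crown_lingual")) {
      t2[[nm]] <- 2 * ctr - t2[[nm]]
    }
    t2$cusp_tips <- lapply(t2$cusp_tips, function(p) 2 * ctr - p)
    i1 <- inclination(t, fr_gen); i2 <- inclination(t2, fr_gen)
    expect_equal(i2$angle_deg, -i1$angle_deg, tolerance = 1e-9)
    expect_false(i1$direction == i2$direction)
  }
})

test_that("all measurements are invariant under rigid motion", {
  gen <- cached_gen()
  d <- gen$dentition
  m0 <- measurement_table(d)
  set.seed(33)
  for (i in 1:5) {
    r <- random_rotation(); tr <- rnorm(3, 0, 100)
    d2 <- transform_dentition(d, r, tr)
    m1 <- measurement_table(d2)
    for (col in c("crown_length", "root_length", "md_diameter", "bl_diameter",
                  "inclination_deg")) {
      expect_equal(m1[[col]], m0[[col]], tolerance = 1e-9,
                   label = paste("rigid invariance of", col))
    }
    expect_identical(m1$direction, m0$direction)
    expect_identical(m1$n_cusps, m0$n_cusps)
    expect_identical(m1$crown_type, m0$crown_type)
  }
})

test_that("cusp merging and crown typing follow the thresholds", {
  # two well-separated tips: bicuspid
  t <- make_simple_tooth(md = 7, cusp_tips = list(c(-2, 0, 0), c(2, 0, 0)))
  cl <- cusp_classification(t)
  expect_equal(cl$n_cusps, 2); expect_equal(cl$crown_type, "bicuspid")
  # one pointed tip (zero edge width): cuspid
  t <- make_simple_tooth(cusp_tips = list(c(0, 0, 0)))
  cl <- cusp_classification(t)
  expect_equal(cl$n_cusps, 1); expect_equal(cl$crown_type, "cuspid")
  # a chain of tips merging into one wide cusp: incisal edge
  t <- make_simple_tooth(md = 6,
                         cusp_tips = lapply(seq(-2.1, 2.1, by = 0.3),
                                            function(o) c(o, 0, 0)))
  cl <- cusp_classification(t)
  expect_equal(cl$n_cusps, 1); expect_equal(cl$crown_type, "incisal_edge")
  # tiny mesiodistal diameter: obscure microdont
  t <- make_simple_tooth(md = 1.5, cusp_tips = list(c(0, 0, 0)))
  t$crown_mesial <- c(-0.75, 0, 0); t$crown_distal <- c(0.75, 0, 0)
  expect_equal(cusp_classification(t)$crown_type, "obscure")
  # four tips: recorded as-is and flagged
  t <- make_simple_tooth(cusp_tips = list(c(-2, -2, 0), c(2, -2, 0),
                                          c(-2, 2, 0), c(2, 2, 0)))
  cl <- cusp_classification(t)
  expect_equal(cl$n_cusps, 4); expect_true(cl$multi_cusped)
})

test_that("root count applies the short-root indeterminacy floor", {
  t <- make_simple_tooth(root = 9)
  expect_equal(root_count(t)$n_roots, 1L)
  t <- make_simple_tooth(root = 0.5)
  rc <- root_count(t)
  expect_true(rc$indeterminate); expect_true(is.na(rc$n_roots))
  # generator supernumeraries are all single-rooted or indeterminate
  gen <- cached_gen()
  sup <- Filter(function(t) t$status == "supernumerary", gen$dentition$teeth)
  for (s in sup) {
    rc <- root_count(s)
    expect_true(rc$indeterminate || rc$n_roots == 1L)
  }
})

test_that("planted size ratios are recovered exactly on the landmark path", {
  gen <- cached_gen()
  d <- gen$dentition
  for (i in seq_len(nrow(gen$truth))) {
    s <- Filter(function(t) t$tooth_id == gen$truth$supernumerary_id[i], d$teeth)[[1]]
    adj <- Filter(function(t) t$tooth_id == gen$truth$adjacent_id[i], d$teeth)[[1]]
    if (gen$truth$region[i] == "maxillary molar") next  # microdont: single tip
    expect_equal(crown_length(s) / crown_length(adj), gen$truth$size_ratio[i],
                 tolerance = 1e-9)
    expect_equal(root_length(s) / root_length(adj), gen$truth$size_ratio[i],
                 tolerance = 1e-9)
  }
})
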