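test_that("root length decides permanent vs supernumerary within a pair", {
  t1 <- make_simple_tooth(tooth_id = "33", region = "canine", root = 12,
                          status = "impacted_unresolved")
  t2 <- make_simple_tooth(tooth_id = "33,", region = "canine", root = 6,
                          oc = c(2, 2, 2), status = "impacted_unresolved")
  d <- resolve_pair_status(dentition("c", list(t1, t2)))
  st <- setNames(vapply(d$teeth, `[[`, "", "status"),
                 vapply(d$teeth, `[[`, "", "tooth_id"))
  expect_equal(unname(st["33"]), "unerupted_permanent")
  expect_equal(unname(st["33,"]), "supernumerary")
  expect_equal(nrow(attr(d, "pair_flags")), 0)
})

test_that("equal root lengths break toward the larger crown with a flag", {
  t1 <- make_simple_tooth(tooth_id = "33", region = "canine", root = 10, crown = 9,
                          status = "impacted_unresolved")
  t2 <- make_simple_tooth(tooth_id = "33,", region = "canine", root = 10, crown = 7,
                          oc = c(2, 2, 2), status = "impacted_unresolved")
  d <- resolve_pair_status(dentition("c", list(t1, t2)))
  st <- setNames(vapply(d$teeth, `[[`, "", "status"),
                 vapply(d$teeth, `[[`, "", "tooth_id"))
  expect_equal(unname(st["33"]), "unerupted_permanent")
  expect_true("equal_root_length_tie" %in% attr(d, "pair_flags")$flag)
})

test_that("clusters of three or more unresolved teeth demand manual status", {
  teeth <- lapply(1:3, function(i) {
    make_simple_tooth(tooth_id = paste0("4", i), region = c("anterior", "anterior", "canine")[i],
                      root = 8 + i, oc = c(i, 0, 0), status = "impacted_unresolved")
  })
  expect_error(resolve_pair_status(dentition("c", teeth)), "manual status")
})

test_that("masked generator statuses are recovered from root lengths alone", {
  for (seed in c(1L, 8L, 21L)) {
    cfg <- default_config(); cfg$seed <- seed; cfg$n_supernumerary <- 10L
    # keep proximity clusters pair-sized: larger offsets can single-link two
    # neighbouring pairs into one cluster, which the resolver (correctly)
    # refuses to decide
    cfg$offset_range_mm <- c(0.5, 1.5)
    gen <- generate_dentition(cfg)
    masked <- mask_pair_status(gen)
    # radius between the max intra-pair span (~2.6 mm) and the closest
    # possible inter-pair distance (5 mm): clusters are exactly the pairs
    resolved <- resolve_pair_status(masked, proximity_radius = 4)
    st <- setNames(vapply(resolved$teeth, `[[`, "", "status"),
                   vapply(resolved$teeth, `[[`, "", "tooth_id"))
    expect_true(all(st[gen$truth$supernumerary_id] == "supernumerary"))
    expect_true(all(st[gen$truth$adjacent_id] == "unerupted_permanent"))
  }
})

test_that("assign_adjacent picks the closest permanent tooth of the jaw", {
  near <- make_simple_tooth(tooth_id = "34", region = "premolar", oc = c(2, 0, 0))
  far1 <- make_simple_tooth(tooth_id = "35", region = "premolar", oc = c(9, 0, 0))
  far2 <- make_simple_tooth(tooth_id = "33", region = "canine", oc = c(-8, 0, 0))
  s <- make_simple_tooth(tooth_id = "34,", region = "premolar",
                         status = "supernumerary", oc = c(0, 0, 0))
  d <- dentition("c", list(near, far1, far2, s))
  res <- assign_adjacent(s, d)
  expect_equal(res$adjacent_id, "34")
  expect_equal(res$distance_mm, 2)
  expect_false(res$tie)
})

test_that("assign_adjacent agrees with the exhaustive distance oracle", {
  set.seed(77)
  for (rep in 1:50) {
    n <- sample(4:10, 1)
    teeth <- lapply(seq_len(n), function(i) {
      make_simple_tooth(tooth_id = sprintf("3%d", i %% 8 + 1),
                        region = NA_character_,
                        oc = rnorm(3, 0, 15))
    })
    # make ids unique
    for (i in seq_len(n)) teeth[[i]]$tooth_id <- paste0("id", i)
    s <- make_simple_tooth(tooth_id = "sup", region = NA_character_,
                           status = "supernumerary", oc = rnorm(3, 0, 15))
    d <- dentition("c", c(teeth, list(s)))
    res <- assign_adjacent(s, d)
    oracle <- vapply(teeth, function(t) sqrt(sum((t$occlusal_center - s$occlusal_center)^2)),
                     numeric(1))
    expect_equal(res$adjacent_id, paste0("id", which.min(oracle)))
    expect_equal(res$distance_mm, min(oracle))
  }
})

test_that("classification reads displacement signs in the local axes", {
  fr <- canonical_frame()
  teeth <- lapply(1:8, function(i) {
    x <- c(-24, -17, -10, -3.5, 3.5, 10, 17, 24)[i]
    make_simple_tooth(tooth_id = paste0("4", i), region = NA_character_,
                      oc = c(x, 35 - 0.04 * x^2, 0))
  })
  d <- dentition("c", teeth)
  arch <- fit_arch_curve(d, "mandible", fr)
  adj <- teeth[[6]]                          # right-of-midline tooth (x = 10)
  ax <- local_axes(fr, arch, adj)
  s <- make_simple_tooth(tooth_id = "s", region = NA_character_,
                         status = "supernumerary",
                         oc = adj$occlusal_center + 2 * ax$coronal -
                           1 * ax$mesial + 3 * ax$lingual)
  row <- classify_position(s, adj, ax)
  expect_equal(row$vertical, "coronal")
  expect_equal(row$mesiodistal, "distal")
  expect_equal(row$labiolingual, "lingual")
  expect_equal(row$disp_coronal, 2, tolerance = 1e-9)
  expect_equal(row$disp_mesial, -1, tolerance = 1e-9)
  expect_equal(row$disp_lingual, 3, tolerance = 1e-9)
  # zero displacement: every axis tied, deterministic apical/mesial/labial
  s0 <- s; s0$occlusal_center <- adj$occlusal_center
  row0 <- classify_position(s0, adj, ax)
  expect_true(all(c(row0$tie_vertical, row0$tie_mesiodistal, row0$tie_labiolingual)))
  expect_equal(c(row0$vertical, row0$mesiodistal, row0$labiolingual),
               c("apical", "mesial", "labial"))
})

test_that("regions come from the FDI code, supernumeraries via their adjacent", {
  expect_equal(assign_region("35"), "mandibular premolar")
  expect_equal(assign_region("33,"), "mandibular canine")
  expect_equal(assign_region("11"), "maxillary anterior")
  expect_equal(assign_region("27"), "maxillary molar")
  expect_error(assign_region("x9"), "not an FDI")
})

test_that("deterministic generator probabilities are recovered exactly", {
  cfg <- default_config()
  cfg$p_coronal <- 1; cfg$p_distal <- 1; cfg$p_lingual <- 0; cfg$p_inverse <- 0
  cohort <- generate_cohort(cfg, 10, counts = rep(12L, 10))
  pairs <- do.call(rbind, lapply(cohort, function(cs) classify_dentition(cs$dentition)))
  truth <- do.call(rbind, lapply(cohort, `[[`, "truth"))
  expect_equal(nrow(pairs), 120)
  expect_true(all(pairs$vertical == "coronal"))
  expect_true(all(pairs$mesiodistal == "distal"))
  expect_true(all(pairs$labiolingual == "labial"))
  expect_true(all(pairs$direction == "normal"))
  # and pairing matches the planted adjacency
  key <- function(x) x[order(x$supernumerary_id), ]
  expect_equal(key(pairs)$adjacent_id, key(truth)$adjacent_id)
})

test_that("classification calls are invariant under rigid motion", {
  gen <- cached_gen()
  p0 <- classify_dentition(gen$dentition)
  set.seed(13)
  for (i in 1:3) {
    r <- random_rotation(); tr <- rnorm(3, 0, 80)
    p1 <- classify_dentition(transform_dentition(gen$dentition, r, tr))
    for (col in c("adjacent_id", "vertical", "mesiodistal", "labiolingual", "direction")) {
      expect_identical(p1[[col]], p0[[col]], label = paste("rigid", col))
    }
    expect_equal(p1$disp_coronal, p0$disp_coronal, tolerance = 1e-9)
    expect_equal(p1$disp_mesial, p0$disp_mesial, tolerance = 1e-9)
    expect_equal(p1$disp_lingual, p0$disp_lingual, tolerance = 1e-9)
  }
})
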