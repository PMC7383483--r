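test_that("unanimous signs give the closed-form exact p", {
  res <- wilcoxon_signed_rank(c(0.4, 1.1, 2.3, 0.9, 3.0, 1.7))
  expect_equal(res$p, 2 / 64)        # 2 * P(all six signs positive)
  expect_equal(res$W, 0)
  expect_equal(res$method, "exact")
})

test_that("identical sessions are degenerate with p = 1", {
  a <- c(1, 2, 3)
  res <- wilcoxon_signed_rank(a, a)
  expect_true(res$degenerate)
  expect_equal(res$p, 1)
  expect_equal(res$n, 0)
})

test_that("exact p equals the 2^n enumeration oracle, with and without ties", {
  set.seed(19)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    d <- if (rep %% 2 == 0) {
      sample(c(-3, -2, -1, 1, 2, 3), n, replace = TRUE)   # heavy ties
    } else {
      round(rnorm(n), 3)
    }
    d <- d[d != 0]
    if (length(d) < 2) next
    expect_equal(wilcoxon_signed_rank(d)$p, brute_force_wilcoxon_p(d),
                 label = sprintf("rep %d (n=%d)", rep, length(d)))
  }
})

test_that("the tie-free exact path reproduces the reference implementation", {
  set.seed(23)
  for (rep in 1:10) {
    d <- rnorm(sample(6:20, 1))
    expect_equal(wilcoxon_signed_rank(d)$p,
                 stats::wilcox.test(d, exact = TRUE)$p.value)
  }
})

test_that("the normal approximation is close to exact at the cross-over n", {
  set.seed(29)
  for (rep in 1:10) {
    d <- rnorm(25, mean = 0.3)
    p_exact <- wilcoxon_signed_rank(d, exact_max_n = 25)$p
    p_norm <- wilcoxon_signed_rank(d, exact_max_n = 10)$p
    expect_lt(abs(p_exact - p_norm), 0.01)
  }
})

test_that("z-scores follow (measurement - mean)/SD", {
  expect_equal(zscore(7.0, c(7.0, 0.5)), 0)
  expect_equal(zscore(6.0, c(7.0, 0.5)), -2)
  row <- norm_lookup(default_norm_table(), "mandible", 4, "M")
  expect_equal(zscore(row$mean_mm + row$sd_mm, row), 1)
  expect_error(zscore(5, c(NA, 1)), "missing norm row")
  expect_error(zscore(5, c(7, 0)), "SD must be > 0")
})

test_that("generator cohorts score supernumeraries below their adjacent teeth", {
  gen <- cached_gen()
  d <- gen$dentition
  norms <- default_norm_table()
  m <- measurement_table(d)
  z_of <- function(ids) {
    vapply(ids, function(id) {
      pos <- fdi_parse(id)$position
      zscore(m$md_diameter[m$tooth_id == id],
             norm_lookup(norms, fdi_jaw(id), pos, "M"))
    }, numeric(1))
  }
  z_sup <- z_of(gen$truth$supernumerary_id)
  z_adj <- z_of(gen$truth$adjacent_id)
  expect_lt(mean(z_sup), mean(z_adj))
})

test_that("Dahlberg error has the closed form and is session-symmetric", {
  expect_equal(dahlberg(c(1, 2), c(1, 2)), 0)
  expect_equal(dahlberg(5, 3), sqrt(4 / 2))
  set.seed(31)
  a <- rnorm(40, 10); b <- rnorm(40, 10)
  expect_equal(dahlberg(a, b), dahlberg(b, a))
  expect_equal(dahlberg(a, b), sqrt(sum((a - b)^2) / (2 * length(a))))
})

test_that("Dahlberg estimates the per-session noise SD consistently", {
  set.seed(37)
  sigma <- 0.4
  truth <- runif(500, 5, 15)
  a <- truth + rnorm(500, 0, sigma)
  b <- truth + rnorm(500, 0, sigma)
  expect_lt(abs(dahlberg(a, b) - sigma) / sigma, 0.1)
})

test_that("ICC(1,1) is 1 for identical sessions, ~0 for unrelated ones", {
  a <- c(4, 7, 9, 12, 15)
  res <- icc(a, a)
  expect_equal(res$icc, 1)
  expect_false(res$undefined)
  expect_true(icc(rep(3, 5), rep(3, 5))$undefined)
  set.seed(41)
  res0 <- icc(rnorm(200), rnorm(200))
  expect_lt(abs(res0$icc), 0.2)
  # session-swap symmetry
  b <- a + rnorm(5, 0, 0.3)
  expect_equal(icc(a, b)$icc, icc(b, a)$icc)
})

test_that("paired t detects a systematic shift and flags degeneracy", {
  set.seed(43)
  a <- rnorm(20, 10, 1)
  b <- a + 1 + rnorm(20, 0, 0.1)   # 1 mm shift, sigma 0.1: huge noncentrality
  res <- paired_t(a, b)
  expect_lt(res$p, 1e-6)
  res_d <- paired_t(a, a)
  expect_true(res_d$degenerate)
  expect_equal(res_d$p, 1)
})

test_that("tabulations conserve counts and report one-decimal percentages", {
  gen <- cached_gen()
  pairs <- classify_dentition(gen$dentition)
  rf <- region_frequencies(pairs)
  expect_equal(sum(rf$count), nrow(pairs))
  expect_true(all(rf$count <= rf$total))
  pf <- position_frequencies(pairs)
  # per region and axis, calls partition the region's pairs
  for (g in unique(pf$region)) {
    for (ax in unique(pf$axis)) {
      sub <- pf[pf$region == g & pf$axis == ax, ]
      expect_equal(sum(sub$count), sub$denom[1])
    }
  }
  # empty input: all-zero table
  empty <- classify_dentition(generate_dentition(
    within_cfg <- local({cfg <- default_config(); cfg$n_supernumerary <- 0L; cfg}))$dentition)
  expect_equal(sum(region_frequencies(empty)$count), 0)
})

test_that("cohort summaries give totals, one-decimal means and ranges", {
  tab <- data.frame(case_id = paste0("c", 1:5),
                    n_supernumerary = c(15, 10, 7, 6, 1),
                    n_unerupted = c(20, 21, 18, 20, 10))
  s <- summarize_cohort(tab)$summary
  sup <- s[s$group == "supernumerary", ]
  expect_equal(sup$total, 39)
  expect_equal(sup$mean, 7.8)
  expect_equal(c(sup$min, sup$max), c(1, 15))
  expect_equal(s$mean[s$group == "unerupted_permanent"], 17.8)
  s1 <- summarize_cohort(data.frame(case_id = "c", n_supernumerary = 4,
                                    n_unerupted = 12))$summary
  expect_equal(s1$mean, c(4, 12))   # single case: mean = count
})

test_that("the pipeline is deterministic and stage-tags its errors", {
  out_dir <- withr::local_tempdir()
  cfg <- list(seed = 3L, counts = c(5L, 3L), out_dir = file.path(out_dir, "run1"))
  b1 <- run_pipeline(cfg)
  cfg$out_dir <- file.path(out_dir, "run2")
  b2 <- run_pipeline(cfg)
  expect_identical(b1$pairs, b2$pairs)
  expect_identical(b1$measurements, b2$measurements)
  expect_identical(readLines(file.path(out_dir, "run1", "stats.json")),
                   readLines(file.path(out_dir, "run2", "stats.json")))
  expect_true(all(file.exists(file.path(out_dir, "run1",
    c("case_summary.csv", "measurements.csv", "pairs.csv",
      "frequencies.csv", "stats.json", "run.log")))))
  # a broken norm table aborts with a stage-tagged message
  expect_error(run_pipeline(list(seed = 3L, counts = c(2L),
                                 norm_table = data.frame(bogus = 1))),
               "stage 'statistics'|stage 'zscore'")
})
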