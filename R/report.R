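#' Frequency tabulations of classification calls
#'
#' `region_frequencies()` counts supernumerary teeth per jaw-by-region bin
#' with the cohort total as denominator; `position_frequencies()` counts, per
#' region bin and overall, the calls on each positional axis with the
#' region's pair count as denominator (the machine-readable twin of a
#' per-region classification figure). Percentages are reported at one
#' decimal.
#'
#' @param classifications a data.frame as returned by [classify_dentition()]
#'   (rows from several cases may be concatenated).
#' @return data.frames of counts, denominators and percentages.
#' @export
region_frequencies <- function(classifications) {
  bins <- region_bins()
  total <- nrow(classifications)
  counts <- vapply(bins, function(b) sum(classifications$region == b), integer(1))
  data.frame(region = bins, count = counts, total = total,
             percent = if (total > 0) round(100 * counts / total, 1) else 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname region_frequencies
#' @export
position_frequencies <- function(classifications) {
  axes <- list(vertical = c("coronal", "apical"),
               mesiodistal = c("mesial", "distal"),
               labiolingual = c("labial", "lingual"),
               direction = c("normal", "inverse"))
  groups <- c(region_bins(), "all")
  rows <- list()
  for (g in groups) {
    sub <- if (g == "all") classifications else
      classifications[classifications$region == g, , drop = FALSE]
    denom <- nrow(sub)
    for (ax in names(axes)) {
      if (!ax %in% names(sub)) next
      for (call in axes[[ax]]) {
        cnt <- sum(sub[[ax]] == call)
        rows[[length(rows) + 1L]] <- data.frame(
          region = g, axis = ax, call = call, count = cnt, denom = denom,
          percent = if (denom > 0) round(100 * cnt / denom, 1) else 0,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Per-case and cohort summary of tooth counts
#'
#' @param cases either a list of `list(dentition, ...)` / [dentition()]
#'   objects (counts derived from tooth statuses) or a data.frame with
#'   columns `case_id`, `n_supernumerary`, `n_unerupted`.
#' @return list with `per_case` (data.frame) and `summary` (data.frame with
#'   total, mean to one decimal, and range for supernumerary and unerupted
#'   permanent teeth).
#' @export
summarize_cohort <- function(cases) {
  per_case <- if (is.data.frame(cases)) {
    stopifnot(all(c("case_id", "n_supernumerary", "n_unerupted") %in% names(cases)))
    cases
  } else {
    stopifnot(is.list(cases), length(cases) >= 1)
    rows <- lapply(cases, function(cs) {
      d <- if (inherits(cs, "dentition")) cs else cs$dentition
      st <- vapply(d$teeth, `[[`, "", "status")
      data.frame(case_id = d$case_id,
                 n_supernumerary = sum(st == "supernumerary"),
                 n_unerupted = sum(st == "unerupted_permanent"),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  smr <- function(x) {
    data.frame(total = sum(x), mean = round(mean(x), 1),
               min = min(x), max = max(x))
  }
  s1 <- smr(per_case$n_supernumerary)
  s2 <- smr(per_case$n_unerupted)
  s1$group <- "supernumerary"
  s2$group <- "unerupted_permanent"
  list(per_case = per_case,
       summary = rbind(s1, s2)[, c("group", "total", "mean", "min", "max")])
}

#' Run the whole analysis pipeline on a synthetic cohort
#'
#' Generates a cohort, builds frames, measures every tooth, pairs and
#' classifies every supernumerary, and runs the statistical layer:
#' supernumerary-vs-adjacent Wilcoxon signed-rank comparison of the four size
#' measures, z-scores of crown mesiodistal diameters against the norm table,
#' and the frequency tabulations. Writes `case_summary.csv`,
#' `measurements.csv`, `pairs.csv`, `frequencies.csv`, `stats.json` and
#' `run.log` under `out_dir` when given. Fully deterministic for a given
#' config.
#'
#' @param config list with elements `seed`, and optionally `n_cases`,
#'   `counts`, `unerupted_counts`, `generator` (overrides merged into
#'   [default_config()]), `norm_table` (data.frame; `NULL` suppresses
#'   z-scores; missing uses [default_norm_table()]), `out_dir`.
#' @return (invisibly) a list bundle with all tables and statistics.
#' @export
run_pipeline <- function(config) {
  stage <- "config"
  out <- tryCatch({
    cfg <- default_config()
    for (nm in names(config$generator %||% list())) cfg[[nm]] <- config$generator[[nm]]
    if (!is.null(config$seed)) cfg$seed <- config$seed
    n_cases <- if (!is.null(config$counts)) length(config$counts) else config$n_cases %||% 5
    norms <- if ("norm_table" %in% names(config)) config$norm_table else default_norm_table()

    stage <- "generate"
    cohort <- generate_cohort(cfg, n_cases, counts = config$counts,
                              unerupted_counts = config$unerupted_counts)

    stage <- "measure"
    frames <- lapply(cohort, function(cs) frame_from_dentition(cs$dentition))
    meas <- do.call(rbind, c(lapply(seq_along(cohort), function(i) {
      m <- measurement_table(cohort[[i]]$dentition, frames[[i]])
      cbind(case_id = cohort[[i]]$dentition$case_id, m)
    }), list(make.row.names = FALSE)))

    stage <- "classify"
    pairs <- do.call(rbind, c(lapply(seq_along(cohort), function(i) {
      p <- classify_dentition(cohort[[i]]$dentition, frames[[i]])
      if (nrow(p)) cbind(case_id = cohort[[i]]$dentition$case_id, p) else NULL
    }), list(make.row.names = FALSE)))

    stage <- "statistics"
    key <- function(case_id, tooth_id) paste(case_id, tooth_id)
    mrow <- function(cid, tid, col) {
      meas[[col]][match(key(cid, tid), key(meas$case_id, meas$tooth_id))]
    }
    size_tests <- list()
    for (col in c("crown_length", "root_length", "md_diameter", "bl_diameter")) {
      a <- mrow(pairs$case_id, pairs$supernumerary_id, col)
      b <- mrow(pairs$case_id, pairs$adjacent_id, col)
      keep <- is.finite(a) & is.finite(b)   # excludes out-of-volume roots
      wt <- wilcoxon_signed_rank(a[keep], b[keep])
      size_tests[[col]] <- list(n = wt$n, W = wt$W, p = wt$p, method = wt$method,
                                mean_supernumerary = mean(a[keep]),
                                mean_adjacent = mean(b[keep]))
    }
    zsum <- NULL
    if (!is.null(norms)) {
      stage <- "zscore"
      zs <- function(ids) {
        vapply(seq_along(ids), function(i) {
          cid <- pairs$case_id[i]; tid <- ids[i]
          info <- fdi_parse(tid)
          dnt <- cohort[[match(cid, vapply(cohort, function(cs) cs$dentition$case_id, ""))]]$dentition
          sex <- dnt$metadata$sex %||% "M"
          zscore(mrow(cid, tid, "md_diameter"),
                 norm_lookup(norms, fdi_jaw(tid), info$position, sex))
        }, numeric(1))
      }
      zsum <- list(mean_z_supernumerary = mean(zs(pairs$supernumerary_id)),
                   mean_z_adjacent = mean(zs(pairs$adjacent_id)))
    }
    cs <- summarize_cohort(cohort)
    freq_region <- region_frequencies(pairs)
    freq_position <- position_frequencies(pairs)
    stats <- list(seed = cfg$seed, n_cases = n_cases,
                  cohort_summary = cs$summary, size_tests = size_tests,
                  zscores = zsum,
                  inverse_fraction = mean(pairs$direction == "inverse"))
    bundle <- list(config = cfg, cohort = cohort, measurements = meas,
                   pairs = pairs, case_summary = cs,
                   region_frequencies = freq_region,
                   position_frequencies = freq_position, stats = stats)

    if (!is.null(config$out_dir)) {
      stage <- "write"
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      w <- function(x, f) utils::write.csv(x, file.path(config$out_dir, f), row.names = FALSE)
      w(cs$per_case, "case_summary.csv")
      w(meas, "measurements.csv")
      w(pairs, "pairs.csv")
      w(freq_position, "frequencies.csv")
      w(freq_region, "region_frequencies.csv")
      jsonlite::write_json(stats, file.path(config$out_dir, "stats.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           dataframe = "rows")
      writeLines(c(paste("seed:", cfg$seed),
                   paste("n_cases:", n_cases),
                   paste("generated:", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                   utils::capture.output(utils::str(cfg, give.attr = FALSE))),
                 file.path(config$out_dir, "run.log"))
    }
    bundle
  }, error = function(e) {
    stop("pipeline stage '", stage, "': ", conditionMessage(e), call. = FALSE)
  })
  invisible(out)
}

#' Positional-tendency simulation study
#'
#' Generates enough synthetic cases to yield `n_pairs` supernumerary-adjacent
#' pairs (15 supernumeraries per case, the maximum observed per case), runs
#' the full reference-frame + arch-axes + classification pipeline on every
#' case, and returns the classified fractions on each axis together with the
#' planted truth.
#'
#' @param n_pairs total number of pairs to simulate; default 3900.
#' @param seed integer seed for the whole study.
#' @param cfg generator configuration; default [default_config()].
#' @return list with `pairs` (classification table), `truth` (planted
#'   labels), and `fractions`: named vector of classified proportions
#'   (coronal, distal, lingual, inverse).
#' @export
simulate_position_study <- function(n_pairs = 3900, seed = 1, cfg = default_config()) {
  per_case <- 15L
  n_cases <- ceiling(n_pairs / per_case)
  counts <- rep(per_case, n_cases)
  counts[n_cases] <- n_pairs - per_case * (n_cases - 1L)
  cfg$seed <- as.integer(seed)
  cohort <- generate_cohort(cfg, n_cases, counts = counts)
  pairs <- do.call(rbind, c(lapply(cohort, function(cs) classify_dentition(cs$dentition)),
                            list(make.row.names = FALSE)))
  truth <- do.call(rbind, c(lapply(cohort, `[[`, "truth"),
                            list(make.row.names = FALSE)))
  fractions <- c(coronal = mean(pairs$vertical == "coronal"),
                 distal = mean(pairs$mesiodistal == "distal"),
                 lingual = mean(pairs$labiolingual == "lingual"),
                 inverse = mean(pairs$inclination_deg < 0))
  list(pairs = pairs, truth = truth, fractions = fractions)
}
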