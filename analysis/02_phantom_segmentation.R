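#!/usr/bin/env Rscript
# Render CBCT-like phantoms of supernumerary-free dentitions, segment them by
# threshold + 26-connected components, and compare the recovered tooth count
# and root lengths against the planted values. Demonstrates the robustness of
# the segmentation path; the precise analysis runs on digitized landmarks
# (03-05). Reads nothing; writes results/phantom/.

suppressPackageStartupMessages(library(supradent3d))

out_dir <- "results/phantom"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

rows <- list()
for (seed in 1:5) {
  cfg <- default_config()
  cfg$seed <- seed
  cfg$n_supernumerary <- 0L   # touching supernumerary pairs merge under
                              # thresholding; see the methods vignette
  gen <- generate_dentition(cfg, case_id = sprintf("phantom-%02d", seed))
  v <- render_phantom(gen$dentition, spacing_mm = 0.6)
  seg <- threshold_segment(v, threshold = 800)
  est <- lapply(seq_len(seg$n_labels), function(i) {
    sel <- which(seg$labels == i)
    k <- arrayInd(sel, dim(seg$labels))[, 3]
    z <- mean(seg$origin[3] + (k - 0.5) * seg$spacing[3])
    estimate_landmarks(seg, i, if (z > 4) "maxilla" else "mandible")
  })
  pl <- gen$dentition$teeth
  pl_oc <- do.call(rbind, lapply(pl, `[[`, "occlusal_center"))
  for (i in seq_along(est)) {
    mi <- which.min(colSums((t(pl_oc) - est[[i]]$occlusal_center)^2))
    rows[[length(rows) + 1L]] <- data.frame(
      case = gen$dentition$case_id, label = i,
      planted_id = pl[[mi]]$tooth_id,
      n_planted = length(pl), n_found = seg$n_labels,
      root_est = root_length(est[[i]]), root_planted = root_length(pl[[mi]]),
      crown_est = crown_length(est[[i]]), crown_planted = crown_length(pl[[mi]]))
  }
  if (seed == 1) write_volume(v, file.path(out_dir, "phantom-01.nii.gz"))
}
tab <- do.call(rbind, rows)
utils::write.csv(tab, file.path(out_dir, "segmentation_recovery.csv"), row.names = FALSE)

cat(sprintf("Tooth count recovered exactly in %d/%d phantoms\n",
            sum(tapply(tab$n_found == tab$n_planted, tab$case, all)),
            length(unique(tab$case))))
cat(sprintf("Root length:  Spearman rho = %.3f, mean |error| = %.2f mm (n = %d teeth)\n",
            cor(tab$root_est, tab$root_planted, method = "spearman"),
            mean(abs(tab$root_est - tab$root_planted)), nrow(tab)))
cat(sprintf("Crown length: Spearman rho = %.3f\n",
            cor(tab$crown_est, tab$crown_planted, method = "spearman")))
cat("Table written to", file.path(out_dir, "segmentation_recovery.csv"), "\n")
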