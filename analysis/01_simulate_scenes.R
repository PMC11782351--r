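#!/usr/bin/env Rscript
# Generate a gallery of synthetic scenes, write them as TIFF stacks with
# JSON manifests, and summarize the ground-truth morphometrics.
#
# Usage: Rscript analysis/01_simulate_scenes.R [--seed N]

suppressMessages(library(vstain))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if (length(i <- which(args == "--seed"))) args[i + 1] else 1)
out <- "results/scenes"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

specs <- list(
  pavement_convex = scene_spec(192, 192, n_cells = 12, lobe_amplitude = 0,
                               seed = child_seed(seed, "g1")),
  pavement_lobed = scene_spec(192, 192, n_cells = 12, lobe_amplitude = 6,
                              seed = child_seed(seed, "g2")),
  by2_file = scene_spec(192, 96, n_cells = 3, shape_model = "by2_file",
                        seed = child_seed(seed, "g3")),
  chloroplasts = scene_spec(192, 192, pixel_size_um = 0.28, n_cells = 8,
                            shape_model = "chloroplast_field",
                            seed = child_seed(seed, "g4")))

summary_rows <- list()
for (nm in names(specs)) {
  s <- generate_scene(specs[[nm]])
  write_scene(s, file.path(out, nm))
  mc <- measure_cells(s$labels, s$spec$pixel_size_um)
  cat(sprintf("%-16s %2d objects | mean area %7.1f um^2 | circ %.3f | sol %.3f\n",
              nm, nrow(mc), mean(mc$area_um2), mean(mc$circularity),
              mean(mc$solidity)))
  mc$scene <- nm
  summary_rows[[nm]] <- mc
}
truth <- do.call(rbind, summary_rows)
write.csv(truth, file.path(out, "ground_truth_morphometrics.csv"),
          row.names = FALSE)
cat("Scenes and ground-truth table written to", out, "\n")
cat("Lobed fields measure visibly lower solidity than convex ones,\n")
cat("the contrast the downstream agreement experiments rely on.\n")
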