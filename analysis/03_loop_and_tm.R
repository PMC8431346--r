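#!/usr/bin/env Rscript
# Loop flexibility and membrane contact; TM-helix tilt.
#
# Two synthetic conditions contrast a stiff loop (narrow prescribed Rg
# spread, both probe glycines in bulk solvent) with a flexible
# membrane-engaged loop (broader Rg spread, Gly-21 held at the phosphate
# plane). Distributions are taken over the 2.25-5.0 us window. The TM
# tilt series is summarized for both; the anchor runs N-to-C downward, so
# its axis deviation angle sits near 180 deg minus the geometric tilt.

suppressMessages(library(memgroove))
dir.create("results", showWarnings = FALSE)

toy <- make_anchored_toy()
slab <- make_membrane_slab()
n <- 500; dt <- 0.01
times <- (seq_len(n) - 1) * dt

conds <- list(
  pc_like = list(rg = withr::with_seed(21, rnorm(n, 10, 0.35)),
                 z21 = rep(12, n), z70 = rep(15, n)),
  tocl_like = list(rg = withr::with_seed(22, rnorm(n, 10, 1.2)),
                   z21 = rep(0, n), z70 = rep(0, n)))

rows <- list()
for (nm in names(conds)) {
  cd <- conds[[nm]]
  gen <- make_rigid_body_trajectory(toy, slab, schedule_constant(100),
                                    n_frames = n, dt_us = dt, loop_rg = cd$rg,
                                    z_targets = list(`21` = cd$z21, `70` = cd$z70))
  tr <- gen$trajectory
  w <- function(df) select_interval(df, 2.25, 5.0)
  rg <- w(rg_series(tr))$rg_A
  z21 <- w(residue_z_series(tr, 21))$z_A
  z70 <- w(residue_z_series(tr, 70))$z_A
  psi <- select_interval(tm_tilt_series(tr), 2.25, 5.0)$values
  rows[[nm]] <- data.frame(condition = nm, rg_mean_A = mean(rg),
                           rg_sd_A = sd(rg), z21_mean_A = mean(z21),
                           z70_mean_A = mean(z70), psi_mean_deg = mean(psi))
  cat(sprintf("%-9s Rg %5.2f +/- %4.2f A | Gly-21 z %5.1f A | Gly-70 z %5.1f A | psi %6.1f deg\n",
              nm, mean(rg), sd(rg), mean(z21), mean(z70), mean(psi)))
}
tab <- do.call(rbind, rows)
write.table(tab, "results/loop_tm_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("the tocl_like condition shows the broader Rg distribution and a\n")
cat("plane-centered Gly-21, mirroring a membrane-engaged flexible loop.\n")
cat("wrote results/loop_tm_summary.tsv\n")
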