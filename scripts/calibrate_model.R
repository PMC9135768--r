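#!/usr/bin/env Rscript
# Calibration of the CPG rhythm parameters.
#
# The current-to-swim-frequency map of the network is anchored at
#   0 nA -> no rhythm, 0.13 -> 6 Hz, 0.15 -> 7 Hz, 0.16 -> 8 Hz,
#   0.3 -> 12 Hz   (each within +/- 0.5 Hz).
# The map is shaped by three ingredients (see the methods vignette):
#   * fast spike-triggered adaptation in dIN (adapt_increment / adapt_tau)
#     sets the concave onset of the f-I curve,
#   * slow adaptation (adapt2_increment / adapt2_tau) linearizes and caps
#     the high end,
#   * a tonic dIN background drive (bias_pa) positions the curve on the
#     current axis.
# This script searches a neighbourhood of the shipped defaults over the
# two most sensitive dials (bias_pa, adapt2_increment) and reports the
# best configuration; run it after any change to the membrane templates
# or the commissural inhibition.
#
# Usage: Rscript scripts/calibrate_model.R [--fine]

suppressMessages(library(tadgaze))

args <- commandArgs(trailingOnly = TRUE)
fine <- "--fine" %in% args

anchor_error <- function(cfg) {
  net <- build_default_network(cfg)
  s1 <- simulate_network(net, list(stim_step("dIN", 0.15)), 5)
  s2 <- simulate_network(net, list(stim_step("dIN", 0.16),
                                   stim_sinusoid(c("VO", "VS"), 0.1, 1)), 5)
  s3 <- simulate_network(net, list(stim_step("dIN", 0.13),
                                   stim_sinusoid(c("VO", "VS"), 0.1, 1)), 5)
  s4 <- simulate_network(net, list(stim_step("dIN", 0.3)), 5)
  f <- c(motoneuron_burst_frequency(s1, "spMN_L"),
         motoneuron_burst_frequency(s2, "AbdMN_L"),
         motoneuron_burst_frequency(s3, "spMN_L"),
         motoneuron_burst_frequency(s4, "spMN_L"))
  list(freqs = f, err = max(abs(f - c(7, 8, 6, 12))))
}

base <- default_model_config()
bias_grid <- if (fine) seq(60, 72, by = 2) else c(62, 66, 70)
z2_grid <- if (fine) seq(0.46, 0.58, by = 0.02) else c(0.48, 0.52, 0.56)

best <- NULL
for (b in bias_grid) for (z2 in z2_grid) {
  cfg <- base
  cfg$membrane$dIN$bias_pa <- b
  cfg$membrane$dIN$adapt2_increment <- z2
  res <- anchor_error(cfg)
  cat(sprintf("bias=%2d adapt2_inc=%.2f -> f = %s (max err %.2f Hz)\n",
              b, z2, paste(sprintf("%.2f", res$freqs), collapse = "/"),
              res$err))
  if (is.null(best) || res$err < best$err)
    best <- list(bias = b, z2 = z2, err = res$err, freqs = res$freqs)
}

cat(sprintf("\nBest: bias_pa = %d, adapt2_increment = %.2f (max anchor error %.2f Hz)\n",
            best$bias, best$z2, best$err))
cat("Anchors (0.15/0.16/0.13/0.3 nA):",
    paste(sprintf("%.2f", best$freqs), collapse = " / "), "Hz\n")
if (best$err > 0.5)
  stop("no configuration in the searched neighbourhood meets the anchors; ",
       "widen the grid or revisit the membrane templates")
cat("Update inst/extdata/default_model.yaml with these values if they differ.\n")
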