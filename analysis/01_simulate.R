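#!/usr/bin/env Rscript
# Step 1: generate the synthetic collagen families used by the analysis.
#
# Two families emulate the published study conditions:
#   * a 19-chain family whose lysine-free C-telopeptide stretches (main-helix
#     end to cross-linking K) total 275 residues;
#   * a 14-chain family whose N-telopeptide stretches (minor-helix end to K)
#     total 176 residues.
# A third, default 19-chain family (with 2% substitution noise) exercises
# the scanners under realistic sequence divergence.

suppressPackageStartupMessages(library(colxlink))

seed <- 20160901L
out <- "results/families"

spec_c <- synthetic_spec(seed = seed, n_chains = 19,
                         c_k_gap = c(rep(14L, 10), rep(15L, 9)))
run_simulate(spec_c, file.path(out, "c_telo_275"))
message("wrote 19-chain C-telopeptide family (275 lysine-free residues)")

spec_n <- synthetic_spec(seed = seed + 1L, n_chains = 14, n_telo_len = 16L,
                         n_k_gap = c(rep(11L, 3), rep(13L, 11)))
run_simulate(spec_n, file.path(out, "n_telo_176"))
message("wrote 14-chain N-telopeptide family (176 lysine-free residues)")

spec_noisy <- synthetic_spec(seed = seed + 2L, n_chains = 19,
                             substitution_rate = 0.02)
run_simulate(spec_noisy, file.path(out, "noisy_02"))
message("wrote 19-chain family with 2% substitution noise")
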