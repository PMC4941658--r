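#!/usr/bin/env Rscript
# Step 1: generate the working dataset.
#
# Emulates a ten-tissue MSAP survey: 10,000 CCGG loci grouped into primer
# pairs, per-tissue biochemical class frequencies in the observed ranges,
# an 18% monomorphic locus block, and log-normal expression in which
# hemi-methylation suppresses transcription more strongly than full
# methylation. Writes the dual-lane band matrix, the biochemical truth in
# called-state space, and the expression table.

library(msapr)
dir.create("results", showWarnings = FALSE)

cfg <- simulation_config(n_loci = 10000, seed = 20160712 %% 10000)
gen <- generate_band_matrix(cfg)
expr <- generate_expression(gen$truth_states, cfg, seed = cfg$seed + 1)

write_band_matrix(gen$bands, "results/bands.tsv")
write_state_matrix(gen$truth_states, "results/truth_states.tsv")
write_expression(expr, "results/expression.tsv")

cat(sprintf("simulated %d loci x %d tissues (%d primer pairs)\n",
            cfg$n_loci, length(cfg$samples),
            length(unique(gen$bands$loci$primer_pair))))
cat(sprintf("true class mix (pooled): %s\n",
            paste(names(table(gen$truth_biochem)),
                  round(100 * table(gen$truth_biochem) /
                          length(gen$truth_biochem), 1),
                  sep = "=", collapse = "% ")))
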