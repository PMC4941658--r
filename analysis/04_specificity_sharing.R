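#!/usr/bin/env Rscript
# Step 4: methylation breadth (tau), tissue-specific loci and shared loci.

library(msapr)

states <- read_state_matrix("results/states.tsv")

tt <- tau_table(states)
utils::write.table(tt, "results/tau.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
cat(sprintf("tau over %d loci: %d uniformly methylated (tau = 1), %d with\n",
            nrow(tt), sum(tt$tau == 1, na.rm = TRUE),
            sum(tt$tau == 0, na.rm = TRUE)))
cat(sprintf("  single-tissue methylation (tau = 0); %d never methylated (NA)\n",
            sum(is.na(tt$tau))))

spec <- specific_sites(states, "METHYLATED")
utils::write.table(spec$per_sample, "results/specific_sites.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("tissue-specific methylation: %d loci (%.2f%% of all loci)\n",
            spec$total, spec$fraction))
for (cl in c("HEMI", "FULL")) {
  s <- specific_sites(states, cl)
  cat(sprintf("  %s-specific total: %d\n", cl, s$total))
}

organs <- c("youngLeaf", "matureLeaf", "root", "maleCatkin", "femaleCatkin")
tissues <- c("shootApex", "phloem", "cambium", "developingXylem",
             "matureXylem")
sets <- list(organs = organs, tissues = tissues)
for (nm in names(sets)) {
  set <- sets[[nm]]
  cat(sprintf("\nshared among all five %s: methylated %d, full %d, hemi %d\n",
              nm,
              shared_sites(states, set, "METHYLATED"),
              shared_sites(states, set, "FULL"),
              shared_sites(states, set, "HEMI")))
}
venn <- venn_regions(states, organs, "METHYLATED")
utils::write.table(venn, "results/venn_organs.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cp <- common_pattern_fraction(states)
cat(sprintf("\ncommon identical pattern in every tissue: %d of %d methylated loci (%.2f%%)\n",
            cp$n_common, cp$n_methylated_loci, cp$fraction))
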