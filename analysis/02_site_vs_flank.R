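#!/usr/bin/env Rscript
# Stage 2: conservation of ubiquitination sites versus flanking regions.
#
# Pools all sites and all flank residues per organism, estimates
# Poisson-corrected distances for both regions, tests them with a z-score
# per organism, and combines the z-scores into one chi-square statistic.
# Negative z: sites more conserved than their background.

suppressPackageStartupMessages(library(ubisitevol))

bundle <- read_bundle("results/data")
obs <- rbind(site_observations(bundle), flank_observations(bundle))
tab <- site_flank_table(obs, bundle$organism_order)

write.table(tab$per_organism, "results/site_flank.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

po <- tab$per_organism
cat("organism          d_site  d_flank       z  stars\n")
for (i in seq_len(nrow(po)))
  cat(sprintf("%-16s %7.4f  %7.4f  %6.2f  %s\n", po$organism[i],
              po$d_site[i], po$d_flank[i], po$z[i], po$stars[i]))
cat(sprintf("combined: chi2 = %.1f (df %d), p = %.3g, mean z = %.2f\n",
            tab$combined$statistic, tab$combined$df, tab$combined$p_value,
            tab$combined$mean_z))
neg <- sum(po$z < 0)
cat(sprintf("%d of %d organisms show sites more conserved than flanks (z < 0)\n",
            neg, nrow(po)))
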