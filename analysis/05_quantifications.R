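#!/usr/bin/env Rscript
# Scalar quantifications: qPCR isoform fractions by 2^-dCt against the
# total transcript, and partner-specificity filtering of a label-free
# proteomics table with known spiked-in truth.

suppressMessages(library(cellmig))
dir.create("results", showWarnings = FALSE)

# Ct table: a rare short isoform (~0.1% of total) next to abundant long ones
ct <- data.frame(
  sample = "parental",
  target = c("total", "i1", "i2", "i3L", "i3S"),
  ct = c(20, 21.2, 20.9, 21.8, 20 + 9.9658))
fr <- qpcr_fractions(ct, total_target = "total")
fr$share <- isoform_shares(setNames(fr$fraction, fr$target))
write.csv(fr, "results/isoform_fractions.csv", row.names = FALSE)
cat("isoform fractions (2^-dCt) and proportioned shares:\n")
print(transform(fr, fraction = signif(fraction, 3), share = signif(share, 3)),
      row.names = FALSE)

# LFQ table with 8 true partners among 12 decoys
lfq <- gen_lfq_table(n_true = 8, n_decoys = 12, seed = 7)
partners <- partner_filter(lfq$table, min_reps = 2, min_peptides = 2)
write.csv(partners, "results/specific_partners.csv", row.names = FALSE)
cat(sprintf("partner filter: %d retained of %d proteins; recall %.0f%%, false positives %d\n",
            nrow(partners), nrow(lfq$table),
            100 * mean(lfq$truth %in% partners$protein),
            sum(!partners$protein %in% lfq$truth)))
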