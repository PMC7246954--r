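#!/usr/bin/env Rscript
# Position-specific amino-acid / codon biases, dipeptide bias and pair
# epistasis of the C-terminal region, on the non-redundant synthetic
# proteome from 01_simulate_proteome.R.

suppressMessages(library(ctermbias))
tab <- load_proteome("results/proteome/synthetic_nr.faa",
                     "results/proteome/synthetic_nr.fna",
                     "results/proteome/synthetic_nr.tsv")

bias_aa <- position_bias(tab, "aa", positions = -20:-1)
write.table(bias_aa, "results/bias_aa.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
k1 <- bias_aa[bias_aa$symbol == "K" & bias_aa$position == -1, ]
t1 <- bias_aa[bias_aa$symbol == "T" & bias_aa$position == -1, ]
message(sprintf(
  "position -1: K odds ratio %.2f (q = %.2g), T odds ratio %.2f (q = %.2g)",
  k1$odds_ratio, k1$q_value, t1$odds_ratio, t1$q_value))
kgrad <- bias_aa[bias_aa$symbol == "K" & bias_aa$position %in% -5:-1, ]
message("K gradient over -5..-1: ",
        paste(sprintf("%.2f", kgrad$odds_ratio[order(kgrad$position)]),
              collapse = " "))

bias_codon <- position_bias(tab, "codon", positions = -1, flag_power = FALSE)
write.table(bias_codon, "results/bias_codon.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
aaa <- bias_codon[bias_codon$symbol %in% c("AAA", "AAG"), ]
message("lysine codons at -1: AAA OR ", sprintf("%.2f", aaa$odds_ratio[1]),
        ", AAG OR ", sprintf("%.2f", aaa$odds_ratio[2]))

dip <- dipeptide_bias(tab)
write.table(dip, "results/bias_dipeptide.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

epi <- pair_epistasis(tab)
write.table(epi, "results/pair_epistasis.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
kk <- epi[epi$aa_m2 == "K" & epi$aa_m1 == "K", ]
message(sprintf(
  "KK epistasis: observed/expected ratio %.2f (injected 1.8, q = %.2g)",
  kk$ratio, kk$q_value))
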