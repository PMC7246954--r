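#!/usr/bin/env Rscript
# Codon bias at position -1 stratified by stop-codon context, with and
# without exclusion of genes whose downstream neighbour's start codon
# overlaps the stop codon; the third-base contrast quantifies the NNA
# preference attributable to those overlaps.

suppressMessages(library(ctermbias))
tab <- load_proteome("results/proteome/synthetic_nr.faa",
                     "results/proteome/synthetic_nr.fna",
                     "results/proteome/synthetic_nr.tsv")

for (excl in c(FALSE, TRUE)) {
  sc <- stop_context_bias(tab, exclude_overlap = excl, flag_power = FALSE)
  tag <- if (excl) "excl" else "all"
  for (stop in names(sc)) {
    write.table(sc[[stop]],
                sprintf("results/stop_context_%s_%s.tsv", stop, tag),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tb <- third_base_comparison(sc$TGA)
  shift <- tb$mean_log2_or_a[1] - tb$mean_log2_or_b[1]
  message(sprintf(
    "TGA context (%s): NNA vs other mean log2 OR shift %.2f (p = %.2g)",
    if (excl) "overlaps excluded" else "all genes", shift, tb$p[1]))
  write.table(tb, sprintf("results/stop_context_thirdbase_%s.tsv", tag),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
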