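#' Partition a protein sequence into N-terminal, bulk and C-terminal regions
#'
#' The N-terminal region (first `n_N` residues) is discarded from all bias
#' statistics to keep well-known start-proximal composition biases out of the
#' null; the bulk (middle) region provides the null composition against which
#' the C-terminal region (last `n_C` residues) is tested.
#'
#' @param aa_seq A single protein sequence.
#' @param n_N,n_C Lengths of the terminal regions (residues).
#' @return A list with elements `nterm`, `bulk`, `cterm`, or `NULL` (with a
#'   message) when the sequence leaves fewer than 2 bulk residues (length
#'   below `n_N + n_C + 2`) and is therefore excluded.
#' @export
partition_regions <- function(aa_seq, n_N = 20, n_C = 20) {
  len <- nchar(aa_seq)
  if (len < n_N + n_C + 2) {
    message("sequence of length ", len, " excluded (< ", n_N + n_C + 2, ")")
    return(NULL)
  }
  list(nterm = substr(aa_seq, 1L, n_N),
       bulk = substr(aa_seq, n_N + 1L, len - n_C),
       cterm = substr(aa_seq, len - n_C + 1L, len))
}

# sequences usable for terminal-vs-bulk statistics
usable_seqs <- function(seqs, n_N, n_C) {
  keep <- nchar(seqs) >= n_N + n_C + 2
  if (any(!keep)) message(sum(!keep), " sequence(s) too short for ",
                          "region partition, excluded")
  keep
}

# concatenate bulk substrings and count symbols; works for residues (k = 1)
# and for codons (on CDS strings, k = 3)
bulk_symbol_counts <- function(strings, from, to, k, alphabet) {
  stopifnot(all(to >= from - 1L))
  big <- paste(substr(strings, from, to), collapse = "")
  n <- nchar(big)
  if (n == 0L) return(stats::setNames(integer(length(alphabet)), alphabet))
  starts <- seq(1L, n, by = k)
  syms <- substring(big, starts, starts + k - 1L)
  table(factor(syms, levels = alphabet))
}

#' Position-specific composition bias of the C-terminal region
#'
#' For every symbol (amino acid or codon) and C-terminal position, compares
#' the count of the symbol at that position against the symbol's count in the
#' bulk region of the same sequences, using a two-sided Fisher's exact test on
#' the 2x2 table \[\[obs, obs_total - obs\], \[bulk, bulk_total - bulk\]\].
#' The unconditional sample odds ratio is reported (with `Inf`/`0` sentinels
#' for zero cells; no continuity correction). Benjamini-Hochberg correction is
#' applied across all cells of the returned table, which forms one
#' multiple-testing family.
#'
#' @param x A `gene_table` (required for `alphabet = "codon"`) or a character
#'   vector of protein sequences.
#' @param alphabet `"aa"` (20 amino acids) or `"codon"` (sense codons of the
#'   codon table(s) in force; TGA is included when table 4 is in use, where it
#'   codes for tryptophan).
#' @param positions Integer vector of C-terminal positions, -1 = last residue.
#' @param n_N,n_C Region sizes passed to the partition.
#' @param fdr False-discovery-rate threshold for the `significant` flag.
#' @param flag_power Whether to compute the `underpowered` flag (see
#'   [flag_underpowered()]).
#' @return A `bias_table` data.frame with columns `symbol`, `position`,
#'   `obs_count`, `obs_total`, `bulk_count`, `bulk_total`, `odds_ratio`,
#'   `p_value`, `q_value`, `significant`, `underpowered`.
#' @export
position_bias <- function(x, alphabet = c("aa", "codon"), positions = -20:-1,
                          n_N = 20, n_C = 20, fdr = 0.05, flag_power = TRUE) {
  alphabet <- match.arg(alphabet)
  positions <- sort(unique(as.integer(positions)))
  stopifnot(all(positions < 0), all(-positions <= n_C))
  if (is.character(x)) {
    if (alphabet == "codon") stop("codon alphabet requires a gene_table")
    seqs <- x
  } else {
    seqs <- x$aa_seq
  }
  keep <- usable_seqs(seqs, n_N, n_C)
  if (!any(keep)) stop("no sequence survives the region partition")
  seqs <- seqs[keep]
  len <- nchar(seqs)

  if (alphabet == "aa") {
    symbols <- AA20
    obs <- sapply(positions, function(p) {
      table(factor(substr(seqs, len + p + 1L, len + p + 1L), levels = symbols))
    })
    bulk <- bulk_symbol_counts(seqs, n_N + 1L, len - n_C, 1L, symbols)
  } else {
    cds <- x$cds_seq[keep]
    tables <- unique(x$codon_table[keep])
    symbols <- sort(unique(unlist(lapply(tables, sense_codons))))
    obs <- sapply(positions, function(p) {
      i <- 3L * (len + p) + 1L
      table(factor(substr(cds, i, i + 2L), levels = symbols))
    })
    bulk <- bulk_symbol_counts(cds, 3L * n_N + 1L, 3L * (len - n_C), 3L,
                               symbols)
  }
  colnames(obs) <- positions
  bulk_total <- sum(bulk)
  if (bulk_total == 0L) stop("bulk region is empty; cannot form a null")

  cells <- expand.grid(symbol = symbols, position = positions,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells$obs_count <- as.integer(obs[cbind(match(cells$symbol, symbols),
                                          match(cells$position, positions))])
  cells$obs_total <- length(seqs)
  cells$bulk_count <- as.integer(bulk[cells$symbol])
  cells$bulk_total <- bulk_total
  finish_bias_table(cells, fdr, flag_power)
}

# shared tail of all bias tables: OR, Fisher p, BH q, flags
finish_bias_table <- function(cells, fdr, flag_power) {
  a <- cells$obs_count; b <- cells$obs_total - cells$obs_count
  c_ <- cells$bulk_count; d <- cells$bulk_total - cells$bulk_count
  # doubles avoid integer overflow on proteome-scale margins
  cells$odds_ratio <- (as.numeric(a) * as.numeric(d)) /
    (as.numeric(b) * as.numeric(c_))       # Inf/0/NaN sentinels intended
  cells$p_value <- vapply(seq_len(nrow(cells)), function(i) {
    stats::fisher.test(matrix(c(a[i], b[i], c_[i], d[i]), 2L,
                              byrow = TRUE))$p.value
  }, numeric(1))
  cells$q_value <- stats::p.adjust(cells$p_value, method = "BH")
  cells$significant <- cells$q_value < fdr
  cells$underpowered <- if (flag_power) {
    mapply(flag_underpowered, cells$obs_total, cells$bulk_count,
           cells$bulk_total)
  } else NA
  class(cells) <- c("bias_table", "data.frame")
  cells
}

# fast two-sided Fisher p for a 2x2 table, by direct summation of the
# hypergeometric pmf with the same minimum-likelihood rule and 1e-7 relative
# tolerance as stats::fisher.test; used only inside power searches, where
# fisher.test would be called thousands of times per table cell
fisher_p2 <- function(a, b, c, d) {
  K <- a + b; n <- a + c; N <- a + b + c + d
  supp <- max(0L, n - (N - K)):min(K, n)
  probs <- stats::dhyper(supp, K, N - K, n)
  obs <- probs[supp == a]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

#' Flag statistically underpowered bias cells
#'
#' A cell is underpowered when even a 2-fold depletion could not reach
#' significance: we find the minimal expected C-terminal count `m*` such that
#' observing half of it (odds ratio 0.5 against the bulk) would give a
#' two-sided Fisher p below `alpha`, and flag the cell when its actual
#' expected count `obs_total * bulk_freq` falls below `m*`. Rare symbols
#' (e.g. cysteine in small groups) typically trigger the flag.
#'
#' @param obs_total Number of sequences contributing to the terminal position.
#' @param bulk_count,bulk_total Bulk occurrences of the symbol and bulk size.
#' @param alpha Significance level of the power criterion.
#' @return `TRUE` when the cell is underpowered.
#' @export
flag_underpowered <- function(obs_total, bulk_count, bulk_total,
                              alpha = 0.05) {
  f <- bulk_count / bulk_total
  if (f == 0) return(TRUE)
  p_at <- function(m) {
    obs <- as.integer(round(0.5 * m))
    fisher_p2(obs, obs_total - obs, bulk_count, bulk_total - bulk_count)
  }
  # doubling search for some m reaching significance, then linear refinement
  hi <- 1L
  while (hi <= obs_total && p_at(hi) >= alpha) hi <- hi * 2L
  if (hi > obs_total) return(TRUE)
  lo <- max(1L, hi %/% 2L)
  m_star <- hi
  for (m in lo:hi) {
    if (p_at(m) < alpha) { m_star <- m; break }
  }
  obs_total * f < m_star
}

#' Composition bias of the C-terminal dipeptide against bulk dipeptides
#'
#' The pair of residues at positions (-2, -1) of each sequence is compared to
#' the frequency of the same dipeptide among all overlapping two-residue
#' windows of the bulk regions, with Fisher tests and BH correction as in
#' [position_bias()].
#'
#' @inheritParams position_bias
#' @return A `bias_table` with `symbol` = dipeptide and `position` = -1.
#' @export
dipeptide_bias <- function(x, n_N = 20, n_C = 20, fdr = 0.05,
                           flag_power = FALSE) {
  seqs <- if (is.character(x)) x else x$aa_seq
  keep <- usable_seqs(seqs, n_N, n_C)
  if (!any(keep)) stop("no sequence survives the region partition")
  seqs <- seqs[keep]
  len <- nchar(seqs)
  symbols <- as.vector(outer(AA20, AA20, paste0))

  pairs <- paste0(substr(seqs, len - 1L, len - 1L), substr(seqs, len, len))
  obs <- table(factor(pairs, levels = symbols))

  big <- paste(substr(seqs, n_N + 1L, len - n_C), collapse = "|")
  ch <- strsplit(big, "", fixed = TRUE)[[1]]
  first <- ch[-length(ch)]; second <- ch[-1L]
  ok <- first != "|" & second != "|"
  bulk <- table(factor(paste0(first[ok], second[ok]), levels = symbols))

  cells <- data.frame(symbol = symbols, position = -1L,
                      obs_count = as.integer(obs),
                      obs_total = length(seqs),
                      bulk_count = as.integer(bulk),
                      bulk_total = sum(ok), stringsAsFactors = FALSE)
  finish_bias_table(cells, fdr, flag_power)
}

#' Epistasis between the last two C-terminal positions
#'
#' Tests, for every ordered amino-acid pair, whether the observed frequency
#' of the pair at positions (-2, -1) deviates from the product of the two
#' positional marginal frequencies computed on the same sequence set (the
#' independence null). Deviation is tested with a two-sided exact binomial
#' test (minimum-likelihood two-sidedness, as implemented by
#' [stats::binom.test()]), BH-corrected across the table.
#'
#' @inheritParams position_bias
#' @return An `epistasis_table` data.frame with columns `aa_m2`, `aa_m1`,
#'   `obs_count`, `n_sequences`, `expected_freq`, `ratio` (observed over
#'   expected frequency), `odds_ratio` (of the implied 2x2), `p_value`,
#'   `q_value`, `significant`.
#' @export
pair_epistasis <- function(x, n_N = 20, n_C = 20, fdr = 0.05) {
  seqs <- if (is.character(x)) x else x$aa_seq
  keep <- usable_seqs(seqs, n_N, n_C)
  seqs <- seqs[keep]
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  len <- nchar(seqs)
  n <- length(seqs)
  a2 <- substr(seqs, len - 1L, len - 1L)
  a1 <- substr(seqs, len, len)
  f2 <- table(factor(a2, levels = AA20)) / n
  f1 <- table(factor(a1, levels = AA20)) / n
  obs <- table(factor(a2, levels = AA20), factor(a1, levels = AA20))

  cells <- expand.grid(aa_m2 = AA20, aa_m1 = AA20,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells$obs_count <- as.integer(obs[cbind(cells$aa_m2, cells$aa_m1)])
  cells$n_sequences <- n
  cells$expected_freq <- as.numeric(f2[cells$aa_m2] * f1[cells$aa_m1])
  cells$ratio <- (cells$obs_count / n) / cells$expected_freq
  e_count <- n * cells$expected_freq
  cells$odds_ratio <- (cells$obs_count / (n - cells$obs_count)) /
    (e_count / (n - e_count))
  cells$p_value <- vapply(seq_len(nrow(cells)), function(i) {
    e <- cells$expected_freq[i]
    if (e == 0) {
      if (cells$obs_count[i] > 0) {
        message("pair ", cells$aa_m2[i], cells$aa_m1[i],
                " observed with zero expected frequency; p set to 0")
        return(0)
      }
      return(1)
    }
    stats::binom.test(cells$obs_count[i], n, e)$p.value
  }, numeric(1))
  cells$q_value <- stats::p.adjust(cells$p_value, method = "BH")
  cells$significant <- cells$q_value < fdr
  class(cells) <- c("epistasis_table", "data.frame")
  cells
}

#' Bias tables stratified by an external grouping
#'
#' Computes [position_bias()] independently within each group, against that
#' group's own bulk composition, with BH correction within each group's
#' table. Used for COG categories, subcellular localization, abundance bins
#' and taxonomic clades alike.
#'
#' @param tab A `gene_table`.
#' @param grouping Named character vector mapping `protein_id` to a group
#'   label; records without a label are ignored (their count is reported).
#' @inheritParams position_bias
#' @return Named list of `bias_table`s, one per group label.
#' @export
stratified_bias <- function(tab, grouping, alphabet = "aa", positions = -1,
                            n_N = 20, n_C = 20, fdr = 0.05,
                            flag_power = TRUE) {
  lab <- grouping[tab$protein_id]
  n_un <- sum(is.na(lab))
  if (n_un > 0) message(n_un, " unlabeled record(s) ignored")
  out <- list()
  for (g in sort(unique(stats::na.omit(lab)))) {
    sub <- tab[!is.na(lab) & lab == g, , drop = FALSE]
    out[[g]] <- position_bias(sub, alphabet = alphabet, positions = positions,
                              n_N = n_N, n_C = n_C, fdr = fdr,
                              flag_power = flag_power)
  }
  out
}

#' Label proteins by within-species abundance bin
#'
#' Proteins are labeled `low` (percentiles 0-20), `medium` (20-80) or `high`
#' (80-100) by the within-species percentile of their abundance. Species
#' where fewer than `coverage_min` of the proteins have an abundance value
#' are excluded entirely. When several abundance values map to one protein,
#' their mean is used.
#'
#' @param tab A `gene_table`.
#' @param ppm A data.frame with columns `protein_id` and `ppm` (possibly
#'   several rows per protein).
#' @param coverage_min Minimum fraction of a species' proteins with abundance.
#' @return Named character vector over the labeled `protein_id`s, suitable
#'   for [stratified_bias()].
#' @export
abundance_bins <- function(tab, ppm, coverage_min = 0.40) {
  stopifnot(all(ppm$ppm >= 0))
  avg <- tapply(ppm$ppm, ppm$protein_id, mean)
  out <- character(0)
  for (g in unique(tab$genome_id)) {
    ids <- tab$protein_id[tab$genome_id == g]
    have <- ids[ids %in% names(avg)]
    if (length(have) / length(ids) < coverage_min) {
      message("species ", g, " excluded: abundance coverage ",
              sprintf("%.0f%%", 100 * length(have) / length(ids)),
              " below ", sprintf("%.0f%%", 100 * coverage_min))
      next
    }
    v <- avg[have]
    pct <- stats::ecdf(v)(v)
    lab <- ifelse(pct <= 0.2, "low", ifelse(pct > 0.8, "high", "medium"))
    out <- c(out, stats::setNames(lab, have))
  }
  out
}

#' Codon bias at position -1 stratified by stop-codon context
#'
#' Sequences are classified by their stop codon, and the codon-level bias at
#' the last sense position is computed within each class against that class's
#' own bulk (BH within each class). With `exclude_overlap = TRUE`, genes in
#' the TGA class whose downstream neighbour's start codon overlaps the stop
#' codon (see [detect_downstream_start_overlap()]) are removed before the
#' computation, isolating the contribution of overlapping start codons to the
#' NNA codon preference.
#'
#' @param tab A `gene_table`.
#' @param exclude_overlap Drop overlap-flagged TGA-context genes first.
#' @inheritParams position_bias
#' @return Named list of codon `bias_table`s, one per stop codon present.
#' @export
stop_context_bias <- function(tab, exclude_overlap = FALSE, positions = -1,
                              n_N = 20, n_C = 20, fdr = 0.05,
                              flag_power = FALSE) {
  if (exclude_overlap) {
    flag <- detect_downstream_start_overlap(tab)
    drop <- tab$stop_codon == "TGA" & flag[tab$protein_id]
    if (any(drop)) message(sum(drop), " overlap-flagged TGA-context gene(s) ",
                           "excluded")
    tab <- tab[!drop, , drop = FALSE]
  }
  out <- list()
  for (sc in intersect(c("TAA", "TAG", "TGA"), unique(tab$stop_codon))) {
    sub <- tab[tab$stop_codon == sc, , drop = FALSE]
    if (nrow(sub) == 0L) next
    out[[sc]] <- position_bias(sub, alphabet = "codon", positions = positions,
                               n_N = n_N, n_C = n_C, fdr = fdr,
                               flag_power = flag_power)
  }
  out
}

#' Compare codon biases by third-base identity
#'
#' Partitions the codons of a codon-level bias table by their third
#' nucleotide and contrasts the distributions of log2 odds ratios with
#' two-sided independent (equal-variance) t-tests: NNA codons against all
#' others, and NNA against NNG. Cells with non-finite odds ratios are
#' dropped; a partition with fewer than two codons yields `NA` statistics.
#'
#' @param bias_table A codon-level `bias_table` (e.g. one class from
#'   [stop_context_bias()]).
#' @return A data.frame with one row per contrast: group sizes, mean log2
#'   odds ratios, t statistic and p-value.
#' @export
third_base_comparison <- function(bias_table) {
  lor <- log2(bias_table$odds_ratio)
  ok <- is.finite(lor)
  lor <- lor[ok]
  third <- substr(bias_table$symbol[ok], 3L, 3L)
  one <- function(name, a, b) {
    if (length(a) < 2L || length(b) < 2L) {
      return(data.frame(contrast = name, n_a = length(a), n_b = length(b),
                        mean_log2_or_a = mean(a), mean_log2_or_b = mean(b),
                        t = NA_real_, p = NA_real_))
    }
    tt <- group_compare(c(a, b), rep(c("a", "b"), c(length(a), length(b))))
    data.frame(contrast = name, n_a = length(a), n_b = length(b),
               mean_log2_or_a = mean(a), mean_log2_or_b = mean(b),
               t = tt$t, p = tt$p)
  }
  rbind(
    one("NNA_vs_other", lor[third == "A"], lor[third != "A"]),
    one("NNA_vs_NNG", lor[third == "A"], lor[third == "G"])
  )
}
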