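#' The fixed read template of the C-terminal reporter library
#'
#' The randomized region covers the last two sense codons (6 nt, `up6`) and
#' the 6 nt following the designed TAA stop codon (`down6`), embedded in
#' constant flanks: `CGCGAAAAAA` + up6 + `TAA` + down6 + `CAGGCCTTGA`.
#'
#' @return The 35-nt template string, with `N` at the randomized positions.
#' @export
elmseq_template <- function() "CGCGAAAAAANNNNNNTAANNNNNNCAGGCCTTGA"

template_parts <- function(template = elmseq_template()) {
  stopifnot(identical(gsub("[^N]", "", template),
                      strrep("N", 12L)))
  npos <- gregexpr("N+", template)[[1]]
  stopifnot(length(npos) == 2L, all(attr(npos, "match.length") == 6L))
  list(left = substr(template, 1L, npos[1] - 1L),
       mid = substr(template, npos[1] + 6L, npos[2] - 1L),
       right = substr(template, npos[2] + 6L, nchar(template)),
       up_at = npos[1], down_at = npos[2])
}

#' Tally template-matching reads into variant counts
#'
#' Reads are matched exactly against the fixed positions of the template (no
#' mismatch tolerance); the two randomized 6-mers are captured as the variant
#' key. Non-matching reads are counted and reported.
#'
#' @param fastq Path to a FASTQ file (plain or gzipped).
#' @param template Template string; see [elmseq_template()].
#' @return Data.frame with columns `up6`, `down6`, `count`; attribute
#'   `n_discarded` carries the number of non-matching reads.
#' @export
filter_reads <- function(fastq, template = elmseq_template()) {
  reads <- as.character(Biostrings::readDNAStringSet(fastq, format = "fastq"))
  tp <- template_parts(template)
  head <- substr(reads, 1L, nchar(template))
  pat <- paste0("^", tp$left, "([ACGT]{6})", tp$mid, "([ACGT]{6})", tp$right,
                "$")
  ok <- grepl(pat, head)
  up6 <- substr(head[ok], tp$up_at, tp$up_at + 5L)
  down6 <- substr(head[ok], tp$down_at, tp$down_at + 5L)
  n_disc <- sum(!ok)
  if (n_disc > 0L) message(n_disc, " read(s) discarded (template mismatch)")
  agg <- table(paste(up6, down6))
  key <- strsplit(names(agg), " ", fixed = TRUE)
  out <- data.frame(up6 = vapply(key, `[`, "", 1L),
                    down6 = vapply(key, `[`, "", 2L),
                    count = as.integer(agg), stringsAsFactors = FALSE)
  attr(out, "n_discarded") <- n_disc
  out
}

#' Combine per-sample tallies into one paired count table
#'
#' @param dpnI,mboI Count tables from [filter_reads()] (or any data.frame
#'   with `up6`, `down6`, `count`) for the DpnI- and MboI-digested samples.
#' @return Data.frame with `up6`, `down6`, `reads_dpnI`, `reads_mboI`
#'   (variants absent from one sample get 0).
#' @export
combine_counts <- function(dpnI, mboI) {
  m <- merge(dpnI, mboI, by = c("up6", "down6"), all = TRUE,
             suffixes = c("_dpnI", "_mboI"))
  m$reads_dpnI <- ifelse(is.na(m$count_dpnI), 0L, m$count_dpnI)
  m$reads_mboI <- ifelse(is.na(m$count_mboI), 0L, m$count_mboI)
  m[, c("up6", "down6", "reads_dpnI", "reads_mboI")]
}

#' Keep variants with enough reads in both enzyme-treated samples
#'
#' @param counts Paired count table (see [combine_counts()]).
#' @param min_reads Minimum read count required in each of the two samples.
#' @return Filtered count table.
#' @export
filter_min_reads <- function(counts, min_reads = 30) {
  keep <- counts$reads_dpnI >= min_reads & counts$reads_mboI >= min_reads
  out <- counts[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove variants whose local sequence contains a GATC site
#'
#' Extra GATC motifs inside the randomized region change the number of
#' methylation-sensitive restriction sites and bias the read ratio, so any
#' variant whose reconstructed local sequence (constant flanks + up6 + TAA +
#' down6), scanned across all junctions, contains `GATC` is dropped.
#'
#' @inheritParams filter_min_reads
#' @param template Template string defining the constant flanks.
#' @return Filtered count table.
#' @export
filter_gatc <- function(counts, template = elmseq_template()) {
  tp <- template_parts(template)
  full <- paste0(tp$left, counts$up6, tp$mid, counts$down6, tp$right)
  out <- counts[!grepl("GATC", full, fixed = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compute per-variant DAMratio and normalized expression effect
#'
#' The DAMratio of a variant is the ratio of its read proportions in the two
#' enzyme-digested samples, (dpnI / total dpnI) / (mboI / total mboI), with
#' totals over the retained variants; the proportion form makes the statistic
#' invariant to sequencing depth. The normalized effect R is the DAMratio
#' divided by the geometric mean over retained variants, so mean(log10 R) = 0.
#'
#' @param counts Filtered paired count table (every count positive).
#' @return A `damratio_table`: the input plus `damratio`, `norm_effect`,
#'   `log10_R`.
#' @export
compute_damratio <- function(counts) {
  stopifnot(nrow(counts) > 0L, all(counts$reads_dpnI > 0),
            all(counts$reads_mboI > 0))
  dr <- (counts$reads_dpnI / sum(counts$reads_dpnI)) /
    (counts$reads_mboI / sum(counts$reads_mboI))
  g <- exp(mean(log(dr)))
  counts$damratio <- dr
  counts$norm_effect <- dr / g
  counts$log10_R <- log10(counts$norm_effect)
  class(counts) <- c("damratio_table", "data.frame")
  counts
}

elmseq_levels <- c("nt_position", "codon_slot", "aa_slot", "aa_pair")

# symbol extraction per aggregation level; returns data.frame slot, symbol
# with one row per (variant, slot)
elmseq_symbols <- function(records, level, codon_table_id = 4) {
  up <- records$up6; down <- records$down6
  if (level == "nt_position") {
    slots <- c(paste0("-2.", 1:3), paste0("-1.", 1:3),
               paste0("+1.", 1:3), paste0("+2.", 1:3))
    sym <- cbind(
      do.call(cbind, lapply(1:6, function(i) substr(up, i, i))),
      do.call(cbind, lapply(1:6, function(i) substr(down, i, i))))
  } else {
    cod <- cbind(substr(up, 1L, 3L), substr(up, 4L, 6L),
                 substr(down, 1L, 3L), substr(down, 4L, 6L))
    if (level == "codon_slot") {
      slots <- c("-2", "-1", "+1", "+2")
      sym <- cod
    } else {
      code <- genetic_code(codon_table_id)
      aa <- matrix(code[cod[, 1:2]], ncol = 2L)
      if (level == "aa_slot") {
        slots <- c("-2", "-1")
        sym <- aa
      } else {                            # aa_pair
        slots <- "pair"
        sym <- matrix(paste0(aa[, 1L], aa[, 2L]), ncol = 1L)
      }
    }
  }
  list(slots = slots, sym = sym)
}

#' Aggregate variant effects by nucleotide, codon, amino acid or pair
#'
#' The effect of a symbol in a slot is 10^(mean of log10 R over all retained
#' variants carrying the symbol), re-centered so that the mean log-effect of
#' the symbols within each slot is zero. Codons at the in-frame slots -2 and
#' -1 are translated under `codon_table_id` (default 4: TGA is tryptophan);
#' TAA/TAG appear as the internal stop controls `*`. Slots +1 and +2 are the
#' two codons following the designed stop.
#'
#' @param records A `damratio_table` from [compute_damratio()].
#' @param level One of `"nt_position"`, `"codon_slot"`, `"aa_slot"`,
#'   `"aa_pair"`.
#' @param codon_table_id Genetic code for the amino-acid levels.
#' @param log_space Average in log space (default, consistent with the
#'   reported log10 DAMratio); `FALSE` averages the effects arithmetically
#'   before re-centering (sensitivity analysis).
#' @return Data.frame with columns `slot`, `symbol`, `n_variants`,
#'   `log10_effect`, `effect`; empty cells are reported with `n_variants = 0`
#'   and NA effects.
#' @export
aggregate_effects <- function(records, level = c("aa_slot", "codon_slot",
                                                 "nt_position", "aa_pair"),
                              codon_table_id = 4, log_space = TRUE) {
  level <- match.arg(level, elmseq_levels)
  es <- elmseq_symbols(records, level, codon_table_id)
  code <- genetic_code(codon_table_id)
  universe <- switch(level,
    nt_position = c("A", "C", "G", "T"),
    codon_slot = sort(names(code)),
    aa_slot = sort(unique(unname(code))),
    aa_pair = {
      aa <- sort(unique(unname(code)))
      as.vector(outer(aa, aa, paste0))
    })
  out <- NULL
  for (k in seq_along(es$slots)) {
    sym <- factor(es$sym[, k], levels = universe)
    n <- tapply(records$log10_R, sym, length)
    n[is.na(n)] <- 0L
    m <- if (log_space) {
      tapply(records$log10_R, sym, mean)
    } else {
      log10(tapply(records$norm_effect, sym, mean))
    }
    m <- m - mean(m, na.rm = TRUE)        # zero mean log-effect per slot
    out <- rbind(out, data.frame(slot = es$slots[k], symbol = names(m),
                                 n_variants = as.integer(n),
                                 log10_effect = as.numeric(m),
                                 effect = 10^as.numeric(m),
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Pairwise epistasis Q between the last two amino acids
#'
#' Under independence the expected effect of a pair is the product of the two
#' single-position effects, R_ind(aa-2, aa-1) = R(aa-2) * R(aa-1); the
#' cooperativity is Q = R_pair / R_ind, i.e. log10 Q = log10 R_pair -
#' log10 R(aa-2) - log10 R(aa-1).
#'
#' @param pair_effects `aa_pair`-level table from [aggregate_effects()].
#' @param slot_effects `aa_slot`-level table computed from the same records.
#' @return Data.frame with `aa_m2`, `aa_m1`, `R_pair`, `R_ind`, `Q`,
#'   `log10_Q` (NA when a marginal is missing).
#' @export
epistasis_q <- function(pair_effects, slot_effects) {
  e2 <- slot_effects[slot_effects$slot == "-2", ]
  e1 <- slot_effects[slot_effects$slot == "-1", ]
  aa2 <- substr(pair_effects$symbol, 1L, 1L)
  aa1 <- substr(pair_effects$symbol, 2L, 2L)
  r2 <- e2$effect[match(aa2, e2$symbol)]
  r1 <- e1$effect[match(aa1, e1$symbol)]
  out <- data.frame(aa_m2 = aa2, aa_m1 = aa1,
                    R_pair = pair_effects$effect,
                    R_ind = r2 * r1, stringsAsFactors = FALSE)
  out$Q <- out$R_pair / out$R_ind
  out$log10_Q <- log10(out$Q)
  out
}

#' Correlation of effects between two libraries
#'
#' Pearson correlation of log10 effects over the symbols shared between two
#' effect tables at the same aggregation level (e.g. weak vs strong promoter
#' libraries).
#'
#' @param effects_a,effects_b Effect tables from [aggregate_effects()].
#' @return Pearson correlation coefficient.
#' @export
cross_library_correlation <- function(effects_a, effects_b) {
  key_a <- paste(effects_a$slot, effects_a$symbol)
  key_b <- paste(effects_b$slot, effects_b$symbol)
  shared <- intersect(key_a[is.finite(effects_a$log10_effect)],
                      key_b[is.finite(effects_b$log10_effect)])
  if (length(shared) < 3L) stop("fewer than 3 shared symbols")
  stats::cor(effects_a$log10_effect[match(shared, key_a)],
             effects_b$log10_effect[match(shared, key_b)])
}

#' Range of pair effects
#'
#' @param pair_effects `aa_pair`-level table from [aggregate_effects()].
#' @return List with `max_pair`, `min_pair` (symbols) and `ratio` of the
#'   maximum to the minimum pair effect.
#' @export
fold_range <- function(pair_effects) {
  ok <- is.finite(pair_effects$effect)
  stopifnot(sum(ok) >= 2L)
  e <- pair_effects$effect[ok]; s <- pair_effects$symbol[ok]
  list(max_pair = s[which.max(e)], min_pair = s[which.min(e)],
       ratio = max(e) / min(e))
}
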