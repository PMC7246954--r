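#' Select triplets of closely related genomes from a dS table
#'
#' An ingroup pair must have synonymous distance dS in `ds_range` (preferring
#' values as close to the lower bound as possible, balancing substitution
#' counts against mutational saturation). The outgroup must lie at 1.2-2
#' times the ingroup distance from both ingroup members, preferring distances
#' near 1.5 times. At most one triplet is returned per genome cluster.
#'
#' @param ds A data.frame with columns `species_a`, `species_b`, `dS` and
#'   optionally `cluster` (without it, all species form one cluster).
#' @param ds_range Admissible ingroup dS interval.
#' @param out_range Admissible outgroup distance, as multiples of ingroup dS.
#' @param out_pref Preferred outgroup multiple.
#' @return A data.frame with one row per selected triplet: `in1`, `in2`,
#'   `out`, `ds_in`, `ds_out1`, `ds_out2`, `cluster`. Empty (with a message)
#'   when no valid triplet exists.
#' @export
select_triplets <- function(ds, ds_range = c(0.2, 1.0),
                            out_range = c(1.2, 2.0), out_pref = 1.5) {
  stopifnot(all(ds$dS >= 0))
  if (is.null(ds$cluster)) ds$cluster <- "all"
  empty <- data.frame(in1 = character(0), in2 = character(0),
                      out = character(0), ds_in = numeric(0),
                      ds_out1 = numeric(0), ds_out2 = numeric(0),
                      cluster = character(0))
  out <- empty
  for (cl in unique(ds$cluster)) {
    d <- ds[ds$cluster == cl, , drop = FALSE]
    sp <- sort(unique(c(d$species_a, d$species_b)))
    m <- matrix(NA_real_, length(sp), length(sp), dimnames = list(sp, sp))
    m[cbind(d$species_a, d$species_b)] <- d$dS
    m[cbind(d$species_b, d$species_a)] <- d$dS
    diag(m) <- 0

    pairs <- which(upper.tri(m) & m >= ds_range[1] & m <= ds_range[2],
                   arr.ind = TRUE)
    if (nrow(pairs) == 0L) next
    pri <- order(abs(m[pairs] - ds_range[1]),
                 sp[pairs[, 1L]], sp[pairs[, 2L]])
    chosen <- NULL
    for (k in pri) {
      i <- pairs[k, 1L]; j <- pairs[k, 2L]
      din <- m[i, j]
      cand <- setdiff(seq_along(sp), c(i, j))
      d1 <- m[cand, i]; d2 <- m[cand, j]
      ok <- !is.na(d1) & !is.na(d2) &
        d1 >= out_range[1] * din & d1 <= out_range[2] * din &
        d2 >= out_range[1] * din & d2 <= out_range[2] * din
      if (!any(ok)) next
      cand <- cand[ok]
      score <- abs((m[cand, i] + m[cand, j]) / 2 - out_pref * din)
      o <- cand[order(score, sp[cand])][1L]
      chosen <- data.frame(in1 = sp[i], in2 = sp[j], out = sp[o],
                           ds_in = din, ds_out1 = m[o, i], ds_out2 = m[o, j],
                           cluster = cl)
      break
    }
    if (!is.null(chosen)) out <- rbind(out, chosen)
  }
  if (nrow(out) == 0L) message("no valid triplet found")
  rownames(out) <- NULL
  out
}

#' Accept or reject a triplet alignment for C-terminal analysis
#'
#' C-terminal regions that vary in length between orthologs (stop-codon gain
#' or loss, frameshifts) are excluded by requiring the last three alignment
#' columns to be gap-free in all three sequences. Internal gaps are allowed.
#'
#' @param aln A list with aligned, equal-length sequences `seq_in1`,
#'   `seq_in2`, `seq_out` (gap character `-`).
#' @return `TRUE` iff the alignment passes.
#' @export
filter_alignment <- function(aln) {
  seqs <- c(aln$seq_in1, aln$seq_in2, aln$seq_out)
  len <- unique(nchar(seqs))
  stopifnot(length(len) == 1L, len >= 3L)
  !any(grepl("-", substr(seqs, len - 2L, len), fixed = TRUE))
}

#' Infer the ancestral state of one alignment column by 3-taxon parsimony
#'
#' On the tree ((in1, in2), out), only two column patterns are informative
#' under the minimum-change criterion with unambiguous placement: identical
#' states (no change), and a single ingroup member differing while the
#' outgroup matches the other ingroup member (one substitution on that
#' ingroup branch, ancestral state = the shared amino acid). All other
#' patterns -- outgroup differing from both ingroups (in1 == in2 != out
#' places the change ambiguously on the stem or outgroup branch), or three
#' distinct states -- are excluded.
#'
#' @param a_in1,a_in2,a_out Amino acids of the column (vectors accepted;
#'   recycled in parallel).
#' @return A data.frame with columns `status` (`"no_change"`,
#'   `"substitution"`, `"excluded"`), `ancestral`, `from`, `to`, `branch`
#'   (1 or 2).
#' @export
infer_ancestral <- function(a_in1, a_in2, a_out) {
  n <- max(length(a_in1), length(a_in2), length(a_out))
  a1 <- rep_len(a_in1, n); a2 <- rep_len(a_in2, n); ao <- rep_len(a_out, n)
  status <- rep("excluded", n)
  ancestral <- from <- to <- rep(NA_character_, n)
  branch <- rep(NA_integer_, n)

  same <- a1 == a2 & a2 == ao
  status[same] <- "no_change"
  ancestral[same] <- a1[same]

  s2 <- a1 == ao & a2 != ao            # change on the in2 branch
  status[s2] <- "substitution"
  ancestral[s2] <- ao[s2]; from[s2] <- ao[s2]; to[s2] <- a2[s2]
  branch[s2] <- 2L

  s1 <- a2 == ao & a1 != ao            # change on the in1 branch
  status[s1] <- "substitution"
  ancestral[s1] <- ao[s1]; from[s1] <- ao[s1]; to[s1] <- a1[s1]
  branch[s1] <- 1L

  data.frame(status = status, ancestral = ancestral, from = from, to = to,
             branch = branch, stringsAsFactors = FALSE)
}

position_labels <- function(max_pos) c(as.character(-seq_len(max_pos)), "bulk")

#' Count position-resolved amino-acid substitutions across triplet alignments
#'
#' Positions are measured as column offsets from the final alignment column
#' (last column = -1); columns beyond `-max_pos` are pooled into `"bulk"`.
#' Alignments failing [filter_alignment()] are skipped with a message; gapped
#' columns are skipped. For every retained column, [infer_ancestral()] either
#' contributes one ancestral-state site (plus, for substitution columns, one
#' i -> j event) or is excluded.
#'
#' @param alns List of triplet alignments (see [filter_alignment()]).
#' @param max_pos Number of distinct C-terminal positions to resolve.
#' @return A `substitution_counts` object: list with `sites` (matrix position
#'   x amino acid of ancestral-state site counts) and `subs` (array position
#'   x from x to of substitution counts).
#' @export
count_substitutions <- function(alns, max_pos = 20) {
  labs <- position_labels(max_pos)
  sites <- matrix(0L, length(labs), 20L, dimnames = list(labs, AA20))
  subs <- array(0L, c(length(labs), 20L, 20L),
                dimnames = list(labs, AA20, AA20))
  skipped <- 0L
  for (aln in alns) {
    if (!filter_alignment(aln)) { skipped <- skipped + 1L; next }
    c1 <- strsplit(aln$seq_in1, "", fixed = TRUE)[[1]]
    c2 <- strsplit(aln$seq_in2, "", fixed = TRUE)[[1]]
    co <- strsplit(aln$seq_out, "", fixed = TRUE)[[1]]
    L <- length(c1)
    gap <- c1 == "-" | c2 == "-" | co == "-"
    pos <- L - seq_len(L) + 1L            # 1 = last column
    lab <- ifelse(pos <= max_pos, as.character(-pos), "bulk")
    use <- which(!gap)
    res <- infer_ancestral(c1[use], c2[use], co[use])
    keep <- res$status != "excluded"
    li <- match(lab[use][keep], labs)
    ai <- match(res$ancestral[keep], AA20)
    nl <- length(labs)
    sites <- sites + matrix(tabulate(li + nl * (ai - 1L), nbins = nl * 20L),
                            nl, 20L)
    ev <- which(keep & res$status == "substitution")
    if (length(ev)) {
      li <- match(lab[use][ev], labs)
      fi <- match(res$from[ev], AA20)
      ti <- match(res$to[ev], AA20)
      idx <- li + nl * (fi - 1L) + nl * 20L * (ti - 1L)
      subs <- subs + array(tabulate(idx, nbins = nl * 400L), c(nl, 20L, 20L))
    }
  }
  if (skipped > 0L) message(skipped, " alignment(s) skipped (gaps in the ",
                            "last 3 columns)")
  structure(list(sites = sites, subs = subs, max_pos = max_pos),
            class = "substitution_counts")
}

#' Default amino-acid grouping for substitution-rate statistics
#'
#' Positively charged (K, R), hydrophobic (A, I, L, M, F, W, Y, V), threonine
#' alone, and the remaining amino acids; the partition used to pool
#' substitution counts into reliable per-position rates.
#'
#' @return Named list of character vectors partitioning the 20 amino acids.
#' @export
aa_groups <- function() {
  list(positive = c("K", "R"),
       hydrophobic = c("A", "I", "L", "M", "F", "W", "Y", "V"),
       T = "T",
       other = c("H", "D", "E", "N", "Q", "S", "P", "C", "G"))
}

#' Substitution rates between amino-acid groups per position
#'
#' The rate from group G to group H at position x is the number of i -> j
#' events with i in G, j in H (i != j) divided by the number of sites whose
#' ancestral state lies in G at x. All ordered group pairs (including
#' within-group) are reported.
#'
#' @param counts A `substitution_counts` object.
#' @param groups Named list partitioning the 20 amino acids.
#' @return Data.frame with columns `position`, `from_group`, `to_group`,
#'   `n_subs`, `n_sites`, `rate` (NA when the denominator is empty).
#' @export
group_rates <- function(counts, groups = aa_groups()) {
  stopifnot(setequal(unlist(groups), AA20),
            sum(lengths(groups)) == 20L)
  labs <- rownames(counts$sites)
  out <- expand.grid(position = labs, from_group = names(groups),
                     to_group = names(groups), KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  out$n_subs <- mapply(function(p, g, h) {
    sum(counts$subs[p, groups[[g]], groups[[h]]])
  }, out$position, out$from_group, out$to_group)
  out$n_sites <- mapply(function(p, g) {
    sum(counts$sites[p, groups[[g]]])
  }, out$position, out$from_group)
  out$rate <- ifelse(out$n_sites > 0, out$n_subs / out$n_sites, NA_real_)
  out
}

#' Compare a group substitution rate between two positions
#'
#' Builds the 2x2 table \[\[events_a, sites_a - events_a\],
#' \[events_b, sites_b - events_b\]\] for the G -> H substitution rate at the
#' two positions and applies a two-sided Fisher's exact test.
#'
#' @param counts A `substitution_counts` object.
#' @param pos_a,pos_b Position labels (e.g. "-1", "-2", "bulk") or integers.
#' @param group_from,group_to Group names from `groups`.
#' @param groups Amino-acid partition, as in [group_rates()].
#' @return List with `rate_a`, `rate_b`, `ratio` (rate_a / rate_b) and `p`.
#' @export
compare_positions <- function(counts, pos_a = -1, pos_b = -2,
                              group_from, group_to, groups = aa_groups()) {
  pa <- as.character(pos_a); pb <- as.character(pos_b)
  g <- groups[[group_from]]; h <- groups[[group_to]]
  ev <- c(sum(counts$subs[pa, g, h]), sum(counts$subs[pb, g, h]))
  si <- c(sum(counts$sites[pa, g]), sum(counts$sites[pb, g]))
  if (any(si == 0)) stop("zero ancestral-site denominator at one position")
  p <- stats::fisher.test(matrix(c(ev[1], si[1] - ev[1],
                                   ev[2], si[2] - ev[2]), 2L,
                                 byrow = TRUE))$p.value
  list(rate_a = ev[1] / si[1], rate_b = ev[2] / si[2],
       ratio = (ev[1] / si[1]) / (ev[2] / si[2]), p = p)
}
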