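# Independent oracles used across the suite. Each is a deliberately naive
# implementation (dynamic programming, exhaustive enumeration, direct pmf
# summation) kept separate from the package's own code paths.

# global-alignment identity with unit match score and free gaps (longest
# common subsequence), divided by the shorter length
oracle_identity <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  d <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d[i + 1L, j + 1L] <- max(d[i, j] + (x[i] == y[j]),
                               d[i, j + 1L], d[i + 1L, j])
    }
  }
  d[n + 1L, m + 1L] / min(n, m)
}

# two-sided Fisher exact p for [[a, b], [c, d]] by enumerating every table
# with the observed margins and summing the probabilities of those no more
# likely than the observed one (1e-7 relative tolerance, as in fisher.test)
oracle_fisher_p <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; k <- a + c
  supp <- max(0L, k - n2):min(n1, k)
  # log space keeps large-margin tables finite
  pr <- exp(lchoose(n1, supp) + lchoose(n2, k - supp) -
              lchoose(n1 + n2, k))
  min(1, sum(pr[pr <= pr[supp == a] * (1 + 1e-7)]))
}

# two-sided exact binomial p (minimum-likelihood rule)
oracle_binom_p <- function(x, n, p) {
  pr <- dbinom(0:n, n, p)
  min(1, sum(pr[pr <= pr[x + 1L] * (1 + 1e-7)]))
}

# Benjamini-Hochberg step-up: indices rejected at level alpha
oracle_bh_reject <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  below <- which(p[o] <= alpha * seq_len(m) / m)
  if (length(below) == 0L) return(integer(0))
  sort(o[seq_len(max(below))])
}

# exhaustive minimum-change classification of a 3-taxon column on the tree
# ((in1, in2), out): enumerate all 400 assignments of the two internal
# nodes, and call the column countable only when the minimal assignment is
# unique, needs at most one change, and places it on an ingroup branch
oracle_parsimony <- function(a1, a2, ao) {
  aa <- ctermbias:::AA20
  best <- Inf
  argmin <- list()
  for (r in aa) {
    for (m in aa) {
      cost <- (r != m) + (m != a1) + (m != a2) + (r != ao)
      if (cost < best) {
        best <- cost; argmin <- list(c(r, m))
      } else if (cost == best) {
        argmin <- c(argmin, list(c(r, m)))
      }
    }
  }
  if (best == 0L) {
    return(list(status = "no_change", ancestral = a1, from = NA, to = NA,
                branch = NA))
  }
  if (best > 1L || length(argmin) > 1L) {
    return(list(status = "excluded", ancestral = NA, from = NA, to = NA,
                branch = NA))
  }
  r <- argmin[[1]][1]; m <- argmin[[1]][2]
  if (m != a1) {
    return(list(status = "substitution", ancestral = m, from = m, to = a1,
                branch = 1L))
  }
  if (m != a2) {
    return(list(status = "substitution", ancestral = m, from = m, to = a2,
                branch = 2L))
  }
  # the single change sits on the stem or outgroup branch: direction unknown
  list(status = "excluded", ancestral = NA, from = NA, to = NA, branch = NA)
}

# small deterministic gene table built by hand (no generator involvement)
toy_gene_table <- function() {
  genes <- list(
    g1 = list(aa = "MKT", cds = "ATGAAAACC", stop = "TAA"),
    g2 = list(aa = "MKK", cds = "ATGAAAAAG", stop = "TGA"),
    g3 = list(aa = "MTL", cds = "ATGACTTTG", stop = "TAG")
  )
  start <- c(1, 100, 200)
  tab <- data.frame(
    protein_id = names(genes), genome_id = "toy", replicon = "chr",
    start = start, end = start + 11,
    strand = "+",
    stop_codon = vapply(genes, function(g) g$stop, ""),
    codon_table = 11,
    cog_category = NA, localization = NA, abundance_ppm = NA,
    taxon_lineage = NA,
    aa_seq = vapply(genes, function(g) g$aa, ""),
    cds_seq = vapply(genes, function(g) paste0(g$cds, g$stop), ""),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  class(tab) <- c("gene_table", "data.frame")
  tab
}
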