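#' Default bulk amino-acid frequencies for synthetic proteomes
#'
#' Approximate average composition of a bacterial proteome (E. coli-like),
#' renormalized to sum to 1; the null composition from which synthetic
#' sequences are drawn.
#'
#' @return Named numeric vector over the 20 amino acids.
#' @export
default_bulk_freq <- function() {
  f <- c(A = 0.095, C = 0.011, D = 0.054, E = 0.058, F = 0.039, G = 0.074,
         H = 0.022, I = 0.060, K = 0.044, L = 0.105, M = 0.028, N = 0.040,
         P = 0.044, Q = 0.044, R = 0.055, S = 0.058, T = 0.054, V = 0.070,
         W = 0.014, Y = 0.029)
  f / sum(f)
}

#' All-ones position-multiplier matrix
#'
#' Rows are amino acids, columns the C-terminal positions -20..-1. Entry
#' (a, p) multiplies the bulk frequency of `a` at position `p` (the column is
#' renormalized), so a value of 2 doubles the odds of seeing `a` there.
#'
#' @return 20 x 20 numeric matrix of ones with dimnames.
#' @export
mu_matrix <- function() {
  matrix(1, 20L, 20L, dimnames = list(AA20, as.character(-20:-1)))
}

#' Generate a synthetic proteome with injected C-terminal biases
#'
#' Sequences are sampled i.i.d. per position: bulk positions from
#' `bulk_freq`, the last 20 positions from `bulk_freq * mu[, pos]`
#' renormalized. An optional pairwise multiplier reshapes the joint
#' distribution of the last two residues (epistasis injection). Codons are
#' sampled per amino acid from `codon_usage` (uniform over synonymous codons
#' by default), genes are laid head-to-tail on one replicon, and verbatim
#' duplicate copies, too-short genes and stop-overlapping downstream starts
#' can be injected at known rates. All injected truth is returned in the
#' `"truth"` attribute.
#'
#' @param n_genes Number of base genes.
#' @param genome_id Genome identifier.
#' @param codon_table_id Genetic code (11 standard bacterial, 4 Mycoplasma).
#' @param bulk_freq Amino-acid frequency vector (sums to 1).
#' @param mu 20 x 20 multiplier matrix (see [mu_matrix()]); NULL = all ones.
#' @param pair_mult 20 x 20 multiplier over (aa at -2, aa at -1); NULL = no
#'   pair interaction.
#' @param codon_usage Named list: per amino acid, a probability vector over
#'   its synonymous codons; NULL = uniform.
#' @param stop_probs Named probabilities over the table's stop codons.
#' @param duplication_rate Fraction of genes copied verbatim (appended with
#'   id suffix `_d`).
#' @param short_frac Fraction of genes drawn short (20-49 residues).
#' @param overlap_frac Fraction of TGA-stop genes whose downstream
#'   neighbour's start codon is made to overlap their stop codon (the
#'   neighbour starts at the focal stop-codon start - 1; the focal last codon
#'   is switched to a synonymous NNA codon where one exists and the
#'   neighbour's first codon is forced to ATG).
#' @param len_meanlog,len_sdlog Log-normal length distribution parameters.
#' @param len_range Length truncation bounds (residues).
#' @param seed Optional RNG seed.
#' @return A `gene_table` with attribute `"truth"`.
#' @export
gen_proteome <- function(n_genes, genome_id = "synth1", codon_table_id = 11,
                         bulk_freq = default_bulk_freq(), mu = NULL,
                         pair_mult = NULL, codon_usage = NULL,
                         stop_probs = NULL, duplication_rate = 0,
                         short_frac = 0, overlap_frac = 0,
                         len_meanlog = log(250), len_sdlog = 0.35,
                         len_range = c(50, 2000), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(abs(sum(bulk_freq) - 1) < 1e-6, all(bulk_freq > 0),
            setequal(names(bulk_freq), AA20))
  bulk_freq <- bulk_freq[AA20]
  if (is.null(mu)) mu <- mu_matrix()
  stopifnot(all(mu > 0), identical(dim(mu), c(20L, 20L)))

  L <- as.integer(pmin(pmax(round(stats::rlnorm(n_genes, len_meanlog,
                                                len_sdlog)),
                            len_range[1]), len_range[2]))
  short_ids <- character(0)
  n_short <- round(short_frac * n_genes)
  if (n_short > 0) {
    idx <- sample.int(n_genes, n_short)
    L[idx] <- as.integer(sample(20:49, n_short, replace = TRUE))
    short_ids <- sprintf("g%05d", sort(idx))
  }
  ids <- sprintf("g%05d", seq_len(n_genes))

  # residues: bulk draw everywhere, then overwrite the last 20 positions
  N <- sum(L)
  ends <- cumsum(L)
  res <- sample(AA20, N, replace = TRUE, prob = bulk_freq)
  for (k in 1:20) {                      # k = 1 is position -1
    p <- bulk_freq * mu[, as.character(-k)]
    res[ends - k + 1L] <- sample(AA20, n_genes, replace = TRUE, prob = p / sum(p))
  }
  if (!is.null(pair_mult)) {
    stopifnot(all(pair_mult > 0), identical(dim(pair_mult), c(20L, 20L)))
    p2 <- bulk_freq * mu[, "-2"]; p1 <- bulk_freq * mu[, "-1"]
    joint <- outer(p2 / sum(p2), p1 / sum(p1)) * pair_mult
    cell <- sample.int(400L, n_genes, replace = TRUE, prob = joint / sum(joint))
    res[ends - 1L] <- AA20[(cell - 1L) %% 20L + 1L]
    res[ends] <- AA20[(cell - 1L) %/% 20L + 1L]
  }

  # codons per residue
  code <- genetic_code(codon_table_id)
  syn <- split(names(code)[code != "*"], code[code != "*"])
  codons <- character(N)
  for (a in AA20) {
    i <- which(res == a)
    u <- if (is.null(codon_usage)) NULL else codon_usage[[a]]
    cs <- syn[[a]]
    codons[i] <- if (length(cs) == 1L) cs else {
      sample(cs, length(i), replace = TRUE, prob = u)
    }
  }

  stops <- stop_codons(codon_table_id)
  if (is.null(stop_probs)) {
    stop_probs <- if ("TGA" %in% stops) {
      c(TAA = 0.63, TAG = 0.08, TGA = 0.29)
    } else c(TAA = 0.85, TAG = 0.15)
  }
  stopifnot(setequal(names(stop_probs), stops))
  stop_codon <- sample(names(stop_probs), n_genes, replace = TRUE,
                       prob = stop_probs)

  # overlap injection: chosen TGA genes get an NNA last codon and their
  # successor starts 4 nt inside them (ATG overlapping the TGA stop)
  overlap_ids <- character(0)
  if (overlap_frac > 0 && "TGA" %in% stops) {
    cand <- which(stop_codon == "TGA" & seq_len(n_genes) < n_genes)
    take <- sort(cand[sample.int(length(cand),
                                 round(overlap_frac * length(cand)))])
    for (i in take) {
      a <- res[ends[i]]
      nna <- syn[[a]][substr(syn[[a]], 3L, 3L) == "A"]
      if (length(nna)) codons[ends[i]] <- nna[1L]
      res[ends[i + 1L] - L[i + 1L] + 1L] <- "M"
      codons[ends[i + 1L] - L[i + 1L] + 1L] <- "ATG"
    }
    overlap_ids <- ids[take]
  }

  big_aa <- paste(res, collapse = "")
  big_nt <- paste(codons, collapse = "")
  aa_seq <- substring(big_aa, ends - L + 1L, ends)
  cds_seq <- paste0(substring(big_nt, 3L * (ends - L) + 1L, 3L * ends),
                    stop_codon)

  # coordinates: sequential layout, 50-nt gaps, except injected overlaps
  start <- integer(n_genes); end <- integer(n_genes)
  pos <- 1L
  for (i in seq_len(n_genes)) {
    start[i] <- pos
    end[i] <- pos + 3L * L[i] + 2L        # CDS incl. stop
    pos <- end[i] + 51L
    if (ids[i] %in% overlap_ids) pos <- end[i] - 3L
  }

  tab <- data.frame(protein_id = ids, genome_id = genome_id,
                    replicon = "chr1", start = start, end = end,
                    strand = "+", stop_codon = stop_codon,
                    codon_table = codon_table_id,
                    cog_category = NA_character_,
                    localization = NA_character_,
                    abundance_ppm = NA_real_, taxon_lineage = NA_character_,
                    aa_seq = aa_seq, cds_seq = cds_seq,
                    stringsAsFactors = FALSE)

  dup_ids <- character(0)
  if (duplication_rate > 0) {
    n_dup <- round(duplication_rate * n_genes)
    src <- sample.int(n_genes, n_dup)
    dup <- tab[src, , drop = FALSE]
    dup$protein_id <- paste0(dup$protein_id, "_d")
    shift <- max(tab$end) + 51L
    width <- dup$end - dup$start
    dup$start <- shift + c(0L, cumsum(width[-n_dup] + 51L))[seq_len(n_dup)]
    dup$end <- dup$start + width
    dup_ids <- dup$protein_id
    tab <- rbind(tab, dup)
  }
  rownames(tab) <- NULL
  class(tab) <- c("gene_table", "data.frame")
  attr(tab, "truth") <- list(bulk_freq = bulk_freq, mu = mu,
                             pair_mult = pair_mult, stop_probs = stop_probs,
                             dup_ids = dup_ids, short_ids = short_ids,
                             overlap_ids = overlap_ids, lengths = L)
  tab
}

#' Generate triplet alignments with position-dependent substitution rates
#'
#' An ancestral (root) sequence is sampled per orthogroup; each ingroup
#' sequence mutates every site independently from the root with its
#' position's probability, and the outgroup likewise at `p_out`. Mutations go
#' to a uniformly random different amino acid, except that at an optional
#' target position a fraction of mutations is redirected to a target residue
#' (directional influx injection). Alignments are gap-free, so every
#' generated triplet passes [filter_alignment()]. A machine-readable truth
#' table of all mutation events is attached.
#'
#' @param n_genes Number of orthogroups.
#' @param len Alignment length (columns).
#' @param anc_freq Ancestral amino-acid frequencies.
#' @param p_in Per-site substitution probability on each ingroup branch:
#'   scalar, or named vector over positions (`"-1"`..`"-20"`, `"bulk"`).
#' @param p_out Per-site substitution probability on the outgroup branch
#'   (defaults to 1.5 * p_in, mirroring the longer outgroup branch).
#' @param target_bias Optional list(position =, to =, prob =): at that
#'   position, each mutation is redirected to amino acid `to` with
#'   probability `prob`.
#' @param max_pos Number of distinct C-terminal positions (for the position
#'   labels of `p_in`).
#' @param seed Optional RNG seed.
#' @return List of alignments (each: `orthogroup_id`, `seq_in1`, `seq_in2`,
#'   `seq_out`) with attribute `"truth"` (events data.frame and parameters).
#' @export
gen_triplets <- function(n_genes, len = 60, anc_freq = default_bulk_freq(),
                         p_in = 0.02, p_out = NULL, target_bias = NULL,
                         max_pos = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labs <- position_labels(max_pos)
  expand_p <- function(p) {
    if (length(p) == 1L && is.null(names(p))) {
      return(stats::setNames(rep(p, length(labs)), labs))
    }
    stopifnot(all(names(p) %in% labs))
    out <- stats::setNames(rep(0, length(labs)), labs)
    out[names(p)] <- p
    out
  }
  p_in <- expand_p(p_in)
  if (is.null(p_out)) p_out <- pmin(1.5 * p_in, 0.99)
  p_out <- expand_p(p_out)
  stopifnot(all(p_in >= 0 & p_in < 1), all(p_out >= 0 & p_out < 1))
  anc_freq <- anc_freq[AA20] / sum(anc_freq[AA20])

  N <- n_genes * len
  colpos <- rep(len:1, n_genes)           # 1 = last column
  lab <- ifelse(colpos <= max_pos, as.character(-colpos), "bulk")
  site_p_in <- p_in[lab]
  site_p_out <- p_out[lab]
  root <- sample(AA20, N, replace = TRUE, prob = anc_freq)
  gene <- rep(seq_len(n_genes), each = len)

  mutate <- function(x, p) {
    hit <- stats::runif(N) < p
    y <- x
    i <- which(hit)
    if (length(i)) {
      # (idx - 1 + k) mod 20, k in 1..19: uniform over the other 19
      y[i] <- AA20[(match(x[i], AA20) - 1L +
                      sample.int(19L, length(i), replace = TRUE)) %% 20L + 1L]
      if (!is.null(target_bias)) {
        at <- i[lab[i] == as.character(target_bias$position) &
                  stats::runif(length(i)) < target_bias$prob &
                  x[i] != target_bias$to]
        y[at] <- target_bias$to
      }
    }
    y
  }
  in1 <- mutate(root, site_p_in)
  in2 <- mutate(root, site_p_in)
  out <- mutate(root, site_p_out)

  events <- NULL
  for (br in c("in1", "in2", "out")) {
    y <- get(br)
    i <- which(y != root)
    if (length(i) == 0L) next
    events <- rbind(events, data.frame(
      branch = br, gene = gene[i], position = lab[i], from = root[i],
      to = y[i], stringsAsFactors = FALSE))
  }

  ends <- seq_len(n_genes) * len
  mk <- function(x) substring(paste(x, collapse = ""), ends - len + 1L, ends)
  s1 <- mk(in1); s2 <- mk(in2); so <- mk(out)
  alns <- lapply(seq_len(n_genes), function(g) {
    list(orthogroup_id = sprintf("og%05d", g), seq_in1 = s1[g],
         seq_in2 = s2[g], seq_out = so[g])
  })
  attr(alns, "truth") <- list(events = events, p_in = p_in, p_out = p_out,
                              target_bias = target_bias, len = len)
  alns
}

#' Write / read triplet alignments as aligned FASTA plus a manifest
#'
#' One aligned FASTA per orthogroup (records in1, in2, out) and a manifest
#' TSV giving the file and the three record ids in order.
#'
#' @param alns List of alignments as produced by [gen_triplets()].
#' @param dir Output directory.
#' @return `write_triplets` invisibly returns the manifest path;
#'   `load_triplets` returns the list of alignments.
#' @export
write_triplets <- function(alns, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- data.frame(orthogroup_id = character(0), file = character(0))
  for (aln in alns) {
    f <- paste0(aln$orthogroup_id, ".afa")
    x <- Biostrings::AAStringSet(c(in1 = aln$seq_in1, in2 = aln$seq_in2,
                                   out = aln$seq_out))
    Biostrings::writeXStringSet(x, file.path(dir, f))
    manifest <- rbind(manifest,
                      data.frame(orthogroup_id = aln$orthogroup_id, file = f))
  }
  path <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_triplets
#' @param manifest Path to the manifest TSV.
#' @export
load_triplets <- function(manifest) {
  dir <- dirname(manifest)
  man <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(man)), function(i) {
    x <- as.character(Biostrings::readAAStringSet(file.path(dir,
                                                            man$file[i])))
    list(orthogroup_id = man$orthogroup_id[i], seq_in1 = unname(x["in1"]),
         seq_in2 = unname(x["in2"]), seq_out = unname(x["out"]))
  })
}

#' Generate paired methylation-digestion read counts with known effects
#'
#' Variant keys cover all 4096 combinations of the last two codons (`up6`)
#' crossed with `n_down6` random downstream 6-mers. The true expression of a
#' variant is the product of the per-slot amino-acid effects and the pair
#' interaction, E = e(-2) * e(-1) * q(pair); the designed internal stop
#' controls (`*` at -2 or -1) have effect `stop_effect`. Methylation follows
#' the saturating link m = E / (E + Km) (a monotone test-harness contract,
#' not a mechanistic model); reads are drawn multinomially with DpnI-sample
#' weights proportional to m and MboI-sample weights proportional to 1 - m,
#' at uniform variant abundance.
#'
#' @param e_m2,e_m1 Named multiplicative effect vectors over amino acids
#'   (missing entries default to 1).
#' @param q_pair Optional named vector of pair interactions, names like
#'   `"KK"` (aa at -2 then -1); missing pairs default to 1.
#' @param n_down6 Number of distinct downstream 6-mers.
#' @param reads_per_sample Sequencing depth of each enzyme-treated sample.
#' @param Km Half-saturation constant of the methylation link.
#' @param codon_table_id Genetic code for translating the two codons.
#' @param stop_effect Effect assigned to the internal stop controls.
#' @param seed Optional RNG seed.
#' @return Paired count table (`up6`, `down6`, `reads_dpnI`, `reads_mboI`)
#'   with attribute `"truth"`.
#' @export
gen_elmseq <- function(e_m2 = NULL, e_m1 = NULL, q_pair = NULL, n_down6 = 4,
                       reads_per_sample = 1e6, Km = 1, codon_table_id = 4,
                       stop_effect = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  code <- genetic_code(codon_table_id)
  cods <- names(code)
  up6 <- as.vector(outer(cods, cods, function(a, b) paste0(a, b)))
  nt <- c("A", "C", "G", "T")
  down6 <- unique(replicate(n_down6 * 3, paste(sample(nt, 6, TRUE),
                                               collapse = "")))[1:n_down6]
  grid <- expand.grid(up6 = up6, down6 = down6, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)

  fill <- function(e) {
    full <- stats::setNames(rep(1, length(unique(unname(code)))),
                            sort(unique(unname(code))))
    full["*"] <- stop_effect
    if (!is.null(e)) full[names(e)] <- e
    full
  }
  e2 <- fill(e_m2); e1 <- fill(e_m1)
  aa2 <- unname(code[substr(grid$up6, 1L, 3L)])
  aa1 <- unname(code[substr(grid$up6, 4L, 6L)])
  E <- e2[aa2] * e1[aa1]
  if (!is.null(q_pair)) {
    q <- q_pair[paste0(aa2, aa1)]
    E <- E * ifelse(is.na(q), 1, q)
  }
  m <- E / (E + Km)
  grid$reads_dpnI <- as.integer(stats::rmultinom(1L, reads_per_sample,
                                                 m / sum(m)))
  grid$reads_mboI <- as.integer(stats::rmultinom(1L, reads_per_sample,
                                                 (1 - m) / sum(1 - m)))
  attr(grid, "truth") <- list(E = unname(E), e_m2 = e2, e_m1 = e1,
                              q_pair = q_pair, Km = Km,
                              m = unname(m), aa_m2 = aa2, aa_m1 = aa1)
  grid
}

#' Expand a count table into FASTQ files
#'
#' Emits one read per count, embedded in the exact library template, in
#' shuffled order, as `dpnI.fastq` and `mboI.fastq` under `dir`.
#'
#' @param counts Paired count table (e.g. from [gen_elmseq()]).
#' @param dir Output directory.
#' @param template Template string; see [elmseq_template()].
#' @return Invisibly, named vector of the two paths.
#' @export
gen_elmseq_fastq <- function(counts, dir, template = elmseq_template()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tp <- template_parts(template)
  full <- paste0(tp$left, counts$up6, tp$mid, counts$down6, tp$right)
  paths <- c(dpnI = file.path(dir, "dpnI.fastq"),
             mboI = file.path(dir, "mboI.fastq"))
  for (s in c("dpnI", "mboI")) {
    n <- counts[[paste0("reads_", s)]]
    reads <- sample(rep(full, n))
    x <- Biostrings::DNAStringSet(stats::setNames(
      reads, sprintf("%s_%07d", s, seq_along(reads))))
    Biostrings::writeXStringSet(x, paths[[s]], format = "fastq")
  }
  invisible(paths)
}

#' Default degradation rates and steady states for the reporter variants
#'
#' Eight C-terminal extensions spanning the charged-to-hydrophobic range.
#' The two anchor rates are the printed extremes of the assay (fastest 0.26
#' per hour for L, slowest 0.072 for D); the remaining rates are interpolated
#' monotonically along the expression ordering. Steady states are the
#' relative expression levels (reference variant P = 1).
#'
#' @return List with named vectors `d` (per hour) and `X0`.
#' @export
default_reporter_params <- function() {
  list(d = c(NK = 0.10, K = 0.105, D = 0.072, T = 0.13, P = 0.14, F = 0.22,
             L = 0.26, WL = 0.24),
       X0 = c(NK = 1.38, K = 1.49, D = 2.04, T = 0.87, P = 1.00, F = 0.80,
              L = 0.70, WL = 0.40))
}

#' Generate shut-off luminescence time courses with known decay rates
#'
#' Luminescence is X0 * exp(-d t) with independent multiplicative log-normal
#' noise (sdlog = `cv`) at every point and replicate.
#'
#' @param d Named degradation rates per variant (per hour).
#' @param X0 Named initial (steady-state) luminescence per variant.
#' @param cv Multiplicative noise (sdlog of the log-normal).
#' @param replicates Number of replicates per variant.
#' @param times Measurement times (hours; must include 0).
#' @param cat_norm Normalization scalar per variant (recycled).
#' @param seed Optional RNG seed.
#' @return Data.frame `variant`, `replicate`, `time_h`, `luminescence`,
#'   `cat_norm`, with attribute `"truth"`.
#' @export
gen_luminescence <- function(d = default_reporter_params()$d,
                             X0 = default_reporter_params()$X0,
                             cv = 0.1, replicates = 3,
                             times = c(0, 2, 4, 6, 8), cat_norm = 1,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(d >= 0), cv >= 0, 0 %in% times,
            setequal(names(d), names(X0)))
  vars <- names(d)
  cat_norm <- rep_len(cat_norm, length(vars))
  names(cat_norm) <- vars
  out <- expand.grid(time_h = times, replicate = seq_len(replicates),
                     variant = vars, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)[, c(3, 2, 1)]
  noise <- if (cv > 0) exp(stats::rnorm(nrow(out), 0, cv)) else 1
  out$luminescence <- X0[out$variant] * exp(-d[out$variant] * out$time_h) *
    noise
  out$cat_norm <- cat_norm[out$variant]
  attr(out, "truth") <- list(d = d, X0 = X0, cv = cv)
  out
}
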