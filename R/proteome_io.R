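#' Load a proteome from protein FASTA + CDS FASTA + gene table
#'
#' Reads the three standard inputs, cross-references identifiers, checks that
#' every coding sequence translates exactly to its protein sequence under the
#' genetic code in force, and returns a validated, coordinate-sorted gene
#' table. Records that fail the translation-consistency check, or whose last
#' codon is not a stop under their codon table (e.g. pseudogenes), are dropped
#' with a message giving the reason; a missing cross-reference between the
#' files is a hard error.
#'
#' @param protein_fasta Path to a protein FASTA file.
#' @param cds_fasta Path to the matching CDS nucleotide FASTA (each CDS
#'   includes its stop codon).
#' @param gene_table Path to a TSV with columns `protein_id`, `genome_id`,
#'   `replicon`, `start`, `end`, `strand`, `stop_codon`, `codon_table`, and
#'   optionally `cog_category`, `localization`, `abundance_ppm`,
#'   `taxon_lineage`. Coordinates are 1-based inclusive and span the full CDS
#'   including the stop codon.
#' @param codon_table_id If non-NULL, overrides the `codon_table` column for
#'   all records.
#' @return A `gene_table`: a data.frame with one row per retained protein,
#'   columns as above plus `aa_seq` and `cds_seq`, sorted by
#'   (replicon, start).
#' @export
load_proteome <- function(protein_fasta, cds_fasta, gene_table,
                          codon_table_id = NULL) {
  prot <- Biostrings::readAAStringSet(protein_fasta)
  cds <- Biostrings::readDNAStringSet(cds_fasta)
  tab <- utils::read.delim(gene_table, stringsAsFactors = FALSE,
                           colClasses = c(protein_id = "character"))
  if (length(prot) == 0L || length(cds) == 0L || nrow(tab) == 0L) {
    stop("empty input: proteome has no records")
  }
  # FASTA description lines may carry annotations after the id
  names(prot) <- sub("\\s.*$", "", names(prot))
  names(cds) <- sub("\\s.*$", "", names(cds))

  ids <- tab$protein_id
  missing_prot <- setdiff(ids, names(prot))
  missing_cds <- setdiff(ids, names(cds))
  extra <- setdiff(union(names(prot), names(cds)), ids)
  if (length(missing_prot) || length(missing_cds) || length(extra)) {
    stop("cross-reference failure between FASTA and gene table; offending ids: ",
         paste(unique(c(missing_prot, missing_cds, extra)), collapse = ", "))
  }
  if (anyDuplicated(ids)) {
    stop("duplicated protein_ids in gene table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }

  tab$aa_seq <- as.character(prot[ids])
  tab$cds_seq <- as.character(cds[ids])
  if (!is.null(codon_table_id)) tab$codon_table <- codon_table_id
  if (is.null(tab$codon_table)) tab$codon_table <- 11L

  keep <- rep(TRUE, nrow(tab))
  reason <- character(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    n <- nchar(tab$cds_seq[i])
    if (n %% 3L != 0L || n < 6L) {
      keep[i] <- FALSE; reason[i] <- "cds_length_not_multiple_of_3"
      next
    }
    last <- substr(tab$cds_seq[i], n - 2L, n)
    if (!(last %in% stop_codons(tab$codon_table[i]))) {
      keep[i] <- FALSE; reason[i] <- "no_stop_codon"
      next
    }
    codons <- cds_to_codons(substr(tab$cds_seq[i], 1L, n - 3L))
    aa <- paste(translate_codons(codons, tab$codon_table[i]), collapse = "")
    if (!identical(aa, tab$aa_seq[i]) || grepl("\\*", aa)) {
      keep[i] <- FALSE; reason[i] <- "translation_mismatch"
      next
    }
    tab$stop_codon[i] <- last
  }
  if (any(!keep)) {
    message(sum(!keep), " record(s) dropped: ",
            paste(sprintf("%s (%s)", tab$protein_id[!keep], reason[!keep]),
                  collapse = "; "))
    tab <- tab[keep, , drop = FALSE]
  }
  if (nrow(tab) == 0L) stop("no record passed validation")
  tab <- tab[order(tab$replicon, tab$start), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("gene_table", "data.frame")
  tab
}

#' Write a gene table back to FASTA + TSV
#'
#' Inverse of [load_proteome()]: emits `<prefix>.faa`, `<prefix>.fna` and
#' `<prefix>.tsv` into `dir`. Loading the written files reproduces the
#' sequences and coordinates byte-identically.
#'
#' @param tab A `gene_table`.
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix.
#' @return Invisibly, a named list of the three paths written.
#' @export
write_proteome <- function(tab, dir, prefix = "proteome") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    protein_fasta = file.path(dir, paste0(prefix, ".faa")),
    cds_fasta = file.path(dir, paste0(prefix, ".fna")),
    gene_table = file.path(dir, paste0(prefix, ".tsv"))
  )
  aa <- Biostrings::AAStringSet(stats::setNames(tab$aa_seq, tab$protein_id))
  nt <- Biostrings::DNAStringSet(stats::setNames(tab$cds_seq, tab$protein_id))
  Biostrings::writeXStringSet(aa, paths$protein_fasta)
  Biostrings::writeXStringSet(nt, paths$cds_fasta)
  cols <- setdiff(colnames(tab), c("aa_seq", "cds_seq"))
  utils::write.table(as.data.frame(tab)[, cols], paths$gene_table,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Pairwise sequence identity for redundancy clustering
#'
#' Identity is defined as the number of matched residues under a global
#' alignment with unit match score and free gaps (i.e. the longest common
#' subsequence), divided by the length of the shorter sequence. This is the
#' deterministic, desk-scale identity used by [deduplicate()]; it does not
#' reproduce CD-HIT's word-filter heuristics.
#'
#' @param a,b Protein sequences (single strings).
#' @return Identity fraction in \[0, 1\].
#' @export
seq_identity <- function(a, b) {
  if (identical(a, b)) return(1)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = unit_match_matrix(), gapOpening = 0, gapExtension = 0,
    type = "global", scoreOnly = TRUE)
  aln / min(nchar(a), nchar(b))
}

unit_match_matrix <- function() {
  alph <- Biostrings::AA_ALPHABET
  m <- matrix(0, length(alph), length(alph), dimnames = list(alph, alph))
  diag(m) <- 1
  m
}

#' Remove redundant paralogs by greedy two-step identity clustering
#'
#' Within each genome, sequences are first clustered greedily at
#' `full_threshold` identity over the whole sequence (each sequence, in
#' decreasing-length order, joins the first existing cluster whose
#' representative it matches, else founds a new one). Clusters with more than
#' one member are then re-clustered on their last `cterm_len` residues at
#' `cterm_threshold` identity. One representative is kept per final cluster:
#' the longest sequence, ties broken lexicographically by id.
#'
#' @param tab A `gene_table`, or a named character vector of protein
#'   sequences (then treated as one genome).
#' @param full_threshold Full-length identity threshold, in (0, 1\].
#' @param cterm_threshold C-terminal identity threshold, in (0, 1\].
#' @param cterm_len Number of C-terminal residues for the second step.
#' @return Object of the same type as `tab`, restricted to representatives
#'   (original order preserved).
#' @export
deduplicate <- function(tab, full_threshold = 0.80, cterm_threshold = 0.85,
                        cterm_len = 20) {
  stopifnot(full_threshold > 0, full_threshold <= 1,
            cterm_threshold > 0, cterm_threshold <= 1)
  if (is.character(tab)) {
    ids <- names(tab)
    if (is.null(ids)) ids <- as.character(seq_along(tab))
    keep <- dedup_one_genome(tab, ids, full_threshold, cterm_threshold,
                             cterm_len)
    return(tab[sort(match(keep, ids))])
  }
  keep_ids <- character(0)
  for (g in unique(tab$genome_id)) {
    sel <- tab$genome_id == g
    keep_ids <- c(keep_ids,
                  dedup_one_genome(tab$aa_seq[sel], tab$protein_id[sel],
                                   full_threshold, cterm_threshold, cterm_len))
  }
  out <- tab[tab$protein_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}

dedup_one_genome <- function(seqs, ids, full_threshold, cterm_threshold,
                             cterm_len) {
  ord <- order(-nchar(seqs), ids)
  seqs <- seqs[ord]; ids <- ids[ord]
  # step 1: greedy clustering on full sequences, comparing to representatives
  cluster <- integer(length(seqs))
  reps <- integer(0)       # index of representative (first = longest) member
  for (i in seq_along(seqs)) {
    assigned <- 0L
    for (k in seq_along(reps)) {
      if (seq_identity(seqs[i], seqs[reps[k]]) >= full_threshold) {
        assigned <- k; break
      }
    }
    if (assigned == 0L) {
      reps <- c(reps, i); assigned <- length(reps)
    }
    cluster[i] <- assigned
  }
  # step 2: within multi-member clusters, re-cluster the C-terminal tails
  keep <- character(0)
  for (k in seq_along(reps)) {
    members <- which(cluster == k)
    if (length(members) == 1L) {
      keep <- c(keep, ids[members])
      next
    }
    tails <- substr(seqs[members],
                    pmax(1L, nchar(seqs[members]) - cterm_len + 1L),
                    nchar(seqs[members]))
    sub <- integer(length(members))
    subreps <- integer(0)
    for (j in seq_along(members)) {
      assigned <- 0L
      for (s in seq_along(subreps)) {
        if (seq_identity(tails[j], tails[subreps[s]]) >= cterm_threshold) {
          assigned <- s; break
        }
      }
      if (assigned == 0L) {
        subreps <- c(subreps, j); assigned <- length(subreps)
      }
      sub[j] <- assigned
    }
    for (s in seq_along(subreps)) {
      mem <- members[sub == s]
      # longest member, ties by lexicographic id
      best <- mem[order(-nchar(seqs[mem]), ids[mem])][1L]
      keep <- c(keep, ids[best])
    }
  }
  keep
}

#' Drop proteins shorter than a minimum length
#'
#' @param tab A `gene_table` or character vector of protein sequences.
#' @param min_len Minimum length in residues; records with length strictly
#'   smaller are removed.
#' @return Filtered object of the same type.
#' @export
filter_min_length <- function(tab, min_len = 50) {
  seqs <- if (is.character(tab)) tab else tab$aa_seq
  keep <- nchar(seqs) >= min_len
  if (any(!keep)) message(sum(!keep), " record(s) shorter than ", min_len,
                          " residues removed")
  out <- if (is.character(tab)) tab[keep] else tab[keep, , drop = FALSE]
  if (!is.character(out)) rownames(out) <- NULL
  out
}

#' Flag genes whose downstream neighbour's start codon overlaps the stop codon
#'
#' A gene is flagged when a same-strand gene on the same replicon starts
#' exactly one nucleotide before the focal gene's stop codon, i.e. the
#' downstream start coordinate equals the stop-codon start coordinate minus 1
#' (strand-adjusted). With an A as third base of the last sense codon and a
#' TGA stop this produces the canonical 4-nt A-TG-A overlap in which the
#' downstream ATG shares its A with the upstream codon and its TG with the
#' stop. Genes at replicon ends are never flagged.
#'
#' @param tab A `gene_table` with coordinates and strands.
#' @return Named logical vector over `protein_id`.
#' @export
detect_downstream_start_overlap <- function(tab) {
  flag <- stats::setNames(rep(FALSE, nrow(tab)), tab$protein_id)
  # forward: stop occupies [end-2, end]; overlap iff some + gene starts at
  # end-3. reverse (mirror): stop occupies [start, start+2]; overlap iff some
  # - gene ends at start+3.
  fwd_starts <- paste(tab$replicon, tab$start)[tab$strand == "+"]
  rev_ends <- paste(tab$replicon, tab$end)[tab$strand == "-"]
  plus <- tab$strand == "+"
  flag[plus] <- paste(tab$replicon, tab$end - 3L)[plus] %in% fwd_starts
  flag[!plus] <- paste(tab$replicon, tab$start + 3L)[!plus] %in% rev_ends
  flag
}
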