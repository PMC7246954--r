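#' Genetic-code helpers
#'
#' Thin wrappers around the NCBI genetic-code tables shipped with Biostrings,
#' keyed by numeric translation-table id (11 = bacterial standard, 4 =
#' Mycoplasma/Spiroplasma, where TGA codes for tryptophan and is NOT a stop).
#'
#' @param codon_table_id Integer NCBI translation-table id (e.g. 11 or 4).
#' @return `genetic_code()` returns a named character vector mapping the 64
#'   codons to one-letter amino acids, with `"*"` marking stops.
#' @examples
#' genetic_code(11)[["TGA"]]  # "*"
#' genetic_code(4)[["TGA"]]   # "W"
#' @export
genetic_code <- function(codon_table_id = 11) {
  Biostrings::getGeneticCode(as.character(codon_table_id))
}

#' @rdname genetic_code
#' @return `stop_codons()` and `sense_codons()` return character vectors of
#'   codons that are (or are not) stops under the table.
#' @export
stop_codons <- function(codon_table_id = 11) {
  code <- genetic_code(codon_table_id)
  names(code)[code == "*"]
}

#' @rdname genetic_code
#' @export
sense_codons <- function(codon_table_id = 11) {
  code <- genetic_code(codon_table_id)
  names(code)[code != "*"]
}

#' Split a CDS string into codons
#'
#' @param cds A single nucleotide string whose length is a multiple of 3.
#' @return Character vector of 3-mers.
#' @export
cds_to_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    stop("CDS length ", n, " is not a multiple of 3")
  }
  if (n == 0L) return(character(0))
  starts <- seq(1L, n, by = 3L)
  substring(cds, starts, starts + 2L)
}

#' Translate a codon vector
#'
#' @param codons Character vector of 3-mers.
#' @inheritParams genetic_code
#' @return Character vector of one-letter amino acids (`"*"` for stops).
#' @export
translate_codons <- function(codons, codon_table_id = 11) {
  code <- genetic_code(codon_table_id)
  aa <- unname(code[codons])
  if (anyNA(aa)) {
    bad <- unique(codons[is.na(aa)])
    stop("non-ACGT codons cannot be translated: ", paste(bad, collapse = ", "))
  }
  aa
}

# The 20 standard amino acids, in the conventional alphabetical one-letter
# order used for all count tables in the package.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
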