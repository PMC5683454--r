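# Standard genetic code tables used throughout the package.
# Codon order is fixed and canonical: the 61 sense codons sorted
# alphabetically (A < C < G < T); all codon vectors follow it.

.BASES <- c("A", "C", "G", "T")

.ALL_CODONS <- sort(apply(expand.grid(.BASES, .BASES, .BASES)[, 3:1], 1, paste, collapse = ""))

.GENETIC_CODE <- {
  gc <- as.character(Biostrings::GENETIC_CODE)
  names(gc) <- names(Biostrings::GENETIC_CODE)
  gc[.ALL_CODONS]
}

.STOP_CODONS <- names(.GENETIC_CODE)[.GENETIC_CODE == "*"]
.SENSE_CODONS <- names(.GENETIC_CODE)[.GENETIC_CODE != "*"]
.CODON_AA <- .GENETIC_CODE[.SENSE_CODONS]

.AA_LEVELS <- sort(unique(unname(.CODON_AA)))

# synonymous family size (degeneracy) per sense codon
.FAMILY_SIZE <- table(.CODON_AA)[.CODON_AA]
.FAMILY_SIZE <- stats::setNames(as.integer(.FAMILY_SIZE), .SENSE_CODONS)

#' Standard genetic code as a tibble
#'
#' One row per sense codon (61 rows) in the package's canonical
#' alphabetical codon order, with the encoded amino acid (one-letter
#' code) and the size of its synonymous family. Stop codons are excluded
#' from all codon-level statistics in this package.
#'
#' @return A tibble with columns `codon`, `aa`, `family_size`.
#' @examples
#' codon_table()
#' @export
codon_table <- function() {
  tibble::tibble(
    codon = .SENSE_CODONS,
    aa = unname(.CODON_AA),
    family_size = unname(.FAMILY_SIZE)
  )
}

# reverse complement of a DNA string (no external state)
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# translate an in-frame DNA string to one-letter amino acids ("*" = stop)
translate_cds <- function(seq) {
  suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAStringSet(seq),
    if.fuzzy.codon = "X"
  )))
}

# split a CDS into its in-frame codons (character vector)
split_codons <- function(seq) {
  n <- nchar(seq)
  stopifnot(n %% 3 == 0)
  if (n == 0) return(character(0))
  starts <- seq.int(1L, n, by = 3L)
  substring(seq, starts, starts + 2L)
}
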