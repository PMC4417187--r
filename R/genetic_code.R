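#' Genetic-code tables and synonymous families
#'
#' Thin wrappers around the NCBI genetic-code tables shipped with Biostrings.
#' Code "1" is the standard code, "2" the vertebrate mitochondrial code (the
#' default throughout this package: ATA encodes Met, TGA encodes Trp, and
#' AGA/AGG are stop codons, leaving 60 sense codons).
#'
#' @param code NCBI genetic-code identifier as a string ("1" or "2" are the
#'   ones exercised here; any id Biostrings knows is accepted).
#' @return `genetic_code_table()`: named character vector codon -> amino acid
#'   (one-letter, "*" for stop). `sense_codons()`: character vector of
#'   non-stop codons. `codon_families()`: list mapping family label to the
#'   codons it contains.
#' @name genetic_code
NULL

#' @rdname genetic_code
#' @export
genetic_code_table <- function(code = "2") {
  Biostrings::getGeneticCode(code)
}

#' @rdname genetic_code
#' @export
sense_codons <- function(code = "2") {
  gc <- genetic_code_table(code)
  names(gc)[gc != "*"]
}

#' @rdname genetic_code
#' @param codonw_compat logical; if TRUE, six-fold degenerate amino acids are
#'   split into a two-fold and a four-fold sub-family keyed on the first two
#'   codon positions, mirroring the convention of the CodonW program. The
#'   split only affects codes with six-fold families (e.g. Leu and Ser).
#' @export
codon_families <- function(code = "2", codonw_compat = FALSE) {
  gc <- genetic_code_table(code)
  gc <- gc[gc != "*"]
  fam <- split(names(gc), gc)
  if (!codonw_compat) {
    return(fam)
  }
  out <- list()
  for (aa in names(fam)) {
    codons <- fam[[aa]]
    if (length(codons) <= 4L) {
      out[[aa]] <- codons
      next
    }
    # split on the first two codon positions, as CodonW does for 6-fold AAs
    prefix <- substr(codons, 1L, 2L)
    sub <- split(codons, prefix)
    for (i in seq_along(sub)) {
      out[[paste0(aa, "_", names(sub)[i])]] <- sub[[i]]
    }
  }
  out
}

#' Translate an in-frame nucleotide string
#'
#' Position 1 is translated as Met whatever the initiation codon, matching
#' the convention used for vertebrate mitochondrial annotations where ATT,
#' ATC or ATA often initiate.
#'
#' @param nt in-frame DNA string (length divisible by 3)
#' @param code NCBI genetic-code id
#' @param init_as_met translate the first codon as "M" regardless of table
#' @return one-letter amino-acid string (may contain "*")
#' @export
translate_cds <- function(nt, code = "2", init_as_met = TRUE) {
  if (nchar(nt) %% 3L != 0L) {
    stop("sequence length not divisible by 3")
  }
  if (nchar(nt) == 0L) {
    return("")
  }
  gc <- genetic_code_table(code)
  codons <- codon_split(nt)
  aa <- unname(gc[codons])
  if (anyNA(aa)) {
    stop("unknown codon(s): ", paste(unique(codons[is.na(aa)]), collapse = ", "))
  }
  if (init_as_met) {
    aa[1L] <- "M"
  }
  paste(aa, collapse = "")
}

# split an in-frame string into its codons
codon_split <- function(nt) {
  n <- nchar(nt) %/% 3L
  if (n == 0L) return(character(0))
  substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# reverse complement of a plain character string
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

stop_codons <- function(code = "2") {
  gc <- genetic_code_table(code)
  names(gc)[gc == "*"]
}
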