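#' Selective sequence-randomization schemes
#'
#' Eight null models that each destroy one attribute of a mitochondrial
#' genome while preserving the rest, all operating on the non-D-loop arc:
#'
#' \describe{
#'   \item{RGO}{randomized gene order: whole-gene blocks permuted, each
#'     intergenic spacer travelling with the gene upstream of it; every
#'     gene's internal sequence is untouched.}
#'   \item{RRNA_SHUFFLE, TRNA_SHUFFLE, PROTEIN_SHUFFLE}{nucleotides permuted
#'     uniformly within each gene of the named class (rRNA, tRNA or CDS) on
#'     its coding strand; everything else untouched; per-gene base
#'     composition preserved.}
#'   \item{FULL}{all non-D-loop nucleotides permuted uniformly; global base
#'     composition preserved.}
#'   \item{CODON_SHUFFLE}{codons permuted within each CDS; per-gene codon
#'     multiset preserved, encoded protein generally changed.}
#'   \item{USCU}{each CDS translated (vertebrate mitochondrial code by
#'     default) and re-encoded drawing synonymous codons with equal
#'     frequency; the amino-acid sequence is exactly preserved while codon
#'     usage bias is erased. Initiation and stop codons are kept as in the
#'     native gene.}
#'   \item{NU}{a fresh i.i.d. sequence with uniform base composition and
#'     the same length as the non-D-loop arc; only length is preserved.}
#' }
#'
#' @name randomization_schemes
#' @format character vector of the eight scheme names
#' @export
randomization_schemes <- c("RGO", "RRNA_SHUFFLE", "TRNA_SHUFFLE",
                           "PROTEIN_SHUFFLE", "FULL", "CODON_SHUFFLE",
                           "USCU", "NU")

#' Generate one selectively randomized sequence
#'
#' Applies one of the eight schemes (see [randomization_schemes]) to the
#' non-D-loop arc of a genome and returns the randomized arc. Uses the
#' current R random-number stream; seed management for ensembles lives in
#' [build_null_ensemble()].
#'
#' @param g `mt_genome`
#' @param scheme one of [randomization_schemes]
#' @param balanced_uscu for USCU: draw each amino acid's codons from a
#'   maximally even multiset instead of i.i.d. uniform draws
#' @param reference_proteins optional named character vector of expected
#'   amino-acid sequences per CDS name; USCU validates its translations
#'   against these and stops on any mismatch
#' @return DNA string covering the non-D-loop arc
#' @export
randomize_genome <- function(g, scheme, balanced_uscu = FALSE,
                             reference_proteins = NULL) {
  scheme <- match.arg(scheme, randomization_schemes)
  arc <- non_dloop_arc(g)
  chars <- strsplit(g$sequence, "")[[1]]
  arc_chars <- chars[arc$positions]
  feats <- g$features[g$features$ftype != "dloop", , drop = FALSE]

  if (scheme == "FULL") {
    return(paste(sample(arc_chars), collapse = ""))
  }
  if (scheme == "NU") {
    return(paste(sample(c("A", "C", "G", "T"), length(arc_chars),
                        replace = TRUE), collapse = ""))
  }
  if (scheme == "RGO") {
    return(randomize_gene_order(g, arc, chars, feats))
  }

  class_of <- c(RRNA_SHUFFLE = "rRNA", TRNA_SHUFFLE = "tRNA",
                PROTEIN_SHUFFLE = "CDS", CODON_SHUFFLE = "CDS",
                USCU = "CDS")[scheme]
  targets <- which(feats$ftype == class_of)
  if (!length(targets)) {
    stop("scheme ", scheme, " requires at least one ", class_of, " feature")
  }
  for (t in targets) {
    pos <- feature_positions(g, feats$start[t], feats$end[t])
    aidx <- arc$lookup[pos]
    if (any(aidx == 0L)) {
      stop("feature ", feats$name[t], " overlaps the D-loop")
    }
    s <- paste(arc_chars[aidx], collapse = "")
    minus <- feats$strand[t] == "-"
    if (minus) s <- revcomp(s)
    s2 <- switch(scheme,
      RRNA_SHUFFLE = ,
      TRNA_SHUFFLE = ,
      PROTEIN_SHUFFLE = paste(sample(strsplit(s, "")[[1]]), collapse = ""),
      CODON_SHUFFLE = shuffle_codons(s),
      USCU = uscu_reencode(s, feats$name[t], g$genetic_code,
                           balanced = balanced_uscu,
                           reference = reference_proteins))
    if (minus) s2 <- revcomp(s2)
    arc_chars[aidx] <- strsplit(s2, "")[[1]]
  }
  paste(arc_chars, collapse = "")
}

# permute complete codons within one coding-strand CDS; a trailing
# incomplete stop (1-2 nt) stays in place
shuffle_codons <- function(s) {
  n <- nchar(s)
  k <- n %/% 3L
  tail_nt <- if (n %% 3L) substr(s, 3L * k + 1L, n) else ""
  codons <- codon_split(substr(s, 1L, 3L * k))
  paste0(paste(sample(codons), collapse = ""), tail_nt)
}

# re-encode one coding-strand CDS with equal-frequency synonymous codons;
# initiation codon and (complete or incomplete) stop are kept native
uscu_reencode <- function(s, gene, code, balanced = FALSE, reference = NULL) {
  n <- nchar(s)
  k <- n %/% 3L
  rem <- n %% 3L
  if (k < 2L) stop("CDS too short for USCU re-encoding: ", gene)
  codons <- codon_split(substr(s, 1L, 3L * k))
  gc <- genetic_code_table(code)
  aa <- unname(gc[codons])
  if (anyNA(aa)) stop("unknown codon in gene ", gene)
  aa[1L] <- "M"
  # internal codons: everything between the initiation codon and the stop
  last_internal <- if (rem == 0L) k - 1L else k
  internal <- if (last_internal >= 2L) 2L:last_internal else integer(0)
  if (any(aa[internal] == "*")) {
    at <- internal[which(aa[internal] == "*")[1]]
    stop("in-frame stop codon in gene ", gene, " at codon ", at)
  }
  if (!is.null(reference) && gene %in% names(reference)) {
    have <- paste(aa[c(1L, internal)], collapse = "")
    want <- reference[[gene]]
    if (have != substr(want, 1L, nchar(have))) {
      d <- which(strsplit(have, "")[[1]] !=
                 strsplit(substr(want, 1L, nchar(have)), "")[[1]])[1]
      stop("USCU translation mismatch vs reference protein in gene ", gene,
           " at position ", d)
    }
  }
  fam <- codon_families(code)
  new_codons <- codons
  if (length(internal)) {
    if (balanced) {
      for (a in unique(aa[internal])) {
        at <- internal[aa[internal] == a]
        syn <- fam[[a]]
        reps <- rep(syn, length.out = length(at))
        new_codons[at] <- sample(reps)
      }
    } else {
      new_codons[internal] <- vapply(aa[internal], function(a) {
        syn <- fam[[a]]
        syn[sample.int(length(syn), 1L)]
      }, character(1))
    }
  }
  paste0(paste(new_codons, collapse = ""),
         if (rem) substr(s, 3L * k + 1L, n) else "")
}

# permute whole-gene blocks on the arc; intergenic bases are attached to
# the gene upstream of them, leading bases (before the first gene) stay put
randomize_gene_order <- function(g, arc, chars, feats) {
  if (!nrow(feats)) stop("RGO requires annotated genes")
  arc_chars <- chars[arc$positions]
  first_base <- vapply(seq_len(nrow(feats)), function(i) {
    arc$lookup[feature_positions(g, feats$start[i], feats$end[i])[1]]
  }, integer(1))
  if (any(first_base == 0L)) stop("gene overlaps the D-loop")
  starts <- sort(unique(first_base))
  n <- length(arc_chars)
  lead <- if (starts[1] > 1L) arc_chars[1:(starts[1] - 1L)] else character(0)
  blocks <- lapply(seq_along(starts), function(i) {
    from <- starts[i]
    to <- if (i < length(starts)) starts[i + 1L] - 1L else n
    arc_chars[from:to]
  })
  paste(c(lead, unlist(blocks[sample.int(length(blocks))])), collapse = "")
}

#' Build a null ensemble of randomized sequences
#'
#' Generates `n` independent replicates under one scheme, scans each for
#' direct repeats and records per-replicate spectra plus summary statistics
#' of the total count. Replicate random streams are derived from the master
#' seed by a counter, so the ensemble is reproducible and replicate order
#' independent.
#'
#' @param g `mt_genome`
#' @param scheme one of [randomization_schemes]
#' @param n number of replicates (>= 2)
#' @param min_len minimum repeat length scanned (bp)
#' @param seed master seed (integer)
#' @param ... passed to [randomize_genome()]
#' @return object of class `null_ensemble`: list with `scheme`, `n`,
#'   `seed`, `min_len`, `spectra` (list of `dr_spectrum`), `totals`,
#'   `mean`, `sd`
#' @export
build_null_ensemble <- function(g, scheme, n = 100L, min_len = 5L,
                                seed = 1L, ...) {
  if (n < 2L) stop("need n >= 2 replicates for ensemble variance")
  spectra <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(replicate_seed(seed, i))
    s <- randomize_genome(g, scheme, ...)
    spectra[[i]] <- dr_spectrum(find_direct_repeats(s, min_len), min_len)
  }
  totals <- vapply(spectra, dr_total, numeric(1))
  structure(
    list(scheme = scheme, n = n, seed = seed, min_len = min_len,
         spectra = spectra, totals = totals,
         mean = mean(totals), sd = stats::sd(totals)),
    class = "null_ensemble"
  )
}

# counter-derived substream seed, kept inside 32-bit integer range
replicate_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 16807) %% 2147483647)
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> %s: n = %d, total(>=%d bp) = %.1f +/- %.1f\n",
              x$scheme, x$n, x$min_len, x$mean, x$sd))
  invisible(x)
}
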