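#' Codon usage table of a coding sequence
#'
#' Counts every codon of an in-frame coding sequence over the sense codons
#' of a genetic code. Terminal (initiation/stop) codons are expected to
#' have been trimmed upstream by [concatenated_cds()]; an in-frame stop is
#' therefore an error.
#'
#' @param cds a `coding_sequence`, or an in-frame DNA string
#' @param code NCBI genetic-code id; defaults to the coding sequence's
#'   genome convention ("2", vertebrate mitochondrial) for `coding_sequence`
#'   input and to "2" for plain strings
#' @return object of class `codon_usage`: named integer vector of counts
#'   over all sense codons, with attributes `code` and `n` (total codons)
#' @examples
#' codon_usage("TTTTTCAAA", code = "1")
#' @export
codon_usage <- function(cds, code = "2") {
  nt <- if (inherits(cds, "coding_sequence")) cds$nucleotides else toupper(cds)
  if (nchar(nt) %% 3L != 0L) stop("coding sequence length not divisible by 3")
  codons <- codon_split(nt)
  gc <- genetic_code_table(code)
  if (length(codons)) {
    aa <- unname(gc[codons])
    if (anyNA(aa)) {
      stop("unknown codon at position ", which(is.na(aa))[1])
    }
    if (any(aa == "*")) {
      stop("in-frame stop codon at codon position ", which(aa == "*")[1])
    }
  }
  sense <- sense_codons(code)
  counts <- table(factor(codons, levels = sense))
  structure(stats::setNames(as.integer(counts), sense),
            class = "codon_usage", code = code, n = length(codons))
}

#' @export
print.codon_usage <- function(x, ...) {
  cat(sprintf("<codon_usage> %d codons over %d sense codons (code %s)\n",
              attr(x, "n"), length(x), attr(x, "code")))
  invisible(x)
}

#' Per-family relative codon frequencies
#'
#' Groups synonymous codons by the amino acid they encode and reports each
#' codon's relative frequency within its family (frequencies sum to 1 for
#' every family that is used at all).
#'
#' @param usage `codon_usage`
#' @param codonw_compat use CodonW's split of six-fold families
#' @return data.frame with columns `family`, `codon`, `count`, `frequency`
#' @export
codon_frequency_table <- function(usage, codonw_compat = FALSE) {
  fam <- codon_families(attr(usage, "code"), codonw_compat = codonw_compat)
  rows <- lapply(names(fam), function(a) {
    cod <- fam[[a]]
    cnt <- as.integer(usage[cod])
    tot <- sum(cnt)
    data.frame(family = a, codon = cod, count = cnt,
               frequency = if (tot > 0) cnt / tot else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Wright's effective number of codons (Nc)
#'
#' Nc measures synonymous codon usage bias on the scale of "how many codons
#' are effectively in use": complete bias (one codon per amino acid) gives
#' 20, perfectly even usage gives the code's sense-codon count (61 for the
#' standard code, 60 for the vertebrate mitochondrial code). Per family of
#' size > 1 with n codons and usage fractions p_i, the homozygosity
#' estimate is F = (n * sum(p_i^2) - 1) / (n - 1); families are grouped by
#' degeneracy k, and Nc is the number of single-codon families plus
#' sum_k (number of k-fold families) / (mean F of the k-fold class).
#'
#' Families observed fewer than 2 times (or with a non-positive F, which
#' finite samples can produce) carry no usable homozygosity estimate and
#' are imputed from their class mean, following common practice in codon
#' usage software; an entirely missing 3-fold class is imputed as the mean
#' of the 2- and 4-fold class means. The raw sum is capped at the code's
#' sense-codon count, which finite-sample F can otherwise exceed.
#'
#' @param usage `codon_usage`
#' @param codonw_compat treat six-fold families as a 2-fold plus a 4-fold
#'   sub-family (the CodonW convention; relevant when reproducing values
#'   computed with that program)
#' @return Nc in codons
#' @export
effective_number_of_codons <- function(usage, codonw_compat = FALSE) {
  code <- attr(usage, "code")
  fam <- codon_families(code, codonw_compat = codonw_compat)
  sizes <- lengths(fam)
  if (sum(usage) == 0L) stop("empty codon usage table")

  fhat <- rep(NA_real_, length(fam))
  for (j in seq_along(fam)) {
    cnt <- as.numeric(usage[fam[[j]]])
    n <- sum(cnt)
    k <- sizes[j]
    if (k == 1L) {
      fhat[j] <- 1
    } else if (n >= 2) {
      p <- cnt / n
      f <- (n * sum(p^2) - 1) / (n - 1)
      if (f > 0) fhat[j] <- f
    }
  }

  ks <- sort(unique(sizes[sizes > 1L]))
  class_mean <- stats::setNames(rep(NA_real_, length(ks)), ks)
  for (k in ks) {
    vals <- fhat[sizes == k & !is.na(fhat)]
    if (length(vals)) class_mean[as.character(k)] <- mean(vals)
  }
  # impute a wholly missing class
  for (k in ks) {
    kk <- as.character(k)
    if (is.na(class_mean[kk])) {
      if (k == 3L && !is.na(class_mean["2"]) && !is.na(class_mean["4"])) {
        class_mean[kk] <- mean(c(class_mean["2"], class_mean["4"]))
      } else {
        warning("no usable family of degeneracy ", k,
                "; imputing uniform-usage homozygosity 1/", k)
        class_mean[kk] <- 1 / k
      }
    }
  }

  nc <- sum(sizes == 1L)
  for (k in ks) {
    nc <- nc + sum(sizes == k) / class_mean[as.character(k)]
  }
  cap <- length(sense_codons(code))
  unname(min(nc, cap))
}

#' Expected Nc under compositional bias alone
#'
#' Wright's null curve: the effective number of codons expected when codon
#' choice is driven purely by the G+C fraction at third positions (GC3),
#' with no selection among synonymous codons:
#' Nc*(s) = 2 + s + 29 / (s^2 + (1 - s)^2).
#'
#' @param s GC3 fraction, strictly between 0 and 1 (vectorized)
#' @return expected Nc in codons
#' @examples
#' expected_nc(0.5) # 60.5
#' @export
expected_nc <- function(s) {
  if (any(s <= 0 | s >= 1)) stop("GC3 must lie strictly between 0 and 1")
  2 + s + 29 / (s^2 + (1 - s)^2)
}

#' Strand-asymmetry skews and base composition
#'
#' GC skew = (G - C) / (G + C) and AT skew = (A - T) / (A + T), computed
#' on the given (heavy-strand) sequence, plus the overall G+C fraction.
#' A skew whose denominator is zero is undefined: it is returned as `NA`
#' with a warning, so the other (well-defined) skew stays usable.
#'
#' @param seq DNA string
#' @return list with `gc_skew`, `at_skew`, `gc_content`
#' @export
skews <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop("empty sequence")
  cnt <- table(factor(strsplit(seq, "")[[1]], levels = c("A", "C", "G", "T")))
  a <- cnt[["A"]]; c_ <- cnt[["C"]]; g <- cnt[["G"]]; t <- cnt[["T"]]
  gc_skew <- if (g + c_ == 0) {
    warning("GC skew undefined: no G or C bases")
    NA_real_
  } else (g - c_) / (g + c_)
  at_skew <- if (a + t == 0) {
    warning("AT skew undefined: no A or T bases")
    NA_real_
  } else (a - t) / (a + t)
  list(gc_skew = gc_skew, at_skew = at_skew,
       gc_content = (g + c_) / sum(cnt))
}

#' G+C fraction at third codon positions
#'
#' @param cds a `coding_sequence` or in-frame DNA string
#' @return fraction of third-position bases that are G or C
#' @export
gc3 <- function(cds) {
  nt <- if (inherits(cds, "coding_sequence")) cds$nucleotides else toupper(cds)
  if (nchar(nt) %% 3L != 0L) stop("coding sequence length not divisible by 3")
  k <- nchar(nt) %/% 3L
  if (k == 0L) stop("empty coding sequence")
  third <- substring(nt, 3L * seq_len(k), 3L * seq_len(k))
  mean(third %in% c("G", "C"))
}
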