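#' Enumerate maximal direct-repeat pairs
#'
#' Exhaustively finds every maximal pair of identical same-strand
#' subsequences of length at least `min_len` in a linear DNA string. The
#' counting unit is the pair of occurrences `(pos1, pos2)`: a motif present
#' k times contributes up to k(k-1)/2 pairs, each assessed for maximality
#' on its own. A pair is maximal when extending both copies one base left
#' or right breaks the identity or runs off an end, and is reported exactly
#' once, at its maximal length; its internal sub-repeats are not counted
#' separately. Pairs whose copies overlap (`pos2 - pos1 < length`, e.g.
#' within homopolymer runs) are included by default and flagged in the
#' `overlapping` column.
#'
#' @param seq DNA string over A,C,G,T
#' @param min_len minimum repeat length in bp (>= 2)
#' @param include_overlapping keep pairs whose two copies overlap
#' @return data.frame with columns `pos1`, `pos2` (0-based start positions,
#'   `pos1 < pos2`), `length`, `motif`, `overlapping`, sorted by
#'   `pos1`, `pos2`
#' @examples
#' find_direct_repeats("ACGTACGT", min_len = 4)
#' @export
find_direct_repeats <- function(seq, min_len = 5L, include_overlapping = TRUE) {
  seq <- toupper(seq)
  if (min_len < 2L) stop("min_len must be >= 2")
  if (grepl("[^ACGT]", seq)) {
    stop("sequence contains characters outside A,C,G,T")
  }
  df <- scan_direct_repeats_cpp(seq, as.integer(min_len))
  df$motif <- if (nrow(df)) {
    substring(seq, df$pos1 + 1L, df$pos1 + df$length)
  } else {
    character(0)
  }
  df$overlapping <- (df$pos2 - df$pos1) < df$length
  if (!include_overlapping) {
    df <- df[!df$overlapping, , drop = FALSE]
  }
  df <- df[order(df$pos1, df$pos2), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Direct-repeat length spectrum
#'
#' Tabulates maximal pairs by exact length. The spectrum is the input to
#' mutagenicity scoring and to the null-ensemble comparisons.
#'
#' @param pairs data.frame from [find_direct_repeats()]
#' @param min_len smallest length the spectrum should cover (lengths with
#'   zero pairs are kept as explicit zeros)
#' @return object of class `dr_spectrum`: named integer vector, names are
#'   lengths in bp
#' @export
dr_spectrum <- function(pairs, min_len = 5L) {
  max_len <- if (nrow(pairs)) max(pairs$length) else min_len
  lens <- min_len:max(max_len, min_len)
  counts <- vapply(lens, function(L) sum(pairs$length == L), integer(1))
  structure(stats::setNames(counts, lens), class = "dr_spectrum",
            min_len = min_len)
}

#' Total pair count at or above a length threshold
#'
#' @param spectrum `dr_spectrum`
#' @param min_len length threshold in bp (default: the spectrum's floor)
#' @return integer count of pairs with length >= `min_len`
#' @export
dr_total <- function(spectrum, min_len = attr(spectrum, "min_len")) {
  lens <- as.integer(names(spectrum))
  sum(spectrum[lens >= min_len])
}

#' @export
print.dr_spectrum <- function(x, ...) {
  cat(sprintf("<dr_spectrum> %d pairs, lengths %s..%s bp\n",
              dr_total(x), names(x)[1], names(x)[length(x)]))
  print(unclass(x))
  invisible(x)
}

#' Length-dependent deletion-propensity models
#'
#' Loads a repeat-length weight table for the total mutagenicity score.
#' Two calibrations ship with the package, `"lambda"` (deletion
#' frequencies between engineered repeats in bacteriophage lambda DNA) and
#' `"yeast"` (deletion frequencies in yeast mtDNA). The original
#' frequencies are not reproduced here: the bundled tables are
#' reconstructed log-linear curves (see their headers) and are meant to be
#' swapped for measured values via `path`. Weights are relative deletion
#' propensities, positive and non-decreasing in repeat length; lengths
#' above the table's support are extrapolated from the fitted log-linear
#' function recorded in the table header, with a warning.
#'
#' @param name "lambda" or "yeast" (ignored when `path` is given)
#' @param path optional TSV with columns `length`, `weight` and header
#'   comment lines `# log2_slope: a` and `# log2_at_min: b` describing the
#'   fitted function log2 w(L) = b + a (L - Lmin)
#' @return object of class `mutagenicity_model`
#' @export
mutagenicity_model <- function(name = c("lambda", "yeast"), path = NULL) {
  if (is.null(path)) {
    name <- match.arg(name)
    path <- system.file("extdata",
                        sprintf("tms_weights_%s_reconstructed.tsv", name),
                        package = "mtdrscan")
    if (!nzchar(path)) stop("bundled weight table not found")
  } else {
    name <- if (is.character(name)) name[1] else "custom"
  }
  hdr <- readLines(path, warn = FALSE)
  hdr <- hdr[startsWith(hdr, "#")]
  get_num <- function(key) {
    hit <- grep(sprintf("^#\\s*%s:", key), hdr, value = TRUE)
    if (!length(hit)) return(NA_real_)
    as.numeric(sub(sprintf("^#\\s*%s:\\s*", key), "", hit[1]))
  }
  tab <- utils::read.delim(path, comment.char = "#", header = TRUE)
  if (!all(c("length", "weight") %in% names(tab))) {
    stop("weight table must have columns 'length' and 'weight'")
  }
  if (any(tab$weight <= 0) || is.unsorted(tab$weight[order(tab$length)])) {
    stop("weights must be positive and non-decreasing in length")
  }
  structure(
    list(name = name,
         weights = stats::setNames(tab$weight, tab$length),
         min_len = min(tab$length),
         log2_slope = get_num("log2_slope"),
         log2_at_min = get_num("log2_at_min")),
    class = "mutagenicity_model"
  )
}

# w(L) for one model, extrapolating above tabulated support
model_weight <- function(model, lens) {
  w <- unname(model$weights[as.character(lens)])
  out <- ifelse(is.na(w), NA_real_, w)
  miss <- is.na(out)
  if (any(miss)) {
    if (is.na(model$log2_slope)) {
      stop("length(s) beyond calibration support and no fitted function: ",
           paste(lens[miss], collapse = ", "))
    }
    warning("extrapolating deletion propensity beyond calibration support ",
            "for length(s): ", paste(lens[miss], collapse = ", "))
    out[miss] <- 2^(model$log2_at_min +
                    model$log2_slope * (lens[miss] - model$min_len))
  }
  out
}

#' Total mutagenicity score (TMS)
#'
#' Sums, over all repeat lengths at or above the model's minimum scored
#' length, the pair count times the model's deletion propensity:
#' TMS = sum over L of count(L) * w(L). A spectrum with no scored lengths
#' gives 0.
#'
#' @param spectrum `dr_spectrum`
#' @param model `mutagenicity_model`
#' @return numeric score (dimensionless, relative units)
#' @export
total_mutagenicity_score <- function(spectrum, model) {
  lens <- as.integer(names(spectrum))
  keep <- lens >= model$min_len & spectrum > 0
  if (!any(keep)) return(0)
  sum(as.numeric(spectrum[keep]) * model_weight(model, lens[keep]))
}
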