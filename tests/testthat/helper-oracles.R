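# Independent oracles and fixture builders shared across the suite.
# These deliberately re-derive results by different algorithms than the
# package (per-length enumeration instead of offset runs; straight-from-
# formula Nc; naive BM recursion) so agreement is evidence, not tautology.

rand_dna <- function(n, probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# Brute-force maximal-pair enumeration: for each length L, find all equal
# substring pairs, keep those not extendable one base left or right.
# Stops at the first L with no repeated substring (none longer can exist).
brute_force_repeats <- function(seq, min_len) {
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  rows <- list()
  L <- min_len
  while (L <= n - 1) {
    starts <- seq_len(n - L + 1L)
    subs <- substring(seq, starts, starts + L - 1L)
    dup_groups <- split(starts, subs)
    dup_groups <- dup_groups[lengths(dup_groups) >= 2L]
    if (!length(dup_groups)) break
    for (grp in dup_groups) {
      cmb <- utils::combn(grp, 2L)
      for (c_ in seq_len(ncol(cmb))) {
        i <- cmb[1, c_]; j <- cmb[2, c_]
        left_ext <- i > 1L && j > 1L && ch[i - 1L] == ch[j - 1L]
        right_ext <- i + L <= n && j + L <= n && ch[i + L] == ch[j + L]
        if (!left_ext && !right_ext) {
          rows[[length(rows) + 1L]] <- c(i - 1L, j - 1L, L)
        }
      }
    }
    L <- L + 1L
  }
  if (!length(rows)) {
    return(data.frame(pos1 = integer(0), pos2 = integer(0),
                      length = integer(0)))
  }
  m <- do.call(rbind, rows)
  df <- data.frame(pos1 = as.integer(m[, 1]), pos2 = as.integer(m[, 2]),
                   length = as.integer(m[, 3]))
  df <- df[order(df$pos1, df$pos2), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Wright's Nc straight from the formula, written independently of the
# package implementation (direct per-amino-acid loop over the code table).
oracle_nc <- function(counts, code = "1", codonw_compat = FALSE) {
  gc <- Biostrings::getGeneticCode(code)
  gc <- gc[gc != "*"]
  aa <- gc[names(counts)]
  if (codonw_compat) {
    six <- names(table(aa))[table(aa) > 4]
    aa <- ifelse(aa %in% six, paste0(aa, substr(names(counts), 1, 2)), aa)
  }
  F_by_fam <- c()
  size_by_fam <- c()
  for (a in unique(aa)) {
    cnt <- counts[aa == a]
    n <- sum(cnt)
    k <- sum(aa == a)
    size_by_fam[a] <- k
    if (k == 1) {
      F_by_fam[a] <- 1
    } else if (n >= 2) {
      f <- (n * sum((cnt / n)^2) - 1) / (n - 1)
      F_by_fam[a] <- if (f > 0) f else NA_real_
    } else {
      F_by_fam[a] <- NA_real_
    }
  }
  ks <- sort(unique(size_by_fam[size_by_fam > 1]))
  means <- sapply(ks, function(k) {
    v <- F_by_fam[size_by_fam == k]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  names(means) <- ks
  for (k in ks) {
    kk <- as.character(k)
    if (is.na(means[kk])) {
      if (k == 3 && !is.na(means["2"]) && !is.na(means["4"])) {
        means[kk] <- mean(c(means["2"], means["4"]))
      } else {
        means[kk] <- 1 / k
      }
    }
  }
  nc <- sum(table(aa) == 1)
  for (k in ks) {
    nc <- nc + sum(table(aa) == k) / means[as.character(k)]
  }
  unname(min(nc, length(counts)))
}

# random codon-usage table over the sense codons of a code
random_usage <- function(code = "1", total = NULL) {
  sense <- sense_codons(code)
  if (is.null(total)) total <- sample(100:10000, 1)
  probs <- as.numeric(stats::rgamma(length(sense), shape = 0.8))
  cnt <- as.integer(stats::rmultinom(1, total, probs / sum(probs)))
  structure(stats::setNames(cnt, sense), class = "codon_usage",
            code = code, n = total)
}

# independent bivariate-BM simulator on a phylo tree (naive recursion)
bm_pair_oracle <- function(tree, root = c(0, 0), sigma2 = c(1, 1), rho = 0) {
  ntip <- length(tree$tip.label)
  states <- matrix(NA_real_, ntip + tree$Nnode, 2)
  states[ntip + 1, ] <- root
  S <- matrix(c(sigma2[1], rho * sqrt(prod(sigma2)),
                rho * sqrt(prod(sigma2)), sigma2[2]), 2)
  R <- chol(S)
  edges <- tree$edge[order(tree$edge[, 1]), , drop = FALSE]
  # walk edges repeatedly until all children are filled (simple, tree-safe)
  todo <- seq_len(nrow(tree$edge))
  while (length(todo)) {
    done <- c()
    for (e in todo) {
      par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      if (!is.na(states[par, 1])) {
        states[ch, ] <- states[par, ] +
          sqrt(tree$edge.length[e]) * drop(t(R) %*% stats::rnorm(2))
        done <- c(done, e)
      }
    }
    todo <- setdiff(todo, done)
  }
  out <- states[seq_len(ntip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

# small fully annotated synthetic genome, cheap enough for per-test reuse
small_genome <- function(seed = 1, kappa = 0.5) {
  generate_genome(genome_spec(
    length = 4200, rrna_lengths = c(250, 400), n_trna = 6, trna_length = 60,
    protein_lengths = c(90, 140, 200, 110), scu_concentration = kappa,
    seed = seed))
}

# base composition of a string as a sorted named table
base_table <- function(s) {
  table(factor(strsplit(s, "")[[1]], levels = c("A", "C", "G", "T")))
}

# coding-strand sequence of feature i read out of an arc string
feature_arc_string <- function(g, i, arc_str = NULL) {
  am <- mtdrscan:::non_dloop_arc(g)
  f <- g$features[i, ]
  idx <- am$lookup[mtdrscan:::feature_positions(g, f$start, f$end)]
  src <- if (is.null(arc_str)) non_dloop_sequence(g) else arc_str
  s <- paste(strsplit(src, "")[[1]][idx], collapse = "")
  if (f$strand == "-") mtdrscan:::revcomp(s) else s
}

# where user-supplied external records (e.g. the human reference genome or
# a downloaded compendium) are looked for; see README
external_data_dir <- function() {
  opt <- getOption("mtdrscan.external_dir", NULL)
  cand <- c(opt,
            "inst/extdata/external",
            "../../inst/extdata/external",
            "../../../inst/extdata/external")
  for (p in cand) {
    if (!is.null(p) && dir.exists(p)) return(normalizePath(p))
  }
  cand[[2]]
}
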