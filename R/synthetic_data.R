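#' Specification for a synthetic mitochondrial-like genome
#'
#' Describes a circular genome with the canonical vertebrate mitochondrial
#' layout — one D-loop (control region), rRNA and tRNA genes and a set of
#' protein-coding genes — with tunable base composition (bias and skew on
#' the heavy strand), tunable synonymous-codon-usage bias and a seedable
#' random stream. Defaults emulate a mammalian mtDNA: 16.5 kb, 2 rRNAs, 22
#' tRNAs, 13 proteins with human-like lengths, human-like heavy-strand
#' base frequencies, and a codon-usage concentration giving a moderate
#' bias (Nc in the low 40s, the mammalian range).
#'
#' Within each synonymous family the codon probabilities are geometric in
#' a single concentration parameter kappa: codons ordered by a fixed
#' third-position preference (A, C, T, G, the order seen in mammalian
#' mtDNA four-fold families) get weights 1, kappa, kappa^2, ...
#' `scu_concentration = 1` is uniform usage (Nc near the code cap);
#' values toward 0 concentrate each family on one codon (Nc toward 20).
#'
#' @param length total genome length in bp
#' @param rrna_lengths lengths of the rRNA genes
#' @param n_trna number of tRNA genes
#' @param trna_length length of each tRNA gene
#' @param protein_lengths protein lengths in amino acids (initiation Met
#'   included); each gene adds a 3-bp stop
#' @param base_probs named probabilities for A, C, G, T on the heavy
#'   strand (non-coding regions and RNA genes); defaults are human-like
#'   (A-rich, G-poor: positive AT skew, negative GC skew)
#' @param scu_concentration kappa in (0, 1]
#' @param aa_freqs amino-acid frequencies for protein bodies; the default
#'   is a fixed, plausible mitochondrial-protein composition (Leu-rich)
#' @param minus_strand_cds indices of protein genes placed on the light
#'   strand (default: the last one, as for ND6)
#' @param genetic_code NCBI code id (default "2")
#' @param seed integer seed
#' @return object of class `genome_spec`
#' @export
genome_spec <- function(length = 16500L,
                        rrna_lengths = c(950L, 1550L),
                        n_trna = 22L,
                        trna_length = 70L,
                        protein_lengths = c(318L, 347L, 513L, 227L, 68L,
                                            226L, 261L, 115L, 98L, 459L,
                                            603L, 174L, 380L),
                        base_probs = c(A = 0.309, C = 0.313,
                                       G = 0.131, T = 0.247),
                        scu_concentration = 0.5,
                        aa_freqs = NULL,
                        minus_strand_cds = length(protein_lengths),
                        genetic_code = "2",
                        seed = 1L) {
  if (abs(sum(base_probs) - 1) > 1e-8) stop("base_probs must sum to 1")
  if (!all(c("A", "C", "G", "T") %in% names(base_probs))) {
    stop("base_probs must be named A, C, G, T")
  }
  if (scu_concentration <= 0 || scu_concentration > 1) {
    stop("scu_concentration must lie in (0, 1]")
  }
  if (is.null(aa_freqs)) aa_freqs <- default_aa_freqs(genetic_code)
  structure(
    list(length = as.integer(length), rrna_lengths = as.integer(rrna_lengths),
         n_trna = as.integer(n_trna), trna_length = as.integer(trna_length),
         protein_lengths = as.integer(protein_lengths),
         base_probs = base_probs[c("A", "C", "G", "T")],
         scu_concentration = scu_concentration,
         aa_freqs = aa_freqs, minus_strand_cds = minus_strand_cds,
         genetic_code = genetic_code, seed = as.integer(seed)),
    class = "genome_spec"
  )
}

# fixed plausible mitochondrial-protein amino-acid composition; hydrophobic
# residues dominate because the 13 proteins are membrane subunits
default_aa_freqs <- function(code = "2") {
  f <- c(L = 0.160, I = 0.090, T = 0.085, S = 0.075, A = 0.070,
         F = 0.060, N = 0.055, M = 0.050, P = 0.050, G = 0.050,
         V = 0.045, Y = 0.040, H = 0.030, W = 0.025, K = 0.025,
         Q = 0.025, E = 0.020, R = 0.020, D = 0.015, C = 0.010)
  f <- f / sum(f)
  fam <- codon_families(code)
  f[names(f) %in% names(fam)]
}

# per-family codon probabilities under geometric concentration kappa,
# codons ordered by third-position preference A > C > T > G
family_codon_probs <- function(code, kappa) {
  fam <- codon_families(code)
  pref <- c(A = 1L, C = 2L, T = 3L, G = 4L)
  lapply(fam, function(codons) {
    ord <- order(pref[substr(codons, 3L, 3L)], codons)
    codons <- codons[ord]
    w <- kappa^(seq_along(codons) - 1)
    stats::setNames(w / sum(w), codons)
  })
}

rand_bases <- function(n, probs) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# one coding-strand CDS: ATG + body drawn from aa/codon distributions + TAA
rand_cds <- function(n_aa, aa_freqs, codon_probs) {
  if (n_aa < 3L) stop("protein too short")
  body_aa <- sample(names(aa_freqs), n_aa - 1L, replace = TRUE,
                    prob = aa_freqs)
  body <- vapply(body_aa, function(a) {
    p <- codon_probs[[a]]
    sample(names(p), 1L, prob = p)
  }, character(1))
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

#' Generate an annotated synthetic genome
#'
#' Lays the genes of a [genome_spec()] head-to-tail around a circular
#' molecule with 0-2 bp intergenic spacers, fills the remainder with a
#' D-loop placed at the end of the sequence, and draws the sequences:
#' protein-coding genes by sampling amino acids and then synonymous codons
#' (valid under the genome's genetic code, with proper initiation and stop
#' codons and no in-frame stops), everything else i.i.d. from the spec's
#' base probabilities. Genes flagged `minus_strand_cds` are built on the
#' coding strand and inserted reverse-complemented.
#'
#' @param spec `genome_spec`
#' @param id genome identifier
#' @return `mt_genome`
#' @export
generate_genome <- function(spec, id = sprintf("synth_%d", spec$seed)) {
  set.seed(spec$seed)
  codon_probs <- family_codon_probs(spec$genetic_code, spec$scu_concentration)

  genes <- list()
  add <- function(name, ftype, len, strand = "+", cds_aa = NA) {
    genes[[length(genes) + 1L]] <<- list(name = name, ftype = ftype,
                                         len = len, strand = strand,
                                         cds_aa = cds_aa)
  }
  add("TRN1", "tRNA", spec$trna_length)
  for (i in seq_along(spec$rrna_lengths)) {
    add(sprintf("RRN%d", i), "rRNA", spec$rrna_lengths[i])
  }
  n_cds <- length(spec$protein_lengths)
  trna_left <- spec$n_trna - 1L
  per_gap <- if (n_cds > 0L) trna_left %/% n_cds else 0L
  extra <- if (n_cds > 0L) trna_left %% n_cds else trna_left
  tc <- 1L
  for (i in seq_len(n_cds)) {
    strand <- if (i %in% spec$minus_strand_cds) "-" else "+"
    add(sprintf("CDS%d", i), "CDS", 3L * (spec$protein_lengths[i] + 1L),
        strand = strand, cds_aa = spec$protein_lengths[i])
    k <- per_gap + (i <= extra)
    for (j in seq_len(k)) {
      tc <- tc + 1L
      strand_t <- if (tc %% 3L == 0L) "-" else "+"
      add(sprintf("TRN%d", tc), "tRNA", spec$trna_length, strand = strand_t)
    }
  }

  spacers <- sample(0:2, length(genes), replace = TRUE)
  used <- sum(vapply(genes, `[[`, integer(1), "len")) + sum(spacers)
  dloop_len <- spec$length - used
  if (dloop_len < 100L) {
    stop("layout infeasible: genes + spacers need ", used,
         " bp, leaving ", dloop_len, " bp for the D-loop")
  }

  parts <- character(0)
  feats <- list()
  pos <- 1L
  for (i in seq_along(genes)) {
    gn <- genes[[i]]
    if (gn$ftype == "CDS") {
      s <- rand_cds(gn$cds_aa, spec$aa_freqs, codon_probs)
      if (gn$strand == "-") s <- revcomp(s)
    } else {
      s <- rand_bases(gn$len, spec$base_probs)
    }
    stopifnot(nchar(s) == gn$len)
    feats[[i]] <- data.frame(name = gn$name, ftype = gn$ftype,
                             start = pos, end = pos + gn$len - 1L,
                             strand = gn$strand, stringsAsFactors = FALSE)
    parts <- c(parts, s)
    pos <- pos + gn$len
    if (spacers[i] > 0L) {
      parts <- c(parts, rand_bases(spacers[i], spec$base_probs))
      pos <- pos + spacers[i]
    }
  }
  feats[[length(feats) + 1L]] <- data.frame(
    name = "D-loop", ftype = "dloop", start = pos,
    end = pos + dloop_len - 1L, strand = "+", stringsAsFactors = FALSE)
  parts <- c(parts, rand_bases(dloop_len, spec$base_probs))

  mt_genome(id, paste(parts, collapse = ""), do.call(rbind, feats),
            circular = TRUE, genetic_code = spec$genetic_code)
}

#' Specification for a synthetic clade
#'
#' A Yule (pure-birth) phylogeny whose leaves carry log-lifespan and
#' log-body-mass evolved under correlated Brownian motion, one synthetic
#' genome per leaf, and an optional linear coupling from each genome's
#' long-DR count into residual log-lifespan with a known effect size.
#' Defaults emulate the comparative setting of mammalian longevity work:
#' lifespan and body mass strongly correlated (0.68 on the log scale in
#' the mammalian compendium), lifespans of order 2-100 years, masses of
#' order 10 g - 1000 kg.
#'
#' @param n_leaves number of species
#' @param birth_rate Yule speciation rate (per unit branch length)
#' @param sigma2_lifespan,sigma2_mass Brownian variances per unit branch
#'   length of log-lifespan and log-mass
#' @param bm_correlation correlation of the two Brownian increments
#' @param coupling effect size: added to log-lifespan per standard
#'   deviation of long-DR count (0 = no coupling)
#' @param coupling_min_len DR length threshold defining the coupled count
#' @param scu_drift Brownian variance of logit(kappa) along the tree
#'   (0 = all genomes share the spec's concentration)
#' @param n_orders number of taxon-order labels carved out of the tree
#' @param root_log_lifespan,root_log_mass root states (natural logs of
#'   years and grams)
#' @param seed integer seed
#' @return object of class `clade_spec`
#' @export
clade_spec <- function(n_leaves = 32L, birth_rate = 1,
                       sigma2_lifespan = 0.25, sigma2_mass = 1.5,
                       bm_correlation = 0.68, coupling = 0,
                       coupling_min_len = 13L, scu_drift = 0,
                       n_orders = 4L,
                       root_log_lifespan = log(15), root_log_mass = log(5000),
                       seed = 1L) {
  if (abs(bm_correlation) > 1) stop("bm_correlation must lie in [-1, 1]")
  if (sigma2_lifespan <= 0 || sigma2_mass <= 0) {
    stop("Brownian variances must be positive")
  }
  structure(
    list(n_leaves = as.integer(n_leaves), birth_rate = birth_rate,
         sigma2_lifespan = sigma2_lifespan, sigma2_mass = sigma2_mass,
         bm_correlation = bm_correlation, coupling = coupling,
         coupling_min_len = as.integer(coupling_min_len),
         scu_drift = scu_drift, n_orders = as.integer(n_orders),
         root_log_lifespan = root_log_lifespan,
         root_log_mass = root_log_mass, seed = as.integer(seed)),
    class = "clade_spec"
  )
}

# correlated bivariate Brownian motion down a phylo tree; returns a
# 2-column matrix of tip states
simulate_bm_pair <- function(tree, root, sigma2, correlation) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  states <- matrix(NA_real_, nn, 2L)
  states[ntip + 1L, ] <- root
  cov12 <- correlation * sqrt(prod(sigma2))
  L <- chol(matrix(c(sigma2[1], cov12, cov12, sigma2[2]), 2L))
  ord <- ape::reorder.phylo(tree, "cladewise")
  key <- paste(tree$edge[, 1], tree$edge[, 2])
  el <- tree$edge.length[match(paste(ord$edge[, 1], ord$edge[, 2]), key)]
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1]
    ch <- ord$edge[e, 2]
    z <- stats::rnorm(2L)
    states[ch, ] <- states[par, ] + sqrt(el[e]) * drop(t(L) %*% z)
  }
  states[seq_len(ntip), , drop = FALSE]
}

# carve n_orders contiguous clades out of a tree for taxon-order labels
assign_orders <- function(tree, n_orders) {
  d <- stats::as.dist(ape::cophenetic.phylo(tree))
  cl <- stats::cutree(stats::hclust(d, method = "average"),
                      k = min(n_orders, length(tree$tip.label)))
  stats::setNames(paste0("order_", cl), tree$tip.label)
}

#' Generate a clade: tree, traits and genomes with known ground truth
#'
#' Simulates the Yule tree, evolves correlated (log-lifespan, log-mass)
#' Brownian traits, generates one genome per leaf (with the codon-usage
#' concentration optionally drifting on the tree on the logit scale), and
#' optionally injects a linear effect of the standardized long-DR count
#' into log-lifespan. The returned `truth` element records every parameter
#' used, for recovery tests.
#'
#' @param cspec `clade_spec`
#' @param gspec `genome_spec` shared by all leaves (per-leaf seeds are
#'   drawn internally)
#' @param scan_min_len minimum DR length scanned for the per-leaf spectra
#' @return list with `tree` (phylo), `records` (data.frame: species,
#'   taxon_order, lifespan, body_mass, dr_total, dr_long), `genomes`
#'   (named list of `mt_genome`), `spectra` (named list of `dr_spectrum`)
#'   and `truth`
#' @export
generate_clade <- function(cspec, gspec = genome_spec(), scan_min_len = 5L) {
  set.seed(cspec$seed)
  tree <- ape::rphylo(cspec$n_leaves, birth = cspec$birth_rate, death = 0)
  tree$tip.label <- sprintf("sp%03d", seq_len(cspec$n_leaves))

  traits <- simulate_bm_pair(
    tree, c(cspec$root_log_lifespan, cspec$root_log_mass),
    c(cspec$sigma2_lifespan, cspec$sigma2_mass), cspec$bm_correlation)

  base_kappa <- gspec$scu_concentration
  if (cspec$scu_drift > 0) {
    lk <- stats::qlogis(base_kappa)
    drift <- simulate_bm_pair(tree, c(lk, 0),
                              c(cspec$scu_drift, cspec$scu_drift), 0)[, 1]
    kappas <- stats::plogis(drift)
  } else {
    kappas <- rep(base_kappa, cspec$n_leaves)
  }
  leaf_seeds <- sample.int(2^30, cspec$n_leaves)

  genomes <- vector("list", cspec$n_leaves)
  spectra <- vector("list", cspec$n_leaves)
  dr_total_v <- integer(cspec$n_leaves)
  dr_long_v <- integer(cspec$n_leaves)
  for (i in seq_len(cspec$n_leaves)) {
    gs <- gspec
    gs$scu_concentration <- kappas[i]
    gs$seed <- leaf_seeds[i]
    genomes[[i]] <- generate_genome(gs, id = tree$tip.label[i])
    sp <- dr_spectrum(
      find_direct_repeats(non_dloop_sequence(genomes[[i]]), scan_min_len),
      scan_min_len)
    spectra[[i]] <- sp
    dr_total_v[i] <- dr_total(sp)
    dr_long_v[i] <- dr_total(sp, cspec$coupling_min_len)
  }
  names(genomes) <- names(spectra) <- tree$tip.label

  log_lifespan <- traits[, 1]
  if (cspec$coupling != 0) {
    z <- dr_long_v
    sdz <- stats::sd(z)
    z <- if (is.na(sdz) || sdz == 0) rep(0, length(z)) else
      (z - mean(z)) / sdz
    log_lifespan <- log_lifespan + cspec$coupling * z
  }

  records <- data.frame(
    species = tree$tip.label,
    taxon_order = unname(assign_orders(tree, cspec$n_orders)),
    lifespan = exp(log_lifespan),
    body_mass = exp(traits[, 2]),
    dr_total = dr_total_v,
    dr_long = dr_long_v,
    stringsAsFactors = FALSE)

  list(tree = tree, records = records, genomes = genomes, spectra = spectra,
       truth = list(cspec = cspec, gspec = gspec, kappas = kappas,
                    log_lifespan_bm = traits[, 1], log_mass = traits[, 2]))
}
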