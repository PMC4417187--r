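# Conservation ledger: every scheme must preserve exactly the attributes
# it declares and destroy the one it targets.

test_that("every scheme preserves arc length", {
  g <- small_genome(seed = 4)
  L <- nchar(non_dloop_sequence(g))
  set.seed(10)
  for (sch in randomization_schemes) {
    expect_equal(nchar(randomize_genome(g, sch)), L, info = sch)
  }
})

test_that("FULL preserves the global base multiset and nothing finer", {
  g <- small_genome(seed = 4)
  arc <- non_dloop_sequence(g)
  set.seed(11)
  out <- randomize_genome(g, "FULL")
  expect_identical(base_table(out), base_table(arc))
  expect_false(identical(out, arc))
})

test_that("gene-class shuffles keep per-gene composition, touch nothing else", {
  g <- small_genome(seed = 4)
  arc <- non_dloop_sequence(g)
  cases <- list(RRNA_SHUFFLE = "rRNA", TRNA_SHUFFLE = "tRNA",
                PROTEIN_SHUFFLE = "CDS")
  for (sch in names(cases)) {
    set.seed(12)
    out <- randomize_genome(g, sch)
    targets <- which(g$features$ftype == cases[[sch]])
    others <- which(!g$features$ftype %in% c(cases[[sch]], "dloop"))
    for (i in targets) {
      expect_identical(base_table(feature_arc_string(g, i, out)),
                       base_table(feature_arc_string(g, i)), info = sch)
    }
    for (i in others) {
      expect_identical(feature_arc_string(g, i, out),
                       feature_arc_string(g, i), info = sch)
    }
  }
})

test_that("CODON_SHUFFLE preserves each gene's codon multiset", {
  g <- small_genome(seed = 4)
  set.seed(13)
  out <- randomize_genome(g, "CODON_SHUFFLE")
  changed <- 0L
  for (i in which(g$features$ftype == "CDS")) {
    before <- feature_arc_string(g, i)
    after <- feature_arc_string(g, i, out)
    expect_identical(sort(mtdrscan:::codon_split(after)),
                     sort(mtdrscan:::codon_split(before)))
    if (!identical(after, before)) changed <- changed + 1L
  }
  expect_gt(changed, 0L)
})

test_that("USCU preserves every encoded protein exactly", {
  g <- small_genome(seed = 4)
  set.seed(14)
  out <- randomize_genome(g, "USCU")
  for (i in which(g$features$ftype == "CDS")) {
    before <- feature_arc_string(g, i)
    after <- feature_arc_string(g, i, out)
    expect_identical(translate_cds(after, "2"), translate_cds(before, "2"))
  }
  expect_false(identical(out, non_dloop_sequence(g)))
  # balanced mode also preserves the protein
  set.seed(15)
  out_b <- randomize_genome(g, "USCU", balanced_uscu = TRUE)
  i <- which(g$features$ftype == "CDS")[1]
  expect_identical(translate_cds(feature_arc_string(g, i, out_b), "2"),
                   translate_cds(feature_arc_string(g, i), "2"))
})

test_that("USCU validates against supplied reference proteins", {
  g <- small_genome(seed = 4)
  cds_names <- g$features$name[g$features$ftype == "CDS"]
  ref <- stats::setNames(rep("MKKKKK", length(cds_names)), cds_names)
  set.seed(16)
  expect_error(randomize_genome(g, "USCU", reference_proteins = ref),
               "mismatch.*CDS1|CDS1.*mismatch")
  # correct references pass
  ok_ref <- vapply(which(g$features$ftype == "CDS"), function(i) {
    translate_cds(feature_arc_string(g, i), "2")
  }, character(1))
  names(ok_ref) <- cds_names
  expect_no_error(randomize_genome(g, "USCU", reference_proteins = ok_ref))
})

test_that("RGO permutes whole gene blocks without touching their insides", {
  g <- small_genome(seed = 4)
  arc <- non_dloop_sequence(g)
  set.seed(17)
  out <- randomize_genome(g, "RGO")
  expect_identical(base_table(out), base_table(arc))
  # every gene's heavy-strand sequence must persist verbatim somewhere
  am <- mtdrscan:::non_dloop_arc(g)
  arc_chars <- strsplit(arc, "")[[1]]
  for (i in which(g$features$ftype != "dloop")) {
    f <- g$features[i, ]
    idx <- am$lookup[mtdrscan:::feature_positions(g, f$start, f$end)]
    gene_seq <- paste(arc_chars[idx], collapse = "")
    expect_true(grepl(gene_seq, out, fixed = TRUE), info = f$name)
  }
})

test_that("NU yields uniform base usage within binomial error", {
  g <- small_genome(seed = 4)
  L <- nchar(non_dloop_sequence(g))
  set.seed(18)
  reps <- 30L
  counts <- c(A = 0, C = 0, G = 0, T = 0)
  for (r in seq_len(reps)) {
    counts <- counts + base_table(randomize_genome(g, "NU"))
  }
  n <- reps * L
  se <- sqrt(n * 0.25 * 0.75)
  expect_true(all(abs(counts - n * 0.25) < 4 * se))
})

test_that("FULL permutation is uniform over distinguishable outcomes", {
  # "AACG" has 4!/2! = 12 distinguishable permutations
  g <- mt_genome("toy", "AACG",
                 data.frame(name = character(0), ftype = character(0),
                            start = integer(0), end = integer(0),
                            strand = character(0)),
                 circular = FALSE)
  set.seed(19)
  draws <- replicate(12000, randomize_genome(g, "FULL"))
  tab <- table(draws)
  expect_equal(length(tab), 12L)
  chi <- stats::chisq.test(tab)
  expect_gt(chi$p.value, 0.001)
})

test_that("USCU equalizes synonymous codon frequencies", {
  # one 300-codon gene, heavily biased, re-encoded 100 times
  set.seed(20)
  gs <- genome_spec(length = 1500, rrna_lengths = 150L, n_trna = 2,
                    trna_length = 60, protein_lengths = 300L,
                    scu_concentration = 0.05, seed = 20)
  g <- generate_genome(gs)
  i <- which(g$features$ftype == "CDS")
  counts <- NULL
  for (r in 1:100) {
    out <- randomize_genome(g, "USCU")
    s <- feature_arc_string(g, i, out)
    internal <- substr(s, 4, nchar(s) - 3)
    u <- codon_usage(internal, code = "2")
    counts <- if (is.null(counts)) unclass(u) else counts + unclass(u)
  }
  fam <- codon_families("2")
  for (a in names(fam)) {
    n_a <- sum(counts[fam[[a]]])
    if (n_a < 200) next
    k <- length(fam[[a]])
    p <- 1 / k
    se <- sqrt(n_a * p * (1 - p))
    expect_true(all(abs(counts[fam[[a]]] - n_a * p) < 5 * se),
                info = paste("family", a))
  }
})

test_that("ensembles are reproducible and replicate-order independent", {
  g <- small_genome(seed = 4)
  e1 <- build_null_ensemble(g, "FULL", n = 3, min_len = 5, seed = 77)
  e2 <- build_null_ensemble(g, "FULL", n = 3, min_len = 5, seed = 77)
  expect_identical(e1$totals, e2$totals)
  expect_identical(e1$spectra, e2$spectra)
  # replicate i is a function of (seed, i), not of how many reps ran before
  e4 <- build_null_ensemble(g, "FULL", n = 4, min_len = 5, seed = 77)
  expect_identical(e4$totals[1:3], e1$totals)
  expect_error(build_null_ensemble(g, "FULL", n = 1, seed = 1), "n >= 2")
})
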