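test_that("a minimal GenBank record parses with its features typed", {
  path <- system.file("extdata", "minimal_synthetic.gb", package = "mtdrscan")
  g <- parse_genbank(path)
  expect_s3_class(g, "mt_genome")
  expect_equal(genome_length(g), 60L)
  expect_true(g$circular)
  expect_equal(nrow(g$features), 2L)
  expect_setequal(g$features$ftype, c("CDS", "dloop"))
  cds <- g$features[g$features$ftype == "CDS", ]
  expect_equal(c(cds$start, cds$end), c(1L, 30L))
  dl <- g$features[g$features$ftype == "dloop", ]
  expect_equal(c(dl$start, dl$end), c(41L, 60L))
})

test_that("parser flags structural problems and unknown keys", {
  lines <- c("LOCUS       X 30 bp DNA linear UNA", "ORIGIN", "//")
  expect_error(parse_genbank(lines), "ORIGIN|empty")

  bad_bounds <- c(
    "LOCUS       X 20 bp    DNA     linear   UNA",
    "FEATURES             Location/Qualifiers",
    "     CDS             1..30",
    "ORIGIN",
    "        1 atgaaacccg ggtttacgta",
    "//")
  expect_error(parse_genbank(bad_bounds), "bounds")

  oddkey <- c(
    "LOCUS       X 20 bp    DNA     circular   UNA",
    "FEATURES             Location/Qualifiers",
    "     misc_feature    1..5",
    "ORIGIN",
    "        1 atgaaacccg ggtttacgta",
    "//")
  expect_warning(g <- parse_genbank(oddkey), "misc_feature")
  expect_equal(nrow(g$features), 0L)
})

test_that("write/parse round-trip preserves sequence and coordinates", {
  g <- small_genome(seed = 3)
  g2 <- parse_genbank(write_genbank(g))
  expect_identical(g2$sequence, g$sequence)
  expect_identical(g2$circular, g$circular)
  f1 <- g$features[order(g$features$start, g$features$name), ]
  f2 <- g2$features[order(g2$features$start, g2$features$name), ]
  rownames(f1) <- rownames(f2) <- NULL
  expect_identical(f2[c("ftype", "start", "end", "strand")],
                   f1[c("ftype", "start", "end", "strand")])
})

test_that("origin-wrapping features survive the round-trip", {
  seq <- rand_dna(100)
  feats <- data.frame(name = c("D-loop", "g1"), ftype = c("dloop", "tRNA"),
                      start = c(91L, 20L), end = c(10L, 60L),
                      strand = c("+", "-"))
  g <- mt_genome("wrap", seq, feats, circular = TRUE)
  g2 <- parse_genbank(write_genbank(g))
  dl <- g2$features[g2$features$ftype == "dloop", ]
  expect_equal(c(dl$start, dl$end), c(91L, 10L))
  expect_error(mt_genome("wrap", seq, feats, circular = FALSE),
               "wrap-around")
})

test_that("D-loop excision returns the complementary arc", {
  # wrapping D-loop 91..10 on a 100 bp circle leaves the arc 11..90
  seq <- rand_dna(100)
  feats <- data.frame(name = "D-loop", ftype = "dloop",
                      start = 91L, end = 10L, strand = "+")
  g <- mt_genome("wrap", seq, feats, circular = TRUE)
  arc <- non_dloop_sequence(g)
  expect_equal(nchar(arc), 80L)
  expect_identical(arc, substr(seq, 11, 90))

  # no D-loop: identity, and idempotent
  g0 <- mt_genome("plain", seq, feats[0, ], circular = TRUE)
  expect_identical(non_dloop_sequence(g0), seq)
})

test_that("excised length equals base-by-base exclusion on random layouts", {
  set.seed(71)
  for (r in 1:50) {
    n <- sample(60:300, 1)
    len <- sample(10:30, 1)
    start <- sample(seq_len(n), 1)
    end <- if (start + len - 1L <= n) start + len - 1L else
      (start + len - 1L) %% n
    seq <- rand_dna(n)
    feats <- data.frame(name = "D-loop", ftype = "dloop",
                        start = start, end = end, strand = "+")
    g <- mt_genome("r", seq, feats, circular = TRUE)
    arc <- non_dloop_sequence(g)
    # oracle: direct exclusion of the D-loop base set
    dpos <- if (end >= start) start:end else c(start:n, 1:end)
    expect_equal(nchar(arc), n - length(dpos))
    expect_identical(sort(strsplit(arc, "")[[1]]),
                     sort(strsplit(seq, "")[[1]][-dpos]))
  }
})

test_that("CDS concatenation trims terminal codons per gene", {
  # two 12-nt genes: trimming start + stop leaves 2 codons each
  seq <- paste0("ATGAAACCCTAA", "ATGGGGTTTTAG", rand_dna(6))
  feats <- data.frame(name = c("g1", "g2"), ftype = "CDS",
                      start = c(1L, 13L), end = c(12L, 24L), strand = "+")
  g <- mt_genome("cds", seq, feats, circular = FALSE, genetic_code = "2")
  cc <- concatenated_cds(g, omit_terminal_codons = TRUE)
  expect_equal(nchar(cc$nucleotides), 12L)
  expect_identical(cc$nucleotides, "AAACCCGGGTTT")
  expect_equal(cc$genes$start, c(1L, 7L))

  full <- concatenated_cds(g, omit_terminal_codons = FALSE)
  expect_equal(nchar(full$nucleotides), 24L)
})

test_that("minus-strand CDS are reverse-complemented before concatenation", {
  # heavy strand holds the complement; coding strand must read ATG..TAA
  coding <- "ATGAAACCCTAA"
  seq <- paste0(rand_dna(6), as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(coding))),
    rand_dna(6))
  feats <- data.frame(name = "gneg", ftype = "CDS",
                      start = 7L, end = 18L, strand = "-")
  g <- mt_genome("neg", seq, feats, circular = FALSE)
  cc <- concatenated_cds(g, omit_terminal_codons = FALSE)
  expect_identical(cc$nucleotides, coding)
  expect_identical(concatenated_cds(g)$nucleotides, "AAACCC")
})

test_that("incomplete stop codons count as the stop and are dropped", {
  # 13-nt gene ending in a lone T completed by polyadenylation
  seq <- paste0("ATGAAACCCGGGT", rand_dna(5))
  feats <- data.frame(name = "gpoly", ftype = "CDS",
                      start = 1L, end = 13L, strand = "+")
  g <- mt_genome("poly", seq, feats, circular = FALSE)
  cc <- concatenated_cds(g, omit_terminal_codons = TRUE)
  expect_identical(cc$nucleotides, "AAACCCGGG")
  # without trimming, a frame-incomplete CDS is an error naming the gene
  expect_error(concatenated_cds(g, omit_terminal_codons = FALSE), "gpoly")
})

test_that("generator output always passes validation and frame checks", {
  for (seed in c(2, 9, 23)) {
    g <- small_genome(seed = seed)
    expect_equal(sum(g$features$ftype == "dloop"), 1L)
    cc <- concatenated_cds(g, omit_terminal_codons = TRUE)
    expect_equal(nchar(cc$nucleotides) %% 3L, 0L)
    # and the non-D-loop arc never contains D-loop bases
    expect_equal(nchar(non_dloop_sequence(g)),
                 genome_length(g) - {
                   dl <- g$features[g$features$ftype == "dloop", ]
                   dl$end - dl$start + 1L
                 })
  }
})
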