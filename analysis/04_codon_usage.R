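#!/usr/bin/env Rscript
# Synonymous codon usage across the compendium: Wright's effective number
# of codons (Nc), GC3, strand skews, per-family codon frequencies, the
# expected-bias curve Nc*(GC3), and the correlation between SCU bias and
# repeat abundance (naive, and partial with composition controlled at the
# contrast level with phylogenetic correction).
#
# Inputs:  scratch/compendium/, results/02_species_dr.tsv
# Outputs: results/04_codon_stats.tsv, results/04_codon_frequencies.tsv,
#          results/04_scu_dr_correlation.tsv

suppressPackageStartupMessages(library(mtdrscan))

traits <- read.delim("scratch/compendium/traits.tsv")
species_dr <- read.delim("results/02_species_dr.tsv")
tree <- ape::read.tree("scratch/compendium/tree.nwk")

rows <- list()
freq_acc <- NULL
for (i in seq_len(nrow(traits))) {
  g <- parse_genbank(file.path("scratch/compendium",
                               paste0(traits$species[i], ".gb")))
  cds <- concatenated_cds(g, omit_terminal_codons = TRUE)
  u <- codon_usage(cds, code = "2")
  sk <- skews(g$sequence)
  s3 <- gc3(cds)
  rows[[i]] <- data.frame(
    species = g$id, nc = effective_number_of_codons(u),
    nc_codonw = effective_number_of_codons(u, codonw_compat = TRUE),
    gc3 = s3, expected_nc = expected_nc(s3),
    gc_content = sk$gc_content, gc_skew = sk$gc_skew, at_skew = sk$at_skew)
  ft <- codon_frequency_table(u)
  freq_acc <- if (is.null(freq_acc)) ft["frequency"] else
    freq_acc + ft["frequency"]
}
stats_tab <- do.call(rbind, rows)
write.table(stats_tab, "results/04_codon_stats.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

freq_tab <- codon_frequency_table(
  codon_usage(concatenated_cds(
    parse_genbank(file.path("scratch/compendium",
                            paste0(traits$species[1], ".gb")))), "2"))
freq_tab$frequency <- freq_acc$frequency / nrow(traits)
names(freq_tab)[names(freq_tab) == "frequency"] <- "mean_frequency"
freq_tab$count <- NULL
write.table(freq_tab, "results/04_codon_frequencies.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("Nc across the clade: %.1f-%.1f (median %.2f); all species %s the Nc*(GC3) expectation\n",
            min(stats_tab$nc), max(stats_tab$nc), median(stats_tab$nc),
            if (all(stats_tab$nc < stats_tab$expected_nc)) "below" else "not all below"))

# SCU bias vs repeat count, merged with the spectra driver's output
m <- merge(stats_tab, species_dr, by = "species")
m <- m[match(tree$tip.label, m$species), ]
naive <- cor.test(m$nc, m$dr_total)
pic <- function(v) independent_contrasts(tree, setNames(v, m$species))
part <- contrast_correlation(pic(m$nc), pic(m$dr_total),
                             control = cbind(pic(m$gc_skew), pic(m$at_skew),
                                             pic(m$gc_content)))
corr_tab <- data.frame(
  analysis = c("naive", "partial_pic"),
  rho = c(unname(naive$estimate), part$rho),
  p = c(naive$p.value, part$p))
write.table(corr_tab, "results/04_scu_dr_correlation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("Nc vs total DR count: naive rho = %.2f (p = %.2g); composition+phylogeny controlled rho = %.2f (p = %.2g)\n",
            corr_tab$rho[1], corr_tab$p[1], corr_tab$rho[2], corr_tab$p[2]))
cat("Wrote results/04_codon_stats.tsv, 04_codon_frequencies.tsv, 04_scu_dr_correlation.tsv\n")
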