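#' Configuration for a full pipeline run
#'
#' @param dr_min_len minimum DR length scanned (bp)
#' @param long_dr_min_len threshold defining "long" DRs (bp); long repeats
#'   are the ones deletion-mutagenicity arguments focus on
#' @param null_schemes randomization schemes for the ensemble comparison
#' @param n_null replicates per null ensemble
#' @param percentiles lifespan percentiles for the subpopulation split
#' @param codonw_compat CodonW-style six-fold family split for Nc
#' @param tms_model "lambda" or "yeast" calibration for the mutagenicity
#'   score
#' @param reference_species species whose genome anchors the ensemble
#'   comparison (default: the first one)
#' @param seed master seed
#' @return object of class `run_config`
#' @export
run_config <- function(dr_min_len = 5L, long_dr_min_len = 13L,
                       null_schemes = randomization_schemes,
                       n_null = 100L, percentiles = c(50, 75, 90),
                       codonw_compat = FALSE, tms_model = "lambda",
                       reference_species = NULL, seed = 1L) {
  if (long_dr_min_len < dr_min_len) {
    stop("long_dr_min_len must be >= dr_min_len")
  }
  if (n_null < 2L) stop("n_null must be >= 2")
  structure(
    list(dr_min_len = as.integer(dr_min_len),
         long_dr_min_len = as.integer(long_dr_min_len),
         null_schemes = null_schemes, n_null = as.integer(n_null),
         percentiles = percentiles, codonw_compat = codonw_compat,
         tms_model = tms_model, reference_species = reference_species,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the complete analysis battery
#'
#' Sequences every stage on a cross-referenced input set: per-species DR
#' spectra and codon statistics, null-ensemble comparisons for a reference
#' genome, the codon-usage-bias vs DR-count correlation (naive, and
#' partial with respect to composition, then phylogenetically corrected),
#' the Nc vs expected-Nc(GC3) table, and the longevity test battery
#' (subpopulation tests plus contrasts of body-mass residuals). The run is
#' a pure function of (inputs, config, seed); every table carries the
#' config hash and seed as attributes.
#'
#' @param genomes named list of `mt_genome`, names matching species
#' @param records data.frame with columns `species`, `taxon_order`,
#'   `lifespan` (years), `body_mass` (grams)
#' @param tree rooted binary `phylo` whose tip labels are the species
#' @param config `run_config`
#' @return list of class `mtdr_report` with elements `species_table`,
#'   `null_table`, `scu_dr`, `nc_table`, `longevity`, `meta`
#' @export
run_full_analysis <- function(genomes, records, tree, config = run_config()) {
  problems <- character(0)
  for (sp in tree$tip.label) {
    if (!sp %in% records$species) {
      problems <- c(problems, paste0("no trait record for tree leaf ", sp))
    }
    if (!sp %in% names(genomes)) {
      problems <- c(problems, paste0("no genome for tree leaf ", sp))
    }
  }
  if (length(problems)) {
    stop("cross-reference failures:\n  ", paste(problems, collapse = "\n  "))
  }
  species <- tree$tip.label
  records <- records[match(species, records$species),
                     c("species", "taxon_order", "lifespan", "body_mass"),
                     drop = FALSE]
  model <- mutagenicity_model(config$tms_model)

  rows <- lapply(species, function(sp) {
    g <- genomes[[sp]]
    arc <- non_dloop_sequence(g)
    spec <- dr_spectrum(find_direct_repeats(arc, config$dr_min_len),
                        config$dr_min_len)
    cds <- concatenated_cds(g, omit_terminal_codons = TRUE)
    usage <- codon_usage(cds, code = g$genetic_code)
    sk <- skews(g$sequence)
    s3 <- gc3(cds)
    data.frame(
      species = sp,
      dr_total = dr_total(spec),
      dr_long = dr_total(spec, config$long_dr_min_len),
      tms = total_mutagenicity_score(spec, model),
      nc = effective_number_of_codons(usage,
                                      codonw_compat = config$codonw_compat),
      gc3 = s3,
      expected_nc = expected_nc(s3),
      gc_content = sk$gc_content, gc_skew = sk$gc_skew,
      at_skew = sk$at_skew,
      stringsAsFactors = FALSE)
  })
  species_table <- merge(records, do.call(rbind, rows), by = "species",
                         sort = FALSE)

  ref <- config$reference_species
  if (is.null(ref)) ref <- species[1]
  gref <- genomes[[ref]]
  native <- species_table$dr_total[species_table$species == ref]
  null_rows <- lapply(seq_along(config$null_schemes), function(i) {
    sch <- config$null_schemes[i]
    ens <- build_null_ensemble(gref, sch, n = config$n_null,
                               min_len = config$dr_min_len,
                               seed = replicate_seed(config$seed, i))
    zt <- ensemble_z_test(native, ens, alternative = "two.sided")
    data.frame(scheme = sch, n = ens$n, null_mean = ens$mean,
               null_sd = ens$sd, native = native, z = zt$z, p = zt$p,
               stringsAsFactors = FALSE)
  })
  null_table <- do.call(rbind, null_rows)

  st <- species_table
  pic_of <- function(v) {
    independent_contrasts(tree, stats::setNames(v, st$species))
  }
  naive <- stats::cor.test(st$nc, st$dr_total)
  # partial correlation: covariates controlled at the contrast level
  # (through-origin regression on contrasts), which keeps the test
  # calibrated; see the methods vignette
  comp_pics <- cbind(pic_of(st$gc_skew), pic_of(st$at_skew),
                     pic_of(st$gc_content))
  part <- contrast_correlation(pic_of(st$nc), pic_of(st$dr_total),
                               control = comp_pics)
  scu_dr <- data.frame(
    analysis = c("naive", "partial_pic"),
    rho = c(unname(naive$estimate), part$rho),
    p = c(naive$p.value, part$p),
    stringsAsFactors = FALSE)

  nc_table <- species_table[, c("species", "nc", "gc3", "expected_nc")]
  nc_table$below_expectation <- nc_table$nc < nc_table$expected_nc

  pic_ls <- pic_of(log(st$lifespan))
  pic_bm <- pic_of(log(st$body_mass))
  pic_vs_lifespan <- function(counts) {
    # a count that is constant across species (e.g. no long DRs at all)
    # has no correlation to estimate
    tryCatch({
      cc <- contrast_correlation(pic_ls, pic_of(counts), control = pic_bm)
      c(rho = cc$rho, p = cc$p, df = cc$df)
    }, error = function(e) c(rho = NA_real_, p = NA_real_,
                             df = length(pic_ls) - 2))
  }
  pic_rows <- rbind(pic_vs_lifespan(st$dr_total),
                    pic_vs_lifespan(st$dr_long))
  pic_correlation <- data.frame(
    count = c("dr_total", "dr_long"),
    rho = pic_rows[, "rho"], p = pic_rows[, "p"], df = pic_rows[, "df"],
    stringsAsFactors = FALSE)
  sub_rows <- lapply(config$percentiles, function(pp) {
    tryCatch({
      tst <- subpopulation_tests(
        data.frame(lifespan = st$lifespan, dr_count = st$dr_long),
        percentile = pp, value = "dr_count")
      data.frame(percentile = pp, threshold = tst$threshold,
                 n_short = tst$n_short, n_long = tst$n_long,
                 t_p = tst$t$p, mwu_p = tst$mwu$p, ks_p = tst$ks$p)
    }, error = function(e) data.frame(
      percentile = pp, threshold = NA_real_, n_short = NA_integer_,
      n_long = NA_integer_, t_p = NA_real_, mwu_p = NA_real_,
      ks_p = NA_real_))
  })
  longevity <- list(
    pic_correlation = pic_correlation,
    subpopulations = do.call(rbind, sub_rows))

  meta <- list(config = config, config_hash = config_hash(config),
               seed = config$seed, n_species = length(species),
               reference_species = ref)
  out <- list(species_table = species_table, null_table = null_table,
              scu_dr = scu_dr, nc_table = nc_table, longevity = longevity,
              meta = meta)
  class(out) <- "mtdr_report"
  out
}

#' Write a report bundle as TSV + JSON
#'
#' @param report `mtdr_report` from [run_full_analysis()]
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, paste0(name, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(report$species_table, "species_table")
  wr(report$null_table, "null_table")
  wr(report$scu_dr, "scu_dr_correlation")
  wr(report$nc_table, "nc_table")
  wr(report$longevity$pic_correlation, "longevity_pic")
  wr(report$longevity$subpopulations, "longevity_subpopulations")
  meta_path <- file.path(dir, "meta.json")
  jsonlite::write_json(
    list(config = unclass(report$meta$config),
         config_hash = report$meta$config_hash,
         seed = report$meta$seed,
         n_species = report$meta$n_species,
         reference_species = report$meta$reference_species),
    meta_path, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, meta_path)
  invisible(paths)
}

#' @export
print.mtdr_report <- function(x, ...) {
  cat(sprintf("<mtdr_report> %d species; reference %s; config %s\n",
              x$meta$n_species, x$meta$reference_species,
              substr(x$meta$config_hash, 1, 8)))
  invisible(x)
}
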