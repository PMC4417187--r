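---
title: "Direct repeats, codon-usage bias and longevity in mitochondrial genomes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct repeats, codon-usage bias and longevity in mitochondrial genomes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtdrscan)
```

## The scientific question

Vertebrate mitochondrial DNA (mtDNA) deletions — the lesions behind
sarcopenia, several neurodegenerative conditions and much of mitochondrial
ageing — are typically flanked by **direct repeats** (DRs): pairs of
identical same-strand subsequences outside the regulatory D-loop. Because
longer repeats hybridize more readily during replication slippage, the
count of long DRs has been read as a deletion-mutagenicity burden, and a
long-standing hypothesis holds that long-lived species should have been
selected to carry fewer of them.

Testing that hypothesis requires three ingredients this package provides:

1. an exhaustive, exactly defined enumeration of DR pairs and a
   length-weighted total mutagenicity score (TMS);
2. null models that ask *what sets the DR count* — eight selective
   randomizations that each erase one sequence attribute (gene order,
   within-gene nucleotide order, codon order, synonymous codon usage,
   global composition) while conserving the rest;
3. comparative statistics that correlate repeat burden with lifespan
   across species while controlling the two classic confounders, body
   mass and shared ancestry.

A synthetic-data module generates annotated mtDNA-like genomes and
trait-bearing phylogenies with known structure, so the entire chain can be
exercised and calibrated without downloading anything.

## Counting direct repeats

A DR pair is `(pos1, pos2, L)` with
`seq[pos1..pos1+L) == seq[pos2..pos2+L)`. The counting unit is the
**maximal pair**: extending both copies one base left or right breaks the
identity or runs off an end. Each maximal pair is counted once, at its
maximal length; its internal sub-repeats are not counted separately
(otherwise per-size counts would be linear combinations of longer sizes
and "the longest repeat" would be ill-defined). A motif occurring $k$
times contributes up to $\binom{k}{2}$ pairs, each assessed for maximality
on its own. Pairs whose copies overlap (`pos2 - pos1 < L`, homopolymer
runs being the extreme case) are included by default and flagged, with a
switch to drop them.

The scanner works per offset $d = pos_2 - pos_1$: positions where
`seq[i] == seq[i+d]` form runs, and every run of length $\ge$ `min_len`
is exactly one maximal pair. The implementation packs bases two bits each
and processes 32 positions per machine word, which matters because the
null-model ensembles rescan a ~16.5 kb genome hundreds of times. The test
suite holds the scanner bit-exact against a brute-force oracle that
enumerates equal substring pairs per length and checks flanks explicitly
— a deliberately different algorithm.

Repeats shorter than 5 bp are excluded by default (`min_len = 5`): such
pairs generally have positive hybridization free energy and are not
credible misalignment substrates. "Long" DRs default to $\ge 13$ bp, the
threshold used for the longevity claims. The D-loop is excised before
scanning because D-loop repeats are not implicated in the deletion
classes of interest; the excised molecule is treated as strictly linear,
so no repeat is counted across the cut.

### Mutagenicity score

`total_mutagenicity_score()` computes
$\mathrm{TMS} = \sum_{L \ge L_{min}} n(L)\, w(L)$ with a weight table
$w(L)$ giving the relative deletion propensity of a repeat of length
$L$ (minimum scored length 10 bp). Two calibrations ship as editable TSV
files, one shaped on deletion rates between engineered repeats in
bacteriophage lambda DNA and one on yeast mtDNA deletion data. **The
bundled tables are reconstructions** — log-linear curves whose fitted
coefficients sit in the file headers — because the measured values are
not reproduced here; users with the original measurements can swap them
in via `mutagenicity_model(path = ...)`. Lengths beyond a table's support
are extrapolated from the fitted function, with a warning.

## The eight randomization schemes

Each scheme conserves everything except one attribute (all operate on the
non-D-loop arc and conserve its length):

| scheme | destroys | conserves |
|---|---|---|
| RGO | gene order | every gene's internal sequence |
| RRNA/TRNA/PROTEIN shuffle | nucleotide order within that gene class | per-gene base composition, everything else |
| FULL | all nucleotide order | global base composition |
| CODON_SHUFFLE | codon order within each CDS | per-gene codon multiset |
| USCU | synonymous codon-usage bias | the encoded protein, exactly |
| NU | everything but length | length |

The conservation ledger above is tested property-by-property. Design
details worth knowing:

* **USCU** re-encodes each protein drawing synonymous codons with equal
  frequency. The default draws i.i.d. uniformly within each amino acid's
  family per site; `balanced_uscu = TRUE` instead assigns a maximally
  even codon multiset and permutes it, for sensitivity analysis. The
  initiation codon and the (possibly incomplete) stop are kept native, so
  annotation quirks survive re-encoding. Translations can be validated
  against user-supplied reference proteins; any mismatch aborts with the
  gene and position.
* **RGO** permutes whole-gene blocks with each intergenic spacer attached
  to the gene upstream of it (the attachment side is not dictated by
  anything biological; bases before the first gene stay in place).
* Gene-class shuffles permute on the coding strand and re-insert
  respecting strand; non-coding, non-D-loop bases are untouched by all
  gene-scoped schemes.
* Ensembles derive per-replicate seeds from the master seed by counter,
  so replicate $i$ is reproducible regardless of how many replicates are
  requested.

## Codon-usage statistics

Synonymous codon usage (SCU) bias is measured with Wright's effective
number of codons. For a synonymous family with $n$ observations and usage
fractions $p_i$, the homozygosity is
$\hat F = (n\sum p_i^2 - 1)/(n-1)$; families are grouped by degeneracy
$k$, and

$$N_c = N_1 + \sum_k \frac{N_k}{\bar F_k},$$

with $N_k$ the number of $k$-fold families. $N_c$ runs from 20 (complete
bias) to the code's sense-codon count (61 standard, 60 vertebrate
mitochondrial). Families observed fewer than twice, or with a
non-positive finite-sample $\hat F$, are imputed from their class mean (a
wholly missing 3-fold class takes the mean of the 2- and 4-fold class
means), and the raw sum is capped at the code's sense-codon count, which
finite samples can otherwise exceed.

The genetic code is a first-class parameter. The default treats the
vertebrate mitochondrial code's families as they are (two 6-fold
families: Leu and Ser); `codonw_compat = TRUE` splits 6-fold families
into a 2-fold plus a 4-fold sub-family keyed on the first two codon
positions, matching the convention of the CodonW program with which
published mtDNA $N_c$ values (e.g. 42.64 for human) were computed. Both
modes are reported by the pipeline.

The null expectation of $N_c$ under compositional bias alone is Wright's
curve $N_c^*(s) = 2 + s + 29/(s^2 + (1-s)^2)$ with $s$ the G+C fraction
at third codon positions; species sitting clearly below the curve carry
more SCU bias than mutation pressure explains. Strand asymmetry is
summarized by GC skew $(G-C)/(G+C)$ and AT skew $(A-T)/(A+T)$ on the
heavy strand; a skew with a zero denominator is returned as `NA` with a
warning rather than poisoning the other statistics.

Codon counting happens on the concatenated protein-coding genes with the
initiation codon and the stop of every gene dropped. Stops annotated as
incomplete ("T"/"TA", completed by polyadenylation — routine in mammalian
mtDNA) count as the stop and are dropped with it. Overlapping CDS
(ATP8/ATP6-style) are concatenated independently — the overlapped bases
are counted for both genes — and reported via a message; the alternative
(resolving overlaps before trimming) would silently change gene
boundaries that annotations define.

## Comparative statistics

Lifespan analyses log-transform lifespan, body mass and TMS (natural
log); DR counts stay untransformed (they are small counts and are
reported as such).

Shared ancestry is removed with Felsenstein's independent contrasts,
implemented by the standard pruning recursion: contrast
$(x_L - x_R)/\sqrt{v_L + v_R}$ at each internal node, ancestral values by
branch-length-weighted averaging, parent branch extended by
$v_L v_R/(v_L+v_R)$. Zero-length branches (e.g. from resolving
polytomies) are replaced by $10^{-8}\times$ tree height, with a message.
The implementation is cross-checked against `ape::pic` in the tests.
Contrast correlations are constrained through the origin (contrast signs
are arbitrary), with $t$-tests on $k - 1 - c$ degrees of freedom for $k$
contrasts and $c$ controls.

**Where covariates are controlled.** Two orderings are possible: (a)
residualize traits on covariates at the leaf level by OLS, then take
contrasts of the residuals; or (b) take contrasts of every trait and
control covariates at the contrast level by through-origin regression on
the control contrasts. The package implements both, and uses (b) for
inference (`contrast_correlation(control = )`, and the pipeline). The
reason is calibration: OLS residuals of phylogenetically correlated
traits no longer follow the Brownian scaling the contrast
standardization assumes, which makes ordering (a) mildly anticonservative
— the acceptance suite measures the type-I error of chain (b) at the
nominal 5% on 128-leaf Brownian nulls, and (b) is the standard
recommendation for contrast regression. Ordering (a) remains available
via `residualize()` for comparison with analyses that were computed that
way.

Subpopulation comparisons split species at the 50th/75th/90th lifespan
percentiles (ties go to the short-lived group), then compare counts with
a two-sample $t$-test (means), Mann–Whitney U (medians; exact for small
tie-free samples, normal approximation with tie and continuity correction
otherwise) and two-sample Kolmogorov–Smirnov (whole distributions).
Pairwise order-level comparisons report raw Mann–Whitney p-values without
multiplicity correction, the reporting convention of the analyses this
package reproduces. Ensemble comparisons use
$z = (\text{native} - \bar x_{null})/s_{null}$ with normal p-values. The
"constraint line" is an ordinary least-squares fit through a hand-chosen
support set of species (with explicit exclusions), reported together with
every species above the fitted line — it is a descriptive device, not an
estimator.

## The synthetic-data generator

`generate_genome()` lays out a circular molecule with the canonical
mammalian gene content — 1 D-loop, 2 rRNAs, 22 tRNAs, 13 protein-coding
genes — head-to-tail with 0–2 bp spacers, the D-loop absorbing the
remainder of the requested length (~1.0–1.1 kb at the 16.5 kb default).
Protein genes are built as ATG + body + TAA with amino acids drawn from a
fixed, plausible mitochondrial-protein composition (hydrophobic-heavy,
Leu at 16%) and codons drawn within each family from a geometric
distribution: codons ordered by the third-position preference seen in
mammalian mtDNA (A > C > T > G) receive weights
$1, \kappa, \kappa^2, \ldots$. The single concentration parameter
$\kappa$ spans uniform usage ($\kappa = 1$, $N_c$ near the 60-codon cap)
to near-complete bias ($\kappa \to 0$, $N_c \to 20$); the default
$\kappa = 0.5$ yields $N_c$ in the low-to-mid 40s, the mammalian range.
Everything non-coding is i.i.d. from the spec's base probabilities, which
default to human-like heavy-strand frequencies (A 0.309, C 0.313,
G 0.131, T 0.247 — positive AT skew, negative GC skew). One protein gene
and every third tRNA sit on the light strand to keep strand handling
honest.

`generate_clade()` grows a Yule tree (`ape::rphylo`), evolves
(log-lifespan, log-mass) by correlated Brownian motion (default
correlation 0.68, the value observed across mammals; root states 15 y and
5 kg; variances chosen so a clade spans roughly 2–100 years and
10 g–1000 kg), generates one genome per leaf — with $\kappa$ optionally
drifting along the tree on the logit scale, which is what makes $N_c$
vary across species — and can inject a known linear effect of the
standardized long-DR count into log-lifespan (`coupling`). Ground truth
is returned alongside, so parameter-recovery and null-calibration tests
have something exact to recover.

What the generator does *not* emulate: real mutational processes
(context-dependent substitution bias), sequence divergence along the tree
(each genome is an independent draw given its $\kappa$), secondary
structure in RNA genes, and repeat content created by mechanisms other
than composition and codon reuse. Passing tests therefore demonstrate
that the *pipeline* measures what it claims on data with known structure
— not that real mtDNA satisfies the generator's assumptions.

## Numerical and procedural choices

* Coordinates are 1-based inclusive in files (GenBank convention);
  wrap-around features carry `end < start` on circular molecules, and all
  conversion happens in the I/O module.
* Ambiguity codes are rejected at genome construction; the analyses are
  defined over A/C/G/T only.
* Nonstandard initiation codons (ATA/ATT/ATC) are accepted and translated
  as Met at position 1 only.
* All randomized quantities flow from explicit integer seeds; ensembles
  and the clade generator derive substreams by counter so results do not
  depend on evaluation order. The full pipeline is a pure function of
  (inputs, config, seed), and every report table carries the config hash
  and seed.
* Problem sizes used by the shipped analyses: the bundled synthetic
  compendium uses 24 species at full 16.5 kb genome scale with
  100-replicate ensembles for the reference species and 20 per species
  elsewhere; test-suite calibrations use 128-leaf trees with 1000 null
  replicates, and scanner verification uses 200 random sequences up to
  2 kb against the brute-force oracle.

## Known limitations

* The GenBank reader covers the single-record flat files mitochondrial
  genomes are deposited as (simple spans, `complement`, origin-spanning
  `join`); multi-segment joins (splicing) are out of scope and rejected.
* $N_c$ under `codonw_compat` reproduces CodonW's family conventions
  best-effort; CodonW's other options (which published values depended
  on) are not modelled.
* The TMS weight tables are reconstructed shapes, not measurements;
  absolute TMS values are only meaningful relative to a chosen table.
* The constraint line inherits all the fragility of fitting five chosen
  points; it is provided because the literature used it, and flagged
  accordingly.
* With very small clades (n around 10) the 90th-percentile subpopulation
  split leaves too few long-lived species for the $t$/MWU tests; the
  pipeline reports `NA` for those cells rather than failing the run.
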