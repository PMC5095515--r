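---
title: "Decomposing genomic differentiation landscapes across contact zones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing genomic differentiation landscapes across contact zones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(crowscape)
```

## The problem

When two recently diverged populations hybridize across a contact zone,
genome scans show a handful of windows with strikingly elevated relative
differentiation (F_ST) against a nearly undifferentiated background. Two very
different processes produce such peaks: divergent selection acting at the
contact zone (interesting for reproductive isolation), and linked selection —
background selection and selective sweeps reducing diversity wherever
recombination is low and the density of selection targets is high — which
operates in *every* population that shares the same genome architecture and
inflates F_ST without any role in isolation.

`crowscape` implements the comparative screen that separates the two. The
reference system is a Holarctic crow species complex: ten populations, two
plumage phenotypes, three phenotypic contact zones with ongoing gene flow,
and allopatric population pairs of matched phenotype available as controls.
The package also ships a synthetic-data generator that reproduces the
statistical structure of such a system with planted truth, so the whole
pipeline is testable end to end without the original sequencing data.

## The decomposition

For each comparison, window F_ST (Weir–Cockerham, components summed within
windows) is z-standardized over all windows:

    F_ST'(w) = (F_ST(w) - mean) / sd

so comparisons of very different overall differentiation share a scale
(genome-wide standard deviations). For a focal contact-zone pair, the
per-window maximum F_ST' over the five allopatric control pairs is a
conservative estimate of how much differentiation shared processes can
generate in that window; subtracting it gives net differentiation:

    ΔF_ST'(w) = F_ST'(w) - max over controls of F_ST'(w)

Windows above the 99th percentile of F_ST' are outliers; maximal runs of
adjacent outlier windows form peaks. A peak containing at least one ΔF_ST'
outlier is classified `contact_zone` (signal exceeding anything the controls
produce there); all other peaks are `shared` (attributed to linked selection
on the common architecture). `classify_peaks()` makes the classes mutually
exclusive and exhaustive over outlier windows.

Supporting evidence computed by the package, mirroring the published
analysis: Moran's I of windowed tracks (lag-1, row-normalized weights along
scaffolds, combined across scaffolds by weight sums); a permutation test for
outlier clustering; correlation panels of window statistics within and
between populations (with partial correlation controlling a mutation-rate
proxy such as dS); an OLS interaction model pi ~ rho + gene density +
rho:gene density whose positive interaction is the background-selection
signature; Mantel isolation-by-distance on F_ST/(1-F_ST) versus great-circle
distance (sphere of radius 6,371 km); and the tension-zone scaling s ~
(sigma/w)^2, under which a zone three times wider implies nine-fold weaker
selection at equal dispersal.

Haplotype scans (EHH, iHH, iHS, nSL, XP-EHH) detect recent positive
selection. Unstandardized iHS is ln(iHH_ancestral / iHH_derived) —
negative under a sweep on the derived background — standardized to mean 0,
s.d. 1 within 100 derived-allele-frequency bins; nSL is identical with
haplotype length counted in segregating sites; XP-EHH contrasts
all-haplotype iHH between two populations and is standardized genome-wide.
Single-SNP outliers take the 0.5th/99.5th percentile tails (1% combined),
and the expected number of SNPs flagged in all three contact zones by
chance is `n_shared * prod(alpha * prop_zone)`, with `prop_zone` the
fraction of a zone's outliers lying in the cross-zone shared-SNP set.

## The synthetic generator

No generative model is available for the real system, so the generator is a
declared stand-in built to reproduce the features the analysis relies on,
validated through the properties below.

**Genome and landscape.** 20 scaffolds x 100 windows of 50 kb. Per-window
recombination (rho) and gene-density covariates are monotone transforms of
AR(1) fields with a 10-window autocorrelation length. The linked-selection
factor B in (0, 1] is a deterministic monotone function of the two —
increasing in rho, decreasing in gene density, with the gene-density effect
strongest at low recombination (positive rho x gene-density interaction) —
reaching its minimum (0.25) exactly where rho is minimal and gene density
maximal.

**Frequencies.** Ancestral derived-allele frequencies follow the neutral
1/x density on (1/2N, 1-1/2N) with 2N = 2000; sampling is stratified within
windows (exact marginals, suppressed between-window composition noise — see
*Numerical choices*). Frequencies evolve down a 10-population tree by
Balding–Nichols draws with per-branch drift F = 1 - exp(-t / B_w), so drift
is amplified where B is small: the shared landscape. Site density per window
also scales with B (deterministically), reflecting diversity loss in the
ancestral population — this is what makes F_ST co-vary negatively with
D_xy and pi. The default tree makes the hybrid-zone pair (cor2–cnx1) among
the shallowest comparisons and cor1 (refugial) and the eastern clade deep,
matching the genome-wide F_ST spread (~0.02–0.25) of the reference system;
sample size is 10 diploids per population.

**Planted truth.** Contact-zone windows (20 by default) redraw the focal
pair's second member with drift boosted by 0.85 — divergent loci near
fixation against a background F_ST of ~0.02, as observed at real
contact-zone peaks, which carry fixed differences. Gene flow mixes sink
frequencies as (1-m) p_sink + m p_source (default: m = 0.05 across the
contact zone). Sweeps place the derived allele of a core SNP on a single
haplotype shared by half the haplotypes over a 400 kb tract — hard-sweep
haplotype spans of several hundred kb, well beyond the background LD scale,
giving slow EHH decay on the derived background. Haplotypes otherwise
follow a lag-1 copying chain (latent uniform persisting over distance d
with probability exp(-d / 10 kb), the fast LD decay typical of large avian
populations), which yields Binomial(2, p) genotypes marginally and a
tunable r^2 decay. The exclusion mask covers 5% of windows, drawn outside
planted features so truth tables remain exact.

**SNP density.** 40 SNPs per 50 kb window. The reference dataset carries
roughly 700 SNPs per 50 kb; 40 is the desk-scale compromise at which
window-level ratio-of-sums F_ST estimates remain stable enough for the
decomposition while a full 25-replicate recovery experiment runs in
minutes. Validation scenarios that are sensitive to per-window estimator
noise (the sign-structure panels, the neutral Tajima's D calibration) use
80–100 SNPs per window.

## What the generator does not emulate

Coalescent genealogical correlation between sites (sites are conditionally
independent given the frequencies), recombination-map realism, sequencing
error and coverage variation, unphased data (haplotypes are emitted
phased), and sex chromosomes. Passing tests therefore demonstrate that the
*pipeline* recovers planted structure of the expected kind and calibration;
they do not certify performance on real data with genealogical noise, nor
the demographic realism of the Balding–Nichols stand-in. Two quantitative
consequences are documented below under *Known limitations*.

## Numerical choices

- **Stratified ancestral frequencies.** Within each window the 1/x density
  is sampled by one uniform jitter per equal-probability stratum, then
  shuffled across positions. Marginals (hence every SFS expectation) are
  exact, while between-window variation in ancestral composition — which
  would couple all populations' diversity tracks through the shared SNP
  catalogue even with a flat landscape — is suppressed by a factor ~k
  relative to iid sampling. Site counts per window are deterministic given
  B for the same reason.
- **2N = 2000** for the ancestral density: the truncation at 1/2N must sit
  well below the sample singleton threshold 1/(2n) or rare variants are
  visibly deficient and Tajima's D shifts positive.
- **Percentiles** are empirical quantiles (type 7), outlier calls strictly
  above the cutoff; with all-equal tracks nothing is flagged.
- **Negative window F_ST** is reported as computed; values are clamped to
  [0, 1-1e-9] only inside PBS logs.
- **PBS** uses the whole-sum-divided-by-two form
  (-ln(1-F12) - ln(1-F13) + ln(1-F23)) / 2, the standard population branch
  statistic.
- **SFS statistics** assume constant sample size; within a window the modal
  called-allele count is used and deviating sites are excluded (count
  reported). Sites without ancestral state are excluded from unfolded
  statistics (Fay & Wu's H, Fu & Li's D) but retained for pi, F_ST and
  D_xy. Windows with fewer than 4 called alleles, or no usable sites, are
  flagged missing, never silently zero.
- **iHH truncation** at EHH < 0.05 (the customary scan default), trapezoid
  integration including the segment that crosses the threshold; sites whose
  EHH never decays before the scaffold end, or whose integral would span a
  physical gap > 200 kb, are flagged NA rather than extrapolated.
- **Coverage filter** "at least 50% of individuals genotyped per
  population" is inclusive at exactly 50%, per pair.
- **Coordinates**: VCF 1-based, BED 0-based half-open; a site at 1-based P
  belongs to window floor((P-1)/w). Trailing short windows are kept and
  flagged; D_xy normalizes by the actual callable span (window minus mask
  overlap).
- **Block jackknife** for Patterson's D uses 50-window (2.5 Mb) blocks,
  larger than any LD scale in the generator.
- **Clustering null.** The test statistic is the mean run length of
  flagged windows. The null shuffles flag positions uniformly within each
  scaffold, keeping per-scaffold outlier counts fixed. (A circular-rotation
  null was considered and rejected: rotation preserves run lengths apart
  from the boundary, so the statistic would be invariant under its own
  null.) The permutation p-value carries the +1 correction. At very sparse
  flag densities the statistic takes few values and the p-value is lumpy;
  the calibration checks run at a density where it is well resolved.
- **Control maximum with missing controls**: max over available controls;
  a window is dropped only when the focal value or all controls are
  missing. Peak merging uses strict adjacency by default (`max_gap`
  configurable).

## Design decisions on open points

- The per-zone outlier fraction in the shared-outlier expectation is 0.01
  (0.5th + 99.5th percentile tails). The alternative reading of the tails
  (0.05th percentile) and any other alpha remain available as parameters.
- F_ST' percentiles are computed per comparison, not pooled across
  comparisons.
- Window F_ST is the ratio of summed variance components (components
  averaged, then the ratio), not a mean of per-site ratios.
- ABBA-BABA uses the ancestral annotation as the outgroup allele and
  supports both a single-representative-individual mode and an
  allele-frequency mode.
- The generator plants contact-zone divergence on exactly one member of the
  focal pair (the second), so the drift excess is lineage-specific, as a
  PBS scan expects.

## Validation properties (computed by the test suite)

- Exact agreement (1e-10 relative) of pi, Watterson's theta, Tajima's D,
  Fay & Wu's H, Fu & Li's D, Weir–Cockerham components, window F_ST, D_xy,
  EHH, mean r^2 and Patterson's D with brute-force oracles on small
  fixtures; Moran's I against an independent implementation.
- Mean pairwise F_ST matches the Balding–Nichols expectation (drift summed
  from the pair's most recent common ancestor) within Monte-Carlo error.
- Decomposition recovery on the default scenario: planted-window
  sensitivity and contact-zone misclassification over 25 seeded replicates.
- The four correlation signs under a heterogeneous shared landscape, and
  their collapse under a flat landscape, on a three-clade validation
  scenario that removes shared ancestry as a confounder.
- Null calibrations: clustering-test and Mantel p-values uniform; per-bin
  mean 0 / s.d. 1 of standardized iHS and nSL; neutral Tajima's D.
- Sweep recovery: planted sweeps in the top 1% of |iHS| and |nSL|; XP-EHH
  positive extreme in the swept population.

Problem sizes in the suite (2,000-window recovery runs, 400–500-window
calibration runs, 25 replicates where replication is asserted) were chosen
as the package's desk-scale working points.

## Known limitations

- **F_ST–D_xy null coupling.** F_ST and D_xy of the same pair are computed
  from the same allele-frequency estimates, so window-level drift and
  sampling realizations couple them positively (r ≈ +0.2 under a flat
  landscape, independent of SNP density). The negative correlation observed
  under a shared landscape is therefore evidence *against* a positive null,
  which is stronger than against an idealized zero null — but a test
  asserting a zero null under flat B fails for this statistic pair, and is
  expected to.
- **Residual Tajima's D bias.** With sites conditionally independent given
  frequencies, the per-window D retains a small positive finite-S ratio
  bias (~+0.01 at 100 SNPs/window); the neutral calibration is run at a
  density where this sits below Monte-Carlo resolution.
- Balding–Nichols tips are not at mutation–drift equilibrium: SFS-shape
  statistics drift positive with increasing branch length, so the neutral
  calibration uses a shallow-drift scenario.
- Single-individual Patterson's D is strongly attenuated at desk-scale
  sample sizes; the frequency mode is the default in the analysis scripts.
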