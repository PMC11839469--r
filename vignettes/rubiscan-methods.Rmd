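---
title: "From pooled selection counts to CO2 kinetics: methods behind rubiscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From pooled selection counts to CO2 kinetics: methods behind rubiscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rubiscan)
```

## The measurement this package models

Rubisco fixes CO2 slowly and with modest affinity, and the question of how
far mutation can push its CO2 kinetics is best answered at scale. The
experimental design `rubiscan` analyzes couples rubisco activity to bacterial
growth: an *E. coli* strain lacking ribose phosphate isomerase (Δrpi) grows
on glycerol only when a plasmid-borne rubisco fixes CO2, so the growth rate
of each cell reports the carboxylation velocity of the rubisco variant it
carries. A library of every single amino-acid substitution of the 466-residue
Form II enzyme (465 mutable positions × 19 substitutions = 8,835 variants)
is tagged with random 30-nt plasmid barcodes (~20 per variant), grown
competitively, and sequenced before and after selection. Repeating the
selection across a titration of CO2 partial pressures turns the fitness
readout into an enzymological one: how a variant's relative fitness changes
with CO2 identifies its effective Michaelis constant for CO2.

## Enrichment statistic

For variant $j$ with barcodes $i$, the raw enrichment is

$$e_j = \mathrm{median}_i\!\left[\log_{10}
  \frac{N_{f,i} + N_{f,\mathrm{tot}}\,\alpha_p}
       {N_{0,i} + N_{0,\mathrm{tot}}\,\alpha_p}
  - \log_{10}\frac{N_{f,\mathrm{tot}}}{N_{0,\mathrm{tot}}}\right],$$

where $N_{0,i}$ and $N_{f,i}$ are a barcode's pre- and post-selection read
counts and the totals normalize sequencing depth. Two processing parameters
enter: a count threshold $c_\mathrm{min}$ (a barcode participates only if it
reaches $c_\mathrm{min}$ reads pre- *or* post-selection — the inclusive OR
reading of "either") and a pseudo-count constant $\alpha_p$ that is scaled by
the total reads of its timepoint, so a given $\alpha_p$ means the same
relative regularization at any depth. The median over barcodes (with the
usual mean-of-central-pair convention for even counts) makes the statistic
robust to individual barcode dropout.

Raw enrichments are then rescaled within every condition and replicate:

$$e_{j,\mathrm{norm}} = \frac{e_j - \tilde e_\mathrm{dead}}
                              {e_\mathrm{WT} - \tilde e_\mathrm{dead}},$$

with $e_\mathrm{WT}$ computed by the same median over the pool of all
wild-type barcodes and $\tilde e_\mathrm{dead}$ the median raw enrichment of
all mutants at the catalytic positions K166, K191, D193, E194, H287 and K329.
After this affine map the wild type sits at exactly 1 and the dead-panel
median at exactly 0, so normalized enrichment reads as a fitness on a
natural scale. The dead median is recomputed per condition and replicate
(normalization is defined "at each condition"; a pooled alternative would
leak between-replicate depth differences into the scale).

$c_\mathrm{min}$ and $\alpha_p$ are semi-arbitrary, so they are chosen by a
two-dimensional sweep (`sweep_processing_params()`): every grid combination
is scored by the mean pairwise Pearson correlation of normalized enrichments
across replicates, and the maximizing pair wins, with ties broken toward the
smaller threshold and smaller pseudo-count (the least interventionist
processing). Correlations equal to within 12 significant digits are treated
as tied so that floating-point noise cannot decide a tie. The defaults
$c_\mathrm{min} = 5$, $\alpha_p = 3.65\times10^{-7}$ are the sweep optimum of
the original selection data set.

## Ratiometric Michaelis–Menten model

Assuming log-phase growth with growth-rate differences proportional to
velocity differences, the normalized enrichment of a variant equals its
velocity relative to wild type, and the CO2 dependence follows

$$e_{j,\mathrm{norm}}([\mathrm{CO_2}]) =
  \frac{\tilde V_{\max,\mathrm{mut}}}{\tilde V_{\max,\mathrm{WT}}}
  \cdot
  \frac{\tilde K_{C,\mathrm{WT}} + [\mathrm{CO_2}]}
       {\tilde K_{C,\mathrm{mut}} + [\mathrm{CO_2}]},$$

with the wild-type constant fixed at the literature value
$\tilde K_{C,\mathrm{WT}} = 149\ \mu M$. The two free parameters are the
velocity ratio $\tilde V_{\max,\mathrm{mut}}/\tilde V_{\max,\mathrm{WT}}$
(which confounds turnover and expression and is therefore reported as a
ratio, not a $k_\mathrm{cat}$) and the mutant affinity
$\tilde K_{C,\mathrm{mut}}$. Gas-phase CO2 percentages convert to dissolved
concentrations by Henry's law with a van 't Hoff correction,
$K_H(T) = 0.0334\,e^{2400(1/T - 1/298.15)}$ mol L$^{-1}$ atm$^{-1}$, which
puts 5% CO2 at 37 °C at ≈1,220 μM — the "approximately 1,200 μM" of the
growth condition. Both constants are arguments of `dissolved_co2()`.

### Fitting

`fit_titration()` minimizes the squared residuals over all replicate points
jointly, with both parameters constrained positive
($0 \le$ ratio $\le 10$, $10^{-2} \le K_C \le 10^4\ \mu M$; equal pointwise
weights). For fixed $K_C$ the model is linear in the velocity ratio, so the
ratio is profiled analytically (clipped into its bounds) and the problem
reduces to one dimension: a 40-point log-spaced multi-start grid over $K_C$,
golden-section refinement, then a box-constrained quasi-Newton polish with
analytic gradients. This is exact on noiseless data (the package's
identifiability tests demand $10^{-6}$ relative recovery, which defeats
Gauss–Newton `nls()` — it fails on zero-residual fits), deterministic, and
fast enough for the bootstrap sweep (~0.4 ms per fit). Degenerate inputs are
resolved explicitly: all-zero enrichments return a velocity ratio of 0 with
an unidentifiable (NA) $K_C$; a flat objective ties toward the smallest
$K_C$; any solution pinned at a bound is flagged `boundary`.

### Reliability

$\tilde K_C$ estimates of weakly growing variants are sensitive to
$c_\mathrm{min}$ and $\alpha_p$. `reliability_sweep()` therefore refits every
variant across the full processing grid (11 $c_\mathrm{min}$ values linearly
spaced 0–50 × 10 $\alpha_p$ values log-spaced $10^{-9}$–$10^{-6}$), drawing
10 resamples of the replicates (with replacement, back to the original
replicate count — the minimal reading of "subsampling the replicates") in
each cell: 1,100 fits per variant. The sweep is summarized by a
quartile-based coefficient of variation,
$\mathrm{CV} = \mathrm{IQR} / (1.349\,|\mathrm{median}|)$, the
Gaussian-consistent robust counterpart of $\sigma/\mu$ — chosen because the
source procedure names both "s.d. over the mean" and "quartile-based", and
the robust form reconciles them against the occasional wild fit; plain
$\sigma/\mu$ remains available (`cv_method = "sd"`). A variant is reliable
iff CV < 1. Boundary-pinned fits contribute no $K_C$ (their affinity is
unidentifiable); a variant lacking a usable $K_C$ in more than half the grid
cells receives an infinite CV. The reported point estimate is the sweep
median $K_C$ — a sweep summary rather than any single "best" parameter set,
since no cell is privileged.

## The synthetic world

Because the deposited sequencing data are far beyond desk scale, every stage
is validated against a generator with known ground truth
(`generate_library()`, `simulate_selection()`, `simulate_reads()`). The
generator states the experiment it emulates; its defaults are fixed once and
are not tuning knobs:

* **Kinetic priors.** Mutant $K_C \sim 149\,e^{N(0,\,0.5)}$ μM (two-sided:
  affinity can improve — the screen's headline finding — or degrade);
  mutant $k_\mathrm{cat} \sim 8\,e^{-|N(0,\,0.7)|}$ s$^{-1}$, a half-normal
  decrement because no observed mutant exceeds wild-type turnover, with
  apparent fitness gains entering through a two-sided log-normal expression
  factor (sdlog 0.25). Wild-type anchors: $K_C = 149$ μM, $k_\mathrm{cat} =
  8$ s$^{-1}$ (a typical Form II turnover). Dead-panel mutants get
  $k_\mathrm{cat} = 0$ exactly.
* **Selection.** Growth rate interpolates linearly between a dead rate
  (0.06 h$^{-1}$) and the wild-type rate (0.6 h$^{-1}$) with relative
  velocity, per the proportionality assumption; the absolute rates are
  arbitrary (they cancel in the normalized enrichment) and only set count
  dynamic range. Selection time is set so the wild type completes
  $\log_2 100 \approx 6.64$ doublings, the 100-fold culture expansion of the
  protocol. Pre-selection barcode abundances are log-normal (sdlog 0.5) to
  mimic bottlenecking; reads are multinomial at the configured depth, so
  counts conserve depth exactly.
* **CO2 grid.** The titration levels of the original experiment are not
  stated, so the default grid {0.3, 0.7, 1.5, 3, 5, 10}% brackets the
  wild-type $K_C$ (149 μM ≈ 0.6% at 37 °C) and reaches saturation — the
  leverage a Michaelis fit needs.
* **Reads.** Long reads are anchor + barcode + anchor + coding sequence with
  i.i.d. substitutions on the coding payload at a PacBio-like 10% rate; the
  barcode region itself is read exactly. This isolates what the consensus
  step must fix (payload errors) from what exact-match counting assumes
  (barcode fidelity; 30-nt random tags make collisions negligible). Short
  reads are barcode amplicons only.

What the generator deliberately omits — and hence what a green test does
*not* establish: oxygenase chemistry and O2 dependence; expression modeled
beyond a scalar factor; barcode sequencing errors and chimeras; indel or
multi-mutation contamination of the library; growth-curve (OD) dynamics and
lag phases; batch effects between replicates beyond multinomial sampling.
End-to-end recovery on this world shows the estimator chain is consistent
and correctly propagates counting noise, not that it is robust to every
failure mode of real sequencing.

## Barcode mapping rules

Long-read bundles are grouped by barcode (default minimum support: 3 reads —
unstated in the source protocol; 3 is the smallest count that gives a
majority under a single corrupted read). Consensus is a per-column majority
vote; a tied column yields `N`, and any non-ACGT symbol invalidates the
record — conservative, because retention is an allowlist: a consensus is kept
only if it is exactly the reference coding sequence (wild type) or carries
exactly one amino-acid change that matches a designed variant with all
nucleotide edits inside that codon. Everything else — indels, second-site
edits, synonymous-only changes, undesigned substitutions — is `INVALID` and
excluded from counting. Comparisons are at the amino-acid level after
in-frame translation, positions 1-based from the initiator methionine.

## Conservation

`column_conservation()` maps each ungapped reference position to its
alignment column and reports, per position, the maximum amino-acid fraction
(a 90%-alanine column scores 0.9). Gaps and unknown residues (X/B/Z) are
excluded from the denominator by default — "fraction of the total sequences"
is ambiguous about gaps, and excluding them keeps conservation a statement
about residues actually observed; `count_gaps = TRUE` switches to the full
denominator. The alignment itself (e.g. a jackhmmer search) is an input, not
a package responsibility.

## In-vitro layer

Initial carboxylation rates come from NADH absorbance decay at 340 nm with a
2:1 NADH-to-carboxylation stoichiometry. The window search scores candidate
rectangles (starts every 5th point; lengths 10/20/40% of the trace) by
$R^2 \times$ (fraction of the total absorbance decrease covered), balancing
linearity against representativeness — a pure-$R^2$ rule would happily pick a
flat tail. Michaelis–Menten fits use the same profiled least squares as the
titration fit, with standard errors from the analytic $J^TJ$ covariance;
triplicate error bands follow the median / median±s.d. triple-fit recipe
(`fit_michaelis_menten_band()`). The CABP titration $k_\mathrm{cat}$ is the
y-intercept over x-intercept of the inhibition line — algebraically the slope
magnitude, which is how it is computed. MIMS specificity is the directly
stated ratio $S_{C/O} = \nu_C[\mathrm{O_2}]/(\nu_O[\mathrm{DIC}])$.
`co2_from_bicarbonate()` exposes the Henderson–Hasselbalch conversion with a
configurable apparent pK$_a'$; no single constant reproduces the printed
bicarbonate→CO2 range of the radiometric assay, so the conversion is a
utility, not a validated target.

## Known limitations

* $\tilde V_{\max}$ ratios confound turnover and expression by construction;
  the package never reports a per-variant $k_\mathrm{cat}$ from selection
  data.
* The CV < 1 reliability cut is calibrated to realistic counting noise; at
  very high simulated depth even near-dead variants can produce stable
  (small-CV) but biologically meaningless $K_C$ fits. Interpretation should
  always consider the velocity ratio alongside the flag.
* The growth model is linear in relative velocity with no saturation;
  variants much fitter than wild type would violate it, which is why the
  generator's priors do not produce them.
* Replicate resampling treats replicates as exchangeable; systematic batch
  effects are out of scope.

## Worked micro-example

```{r example, eval = FALSE}
ref <- random_reference(n_res = 466, seed = 42)
design <- reference_design(ref$protein, ref$cds,
                           mutable_positions = sort(c(dead_panel_positions(),
                                                      150, 200, 250)))
lib <- generate_library(design, sim_config(seed = 7, barcodes_per_variant = 20,
                                           depth = 1e6))
counts <- simulate_selection(lib, selection_conditions(replicates = 3))
norm <- normalize_enrichment(compute_enrichment(counts, lookup_from_library(lib)))
pairwise_replicate_correlation(norm)
fits <- reliability_sweep(counts, lookup_from_library(lib),
                          fit_config(c_min_grid = c(0, 25, 50),
                                     alpha_p_grid = 10^c(-9, -7.5, -6),
                                     n_subsamples = 3, seed = 7))
```

The README shows this example with the numbers it prints.
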