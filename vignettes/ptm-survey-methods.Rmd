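---
title: "Methods behind the ptmforge pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the ptmforge pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmforge)
```

ptmforge packages the computational methods of a systematic PTM survey of
the yeast histone methyltransferases (MTases) and demethylases (DMases):
eight enzymes digested with four proteases (trypsin, LysargiNase, Asp-N,
chymotrypsin) and fragmented two ways (HCD, EThcD), giving an
eight-experiment design per protein. This vignette explains each model and
procedure, the parameters that matter, the numerical choices, and what the
synthetic-data generators do and do not emulate.

## Peptide chemistry

Peptide neutral monoisotopic mass is the sum of residue masses plus one
water plus the modification mass shifts; m/z at charge $z$ is
$(M + z \cdot 1.007276)/z$. Residue masses come from the standard
monoisotopic elemental table and the modification registry
(`inst/extdata/modifications.tsv`) carries the usual shifts (phospho
+79.96633 Da, methyl +14.01565, dimethyl +28.03130, trimethyl +42.04695,
acetyl +42.01057, propionyl +56.02621, carbamidomethyl +57.02146, GG
+114.04293, oxidation +15.99491). Reported m/z values are rounded
half-even to 2 decimals; comparisons against printed values use a 0.005 Th
tolerance, i.e. agreement at the printed precision.

Histone samples are derivatized with propionic anhydride before digestion.
`propionylate()` encodes the resulting chemistry: propionylation requires a
free lysine ε-amine, so me0 lysines gain propionyl, me1 lysines gain
methyl + propionyl, and me2/me3 lysines carry only their methyl marks.
For the triply charged H3 peptide KSAPSTGGVKKPHR (H3 residues 27–40;
peptide position 10 is K36) this yields the four quantified species —
me0/me1 triply propionylated, me2/me3 doubly propionylated — whose m/z the
package reproduces to 2 decimals. The peptide N-terminus is left
underivatized because digestion follows derivatization, so tryptic termini
are generated after the propionylation step.

Protease rules are fully specific: trypsin cleaves C-terminal to K/R but
not before proline; LysargiNase N-terminal to K/R; chymotrypsin (the
TrypChymo search specificity) C-terminal to F/Y/W/L/K/R, not before
proline. Asp-N search configurations differ between laboratories on
whether cleavage is N-terminal to D only or to D and E; both are
supported, and D+E is the default here (matching the ambic variant of the
search-engine definition). Digestion enumerates all products with up to
`max_missed` missed cleavages (three in the original searches).

## PSM filtering and site collation

`filter_psms()` applies the survey's thresholds with the boundary
semantics of the printed inequalities: FDR strictly below 0.01 and
expectation value strictly below 0.05; ion score and localization
probability inclusive (≥ 30 and ≥ 95%). When one PSM reports several
modified residues, every site must clear the localization cutoff or the
whole PSM is discarded — the conservative reading of a "high-confidence"
site list, since a partially localized PSM does not cleanly support any of
its sites. The upstream survey also manually inspected spectra; that step
has no algorithmic definition, so it is represented only as an optional
pass-through flag and is not applied by the filter.

`collate_sites()` maps peptides to their proteins by exact substring
match, converts peptide-local modification positions to protein
coordinates (1-based throughout), deduplicates peptidoforms on
(sequence, modification set) and sites on (protein, position, type), and
aggregates the (protease, fragmentation) evidence per site. Novelty is
assigned against a plain-TSV known-site list so literature collations can
be dropped in.

## Coverage

`map_peptides()` marks, per experiment, every residue covered by at least
one peptide occurrence (a peptide occurring at several positions marks all
of them; at observed peptide lengths such ambiguity is rare and the
choice inflates nothing downstream). Depth is the number of distinct
experiments covering a residue (0–8 in the full design); combined coverage
is the fraction of residues with depth ≥ 1, reported as percent with one
decimal.

## XIC integration and stoichiometry

The original analysis used a vendor integrator (ICIS) whose smoothing and
baseline parameters are unpublished; `integrate_peak()` is therefore a
documented functional replacement satisfying the same contract — the area
under the XIC peak:

* baseline: median of the lowest decile of in-window intensities;
* peak bounds: walk outward from the apex of a lightly smoothed
  (5-point running mean) copy of the signal while it stays above the
  window median plus 2% of the apex rise. The median is used as the bound
  floor because the decile baseline sits below the noise band and would
  let the bounds run to the window edges; truncating a Gaussian peak at 2%
  of its apex forfeits about 0.5% of its area, within the 1% accuracy
  target;
* a no-peak guard declares the trace empty (zero area, flagged, not an
  error) when the smoothed apex fails to clear five robust standard
  deviations (MAD) of the smoothed signal — the all-zero and pure-noise
  cases, e.g. a deletion strain with all methylation ablated;
* area: trapezoidal integral of baseline-subtracted intensity, clipped at
  zero, between the bounds. An explicit `rt_window` overrides detection.

Occupancy is relative: modified/(modified + unmodified) peak area, with no
correction for ionization-efficiency differences between the forms, and
the methylation-state distribution likewise normalizes the four state
areas by their total. Isobaric peptidoforms are distinguished by
retention time: each detected peak is assigned to the nearest expected
retention time, with a configurable 0.5-minute tolerance; numerically
equidistant or out-of-tolerance peaks are flagged rather than guessed.

## Disorder, domains, alignment, and the net-charge model

A residue is called disordered when its score reaches the 0.5 threshold
(the usual convention for DISOPRED-style scores; configurable). Domain
intervals are 1-based and endpoint-inclusive; BED-style half-open input is
converted on read.

Cross-species anchoring uses global alignment with free end gaps
(semi-global Needleman–Wunsch): internal gaps pay an affine cost
(open 12 + 3 per position by default) while terminal gaps are free. The
original analysis names only the alignment mode, not the scoring, so
BLOSUM62 with those common free-end-gap penalties is the default and all
three are configurable; conserved-site counts on real orthologs are
consequently not bit-reproducible and are validated instead against a
brute-force alignment-enumeration oracle on short sequences. Ties in the
dynamic program break deterministically (diagonal, then a residue of the
anchor against a gap). A site aligned to a gap is "not aligned"; aligned
to S/T/Y it is "residue conserved"; and additionally listed in the partner
phosphosite set, "phosphosite conserved". Extended multi-species
comparisons are realized as repeated pairwise anchoring to the yeast
sequence rather than a full multiple alignment — a documented limitation.

The net-charge model for the Set2p N-terminus counts +1 for the free
N-terminus and each K/R, −1 for each D/E, −2 for a phosphorylatable serine
in its phosphorylated state, 0 for a phosphonull S→A, and −1 for a
phosphomimetic S→D (a mimetic carries one, not two, negative charges);
histidine counts 0. `set2_nterm_window()` builds the 15-residue window
from the documented charge-bearing features (K3, phosphoserines 6/8/10,
EDEKE acidic patch at 11–15) with neutral Gly/Ala placeholders at the
remaining positions: the charge depends only on the documented features,
and the window is a feature-faithful model, not the native UniProt
sequence.

## Ordinal regression on methylation states

Strain effects on the ordered states me0 < me1 < me2 < me3 are estimated
with the cumulative-logit proportional-odds model,
$\mathrm{logit}\, P(Y \le j \mid s) = \theta_j - \beta_s$, reference
strain at $\beta = 0$; $e^{\beta}$ is the common odds ratio of sitting
above any state boundary relative to the reference. The source analysis
does not state whether replicate proportions or raw counts were modeled,
nor the effective sample size behind its p-values; ptmforge therefore
treats each replicate's fractions as a weighted multinomial of a declared
effective size (default 1000) and exposes a raw-counts mode, so
significance depends on an explicit precision rather than hidden scaling.

Fitting maximizes the weighted multinomial likelihood with an analytic
gradient: a BFGS warm start from the pooled cumulative logits, then Newton
iterations with step-halving on a finite-difference Hessian until the
gradient norm is below 1e-6 (an explicit non-convergence error otherwise).
Standard errors come from the inverse observed information; per-strain
p-values are Wald, with the figure convention `**` marking p < 0.01.
Complete separation (e.g. a strain with all mass in one state) is detected
via extreme coefficients or a singular information matrix and flagged as a
diagnostic rather than reported as a trustworthy estimate.

The proportional-odds assumption is checked against the adjacent-category
model with separate per-boundary slopes. With a single categorical
covariate that model is saturated, so its ML solution is the weighted
per-strain state proportions and is computed in closed form (zero cells
flagged). The likelihood-ratio statistic $2(\ell_1 - \ell_0)$ is referred
to a chi-square with degrees of freedom equal to the parameter-count
difference, $2(S-1)$ for $S$ strains and four states.

## Network assembly

Evidence admission follows the printed thresholds: motif predictions with
score strictly above 2; perturbation quantifications with p < 0.05 and
fold-change < −1.5 for kinases or > +1.5 for phosphatases (deleting a
kinase should deplete, deleting a phosphatase enrich, the substrate
phosphopeptide). The fold-change scale is taken as the signed linear scale
as printed, with a configuration switch, since the source does not state
log transformation. Physical interactions are admitted as their own
evidence line; genetic interactions never create an edge and only
corroborate edges already supported by a non-genetic line. Edges merge on
(regulator, substrate, site); protein-level records coexist with
site-level ones. Regulators touching two or more enzymes are flagged as
multi-substrate hubs. Conflicting quantification records from different
source datasets are kept as separate evidence lines rather than
deduplicated, since the original merging rule is unstated.

## Synthetic data: what it emulates, and what it does not

All generators are pure functions of (parameters, seed); a global seed
fans out to per-generator child seeds via the documented derivation in
`child_seed()`, so any fixture can be regenerated independently. Defaults
mirror the study conditions: PSM quality scores straddle the four filter
thresholds; XIC pairs carry Gaussian chromatographic peaks (σ = 0.15 min
on a 30-min gradient sampled at 0.02 min) with planted occupancies
spanning the observed sub-0.1%–26% range, and iid Gaussian noise at 5% of
each trace's own apex (electrospray XIC noise scales with signal; a trace
with no planted peak receives noise scaled to its partner so an
occupancy-zero trace is pure noise, not a blank); methylation counts are
multinomial draws from the proportional-odds model itself, three
replicates of effective size 1000 per strain as in the triplicate
cultures; evidence tables plant passing records and noise records that
each fail at least one admission rule.

The generators deliberately do not simulate raw spectra, fragment ions,
chromatographic tailing or drift, correlated (shot-noise) baselines,
ionization-efficiency differences between peptidoforms, or
search-engine score distributions conditioned on spectral quality. Passing
the recovery tests therefore demonstrates correctness of the computations
under the stated noise model — not robustness to every artifact of real
LC-MS data.

Validation problem sizes were chosen to exercise the methods at desk
scale: 100 seeded occupancy replicates across the planted range
(recovered within ±0.03), 100 proportional-odds recovery replicates at
effective n = 2000 per strain (95% CI coverage ≥ 90%), 200 null
simulations for the LR-test calibration (Kolmogorov–Smirnov uniformity not
rejected at 0.01), and exhaustive alignment-path enumeration for one
random pair per length combination up to 8×8 over a reduced alphabet.

## Known limitations

* The XIC integrator is a stand-in for an unpublished vendor algorithm;
  absolute areas can differ from ICIS output even where relative
  quantities agree.
* Occupancies are relative, not absolute stoichiometries.
* The adjacent-category fit is closed-form only because the covariate is
  categorical; continuous covariates would need iterative fitting.
* Real-data site tallies and p-values from the original survey require
  the deposited raw data and unprinted replicate counts, and are out of
  scope; the package validates against planted ground truth instead.
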