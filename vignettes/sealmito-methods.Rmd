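---
title: "sealmito: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sealmito: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`sealmito` implements two linked analyses for fasting, molting phocid
seals, plus the transcriptomic scoring conventions that accompany them:

1. **SUIT high-resolution respirometry** of permeabilized skeletal muscle:
   converting chamber oxygen traces into respiratory-state fluxes (leak
   without adenylates `L_n`, OXPHOS capacity `P`, oligomycin-inhibited leak
   `L_Omy`, uncoupled ETS capacity `E`, and maximal complex I/II fluxes),
   quality control, OXPHOS-anchored standardization, control ratios
   (`FCR = P/E`, `SCR_CI = CI/P`, `SCR_CII = CII/P`, `CCR_Ln = L_n/P`), and
   paired pre/post-molt comparison.
2. **A mass-loss bioenergetic budget**: apportioning daily mass loss into
   pelage, water, fat and fat-free mass, converting to energy with tissue
   energy equivalents, and extrapolating a whole-muscle leak respiratory
   capacity from the lowest measured leak flux.

Everything runs from synthetic data generated in-package: no animal data,
instrument files, or sequencing downloads are required or used.

# Respirometry model

## From concentration to flux

A chamber run records oxygen concentration $c(t)$ (nmol ml$^{-1}$). The
tissue's mass-specific flux is

$$J(t) = -\frac{dc}{dt}\,\frac{V}{m}\times 1000
\quad \text{(pmol O}_2\text{ s}^{-1}\text{ mg}^{-1}),$$

with chamber volume $V$ (ml) and wet tissue mass $m$ (mg). The derivative
is estimated by a local quadratic fit over a `smoothing_window` (default
20 s); on uniformly sampled traces this reduces to a Savitzky–Golay
convolution. Samples within one smoothing window of a reoxygenation event
are masked: the concentration jump makes the derivative meaningless there.

## Steady-state detection

Instrument software leaves the plateau-selection rule unspecified, so the
detector is explicit and parameterized. Titration events are clustered
into steps (additions within 5 s count as one step) and each inter-event
segment is searched for the *latest* steady window, reflecting the
protocol logic that a new steady state is established before the next
titration:

* a fixed-length window (default 60 s) slides backwards from the segment
  end in 10 s steps;
* a window is *steady* when its two half-window concentration slopes,
  expressed as fluxes $J_1$, $J_2$, satisfy
  $|J_2 - J_1| \le \max(\tau\,|J|,\; 3\,\mathrm{SE}(J_2-J_1))$
  with relative tolerance $\tau$ (`stability_tol`, default 2%) and the
  standard error taken from the two half-window regressions;
* the first steady window is then extended backwards while stability
  holds, and the reported flux is the linear-regression slope of
  concentration over the maximal stable span.

Two choices here deserve justification. First, the **noise-aware escape**
(`3 SE`): with clean data the SE is ~0 and the criterion is exactly the
relative 2% rule, but with realistic concentration noise (sd up to
1 nmol ml$^{-1}$) the slope difference over 60 s cannot be resolved to 2%
of a small flux, and a purely relative rule would reject every window of
honestly steady data. A window is therefore rejected only when its drift
is both practically and statistically distinguishable from flat. Second,
the **maximal-span regression** rather than the accepted window's mean: a
60 s window's flux estimate has an irreducible standard deviation of
several pmol s$^{-1}$ mg$^{-1}$ at that noise level (slope-estimate sd
$\sigma\sqrt{12/T^3}$ scaled by $1000\,V/m$), which is larger than the
smallest states of interest. Regressing over the whole stable span (often
~250 s) is unbiased, identical for noiseless data, and several-fold more
precise. Because even a full segment cannot pin a small flux to 5% in a
*single* noisy run, recovery under noise is asserted on the mean across
seeded replicates (unbiasedness), not per replicate; the noiseless
round trip is asserted to 10^-6^.

Steps with no qualifying window are reported with missing flux and a QC
flag (`no_window` / `unstable`), never dropped silently.

## QC and standardization

* **Baseline correction**: the chamber's background flux (step 1, before
  any titration) is subtracted from every state; negative corrected fluxes
  are clipped to 0 with a warning (respiration below instrument background
  is non-physical noise). Baseline is measured per run.
* **Cytochrome-c test**: a strictly greater than 10% flux increase after
  exogenous cytochrome c marks a damaged outer mitochondrial membrane and
  excludes the whole run from aggregation. The comparison uses
  baseline-corrected OXPHOS vs the post-CytC flux.
* **Oxygen window**: excursions outside the closed interval
  [250, 400] nmol ml$^{-1}$ are warnings only — diffusion limitation is a
  data-quality concern, not an exclusion rule.
* **Aggregation**: states measured in several protocols (Ln, OXPHOS, ETS)
  are averaged across non-excluded runs; OXPHOS is pooled across all four
  protocols unconditionally (the package reproduces the lipid-substrate
  justification test as an ordinary paired comparison in the pipeline, but
  pooling does not branch on it). Single-measure states are standardized
  to the sample's mean OXPHOS:
  $\mathrm{std}_X = (X_p / P_p) \times \bar P$, where $P_p$ is the
  measuring run's own OXPHOS. The two leak estimates `L_n` and `L_Omy`
  are kept distinct end to end; they estimate different quantities and are
  known to differ.
* **Paired comparison**: two-sided paired t-test at $\alpha = 0.05$ with
  listwise deletion of incomplete pairs; identical differences raise a
  no-variance error rather than returning an undefined statistic.
  "Repeated measures t-tests" and "paired t-tests" are treated as the same
  procedure.

## Protocol definitions

The four shipped protocols follow the standard SUIT design: A and B reach
`L_n` with complex-I substrates and no adenylates, OXPHOS with saturating
ADP and combined CI+CII substrates, then uncouple (CCCP) for ETS; B
additionally inhibits ATP synthase (oligomycin) for `L_Omy`; CI and CII
reach OXPHOS and ETS and then isolate complex I (malonate) or complex II
(rotenone). Octanoylcarnitine appears only in A and B. Every protocol
includes a cytochrome-c step after OXPHOS. The table ships as a TSV
(`inst/extdata/suit_protocols.tsv`) and is user-overridable; agent working
concentrations follow the published titration list (e.g. 5 mM ADP, 10 µM
cytochrome c, 0.5 µM CCCP).

# Bioenergetic model

Daily mass loss $\dot m = (m_{pre} - m_{post})/d$ is apportioned with
fixed composition fractions (pelage 0.14, fat 0.41, water 0.25,
metabolizable fat-free mass 0.20 of total loss; they must sum to 1).
Energy comes from tissue equivalents — fat 9 kcal g$^{-1}$
(37.7 kJ g$^{-1}$), FFM 1 kcal g$^{-1}$ (4.2 kJ g$^{-1}$):

* the **kcal path** ($1000(9\,\dot m_{fat} + 1\,\dot m_{ffm})$) is
  canonical for the kcal figure;
* the **kJ path** ($37.7\,\dot m_{fat} + 4.2\,\dot m_{ffm}$, MJ day$^{-1}$)
  is canonical for the MJ figures.

The two differ by ~0.3% because 9 kcal g$^{-1} \ne 37.7/4.184$; both are
reported and asserted to agree within 1%. The FFM hydration detail (5%
dry matter, 15% additional water) is stored but not used in the energy
arithmetic: the 1 kcal g$^{-1}$ equivalent applies to hydrated FFM, which
is the only reading consistent with the published kcal figure.

Flux conversion uses the identity 1 pmol s$^{-1}$ mg$^{-1}$ =
1 µmol s$^{-1}$ kg$^{-1}$ and the STP molar volume (22.4 l mol$^{-1}$,
configurable), giving
$\mathrm{ml\,O_2\,kg^{-1}\,min^{-1}} = 1.344 \times
\mathrm{pmol\,s^{-1}\,mg^{-1}}$. Whole-muscle leak capacity multiplies by
muscle mass (28% of body mass), 1440 min day$^{-1}$ and the fat-oxidation
oxygen equivalent 19.7 kJ l$^{-1}$, with unrounded intermediates
throughout. Field metabolic rate scales body mass by
106.5 kJ kg$^{-1}$ day$^{-1}$. Cohort-level figures are derived from
cohort-mean inputs (mean of pre/post masses averaged over animals), the
convention behind the published table; per-animal rows are also emitted.

# Enrichment scoring

Differentially expressed genes are called with strict cut-offs
(`padj < 0.05` and `|log2FC| > 1`; boundary values excluded, `NA` adjusted
p never called). Per gene set, the one-sided Fisher exact p is the
hypergeometric upper tail of the 2×2 overlap table; BH adjustment is a
hand-implemented step-up tested against `stats::p.adjust`. The background
universe defaults to the genes present in the DE table (the assayed
universe), not the whole genome; it is configurable.

The combined score is $\ln(p) \times z$, where $z$ is the deviation of the
set's p-value *rank* from its expected rank under random queries of the
same size: the proprietary lookup used by the popular web tool is replaced
by an explicit seeded permutation scheme (`n_permutations >= 100`).
**Sign convention**: $z = (\mathrm{rank}_{obs} -
\mathbb E[\mathrm{rank}])/\mathrm{sd}(\mathrm{rank})$, so a set more
enriched than chance ranks better (lower) than expected, $z < 0$, and
$\ln(p) \times z > 0$ — enriched sets with small p get large positive
scores, matching the published description of the score. The natural log
is used ("log" unqualified). Ties get mean ranks, so duplicated sets score
identically; $p = 0$ is capped at the smallest positive double with a
warning.

# Synthetic data: what it emulates, and what a green test establishes

The trace generator integrates piecewise-constant true fluxes (state flux
plus instrument baseline) into a declining concentration, switches states
at protocol-ordered titration events (default dwell 300 s, optional
jitter), reoxygenates to 400 nmol ml$^{-1}$ whenever oxygen reaches
250 nmol ml$^{-1}$, bumps flux by `cytc_bump_frac` at the cytochrome-c
step (2% for a healthy membrane; set 15% to synthesize a failing run), and
adds i.i.d. Gaussian noise to the *observed* concentration. Noise is not
truncated at the chamber bound — sensor noise rides on the reading, and
clamping it at 400 would bias the baseline segment's slope (this was
observable as a spurious ~3% leak bias before the choice was made); the
$(0, \mathrm{o2\_start}]$ range invariant therefore applies to the
noise-free path. Defaults are the stated study world: 2 ml chamber,
2–5 mg tissue (default 3.5), leak `L_n` = 13 pmol s$^{-1}$ mg$^{-1}$ (the
lowest published leak measure), `L_Omy` about twice that, OXPHOS 55, ETS
70, CI 40, CII 35.

What the generator does **not** emulate: exponential transients after
titrations (states switch instantaneously), instrument drift and
calibration error, oxygen back-diffusion, substrate depletion within a
segment, or biological run-to-run variance beyond the lognormal
between-animal factors used by the pipeline driver. A green round-trip
test therefore establishes that the detector is unbiased and exact on
piecewise-steady signals under Gaussian sensor noise — not that it is
robust to every pathology of real instrument data.

The cohort generator draws from the published cohort conditions
(388 ± 50 kg pre-molt, 3 kg day$^{-1}$ loss, ~34 days ashore) and floors
post-molt mass at half the pre-molt mass. The DE generator gives null
genes uniform p-values and `N(0, 0.3)` fold changes, spiked genes
p < 10$^{-6}$ and |log2FC| at or above the requested effect.

# Numerical and interface choices

* All fluxes are pmol O$_2$ s$^{-1}$ mg$^{-1}$ internally; conversions
  happen only at I/O and in the bioenergetics module.
* Every stochastic routine takes an explicit seed; `NULL` means the
  ambient RNG stream. Generators are deterministic given a seed and
  pinned by frozen checksum fixtures.
* Output TSVs use 6-significant-digit fixed formatting so reruns are
  byte-identical and diffable; a JSON QC report lists excluded runs with
  reasons, oxygen-window warnings and missing states.
* Run metadata dialects: a `# key: value` comment block in the trace CSV
  and/or a JSON sidecar (no YAML parser is available in the supported
  dependency set; the comment block covers the human-editable case).
* Degenerate inputs fail loudly with classed conditions
  (`sealmito_no_variance`, `sealmito_zero_denominator`,
  `sealmito_missing_baseline`, ...) rather than returning NaN.

# Known limitations

* No instrument-vendor binary parsing; CSV export only. No
  oxygen-solubility/temperature recalibration — calibration is assumed
  upstream.
* The steady-state criterion used by the original instrument software is
  unknown; the detector's parameters are exposed and its defaults
  documented above, but parameter choices can move individual state
  estimates by a few percent at high noise.
* Statistical treatment is limited to the paired t-test; no
  repeated-measures ANOVA or mixed models.
* The permutation z-score is a calibrated replacement, not a reimplementation,
  of the web tool's expected-rank tables; combined scores are comparable
  within a run, not across tools.
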