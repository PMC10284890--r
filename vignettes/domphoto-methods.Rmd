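---
title: "Methods: coupled photochemical and biological DOM degradation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled photochemical and biological DOM degradation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

Sunlight alters the chemistry of dissolved organic matter (DOM) in lake
water, and that alteration changes how much of the dissolved organic carbon
(DOC) microbes subsequently respire to CO2. `domphoto` implements the full
analysis chain used to ask *which* photochemical products drive that
response across a set of lakes: ultrahigh-resolution mass spectrometry
(FT-ICR MS) peak lists are converted to molecular formulas, formulas to
aromaticity and oxidation-state indices and compound classes, paired
light/dark samples to photo-produced and photo-degraded formula sets, and
per-lake respiration contrasts to a log response ratio that is regressed on
the chemistry of those sets. A seeded synthetic-study generator provides
ground truth for every stage, so the pipeline's statistical behaviour
(sensitivity, specificity, type-I error, coefficient recovery) is testable
end to end without any external data.

# Formula assignment

Peaks are singly charged deprotonated ions, so the neutral monoisotopic
mass is `m/z + 1.00727646677`. Candidate CHONS compositions (N and S at
most one atom each) are enumerated exhaustively by mass balance: oxygen up
to `mass/15.994`, carbon up to `mass/12`, hydrogen solved and rounded (at
the sub-2-ppm tolerances used here the rounded hydrogen count is the only
one that can fall inside the window, one hydrogen being about 1250 ppm at
800 Da). Candidates are filtered to `0.3 < H/C < 2.2` and `O/C < 1.2`
(strict bounds, as printed), a neutral-mass window of 100-800 Da
(inclusive), and the valence rule `H <= 2C + N + 2` (DBE >= 0) -- without
the valence rule the H/C ceiling alone admits compositions more
hydrogen-rich than a saturated acyclic molecule, which cannot exist.
Ambiguity is resolved by the least-heteroatom rule: the candidate with the
smallest N + S wins; ties are broken by the smallest absolute mass error,
and a residual exact tie is reported as `ambiguous` rather than resolved
arbitrarily. The default tolerance is 1 ppm; the instrument-grade
post-calibration accuracy this represents is configurable
(`assign_peaklist(tol_ppm = )`), as is the S/N gate (default: peaks with
S/N at or below 4 are skipped).

For speed, `assign_peaklist()` serves the enumerate-and-filter step from a
precomputed, mass-sorted table of every rule-passing formula
(`enumerate_formula_space()`, about 1.8e5 compositions for the default
rules). Because the filter rules do not depend on the peak, a window lookup
in this table is exactly equivalent to running the per-peak chain, and the
test suite asserts that equivalence directly.

# Molecular indices and compound classes

Per formula the package computes double bond equivalence
`DBE = 1 + (2C - H + N)/2`, the nominal oxidation state of carbon
`NOSC = 4 - (4C + H - 3N - 2O - 2S)/C`, and the modified aromaticity index
`AImod = (1 + C - O/2 - S - (N + H)/2) / (C - O/2 - N - S)`. When the AImod
numerator or denominator is non-positive the raw value is not a meaningful
aromaticity and the index is clamped to 0, the conventional treatment.
Classes are assigned in decreasing order of aromaticity -- polycyclic
aromatics (CA, `AImod > 0.66`), polyphenols (Pol, `0.50 < AImod <= 0.66`),
highly unsaturated/phenolic (Uns, `AImod <= 0.50` and `H/C < 1.5`),
aliphatics (Ali, `1.5 <= H/C <= 2.0`, boundaries inclusive as printed) --
so the precedence resolves the rare overlap where a high-AImod formula also
has aliphatic-range H/C. Formulas with `2.0 < H/C < 2.2` pass the
assignment filter but fall outside all four printed classes; they are
labelled `Other`, carried in the class shares (which always sum to 1), and
excluded from the four-class ratios. Sample summaries default to
intensity-weighted class shares and unweighted index means; both estimators
are exposed because the choice is not dictated by the method itself.

# Optical indices

Spectra are stored as decadic absorbance exactly as measured;
`napierian_a()` applies the 2.303 conversion and the path length at the
point of use. SUVA254 is `A(254) / (path_m x DOC)`. Spectral slopes are
log-linear ordinary least squares over 275-295 and 350-400 nm (the fit is
on `ln a` versus wavelength, not a nonlinear exponential fit), returned
with positive sign, and their ratio S_R is the standard inverse
molecular-weight proxy; at least five positive-absorbance grid points are
required per window. BIX is the emission ratio 380/430 nm at 310 nm
excitation with bilinear interpolation; HIX uses the overlapping-band form,
integrating emission 435-480 nm over 300-445 nm at the excitation row
nearest 254 nm (within 2 nm), by the trapezoid rule with interpolated band
endpoints. Interpolation is linear/bilinear throughout: the instruments
produce ~1 nm-class grids on which higher-order schemes buy nothing.
Scatter (Raman/Rayleigh) correction of EEMs is assumed done upstream.

# Differential formula sets

Two paired samples (dark control versus light-exposed, or light-exposed
versus post-incubation) are compared formula by formula. A formula present
in only one sample is produced or degraded by presence alone. For shared
formulas the dual-threshold method requires the raw-intensity ratio *and*
the total-normalised relative-intensity ratio to exceed `1 + frac`
(produced) or fall below `1/(1 + frac)` (degraded), with `frac = 0.20` by
default. Two readings of a "20% change" rule were possible; thresholding
the ratio was chosen because it is the only form that is exactly symmetric
(swapping the samples swaps produced and degraded, a property the package
tests) and because its large-`frac` limit degenerates cleanly to the
presence/absence method, which is also provided as a cross-validation
(`compare_presence_absence()`, with `method_concordance()` reporting
per-label Jaccard indices and cross-pair correlations of set-level
chemistry). The dual raw/normalised condition guards against total-signal
drift between acquisitions; requiring both (a conjunction) is the stricter
and more conservative reading. The threshold is a fixed effect-size
criterion, not a statistical test, so no multiple-testing correction
applies inside it; rank-sum comparisons across sets use two-sided tests
with Benjamini-Hochberg control where families of comparisons arise.

`set_overlap_analysis()` implements the overlap diagnostic: per lake, the
median AImod of photo-produced (PP), photo-degraded (PD) and bio-degraded
(BD) sets, Wilcoxon rank-sum contrasts, and which of PP or PD sits closer
to BD -- the signature of whether sunlight makes, or removes, what the
microbes eat.

# Respiration and the statistical layer

CO2 production over an incubation interval is the rise in cumulative
headspace CO2 from the day-0 background to day 7 or 28, minus the same rise
in a sterile blank; negative corrected values are retained and flagged
because they are legitimate measurement noise around zero. The response
ratio is `ln(light mean / dark mean)` with treatment means pooled over the
two incubation temperatures -- pooling is justified inside the pipeline by
the sunlight-by-temperature interaction being null by construction in the
generator, and testable on real data via `factorial_anova()` (type-II sums
of squares, identical to type I/III on the balanced design; interaction
terms keep `A:B` names). Chemistry response ratios default to the same log
form, with a plain-ratio option. DOM content is the first principal
component of z-scored DOC and DON, oriented so the DOC loading is positive;
with two variables its variance explained has the closed form
`(1 + r)/2`, which the tests pin. Standardized regression coefficients are
Pearson correlations with the usual two-sided t test on n - 2 degrees of
freedom. Log transformation of responses is an explicit per-call choice,
never silent.

# The synthetic-study generator

The generator emulates the incubation design the analysis targets: 10
lakes spanning a DOM gradient, 2 light treatments x 2 temperatures x 3
replicates (120 microcosms plus sterile blanks), DOC 5.69-16.76 mg C/L,
DON 0.33-1.35 mg/L, CDOM a300 8.44-65.87 1/m, BIX in the 0.5-0.8
terrestrial range, and a CO2 response ratio spanning roughly -0.6 to +1
across lakes. Each lake's dark formula pool is a class-stratified draw from
a shared library (default mix CA 4%, Pol 8%, Uns 62%, Ali 22%, Other 4%,
the aromatic-poor, unsaturated-rich composition typical of terrestrial
DOM). Light exposure removes a fixed per-class fraction and injects new
formulas at per-class rates `base + slope x z`, where `z` is the lake's
standardized DOM score; the CA and Pol injection slopes are positive, so
high-DOM lakes photo-produce more aromatics, and the aliphatic slope is
negative. Microbial incubation then removes a class-biased fraction of the
light pool (CA and Ali hardest). The respiration model is stated and
linear: `RR = 0.21 + 14 x (x - 0.28) + N(0, 0.15)`, with `x` the true mean
AImod of the lake's photo-produced set; the slope, centring and noise were
chosen once so that the generated RR spans the realistic -0.6 to +1 band at
a signal-to-noise giving the pipeline high but not trivial power. Intensities
are lake-level lognormal (meanlog 14, sdlog 1) base values shared by the
paired samples, perturbed by a 5% analytical CV per acquisition -- paired
acquisitions of the same water must share base intensities, otherwise
population-scale intensity noise would swamp any 20% threshold.

Two generator properties deserve emphasis. First, every random draw runs on
a per-lake substream derived from the master seed, so results are
bit-reproducible and adding lakes does not perturb existing lakes. Second,
the truth library contains only formulas that win the least-heteroatom rule
outright within a 2.5 ppm guard window. The CHONS space contains sub-mDa
doublets -- exchanging C7 + N + S for O8 + H2 shifts the mass by only
0.18 mDa -- where the assignment rule deterministically prefers the CHO
member; a "true" formula on the losing side of such a doublet is
unrecoverable by construction. Real assigned-formula tables are themselves
outputs of this rule and therefore have the same property, so the screen is
part of emulating the data, not a relaxation of the test.

What the generator does *not* emulate: isotopologue peaks, instrument
drift and recalibration residuals, scatter artefacts in EEMs, correlated
chemistry between neighbouring lakes, and any microbial community
structure. Passing tests therefore demonstrate the correctness and
statistical calibration of the analysis chain, not robustness to every
artefact of real spectra.

# Problem sizes and numerical choices

The test suite exercises candidate enumeration against an independent
brute-force enumerator on 1,000 random masses, assignment recovery on a
10,000-peak list (the package recovers > 99% of S/N-qualifying peaks at
0.3 ppm noise and 1 ppm tolerance), classification as an exact partition of
the complete assignable space up to 400 Da, slope recovery over 100 noisy
spectra, differential sensitivity/specificity on three simulated lake
pairs of 1,000 formulas, 1,000 null simulations of the three-way ANOVA
(the sunlight-by-temperature rejection rate must sit in 3-7% at
alpha = 0.05), and 100 + 100 full-pipeline runs at 10 lakes x 500 formulas
for coefficient power and null calibration. These sizes were chosen as the
smallest at which the binomial noise of the checked rates is clearly
inside the asserted bands.

Numerical details worth knowing: text output uses 17 significant digits so
write-read round-trips are lossless; candidate windows are widened by 1e-9
Da before the explicit tolerance check so boundary formulas are never lost
to floating-point comparison; weighted medians use the cumulative-weight
0.5 crossing with the midpoint convention at exact crossings, matching
`stats::median` under unit weights; duplicate m/z closer than 0.1 ppm is
rejected as an input error, and the generator resolves the rare synthetic
collision by dropping the less intense peak and recording it in the truth
table.

# Known limitations

Only singly charged [M-H]- ions are supported; isotopologue flagging,
Kendrick series and internal recalibration are out of scope. The
photon-flux-dependent CDOM light-absorption rate is not computed. The
presence/absence method inherits the detection limit of the instrument: a
formula dipping below S/N 4 in one acquisition counts as absent. PARAFAC
decomposition of EEMs is not provided; BIX and HIX are point/band ratios
only.
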