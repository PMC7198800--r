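---
title: "Methods: growth phenotypes, ensemble gapfilling and proteomic statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth phenotypes, ensemble gapfilling and proteomic statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitrofill)
```

`nitrofill` models one recurring experimental design in microbial
nitrogen physiology: a panel of strains is grown on media that differ
only in their nitrogen source, growth is scored kinetically, the
phenotypes train ensembles of gapfilled metabolic networks whose
predictions are then evaluated against held-out phenotypes, and
label-free proteomics characterizes the protein-level response to each
source. This vignette explains the models, the tunable parameters, the
design choices made where the methodology leaves room, and what the
synthetic benchmarks do and do not demonstrate.

## Growth scoring

Plate-reader series (absorbance, one reading per 10 minutes over 72 h
for phenotype arrays) are first background-corrected by subtracting
the negative-control well (A1 by convention) time point by time point;
the control itself is retained for QC. Each corrected series is fitted
by Levenberg–Marquardt least squares to the logistic model

$$N(t) = \frac{K}{1 + \frac{K - N_0}{N_0} e^{-rt}},$$

with carrying capacity $K$ (absorbance units), intrinsic rate $r$
(h⁻¹) and initial density $N_0$. Initialization is $N_0$ = first
value (floored at 10⁻³), $K$ = maximum value, $r$ = 0.2 h⁻¹, with
bounds $K \in (0, 2\max]$, $r \in (0, 5]$. Background subtraction can
produce small negative values; these are clipped at zero before
fitting. Non-convergent or flat series are flagged and reported with
$K$ = maximum observed value and $r = 0$, so downstream growth calls
remain defined. The area under the curve is the analytic integral of
the *fitted* curve over the observed span (an empirical trapezoid is
the fallback for non-convergent fits); fitting first and integrating
the model smooths single-well noise out of the AUC.

A well is growth-positive when $K$ exceeds `k_threshold` (default 0.1
absorbance units — an A590 respiration-signal cut) in at least
`min_replicates` of its replicates (default 2 of 3). Intensities are
then scored 0–4: within each strain, AUCs of growth-positive wells are
z-scored within each replicate assay, averaged across replicates, and
the averaged z-scores are split at their empirical quartiles (type-7
interpolation), intensity 1 = lowest quartile through 4 = highest;
non-growth wells are 0. Ties on a quartile boundary fall to the lower
bin, and the all-equal degenerate case scores every positive well 1
with a warning. Z-scoring before averaging (rather than averaging raw
AUCs first) keeps assay-to-assay gain differences from dominating;
with fewer than four growth-positive substrates quartiles are
undefined and the scorer refuses rather than guessing.

## Flux balance analysis

A network is a set of metabolites and stoichiometric reactions with
flux bounds, exactly one biomass reaction, and exchange reactions that
open the boundary (negative flux = uptake, positive = secretion). FBA
maximizes biomass flux subject to the steady state $S v = 0$ and the
bounds; a medium opens the listed exchanges to uptake at their stated
maxima while every unlisted exchange is closed to uptake but free to
secrete. Growth means the optimum strictly exceeds `epsilon` (default
10⁻³ flux units), separating real flux from solver noise; an
infeasible program is reported as zero growth with a flag, while
solver failures raise errors rather than returning silent zeros.

The linear programs are solved by a dense two-phase primal simplex
implemented in the package (Dantzig pricing with a Bland-rule
fallback that guarantees termination on degenerate instances; all
bounds finite, steady-state residual tolerance 10⁻⁶). At the tens of
metabolites × low hundreds of reactions this package targets, dense
tableau pivots are fast and exactly reproducible; the solver is
validated in the test suite against hand-computed optima and
enumeration-style oracles on toy networks.

## Gapfilling and ensembles

*Positive gapfilling* finds a smallest set of universal-database
reactions whose addition lets a draft grow on a medium. When the
candidate set (database reactions absent from the draft) has at most
`exact_limit` members (default 12), an iterative-deepening exhaustive
search certifies minimum cardinality, breaking ties toward the
lexicographically smallest sorted id tuple so results are
deterministic. Above that size the solver takes the additions carrying
flux in an all-candidates-open optimum and greedily prunes them to an
irreducible set — minimal in the sense that no single member can be
dropped, but not certified minimum-cardinality; the result carries
`certified = FALSE` to keep the distinction visible. A condition no
database subset can rescue raises a typed error naming the condition.

*Negative gapfilling* silences growth on a non-growth condition by
removing reactions, under two guardrails: only reactions added during
this member's own gapfilling are removable (draft-original content is
never deleted), and a removal is kept only if every already-satisfied
positive condition still grows. Candidates are the removable reactions
carrying flux on the negative condition, tried in a seeded random
order until the condition is silent; if it cannot be silenced the
network is returned unchanged with an `unresolved` flag — a recorded
outcome, not an error — so the positive-growth guarantee is
unconditional.

An *ensemble* is built from one draft by repeating this training
`size` times (the study-scale default is 50 members trained on 26
growth and 11 non-growth conditions), each member on its own
without-replacement draw of `n_pos` positives and `n_neg` negatives
under a member seed derived from the master seed: positives are
gapfilled in drawn order, negatives trimmed in drawn order, and all
positives re-verified at the end. Records store each member's draw,
additions, removals and seed, making every member reproducible and
every prediction maskable. Ensemble growth predictions report the
fraction of members growing, the weighted activity — mean growth rate
over growing members times that fraction, identically the mean over
all members with non-growers contributing zero, which is why the
"growing members only" and "all members" readings of an average
coincide here — and a binary call at a configurable vote threshold
(default ≥ 0.5). Weighted fluxes are analogous per reaction: the mean
flux over members where the reaction is active times the fraction of
all members in which it is active; members lacking the reaction count
only in the denominator. Flux comparisons between two media floor
magnitudes at 10⁻⁶ before taking log2 ratios (so inactive reactions
yield large finite fold changes rather than infinities), use absolute
values for reversible fluxes, and report reactions beyond a log2
threshold of 1.

## Evaluation

Predictions are scored against an experimental growth matrix with
per-member masking: a member abstains on any condition present in its
own training record, so no phenotype is predicted by a network that
was gapfilled with it. Conditions on which every member trained are
excluded (with a warning) rather than scored. Accuracy, precision and
recall come from the pooled confusion counts, with undefined ratios
reported as missing rather than coerced to zero. The random baseline
draws i.i.d. Bernoulli predictions — by default at the truth's
prevalence, the stronger and therefore more honest comparator; an
information-free 0.5 coin is available — and returns the empirical
metric distribution, summarized by mean and percentiles. Activity is
compared to measured growth intensity on percentile ranks (average
ranks for ties, squared Pearson correlation), which is robust to the
unknown monotone mapping between model flux units and dye-reduction
signal. A global-holdout mode supports designs that reserve a fixed
substrate set for downstream integration instead of per-member
masking.

## Proteomics statistics

LFQ intensities are analyzed on the log2 scale; zeros are treated as
not-detected, and no imputation is performed — detection counts route
each protein instead. For a pairwise treatment comparison, proteins
detected in ≥ `min_reps` replicates (default 3) of both groups are
tested: log2FC is the difference of group means and the p-value a
Welch t-test (a pooled-variance switch exists; Welch is the default
because replicate variances need not be equal). BH adjustment is
applied within each strain × comparison, matching per-volcano
presentation, and a differentially expressed protein requires
|log2FC| > 1 *and* BH-p < 0.05. Proteins with ≥ `min_reps` detections
in one group and zero in the other are classified presence/absence
and excluded from testing — a qualitative change that a t-test cannot
quantify honestly.

KEGG-ortholog matching keeps KOs detected in every treatment of every
strain (≥ `min_reps` replicates; the filter threshold is a parameter
because reasonable analyses use 3 or all 4), picks as representative
the protein with the highest grand-mean LFQ (missing counted as zero,
the LFQ convention), and derives within-strain z-scored and
ammonium-ratio views for cross-strain comparison. Pathway-level
significance combines the member proteins' BH-adjusted p-values with
Fisher's combined probability method, $X = -2\sum\ln p_i \sim
\chi^2_{2k}$; pathways with fewer than three tested proteins are
excluded and a blacklist drops non-bacterial pathways. A 2×2
enrichment variant (DEP × pathway membership, Fisher's exact test) is
available behind a flag for users who prefer an enrichment reading;
the combined-probability form is the default because the quantity
being aggregated is per-protein evidence, not set overlap.

The PII screen compares each protein's five treatment-mean abundances
to the PII (GlnK) profile by Pearson correlation and by the ordinary
least-squares slope of the protein profile on the PII profile,
$\beta = r\,\mathrm{sd}(p)/\mathrm{sd}(\mathrm{PII})$. This slope is
invariant under any common normalization of the abundance matrix and
equals 1 when a protein's profile coincides with PII's. It is *not*
computed after z-scoring each protein individually: per-protein
z-scoring forces $\beta = r \in [-1, 1]$, which would make the
classification thresholds (correlation beyond ±0.75 *and* slope
beyond ±2) unsatisfiable — the slope axis is informative precisely
because it keeps each protein's dynamic range relative to PII's.
Constant profiles have undefined correlation and class `none`; the
negative class mirrors the positive one at negated thresholds.

## Synthetic data: what it emulates, and what it does not

The universe generator builds a universal reaction database from
layered pathways: a carbon/ammonium core (glucose uptake and
glycolysis into a pyruvate pool, ammonium assimilation into an
amino-acid pool, a toy biomass consuming both), one catabolic route
per organic nitrogen source, and inert distractor reactions that pad
the database without creating nitrogen shortcuts. Catabolic routes
either carry a private deaminase or feed a family-shared intermediate
whose downstream deaminase is common to several sources — mirroring
how real amino-acid catabolism converges on shared intermediates, and
giving gapfilling the cross-condition transfer that makes ensemble
training informative. Each source has two independent uptake
reactions, as bacterial amino-acid uptake is typically redundant.
Strain truth matrices are *computed* by FBA on the true networks,
never asserted; generation retries until every strain grows on
ammonium, has at least one non-growth source, and uses roughly one to
four fifths of the panel — wide bounds around the generalist regime
(about three in five substrates) that such panels typically show.
Drafts arise by seeded deletion of reactions non-essential for
ammonium growth; exchange reactions are exempt because they encode
boundary conditions rather than gene-associated functions, so draft
reconstructions retain them. Default scale is 40 metabolites, 120
database reactions, 12 sources, 3 strains, 15% deletion — large
enough for non-trivial gapfilling, small enough that exhaustive
oracles stay feasible.

Plate simulation produces logistic curves with seeded kinetic priors
($K \in [0.15, 0.6]$ for growth wells, flat 0.02 baselines for
non-growth), replicate-level jitter, Gaussian noise, a shared
saturating background drift captured by the control well, and one
planted high-background well to exercise the exclusion rule.
Proteomics simulation plants log-normal baselines per strain,
fixed-size log2 effects in chosen treatments, a PII-coupled block
built as slope × PII profile plus noise, planted below-detection
treatments for presence/absence logic, and left-censors everything
under the detection limit — the missingness mechanism the
presence/absence rules assume, rather than missingness at random.

These generators validate the *statistics*, not the biology: real
phenotype arrays have well-to-well artifacts and non-logistic
kinetics, real LFQ data have correlated proteins and
intensity-dependent variance, and real metabolic networks are three
orders of magnitude denser with far more redundant routes. Passing
recovery tests here shows the machinery is correct and calibrated
under its stated model, not that the model captures any particular
organism.

## Numerical choices and benchmark sizes

Solver tolerances are 10⁻⁶ for steady-state residuals and flux
activity, 10⁻⁹ for simplex pivoting; the growth threshold is strict
(`objective > epsilon`). All randomness descends from explicit master
seeds through fixed arithmetic (member seeds, stage seeds), so
ensembles, universes and matrices serialize bit-identically across
runs. The test suite sizes its benchmarks for quick, deterministic
runs: the gapfill-guarantee property uses twenty universes at 25
metabolites / 50 database reactions / 6 sources with 3-member
ensembles trained on full panels; minimality is checked against
exhaustive search on instances of at most 12 database reactions; the
end-to-end benchmark uses the default 3-strain universe with
10-member ensembles trained on 60% of conditions, pooling confusion
counts across strains (36 strain × condition pairs) before comparing
accuracy to the random baseline's 95th percentile — per-strain panels
of 12 alone would make that percentile a coarse 12-draw binomial
statistic. On those benchmarks the masked accuracy typically lands in
the 0.78–0.94 range with rank-r² between 0.2 and 0.6, the regime
reported by ensemble-gapfilling studies on real substrate panels.

## Known limitations

Gapfill minimality is certified only on enumerable candidate sets;
the greedy route above `exact_limit` is order-dependent (though
deterministic) and can over-add on pathological instances. The
negative-trimming scheme is a conservative stand-in for procedures
that workflows in this area leave undocumented; it never sacrifices a
satisfied positive, at the cost of leaving some negatives unresolved.
The toy biomass (amino-acid pool plus pyruvate) is deliberately
minimal — biomass composition is a known accuracy bottleneck for real
models and is out of scope here. The simplex solver is dense and
single-threaded by design; it is not intended for genome-scale
networks.
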