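---
title: "Comparative thermostability surveys with ThermoComp: models, parameters and design choices"
author: "ThermoComp authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative thermostability surveys with ThermoComp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ThermoComp)
```

# The scientific problem

Thermophilic proteomes differ from mesophilic ones in bulk amino-acid
composition: charged residues (E, D, K, R) are enriched at the expense of
polar ones (S, T, N, Q). ThermoComp turns this observation into a pipeline
for comparing a candidate heat-adapted species against mesophilic
relatives over a common set of orthologous proteins, and for validating
each composition measure on data where the truth is known — labelled
thermophile/mesophile protein sets, experimentally melted protein pairs,
and synthetic data with planted effects.

# Measures and their directions

Every measure is computed on the *effective length* L: residues left after
removing the ambiguity letters B, Z, X, U, O. Ambiguity letters leave both
the numerator and the denominator, so percentages remain comparable across
records with different ambiguity loads (a sequence that is half X still
reports composition over what is actually known).

| measure | definition | direction |
|---|---|---|
| `cvp_bias` | 100·(N(EDKR) − N(STNQ))/L | + |
| `ivywrel` | 100·N(IVYWREL)/L | + |
| `ek_qh` | N(E,K)/N(Q,H); `NA` when Q+H = 0 | + |
| `serine` | 100·N(S)/L | − |
| `charged` | 100·N(DEKR)/L | + |
| `hydrophobicity` | mean Kyte–Doolittle hydropathy | + |
| `length` | effective length of the trimmed fragment | − |

Direction +1 means larger values read as more thermostable. Serine content
and fragment length are inverted: low serine content and compact proteins
(short surface loops) are the thermophilic signatures. No authoritative
hydropathy scale is mandated for bulk-hydropathy comparisons, so
Kyte–Doolittle is the default and the scale is selectable; the direction
of `hydrophobicity` is likewise a registry default (+, reflecting stronger
hydrophobic cores in thermophiles) rather than a settled convention, and
external score tables (`scoreTable()`) declare their own directions when
imported predictors are merged. The (E+K)/(Q+H) ratio is undefined for
sequences without Q or H; it propagates as a missing value so that a
single degenerate protein invalidates one set's ranking rather than
producing infinite rank positions.

# Orthology and trimming

`bestHits()` reduces an all-vs-all tabular hit list to one best subject
per query and target species (maximal bitscore, then minimal evalue, then
lexicographic subject id — fully deterministic). `buildOrthologSets()`
emits a set only when one protein per species satisfies the *strictest*
reading of reciprocal-best-hit consistency: every one of the S·(S−1)
directed best-hit relations maps within the set. This is deliberately
conservative — it can only lose sets relative to laxer schemes (a
star-reciprocity mode is available via `mode = "star"`), but emitted sets
are unambiguous and the construction is provably order-independent, which
we verify against brute-force clique enumeration in the test suite.
Proteins absent from any pairwise search are simply ineligible; nothing is
imputed.

Because survey inputs are frequently partial transcripts, alignments are
trimmed from both ends to the first and last column that is gap-free in
*every* row (`trimAlignment()`); interior gaps are removed from the
retained window, so per-species fragment lengths may still differ — that
difference is itself the `length` measure. An alignment with no gap-free
column is excluded and logged rather than guessed at. Alignment
construction itself is delegated to external aligners; the package
consumes aligned FASTA.

Transcript preprocessing follows the longest stop-free fragment rule: the
translated frame is split on stops, the longest fragment wins (leftmost on
ties), and a fragment preceded by a stop codon has its start advanced to
its first methionine (discarded if it has none). Whether the Met scan
should apply before or after fragment selection is genuinely ambiguous;
both behaviours are implemented (`metScanFirst`), defaulting to
scan-after-selection, which matches the natural reading of the procedure.
Fragments under 60 residues are discarded by default. Redundancy reduction
is a deterministic greedy clusterer at 98% identity: records in decreasing
length order join the first representative within threshold, with global
identity defined as exact matches over alignment columns (end gaps
included) under match +1 / mismatch 0 / linear gap −1 scoring — a
transparent, order-stable stand-in for word-filter heuristics whose output
the downstream statistics do not depend on finely.

# Ranking, ROC, and correlations

Within each set, species are ranked 1…S under each measure's direction
with average ranks on ties; a set missing any species' value is skipped
for that measure entirely (not re-ranked over the subset), so cumulative
sums stay comparable — their total is always nSetsUsed·S(S+1)/2, an
invariant checked at construction time by the `RankSummary` validity
method. ROC AUC is computed by the rank/pair method
(AUC = (#correctly ordered pairs + ½·ties)/(n₊·n₋)), which equals the
trapezoidal area under the threshold-swept curve; per-sequence pooled
scoring is the default and a pair-level read-out (`pairedConcordance()`)
is provided separately, since published benchmark sets of homologous
pairs can be read either way.

Correlations are plain Pearson product-moment with the two-sided t-test
on n−2 degrees of freedom and an OLS line with a 95% slope interval —
species are treated as independent points (no phylogenetically independent
contrasts). Proteome means are unweighted by protein length. For
ortholog-pair stability comparisons the difference convention is fixed to
**mesophilic − thermophilic** for both the measure and Tm; a pair is
concordant when both differences share a non-zero sign, zero differences
counting as discordant and flagged. Tm values printed as ranges take their
midpoint when a scalar is needed; the printed range is retained in
reports.

# Boltzmann melt-curve fitting

Thermal-shift fluorescence follows a rising sigmoid
f(T) = f_low + (f_high − f_low)/(1 + exp((Tm − T)/a)) up to the unfolding
transition, then decays as aggregates quench the dye. `fitTm()` therefore
restricts the least-squares fit to the region between the global minimum
and the global maximum of a lightly smoothed copy of the curve (centred
moving average, 5 points — smoothing affects region selection and
initialisation only, never the objective). Initialisation uses the
5th/95th fluorescence percentiles for the baselines, the temperature of
maximal finite-difference slope for Tm, and a = 1 °C; if the
Levenberg–Marquardt optimizer (relative tolerance 1e-8) fails, two
deterministic restarts perturb the starting Tm by +5 and −5 °C — no
randomness anywhere in the fit. Degenerate inputs fail loudly: flat or
falling curves raise a no-transition error, and a fitted Tm outside the
observed range clears the `reliable` flag with a warning instead of
silently extrapolating. On noiseless synthetic curves the planted Tm is
recovered to well under 0.01 °C across Tm ∈ [35, 65] and a ∈ [0.5, 3]; at
1% amplitude Gaussian noise recovery stays within 0.2 °C.

# What the synthetic generator emulates — and what it does not

`genOrthologSets()` plants the exact statistical structure the analysis
assumes: per-species sequences derived from a common ancestor (drawn from
the mean residue profile) by positional resampling, indels, and a
charged-versus-polar shift δ. The shift is realised generatively —
each polar residue converts to a random charged residue with probability
δ/p(polar) — so that the expected CvP-bias excess of a shifted species is
*exactly* 200·δ percentage points. This closed form is the oracle for the
recovery tests: moving probability mass δ from the polar to the charged
set changes C − P by 2δ, hence CvP by 200δ. The same mechanism drives
`genPairDataset()`, whose homolog pairs share a backbone (length 300,
background mutation rate 0.05 per position by default) with only the
thermophilic member shifted; at δ = 0 the pairs are exchangeable and CvP
AUC sits at 0.5, rising above 0.99 by δ = 0.08 at 500 pairs. Hit-table
bitscores are pairwise identities ×100 taken from the true alignments
plus low-identity decoys — identity proxies sufficient for exercising
best-hit logic, not alignment scores. `genCodingSequences()`
reverse-translates with a Bernoulli(gc3) preference for G/C third
positions, giving exact round-trip translation and a controllable GC3
axis for confound analyses. All generators are pure functions of their
seed.

What passing these tests shows is that every stage does what it claims on
data matching its assumptions. What they do not show: real proteomes have
phylogenetic covariance, domain-level composition heterogeneity,
alignment errors, unequal taxon sampling and incomplete transcripts —
none of which the generator models (substitutions are i.i.d., not
matrix-driven; codon usage is synthetic, not organismal). Conclusions
about a real species still require the real orthologous data.

# Problem sizes and numerical choices

Test and acceptance runs use desk-scale sizes chosen to make sampling
error comfortably smaller than the planted effects: 150–200 sets of
150–250-residue sequences for composition expectations (Monte-Carlo SE on
the CvP excess ≈ 0.3 points against an effect of 20), 500 pairs for AUC
estimates (SE < 0.02 near AUC 0.5), 15 planted sets over 4 species for
recovery, and 10 noisy replicates per Tm across a 35–65 °C grid for melt
fitting. Exhaustive oracles (pair counting, clique enumeration) run on
instances small enough to enumerate completely (≤ 8 scores, ≤ 4 species ×
6 proteins). Floating-point identities (CvP = charged% − polar%,
AUC = trapezoid) are asserted at 1e-12; composition conservation at 1e-9.

The bundled `inst/extdata` tables carry published per-species proteome
means with body temperatures for ten homeothermic vertebrates, and
published CvP/Tm values for seven thermophile/mesophile ortholog pairs;
re-running the correlation and concordance stages on them reproduces
Pearson r values of 0.71 (CvP, p ≈ 0.02), 0.23, −0.44 and 0.02, the
mesophilic-minus-thermophilic differences 5.714 (Rrp4) and −6.22
(U2AF65), and 7/7 sign concordance — the same numbers
`scripts/acceptance.R` recomputes.

# Known limitations

- The greedy identity clusterer is quadratic in proteome size; it is a
  preprocessing option (off by default in `runSurvey()`) intended for
  modest transcriptome-scale inputs, not whole mammalian proteomes.
- Strict-clique orthology requires every species present; lineage-specific
  losses reduce the usable set count rather than producing partial sets.
- The melt model is single-transition; biphasic curves will fit the
  dominant transition of the rising region only.
- External predictors are imported as score tables; their internals are
  out of scope by design.
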