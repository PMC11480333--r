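---
title: "Stage-resolved phosphoproteome dynamics with phosphodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-resolved phosphoproteome dynamics with phosphodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphodyn)
```

## The analysis problem

A stage-resolved phosphoproteomics experiment quantifies thousands of
phosphosites across an ordered series of developmental stages — here the
oocyte maturation series GV → GVBD → MII, with five replicates per stage in
a TMT-like multiplexed design — together with a matched proteome. The raw
site intensity confounds two signals: how phosphorylated the residue is,
and how much of the parent protein is present. Every downstream claim
(which sites are regulated, what temporal shapes exist, which kinases
drive them) depends on separating the two, testing at scale with error
control, and screening the results against reference catalogs and other
species. `phosphodyn` implements this chain end to end; this vignette
documents the model, the defaults, the numerical choices, and what the
synthetic benchmark does and does not establish.

## Site model

A phosphosite is a (protein, 1-based position, residue ∈ {S, T, Y}) with a
search-engine localization probability. Sites are binned into class I
(probability strictly above 0.75), class II (0.50–0.75, both ends
included) and class III (strictly below 0.50); the strict inequality for
class I follows the conventional "probability > 75 %" definition, so an
exact 0.75 is class II. When a site is reported multiple times, the entry
with the highest class wins (I > II > III), ties broken by higher
probability, then larger total intensity — `dedupe_by_class()` is
order-invariant by construction. Isoform suffixes on accessions are kept
as distinct proteins, since positions are isoform-specific.

Missing intensities are carried as explicit `NA` and excluded pairwise
from means and tests; a site needs at least two non-missing values per
compared stage to be testable. Exact zeros in the *site* matrix are
treated as missing, not replaced — the zero-replacement rule below is
specific to the protein matrix.

## Calibration

The quantification chain is a fixed order of operations:

1. `replace_zeros(protein_raw)` — every exact-zero protein cell becomes
   the global minimum non-zero value of the protein matrix. "Lowest value"
   is read as lowest *non-zero* value: a literal minimum would be zero and
   defeat the rule's purpose (avoiding division by zero).
2. `rowmean_normalize()` of the protein matrix, then of the site matrix:
   each row divided by its mean over non-missing entries, so every row has
   mean 1 and global per-row scale cancels exactly.
3. `calibrate_sites()` — calibrated(site, sample) = site_norm /
   protein_norm of the parent protein. When the protein was not
   quantified, the normalized site level is used directly and the row is
   flagged `site_only`.

Two consequences are tested as invariants: multiplying any raw row by a
positive constant leaves the calibrated matrix unchanged (to 1e-12), and
in noise-free simulations with protein-level drift and flat phosphorylation
the calibrated profiles are constant at exactly 1 — calibration, not raw
intensity, is what classifies drifting-but-unregulated sites correctly.

## Differential calling

Tests run on log2 calibrated values (variance stabilization); the fold
change is the ratio of arithmetic stage means of calibrated values, and
the significance gate is BH-adjusted p < 0.05 together with
|log2 FC| > log2 1.5, so down-regulation counts symmetrically. Student's
pooled-variance t test is the default; Welch (Satterthwaite df) is an
option. Both are implemented with explicit degenerate-input handling —
identical constant groups give t = 0, p = 1; constant groups with
different means give p = 0; under-replicated sites return a missing p with
an `untestable` reason code — and are cross-checked against
`stats::t.test` on random data. BH adjustment is the step-up procedure
(sort, p·m/i, enforce monotonicity from the top, cap at 1), applied per
comparison, and cross-checked against both a naive brute-force step-up and
`stats::p.adjust`. Note that the per-family guarantee
P(any adjusted p < α) ≤ α under the global null holds per comparison;
the union over the three stage comparisons does not (and is observed at
≈ 1 − 0.95³ on all-null simulations, as expected).

A site is **regulated** when significant in at least one of the three
pairwise comparisons (GVBD vs GV, MII vs GV, MII vs GVBD). The union is
the most inclusive reading and is configurable through the `comparisons`
argument. For label-free two-group protein designs,
`differential_proteins_dia()` applies the raw-p variant (p < 0.05,
FC > 1.2, no multiplicity adjustment), matching common DIA practice.

## Temporal clustering

Regulated sites are summarized as per-stage mean profiles, standardized
per row to mean 0 and *population* SD 1 (divisor n; constant rows are
dropped with a diagnostic), and clustered with fuzzy c-means under squared
Euclidean distance on the 3-vector of stage means. The implementation
tracks the objective J = Σᵢ Σⱼ uᵢⱼᵐ‖xᵢ − cⱼ‖² at every iteration and the
alternating center/membership updates guarantee it is non-increasing — an
invariant asserted on every test run. Defaults: c = 5 clusters, fuzzifier
m = 2, tolerance 1e-6 on the largest membership change, 1000 iterations
maximum, memberships initialized from a seeded uniform Dirichlet, and 8
restarts keeping the lowest objective (restart seeds derived
deterministically from the user seed, so runs are bit-reproducible). A
profile exactly coincident with centers has its membership split over
them; hard assignments are the membership argmax with ties to the lowest
cluster index. The c = 1 limit returns the mean profile, and on
well-separated data the solution matches `e1071::cmeans` in objective and
partition — that library serves as a cross-check, never as the
implementation.

## Conservation and novelty screens

Windows are 13-mers: the phosphoresidue plus six flanking residues per
side, padded with `_` beyond the termini. Identity is counted
position-wise on the aligned windows with no gaps or shifts, and a pad
never matches anything, including another pad. The similarity rule is
≥ 9 identical residues of 13 — the smallest integer count whose fraction
exceeds 69 % (9/13 ≈ 0.692) — and a site is conserved when at least 3
species, the reference included, carry a similar window. Per species the
best match maximizes the identity count with ties to the first occurrence.
The center residue participates in the count like any other position but
matching center residue types is not required by default
(`require_center_match = TRUE` gives the strict variant). Comparison is
all-vs-all within each species set; no orthology mapping is attempted.
Monotonicity (lowering either threshold never removes a conserved site)
and exact equivalence with a brute-force double loop are tested.

Novelty is set membership: a site is novel when its
(protein, position, residue) key appears in no reference catalog.

## Kinase–substrate analysis

Kinase and phosphatase accession lists annotate each enzyme as detected
(in the proteome or phosphoproteome), phosphorylated (≥ 1 site) and
regulated (≥ 1 regulated site), a nested classification reported with
counts. Kinase–substrate edges are an *input* (e.g. exported from a
sequence-based predictor); the package defines the format, not the
predictor. Enrichment, per kinase, is a two-sided Fisher exact test of the
2×2 (substrate membership) × (significantly upregulated vs rest) over the
quantified site universe, BH-adjusted across kinases; the implementation
enumerates the hypergeometric support with the conventional relative tie
tolerance and matches `stats::fisher.test` p-values. The reported odds
ratio is the sample odds ratio ad/bc, not the conditional MLE.

Activity inference standardizes each substrate's stage profile to a
z-profile and averages per stage (optionally weighted by edge scores); the
trend label compares consecutive stage steps to a 0.25 z threshold:
all-positive steps increasing, all-negative decreasing, mixed signs
transient, otherwise flat. The z-mean is a documented package choice — the
underlying idea ("activity follows the phosphorylation changes of known
substrates") fixes no particular summary — and min_substrates = 3 and the
0.25 threshold are configuration defaults, not biological constants.

## The synthetic benchmark

`simulate_phosphoproteome()` emulates the statistical structure of the
motivating study at desk scale: 500 proteins, a zero-truncated geometric
sites-per-protein distribution with mean 3 (~1500 sites), residue mix
86.5/13.0/0.5 % S/T/Y, 3 stages × 5 replicates, 75 % of sites regulated
across five temporal archetypes over (GV, GVBD, MII) —
A1 (1, 0.7, 0.3) monotone down, A2 (0.6, 1, 0.3) transient,
A3 (0.3, 0.5, 1), A4 (0.3, 0.9, 1), A5 (0.5, 0.6, 1) up-shapes with
differing onset. Noise is multiplicative log-normal with σ = 0.15 on the
natural-log scale, chosen so that planted 1.5× effects are recoverable at
n = 5; 10 % of proteins drift 1.5–2× across stages, and 90 % of proteins
are covered by the proteome table, so both the calibration path and the
site-only fallback are exercised. Site intensity is
base × protein_profile(stage) × template(stage) × exp(N(0, σ²)); the
protein matrix carries independent noise of the same magnitude. All
magnitudes are generator choices surfaced in `sim_config()`; a single seed
governs all draws and identical seeds reproduce byte-identical tables.

Companion generators plant cross-species windows at exact Hamming
distances (substitutions never at the center; only pad-free windows are
used, so distance d maps exactly to 13 − d identity matches under the
pad-never-matches rule) and kinase–substrate sets drawn 90 % from one
archetype, plus neutral control kinases drawing substrates uniformly.

What the benchmark shows: the calibration algebra is exact; the
differential gate recovers the planted regulated fraction within a couple
of percentage points at the default noise; the conservation screen
recovers planted truth exactly; planted kinase trends and enrichment
ranks are recovered. What it does not show: behavior under TMT ratio
compression, peptide-level ambiguity, batch structure, missing-not-at-
random dropout, or real phosphosite sequence composition — none of which
the generator models.

### A known recovery limit

The standardized shapes of archetypes A3 (0.3, 0.5, 1) and A5
(0.5, 0.6, 1) are nearly identical (Euclidean distance ≈ 0.16 in z-space),
while σ = 0.15 noise on 5-replicate stage means spreads standardized
profiles by ≈ 0.2–0.3 per coordinate. The two archetypes therefore overlap
heavily and no distance-based clustering can separate them reliably at
this noise level: five-cluster solutions recover A1, A2 and A4 cleanly and
split the A3/A5 blob, giving an adjusted Rand index of ≈ 0.73–0.81
against the planted labels (exactly 1 at σ = 0, where the archetypes are
point masses). Our fuzzy c-means reaches the information limit — it
slightly outperforms both `e1071::cmeans` and k-means on the same
profiles — so the residual disagreement reflects the archetype geometry,
not the optimizer.

## Problem sizes and determinism

The test suite and the acceptance script run the default 500-protein
(~1500-site) study, 200 all-null replicate runs of a ~500-site
configuration for the false-discovery check, an exhaustive Fisher oracle
over all 2×2 tables with total ≤ 40, and a 1000-vector BH oracle — sizes
chosen to give tight Monte-Carlo bounds while keeping a full run in the
order of a minute. Every stochastic step takes an explicit seed;
sub-generators (species sets, networks, restarts) derive their streams
deterministically from it.

## Known limitations

- One row per site is taken at face value; multiply-phosphorylated
  peptide forms are not disentangled.
- No column (sample-loading) normalization, batch correction or
  imputation is applied — by design, none is part of the modelled chain.
- The conservation screen is purely sequence-based; assessing functional
  conservation requires manual curation of the screen's output table,
  outside the package.
- Welch's test is exposed but no automatic criterion selects it over
  Student's; the choice is the caller's.
- The cluster count c is a parameter; no validity-index selection is
  implemented.
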