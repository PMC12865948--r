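---
title: "Profiling, testing and genus-level attribution of metagenome functions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling, testing and genus-level attribution of metagenome functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funtaxa)
```

## Scope and model

`funtaxa` starts where annotation ends: a non-redundant gene catalog with
lengths, domain-to-genus lineages and functional labels (one best-hit KO per
gene, zero or more CAZy families, optionally a hydrogenase group/category),
plus a samples-by-genes matrix of mapped-read counts and a two-group sample
design. Everything upstream — read QC, assembly, ORF calling, clustering,
homology search — is out of scope, as is any host transcriptomics.

### TPM and profiles

Per sample, gene rates are `count / length(kb)` and are renormalized to sum
to 10⁶ (TPM). Because of the per-sample renormalization the bp-vs-kb choice
cancels; kilobases are used by convention and the closure `Σ TPM = 10⁶`
holds to a relative tolerance of 10⁻⁹ (tested; in practice it is exact to a
few ulps).

Taxon profiles sum the TPM of genes assigned at the requested rank;
unassigned genes are excluded from the profile and their total is reported
separately rather than silently dropped. Functional profiles aggregate the
*annotated subset* of a catalog normalized over the *full* catalog: profiles
are deliberately not renormalized to the annotated fraction, since in real
catalogs only about half of genes receive a KO and a few percent a CAZy
family, and rescaling would entangle annotation coverage with abundance.
A multi-family CAZy gene books its full TPM in every family it carries
(per-domain HMM hits imply per-family booking); the class-level scheme
deduplicates classes so a gene with two GH families counts once in GH. An
even-split alternative was considered and rejected: it would make family
abundances depend on the annotation density of neighbouring families.

The function-by-taxon matrix sums TPM over genes sharing a (feature, genus)
pair, booking genus-unassigned genes under the pseudo-genus `unassigned`.
The function profile is computed as the genus-marginal of the same internal
cell sums, which makes the conservation identity between the two outputs
bitwise exact instead of merely within floating-point tolerance; both
objects are independently tested against brute-force per-gene loops.

Display pooling retains a feature if its within-sample relative abundance
reaches the threshold (1% at phylum rank, 0.1% at genus rank by default) in
*at least one* sample, pooling the rest into `Others`. The operation
conserves per-sample totals and is idempotent: an existing `Others` column
is treated as the pooled bucket and merged, never re-tested.

### Differential testing

Feature-level comparisons use two-sided Wilcoxon rank-sum tests, by default
on within-sample relative abundances (raw TPM gives the same ranks only when
library compositions close identically, so relative abundance is the safer
default; a flag restores raw values). The exact mode enumerates the null
rank-sum distribution by dynamic programming and is selected automatically
when `min(n1, n2) ≤ 12` and the data are tie-free; otherwise a normal
approximation with tie correction and continuity correction is used. These
switching rules are not dictated by the underlying study design (which at
13 + 13 always lands in the normal branch); they were chosen to match
mainstream implementations so P values are comparable, and the exact mode is
verified against a full-enumeration oracle to 10⁻¹².

Tiers are `significant` (P < 0.05) and `trend` (0.05 ≤ P < 0.10), both
configurable; raw P values drive the tiers, mirroring the practice of
reporting unadjusted P with a trend band, while Benjamini–Hochberg q-values
are emitted as an extra, clearly auxiliary column. Constant features are
skipped and listed rather than tested.

Phenotype comparisons run per-group Shapiro–Wilk tests (skipped with a
warning below n = 3), a median-centered (Brown–Forsythe) Levene test —
chosen over mean centering for robustness, as the plain name "Levene" leaves
the centering open — and then Student's t-test, switching to Welch when the
variance test rejects at 0.05. A normality failure is warned about but does
not switch the branch to a nonparametric test, because the procedure being
modelled specifies only the Student/Welch fork. Mean-difference confidence
intervals are Welch-based by default: with a variance pre-test already in
the pipeline, the Welch interval is the one that remains valid on both
branches.

### Diversity and community tests

Shannon (natural log) and Simpson (1 − Σp²) match the defaults of the
standard ecology toolkit and are computed from within-sample relative
abundances. Bray–Curtis is `Σ|x−y| / Σ(x+y)`; a pair of all-zero samples is
an error, not a silent 0/0. PCoA double-centers `−½D²`, reports *all*
eigenvalues (no Lingoes/Cailliez correction — keeping negative eigenvalues
visible preserves the Euclidean-reconstruction test property), and retains
axes above a relative tolerance of 10⁻⁸.

PERMANOVA partitions `Σd²/n` into among/within components for the one-factor
two-group design; ANOSIM uses ranks of all pairwise dissimilarities with
denominator `n(n−1)/4`, the standard form that confines R to [−1, 1] and
reaches R = 1 exactly at full separation (a candidate variant with half that
denominator was rejected because it violates both properties). The
dispersion test embeds samples by PCoA, measures each sample's distance to
its group centroid — combining positive- and negative-eigenvalue parts by
subtracting squared imaginary distances, floored at zero — and refers a
one-way F to permutations of the observed distances across groups (the
one-way equivalence used by the standard implementation; centroids are not
recomputed per relabeling). Centroids rather than spatial medians are used:
simpler, deterministic, and verified against the reference implementation's
distances in tests.

All permutation P values use `(1 + b)/(1 + m)`, so the smallest attainable P
is `1/(m + 1)` and P = 0 is impossible. Every permutation stream is seeded
and restores the caller's RNG state.

### Contribution decomposition

For each differential feature, TPM is summed over all samples of each group
within each genus; `Δ_g` is the difference of group sums (positive group
first, LFCR − HFCR with those labels), `Δ_total = Σ|Δ_g|`, and each genus
contributes `|Δ_g|/Δ_total × 100` percent with direction from the sign.
Group *sums* — not means — are used, exactly as defined; with unequal group
sizes the sums bias Δ toward the larger group, so the function warns in that
case. Before pooling, contributions sum to 100 per feature (a tested
invariant), and the whole decomposition is invariant to a global rescaling
of TPM.

Pooling is per direction: genera strictly below 20% of Δ_total are pooled
into `Others`; of the remainder at most the top five per direction are
retained (ties broken by contribution descending, then genus label
ascending, for determinism); whatever is not retained also folds into
`Others`, so retained + Others = 100 always. The `unassigned` pseudo-genus
participates in Δ_total — keeping the decomposition a true decomposition —
but is never retained by name. The ≥ 3% label flag coexists awkwardly with
the 20% pooling rule (a sub-20% contribution can never be retained, hence
never labelled, under the literal rule); the implementation follows the
literal rule and exposes both thresholds, rather than guessing an intended
value.

## The synthetic cohort

The generator's defaults state the world the pipeline is tested in: two
groups of 13 samples; 50 genera whose mean relative abundances follow a
power-law rank-abundance curve (`∝ rank^−1.2`) under a Dirichlet model with
total concentration 150 (moderate between-animal compositional variation);
5,000 genes partitioned over genera proportionally to genus abundance with
exponential within-genus weights; lengths uniform on 300–3,000 bp; 50% of
genes KO-annotated and 7% CAZy-annotated (matching the coverage reported for
real rumen catalogs, ~48.8% and ~6.8%), with a 0.2% hydrogenase rate
dominated by [FeFe] enzymes; 10% of lineages truncated at a random rank;
log-normal library sizes (mean 2 × 10⁶ counts, CV 0.25) and
negative-binomial counts with dispersion φ = 0.2 (variance μ + φμ²), a
standard overdispersed metagenome count model. Phenotypes are normal draws
with the efficient group given lower FCR and higher gain, at effect sizes
typical of divergent-FCR sheep cohorts.

A planted feature is a (feature, target genus, log2 effect, intended
dominant share) tuple. Carrier genes are designated in the target genus and
(for shares below 1) in other genera, with within-genus weights rescaled so
the target genus holds the intended share of the feature's expected mass;
the effect multiplies the target-genus carriers in the positive group only,
followed by compositional renormalization. Two consequences are deliberate:
carriers of different planted features never share a gene (otherwise one
feature's boost contaminates another's attribution), and lineage truncation
is undone on carriers (a planted feature-by-genus effect is meaningless if
the carrier loses its genus call). The *realized* expected contribution is
computed analytically from the noise-free expected abundances — the
renormalization spreads small opposite-direction changes across all other
genes, so the realized share exceeds the intended one — and this truth
channel is required to agree exactly with the attribution module run on the
expectations themselves.

What a green test establishes: the pipeline's algebra (closure,
conservation, recovery, calibration) on an idealized community with
independent genera, a shared dispersion and no phylogenetic or longitudinal
structure. What it does not establish: behaviour under real-data pathologies
such as copy-number variation, chimeric assembly, annotation bias between
groups, or strong compositional effects from a few dominant taxa.

## Numerical choices and degenerate inputs

- TSV dialect: tab-separated, mandatory header, `.`/empty = missing, `;`
  separates CAZy families. One dialect, no sniffing.
- Serialization: numeric output at 6 significant digits, fixed column
  order, byte-identical across reruns; manifests carry input/output digests
  (timestamps excluded from determinism claims).
- All-zero samples are errors in TPM and alpha diversity; a zero-variance
  feature is skipped, not tested; Δ_total = 0 is an explicit "no net change
  to attribute" error (and a warning when a planted effect cancels).
- All-ties Wilcoxon (zero variance of ranks) returns P = 1; an all-equal
  dispersion embedding is reported as degenerate with P = 1.
- Exact-mode Wilcoxon refuses ties with a message pointing to normal mode.
- Seeds: one global seed in the config; stage-local streams use fixed
  offsets (+101 PERMANOVA, +102 ANOSIM, +103 dispersion) so adding a stage
  never perturbs earlier stages' draws.

## Limitations

No FDR-gated inference (q-values are informational); no paired designs,
covariates or more than two groups; no UniFrac or other phylogeny-aware
metrics; no copy-number correction or compositional (CLR) modelling; no
statistical uncertainty on contribution percentages — the decomposition is a
descriptive partition of the observed group-sum change, and its stability
should be judged through the planted-recovery simulations rather than
analytic intervals.
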