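---
title: "Models and methods: the ecology of mucosal glycan degraders"
author: "glycoguild"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: the ecology of mucosal glycan degraders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoguild)
```

## The scientific question

The secreted mucus layer of the gut is both a barrier and a nutrient
source: its mucin glycans (galactose, GalNAc, GlcNAc, fucose, sialic
acid, often sulfated) feed a guild of microbial degraders. Many gut
species *encode* carbohydrate-active enzymes that can attack these
glycans, but far fewer *transcribe* them in vivo, and those that do
appear to follow different strategies: some couple transcription
tightly to their own abundance ("competitive" degraders), others
transcribe only sporadically, apparently when more competitive species
are absent ("opportunistic" degraders).

`glycoguild` implements the analysis chain that makes these claims
testable on paired metagenome/metatranscriptome profiles:

1. **Screening** — which species encode, transcribe, versatilely
   transcribe (> 1 enzyme), and prevalently transcribe mucin
   degradation ECs.
2. **Co-occurrence** — which species rise and fall together across
   samples, via permutation-calibrated Spearman networks on clr
   abundances, clustered by greedy modularity.
3. **Abundance-driven transcription** — per EC and species, ordinary
   least squares of the species' share of the EC's transcription on its
   own clr abundance; the adjusted R-squared is the "percentage of
   abundance-driven transcription".
4. **Response-predictor networks** — per EC, each prevalent
   transcriber's share regressed on the clr abundances of all *other*
   prevalent transcribers; significant coefficients become directed
   signed edges, aggregated into a cross-EC consensus network.
5. **The continuum** — per species, the median adjusted R-squared
   versus the average number of species it inhibits or facilitates.

## Data model

Two input dialects are supported, matching the de facto standards of
taxonomic and functional profilers:

* per-sample taxonomic profiles with `clade_name`,
  `relative_abundance` and `estimated_number_of_reads_from_the_clade`
  columns; species-level rows are selected by the terminal `s__`
  convention (strain rows `t__` are dropped; the regex is
  configurable);
* species-stratified functional tables in copies per million (cpm)
  with bare `EC` rows as community totals, `EC|...s__Species` strata
  and `EC|unclassified` for the unattributed remainder.

The shipped enzyme catalog lists the 11 detectable mucin-degradation
ECs with their CAZy GH families and two flags: the
alpha-/beta-galactosidases (3.2.1.22/3.2.1.23) do not count on their
own towards versatility (galactose is abundant in dietary glycans),
and N-acetylglucosamine-6-sulfatase (3.1.6.14) is inactive (detected
in ~1% of samples, unmappable to reference genomes).

## The clr transform

Read counts from shotgun profiles are compositional; we use the
centered log-ratio transform,
\(\mathrm{clr}_i = \log x_i - \tfrac1p \sum_j \log x_j\),
on estimated read counts with a pseudocount of 1. The pseudocount is
added to the **counts before the geometric mean**, not to the ratio:
the two readings are equivalent in intent, but adding to counts makes
every transformed row sum exactly to zero, a cleaner invariant that
the tests exploit. Both placements are available
(`clr_transform(..., pseudocount = )` with `0` allowed for strictly
positive counts, where clr is exactly scale invariant).

## The filter cascade

Starting from all species with any catalog-EC transcript:

1. drop species whose transcribed set is contained in
   {3.2.1.22, 3.2.1.23};
2. drop species transcribing exactly one catalog EC. The count
   *includes* the galactosidases: a species transcribing
   beta-galactosidase plus a sialidase is versatile. This was a
   genuinely open reading — excluding them is available via
   `count_excluded_in_versatility = FALSE` — but the inclusion reading
   matches the stated rule that only *pure* galactosidase transcribers
   are removed;
3. keep species whose transcription prevalence reaches 10% for at
   least one EC.

Prevalence is per (EC, species): the number of samples in which the
species' stratum is detectable divided by the number of samples in
which the EC is transcribed *at all*. The denominator never depends on
the focal species. "Detectable" means cpm > 0 after treating values
below 1e-12 as exact zeros; no minimum-cpm floor is applied. Boundary
semantics differ deliberately between the two prevalence rules:
species-level retention is `>= 10%` while EC-level prevalence is a
strict `> 5%`; both thresholds are configurable.

## The co-occurrence network

Pairwise Spearman correlations (average ranks under ties) are computed
between species present in at least `min_present_samples = 20` samples
— correlation networks on fewer informative samples are unreliable.
Significance is calibrated by a permutation null: each species' values
are permuted independently across samples (destroying all
cross-species association, preserving marginals), all pairwise
correlations recomputed, and the results of all 1000 replicates pooled
into one global null whose central 99% interval defines significance.
Pooling, rather than one null per pair, was an open choice: with 1000
replicates a per-pair null has unusable 1% tails, while the pooled
null has hundreds of thousands of draws; a per-pair variant would be a
straightforward extension. Because Spearman correlations depend only
on ranks, permuting raw counts and permuting clr values give
identical null correlations under this shuffling unit.

Edges are retained when significant **and** positive **and**
rho >= 0.2; the network is restricted to degraders and their first
neighbors (species sharing a retained edge with a degrader; edges
between two first neighbors are kept, nodes with no path to a degrader
are not). Communities are found by Clauset–Newman–Moore greedy
modularity on the unweighted adjacency. Two determinism choices are
documented and enforced: vertices enter in lexicographic order, and
the agglomeration path is cut at its modularity maximum with ties
broken towards the coarsest partition (so a single clique is one
cluster). Isolated nodes form singleton clusters.

## Regression models

Contributions are `100 * stratum / community_total` per (sample, EC),
undefined (excluded) where the EC total is zero. The denominator
includes the UNCLASSIFIED stratum, so species + unclassified
contributions close to 100; `classified_only = TRUE` switches to the
attributed-only denominator. Contributions are modelled untransformed
on the percent scale.

The abundance-driven fit for species *s* and EC *e* is
`contribution(s, e) ~ clr(s)` over the samples where *e* is
transcribed; a model is significant at p < 0.05 and its adjusted
R-squared may be slightly negative for uninformative fits. The
response-predictor model is
`contribution(s1, e) ~ clr(s2) + ... + clr(sn)` over the same samples,
with the response's own abundance **excluded** from the predictors (a
self-inclusive variant is not fitted by default). Each non-intercept
coefficient with p < 0.05 becomes a directed edge `predictor ->
response` with the coefficient's sign. No multiple-testing correction
is applied by default, mirroring the per-coefficient convention of the
source analyses; Benjamini–Hochberg is available via `p_adjust`.
Models need at least 10 observations and more observations than
predictors plus one; under-determined or constant-response models are
skipped and reported, and the condition number of the design matrix is
logged for collinearity diagnostics.

The continuum summary computes, per species, the median adjusted
R-squared across its ECs, and the averages
`avg_inhibited = (# negative out-edges) / (# EC networks where the
species is an eligible predictor)` (and analogously for facilitation).
The denominator was another open reading — "average number" could also
be over all ECs — and is configurable by passing a different
`eligible` table. Species above median adjusted R-squared 0.2 are
classed competitive.

## The synthetic community generator

Real cohort data (hundreds of paired SRA metagenomes and
metatranscriptomes plus profiler databases) are far beyond desk scale,
so every stage is validated against a generator whose planted
structure is known exactly.

**Abundances.** Species mean log-abundances are drawn once per
configuration (`mu_sd = 1.5`); per-sample latent log-abundances add a
unit-scale multivariate normal with block-equicorrelation
(`within_cluster_rho = 0.8` inside each of `n_clusters = 4` planted
blocks, zero between). Latents are softmax-closed and read counts
drawn multinomially at `total_reads_per_sample = 1e5`. The
log-normal–multinomial construction (rather than a Dirichlet) keeps a
latent correlation target to validate the network stage against and
produces overdispersed, compositional counts like real profiles.

**Transcription.** Competitive transcribers emit
`coupling_strength * (clr - expression_offset)` cpm plus Gaussian
noise truncated at zero (`coupling_strength = 8`,
`expression_offset = -4`, `noise_sd = 3`): transcription rises with
abundance and rare species fall silent. Opportunists emit
`opportunist_baseline / (1 + exp(suppression_strength * (C -
mean(C))))` plus noise (`baseline = 25`, `suppression_strength =
1.2`), where `C` is the per-sample summed clr abundance of the EC's
competitive transcribers. The logistic (rather than a hard switch)
keeps regression recovery a fair test instead of a separability
artifact. The UNCLASSIFIED remainder is ~2% of the species strata with
lognormal noise, so contributions vary even for single-transcriber
ECs. Default roles place competitive degraders in the first half of
the clusters and opportunists in the second, so an opportunist's own
abundance is uncorrelated with its suppressors — the cleanest version
of the planted decoupling. Repertoires deal 2–4 catalog ECs per
degrader round-robin (never a pure galactosidase pair), giving every
EC several competitive and opportunistic transcribers; each degrader
also carries about twice as many non-catalog glycoside hydrolase ECs
(`gh_ratio = 2`) to support the repertoire-comparison analysis.

What the generator does **not** emulate: repeated samples per subject
(real cohorts are longitudinal; the pooled OLS here mirrors that
published choice and simply flags the non-independence), strain-level
variation, sequencing error, database incompleteness, and any coupling
between transcription regimes and phylogeny. Passing recovery tests
therefore show the estimators work when their assumptions hold, not
that real data satisfy those assumptions.

## Validation scales and what the tests check

The packaged checks run at the smallest scales at which the targeted
properties are stable: null calibration on 200 samples x 50 species
with 1000 shuffle replicates (the pre-filter significant-edge rate
must sit at 1%); cluster recovery on 300 samples over 10 seeds
(adjusted Rand index >= 0.8 against the planted blocks); role and
suppression-edge recovery over 20 and 5 seeds at 300 samples; and a
false-edge rate under zeroed couplings within 3 points of the nominal
5%. `scripts/acceptance.R` recomputes all of these from scratch for
any seed. Oracle tests compare clr, Spearman and OLS
coefficient/p/adjusted-R-squared values against independent
brute-force implementations (hand ranks, normal equations, t and F
tails) to 1e-8, and the filter cascade on a 12-sample packaged fixture
is frozen against golden files.

## Known limitations

* The pooled permutation null calibrates the *family* of pairwise
  tests, not each pair; heavy-tailed species with many ties can be
  slightly mis-calibrated individually.
* Contributions are percentages and therefore themselves
  compositional within an EC; the OLS models ignore this, as did the
  analyses this package operationalizes.
* Greedy modularity has a resolution limit; very small planted
  clusters may be absorbed.
* With file inputs the encoder tier depends entirely on the
  metagenome table supplied; without one, only transcription tiers are
  called.
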