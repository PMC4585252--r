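---
title: "Fe/Cu metalloprotein fold-family inventories: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fe/Cu metalloprotein fold-family inventories: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metfam)
```

# The scientific problem

Microbial communities in oxygen minimum zones (OMZs) sit across one of
the steepest redox gradients in the ocean. Dissolved iron is released
and retained under anoxia while dissolved copper varies little, so the
Fe:Cu molar ratio of the water column changes by an order of magnitude
between the oxic surface and the anoxic core. Because many respiratory
and nitrogen-cycle enzymes are obligate Fe or Cu metalloproteins, the
community's *genetic* inventory of Fe- vs. Cu-binding protein families
is expected to track that chemistry: Fe-enzyme-rich anaerobic
metabolisms (denitrification steps, anammox) under anoxia, Cu-enzymes
(multicopper oxidases, Cu-nitrite reductase nirK, cytochrome c oxidase's
Cu centers) where oxygen is present.

`metfam` implements the full chain needed to test that expectation on
sequence data: build Fe/Cu reference sets from a structural
classification, profile reads against them, normalize to comparable
units, assign taxonomy, and correlate inventories with geochemistry.
This vignette records the models, the parameters that matter, and the
design decisions taken where the procedure was genuinely open.

# Reference construction

The unit of counting is the *fold family* — the family level of a
SCOPe-style structural classification, identified by a dotted `sccs`
label (e.g. `b.6.1.3`) and an integer `sunid`. `parse_hierarchy()`
accepts the tab-separated description/classification dialect (level
codes `cl`, `cf`, `sf`, `fa`, `px`); parentage is reconstructed from the
`sccs` prefix structure, with the classification file's lineage column
(`fa=`) taking precedence for domains. We model exactly one
sequence-bearing level (the domain); species/duplicate levels of the
full classification are outside the data model.

`expand_sunids()` performs the recursive traversal from family (or any)
seeds down to domain sequences. Two properties pin its semantics and
are enforced by tests: expansion of the root yields every leaf, and
expansion of any node equals the union of its children's expansions.
Output order is ascending sunid so results are diffable.

`build_metal_reference()` labels expansions Fe or Cu and applies
family-level exclusions. The default downstream exclusion is
`c.83.1.1` (aconitase): it is an Fe *regulatory* protein and would
otherwise inflate the catalytic Fe signal. Proteins reachable from both
metal seed sets are retained once per metal and flagged `dual_metal`
rather than dropped — dropping would silently lose signal, and
downstream code can deduplicate if desired. Identical sequences under
multiple sunids are likewise retained and flagged by the round-trip
writer rather than collapsed: deduplication is a user decision, not a
parser side effect.

Seed lists are configuration, not code. The full published Fe (108
families) and Cu (16 families) lists belong to prior compilations;
the package ships small editable fixture lists plus `read_seed_list()`.

# The translated search

The search emulates a translated (BLASTX-style) protein search at
fixture scale, where exhaustive alignment is affordable and exactness
is worth more than speed.

* **Quality filter and merge** (`quality_filter_merge()`): pairs are
  dropped when either mate's *mean* Phred quality is below 25 (a
  "Phred 25" cutoff can be read per-base or on the mean; the mean is
  used and the threshold is a parameter).
  Merging scans overlap lengths from the maximum down to
  `min_overlap = 10`, accepts mismatch fractions up to 0.25, and keeps
  the overlap with the fewest mismatches (ties to the longer overlap);
  within the overlap the higher-quality base wins.
* **Translation** (`translate_six_frames()`): all six frames, stops
  rendered `*`, `N`-containing codons rendered `X`. The aligner assigns
  `*` a prohibitive penalty, so no local alignment ever crosses a stop.
* **Low-complexity masking** (`mask_low_complexity()`): a DUST-style
  triplet over-representation score on sliding windows, on by default.
  It stands in for MEGAN's "min complexity 0.3" pre-filter as an
  approximation; no numeric parity with MEGAN is claimed.
* **Alignment** (`align_local()`, C++): affine-gap Smith–Waterman under
  BLOSUM62 with gap open 11 and extend 1 (a gap of length L costs
  11 + L). Traceback ties break diagonal > up > left, and the best cell
  is the first maximum in row-major order, so coordinates are fully
  deterministic. The test suite proves score equality against an
  independently coded quadratic dynamic program on thousands of random
  pairs.
* **Statistics**: bit score `(0.267 * S - ln 0.041) / ln 2` (gapped
  BLASTX convention); E-value `space * 2^-bits` with the effective
  space defaulting to total reference residues x query peptide length.
  Hits require bit >= 50 *and* E <= 0.1, both configurable
  (`search_params()`). The integer raw-score threshold is derived from
  the bit cutoff, so the 50-bit boundary is honoured exactly: the
  largest raw score below threshold maps to < 50 bits and the smallest
  retained raw score to >= 50 bits.

Externally produced hits in the common 12-column tabular dialect can be
injected via `parse_tabular_hits()`, which joins rows to the reference
by subject id and drops (with a count) rows naming unknown subjects.

# From hits to inventories

`assign_top_hits()` implements the fractional top-hit rule: per query,
the k hits whose bit scores round (at 1 decimal, matching tabular
output precision) to the maximum each receive weight 1/k. Weights sum
to exactly 1 per query, and that invariant is carried unchanged through
every later step — the central conservation law of the pipeline.
Queries hitting both the Fe and the Cu reference are assigned within
each metal independently, because the two searches are separate
experiments.

`split_cupredoxins()` relabels `b.6.1.3` parts as `b.6.1.3/nirK` or
`b.6.1.3/MCO` by ordered case-insensitive substring rules on the hit
description (nirK patterns first); non-matching parts keep the plain
label and are always routed to "others" by `cluster_minor()`. The split
runs *before* the 4% minor-family clustering because the split classes
are reported as major categories; the rule table is ordinary data and
can be edited (`cupredoxin_rules()`).

`cluster_minor()` merges labels below 4% of the per-sample, per-metal
total into "others" (labels at exactly 4% are retained). The 4% base is
per sample and per metal, since inventories are reported per sample.
`normalize_per_100k()` divides by the sample's total protein-coding
sequence count and multiplies by 100,000. That denominator is an
explicit input everywhere — it comes from a bulk (non-metal) search and
cannot be inferred from the metal hits, so the package never guesses
it.

# Taxonomy

`assign_lca()` is the standard lowest-common-ancestor binning: discard
hits below 50 bits or above E = 0.01, retain hits within 10% of the
best bit score (multiplicative, i.e. bit >= 0.9 x best), return the
deepest taxon ancestral to all retained subjects. `min_support`
defaults to 1; when raised, taxa with fewer supporting queries are
reported unassigned (interactive LCA tools instead promote such reads
up the tree — at the default the behaviours coincide).
Raising `top_percent` can only coarsen the assignment, and the result
is provably an ancestor of every retained hit's taxon; both properties
are tested. `rollup_phylum()` climbs to the phylum rank for the
bulk-vs-metal community comparisons.

# Geochemistry and statistics

**Zones.** Five joint depth/O2 boxes: upper oxic (15–30 m, > 200 µM),
upper oxycline (50–85 m, 10–200 µM), upper OMZ (70–125 m, < 10 µM),
core OMZ (200–300 m, < 5 µM), lower oxycline (500–1000 m, 5–50 µM).
The printed ranges do not state inclusivity, so the package fixes a
convention: depth windows closed on both ends, O2 intervals closed
below and open above (upper oxic requires strictly > 200). Where depth
windows overlap (70–85 m) the O2 ranges are disjoint, so the classifier
is a partition; anything outside every box is `unclassified`.

**Fe:Cu vs O2.** `fit_fe_cu_vs_o2()` is ordinary least squares of the
molar ratio on O2; `predict_zero_oxygen()` returns the intercept — for
a negative slope, the predicted maximum ratio in the zero-oxygen limit
(a nonnegative slope returns the value flagged `is_maximum = FALSE`).
A constant response is reported as slope 0 with R² = 0 rather than NaN.

**Spearman screens.** rho is Pearson correlation on mid-ranks (ties
averaged). For n ≥ 10 the two-sided p uses the t approximation with
n − 2 df; for n < 10 it is the exact two-sided permutation probability
over all n! orderings of one margin. No multiple-testing correction is
applied to the primary p-values; Benjamini–Hochberg q-values are
reported alongside and labelled as such. Missing values are handled by pairwise-complete deletion, never
imputation; constant vectors are skipped with a note.

**Rarefaction.** `rarefy_matrix()` subsamples each sample without
replacement to the target depth, 999 times by default, and returns the
per-label mean. The analytic expected-richness formula is deliberately
not used: repeated subsampling is the convention this package follows,
and its mean converges on the hypergeometric expectation (verified
within 3 standard errors in the tests).

**Partial CCA.** `partial_cca()` delegates to `vegan::cca` (community
matrix, constraints, optional conditions) behind a stricter surface:
constant constraint columns are dropped with a note (alone they yield
exactly zero constrained inertia), non-constant collinear constraints
raise an error naming the aliased columns, and species scores use
vegan's scaling 2 (eigenvalue-square-root scaling), stated here because
the choice affects plots but not eigenvalues. The tests pin the
correspondence-analysis identities independently of vegan: total
inertia equals the chi-square statistic over the grand total, and the
single-constraint eigenvalue equals a directly coded
weighted-projection/SVD oracle.

# The synthetic-data generator

The generator defines the package's study conditions; its defaults are
fixed, not tuning knobs.

* **Hierarchy** (`make_hierarchy_fixture()`): always contains
  `b.6.1.3` (with nirK-, MCO- and unannotated-styled domain
  descriptions), `b.6.1.2`, `c.81.1.1`, `c.83.1.1` and `f.24.1.1`, so
  the description-splitting and exclusion rules are exercised; extra
  families are synthetic. Domains are ~10%-mutated copies of a family
  ancestor: within-family identity is high, between-family identity is
  background, which is the property the family-level counting model
  relies on.
* **Reads** (`simulate_reads()`): 120-nt fragments (a merged-read
  scale), uniform synonymous codon choice (the simplest defensible
  null — no organism codon bias), 1% substitution rate by default,
  random strand, constant base qualities consistent with the rate
  (Q = −10 log10 rate). Truth tables record family, source protein and
  taxon per read.
* **Profiles** (`simulate_profiles()`): 15 depths from 15 to 1000 m
  with target curves giving O2 > 200 µM at the surface, an oxycline
  decline, < 5 µM at the 200–300 m core and partial recovery below;
  dissolved Fe rising from ~0.1 nM to ~2 nM across the oxic–anoxic
  transition; dissolved Cu flat within 0.9–1.6 nM; plus a secondary
  nitrite maximum, a nitrate dip and a thermocline. Lognormal noise
  (default 5% relative) perturbs O2 and Fe and is clamped so each depth
  stays inside its designed zone box — the generator's contract is that
  all five zones are representable at every seed, which the clamping
  guarantees by construction (and the vignette states openly: the noise
  model is zone-preserving, not free).

What the generator does *not* emulate: realistic community abundance
distributions (log-normals), indel sequencing errors, chimeras, codon
bias, database redundancy, or taxonomies at NCBI scale. Passing tests
therefore demonstrate the correctness of the pipeline's rules and
statistics under controlled conditions, not field performance against
full-scale databases.

# Numerical choices and degenerate inputs

* Bit-score ties for the 1/k rule are decided after rounding to 1
  decimal (`tie_decimals`), matching tabular output precision.
* The search's raw-score gate is the smallest integer whose bit score
  reaches the cutoff, so floating-point drift cannot move the 50-bit
  boundary.
* `cluster_minor()` conserves totals exactly (sums, no renormalization).
* Empty inputs: an empty read stream yields an empty hit table; an
  empty seed list yields an empty reference; comments-only hierarchy
  files yield a root-only hierarchy.
* All list-like outputs are deterministically ordered (ascending sunid,
  lexicographic labels); every random operation takes an explicit seed
  and restores the caller's RNG state.
* `run_pipeline()` validates all referenced paths before any stage
  runs, aborts naming the failing stage, writes an `INCOMPLETE` marker
  on stage failure, and emits a manifest with md5 checksums and no
  timestamps, so reruns with one config are byte-identical.

# Problem sizes used by the test suite

The suite runs the alignment oracle on 1,000 random peptide pairs
(length ≤ 30), composition recovery on 20 independent simulations of
2,000 reads from a 0.40/0.30/0.15/0.10/0.05 five-family mixture
(recovered within 3 percentage points in at least 19 of 20), hierarchy
expansion against exhaustive DFS on 100 random trees, LCA against the
ancestor-intersection oracle on 500 random hit sets over the ~40-node
fixture taxonomy, Spearman against full 720-permutation enumeration at
n = 6, CCA identities on 50 random matrices, and the five-sample demo
pipeline twice for byte-identity. These sizes were chosen as the
smallest at which the binomial and permutation tolerances quoted above
are meaningful.

# Known limitations

* The search is exhaustive Smith–Waterman: exact and deterministic, but
  not intended to compete with seeded heuristics on large references.
* The low-complexity mask approximates, and does not reproduce, MEGAN's
  min-complexity filter; LCA counts are therefore not numerically
  comparable to MEGAN output on real data.
* Genome mode (protein input) is a supported pipeline mode, but
  reproducing published per-genome gene counts would require the dated
  external databases those counts came from.
* CCA axis significance testing by permutation is not implemented.
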