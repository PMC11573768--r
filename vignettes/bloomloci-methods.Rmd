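---
title: "bloomloci: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{bloomloci: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloomloci)
```

## The scientific setting

Spring phytoplankton blooms release large amounts of algal polysaccharide
(laminarin, mannans, alginate, fucoidan) into seawater, and heterotrophic
bacterioplankton — Bacteroidetes above all — respond. Their degradative
machinery is organized in two layers that shotgun metagenomics can see:
the per-genome dosage of carbohydrate-active enzymes (CAZymes, the
GH/GT/PL/CE/AA/CBM families of the CAZy classification), and the
polysaccharide utilization loci (PULs), operon-like clusters pairing a
SusC TonB-dependent transporter with a SusD glycan-binding lipoprotein and
several degradative CAZymes aimed at one substrate.

bloomloci implements the post-annotation statistics for such a dataset: it
takes an ORF table with multi-database annotations, per-sample coverages
and a chlorophyll *a* series, and produces filtered CAZyme calls, per-taxon
copy numbers, profile ordinations, bloom-correlation tables and PUL calls.
Everything upstream (assembly, gene calling, homology searches) and
everything interpretive is out of scope.

## Consensus CAZyme filtering

Homology assignment to a CAZy family is error-prone: a protein can score
against a family while being, over broad databases, more similar to
something else entirely. The consensus rule demands corroboration — an
ORF's CAZy families are kept only if at least one of its PFAM, KEGG or COG
annotations belongs to a curated carbohydrate-related set.

Three readings of the rule were genuinely open and are fixed as follows:

* **Positive evidence is required.** An ORF with a CAZy hit and *no*
  PFAM/KEGG/COG annotation at all is dropped; the rule asks for a
  carbohydrate-related co-annotation, not merely the absence of a
  contradicting one. `keep_unannotated = TRUE` inverts this.
* **Filtering is ORF-level.** Co-annotations are not family-resolved, so
  one satisfying hit keeps all of the ORF's families.
* **"Accuracy" is precision.** `evaluate_annotation()` reports recall
  `100·TP/n_ref` and accuracy `100·TP/n_pred`; this is the only reading
  under which published N/recall/accuracy triples for this kind of
  benchmark are arithmetically coherent. Matching is at family level
  (subfamily suffixes stripped). Percentages are kept real-valued
  internally and rounded half-away-from-zero only for display.
* TIGRFAM evidence does not count toward the consensus by default (its
  contribution is unclear in practice); the carb-related map is pure
  configuration.

The packaged `carb_related` sets are small synthetic stand-ins — real
analyses must supply their own curated CAZy↔PFAM/KEGG/COG equivalence map
through `load_function_sets()`.

## Copy numbers and the USiCG denominator

For a taxon subset, sample and function *f*:

cn(*f*) = Σ coverage(subset genes carrying *f*) / median over the USiCG
panel of Σ coverage(subset genes carrying that USiCG).

Because a universal single-copy gene occurs once per genome, the median
aggregate USiCG coverage estimates "genome equivalents" of the clade, and
the ratio is the average gene count per genome. Choices that matter:

* **Aggregate per USiCG, then median.** Coverages are summed per panel
  member across the subset's genes first; the median runs over the 11
  panel members (even counts: mean of the central pair). Taking a median
  over individual genes instead would conflate panel composition with gene
  fragmentation.
* **Absent USiCGs count as zero** in the median rather than being skipped:
  skipping silently inflates denominators for poorly covered clades
  (`skip_absent = TRUE` opts out). A zero median flags the cell as
  undefined — never coerced to zero.
* **Missing coverage is an error**, not zero; silent zeros bias ratios.
* **CAZy class queries count genes once**: the numerator for `"GH"` sums
  genes having ≥ 1 GH family, whatever their family multiplicity —
  class-level dosage is a gene-level quantity, not a sum of per-family
  copy numbers.
* The 11-member USiCG panel identity is configuration; the shipped default
  is a clearly labelled stand-in of ribosomal-protein COGs.

Read percentages per taxon use only ORFs classified at the queried rank in
the denominator, so sibling taxa plus the unclassified remainder close to
100%.

## Profile distances and ordination

CAZyme family profiles are compared with the community-ecology chi-squared
distance on proportional data, `d(i,j) = sqrt(N · Σ_k (x_ik/r_i −
x_jk/r_j)²/c_k)`. The √N scaling is the common convention (vegan's);
it affects axis units, never the MDS shape. Rows enter as proportions, so
per-row scaling is immaterial; all-zero rows are rejected and all-zero
columns dropped with a warning.

`classical_mds()` is plain Torgerson scaling: double-center the squared
distances, eigendecompose, scale eigenvectors by √λ. Explained variance is
relative to the positive-eigenvalue total; negative eigenvalues are
reported but no correction (Cailliez/Lingoes) is applied, keeping the
embedding faithful to the distances actually supplied. Axis signs are made
reproducible by forcing each axis's largest-magnitude coordinate positive.
The default profile rows are per-taxon family profiles averaged over the
series; `per_sample = TRUE` keeps taxon–sample rows.

## The chlorophyll screen

Each family's copy-number series is correlated with chlorophyll *a* by
Spearman's ρ, computed as the Pearson correlation of average-rank vectors
(authoritative under ties; the classic `1 − 6Σd²/n(n²−1)` shortcut is only
valid untied). Two-sided p-values use **full permutation enumeration for
n ≤ 8** — series of a dozen samples sit exactly where t-approximations are
unreliable, and enumeration is exact even under ties — and the
t-approximation with n − 2 degrees of freedom above that
(`method = "approx"` forces the common package default). Benjamini–Hochberg
step-up adjustment runs across the screened families; significance is
q ≤ 0.01. Note the guard implied by enumeration: with n samples the
smallest achievable two-sided p is 2/n!, so very short series cannot reach
small α no matter how perfect the trend. Families with all-zero or
constant series are skipped and logged, not errored. The screen is
taxon-scoped (Bacteroidetes in the canonical use); community-wide
screening is just `taxon = NULL` upstream.

## PUL detection rules

* susC: PFAM∪TIGRFAM ∩ {PF00593, PF07715, PF13715, TIGR04056} ≠ ∅;
  susD: PFAM ∩ {PF07980, PF12741, PF12771, PF14322} ≠ ∅. A double match is
  logged and resolved to susC (configurable).
* **Tandem**: adjacent genes (no intervening ORF), same strand, intergenic
  gap < 102 bp. "Less than 102 bp apart" is read as the count of bases
  strictly between the genes being ≤ 101; overlapping genes are
  contiguous (negative gaps clamp to 0). Either linear order susC–susD or
  susD–susC counts by default (`strict_order` restricts to susC upstream).
  The gap rule applies to the pair itself, not only to flanking genes.
* **Extension** walks outward from the tandem; the next gene joins the
  locus iff it is on the tandem strand and (gap < 102 bp or it is a
  post-filter cazyme — cazymes are exempt from the gap limit). The walk
  stops at the first failure, a strand change, or the contig edge; loci
  never cross contigs.
* **Calling**: funnel stages are small contig (< 3 genes besides the
  pair), big contig, ≥ 3 post-filter cazymes on the contig, and called —
  requiring ≥ 3 cazymes in the locus and **no opposite-strand cazyme
  within the locus span** (the "same direction" veto; the veto window is
  the span, not the whole contig). Counts are cumulative, so the funnel is
  monotone by construction.
* Accessory genes (sulfatases, peptidases, regulators) are labelled in the
  report but never influence calling.

The original analysis verified distance/direction criteria partly by eye;
an automated veto can be stricter or looser than such manual checks. The
equivalence we *can* establish is internal: an independent brute-force
window oracle (enumerate whole candidate windows, test every gene's
predicate directly) agrees with the incremental walk on 1,000 random
synthetic contigs with zero disagreements.

## The synthetic world

`simulate_community()` states a world and sticks to it:

* Each planted genome is a list of function copy counts; every USiCG has
  exactly one copy. Every copy is its own ORF, so summed function coverage
  over the USiCG median recovers planted copies identically at zero noise.
* Coverage of a gene in a sample is `abundance × depth × m × (1 + ε)`,
  with `m` a per-sample copy multiplier (1 except for planted correlated
  families) and ε Gaussian with `noise_sd` (default 0.1), truncated at
  −0.99 to keep coverage positive; a matched-mean lognormal is available.
  Multiplicative noise is adequate for the rank statistics downstream.
* Reads are `round(coverage × gene_length / 100)` (100 bp reads); only
  relative counts matter.
* The default series has 12 samples: chlorophyll flat at ≈ 0.1 µg/L for
  three late-winter samples, then a logistic rise to an early-summer peak
  of 8 µg/L — the Arctic under-ice-to-bloom shape.
* Correlated families are planted as strictly monotone transforms of
  chlorophyll, `base·(1 + effect·c̃)` (or the reversed ramp), so noiseless
  Spearman ρ is exactly ±1.
* Genes on simulated genome contigs sit 150 bp apart — outside the PUL gap
  rule — so locus geometry enters only through explicit `pul_layout()`
  plans; the packaged decoy library covers the callable case, too few
  cazymes, opposite-strand cazymes, a severing non-cazyme gap, the
  gap-exempt distant cazyme, the bare tandem and the in-span
  opposite-strand veto.
* `plant_annotation_noise()` controls the carbohydrate co-annotation rate
  of true cazymes (`p_true`) and appends spurious cazyme ORFs carrying
  co-annotations at `p_false`, recording all labels in the manifest.

What the generator does **not** emulate — and hence what a green test does
not establish: real assembly artifacts (chimeras, fragmented ORFs),
taxonomic misassignment, correlated annotation errors across databases,
uneven genome sizes within a clade, and read-mapping biases. Green tests
establish that the *statistics* do what they claim on data satisfying
their assumptions, not that the assumptions hold for any particular
metagenome.

## Numerical conventions

* Coordinates are 1-based inclusive throughout; GFF3 export shifts
  nothing. Strand is `+`/`-`.
* Median of an even count is the mean of the central pair (R's default).
* Exact-permutation p uses a tolerance of 1e−12 on |ρ| comparisons to
  absorb floating-point ties.
* Display rounding of percentages is half-away-from-zero; internal values
  are never rounded.
* The abundance simplex is enforced to 1e−9; copy-number recovery at zero
  noise is asserted to 1e−9; MDS reconstruction of Euclidean inputs to
  1e−8.

## Known limitations

* PUL substrate prediction, cross-PUL clustering and genome-resolved
  (binned) copy numbers are out of scope.
* The shipped USiCG panel and carbohydrate-related sets are stand-ins;
  results on real data are only as good as the supplied configuration.
* The t-approximation p-values for n > 8 are approximate in the tails;
  for strict control on short series, stay within the exact regime.
* The veto-window and gap thresholds are exposed (`max_gap`,
  `min_cazymes`) but the defaults are the canonical published rules; the
  package takes no position on alternative PUL definitions (e.g.
  susCD-only "PUL-like" loci).
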