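---
title: "Structural variant clusters: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural variant clusters: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svcluster)
```

## The model

Archives of submitted structural variants (SSVs) are redundant by
design: many studies report presumably identical events with slightly
different, sometimes fuzzy, breakpoints. A structural variant cluster
(SVC) set replaces that redundancy with a partition of the covered
genome: within one grouping key (a variant type, optionally restricted
to one study) and one chromosome, the union of all resolved placements
is split at *every* placement endpoint, and each resulting segment
carries the number of placements that fully contain it — its
concordance count.

Three consequences define the semantics:

* a solitary placement is its own cluster with count 1;
* adjacent clusters always differ in their member set (the endpoint
  separating them belongs to a placement lying on exactly one side);
* coverage is conserved: the sum of segment length × count equals the
  summed length of the input placements. This identity is asserted on
  every random instance in the test suite — it is the cheapest complete
  detector for off-by-one errors in the segmentation.

Counts are **per placement**, not per study: two identical submissions,
whether from one study or two, both count (duplicated `ssv_id`s are
logged, never collapsed). A separate retained set of contributing study
accessions supports per-study reporting without changing the counts.
Regions with zero coverage are never emitted; a cluster exists only
where at least one submission exists.

The rare/common convention follows the field's working definition over
such counts: count ≤ 2 is *rare*, count > 2 *common*
(`classify_frequency()`, threshold configurable).

## Coordinates and fuzzy placement

All internal arithmetic is 0-based half-open; study-file and GVF
coordinates are 1-based inclusive and are converted exactly once, in the
readers and writers. Half-open semantics make the segmentation algebra
exact and settle the tie-break: a placement ending at position *p* and
another starting at *p* do not overlap.

A fuzzy placement carries up to three tiers per side,
`outer_start ≤ start ≤ inner_start` and `inner_stop ≤ stop ≤ outer_stop`.
Resolution to one concrete interval is a policy:

* `outermost` (default): minimum available start-side tier, maximum
  available stop-side tier — the conservative superset of all placements
  consistent with the reported uncertainty;
* `innermost`: the opposite extremes — the region the submitter was
  certain about.

The default is `outermost` because downstream users of the clusters
typically ask "could a variant plausibly touch this region?"; the choice
is a flag, not a constant, because the source tooling never states which
convention it used. Records whose resolved interval is empty under the
requested policy are routed to the rejection channel, as is every parse
failure — rows are never silently dropped.

Chromosomes sort naturally (1..22, X, Y, MT, with or without `chr`
prefix) with unrecognized names lexicographically after them; GRCh38
RefSeq `NC_` accessions are translated via `refseq_chrom_aliases()`.
Each input row names a single chromosome, so inter-chromosomal
placements (translocation endpoint pairs) cannot be expressed in this
dialect; `partition()` and `cluster_records()` additionally refuse
mixed-chromosome interval lists at the API level.

## Algorithm and numerical choices

`partition()` performs one sweep over the 2*n* sorted endpoints: the net
start/end delta at each breakpoint is accumulated into a running
coverage, and a segment is emitted between consecutive breakpoints
whenever coverage is positive. O(n log n) time, vectorised per
(group, chromosome) via data.table grouping, which is what makes the
million-record acceptance run finish in well under a minute on one CPU.

Member/study retention is optional and defaults off above a configurable
input size (100,000 records), because member lists grow with
coverage × segments while counts do not; at archive scale only the
counts are wanted.

`assign_ids()` numbers clusters `SVC1, SVC2, …` in a canonical order —
variant type lexicographically, then study accession, then genome
position — so identical inputs always yield identical identifiers, and
all writers emit byte-identical files for identical input.

Variant-type tokens are case-folded with collapsed whitespace and a
small configurable alias map (e.g. `CNV` → `copy number variation`);
the GVF `type` column carries the normalized token verbatim rather than
a Sequence Ontology accession, matching how such summary tables name
types in practice. Summary percentages use round-half-up to integers:
this is the only rounding rule that reproduces all nine printed
percentages of the published combined-set per-type table from its raw
counts (including the 0.52% "Others" row printed as 1%).

## File formats

* **GVF** (GFF3 syntax): one feature line per cluster with attributes
  `ID`, `variant_count`, `variant_type`, optional `study`/`studies`, and
  any annotation attributes. The attribute name `variant_count` is this
  package's contract (the source tooling's attribute vocabulary is not
  public). Pragmas record the format version (default `1.10`,
  overridable), genome build, and grouping mode, so write → read is an
  identity; foreign attributes on input are preserved. Attribute values
  must not contain `;`, `=`, `,` or tabs — they are not percent-escaped.
* **bedGraph**: `chrom start end count`, 0-based half-open; the chosen
  BED-family export because the count is the payload. Plain BED3 via
  `write_bed3()`.
* **WIG**: `variableStep` with `span`, a new stanza whenever chromosome
  or span changes, positions 1-based. bedGraph and WIG encode the same
  per-base step function; the tests reconstruct both profiles and
  compare them, and check Σ span × value against Σ length × count.
* Track export requires a single variant-type (and study) group per
  file — one value dimension per track; mixed sets are refused with a
  pointer to `filter_clusters()`.

Comparison (`overlap_query()`) reports every (query, cluster) pair
overlapping by ≥ 1 base, with the overlap extent and Jaccard index; a
`min_jaccard` option refines, since no principled universal threshold
exists. Annotation (`annotate_clusters()`) is the symmetric operation —
a feature annotates a cluster iff the pair would be reported as an
overlap — offered in any-overlap (default) and containment-only modes
because "co-located" has no single agreed rule; it adds metadata only
and never touches intervals or counts.

## The synthetic world

`synth_config()` describes the stand-in for a multi-study archive
download; its defaults are a stated world, fixed once:

* variant-type mix from the shares observed in the large public
  combined-set release (deletion 0.35, copy number loss 0.18, mobile
  element insertion 0.15, duplication 0.09, insertion 0.07, indel 0.05,
  copy number gain 0.05, copy number variation 0.05, inversion 0.01);
* log-uniform event sizes 100 bp – 10 kb (the mid-range of submitted SV
  sizes; desk-scale per-base verification stays tractable);
* a two-chromosome toy genome (1 Mb + 0.8 Mb) — a deliberate scale-down;
* one 10× overlap hotspot on chr1 (archives show strong regional
  clustering), implemented as a mixture over a uniform baseline;
* 20% of records fuzzy, with tier offsets ≤ 50 bp constructed to satisfy
  the ordering invariants;
* every draw routed through one generator seeded from the config; the
  caller's RNG state is restored afterwards, and output files are
  byte-identical across runs.

What the generator does **not** emulate: real per-study size/type biases,
assembly gaps and problem regions, breakpoint-uncertainty correlations,
and genuine inter-study duplication structure. A green test therefore
establishes algorithmic correctness on archive-*shaped* data, not
fidelity to any particular archive release.

The generator's companion, `ground_truth_segmentation()`, is the
independent oracle: it enumerates, for every covered base, the member
set by direct comparison, and merges runs of identical sets. It is
deliberately quadratic and refuses instances beyond 5 × 10⁷
position-record comparisons; large-instance validation uses
`per_base_counts()` (literal per-record coverage increments) against the
profile implied by the emitted clusters. Sweep-versus-oracle equality on
every generated dataset is the synthetic module's reason to exist.

## Design decisions that were genuinely open

* **Grouping-mode cluster totals.** No inequality between study-set and
  combined-set cluster counts holds in general: a placement duplicated
  across studies is one combined segment but two study-set segments,
  while cross-study overlaps split combined segments invisible to
  single-study streams (large archives in fact report fewer study-set
  regions). The suite therefore asserts the true invariant — pooled
  per-study per-base profiles reconstruct the combined profile exactly —
  rather than a count inequality.
* **Filtering precedes export.** Whether a count cut (e.g. the common
  browser-track cut at count ≥ 100) should apply before or after track
  binning is unspecified in the field; here filters always apply to the
  cluster set, and tracks render whatever set they are given.
* **Column schema.** Archive dump column layouts vary by release, so the
  reader takes an explicit column map (flat `field: column` file) rather
  than guessing headers; the bundled default names columns after the
  semantic fields.
* **"Others" bucket.** The per-type summary pools any type below a 1%
  share (configurable) into `Others`, mirroring the convention of the
  published summary table whose bucket membership is not enumerated.

## Known limitations

* No breakpoint-uncertainty-aware clustering and no reciprocal-overlap
  merging — those are different method families; fuzziness is resolved
  to one interval *before* clustering.
* No VCF ingestion, no network retrieval, no binary track outputs
  (bigWig/tabix).
* GVF attribute values are written unescaped (see above).
* The absolute cluster totals of any real archive release are
  version-dependent and reproducible only from the corresponding dated
  download; the package verifies the published table's internal
  consistency (counts → percentages, copy-number subtotal) instead.
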