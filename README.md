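# svcluster

Structural variant clusters (SVCs) from multi-study structural variant
submissions.

## The problem

Public structural-variant archives collect millions of submitted
structural variants (SSVs) — deletions, duplications, insertions, copy
number variants — from many independent studies, placed on a reference
assembly, often with *fuzzy* breakpoints (outer/inner coordinate tiers
bracketing the true but unknown start and end). Presumably identical
variants are submitted repeatedly by different platforms and samples, so
there is no single reference record per locus, which makes comparison,
annotation and frequency estimation across studies awkward.

`svcluster` computes a non-redundant set of disjoint genomic regions —
structural variant clusters — from any such collection, for people who
need a reference coordinate system over redundant SV submissions:
database curators, SV pipeline authors, and anyone comparing their calls
against an archive.

## The method

Let the resolved placements of the SSVs of one variant type (optionally:
of one study) on one chromosome be half-open intervals
$I_1, \dots, I_n$, $I_i = [s_i, e_i)$. The breakpoint set
$B = \{s_1, e_1, \dots, s_n, e_n\}$, sorted as $p_1 < p_2 < \dots < p_k$,
partitions the union $\bigcup_i I_i$ into segments
$[p_j, p_{j+1})$. Every segment with positive coverage is an SVC, and its
**concordance count** is

$$c([p_j, p_{j+1})) \;=\; \#\{\, i : I_i \supseteq [p_j, p_{j+1}) \,\}.$$

A solitary SSV is its own SVC with count 1. Adjacent segments always
differ in their member set, counts are conserved
($\sum_\text{SVC} \text{len} \times c = \sum_i |I_i|$), and a region with
count $\le 2$ is classified *rare*, $> 2$ *common*. The implementation is
a single $O(n \log n)$ sweep over the sorted endpoints, validated against
a literal per-base counting oracle.

## Worked example

Three deletions whose endpoints are the five ordered positions
100, 200, 300, 400, 500 (1-based), i.e. half-open `[99,300)`, `[199,400)`,
`[199,500)`:

```r
library(svcluster)
ssv <- data.frame(chrom = "chr1", start0 = c(99, 199, 199), end0 = c(300, 400, 500),
                  ssv_id = c("ssv1", "ssv2", "ssv3"),
                  study_id = c("nstd001", "nstd002", "nstd001"),
                  variant_type = "deletion")
svc <- assign_ids(cluster_records(ssv))
svc
#> <cluster_set> 4 SVC region(s), grouping combined_by_type, assembly GRCh38
#>    svc_id  chrom start   end count variant_type study_id
#> 1:   SVC1   chr1    99   199     1     deletion     <NA>
#> 2:   SVC2   chr1   199   300     3     deletion     <NA>
#> 3:   SVC3   chr1   300   400     2     deletion     <NA>
#> 4:   SVC4   chr1   400   500     1     deletion     <NA>
```

The three variants induce four disjoint regions: the middle stretch
`[199,300)` lies inside all three submissions (count 3 — all studies
concur there), the flanks inside one or two. Comparing a user interval
against the set reports every overlap with its extent and Jaccard index:

```r
overlap_query(svc, data.frame(chrom = "chr1", start = 250, end = 450, name = "my_cnv"))
#>    query_id svc_id overlap_start overlap_end svc_count   jaccard
#> 1:   my_cnv   SVC2           250         300         3 0.1992032
#> 2:   my_cnv   SVC3           300         400         2 0.5000000
#> 3:   my_cnv   SVC4           400         450         1 0.2000000

classify_frequency(svc)
#> [1] "rare"   "common" "rare"   "rare"
```

`write_gvf()` / `read_gvf()` serialize a cluster set losslessly;
`write_bedgraph()` / `write_wig()` export the counts as genome-browser
histogram tracks; `filter_clusters()` subsets by type, chromosome, size
and count; `annotate_clusters()` attaches co-located features from BED or
GFF3 files; `summarize_by_type()` and `distribution_stats()` produce
summary tables; `synth_config()` / `generate_studies()` create
reproducible multi-study test inputs with a known ground truth.

## Command line

A subcommand launcher is installed at
`system.file("scripts", "svc", package = "svcluster")`:

```sh
svc simulate --out-dir studies --seed 1
svc merge    --in studies/nstd001.tsv,studies/nstd002.tsv,studies/nstd003.tsv --out merged.tsv
svc cluster  --in merged.tsv --group-by type --out svc.gvf
svc filter   --in svc.gvf --type "copy number loss" --min-count 100 --out common_loss.gvf
svc tracks   --in common_loss.gvf --format bedgraph --out common_loss.bedgraph
svc compare  --svc svc.gvf --bed my_calls.bed --out hits.tsv
```

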