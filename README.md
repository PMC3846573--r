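# tagdge

Digital gene expression (DGE) tag profiling in R: simulate, filter,
annotate, and compare NlaIII-anchored 21-nt tag libraries from a
two-condition, no-replicate sequencing design.

## The problem

In DGE tag profiling, each cDNA molecule contributes one sequenced tag:
the CATG recognition site of NlaIII closest to the 3' end plus the 17 nt
downstream of it. Tag counts are a direct census of transcript
abundance, so comparing two libraries — a control (CO) and a treated
(DS) condition — reduces to comparing two sets of counts with known
library totals. `tagdge` is for analysts who want that entire pipeline
— QC ladder, virtual digestion, tag-to-gene mapping, saturation,
differential expression, pathway enrichment and qPCR validation — as
tested, scriptable R functions, plus a synthetic-data generator that
makes every stage exercisable without any external download.

## The statistics at the core

**Two-library exact test.** For a gene with $x$ tags among $N_1$
retained CO tags and $y$ among $N_2$ DS tags, the equal-expression
probability is

$$P(y \mid x) = \left(\frac{N_2}{N_1}\right)^{\!y}
 \frac{(x+y)!}{x!\,y!\left(1+\frac{N_2}{N_1}\right)^{x+y+1}}$$

(a negative-binomial law in $y$). Two-sided p-values double the smaller
tail; genes are called differentially expressed at FDR ≤ 0.001
(Benjamini–Hochberg) and $|\log_2(\mathrm{TPM_{DS}/TPM_{CO}})| \ge 1$,
where TPM is tags per million retained tags.

**Pathway enrichment.** With $N$ annotated genes, $n$ DEGs, $M$ pathway
members and $m$ DEG members, enrichment is the hypergeometric upper
tail $P(X \ge m)$, BH-adjusted across pathways; $Q < 0.05$ is called
enriched.

**qPCR validation.** Reference-gene stability by Welch t-test on Ct
values; fold changes by the Livak $2^{-\Delta\Delta C_t}$ method with
SDs propagated in quadrature.

## Worked example

```r
library(tagdge)

cfg <- sim_config(n_genes = 300, n_tags_per_library = 1e5, seed = 2013)
b   <- run_pipeline(cfg)          # simulate -> filter -> map -> test -> enrich

library_summary(b$tables$CO)
#> $retained_pct 95.76    $useless_pct 4.24

b$de_summary[c("n_up", "n_down", "n_tested")]
#> $n_up 11    $n_down 11    $n_tested 300

head(b$de[order(b$de$fdr), c("gene_id","x","y","log2_ratio","p","fdr","call")], 3)
#>       gene_id   x    y log2_ratio          p        fdr call
#> 167 gene_0167 480 3599      2.907  0.000e+00  0.000e+00   up
#> 296 gene_0296 268 2007      2.905  0.000e+00  0.000e+00   up
#> 129 gene_0129 284 1935      2.768 2.645e-301 2.645e-299   up

truth_evaluation(b$de, b$truth)$by_stratum
#>   fold_change n_planted n_called recall
#> 1       0.125         5        5    1.0
#> 2       0.250         5        4    0.8
#> 3       0.500         5        2    0.4
#> 4       2.000         5        1    0.2
#> 5       4.000         5        5    1.0
#> 6       8.000         5        5    1.0
```

Reading the output: of 100,000 simulated CO reads, 95.76% survive the
QC ladder (N-containing, adapter and singleton tags removed). The test
recovers every planted 8-fold and 4-fold change and none of the null
genes (FDP 0); 2-fold changes sit at the calling threshold and are
recovered only partially — planted folds near the $|\log_2| \ge 1$ gate
are further attenuated by library renormalisation (see the methods
vignette). Note the top genes' observed `log2_ratio` ≈ 2.9 for a planted
8-fold change, the same compositional effect.

Individual stages are plain functions: `filter_tags()`,
`build_tag_index()`, `map_tags()`, `saturation_curve()`, `de_test()`,
`enrich_all()`, `qpcr_fold_change()` — see `?tagdge` and the vignette
in `vignettes/tag-profiling-methods.Rmd`.

## Command line

```sh
tagdge simulate --config sim.json --outdir sim/       # or sim.yaml
tagdge filter   --in sim/CO.fastq --out CO.tsv --library CO
tagdge annotate --fasta sim/reference.fa --tags-co CO.tsv --tags-ds DS.tsv --out-prefix ann
tagdge de       --counts ann_counts.tsv --n1 95757 --n2 95700 --out de.tsv
tagdge enrich   --annot kegg.tsv --de de.tsv --q 0.05
tagdge qpcr     --ct ct.csv --ref actin
tagdge run      --outdir results/ --seed 7            # full pipeline
```

The launcher is installed at `exec/tagdge` inside the package
installation; equivalently `Rscript -e 'tagdge::tagdge_cli()' ...`.

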