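---
title: "Methods: DGE tag profiling with tagdge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DGE tag profiling with tagdge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagdge)
```

## The assay and its model

Digital gene expression (DGE) tag profiling measures a transcriptome by
sequencing one short tag per cDNA molecule. Double-stranded cDNA is cut
with NlaIII, which recognises CATG; the kit then releases the 17 nt
immediately downstream of the 3'-most CATG, so each read is a 21-nt tag
(CATG anchor + 17 nt) whose count is proportional to the transcript's
abundance. Two libraries — a control (CO) and a treated (DS) condition,
one library each, no replicates — are compared gene by gene.

`tagdge` implements the full desk-side analysis of such an experiment:

1. **Filtering ladder** (`filter_tags`): raw reads → *clean* tags (drop
   reads containing N, adapter-only artifacts, and reads not anchored by
   CATG) → drop tags seen exactly once → *retained* tags and the
   *unique*-tag census, with a ledger mirroring the standard QC table.
2. **Virtual digestion and annotation** (`build_tag_index`, `map_tags`):
   every CATG-anchored 21-mer on the sense strand of the reference
   transcriptome becomes an index key. A clean tag is assigned to a gene
   when its match set — exact matches if any exist, otherwise all
   Hamming-distance-1 matches over the 17-nt variable region — contains
   exactly one gene; ambiguous tags are discarded. Per-gene counts are
   normalised to TPM (tags per million retained tags).
3. **Saturation** (`saturation_curve`): detected genes as a function of
   subsampled depth, by sampling reads without replacement.
4. **Differential expression** (`de_test`): the exact two-library test
   with BH FDR and a log2-ratio gate.
5. **Enrichment** (`enrich_all`): hypergeometric upper-tail test of DEG
   over-representation per pathway, with BH-adjusted Q values.
6. **qPCR validation** (`reference_stability`, `qpcr_fold_change`):
   Welch t-test of reference-gene stability and Livak 2^-ddCt fold
   changes.

## The two-library exact test

For a gene with `x` tags in a CO library of `N1` retained tags and `y`
tags in a DS library of `N2`, the equal-expression probability is

$$P(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
  \frac{(x+y)!}{x!\,y!\,\left(1 + N_2/N_1\right)^{x+y+1}},$$

which is the negative-binomial law $y \sim \mathrm{NB}(x+1,
N_1/(N_1+N_2))$. The two-sided p-value is $\min(1, 2\min(P(Y\le y),
P(Y\ge y)))$: both up- and down-regulation are reported, and the
standard two-tail doubling is the construction consistent with that.
Genes undetected in both libraries are excluded from testing. A gene is
called differentially expressed when FDR $\le 0.001$ **and**
$|\log_2(\mathrm{TPM_{DS}}/\mathrm{TPM_{CO}})| \ge 1$; the boundary is
implemented as $\le$ (the source material prints both < and $\le$) and
both thresholds are arguments.

### Numerical choices

* The pmf is evaluated in log space with `lgamma`; counts of 10^4-10^5
  stay finite and the relative error against an exact-rational oracle is
  below 10^-12 for all counts up to 200.
* Tail sums are taken over the exact pmf. The lower tail is a sorted
  ascending sum of `exp(log pmf)`. The upper tail uses the complement
  `1 - P(Y <= y-1)` only while that complement is at least 0.5 (no
  cancellation); otherwise — exactly the regime where p-values get small
  and precision matters — it is summed directly upward from `y` with
  Kahan compensation until terms fall below machine noise. A pure
  complement construction could never resolve a 10^-12 upper tail to ten
  significant digits, which the package's acceptance surface requires.
* The TPM floor (default 0.001 TPM) applies only inside the log2 ratio,
  never to the test statistic, so zero counts give finite ratios without
  perturbing p-values.
* `fdr_adjust` is an authored Benjamini-Hochberg step-up (BY optional);
  the reference procedure in the source material is cited but not
  reproduced there, and BH is the field default. It is tested against
  `stats::p.adjust`.

## Pathway enrichment

With `N` annotated background genes, `n` of them DEGs, `M` genes in a
pathway and `m` DEG members, the p-value is the hypergeometric upper
tail $P(X \ge m) = 1 - \sum_{i=0}^{m-1}\binom{M}{i}\binom{N-M}{n-i} /
\binom{N}{n}$. The printed form of this formula elsewhere carries an
upper summation bound that is not a valid probability unless read as
$m-1$; the standard upper-tail form is implemented, evaluated by
log-gamma summation of the upper tail directly (again to avoid
cancellation). Q values are BH across tested pathways; pathways are
flagged `low_power` below 3 background members but never dropped, and a
pathway is *enriched* when Q < 0.05 (strict, as printed). The table is
ordered by DEG count, then p.

## The synthetic-data generator: a stated world

`sim_config()` fixes the world the tests exercise. Defaults, chosen once:

| parameter | default | rationale |
|---|---|---|
| `n_genes` | 2000 | large enough for multiplicity and composition effects, small enough to run in seconds |
| `length_range` | 300-3000 nt | typical mRNA lengths; min >= 25 nt guarantees a tag site fits |
| `n_tags_per_library` | 10^6 | the desk-scale stand-in for the ~4.7-4.8 M tags of a real run |
| `frac_de` | 0.1 | a regulated minority, as in stress-response experiments |
| `fold_change_set` | 2, 4, 8 and reciprocals | spans the calling threshold (2x) to far above it |
| `baseline_meanlog`, `baseline_sdlog` | 0, 1.5 | log-normal abundance; sdlog 1.5 gives the few-orders-of-magnitude spread of bulk expression |
| `digestion_decay` | 0.2 | a non-3'-most CATG site receives 20% the weight of the next site towards the 3' end, emulating incomplete digestion; the real frequency is unquantified, so this is a free parameter, not an inference target |
| `error_rate`, `n_rate` | 10^-3 each | Illumina-like per-base substitution and ambiguity rates |
| `adapter_rate` | 0.005 | a visible but small artifact fraction for the QC stage to remove |

Reads are drawn per-read: gene proportional to expression (baseline for
CO, baseline x fold for DS), site within gene by normalised
`decay^rank`, then corruption (adapter replacement, N calls,
substitutions). Only the sense strand is used — tags originate from
oligo-dT-captured mRNA. Adapter-only reads are the GEX adapter-1
sequence trimmed to 21 nt.

What the generator does **not** model: PCR and GC bias, positional
quality decay, replicate structure (the design has one library per
condition), alternative isoforms sharing tags beyond what random
sequence collisions produce, and partial reference sequences. A green
test therefore establishes correctness of the *analysis* under the
stated sampling model, not robustness to every artifact of a real
sequencer.

## Design decisions that were genuinely open

* **Adapter matching** is an exact prefix match of >= 8 nt; the original
  rule is unstated, and prefix matching mirrors adapter-only ligation
  artifacts.
* **"Low quality"** means N-containing or adapter — no quality-score
  filtering. Additionally, reads not beginning with CATG are dropped at
  the cleaning stage (`require_anchor = TRUE`, liftable): every genuine
  tag carries the enzymatic anchor, and downstream mapping requires it.
* **Mismatch scope**: the single tolerated mismatch lies in the 17-nt
  variable region only; anchor errors produce non-tags, already removed.
* **Exact-match precedence**: a unique exact hit wins even when other
  genes sit at distance 1 — the tolerance is printed, the precedence is
  not, and precedence keeps assignment stable under index growth.
* **Ambiguity is resolved at gene level**: a tag hitting several sites
  of one gene counts once for that gene; only multi-*gene* tags are
  discarded.
* **Saturation** subsamples reads without replacement (sequencing fewer
  reads from the same library), on a default grid of 10 depths averaged
  over 3 replicates; the plateau rule (< 0.1% new genes over the final 2
  grid steps) makes the qualitative "few new genes" operational.
  Detection means >= 1 assigned tag.
* **qPCR**: the cited quantification method is implemented as Livak
  2^-ddCt with 100% efficiency; an efficiency-corrected variant is
  available. Replicates are aggregated as mean Ct before differencing;
  SDs propagate in quadrature and are reported as a fold range.
* **Library size for TPM and the test** is the retained-tag total (the
  "clean tags remaining" after singleton removal) — the quantity the QC
  ladder actually carries forward.

## Degenerate inputs and tie-breaks

Empty read sets yield a zeroed ledger, not an error. An empty index maps
nothing and reports it. Zero-variance qPCR replicates fall back to an
epsilon-guarded t statistic instead of erroring. `m = 0` enrichment is
p = 1 by construction; infeasible hypergeometric tuples error. Depths
beyond the library size error; duplicated depths are collapsed.

## Known limitations

The test is exact only under its Poisson-sampling assumptions; with a
single library per condition, biological variability is invisible and
p-values overstate certainty — a known property of this design, not of
the implementation. Composition effects are real: when up-regulated
genes dominate a library, TPM ratios of other genes shift towards the
opposite direction, and genes with a true 2-fold change can fall under
the log2-ratio gate. The parameter-recovery tests therefore anchor on
strong (8-fold) changes.
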