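# diffunet

Sample-specific gene function assignment by network diffusion, and
condition-associated functional gain/loss analysis.

## The problem

A gene's function is informed by its neighborhood in the protein
interaction network (PIN) — the guilt-by-association principle. When a
disease such as breast cancer rewires that neighborhood (because
interaction partners stop being expressed), a gene's effective function
can change even though its own expression does not. `diffunet`
quantifies this: it infers, for every individual expression sample,
which genes are involved in which functions, and then asks which
functions have significantly *gained* or *lost* genes between two
conditions (e.g. tumor vs. normal) for reasons attributable to network
rewiring rather than to differential expression of the annotated genes
themselves.

It is aimed at computational biologists with (i) a confidence-weighted
PIN edge list, (ii) a gene × sample expression matrix with a condition
label per sample (RPKM or array intensities), (iii) gene sets in GMT
format, and optionally (iv) per-gene mutation/CNV event frequencies.

## The method

For each sample *s*, the PIN is projected onto the transcriptome by
deleting genes expressed below 1 RPKM (arrays use a percentile-matched
threshold), giving the sample network *G\_s* with adjacency *W\_s* and
degree matrix *D\_s*. For a function *f* with annotated gene set
*A\_f*, the seed vector *Y\_s* indicates *A\_f ∩ V\_s*, and the raw
involvement score of every gene is the random-walk-with-restart
diffusion

&nbsp;&nbsp;&nbsp;&nbsp;*F\_s* = α (I − (1−α) *D\_s*^−1/2 *W\_s* *D\_s*^−1/2)^−1 *Y\_s*,&nbsp;&nbsp;&nbsp;&nbsp;α = 0.2,

solved by conjugate gradients (the system is symmetric positive
definite; a sparse Cholesky path batches many seed vectors per sample).
Raw scores are calibrated against nulls obtained by diffusing random
seed sets of matching size: functions are grouped into seed-size bins
(every member within ±10 of the bin median), each bin's null is
estimated from 100 random diffusions and approximated per gene as a
normal distribution, and a gene is *assigned* the function when its
upper-tail p-value is ≤ 0.01.

Between two conditions, each (gene, function) pair gets a Fisher exact
test on assigned/not-assigned counts over the samples where the gene is
expressed, with odds ratio θ = (n00·n11)/(n10·n01); a *gain* call
requires significance and θ ≥ θ\_min (default 10), a *loss* call
θ ≤ 1/θ\_min. Genes whose expressed/unexpressed split is itself
condition-biased (Fisher p ≤ 0.05) are excluded. Per function,
Δ\_f = #gained − #lost over *un-annotated* genes summarizes the net
change; downstream statistics test whether gained/lost gene sets carry
elevated missense/nonsense mutation or deletion-CNV frequencies
(one-sided rank-sum tests), whether those labels are enriched among
gained vs. lost functions (2×2 Fisher), driver-gene AUCs with
label-permutation nulls, and per-sample functional activity profiles
for survival/classification tooling.

A synthetic-cohort simulator generates every input with planted signal
(cohesive modules, bridge genes silenced in one condition so that
un-annotated target genes gain or lose proximity to a module), so the
whole pipeline is testable without external data.

## Worked example

```r
library(diffunet)

co  <- simulate_cohort(simulation_config())        # 2000 genes, 20 functions, 30+30 samples
res <- assign_functions(co$network, co$expression, co$collection, global_seed = 11)
res
#> assignment_result: 95855 assignments | 20 functions x 60 samples (p <= 0.01)

rec <- gain_loss(res, case = "tumor", control = "normal", theta_min = 2)
del <- function_deltas(rec, res)
head(del[, c("function_id", "n_gained", "n_lost", "delta_f",
             "normalized_delta", "annotation_logfc")], 6)
#>   function_id n_gained n_lost delta_f normalized_delta annotation_logfc
#> 1         F04       16      1      15            0.195         -0.00264
#> 2         F05       14      0      14            0.159         -0.00116
#> 3         F03       15      4      11            0.138          0.00427
#> 4         F01       10      0      10            0.110         -0.00075
#> 5         F02       15      5      10            0.147          0.00251
#> 6         F19        2      1       1            0.014          0.00394
```

The five functions with the largest positive Δ\_f are exactly the five
planted-gain modules (F01–F05); the planted losses (F06–F10) occupy the
bottom with Δ\_f near −14, and the no-signal functions sit at |Δ\_f| ≤ 1
with near-zero annotation log fold change — the gains and losses are
network-rewiring effects, not expression effects on the annotated
genes. The mutation/CNV coupling planted by the simulator is recovered
by the labeling stage:

```r
labels <- label_functions(del, co$gene_stats)
head(labels[order(labels$mut_p), ], 5)
#>    function_id direction   mut_p mut_flag   cnv_p cnv_flag
#> 19         F07      loss 5.7e-11        1 5.8e-11        1
#> 5          F02      gain 6.1e-11        1 6.6e-01        0
#> 3          F03      gain 7.1e-11        1 8.5e-01        0
#> 1          F04      gain 1.5e-10        1 1.1e-01        0
#> 16         F09      loss 2.9e-10        1 3.4e-10        1
```

Gained functions show elevated missense frequencies among their gained
genes, lost functions elevated nonsense and deletion-CNV frequencies
among their lost genes — `mut_flag`/`cnv_flag` are the binary labels
used by the 2×2 class-enrichment test (`class_enrichment()`).

A thin command-line wrapper with `simulate`, `project`,
`filter-functions`, `assign`, `gainloss`, `delta` and `assoc`
subcommands lives at `inst/cli/diffunet.R`; it reads a YAML config and
exposes the sample-shuffling control via `--shuffle-seed`.

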