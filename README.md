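# mgogp — module- and Gene-Ontology-based disease gene prioritization

`mgogp` ranks candidate disease genes for researchers who have a tumor/normal
expression study, a gene-set (module) collection, GO annotations, and a list
of known disease genes, and who want a single genome-wide ordering of
candidates that respects the module structure of cellular function. Instead
of scoring genes in isolation or walking a protein-interaction network, it
scores **modules** and **module-specific genes**, then merges the per-module
rankings into one global list.

## The method

Three signals are combined, each robust to sampling noise through repeated
stratified subsampling (`S` rounds, vote thresholds `ω` and `δ`):

**Module importance.** For module *m* with *N* genes and *K = N(N−1)/2*
pairs:

- *Ncr(m)* = Σ DEG(gᵢ)/N — the fraction of consensus differentially
  expressed genes (per round: adjusted p ≤ μ; consensus: passing in ≥ ω of
  rounds);
- *Ecr(m)* = Σ DEE(gᵢ,gₕ)/K — the fraction of consensus differentially
  correlated pairs, tested with Fisher's z-test
  *Z = (arctanh r_N − arctanh r_T)/√(1/(L−3) + 1/(Q−3))* and thresholded on
  a local false discovery rate (fdr ≤ υ), consensus across rounds at δ;
- *info(m)* = (num(d) + 1)/N for its num(d) known disease genes;
- *p(m)* = ((Ncr + Ecr)/2) · info(m).

**Gene importance** inside a module adds three bounded terms: a
differential-expression term (default 1 − padj), the gene's flagged-pair
fraction *CorC(g)* = Σ flagged pairs/(N−1), and *info(g)* — a Sugeno
λ-fuzzy-measure GO similarity to the module's known disease genes (1 if the
gene is itself one). Term densities are normalized information content over
the annotation corpus with descendant-closed term counts; λ solves
(1 + λ) = Π(1 + λ·Smₖ), and two genes' similarity is the average of their
own measures on the shared term intersection.

**Rank fusion.** With *i* genes globally ranked and *m(i,j)* of them from
module *j*, the next position goes to the module maximizing
*e(i,j) = (i+1)·p(m_j) − m(i,j)* (normalized importances as probabilities),
producing a deterministic permutation of all genes that interleaves modules
in proportion to their importance.

Default operating point: `S = 1000`, `ω = 0.9`, `δ = 0.9`, `μ = 0.01`,
`υ = 0.05`.

## Worked example

All inputs can be emulated with the deterministic fixture generator, which
plants differentially expressed genes, condition-specific correlation
blocks, seed genes, and GO-similar "related" genes, and records the ground
truth:

```r
library(mgogp)

mf    <- generate_fixture(fixture_spec(rng_seed = 1), "fixture_dir")
expr  <- read_expression(mf$paths$expression, mf$paths$conditions)
ms    <- read_gmt(mf$paths$modules)
go    <- read_go(mf$paths$annotations, mf$paths$obo)
seeds <- read_seed_genes(mf$paths$seeds)

res <- mgogp_run(expr, ms, go, seeds,
                 de = de_params(S = 100), corr = corr_params(S = 50),
                 seed = 17, out_dir = "run_out")
head(res$ranking, 8)
```

```
  rank  gene          module local_rank gene_score module_score
1    1 G0167 signal_module01          1       2.70       0.1686
2    2 G0263 signal_module03          1       2.70       0.1686
3    3 G0165 signal_module04          1       2.64       0.1364
4    4 G0187 signal_module02          1       2.47       0.0688
5    5 G0324 signal_module01          2       2.70       0.1686
...
```

`gene_score` is the gene's importance (up to 3 = perfect DE + all pairs
differentially correlated + seed-level GO similarity); `module_score` is its
module's importance p(m). The top positions interleave the high-importance
signal modules — each emits its locally top-ranked genes — exactly in
proportion to their scores. The module table shows why:

```r
head(res$module_scores[order(-res$module_scores$p_module), ], 5)
```

```
           module n_genes n_seeds  ncr   ecr info p_module
1 signal_module01      11       2 0.73 0.509 0.27    0.169
3 signal_module03      11       2 0.73 0.509 0.27    0.169
4 signal_module04      12       2 0.67 0.424 0.25    0.136
2 signal_module02      16       2 0.50 0.233 0.19    0.069
5 signal_module05      24       2 0.33 0.098 0.12    0.027
```

Modules carrying the planted correlation blocks and DE genes dominate; all
50 planted DE genes are recovered as consensus DEGs
(`res$report$n_consensus_deg` prints `50`) with no false positives at this
effect size. Pure-noise modules score ~0 and are emitted after the signal
modules.

Real data run the same way — point the readers at your expression TSV
(genes × samples), two-column condition map, GMT collection, GO annotations
(GAF 2.x or gene–term TSV), OBO file and seed list. A thin CLI does the
same from a shell:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "mgogp.R", package = "mgogp"))') \
    run --expr E.tsv --conditions C.tsv --modules M.gmt \
    --go-annot A.tsv --go-obo G.obo --seeds S.txt --out OUT --seed 17
```

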