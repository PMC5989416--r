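---
title: "Module- and GO-based gene prioritization: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Module- and GO-based gene prioritization: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgogp)
```

## The problem and the method

Disease genes rarely act alone: they operate inside functional modules
(pathways, complexes, curated gene sets). `mgogp` prioritizes candidate
disease genes by scoring both the modules and the genes within them, then
fusing the per-module rankings into a single genome-wide ordering. Three
signals drive the scores:

1. **Consensus differential expression (DEG).** On each of `S` rounds a
   stratified random subsample of the samples is drawn (the same fraction of
   each condition, without replacement), a per-round differential-expression
   test is run across all genes, and each gene's adjusted p-value is
   thresholded at `mu`. A gene is a consensus DEG when it passes in at least
   a fraction `omega` of rounds. A module's *Ncr* is the fraction of its
   genes that are consensus DEGs.

2. **Consensus differential correlation (DEE).** For every within-module
   gene pair, Pearson correlations are computed separately in normal and
   tumor samples, variance-stabilized with the Fisher z-transform
   `arctanh(r)`, and compared with the z statistic

   `Z = (arctanh(rN) - arctanh(rT)) / sqrt(1/(L-3) + 1/(Q-3))`,

   approximately standard normal when the population correlations agree.
   Per round, each pair's z is converted into a local false discovery rate
   and thresholded at `upsilon`; a pair is a consensus differential
   correlation when it passes in at least a fraction `delta` of the same
   kind of subsampling rounds. A module's *Ecr* is the flagged fraction of
   its `K = N(N-1)/2` pairs.

3. **Prior knowledge.** A module's basic importance is
   `(number of known disease genes in it + 1) / N`; module importance is
   `p(m) = ((Ncr + Ecr)/2) * info(m)`. A gene's basic importance is its GO
   fuzzy-measure similarity to the known disease genes of its module (1 if
   it is itself a known disease gene, 0 if the module has none), and its
   importance adds three bounded terms: the differential-expression term,
   the gene's flagged-pair fraction *CorC*, and that similarity.

**Rank fusion.** Local rankings (descending gene importance) are merged by a
recursive expectation rule. With `i` genes already ranked globally and
`m(i,j)` of them claimed by module `j`, the next position goes to the module
maximizing `e(i,j) = (i+1) p(m_j) - m(i,j)`, where `p(m_j)` is the module's
normalized importance: the module whose expected share of the top `i+1`
most exceeds what it has already placed. The result is a strict permutation
of all module genes; the recursion interleaves modules in proportion to
their importance while preserving each module's internal order.

## The GO fuzzy-measure similarity

Each gene's annotation terms get a *fuzzy density*: the term's information
content `-ln p(T)` divided by the maximum information content among the
gene's terms, so the most specific term has density 1 and a term annotated
to everything has density 0. The term probability `p(T)` is the fraction of
annotation records in the loaded corpus that hit `T` *or any of its
descendants* (transitive `is_a` closure), which makes `p` monotone
non-increasing down the DAG. Densities are completed into a Sugeno
lambda-measure: `lambda` solves

`(1 + lambda) = prod_k (1 + lambda * Sm_k)`, `lambda > -1`,

and subset measures follow the lambda-rule
`Sm(A) = (prod_{k in A}(1 + lambda Sm_k) - 1) / lambda`. The similarity of
two genes is the average of their own measures evaluated on the shared term
intersection — identical term sets score 1, disjoint sets 0, and the score
weights shared terms by how informative they are *for each gene*.

### Numerical behaviour of the lambda equation

With densities normalized so that the maximum is exactly 1, the only exact
root of the normalization equation is the degenerate `lambda = 0`, because
the factor `(1 + lambda)` cancels. We therefore clamp densities at
`1 - 1e-9` before root finding. The consequence is principled: the solved
root sits next to `-1`, where the lambda-rule converges to the
probabilistic-sum measure `Sm(A) = 1 - prod(1 - Sm_k)` — still a valid,
monotone fuzzy measure with `Sm(full) = 1`, and singleton measures equal to
the densities exactly. Root finding itself uses the log form
`sum(log1p(lambda d)) - log1p(lambda)`, which stays well conditioned for
large positive `lambda` (small densities), bracketed analytically: the root
is negative when densities sum above 1 and positive when below. A short
Newton polish brings residuals of the product form below `1e-12` in
practice; the test suite enforces `1e-10` across random density sets.

Degenerate inputs are explicit: fewer than two positive densities leave
`lambda` undefined by the equation (0 by convention, flagged); genes whose
usable terms all have probability 1 carry no information and fall back to
similarity 0.

## The local false discovery rate

The per-pair fdr uses a deliberately small empirical-null estimator: the
null is `Normal(0, sigma)` with `sigma` matched to the interquartile range
of the z values (central matching), the null proportion is the mass within
one `sigma` relative to its null expectation, the marginal density is a
kernel estimate, and `fdr(z) = min(1, pi0 f0(z) / f(z))`. It requires at
least 200 values; below that the method falls back to Benjamini–Hochberg
q-values on two-sided normal p-values (also selectable directly with
`fdr_method = "bh"`). Because a local fdr needs a distribution to estimate
from, modules with fewer than 200 pairs are pooled into one joint fit per
round when the whole collection is processed with
`consensus_diffcorr_all()`; modules with enough pairs get their own fit.

## Parameters

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `S` | subsampling rounds | 1000 | the published operating point; validation suites use 50–100 where the planted effects are far above the detection boundary |
| `omega` | DEG vote threshold | 0.9 | fraction of rounds a gene must pass |
| `mu` | per-round adjusted-p threshold | 0.01 | BH-adjusted across genes |
| `delta` | DEE vote threshold | 0.9 | fraction of rounds a pair must pass |
| `upsilon` | per-round fdr threshold | 0.05 | local fdr (or BH q-value) |
| `subsample_fraction` | per-condition draw | 0.8 | must leave ≥ 4 samples per condition |
| `padj_mode` | DE addend direction | `complement` | `1 - padj`, so smaller padj ⇒ larger importance; `raw` adds padj itself for literal reproduction |
| `corc_indicator` | pair indicator in *CorC* | `dee` | the consensus indicator; `sc_full` uses the single full-data round |

Two of these defaults resolve genuine ambiguities and deserve their
rationale. *CorC* is defined over the single-round indicator in one place
and the consensus indicator at the module level in another; we default to
the consensus `dee` because it is sampling-robust and internally consistent
with *Ecr*, and expose the literal variant. The gene-importance DE addend,
taken literally, rewards non-significant genes; `complement` restores the
intended direction while `raw` preserves the literal sum.

Other settled choices:

- **Per-round DE test.** A two-sided Welch t-test on `log2(x + 1)` with BH
  adjustment. It is self-contained, fast enough to re-run hundreds of
  times, and pluggable: a precomputed per-gene adjusted-p table (e.g. from
  a negative-binomial DE tool) can replace the full-data test via
  `padj_table`.
- **Scale.** All correlations and tests operate on `log2(x + 1)`:
  variance-stabilizing for expression data, and linear correlation on the
  log scale is what the synthetic generator plants.
- **Sampling scheme.** Stratified subsampling without replacement preserves
  the class balance and is the simplest reading of repeated random
  sampling; DE and correlation stages use the same discipline with
  independent draws from per-stage seed streams derived from one master
  seed.
- **GO relations.** Only `is_a` edges build the DAG; `part_of` is ignored as
  the conservative choice. "Term plus children" in the probability
  definition is implemented as the full descendant closure — one-step
  counting makes `p` non-monotone on deep DAGs, while closure counting is
  the information-content convention. All three GO aspects are pooled.
- **Identifiers.** Exact string match after whitespace trimming; no alias
  resolution. Modules are intersected with the expression universe at load
  time; modules falling below 2 genes are dropped with a count.
- **Fusion details.** Overlapping modules: the first module to emit a gene
  claims it; later modules skip it with both the local pointer and
  `m(i,j)` advanced, keeping the expectation bookkeeping consistent.
  Argmax ties break to the larger probability, larger raw importance, then
  module file order. Zero-importance modules are emitted last, in file
  order. Genes in the expression matrix but in no module are appended
  after all module genes, ordered by `1 - padj`, flagged `unmoduled`, so a
  genome-wide prioritization never silently drops genes.
- **Degeneracy.** Zero-variance genes never vote in the DE stage (p = 1);
  zero-variance pairs get `Z = 0`, `fdr = 1` and never vote; correlations
  at `|r| >= 1` are clamped before the z-transform.
- **Small modules.** The basic importance `(seeds + 1)/N` can exceed 1 for
  tiny seed-dense modules; the literal formula is kept and such modules are
  flagged rather than capped.

## What the synthetic generator emulates — and what it does not

`generate_fixture()` emulates all five inputs with planted ground truth:
log-normal expression with a tumor log2 shift for DE genes; within-block
correlation induced by a shared latent factor per condition
(`sqrt(rho) * factor + sqrt(1 - rho) * noise`, giving expected pairwise
correlation `rho`, checkable analytically); signal modules built around the
blocks with known disease genes and designated related genes; pure-noise
modules; a balanced `is_a` tree whose deep subtrees are shared between each
module's seed and related genes; and a JSON manifest of every planted
label. Output is byte-identical under one seed.

The default conditions — 500 genes, 50+50 samples, 20 modules, 50 DE genes
at fold change 4, five correlation blocks moving from r = 0.9 to r = 0, 10
seed genes — are desk-scale stand-ins for a tumor/normal expression study:
effect sizes are deliberately far above the detection boundary so that
recovery failures indicate implementation defects, not statistical bad
luck. Validation suites run the consensus stages at S = 50–100 rounds and
the calibration checks at 2000 replicates; these sizes are the package's
own choice of a fast, decisive test bed.

What passing these suites does **not** show about real data: the generator
has no library-size or batch artifacts, no count noise (a `counts`-like
regime can be approximated by exponentiating, but no Poisson sampling is
applied), no correlated null structure between modules, no annotation bias
(real GO corpora annotate well-studied genes more densely), and GMT
collections in the wild overlap far more heavily than the generated ones.
Recovery at fold change 4 with 100 samples says nothing about power at
fold change 1.3 with 20.

## Known limitations

- The built-in Welch test on log-transformed values is not a
  negative-binomial count model; for raw RNA-seq counts, import externally
  computed adjusted p-values and keep the subsampling consensus on top.
- The empirical-null local fdr is a simplified estimator; with strong,
  widespread signal (most pairs non-null) its central-matching sigma
  inflates and calls become conservative. The `bh` method is the
  transparent alternative.
- Module importance is a heuristic score, not a calibrated probability;
  the fusion consumes its normalization, so only ratios matter.
- Seeds outside the expression universe still count for the GO similarity
  if listed in a module, but cannot themselves be ranked.

## Reproducing a run

```{r, eval = FALSE}
mf <- generate_fixture(fixture_spec(rng_seed = 1), "fixture_dir")
expr <- read_expression(mf$paths$expression, mf$paths$conditions)
ms <- read_gmt(mf$paths$modules)
go <- read_go(mf$paths$annotations, mf$paths$obo)
seeds <- read_seed_genes(mf$paths$seeds)

res <- mgogp_run(expr, ms, go, seeds,
                 de = de_params(S = 100), corr = corr_params(S = 50),
                 seed = 17, out_dir = "run_out")
head(res$ranking)
```

Every output (`ranking.tsv`, `module_scores.tsv`, `gene_scores.tsv`,
`report.json`) is reproduced bit-identically by re-running with the same
inputs and seed; `report.json` echoes the full parameter set and the
derived per-stage seeds.
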