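# lncsim

Functional similarity between long non-coding RNAs (lncRNAs), computed from
the diseases they are associated with, plus a Laplacian regularized
least-squares predictor for new lncRNA–disease associations and a
leave-one-out cross-validation (LOOCV) harness to evaluate it.

## The science

Functionally related lncRNAs tend to be implicated in similar diseases.
`lncsim` turns that observation into a similarity measure in three steps.

**1. Disease semantic similarity.** Diseases live in a hierarchical
vocabulary (MeSH Category C style tree numbers such as `C04.557.337`). Each
disease *A* induces a DAG of itself plus all ancestors. Two contribution
models weight the nodes of that DAG:

- *Model 1 (decay)*: the disease itself contributes 1, and each step up the
  hierarchy multiplies the contribution by a decay factor Δ (default 0.5),
  taking the maximum over paths: `D_A(t) = max over children t' in DAG(A) of
  Δ·D_A(t')`.
- *Model 2 (frequency)*: a node contributes `−log(count(t)/n)`, where
  `count(t)` is how many of the *n* studied diseases contain *t* in their
  DAG — rare, specific terms count more, and terms shared by every disease
  count zero.

Either way, the similarity of diseases *A* and *B* is the contribution mass
of the shared DAG nodes relative to the total:

```
SS(A, B) = Σ_{t ∈ DAG(A)∩DAG(B)} (D_A(t) + D_B(t)) / (DV(A) + DV(B)),
DV(A) = Σ_{t ∈ DAG(A)} D_A(t)
```

**2. lncRNA functional similarity.** Let G(u) be the disease group of lncRNA
*u*. With `S(d, G) = max_{d'∈G} SS(d, d')` the best match of a disease
against a group, the functional similarity is the best-match average

```
FS(u, v) = [ Σ_{d∈G(u)} S(d, G(v)) + Σ_{d∈G(v)} S(d, G(u)) ] / (|G(u)| + |G(v)|)
```

Thresholding FS (default cutoff 0.3) gives a functional similarity network.

**3. Association prediction.** Gaussian interaction-profile kernels over the
known association matrix provide similarity where functional similarity is
undefined; an optional Spearman-based expression similarity can be averaged
in. In each space (lncRNA and disease) the predictor solves the Laplacian
regularized least-squares problem `min_F ||Y − F||² + η·tr(FᵀLF)` with the
normalized graph Laplacian L, in closed form, and combines the two spaces as
`w·F_l + (1−w)·F_dᵀ` (defaults η = 1, w = 0.5). LOOCV leaves out each known
association in turn — recomputing kernels and the test lncRNA's disease group
without it — and reports an AUC that is exactly the Mann–Whitney concordance
of held-out pairs against unknown pairs, averaged over folds.

See the vignette (`vignettes/lncrna-functional-similarity.Rmd`) for full
definitions, edge-case conventions, and the synthetic data generator.

## Worked example

A four-term toy vocabulary: root `R` (code `C`) with children `A` (`C.1`) and
`B` (`C.2`), and `C` (`C.1.1`) below `A`.

```r
library(lncsim)

onto <- disease_ontology(data.frame(
  term_id = c("R", "A", "B", "C"),
  name = c("root", "alpha", "beta", "gamma"),
  tree_numbers = c("C", "C.1", "C.2", "C.1.1")))

S1 <- disease_similarity(onto, c("R", "A", "B", "C"), model = 1, delta = 0.5)
round(S1, 4)
#>        R      A      B      C
#> R 1.0000 0.6000 0.6000 0.4545
#> A 0.6000 1.0000 0.3333 0.6923
#> B 0.6000 0.3333 1.0000 0.2308
#> C 0.4545 0.6923 0.2308 1.0000
```

`S1["C", "A"]` is `2.25/3.25 ≈ 0.6923` by hand: DAG(C) = {C, A, R} with
contributions 1, 0.5, 0.25; DAG(A) = {A, R} with 1, 0.5; shared nodes {A, R}
carry (0.5 + 1) + (0.25 + 0.5) = 2.25 of the total 1.75 + 1.5 = 3.25.

A lncRNA associated with {C} against one associated with {A, B}:

```r
functional_similarity("C", c("A", "B"), S1)
#> [1] 0.5384615     #  (2·(2.25/3.25) + 0.75/3.25) / 3
```

A full study on simulated data with planted cluster structure (the package
defaults: a depth-3 ternary hierarchy of 40 terms whose cluster subtrees
cover 16 diseases, 40 lncRNAs in 4 clusters, 3 associations each, 5% noise,
seed 1):

```r
cfg   <- sim_config()
onto  <- simulate_ontology(cfg)
assoc <- simulate_associations(onto, cfg)
SS1   <- disease_similarity(onto, assoc$disease_ids, model = 1)
FS    <- functional_similarity_matrix(assoc, SS1)
round(FS[1:4, 1:4], 4)
#>        lnc001 lnc002 lnc003 lnc004
#> lnc001 1.0000 0.9080 0.7931 1.0000
#> lnc002 0.9080 1.0000 0.7931 0.9080
#> lnc003 0.7931 0.7931 1.0000 0.7931
#> lnc004 1.0000 0.9080 0.7931 1.0000

net <- build_network(FS, cutoff = 0.3)
nrow(net$edges)
#> [1] 355

loocv(assoc, disease_ss = SS1)
#> loocv_result: 134 folds, AUC = 0.8468
```

The same run without the semantic similarity (interaction-profile kernel
only) gives AUC 0.8194, and a random-score control gives 0.4762 ± 0.0254 —
the semantic similarity carries real signal. In the perfectly separable limit
(no noise, cluster subtrees exactly the size of each lncRNA's disease group)
the AUC is exactly 1.

## Command line

```sh
Rscript inst/cli/lncsim.R simulate --out results --seed 1
Rscript inst/cli/lncsim.R loocv --ontology results/ontology.tsv \
    --associations results/associations.tsv --out results --seed 1
```

Subcommands: `simulate`, `disease-sim`, `lncrna-sim`, `network`, `predict`,
`loocv`. Options can also come from a YAML file via `--config` (explicit
flags win). Every step writes a JSON manifest with its parameters and input
checksums; identical configurations produce byte-identical outputs.

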