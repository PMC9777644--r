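# enmesim

Simulation of epistasis models **without marginal effects** (eNME models)
and of case-control SNP datasets that carry them.

## The problem

Epistasis detection methods — tools that search genome-wide association
data for interacting SNP pairs, triples, and beyond — are benchmarked on
simulated case-control data in which a known interaction is embedded.
The hardest interactions to simulate are those *without marginal
effects*: every single SNP's marginal penetrance equals the population
prevalence, so no single-locus scan can see the signal, yet the K-locus
genotype combination has a strong effect.  Such models have no closed
functional form; their 3^K penetrance values P(D|g_i) must be solved for
directly, subject to

- **prevalence**:  P(D) = Σ_i P(D|g_i) P(g_i),
- **heritability**:  h² = Σ_i (P(D|g_i) − P(D))² P(g_i) / (P(D)(1 − P(D))),
- **no marginal effects**:  P(D | SNP k = j) = P(D) for every SNP k and
  genotype j,

with the joint cell frequencies P(g_i) given by Hardy-Weinberg genotype
frequencies ((1−p)², 2p(1−p), p²) at each SNP's minor allele frequency,
multiplied across SNPs (linkage equilibrium).

`enmesim` treats the penetrance table itself as the unknown of an
under-determined system of equations:

- **prevalence-only mode** — the 3K marginal constraints plus the
  prevalence constraint are *linear* in the 3^K unknowns (`A x = b`,
  with 3K + 1 rows, rank-deficient).  The unique minimum 2-norm solution
  is obtained through a complete orthogonal decomposition
  `A P = Q [R11 0; 0 0] Zᵀ`, and a non-degenerate table inside the
  [0, 1] box is drawn by hit-and-run sampling along null-space
  directions, which never leaves the constraint manifold.
- **joint mode** — adding the heritability constraint makes the system
  nonlinear (one quadratic equation).  It is solved by Newton iteration
  from the zero vector, each step taking the minimum-norm least-squares
  solution of the wide linearized system `J Δx = −F`, with random
  restarts when the iteration leaves the [0, 1] box.

Simulated genotypes are generated by **column-segment resampling** of a
reference panel: a window of consecutive SNPs is cut at random column
breakpoints, and each output sample splices together, segment by
segment, the genotypes of randomly chosen reference samples.  This
preserves minor allele frequencies and local linkage disequilibrium.
The solved model is embedded by labeling each sample a **case with
probability equal to the penetrance** of its genotype combination at K
chosen loci, until exact case/control quotas are met.

## Worked example

```r
library(enmesim)

## 1. solve a two-locus eNME model at MAFs (0.2, 0.3), prevalence 0.1
spec <- modelSpec(mafs = c(0.2, 0.3), prevalence = 0.1)
res  <- solvePrevalenceModel(spec, seed = 42)
res
#> SolverResult: order-2 table; residual 8.21e-17, heritability 0.0359
#>   attempts 1, iterations 0, seed 42
solverTable(res)
#> PenetranceTable: order 2 (9 cells)
#>   MAFs: 0.2, 0.3
#>   prevalence 0.1000, heritability 0.0359
#>     SNP2
#> SNP1     BB     Bb     bb
#>   AA 0.1344 0.0560 0.1184
#>   Aa 0.0311 0.1946 0.0338
#>   aa 0.1019 0.0476 0.3342
validateTable(solverTable(res), spec)$maxMarginalDev
#> [1] 6.938894e-17
```

Every marginal penetrance equals the prevalence 0.1 to machine
precision: a single-locus test sees nothing, while e.g. the (aa, bb)
cell carries penetrance 0.33.  The residual is the constraint violation
`‖Ax − b‖`; `heritability` is the spread the sampled table happens to
achieve (constrain it exactly with
`modelSpec(..., heritability = ...)` and `solveJointModel()`).

```r
## 2. a reference panel and a resampled simulated panel
ref <- synthReferencePanel(2000, 500, ldRho = 0.4, labelRate = 0.3, seed = 42)
sim <- simulatePanel(ref, nSnps = 300, nOut = 2000, seed = 43)
sim
#> GenotypePanel: 2000 samples x 300 SNPs (unlabeled)

## 3. embed the model at MAF-matched loci, 1000 cases + 1000 controls
tab  <- solverTable(res)
set.seed(44)
loci <- selectModelLoci(sim, tab)       # columns with MAF near 0.2 / 0.3
dat  <- generateCaseControl(sim, makeSegments(300, 15),
                            embeddingPlan(loci, tab, 1000, 1000), seed = 45)
dat
#> GenotypePanel: 2000 samples x 300 SNPs (1000 cases / 1000 controls)
```

`mafConcordance(sim, ref_window)` reports, per SNP, the reference MAF,
the simulated MAF and a 95% confidence band;
`empiricalPenetrance(dat, loci)` tabulates per-cell case fractions
(note these are distorted in the final dataset by the imposed 1:1
case:control ratio; penetrance is recovered on the pre-truncation
stream — see the vignette).

A command-line front end with subcommands `solve`, `synth-panel`,
`simulate`, `embed` and `validate` is installed at
`system.file("scripts", "enmesim", package = "enmesim")`; run it with
`Rscript` and `--help` for usage.

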