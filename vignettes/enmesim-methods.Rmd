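---
title: "Solving and embedding epistasis models without marginal effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Solving and embedding epistasis models without marginal effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enmesim)
```

## The model

A K-order epistasis model is a penetrance table: a map from each of the
3^K multi-locus genotypes $g_i$ to the disease probability
$x_i = P(D \mid g_i)$.  Under Hardy-Weinberg equilibrium each SNP $k$
with minor allele frequency $p_k$ has genotype frequencies
$q_k = ((1-p_k)^2,\; 2p_k(1-p_k),\; p_k^2)$, and under linkage
equilibrium between the model SNPs the joint cell frequency is the
product $P(g_i) = \prod_k q_k[d_k(i)]$, where $d_k(i) \in \{0,1,2\}$ is
SNP $k$'s genotype digit in cell $i$.  The model's population prevalence
and heritability are

$$P(D) = \sum_i x_i P(g_i), \qquad
  h^2 = \frac{\sum_i (x_i - P(D))^2 P(g_i)}{P(D)(1 - P(D))}.$$

A model has **no marginal effects** (eNME) when every single-SNP
marginal penetrance — the disease probability given one SNP's genotype,
averaging over the others — equals the prevalence.  These are the
models single-locus association scans cannot detect, which makes them
the interesting test bed for interaction-detection methods, and the
awkward ones to construct: the no-marginal-effect condition admits no
parametric family, so the $3^K$ values must be solved for.

Cells are stored in a fixed base-3 order with SNP 1's digit varying
fastest (`cellIndex()`), which for two loci is the usual left-to-right,
top-to-bottom reading of the 3×3 table.  Nothing in the mathematics
prefers one order; fixing one makes tables, files and loci assignments
unambiguous for any K.  Indices are 1-based, as everywhere in R; digits
keep the 0/1/2 copies-of-rare-allele coding.

## Prevalence-only solving (linear mode)

The 3K marginal constraints and the prevalence constraint are linear in
$x$: `buildLinearSystem()` assembles $A x = b$ with $m = 3K+1$ rows and
$n = 3^K$ columns.  Rows are written in *conditional* form — the
marginal row for (SNP $k$, genotype $j$) carries, on each cell with
$d_k(i) = j$, the conditional frequency of that cell given the genotype
(the product of the other SNPs' genotype frequencies) — so every row
sums to 1 and every entry of $b$ is the target prevalence.  The
equivalent joint form would scale each row by the fixed genotype's
frequency; the conditional form is used because it is exactly the
arithmetic of a worked marginal-penetrance computation, weight by
weight.

$A$ is structurally rank-deficient (the prevalence row lies in the span
of each SNP's three marginal rows), so the solve must be
rank-revealing.  `codFactor()` builds a complete orthogonal
decomposition $AP = Q \left[\begin{smallmatrix} T & 0 \\ 0 & 0
\end{smallmatrix}\right] Z^\top$ from two LAPACK QR factorizations: a
column-pivoted QR of $A$ reveals the numerical rank $r$, and a second QR
of the transposed leading $r$ rows compresses them to an $r \times r$
triangular block.  With this construction $T$ comes out
lower-triangular; the factorization is otherwise the standard one, and
all of its contracts (orthogonality, reconstruction, minimum-norm
solves, null-space basis) are independent of which triangle is used.
Diagonal entries below $\max(m,n)\,\varepsilon$ relative to the largest
are treated as zero; tests confirm the rank agrees with an independent
SVD for all the system shapes used.

The minimum 2-norm solution is unique, but it is near the *constant*
table $P(D)\cdot\mathbf 1$ — which always solves the system and has
zero heritability, i.e. no model at all.  The solution set is the
affine space $x_{\min} + \mathrm{null}(A)$ intersected with the
$[0,1]^n$ box: a polytope with, generically, $3^K - (2K+1)$ free
dimensions.  `sampleFeasibleTable()` draws a non-degenerate table by
**hit-and-run**: from a feasible point, draw a random null-space
direction $u = Nz$ ($z$ standard normal, normalized), compute the exact
feasible step interval $[t_{lo}, t_{hi}]$ that keeps all coordinates in
$[0,1]$, jump to a uniform point of it, and repeat (default 20 mixing
steps).  Every iterate satisfies $Ax = b$ to rounding error, so the
marginal-penetrance contract is never at risk; the walk only explores
the polytope.  A final table whose heritability falls below
`minHeritability` (default 1e-3 — below that the model is effectively
null) triggers a fresh walk, up to `maxAttempts` (default 1000)
restarts.

## Joint solving (prevalence + heritability)

The heritability constraint is quadratic.  It is used in
cleared-denominator form,
$\sum_i (x_i - P)^2 P(g_i) - h^2 P(1-P) = 0$ with $P$ the *target*
prevalence (held fixed by its own linear row), which keeps the residual
polynomial and the Jacobian linear in $x$: rows $1..3K{+}1$ of $J$ are
the constant matrix $A$, and the heritability row is
$2(x_i - P)P(g_i)$.  Newton's update solves the wide linearized system
$J\,\Delta x = -F$; since $J$ has $3K+2$ rows but $3^K$ columns, the
step is itself under-determined and the minimum-norm least-squares
solution (through the same decomposition machinery) plays the role of
the pseudo-inverse.  Least-squares semantics matter at the very first
step: at a constant iterate the heritability row is parallel to the
prevalence row with an incompatible right-hand side, so the exact
linearized system is inconsistent; the least-squares step still reduces
what can be reduced and the next iterate has full row rank.

Convergence is declared at $\|F\|_\infty \le$ 1e-8; divergence after
five consecutive residual increases; at most 100 iterations per
attempt.  Box constraints are *not* enforced during the iteration —
projecting would destroy the exactness of the steps — and an out-of-box
limit point simply triggers a restart.

The restart schedule is where the design was genuinely open.  The first
attempt starts from the zero vector.  Newton converges from almost
anywhere on this system (one quadratic equation on an affine space),
but its limit point inherits much of the start's dispersion around $P$,
while the box demands dispersion of roughly
$\sigma^\star = \sqrt{h^2 P(1-P)}$.  Plain uniform draws on $(0,1)^n$
(dispersion ≈ 0.29) therefore essentially never yield in-box solutions
at realistic prevalences — measured empirically, they fail for every
recommended parameter combination with $P \le 0.2$.  Attempts 2–10
instead draw uniformly on $[P - \sqrt3\,\sigma^\star,\,
P + \sqrt3\,\sigma^\star] \cap [0,1]$, matching the target dispersion.
When even those all converge outside the box — typical when
$\sigma^\star$ is comparable to $P$, so solutions hug the zero boundary
— later restarts are seeded *on the solution set itself*: a random
greedy walk on the linear manifold increases heritability by jumping to
whichever end of each feasible null-space step interval raises it most,
until it exceeds the target; shrinking the resulting table toward the
constant table by $t = \sqrt{h^2/h^2_{\text{reached}}}$ then scales its
heritability by exactly $t^2$ (deviations scale linearly and the linear
constraints are affine), landing the start numerically on the solution
set for Newton to polish.  Such attempts typically converge in zero or
one iteration, which the diagnostics report honestly
(`iterations` in `SolverResult`).

Not every (prevalence, heritability) pair is attainable: the maximum
heritability on the constraint polytope depends on the MAFs and shrinks
with the prevalence (e.g. at MAFs (0.1, 0.2) and $P = 0.1$ it is about
0.05).  A clean infeasibility error after the restart budget (default
50) is then the correct outcome, and the error message points to the
parameter ranges with reliable solves: prevalence and heritability up
to 0.3 for orders 2–3, up to 0.2 for order 4, MAFs in $[0.05, 0.3]$.
`modelSpec()` warns — never errors — outside those ranges.

## Resampling and embedding

`simulatePanel()` chains the four resampling steps: a random window of
consecutive SNPs at the requested width; removal of case-labeled rows
(so whatever disease process produced the reference panel does not leak
into the simulation); a random contiguous column segmentation; and
splicing, where each output sample copies each segment verbatim from an
independently, uniformly chosen source row.  Within a segment the
output reproduces the source's joint genotype distribution — MAFs and
local LD included — while across boundaries genotypes mix.

Three details the procedure leaves open are fixed as follows.  The
segment count (not a length distribution) is the user's knob, default
one segment per 20 SNPs, realized as uniformly random distinct
breakpoints, so segment lengths are random as intended.  One
segmentation is drawn per generated dataset, not per output row — the
partition is a property of the dataset's provenance, and per-row
re-segmentation would only blur the LD-preservation guarantee that
within-segment structure is copied intact.  Source rows are drawn with
replacement, independently across output rows and segments; without
replacement would tie output rows together for no modeling gain.

`generateCaseControl()` embeds a solved table at K loci by labeling
each streamed sample a case with probability equal to the penetrance of
its genotype cell, accumulating until the requested case and control
counts are both met, then shuffling.  Loci are chosen by MAF matching
(`selectModelLoci()`, tolerance 0.05) because the model's statistics
hold only at the MAFs it was solved under; a useful consequence of the
no-marginal-effect property is that the embedded prevalence is
*first-order insensitive* to small MAF mismatch, since the gradient of
the prevalence with respect to each locus's MAF vanishes at the solved
point.  Penetrance recovery is defined on the *pre-truncation* stream:
fixing the case:control ratio reweights the conditional case fractions
of the final dataset (a 1:1 dataset embedded from a prevalence-0.1
model over-represents cases by design), so `empiricalPenetrance()` on
the final dataset estimates the ratio-distorted quantity, and tests of
label fidelity use the raw stream.

## The synthetic reference generator

`synthReferencePanel()` stands in for a real SNP panel: two haplotypes
per sample, generated left to right, each allele copying its left
neighbor with probability `ldRho` and otherwise drawn fresh as
Bernoulli(MAF).  With `ldRho = 0` every SNP is an exact
Hardy-Weinberg draw; positive `ldRho` produces geometrically decaying
adjacent-SNP correlation, the one feature of real LD the resampler's
guarantees depend on.  Labels are independent Bernoulli, which is the
*null* reference: real case-control panels carry genotype-label
structure, which is precisely what `dropCases()` is there to remove.
What the generator deliberately does not emulate: haplotype-block
boundaries, recombination hotspots, allele-frequency spectra of real
cohorts, population stratification.  Tests passing on these panels
therefore certify the mechanics (provenance, frequency preservation,
label fidelity) — not that simulated data are indistinguishable from
any particular cohort.

When validating MAF concordance, the simulated panel should be compared
against the panel it was actually resampled from (after the window and
case removal): comparing against a larger labeled superset adds
sampling noise the per-SNP confidence band does not model and deflates
the coverage below its nominal 95%.  The band itself is the normal
approximation $\hat p \pm 1.96\sqrt{\hat p(1-\hat p)/(2n)}$ on $2n$
alleles, clipped to $[0, 0.5]$; MAFs are folded at 0.5 since the minor
allele may flip between panels.

## Numerical choices and problem sizes

- Rank threshold: pivoted-QR diagonal entries below
  $\max(m,n)\,\varepsilon$ of the largest are zero.
- Linear-solve consistency tolerance 1e-8; Newton convergence 1e-8 in
  the max-norm; solver contract verified at 1e-6 in `validateTable()`.
- Benchmark-table checks use 1e-3 (5e-4 for marginals/prevalence):
  the published table is printed to four decimals, and whether the
  underlying model is exact at higher precision is unknowable from the
  printed values.
- Degenerate inputs: heritability of a table with prevalence exactly 0
  or 1 is an error (the variance ratio is 0/0), not 0; a MAF of 0 is
  accepted in frequency arithmetic (monomorphic locus) but rejected in
  a `ModelSpec`; a heritability target of 0 is accepted and returns the
  null model.
- Test suite problem sizes: solver contracts at orders 2–4 (20 random
  specs each), resampling provenance on a 2000×1000 panel with 50
  segments and 1000 output rows, label fidelity on a 5×10⁴-sample
  stream, pipeline runs at a few hundred samples.  These sizes hold
  every stochastic check's 3σ bound comfortably while keeping the whole
  suite under a minute of compute.

## Known limitations

- Model SNPs are assumed in linkage equilibrium with each other; tables
  embedded at loci that are themselves in strong LD will not reproduce
  the solved statistics.
- The hit-and-run draw is a polytope explorer, not a uniform sampler at
  20 mixing steps; tables are reproducible under a seed but their
  distribution over the polytope is not characterized.
- Joint-mode feasibility is decided empirically by the restart budget;
  a failure is strong evidence, not proof, that the target pair is
  unattainable.
- Binary phenotypes only, and no environmental interactions.
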