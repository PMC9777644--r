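Package: enmesim
Title: Simulation of Epistasis Models Without Marginal Effects and
    Case-Control SNP Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Solves penetrance tables of K-order epistasis models without
    marginal effects (eNME models) under prevalence-only or joint
    prevalence-and-heritability constraints, by treating the table as the
    unknown of an under-determined system of equations: a complete
    orthogonal decomposition minimum-norm solve with null-space sampling
    in the linear case, and Newton iteration with minimum-norm steps in
    the nonlinear case.  Generates simulated case-control SNP genotype
    panels by column-segment resampling of a reference panel, which
    preserves minor allele frequencies and local linkage disequilibrium,
    and embeds a solved model by labelling each sample as a case with
    probability equal to the penetrance of its genotype combination.
    Includes diagnostics (per-SNP minor allele frequency concordance with
    confidence bands, empirical penetrance recovery) and a synthetic
    reference-panel generator so the full pipeline runs without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
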