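Package: oncomodules
Title: Driver-Attributed Expression Modules and Survival-Stratified Tumour Subgroups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Turns tumour-specific assignments of somatic genome alterations
    (SGAs) to differentially expressed genes (DEGs) into co-regulation DEG
    modules and survival-stratified patient subgroups. Implements posterior
    and recurrence filtering of causal assignments, construction of a
    weighted DEG co-regulation network with per-edge provenance, spectral
    consensus clustering of the network with Gaussian-kernel affinities and
    stability-based selection of the module count, dominant-driver
    attribution and hypergeometric gene-set overlap per module, module-level
    patient features, PAM (k-medoids) consensus clustering of patients with
    consensus-CDF-area model selection, and Kaplan-Meier, log-rank, Cox
    proportional-hazards and concordance-index evaluation of the resulting
    subgroups. A seedable synthetic-cohort generator with planted pathway
    structure supports end-to-end testing without access to restricted
    cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    jsonlite,
    stats,
    survival,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
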