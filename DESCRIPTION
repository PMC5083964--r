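Package: mobpso
Title: Multi-Objective Binary Particle Swarm Feature Selection for Gene
    Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Selects small, highly discriminative gene subsets from
    two-class (or multi-class) expression matrices. Expression values are
    normalized per gene, discretized to a ternary low/high/don't-care
    table via grouped-frequency quartile thresholds, and reduced to a
    rough-set style distinction table over inter-class sample pairs. A
    multi-objective binary particle swarm optimizer with Pareto
    non-dominated sorting and elitist 50 percent survival then searches
    for minimal covering subsets (reducts), trading subset cardinality
    against discernibility. Selected subsets are validated by stratified
    k-fold cross-validation with a native k-nearest-neighbour classifier
    and summarized by per-array z-scores. Includes a synthetic two-class
    expression generator with planted minimal covers, an exhaustive
    Pareto oracle for small instances, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    class,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
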