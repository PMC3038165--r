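Package: hoxsurvey
Title: Hox Gene Inventory Surveys by Degenerate PCR and Dollo Parsimony
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing Hox gene inventories of sarcopterygian
    (lobe-finned fish and tetrapod) lineages from degenerate-primer PCR clone
    surveys. Models IUPAC-degenerate primers and performs in-silico PCR against
    genomic templates with the tiered escalation strategy used in comprehensive
    homeobox surveys (general, paralogue-group-specific and member-specific
    primers); collapses sequenced clones to unique fragments and separates
    allelic variants (synonymous, multi-clone) from PCR or sequencing errors
    (non-synonymous singletons); assigns validated homeobox fragments to exact
    Hox gene members by neighbor-joining over Kimura two-parameter nucleotide
    and maximum-likelihood JTT protein distances with nonparametric bootstrap
    support; and reconstructs gene presence/absence evolution on a species tree
    by Dollo parsimony, including step-count comparison of competing topologies
    such as the four hypotheses for the phylogenetic position of turtles. A
    fully seeded synthetic-data generator produces reference panels, genomic
    templates and clone libraries with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
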