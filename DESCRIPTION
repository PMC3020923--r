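Package: ontobench
Title: Corpus-Grounded Benchmarking of Ontologies and Thesauri
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures how well an ontology represents the discourse of its
    domain. Concept usage frequencies and concept-pair association
    probabilities are estimated from a reference corpus by dictionary-based
    concept recognition and unit-level co-occurrence; synonym substitution
    probabilities are estimated by probabilistic conditioning on shared
    part-of-speech-filtered context windows. On top of these estimates the
    package computes the Breadth and Depth metric family at three granularity
    levels, constructs the complete ontology of a corpus and the fittest
    ontology of fixed size, and quantifies Depth Loss and its normalized
    variants, alongside classical precision/recall baselines. A synthetic
    corpus and ontology generator with known ground truth supports testing
    and calibration without licensed resources.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
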