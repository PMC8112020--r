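Package: spliceflow
Title: Exact Transcript Quantification over Splice Graphs via Prefix-Graph
    Network Flows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Graph quantification for RNA-seq: instead of estimating the
    abundances of a fixed list of transcripts, the generative model of
    fragment sequencing is reparameterized onto phasing-path abundances,
    which are encoded as network flows on a prefix graph -- an unrolling of
    the splice graph derived from an Aho-Corasick automaton over the
    observed phasing paths.  Inference of the flow by EM with a
    column-generation M-step is provably equivalent to running a standard
    transcript quantifier with every compatible source-sink path of the
    splice graph enumerated as a candidate transcript, while handling
    variable fragment lengths and an affinity (bias) interface.  Includes
    flow decomposition, percent-spliced-in (PSI) computation, a synthetic
    data generator, and a brute-force transcript-enumeration oracle for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
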