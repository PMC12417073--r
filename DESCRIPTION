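Package: retap
Title: Reaction Target Prioritization for Metabolic Engineering from
    Genome-Scale Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ranks every reaction in a constraint-based genome-scale
    metabolic model by how strongly its feasible flux range must shift
    between low-production and high-production states of a desired
    product. The method scans enforced production levels from a small
    fraction up to the maximum theoretical yield, runs flux variability
    analysis at each level, summarizes the low and high production states
    of each reaction as gaussian distributions, and scores reactions by
    the inverse of the overlap index between the two gaussians. Ranked
    reactions are translated into overexpression, downregulation, or
    knockout gene targets through their gene-protein-reaction rules.
    Reads SBML Level 3 FBC v2 and BiGG-style JSON models, and generates
    small toy models with planted, analytically known targets for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    pracma,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
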