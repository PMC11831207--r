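Package: drivebalance
Title: Deterministic Modeling of Self-Limiting Genetic Biocontrol by
    Drive-Selection Balance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic population-genetics and demographic simulator for
    self-limiting genetic biocontrol of pest populations. Implements a
    protected dominant-negative editor (PDNE): an autosomal toxin-antidote
    construct whose germline editor converts wild-type alleles into dominant
    lethal edits while the construct haplotype is protected in cis, so that
    preferential transmission balances selection against its recessive
    lethality. Provides the closed-form single-locus fitness and load model,
    a sex-structured discrete-generation life cycle with juvenile
    density-dependent (Beverton-Holt) mortality, comparator release
    strategies (SIT, RIDL, fsRIDL, X-shredder, Y-linked editor,
    fs-RIDL-drive), homing and cleave-and-rescue booster constructs,
    robustness parameters (editing rate, edit cost and dominance,
    loss-of-function mutation), bisection search for minimal release rates,
    and a small command-line interface over YAML run configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
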