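Package: vsdscout
Title: Discovery of Voltage-Sensing Domains and Design of Chimeric
    Voltage Indicators
Version: 1.0.0
Authors@R:
    person("Dana", "Seo", email = "dseo@example.org", role = c("aut", "cre"))
Description: Scans protein sequences for the conserved S2 transmembrane
    anchor motif of voltage-sensing domains (VSDs), predicts candidate
    transmembrane helices from Kyte-Doolittle hydropathy, assembles
    four-helix S1-S4 architecture calls, classifies candidates into
    voltage-sensor families (Hv, VSP) by the basic-residue periodicity of
    the S4 helix, clusters candidates with pairwise global alignment and
    neighbor joining, and designs chimeric genetically encoded voltage
    indicators (GEVIs) by swapping a candidate VSD into a scaffold
    sensor. Ships a deterministic generator of synthetic proteins with
    planted VSD architectures so the whole pipeline is testable without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
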