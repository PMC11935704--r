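Package: sentinelchd
Title: Long-Term Outcome Metrics for Sentinel Congenital Heart Diseases from
    Procedure Registries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives long-term outcome metrics (survival and cumulative
    incidence of reintervention at ages 1, 5 and 10 years) for nine sentinel
    congenital heart disease diagnoses from procedure-level registry records.
    Provides clinical-code phenotyping of sentinel diagnoses and subgroups,
    expected treatment-pathway classification (prepathway, staged palliation,
    reparative surgery), reintervention adjudication under the one-occurrence
    rule, data-quality flagging of implausible procedure sequences, life-status
    ascertainment with source precedence, Kaplan-Meier survival and
    Aalen-Johansen competing-risks estimation, and a seeded synthetic registry
    generator calibrated so the whole pipeline is testable without access to
    controlled national audit data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    cmprsk,
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
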