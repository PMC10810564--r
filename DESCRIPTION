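Package: brainco2
Title: Model-Assisted Analysis of Cerebral Blood Flow and Mitochondrial
    Metabolism During Hypercapnia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward dynamic-systems modelling of the cerebral circulation and
    mitochondrial oxidative metabolism during CO2 challenges, in the
    BrainSignals tradition. Couples a lumped cerebrovascular compartment
    (pressure autoregulation and CO2 vasoreactivity acting on vessel radius)
    to a reduced electron-transport-chain model (NAD/NADH pool, cytochrome
    oxidase CuA and haem a3 redox states, mitochondrial oxygen and proton
    motive force), producing the signals measured non-invasively in adult
    hypercapnia studies: cerebral blood flow, tissue oxygenation index (TOI)
    and the cytochrome-c-oxidase redox change (oxCCO). Two candidate pathways
    by which CO2 may depress oxygen metabolism, reduced substrate supply and
    reduced ATP demand, are implemented as gain parameters on filtered CO2
    stimuli. A modified-Fick estimator of relative CMRO2 change, a seeded
    real-coded genetic-algorithm fitting pipeline with repeat statistics, a
    synthetic hypercapnia-challenge generator, and plotting/reporting tools
    complete the analysis workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
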