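Package: antair
Title: Activity Regulation in Ant Colonies via Social and Reverse Social Contagion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Models collective activity regulation in social insect colonies with a
    three-state compartmental model in which inactive individuals are activated by
    contact with active ones (social contagion) and active individuals are driven
    into a refractory rest state by contact with other active ones (reverse social
    contagion). Provides closed-form equilibria, local (Routh-Hurwitz) and global
    (Lyapunov) stability diagnostics, Kleiber-like scaling analysis of steady-state
    activity with colony size, ablation variants without the refractory state or
    without reverse social contagion, a discrete-time Monte Carlo counterpart on
    switching Erdos-Renyi interaction networks, calibration of transition rates
    from tracked trajectories and proximity contact networks, and synthetic fixture
    generators for end-to-end testing of the calibration pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
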