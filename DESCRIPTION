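Package: qebss
Title: Quality-Evaluation-Based Selection of Molecular Dynamics Ensembles
    from NMR Spin Relaxation Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Back-calculates protein backbone 15N T1 and T2 spin relaxation
    times and heteronuclear NOE values from molecular dynamics trajectories
    via second-order rotational correlation functions of N-H bond vectors,
    multi-exponential fits on a logarithmic timescale grid, and Redfield
    theory. Ranks candidate trajectories against experimental relaxation
    tables with per-observable RMSD comparison numbers, selects the
    trajectories that simultaneously reproduce all observables, and combines
    them into a quality-evaluated ensemble by averaging correlation
    functions. Includes ensemble characterization (radius of gyration,
    backbone orientational correlation maps, minimum-distance maps,
    C-alpha principal component analysis), timescale landscapes, SAXS
    profile scale/offset fitting with RMSE scoring, and seeded synthetic
    generators (multi-exponential correlation functions, isotropic
    rotational diffusion, planted-truth selection fixtures, bead ensembles)
    so the full pipeline is testable without external trajectory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    bio3d,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
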