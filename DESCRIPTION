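Package: decisionlandscape
Title: Decision Landscapes from Mouse-Tracking Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstructs two-attractor decision landscapes from two-choice
    mouse-cursor trajectories. Trajectories are spatially normalized, trimmed,
    time-resampled and differentiated; a parametrized polynomial potential
    V(x, y) whose negative gradient (scaled by a time constant tau) models the
    cursor velocity is then fitted to one or many trajectories by least-squares
    velocity matching with an analytic Jacobian. Includes conventional
    trajectory measures (motion time, signed maximum deviation), a forward
    simulator of the gradient dynamics for synthetic data and parameter
    recovery, and 3D surface rendering of fitted landscapes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
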