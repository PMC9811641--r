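Package: jetcavity
Title: Cavity Dynamics of Microfluidic Jet Impact on Confined Capillary Bridges
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of microfluidic-jet impact on capillary
    bridges (Newtonian liquids, viscoelastic polymer solutions, agarose gels)
    confined between parallel walls. Provides material property records and
    the dimensionless groups governing impact (Weber, Froude, Ohnesorge,
    Deborah, elastic Froude), Rayleigh-type cavity expansion models (inertial
    parabolic profile, viscous droplet-train superposition, cavity-velocity
    prediction), traverse/embed classification from a critical Weber number,
    four-way seal-regime logic with bubble-outcome expectations, wettability
    energetics of the bridge on its confining walls (Laplace pressure,
    adhesion force, contact-line dissipation, Worthington-jet favourability),
    shadowgraph metrology (cavity contour extraction, front-velocity fitting,
    entrained-bubble quantification), and a seeded synthetic shadowgraph
    generator so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    EBImage,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
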