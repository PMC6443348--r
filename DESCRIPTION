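Package: awiorient
Title: Orientation of Partly Denatured Particles Relative to the Air-Water
    Interface in Cryo-Electron Tomograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify how protein particles adsorbed to the
    air-water interface of an unsupported vitreous film are oriented
    relative to that interface. The interface is modelled as a thin-plate
    spline height field fitted through particle centers; a per-particle
    denaturation direction is derived from the difference between intact
    and damaged reference maps and rotated into the tomogram frame; the
    displacement angle between that direction and the local interface
    normal is binned at 7.5 degrees. Includes the minimal subtomogram
    averaging machinery this analysis rests on (exhaustive-rotation
    alignment, gold-standard half-set averaging with Fourier shell
    correlation and mask-bias checks, multi-reference classification),
    MRC2014 volume I/O, and a synthetic vitreous-slab scene generator
    with analytic menisci for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
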