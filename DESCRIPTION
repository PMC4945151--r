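Package: astroborder
Title: Stereology of Astrocyte Process Confinement at Cortical Functional Borders
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify the confinement of astrocyte processes at
    cortical functional borders (barrel septa, the A1/A2 boundary, human
    sublayers IIIa/IIIb and cytochrome-oxidase blobs) with oriented
    line-intercept stereology. Provides a synthetic generator of labeled
    region maps, boundary-confined fiber arbors and unconfined capillary
    beds; placement of border-aligned measurement lines, offset lines and
    perpendicular density bands; landmark-based rigid alignment;
    exact segment-crossing counts; density profiles and percent drops;
    and the associated statistical battery (pooled t, log-ratio ANOVA
    with Tukey HSD, Pearson correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
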