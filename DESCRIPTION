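Package: polwave
Title: RNA Polymerase II Pausing Indices and DRB/4sU Clearance Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying RNA polymerase II behaviour from genomic
    coverage tracks: promoter-proximal pausing indices from occupancy data,
    spike-in and library-size normalization of nascent-RNA (4sU-seq) signal,
    metagene and anchored heatmap matrix construction, and estimation of
    elongation velocity from DRB time-course clearance wavefronts. Includes a
    stochastic initiation-pause-release-elongation simulator that generates
    ground-truthed coverage fixtures for validating every stage of the
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    IRanges,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
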