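Package: ringtime
Title: Stable Ring Representations of Time from Episodic Neural Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for chronic calcium-imaging population
    recordings during a repeated natural movie. Detects temporally precise
    spiking episodes from inferred spikes, fits masked nonnegative tensor
    component analysis (TCA) to DeltaF/F tensors with cross-validated rank
    selection, embeds denoised population activity with Isomap, fits a
    closed piecewise-linear ring curve for unsupervised decoding of
    time-in-movie (SPUD), and decomposes trial-to-trial and week-to-week
    variability along and perpendicular to the coding direction. Includes
    a synthetic-data generator with planted episodic structure and gain
    drift so that every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
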