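Package: vtaclust
Title: Electrophysiological Classification of Ventral Tegmental Area Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies ventral tegmental area (VTA) neurons recorded with in
    vivo extracellular electrophysiology from six features of their spike
    trains and mean action-potential waveforms: firing rate, firing-rate
    coefficient of variation, percentage of spikes in bursts (80/160 ms
    interspike-interval rule), total action-potential duration, duration from
    depolarization onset to end of repolarization, and presence of a notched
    waveform. High-firing units (>10 Hz, putatively GABAergic) are separated
    first; the remainder are grouped by Ward agglomerative clustering on the
    min-max-scaled feature matrix, with the number of clusters chosen by a
    majority vote of internal validity indices led by the silhouette width.
    Includes principal component analysis by singular value decomposition,
    cluster characterization statistics (Kruskal-Wallis with Dunn post hoc
    tests, chi-square contingency tests, log-normal distribution checks), a
    seeded synthetic-cohort generator with exactly known burst structure for
    offline validation, and a one-command pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
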