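Package: nirsgraph
Title: Graph-Closeness Intersubject Similarity Analysis for Naturalistic fNIRS
Version: 0.1.0
Authors@R:
    person("nirsgraph", "developers", email = "nirsgraph@example.org",
           role = c("aut", "cre"))
Description: Statistical analysis of multichannel functional near-infrared
    spectroscopy (fNIRS) recordings acquired under naturalistic stimulation
    (e.g. movie watching), where no event design matrix exists. At every time
    frame the pairwise Euclidean distances between participants' multivariate
    hemodynamic states define a complete weighted graph; the mean closeness
    centrality of that graph measures momentary intersubject similarity, and
    its average over frames is tested against a circular-permutation null that
    preserves each participant's autocorrelation and cross-channel
    correlation. Post-hoc tools identify the most consistent time points
    (top-quantile frames, with hemodynamic-delay-corrected timestamps) and the
    channels driving them (leave-one-channel-out relevance mapping). Includes
    the standard fNIRS conditioning chain (modified Beer-Lambert law, wavelet
    despiking, zero-phase band-pass, short-separation channel regression), a
    synthetic multi-participant data generator with known ground truth, plain
    text and SNIRF readers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    igraph,
    rhdf5,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
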