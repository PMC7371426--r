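Package: persistfire
Title: Quantification of Carbachol-Evoked Persistent Firing and Trace
    Eyeblink Conditioning Behavior
Version: 0.1.0
Authors@R:
    person("persistfire", "developers", email = "persistfire@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying persistent firing in current-clamp
    recordings of cortical neurons under cholinergic stimulation: spike
    detection and action-potential waveform features, per-cell incidence and
    firing-probability summaries, binned firing-rate trajectories with a
    one-phase exponential rise fit, postburst afterhyperpolarization (mAHP,
    sAHP) and afterdepolarization/plateau-potential measurements, and EMG
    conditioned-response scoring for trace eyeblink conditioning with
    learning curves and impaired/unimpaired grouping. Includes a synthetic
    cohort generator with emitted ground truth so every stage of the
    pipeline is verifiable at desk scale, a diffable native on-disk cohort
    format (JSON metadata plus CSV series), a read-only adapter for Axon
    Binary Format episodic files, and the nonparametric and parametric
    group-comparison statistics used in this literature.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
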