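Package: eegwelch
Title: Parallel Welch Power Spectral Density Estimation for Multi-Channel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Welch's method for power spectral density estimation of
    multi-channel EEG recordings, with a master-worker parallel scheduler
    that distributes overlapped signal segments round-robin over worker
    ranks and reduces them deterministically, so parallel results are
    bitwise-identical to serial ones. Includes a plain-text multi-channel
    interchange format ("middle files"), spreadsheet-readable PSD tables,
    a seeded generator of EEG-shaped synthetic datasets, a speedup
    benchmarking harness, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
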