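Package: dcse
Title: Dual-Channel Speech Enhancement for Cochlear-Implant Front Ends
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-microphone speech enhancement for cochlear-implant signal
    acquisition. Forms first-order differential channels with a maximally-flat
    FIR fractional-delay filter, detects noise-only frames by cepstral
    distance, estimates and tracks the directional noise's inter-channel
    directivity coefficient, estimates the speech magnitude spectrum by
    directivity-weighted power subtraction, compensates the array's
    low-frequency roll-off per cochlear-implant filter-bank band, and
    reconstructs by overlap-add with channel-1 phase. Includes a seeded
    synthetic two-microphone scene simulator, a CIS sine vocoder, SNR and
    speech-distortion metrics, WAV input/output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    optparse,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
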