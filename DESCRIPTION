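Package: ibipics
Title: Cognitive Stress Classification from ECG Interbeat-Interval Pictures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Classifies cognitive stress level from single-channel ECG by
    encoding consecutive interbeat intervals (IBIs) as binary one-hot
    "pictures" and training a small convolutional neural network on them,
    with a time-domain HRV feature + feed-forward network baseline for
    comparison. Includes a protocol-structured synthetic ECG session
    generator with known beat times, powerline-notch and baseline-wander
    removal, a Pan-Tompkins style QRS detector, the 28-bin IBI picture
    encoding with chronological train/validation/test splitting, mean
    IBI/SDNN/RMSSD feature extraction over sliding windows, and an
    accuracy/relative-standard-deviation sweep over the number of IBIs
    per picture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    png,
    signal,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
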