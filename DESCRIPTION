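Package: rrtaf
Title: Continuous Knee-Joint Angle Estimation from Surface EMG with
    Time-Advanced RMS Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the continuous knee-joint angle during gait
    from multichannel surface electromyography (sEMG). Implements 50 Hz notch
    and 10-500 Hz Butterworth band-pass preprocessing, non-overlapping
    sliding-window RMS features together with their electromechanically
    time-advanced counterparts (the combined 16-column RRTAF feature set for
    eight lower-limb muscles), leakage-safe min-max normalization, a
    from-scratch LSTM sequence regressor and a momentum-trained
    back-propagation neural network baseline, RMSE and cross-correlation
    evaluation with cross-method summary arithmetic, and a synthetic gait/sEMG
    simulator with a known electromechanical delay so the whole pipeline is
    testable without subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
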