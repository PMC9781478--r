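Package: pulserules
Title: Rule-Ensemble Prediction of Beat-to-Beat Blood Pressure from ECG and PPG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates time-aligned ECG, photoplethysmogram (PPG) and continuous
    arterial blood pressure (ABP) recordings with known per-beat ground truth,
    extracts per-beat hemodynamic features (pulse arrival times, pulse wave
    velocities, amplitudes and waveform descriptors) via automatic fiducial-point
    detection, and fits an interpretable rule-ensemble regression (decision rules
    from boosted trees combined with winsorized linear terms under an L1 penalty)
    to predict systolic, diastolic and mean blood pressure beat by beat.
    Includes term and variable importance, Friedman-Popescu H-statistic
    interaction screening with a null reference distribution, partial dependence,
    k-fold cross-validated model comparison and exact Wilcoxon signed-rank
    comparisons between physiological states.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
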