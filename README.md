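# semgFatigue

Recognising lower-limb muscle fatigue from multi-channel surface
electromyography (sEMG).

During sustained cyclic exercise, fatiguing muscle shows a rising sEMG
amplitude (RMS, IEMG), a spectral shift toward lower frequencies
(median frequency MF, RMS frequency RMSF) and decreasing signal
complexity (sample entropy). This package implements the full analysis
chain that exploits those signatures, for researchers in sports
biomechanics and electrophysiological signal processing:

1. **Synthetic trials** — a seeded generator of multi-channel sEMG with
   planted muscle-synergy structure and a controllable fatigue
   trajectory (`simConfig()`, `generateTrial()`), so the whole pipeline
   is testable without recordings.
2. **Preprocessing** — zero-phase Butterworth band-pass (20–150 Hz),
   50 Hz notch, rectified 5 Hz envelope (`bandpassFilter()`,
   `notchFilter()`, `rectifyEnvelope()`).
3. **Muscle synergy analysis** — non-negative matrix factorisation
   `V = WH + E` by multiplicative updates, model selection by
   variance-accounted-for, `VAF = 1 − ‖V − WH‖²_F / ‖V‖²_F`, choosing
   the smallest k with mean VAF > 0.95, and dominant-channel ranking by
   summed normalised loadings (`nmfDecompose()`, `selectK()`,
   `contributionScores()`).
4. **Features** — eight per 100 ms window (25 ms step): RMS, IEMG,
   waveform length, slope sign changes, MF, RMSF, sample entropy and
   Higuchi fractal dimension (`extractFeatures()`).
5. **Dataset preparation** — per-trial min–max normalisation,
   equal-length resampling, ground-truth labelling (first 30 % relaxed,
   last 30 % fatigued), stratified 80/20 + 5-fold CV splits.
6. **Models** — a Transformer-encoder sequence classifier
   (`Attention(Q,K,V) = softmax(QKᵀ/√d_k)V`, multi-head, sinusoidal
   positional encoding, residual + layer norm, mean pooling) written in
   plain R with hand-derived backpropagation, plus LSTM and
   gradient-boosted-tree baselines (`trainTransformer()`, `trainLSTM()`,
   `trainXGBoost()`).
7. **Evaluation** — confusion-based metrics with fold dispersion,
   ROC/AUC, permutation-sampling Shapley feature attribution, and
   Friedman + Nemenyi model comparison (`evaluateClassifier()`,
   `shapleyAttribution()`, `friedmanNemenyi()`).

See the methods vignette (`vignettes/fatigue-pipeline.Rmd`) for the
model details, parameter choices and limitations.

## Worked example

```r
library(semgFatigue)

report <- runPipeline(seed = 7, nTrials = 2, duration = 40,
                      includeShapley = TRUE)

report$kSelected
#> [1] 3
round(report$vafByK$mean, 3)
#> [1] 0.845 0.937 1.000 1.000 1.000 1.000 1.000 1.000
report$channelsSelected
#> [1] 1 2 3
round(sapply(report$cvMetrics, function(m) mean(m$acc)), 4)
#> transformer        lstm     xgboost
#>      1.0000      0.9944      0.9944
report$holdout$metrics
#>   metric mean sd
#> 1    acc    1  0
#> 2    pre    1  0
#> 3 recall    1  0
#> 4     f1    1  0
round(report$attribution, 4)
#>    RMS   IEMG     WL    SSC     MF   RMSF     SE     FD
#> 0.0458 0.1250 0.0231 0.1310 0.0640 0.1516 0.0182 0.0319
```

Reading the output: the synergy stage recovers the three planted
synergies — the VAF curve first exceeds 0.95 at k = 3 — and ranks the
planted dominant channels 1–3 on top. The Transformer trained on the
fused eight-feature sequences of the top channel separates relaxed from
fatigued windows perfectly on these clean synthetic conditions
(cross-validated accuracy 1.0, holdout accuracy 1.0); the baselines sit
at the same ceiling, which is expected here — the generator plants
strong, clean trends. The Shapley attribution spreads credit across
amplitude (IEMG), oscillation (SSC) and spectral (RMSF, MF) features,
reflecting that several feature families carry the planted signal.

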