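# dilipattern

Prognosis of drug-induced liver injury (DILI) from the **joint dynamics** of
alanine aminotransferase (ALT) and total bilirubin (TB), for hepatologists
and biostatisticians evaluating acute-liver-failure (ALF) prediction rules.

Classical rules (Hy's law, new Hy's law, Robles-Diaz) read one biochemical
panel.  This package instead classifies each patient's ALT/TB trajectories —
in days since DILI onset, normalized to fold of the upper limit of normal
(×ULN) — into four *dynamic evolution patterns* based on the peak folds
(A = ALT peak ×ULN, B = TB peak ×ULN) and the interval Δ between the peaks:

* **ALT-mono-peak** — A ≥ 3, B < 2.5
* **TB-mono-peak** — A < 3, B ≥ 2.5
* **double-overlap-peak (DOP)** — A ≥ 3, B ≥ 2.5, Δ < 3 days
* **double-separate-peak (DSP)** — A ≥ 3, B ≥ 2.5, Δ ≥ 3 days

DSP — a second bilirubin peak separated from the transaminase peak — marks
progressive excretory failure and is the high-risk class.  The optimized
risk model combines it with onset coagulation and cholestasis markers:

    score = 1.347 · DSP + 8.363 · INR + 0.004 · ALP

The package provides the pattern classifier (including the day a pattern
became determinable in real time), the comparator rules with their exact
published inequality senses, the CIOMS R/nR injury-type values,
self-contained logistic regression with likelihood-ratio-based forward
selection, ROC/AUROC with DeLong confidence intervals and paired
comparisons, Brier scores, seeded bootstrap internal validation, and a
synthetic-cohort simulator (pattern mixture 130:25:228:221 over 604
patients, ALF prevalence 28/604) so the full analysis runs without
patient-level data.

## Worked example

The numbered drivers under `analysis/` run the whole workflow
(simulate → classify → rules → fit → evaluate → reproduce) and write their
tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R 1   # seed 1
Rscript analysis/02_classify_patterns.R
Rscript analysis/04_fit_optimized_model.R
Rscript analysis/05_evaluate_models.R 1
```

On the seed-1 synthetic cohort (604 patients, 27 ALF events) this prints:

```
Forward-LR selection path:
  variable   lr_stat            p    loglik
1      dsp 22.070303 2.628447e-06 -99.26108
2      inr  6.327308 1.188926e-02 -96.09743

Model operating characteristics (simulated discovery-style cohort):
  dsp          AUROC 0.725 (0.648-0.803)  sens 81.5%  spec 63.6%
  hys_law      AUROC 0.564 (0.477-0.650)  sens 74.1%  spec 38.6%
  new_hys_law  AUROC 0.481 (0.383-0.579)  sens 48.1%  spec 48.0%
  robles_diaz  AUROC 0.490 (0.485-0.496)  sens 0.0%   spec 98.1%
  optimized    AUROC 0.733 (0.625-0.842)

Brier score of the optimized model: 0.056
Bootstrap (B = 200): AUROC 0.729 (0.624-0.836), Brier 0.055
```

DSP membership enters the forward selection first (likelihood-ratio
p ≈ 3·10⁻⁶) and the DSP rule alone discriminates ALF well above the
single-panel rules; the DeLong table (in `results/report.json`) tests those
AUROC differences pairwise.  With only 27 events the optimized score's
advantage over the bare DSP rule is not significant on this one cohort
(z = 0.23) — cohort-to-cohort variability at a 4.6 % event rate is large,
which is exactly what the bootstrap interval shows.

The same computations are available programmatically:

```r
library(dilipattern)
report <- run_pipeline(sim_config(n = 604, seed = 1), bootstrap_B = 200)
report$models$dsp
reproduce_published_targets()
```

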