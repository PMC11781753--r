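# cmcisway

Complexity analysis of center-of-pressure (CoP) balance recordings.

Standing still is an active control process. A force platform records its
signature as the CoP trajectory — anterior–posterior and medial–lateral
displacement over time — and classical posturographic descriptors (means,
standard deviations, path radius, tilt angle) summarize how *much* a
person sways. Between groups with only subtle skill differences, such as
elite versus expert athletes, sway magnitude often fails to discriminate;
the structure of the sway is where the information lives. `cmcisway` is
for researchers in motor control, sports science, and balance assessment
who want a structure-sensitive index with a fully reproducible pipeline
around it.

## The index

The Composite Multiscale Complexity Index (CMCI) of a scalar series
$S(t)$ is built in five steps:

1. Empirical mode decomposition,
   $S(t) = \sum_{i=1}^{n} \mathrm{IMF}_i(t) + r(t)$, by iterative
   envelope-mean sifting; modes with under 1% of the total mode energy
   are discarded.
2. The Hilbert analytic signal of each retained mode,
   $a_i(t)\,e^{j\varphi_i(t)}$.
3. Sample entropy ($m = 2$, $r = 0.2\,\mathrm{sd}$, Chebyshev distance,
   self-matches excluded) of the instantaneous amplitude $a_i(t)$ and of
   the wrapped phase $\varphi_i(t)$.
4. Per-mode total complexity
   $\mathrm{TC}_i = \tfrac12 \mathrm{SE}_{a_i} + \tfrac12 \mathrm{SE}_{\varphi_i}$.
5. $\mathrm{CMCI} = \frac{1}{m} \sum_{i=1}^{m} \mathrm{TC}_i$ over the
   $m$ retained modes.

The index is scale-invariant (units of the input cancel), deterministic,
and rises with the irregularity of amplitude and phase modulation across
the signal's intrinsic time scales.

Around the index the package provides: recording I/O (CSV/TSV plus a
cohort manifest), the classical descriptors
$\mathrm{COPLen} = \sqrt{x^2 + y^2}$ and
$\mathrm{TiltAngle} = \cos^{-1}\!\big(\mathrm{COPLen} / (0.55\,h)\big)$,
time-domain and CMCI feature tables, a classifier bench (ranking forest =
50 bagged CART trees, naive Bayes, L2 logistic regression, RBF SVM) with
stratified 70/30 splits, exact ROC/AUC and 10-fold cross-validation,
normality-gated group comparisons (Lilliefors KS → Welch t / Mann–Whitney
U) with per-descriptor SVM AUC, and a seeded synthetic stabilogram
generator for two groups × four conditions.

## A worked example

```r
library(cmcisway)

t <- seq(0.01, 30, by = 0.01)                     # 30 s at 100 Hz
x <- sin(2*pi*1.5*t) + sin(2*pi*0.3*t)            # clean structured sway
cmci(x)
#> <cmci_result> CMCI = 0.00748 over 3 retained IMF(s) (m = 2, r = 0.20 sd)

set.seed(1)
cmci(x + rnorm(3000, sd = sqrt(mean(x^2))))$cmci  # + broadband noise, SNR 0 dB
#> [1] 0.3669
```

A clean two-tone signal is highly regular in every mode (CMCI ≈ 0.007);
matched-power broadband noise multiplies the index fifty-fold. The same
contrast drives group recovery on a synthetic cohort:

```r
cfg <- sim_config(n_per_group = 8, n_expert = 8,
                  group_complexity_gap = 0.8, seed = 42)
cohort <- generate_cohort(cfg)
tabs <- run_extract(cohort$recordings, variables = "COPLen")

t2 <- dplyr::filter(tabs$cmci, condition == "T2")   # firm surface, eyes closed
cross_validate(t2, "ranking_forest", k = 8, seed = 1)
#> <cv_result> ranking_forest, 8-fold: mean AUC 1.000, SEN 1.000, SPC 1.000

td <- dplyr::filter(tabs$time_domain, condition == "T2")
cross_validate(td, "ranking_forest", k = 8, seed = 1)
#> <cv_result> ranking_forest, 8-fold: mean AUC 0.750, SEN 1.000, SPC 0.750

compare_groups(t2$CMCI_COPLen[t2$group == "elite"],
               t2$CMCI_COPLen[t2$group == "expert"])
#> … mean_a 0.0816 (sd 0.0285) vs mean_b 0.333 (sd 0.0250),
#>   test = t_test, p = 3.4e-11, descriptor_auc = 1
```

The complexity feature separates the groups perfectly (CV AUC 1.000)
where the magnitude-based features of the *same* series reach only 0.75 —
the generator injects the group difference into signal irregularity, not
sway size. Fitted objects support `tidy()`, `glance()` and `autoplot()`
(per-mode entropies, ROC curves, IMF panels).

A command-line interface wrapping the same functions ships at
`inst/cli/cmcisway.R` with subcommands `simulate`, `extract`, `classify`
and `compare`.

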