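# wormMotility

Longitudinal motility quantification and acquisition-protocol simulation
for *C. elegans*.

Individually housed worms confined to small circular bacterial food pads
can be imaged for their whole lives, and their movement — the displacement
of the animal's centroid between frames — already declines during the
first six days of adulthood. Whether a given experiment can *detect* that
decline depends on the acquisition schedule: one image every few hours, a
daily video, or something in between. This package is for researchers
designing or analysing such longitudinal movement assays. It provides:

- a calibrated stochastic generator of per-second centroid trajectories
  for cohorts of confined animals, with age-declining, individually
  variable activity (roaming/dwelling/quiescent state dynamics, persistent
  headings, edge-biased occupancy, stimulus-exclusion windows);
- gold-standard scoring: displacement series at any subsampled interval,
  3-hour block totals and daily totals (mm), with exclusion bookkeeping;
- protocol simulators implemented as pure temporal subsampling: **Single
  Snapshot** (net displacement between images Δ apart), **Daily / Twice
  Daily Video** (15-minute 1-fpm bouts), **Hybrid Multipass** (7 images
  3 min apart every 3 h);
- decline statistics: OLS fits of movement vs. age with the Wald test,
  within-block bootstrap confidence intervals for the decline rate,
  coefficients of variation, pairwise day correlation matrices,
  animal-subset bootstrap intervals for R², Bonferroni-aware decline
  classification;
- bacterial-lawn segmentation of brightfield arena frames by a
  two-component Gaussian-mixture fit to the intensity histogram, with
  multi-frame mask union and area calibration.

The central quantities, in the field's notation: for individual $i$,
movement in a 3-hour block starting at age $t$ (days) is
$M_i(t) = \sum_k \lVert p_i(t_{k+1}) - p_i(t_k)\rVert$ over retained 1-fpm
frames, the decline rate is the OLS slope $\beta_i$ of $M_i(t)$ on $t$
(mm per 3-h block per day), a protocol's fidelity is the squared Pearson
correlation between its per-timepoint scores and the matching gold-standard
totals, and inter-individual variability on a day is
$\mathrm{CV} = s/\bar{x}$ of that day's per-individual totals.

## Worked example

```r
library(wormMotility)

cfg    <- generatorConfig(seed = 44)     # defaults = calibrated conditions
cohort <- simulateCohort(cfg, 33)        # 33 individuals, 6 days at 1 fps
s      <- cohortSummary(cohort)

round(s$day0BlockMean, 1)   # 62.5  mm per 3-h block on day 0
round(-s$groupFit@slope, 2) # 7.93  mm per block per day group decline
round(s$finalDayBlockMean, 1) # 22.5 mm per block on the final day
round(s$day1CVpct, 1)       # 26    % CV of day-1 totals across individuals
round(s$netTotalR2, 2)      # 0.63  per-minute net vs total displacement R^2
s$nDeclineDetected          # 32    of 33 with a significant decline

s$individualFits[[1]]
#> DeclineFit: slope -6.468 /day, intercept 61.51, R^2 0.268,
#>   p 0.000163 (n = 48)
#>   biological interest (p<0.05 & R^2>0.10): TRUE

sweep <- protocolSweep(cohort, list(singleSnapshotProtocol(900),
                                    singleSnapshotProtocol(9000),
                                    dailyVideoProtocol(),
                                    hybridProtocol()))
aggregate(cbind(fidelity_r2, decline_detected) ~ protocol, sweep, mean)
#>                 protocol fidelity_r2 decline_detected
#> 1            daily_video       0.296            0.152
#> 2       hybrid_7x3min_3h       0.258            0.606
#> 3 single_snapshot_150min       0.020            0.061
#> 4  single_snapshot_15min       0.223            0.697
```

Reading the sweep: at 150-minute snapshot spacing the score is essentially
uncorrelated with true movement (R² = 0.02) and decline is almost never
detected; a once-daily 15-minute video detects decline in only ~15% of
individuals, while the hybrid scheme — the same image budget spread as
7 images every 3 h — detects it in ~61%.

`runPipeline(runConfig(generator = cfg))` runs everything (block totals,
per-individual fits with bootstrap CIs, daily CVs, day correlations,
protocol sweep) and writes tab-separated tables plus a versioned JSON
summary. A thin command-line wrapper with `simulate`, `score`,
`protocols`, `stats`, `lawnseg` and `run` subcommands is installed at
`inst/scripts/wormmotility.R`. The methods vignette
(`vignettes/movement-decline-methods.Rmd`) documents the movement model,
its calibration, and every numerical convention.

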