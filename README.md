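# intermove

Analysis of intermittent animal locomotion recorded as high-frequency
planar trajectories in an annular arena — the kind of data produced by
tracking a single walking insect at 5 Hz for hours. The package is
aimed at movement ecologists who want to go from raw positions to (i)
move/pause bout statistics, (ii) evidence for heavy-tailed (Lévy-like)
bout-length distributions, and (iii) slower behavioural organisation
(local search vs relocation), with every step testable against a
synthetic generator that knows its own ground truth.

## What it computes

**Discretization.** Frame transitions are moves when the displacement
between successive frames exceeds 0.3 cm (at 0.2 s frames), pauses
otherwise; runs become bouts. Rotational direction (clockwise vs
anti-clockwise around the arena) comes from the sign of the cross
product of successive position vectors. Frames within 3 cm of the walls
are censored and bouts touching a gap are dropped from duration
statistics.

**Reorientation.** The probability that the travel direction reverses
across a pause, as a function of pause length `t` (log-binned, with
95% CIs), plus within-bout "fidgeting" (CW/ACW switch proportions) and
the influence of each pause scale on overall turning.

**Bout-length distributions.** Binned maximum likelihood for five
candidate families; the centrepiece is the power law with a
stretched-exponential tail,

    f(x) ∝ x^(-μ) exp[-(x/θ)^β],   x ≥ 0.2 s,  0 < β ≤ 1,

where `μ` is the Lévy/scaling exponent, `θ` the tail-onset scale and
`β` the tail stretch. Model comparison uses Akaike weights, including
sequential pointwise model comparison (SPWMC) over truncation points;
model criticism uses Poisson ±2 SD bands per log bin, and a
parametric-bootstrap G-test provides goodness of fit.

**Sequence structure.** Partial autocorrelation (Durbin–Levinson),
move–pause cross-correlation against a shuffle null, and adjacent
move/pause pairing, on log durations.

**Behavioural modes.** A partial-sums (CUSUM) segmentation of the
signed bout series (+moves, −pauses, reference T = 0) with a minimum
mode duration `ε` (default 5 min), labelling segments local-search or
relocation by the sign of their net sum, and population
mode-probability curves over time.

**Synthetic data.** `generator_config()` encodes the study conditions
(8 h at 5 Hz, reference bout-law parameters, a turn-probability curve
with a 0.2–0.3 plateau for 6–100 s pauses, relocation occupancy
drifting 0.2 → 0.6) and `simulate_trajectory()` renders trajectories
whose re-discretization reproduces the generator's bout ledger exactly.

See `vignettes/intermittent-motion.Rmd` for the model details,
numerical choices and known limitations (in particular the weak
identifiability of `θ` at realistic sample sizes).

## A worked example

```r
library(intermove)

cfg  <- generator_config(duration = 7200, seed = 1)  # 2 h record
traj <- simulate_trajectory(cfg)
seq  <- discretize_trajectory(traj)
seq
#> Bout sequence for ind01
#>   4740 bouts ( move 2370, pause 2370 )
#>   frame_dt: 0.2 s; blocks: 1 ; censored gaps: 0

head(turn_probability_curve(turn_after_pause(seq)), 5)
#>   bin_left bin_right      p     lo     hi    n
#> 1      0.2       0.4 0.0480 0.0349 0.0612 1020
#> 2      0.4       0.8 0.0946 0.0706 0.1186  571
#> 3      0.8       1.6 0.1675 0.1301 0.2050  382
#> 4      1.6       3.2 0.1451 0.0954 0.1948  193
#> 5      3.2       6.4 0.2955 0.2176 0.3733  132
```

The turn probability climbs with pause length exactly as configured:
short pauses are rests (reversal probability ≈ 0.05), pauses of a few
seconds reorient the animal a quarter of the time.

```r
partial_sums_segment(signed_series(seq), epsilon = 300)
#> Partial-sums segmentation (epsilon = 300 s): 5 segment(s)
#>  block start_bout end_bout t_start  t_end     net        label
#>      1          1      840     0.0 1216.0  -476.0 local_search
#>      1        841     2697  1216.0 3386.8   752.4   relocation
#>      1       2698     3168  3386.8 4978.6 -1175.4 local_search
#>      1       3169     3573  4978.6 5499.2   253.8   relocation
#>      1       3574     4740  5499.2 7200.0  -809.6 local_search
```

Negative net sums mark stretches dominated by pausing (local search),
positive ones stretches dominated by displacement (relocation).

Parameter recovery at the pooled sample size:

```r
set.seed(1)
d <- sample_bout_lengths(list(mu = 1.49, beta = 0.55, theta = 8,
                              xmin = 0.2), 50000)
fit_mle(d, candidate_model("pl_stretched_tail", c(0.2, Inf)))
#> Binned MLE fit: pl_stretched_tail
#>   n = 50000  support = [ 0.2 , Inf )
#>   params: mu = 1.483, beta = 0.56792, theta = 8.4033
#>   loglik = -125825.77  AIC = 251657.55
```

The scaling exponent is recovered to ±0.01 here; `θ` and `β` carry the
larger uncertainty discussed in the vignette.

## Command line

A thin CLI over the pipeline lives at
`inst/scripts/intermove-cli.R`:

```sh
Rscript inst/scripts/intermove-cli.R all --config my-run.yaml --out out/
```

with subcommands `generate`, `discretize`, `turning`, `distfit`,
`correlate`, `modes`, `all`; the YAML config fills any missing entries
with the standard study defaults (0.3 cm threshold, 0.2 s frames, 3 cm
margin, ε = 300 s, 1000 s pause-length cap).
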