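# dose2pba

Reverse dosimetry for the pyrethroid insecticide lambda-cyhalothrin:
linking probabilistic **dietary exposure estimates** (mg/kg/day, per
Monte Carlo iterate) to **measured urinary concentrations** of its
metabolite 3-phenoxybenzoic acid (3PBA, µg/L with urinary creatinine in
mg/dL) for the same survey participants.

The package is aimed at exposure scientists and biostatisticians who
want to (a) forward-model what a dietary exposure estimate implies for a
spot urine biomarker, and (b) use the measured biomarker to discard
implausible exposure iterates — a likelihood-free Bayesian update.

## The model

**Forward pharmacokinetics.** For participant *i*, ingested dose is laid
out on an hourly grid: the day's total dose is split equally across the
reported meal hours; meals on the collection day repeat the previous
day's mealtimes and per-meal doses, minus any meal inconsistent with the
reported pre-collection fast. Food washers (Bernoulli, p = 0.5) have
their dose reduced by a Beta-distributed washing factor (mean 30%).
Serum 3PBA follows a one-compartment model with first-order elimination
under a piecewise-constant intake rate, which has the exact hourly
update

```
C[i,t+1] = C[i,t] exp(-k_i) + (f_i D[i,t])/(V_i k_i) (1 - exp(-k_i))
```

with `k` the elimination rate (1/h), `f` the fraction of ingested
lambda-cyhalothrin absorbed and metabolized to 3PBA, `V` the volume of
distribution (L), and `D[i,t]` the mg ingested during hour *t*. The
initial condition at midnight of the first recall day is the
steady-state concentration `f·r/(k·V)` for the washing-adjusted mean
daily intake rate `r` (mg/h) of the two recall days. Urine entering the
bladder is creatinine-standardized,

```
U[i,t] = R_i k_i V_i C[i,t] / N_i      (µg 3PBA / µg creatinine)
```

where `R` is the 3PBA share of total urinary metabolite and `N` the
creatinine excretion rate (mg/h) predicted from weight, height, age and
sex. The measured spot sample is modelled as the mean of `U` over the
4–6 h bladder void interval ending at the collection hour.

**Rejection ABC.** An exposure iterate is accepted at threshold *c*
when `|log10(measured) − log10(predicted)| < c`, with c = 1 (order of
magnitude) and c = 0.5 by default. Exposures and predictions are then
summarized per participant (mean over accepted iterates) with
survey-weighted percentiles (left-continuous inverse CDF; exam weights
divided by the number of pooled survey cycles).

**Synthetic data.** Because the real survey and regulatory-model inputs
are not redistributable, a generator emulates their structure —
demographics, mealtime patterns, collection times and fasting,
log-normal episodic daily doses, LOD-censored biomarkers (LOD/√2
substitution), and a two-cycle stratified design — with a designated
"true" iterate so recovery can be verified end to end.

## Worked example

```r
library(dose2pba)
cfg <- pipeline_config(seed = 42, n_participants = 500, n_iterates = 5)
res <- run_pipeline(cfg)
d <- res$diagnostics
cat(sprintf("coverage within 1 log10:   %.2f\n", d$coverage$c1))
cat(sprintf("coverage within 0.5 log10: %.2f\n", d$coverage$c0.5))
cat(sprintf("r (log10)  unfiltered / c=1 / c=0.5: %.2f / %.2f / %.2f\n",
            d$correlation$unfiltered$log10_r,
            d$correlation[["c=1"]]$log10_r, d$correlation[["c=0.5"]]$log10_r))
subset(res$summary, quantity == "exposure_mgkgday" & percentile %in% c(50, 95))
```

prints

```
coverage within 1 log10:   0.89
coverage within 0.5 log10: 0.55
r (log10)  unfiltered / c=1 / c=0.5: 0.31 / 0.50 / 0.80
           quantity     filter percentile        value   n
1  exposure_mgkgday unfiltered         50 0.0001520241 500
3  exposure_mgkgday unfiltered         95 0.0002337237 500
13 exposure_mgkgday        c=1         50 0.0001488404 493
15 exposure_mgkgday        c=1         95 0.0002433531 493
25 exposure_mgkgday      c=0.5         50 0.0001409362 428
27 exposure_mgkgday      c=0.5         95 0.0003372316 428
```

Most forward predictions land within an order of magnitude of the
measurements; tightening the ABC threshold raises the predicted-vs-
measured correlation (here 0.31 → 0.50 → 0.80) while the filtered
exposure percentiles stay anchored near the prior's median — the
package's synthetic analogue of the behavior expected on real
biomonitoring data. `res$records` holds every participant-iterate with
its acceptance flags, and `write_pipeline_outputs(res, "out/")` writes
the CSV/JSON artifact set.

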