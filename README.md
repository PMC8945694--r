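# phasim

Respiration kinetics and continuous-flow process simulation for
polyhydroxyalkanoate (PHA) accumulation by mixed microbial cultures
(MMCs).

Feast/famine-enriched MMCs take up volatile fatty acids and store them as
PHA. For dilute feedstocks (~1 gCOD/L) accumulation must run as a
flow-through process, which pits volumetric productivity against substrate
utilization efficiency. The escape is a kinetic hysteresis: the substrate
concentration required to *stimulate* a high specific uptake rate
(upshift half-saturation `k_u`, tens of mgCOD/L) is far larger than the
concentration required to *maintain* it (downshift affinity `k_s`, a few
mgCOD/L or less). phasim implements, end to end:

- the batch pulse-respiration mass balance
  `dC_O/dt = k_a(C_O* − C_O) − Q_oe − Q_os − Q_op`, with Haldane–Monod
  uptake `q_s = q_se · min(C_s/(k_s + C_s + C_s²/k_h), C_O/(k_O + C_O))`,
  a dose-dependent induction lag, the upshift law
  `q_sm = q_sr + q_su·C_si/(k_u + C_si)`, storage
  `X_p = (1 − Y_os)(C_si − C_s)` and PHA inhibition
  `1 − (f_PHA/f_PHA,max)^1.24`;
- a synthetic respirogram generator (probe lag 0.14 s⁻¹, 0.1 Hz logging,
  seeded noise) standing in for raw logger files;
- Savitzky–Golay signal conditioning, probe-dynamics correction and
  pre-aeration / consumption / re-aeration zone segmentation;
- the six-step respirometric estimation pipeline (`k_a`, `Q_oe`, `Q_op`,
  `Q_os(t)`, `Y_os`, `C_s(t)`, then `k_s`, `k_i`, `q_sm`, `k_h`, `f_i`),
  a non-aerated direct-fit variant, and the cross-experiment upshift fit;
- a Monte Carlo two-zone (stimulation/maintenance) continuous-flow
  accumulation simulator with per-floc stimulation memory, a loading
  controller, an analytic fixed-point oracle and loading sweeps.

It is aimed at bioprocess engineers and modellers characterizing MMC
biomass by respirometry or exploring flow-through accumulation designs.

## Worked example

Generate a synthetic pulse experiment with the laboratory-culture preset,
estimate its kinetics, and compare a stimulated against an unstimulated
continuous process:

```r
library(phasim)
p <- kinetic_preset("lab")

# how much polymer does the median 57 mgCOD/L pulse store at 1 gVSS/L?
100 * pha_content(pha_stored_cod(57, 0, p), xa = 1, p)
#> [1] 2.519713

resp <- generate_respirogram(pulse_config(csi = 57, xa = 1, seed = 1), p)
fit  <- estimate_experiment(resp, seed = 1)
fit
#> <pha_fit> ( aerated ) csi = 57 mgCOD/L, xa = 1 gVSS/L
#>   ka = 1.104        # aeration mass transfer, 1/min (preset: 1.11)
#>   qoe = 0.6375      # endogenous respiration, mgO2/gVSS/min (0.64)
#>   yos = 0.2601      # oxygen yield on substrate, gO2/gCOD (0.26)
#>   ks = 2.092        # downshift affinity, mgCOD/L (2.0)
#>   qsm = 20.12       # maximum uptake rate, mgCOD/gVSS/min (20.06)
#>   ...

# continuous flow at 70% of the maximum loading, 1000 mgCOD/L feed
unstim <- run_process(process_config(kinetics = p, recirculate = FALSE,
                                     t_end = 30, seed = 1))
stim   <- run_process(process_config(kinetics = p, hrt_m = 10,
                                     t_end = 35, seed = 2))
steady_state(unstim)$csm_ss   # effluent without stimulation
#> [1] 52.17584
steady_state(stim)$csm_ss     # effluent with a 500 mgCOD/L stimulation zone
#> [1] 6.110282
```

Same uptake, an order of magnitude less substrate lost in the effluent:
that is the hysteresis benefit the process design exploits. The numbers in
parentheses are the preset values the synthetic record was generated
from; the printed estimates are what the pipeline recovered from the
noisy, probe-lagged, 0.1 Hz trace alone.

`autoplot()` works on respirograms, fits, upshift fits and process
trajectories; `tidy()`/`glance()` return broom-style tables.

A thin command-line front end over the same functions ships in
`inst/cli/phasim.R` (subcommands `synth`, `estimate`, `batch-estimate`,
`simulate-process`, `sweep`).

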