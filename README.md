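# hedgesim

Stochastic bistable switches as a genotype–phenotype map: how molecular
network structure controls the persistence of bet-hedging, and what that
means for treatment holidays.

## The problem

Isogenic populations of bacteria and cancer cells often harbour a small,
stochastically arising subpopulation of slow-growing, drug-tolerant
*persister* cells — a bet-hedge against environmental catastrophe. In a
benign environment persisters are a fitness cost, so selection should erase
the hedge; yet it persists. hedgesim implements a mechanistic explanation:
when phenotype determination is carried out by a bistable chemical reaction
network (CRN) seeded with genetically encoded molecule counts, the *shape*
of that network sets the speed at which selection can erode the hedge — from
a few hundred mutational events to never.

The package is aimed at researchers in evolutionary systems biology and
mathematical oncology who want a small, fully reproducible simulation stack
for stochastic phenotype switches, invasion analysis, and treatment-holiday
experiments.

## The model

* **GP map.** A genotype is `g = (x0, y0)` with `x0 + y0 = gmax` (default
  60), the initial counts of two gene products. A bistable CRN (Gillespie
  jump chain) absorbs into all-`x` (phenotype A, proliferative) or
  `x`-depleted (phenotype B, persister-like); the genotype fixes only the
  switching probability `p(g)`. Switch library: direct competition `DC`
  (`x+y → 2x`, `x+y → 2y`), biased variants `DCx`/`DCy`, approximate
  majority `AM` (adds an intermediate species `b`), and the redundant
  `DCdup`. `p(g)` is exact: gambler's-ruin closed forms for the DC family
  (`p = (1 − r^x0)/(1 − r^gmax)`), a sparse Markov-chain absorption solve
  for AM.
* **Population dynamics.** Phenotype composition follows the projection
  matrix `P = (1/⟨w⟩) [wA p, wB p; wA(1−p), wB(1−p)]`,
  `⟨w⟩ = p wA + (1−p) wB`; stationary composition `(p, 1−p)`. Defaults
  `wA = 2.0`, `wB = 1.01` offspring per hour.
* **Invasion.** A single mutant with hedge `p2` in a `p1`-resident founds a
  two-type branching process with Poisson offspring; its fixation
  probability solves `1 − π_j = exp(−Σ_i M_ij π_i)`, `M_ij = w_j q_i / ⟨w⟩`,
  reduced exactly to a scalar fixed point and solved by Newton iteration.
  Neutral and deleterious mutants (`p2 ≤ p1`) never fix.
* **Evolution (SSWM).** One-step mutations `x0 → x0 ± 1` arrive singly and
  fix with probability `π`; evolution ratchets toward `x0 = gmax` (hedge
  lost). Expected loss time: `Σ_g 1/(0.5 π(g → g+1))`.
* **Therapy.** A treatment holiday of `T` mutational events erodes the hedge
  to an expected post-holiday genotype; an hourly stochastic death–birth
  simulation (binomial compartments from `N0 = 1e10`) then yields extinction
  times under cytostatic, cytotoxic or mixed drug regimes.

## Worked example

```r
library(hedgesim)

dcy <- make_switch("DCy")          # y-biased direct competition
#> DCy switch (gmax = 60, bias = 1.1004881): 2 species, 2 reactions

hedge_probability(dcy, 53)         # most even hedge this switch can express
#> [1] 0.51

fixation_probability(hedge_probability(dcy, 53), hedge_probability(dcy, 54))
#> fixation probability pi = 0.0588007 (pi_A = 0.0746931, pi_B = 0.0384445; supercritical)

expected_loss_time(dcy, 53)        # mutational events until the hedge is gone
#> [1] 195.1887

sswm_trajectory(dcy, 53, seed = 1) # one stochastic realization
#> SSWM trajectory: bet-hedging lost after 182 sampled mutational events

holiday_sweep(dcy, 53, T_list = c(0, 3000), regime = drug_regime("cytotoxic"),
              replicates = 200, seed = 1)
#>      T  g    p extinct_fraction success_fraction min_t_ext median_t_ext classification
#> 1    0 53 0.51                0                0     20000           NA  no_extinction
#> 2 3000 60 1.00                1                1        23           25     successful
```

Reading the output: at `x0 = 53` the DCy switch hedges 51/49, and a single
beneficial mutation fixes with probability ≈ 0.059, so the hedge is expected
to be lost after ≈ 196 sampled mutations. Without a holiday (`T = 0`) the
persister fraction shields the population and a cytotoxic drug never clears
it within 20,000 h; after a 3,000-event holiday the hedge is fully lost
(`p = 1`) and every replicate is extinct within ~25 h — inside a 240-hour
course of therapy. Swapping `DCy` for `AM` reverses the conclusion: the AM
ladder stalls (`expected_loss_time(make_switch("AM"), 30)` is `Inf`), so no
holiday restores drug sensitivity.

A thin command-line wrapper with the same functionality ships in
`inst/cli/hedgesim` (subcommands `switch-prob`, `switch-grid`, `invasion`,
`evolve`, `therapy`, `sweep`, `fixtures`; config files via
`load_config()`/`run_experiment()`, outputs as CSV/JSON with a manifest).

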