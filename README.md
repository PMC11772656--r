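# pacedraft

Drafting and pacing strategy models for elite marathon running.

## What problem this package addresses

When Eliud Kipchoge set his world records at the 2018 and 2022 Berlin
marathons he ran most of each race shielded by pacers — but in formations
that were far from the most aerodynamically effective, and with pacers
dropping out on an improvised schedule. `pacedraft` is for sports
scientists and modellers who want to put numbers on the question this
raises: *how much faster could the same runners have covered the same
distance with better drafting and pacing, without anyone spending more
energy than they actually did?*

The package provides the full accounting chain:

* **Running power.** Total mechanical power is mass times speed times the
  cost of running measured on elite Kenyan marathon runners,
  `W_tot(v) = m·v·(0.018 v² + 3.2833)` W. Because that measurement
  includes air resistance, the solo drag curve is subtracted back out to
  give the non-aerodynamic power `W_na(v) = W_tot(v) − v·F_D(v)`, and a
  drafted runner costs `W_na(v) + v·F_D^(f,p)(v)` for the drag curve of
  his formation and position.
* **Drag curves.** Per-(formation, position) drag is quadratic in speed,
  `F_D(v) = a v² + b v + c` (the solo curve `0.493 v² − 3.256 v + 7.878` N
  gives 5.73 N at the 5.86 m/s target pace), fitted from four-speed sample
  tables and collected in catalogs with per-entry provenance.
* **Energy ledgers.** Split tables of the actual races (shipped for Berlin
  2018 and 2022) are parsed into per-phase speeds; each runner's energy
  spend per phase is duration × positional power, and the totals become
  frozen budgets.
* **Race-time optimization.** A three-phase projected race (both pacers in
  F12 → remaining pacer in F4 → solo) is simulated forward from the
  budgets; the optimizer minimises `t₁+t₂+t₃` over phase speeds in
  [5, 6] m/s under the main runner's energy-conservation constraint, plus
  a cooperative variant in which the pacers swap positions halfway through
  phase 1.
* **Synthetic data.** A seeded generator emulates every input (drag
  samples, catalogs, rosters, split tables) so the whole pipeline, and its
  property tests, run without external data.

## Worked example

```r
library(pacedraft)

phases <- parse_splits(berlin_splits(2022))
phases
#> # A tibble: 3 × 5
#>   phase duration_s distance_m speed_mps formation
#>   <int>      <dbl>      <dbl>     <dbl> <chr>
#> 1     1       3848      22590      5.87 F3
#> 2     2        360       2070      5.75 F1
#> 3     3       3061      17535      5.73 SOLO

budgets <- budgets_from_actual_race(phases, berlin_roster(2022),
                                    berlin_exposure(2022))
budgets
#> # A tibble: 3 × 4
#>   runner         mass_kg budget_J provenance
#>   <chr>            <dbl>    <dbl> <chr>
#> 1 Eliud Kipchoge      52 8478650. recomputed from actual-race splits
#> 2 Jacob Kiplimo       52 4998772. recomputed from actual-race splits
#> 3 Isiah Koech         52 4581637. recomputed from actual-race splits

optimize_strategy(budgets)
#> <race_outcome> total 7180.33 s (7181 s on the clock), feasible, residual 0 J
#> # A tibble: 3 × 5
#>   phase formation speed_mps time_s distance_m
#>   <int> <chr>         <dbl>  <dbl>      <dbl>
#> 1     1 F12            5.99  3802.     22791.
#> 2     2 F4             5.95   284.      1694.
#> 3     3 SOLO           5.72  3094.     17710.
```

Reading this: the actual 2022 race took 7269 s (2:01:09). With the same
energy budgets but the better formations, the optimizer finds a 7181 s
(1:59:41) race — 88 s faster and under two hours — run with a *positive
split*: fast while shielded (5.99, 5.95 m/s), slower once alone
(5.72 m/s, about 4% below the paced phases). The same analysis of the 2018
race gives 7185 s (1:59:45), 114 s under the actual finish. The wrapper
`berlin_analysis(year)` runs the whole chain, including the cooperative
pacer swap (worth a further ~1.3 s in 2022 and ~0.9 s in 2018):

```r
berlin_analysis(2022)
#> == Berlin 2022 marathon ==
#> actual finish:   02:01:09 (7269 s)
#> optimized:       01:59:41 (7181 s on the clock, 7180.33 s raw)
#> improvement:     88 s; splitting: positive (phase-3 deficit 4.2%)
#> cooperative:     additional 1.29 s
```

Results are tibbles throughout; `tidy()`, `glance()` and `autoplot()`
methods cover drag curves, ledgers and race outcomes. See the
`drafting-pacing` vignette for the model, its assumptions, the numerical
choices and the known limitations — in particular why optimized totals are
sensitive to the drag-curve inputs at the level of a few seconds.

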