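# rore

Automated review of cardiac-arrest resuscitation episodes from
defibrillator event logs and minimal event annotations.

When an EMS crew treats an out-of-hospital cardiac arrest, the defibrillator
records an event log (power-on time, every "shock delivered" with energy and
impedance, mode switches) and reviewers annotate the ECG afterwards: rhythm
transitions (ventricular fibrillation `vf`, ventricular tachycardia `vt`,
asystole `as`, pulseless electrical activity `pe`, pulse-giving rhythm `pr`)
and the start/stop of chest-compression sequences (`c1`/`c2`) and
defibrillations (`d1`/`d2`). Registries then abstract dozens of per-shock
review variables from these sources by hand — slow, expensive, and subject
to inter-observer variation. `rore` automates that abstraction and audits
the result.

## The representation and the reasoning

The episode is modeled as contiguous labeled half-open time intervals in two
domains:

- **therapy**: S_T over states {C, H, D} — compressions, hands-off interval,
  defibrillation;
- **response**: S_R over states {VF, VT, AS, PE, PR, UN} — each annotation
  opens a rhythm state that persists until the next annotation.

A change in either domain is a change of the combined episode
representation S_C, whose transition times are the union of both domains'
transition times and whose labels concatenate therapy and rhythm (e.g.
`HVF`, `DVF`, `CPE`). For example, given

    S_T = {([740.8,805.2],H), ([805.2,887.2],C), ([887.2,903.3],H),
           ([903.3,908.3],D), ([908.3,938.8],H), ([938.8,1062.0],C)}
    S_R = {([793.6,908.3],VF), ([908.3,944.0],PE), ([944.0,1062.0],VF)}

the combined sequence is the seven states
`HVF, CVF, HVF, DVF, HPE, CPE, CVF` over [793.6, 1062.0).

The review engine segments the episode into pre-/post-shock windows bounded
by neighbouring shocks (or the beginning/end-of-episode markers) and derives
every registry variable by rule-based search over the representation:
first/last compression before each shock, absolute shock times through a
serial-day-number clock reconciliation, post-shock rhythm checkpoints at 10,
30, 60 and 120 s (with a ±5 s reading window, a transition-into-VF override
and an unknown-rhythm fallback), persistent-VF detection, VF recurrence
(`vfpr`), organized rhythm (`orgpr`), ROSC, stacked-shock runs, device mode,
CPR presence, energy and impedance. Time variables use the registry's
hr:mn:sc triplets with the sentinel codes `99:99:99` (unknown / persistent
VF), `88:88:88` (no CPR / no onset) and `66:66:66` (no data).

The audit engine compares a derived database against a manually abstracted
one, row-aligned by (episode, shock number), coding every cell correct (1),
wrong (2) or missing (3) — missing when either side carries a sentinel —
with a 1 s time tolerance by default (5 s available via
`compare_databases(tolerance = 5)`).

## Worked example

```r
library(rore)

log <- read_event_log(system.file("extdata", "worked_example_log.jsonl", package = "rore"))
ann <- read_annotations(system.file("extdata", "worked_example_annotations.csv", package = "rore"))
ep  <- build_episode(log, ann, id = "worked")
writeLines(format_rore(ep))
#> ...
#> episode representation:
#> 793.6–805.2: HVF
#> 805.2–887.2: CVF
#> 887.2–903.3: HVF
#> 903.3–908.3: DVF
#> 908.3–938.8: HPE
#> 938.8–944.0: CPE
#> 944.0–1062.0: CVF

derive_review(ep)[, c("shkn", "fchr", "fcmn", "fcsc", "lchr", "lcmn", "lcsc", "r10", "r60", "vfpr")]
#>   shkn  fchr  fcmn  fcsc  lchr  lcmn  lcsc   r10   r60  vfpr
#>      1    14    43    25    14    44    47     4     2     1
```

With power-on at 14:30:00, the first compression before the shock starts at
elapsed 805.2 s (14:43:25) and the last ends at 887.2 s (14:44:47); ten
seconds after the shock the rhythm is organized (code 4), at sixty seconds
VF has recurred (code 2), so VF before the next shock is coded yes (1).

A full synthetic study in one call:

```r
sim <- simulate_cohort(50, seed = 1)        # episodes + ground truth + derived
aud <- compare_databases(sim$truth, sim$derived)
summarize_audit(aud)                         # per-variable correct/wrong/missing
glance(aud)                                  # overall match rate
autoplot(aud)                                # concordance bar chart
```

A thin command-line front end with `build`, `derive`, `compare`, `simulate`
and `roundtrip` subcommands is installed at `inst/cli/rore.R`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "rore.R", package = "rore"))') \
  roundtrip --episodes 20 --seed 1
```

## Scope

The package reasons over annotations; it does not detect rhythms or
compressions from ECG/impedance waveforms, parse vendor binary files, or
handle medication/etiology variables that require narrative review. See the
methods vignette (`vignettes/resuscitation-review.Rmd`) for the model,
parameter choices, and known limitations.
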