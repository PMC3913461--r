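---
title: "Automated review of resuscitation episodes: model, rules, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated review of resuscitation episodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rore)
```

## The state-sequence model

A resuscitation episode is described by a minimal set of timestamped
events. Therapeutic events `c1`/`c2` and `d1`/`d2` delimit compression
sequences and defibrillation discharges; rhythmic events `vf`, `vt`, `as`,
`pe`, `pr` (and `un`) mark transitions between cardiac rhythms. From these
the package builds two domain sequences of contiguous labeled intervals —
therapy over {C, H, D} and response over {VF, VT, AS, PE, PR, UN} — and
their combination, in which a change in either domain is a change of state
and labels concatenate therapy-first (`HVF`, `DVF`, `CUN`).

Three representational choices deserve comment:

* **Half-open intervals.** Adjacent states share a boundary instant; storing
  intervals as `[start, end)` makes every point query unambiguous — a
  transition time belongs to the state it opens. The same convention
  resolves the shock-boundary tie: a rhythm state opening exactly at the
  shock time is post-shock, not pre-shock.
* **The response domain starts at its first annotation.** Before the leads
  are on there is no rhythm information, and we do not pad with UN: UN is a
  positive annotation (reviewer looked and could not tell, or the recording
  ended), not a default. Consequently the combined representation covers the
  *intersection* of the two domains, which is what reproduces the worked
  example's span exactly.
* **Maximal runs.** Adjacent same-label intervals are merged in the single
  domains, so "the last H before the shock" and similar searches are
  well-defined. Simultaneous rhythm annotations are rejected as annotation
  errors rather than tie-broken.

Times are elapsed seconds since device power-on, stored at millisecond
resolution and printed at 0.1 s. Wall-clock reconciliation goes through a
serial day number (fractional days since January 1 of year 0, proleptic
Gregorian); only differences and round trips are observable, and both are
exact to well under 1 ms. Derived clock triplets round half-up to whole
seconds because the registry sheets store whole seconds; the audit's 1 s
tolerance absorbs the sub-second residue. The device clock is assumed
synchronized; no drift correction is attempted.

## Derivation rules

For each shock, the pre-shock window runs from the previous shock (or the
beginning of episode) and the post-shock window to the next shock (or the
end of episode); the windows tile the episode.

* **Compression times.** `fctm` is the start of the first C in the
  pre-shock window, `lctm` the end of the last C (equivalently the start of
  the last hands-off interval before the discharge). No C yields the
  `88:88:88` (no CPR) sentinel. A first compression already ongoing at the
  start of recording is flagged (`fc_ongoing`), since its annotated start
  time is only a lower bound.
* **Rhythm checkpoints.** The rhythm at 10/30/60/120 s after the shock is
  read at `q = shock_time + shock_end_offset + offset` with two window
  rules inside ±5 s of `q`: a transition *into* VF inside the window
  overrides the reading to VF, and if the state at `q` is UN the last known
  rhythm stands in provided it was still present inside the window. A
  checkpoint past the end of the annotated domain reads unknown (code 9).
* **Persistent VF.** If the pre-shock rhythm and the 10/30/60 s checkpoints
  are all VF, the VF-onset time is coded `99:99:99` ("no onset, patient
  remained in VF"). The 120 s checkpoint is deliberately excluded — an
  unsuccessful shock is evident well before two minutes, and including it
  would misclassify episodes whose recording ends between 60 and 120 s. A
  pre-shock VF with an unknown 10 s checkpoint is *not* persistent VF; if
  no VF onset is then found, the derived code is `88:88:88`.
* **Onsets.** VF-onset and ROSC times are the first transition into VF/PR
  strictly after the shock. The domain's first interval never counts as an
  onset: its start marks where annotation begins, not a transition.
* **Presence variables.** `vfpr`/`orgpr` are yes if any VF/{PE, PR}
  interval intersects the open post-shock window, no if the window holds
  some known rhythm without one, and unknown if only UN is seen. `rosc` is
  yes only on an explicit PR annotation — the representation carries no
  pulse information beyond that, a known limitation inherited from the
  annotation vocabulary.
* **Device variables.** Shock number and count come from the time-ordered
  shock records; the stacked-shock count `shks` is the size of the maximal
  run of consecutive shocks with no compression between successive members
  (every member reports the run size). Mode follows the latest
  `modeSwitchMonitor`/`modeSwitchAED` log entry before the shock, advisory
  if none. Energy and impedance are copied verbatim from the log (sentinel
  999 when absent).

### Configuration

`rore_config()` exposes the tunables, all in seconds:
`shock_end_offset_s` (default 0; 3 treats the end of shock as three seconds
after delivery — both conventions appear in practice and the default
reproduces the worked checkpoint arithmetic 198 + 10 = 208),
`checkpoint_offsets_s` (10, 30, 60, 120), `window_halfwidth_s` (5) and
`time_tolerance_s` (1; 5 is less restrictive and clinically defensible —
the audit's monotonicity property guarantees widening never loses correct
codes).

Organized rhythms PE and PR share registry code 4; PR is distinguished only
through the ROSC variables.

## The audit coder

`compare_databases()` aligns rows by (episode, shock number) — never file
order, so dropped or duplicated shock registrations surface as alignment
errors — and codes each cell correct/wrong/missing (1/2/3). A time pair is
missing when *either* side carries a sentinel (`66`, `88`, `99` triplets,
or the `00:00:00`/`12:00:00` placeholder literals when the manual source is
flagged), correct when the absolute deviation is within tolerance (minimal
difference modulo 24 h, so midnight-straddling episodes compare sanely),
else wrong with the deviation recorded. Categorical codes must be
identical; impedance and energy require zero integer deviation. Per
variable, `summarize_audit()` reports correct/(correct + wrong) as the
match rate — missing pairs are excluded from the denominator — and the
fraction of missing pairs whose sentinel classes agree on both sides.

One reconciliation rule crosses the derive/audit boundary: when the manual
first- and last-compression triplets are both coded unknown (99) the
reviewer witnessed CPR but could not time it, so a derived "no CPR" is read
as CPR present before comparison (`reconcile_unknown_cpr`, on by default).
The `66:66:66` code is treated as "no data available" and classified
separately from `99`/`88` so that class-agreement statistics remain
informative.

## The synthetic-episode generator

No public registry episodes exist, so `simulate_episode()` emulates the
study material: a therapy duty cycle of compression sequences (mean 90 s,
clipped to 20–180 s) alternating with hands-off intervals (8–30 s), a
leading hands-off period of 45–70 s before the first compression, shocks
(1–5 per episode, 20% stacked) placed inside hands-off intervals at least
7 s long and only after rhythm annotation has begun at 20–40 s (leads on),
a 5 s discharge state, a semi-Markov rhythm process with state-specific
exponential dwell times (means: VF 120 s, VT 60 s, AS 90 s, PE 80 s, PR
150 s, clipped to 15–400 s) and a 60% chance that a shock forces a rhythm
transition 1–8 s later, a 30% chance the rhythm annotation ends early in an
UN tail, energies from {150, 200, 360} J, impedances 50–150 Ω, and episode
durations of 600–1800 s. All generated times sit on a 0.1 s grid, which
also makes the text rendering of the representation a lossless round trip.

Ground truth is computed analytically from the raw generated tables
(compressions, shocks, rhythm segments) by a code path that never touches
the sequence algebra or the review engine — the recovery tests therefore
compare two independent derivations of the same rules. `corrupt_database()`
injects sentinel codes, placeholder literals and 2–5 s jitter into a
database copy to exercise the audit's missing taxonomy and tolerance
behaviour.

What the generator does *not* emulate: ECG/impedance waveforms and their
annotation noise, reviewer disagreement about transition times, device
clock desynchronization, incomplete shock registrations, and medication or
etiology context. Passing the round-trip tests therefore demonstrates that
the reasoning rules are exact inverses of the data model under clean
annotations — not that the engine is robust to every failure mode of real
manual review, which is precisely what the audit coder is for.

## Numerical choices and degenerate inputs

Interval contiguity is validated to 1e-9 s. Zero-length states are never
stored; coincident transitions in both domains produce a single combined
transition. An episode with no shocks segments to an empty context table
with a notice. An empty restriction window result is a valid empty
sequence. Unknown power-on propagates `99:99:99` through every absolute
time variable. Checkpoint queries beyond the annotated response domain read
unknown rather than extrapolating.

Problem sizes in the shipped tests and acceptance script — 1,000 random
sequence pairs against a 0.01 s grid oracle, 200-episode recovery cohorts,
100-episode acceptance cohorts — were chosen to exercise every rule path
many times over while keeping a full run comfortable on a laptop.

## Known limitations

* ROSC is only as good as the PR annotations; pulseless and pulse-giving
  organized rhythms are otherwise indistinguishable in the representation.
* The engine assumes complete shock registrations; a missing shock row
  corrupts the window segmentation downstream (the audit's alignment check
  exists to catch this, not repair it).
* Only two domains are combined; ventilation/circulation channels would
  need an n-way merge the current algebra does not provide.
* Vendor binary log formats are out of scope; the open JSONL/CSV dialects
  defined here are the interchange contract, and adapters from device
  exports are the integrator's responsibility.
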