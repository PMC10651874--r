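# selfsound

Analysis of auditory cortical responses to self-generated sounds.

When a mouse triggers a sound with its own lever press, auditory cortex
responds more weakly than to the identical sound played at a random
time — *sensory attenuation*, a signature of corollary-discharge
signaling and a phenotype of interest in schizophrenia-risk models.
`selfsound` implements the spike-train analysis pipeline that
quantifies this effect from sorted extracellular recordings, plus a
synthetic-session generator that provides ground truth for every stage.

For a unit with mean evoked amplitudes *S* (self-generated) and *R*
(random sounds), each the firing rate 10–50 ms after sound onset minus
the 0–200 ms pre-onset baseline, the core statistic is the modulation
index

    MI = (S − R) / (S + R)

with MI = −1 meaning response only to random sounds and 0 equal
responses; MI inverts to a percent reduction
`100 (1 − (1+MI)/(1−MI))`. Around it the package provides:

* **Event selection** — refractory and behavioral-state rules for
  analyzable sounds, early/late experience blocks, preparatory press
  selection (`select_sounds()`, `split_blocks()`,
  `select_preparatory_presses()`).
* **Evoked responses** — PSTHs, per-trial amplitudes, the 2×baseline-SD
  responsiveness criterion, preparatory ramps, paired-pulse adaptation
  (`response_profile()`, `preparatory_activity()`,
  `paired_pulse_ratio()`).
* **Modulation analysis** — per-unit MI and rank-sum significance
  class, depth profiles, block comparisons, genotype summaries
  (`modulation_index()`, `depth_profile()`, `genotype_summary()`).
* **Cell typing** — waveform half-width and trough-to-peak features and
  a two-component Gaussian-mixture classifier with a 0.95 posterior
  confidence gate (`waveform_features()`, `classify_cells()`).
* **Optogenetic mapping** — bin-wise ΔFR against a surrogate-PSTH null,
  latency rule, excitatory/inhibitory criteria
  (`opto_surrogate_null()`, `classify_opto()`, `opto_map_session()`).
* **Hierarchical statistics** — the animals-then-neurons bootstrap and
  wrappers for the standard tests (`hierarchical_bootstrap()`).
* **Simulation** — configurable cohorts with known attenuation,
  adaptation, ramps, waveform classes and opto responses
  (`sim_config()`, `simulate_cohort()`, `generate_opto_session()`).

## Worked example

Simulate a small cohort (three animals per genotype, attenuation
factors 0.60 for wild type and 0.852 for the mutant) and run the full
pipeline:

```r
library(selfsound)
cfg <- sim_config(seed = 424242, n_animals_per_genotype = 3,
                  n_units_per_animal = 15, ramp_amplitude = 0)
coh <- simulate_cohort(cfg)
rep <- run_full_analysis(coh, n_boot = 1000, seed = 424242)
```

This prints (via the report's summary):

```
WT:    45/45 responsive (100.00%), MI -0.245 +/- 0.007, attenuated 100.00%
DF16A: 45/45 responsive (100.00%), MI -0.077 +/- 0.007, attenuated 46.67%
rank-sum p = 3.2e-16, hierarchical bootstrap p = 0.000
cell typing: 78 pPN, 12 pIN, 0 unclassified (13.33% pIN of classified)
```

The recovered genotype means match the analytic MI of the configured
attenuation factors, `(a − 1)/(a + 1)` = −0.25 and −0.08; the mutant
shows fewer significantly attenuated units; and the waveform classifier
recovers the simulated 14% narrow-spiking fraction. An MI of −0.25
corresponds to a 40% smaller response to self-generated sounds
(`percent_reduction(-0.25)`).

See `vignettes/attenuation-methods.Rmd` for the full account of the
measures, the generator, and the numerical conventions.

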