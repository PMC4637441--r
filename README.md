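# eegwp — wavelet-packet rhythm analysis of multichannel EEG

`eegwp` is an R package for extracting the classical EEG rhythm bands
(delta, theta, alpha, beta) from short 8-channel recordings and
summarising how their relative power differs between hemispheres,
tasks and subject groups. The motivating application is cognitive
studies of information-security awareness, where the beta share of
band power acts as a marker of attentional engagement with risk cues
(e.g. fraudulent payment prompts versus ordinary chat). It is aimed at
researchers who have — or want to simulate — event-structured
multichannel voltage records at 128 Hz on the 10–20 electrodes
Fp1, Fp2, T3, T4, C3, C4, O1, O2.

## Method

The pipeline is:

1. **Read / simulate** record tables (13 columns: tester, event,
   minutes, seconds, 8 channel voltages in µV, baseline) and split them
   into per-event epochs.
2. **Denoise**: common average reference (each channel minus the
   instantaneous 8-channel mean), then removal of content above 30 Hz
   by zeroing wavelet subbands.
3. **Decompose**: a four-level db5 wavelet-packet transform tiles
   0–64 Hz into 16 subbands of width Δf = (1/2⁴)(f_s/2) = 4 Hz.
   Natural (Paley) node order is converted to frequency order by the
   Gray-code permutation, and bands map to frequency-ordered leaves
   S(4, i): delta → {0}, theta → {1}, alpha → {2}, beta → {3,…,7}
   (12–32 Hz). The underlying cascade satisfies the multiresolution
   identity f₀ = f_N + d_N + … + d₁ to machine precision.
4. **Features**: per channel and band, *rhythm energy* E_b / E_total
   (share of all 16 subbands) and *energy ratio* E_b / Σ₄ E_b (share of
   the four rhythm bands; sums to 1, gain-invariant).
5. **Contrasts**: descriptive left-right homologous-pair differences,
   task differences, trained-vs-untrained group means, and region
   summaries of a band's energy ratio.

A deterministic synthetic generator produces cohorts in the same record
layout with known band fractions, event/gap structure (9 scenes,
1000–2000 ms inter-stimulus intervals), and injectable hemispheric /
task / training effects, giving every stage a ground truth.

## Worked example

```r
library(eegwp)

cfg <- headline_preset(seed = 1)          # 12 subjects, 4 trained, 9 scenes
sim <- simulate_cohort(cfg)
res <- run_pipeline(sim$recordings, task_map = cfg$task_map,
                    groups = sim$groups)
res
#> <pipeline_result> 108 epochs, 768 feature rows, band beta
#>   hemisphere left=0.3096  right=0.2712
#>   region     frontal=0.2917  occipital=0.2877  parietal=0.2911
#>   task       online chat=0.2689  online payment=0.3119
#>   training   trained=0.3138  untrained=0.2787

res$contrasts$hemisphere
#> <contrast_report> band beta by hemisphere
#>   group means: left = 0.3096, right = 0.2712
#>   larger group: left
#> # A tibble: 4 × 5
#>   left  right left_ratio right_ratio difference
#>   <chr> <chr>      <dbl>       <dbl>      <dbl>
#> 1 Fp1   Fp2        0.312       0.272     0.0399
#> 2 T3    T4         0.310       0.273     0.0376
#> 3 C3    C4         0.312       0.270     0.0413
#> 4 O1    O2         0.305       0.270     0.0348
```

Reading the numbers: every left electrode carries a higher beta energy
ratio than its right homologue (the injected 1.3 left boost recovered
as a ~0.04 ratio difference), the online-payment task sits above online
chat (0.3119 vs 0.2689), and trained subjects above untrained (0.3138
vs 0.2787) — the three directional effects the preset encodes.
`plot_band_ratio(res$features, "beta")` draws the per-channel bar chart
of the task contrast.

A thin command-line wrapper is installed at `inst/cli/eegwp.R`:

```sh
Rscript inst/cli/eegwp.R simulate --seed 1 --dir records/
Rscript inst/cli/eegwp.R run --input records/ --output results/
```

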