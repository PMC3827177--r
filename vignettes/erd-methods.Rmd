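---
title: "Spectral ERD methods: from raw epochs to onset and depth"
author: "erdvoice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral ERD methods: from raw epochs to onset and depth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette documents the analysis conventions the package implements,
why two different depth readouts exist, and which one to use.

## Epochs, baseline, and the Welch grid

Perception epochs span [−1, +5] s around stimulus onset and production
epochs [−1, +6] s around the Go signal, both at 512 Hz, so they hold
exactly 3072 and 3584 samples. Band power inside an analysis window is a
Welch estimate: 512-point Hann segments with 50 % overlap, zero-padded to
1024 points, which puts the spectral grid at exactly 0.5 Hz. The mu band
is 7.5–12 Hz, low beta 14–21 Hz; band values are overlap-weighted mean
densities (µV²/Hz), so estimates from different grids are comparable.

The baseline is deliberately different: a single 256-point Hann
periodogram of the [−0.5, 0] s pre-event interval (2-Hz bins). The ERD
value reported per trial, electrode and window is

```
erd = band_density(window, 512-pt Welch) - band_density(baseline, 256-pt periodogram)
```

averaged over trials within condition and then over each region's
electrodes (`erd()`).

```{r}
library(erdvoice)
prof <- make_cohort(3, rng_seed = 1)[1, ]
sch  <- make_schedule(40, rng_seed = 1)
raw  <- simulate_eeg(prof, sch, rng_seed = 1)
ep   <- preprocess(raw)$perception
bp   <- erd(ep)          # band_power_table with per-trial values attached
head(bp)
```

## Why subtraction and ratio disagree: taper leakage

A 0.5-s Hann taper has a ~4-Hz-wide main lobe; the 1-s analysis taper's
lobe is half that. A narrowband source (the simulated mu rhythm has a ~2 Hz
bandwidth) therefore loses more of its power to out-of-band leakage in the
short baseline window than in the analysis windows. The subtractive ERD
above inherits that mismatch as a constant positive offset: with no
modulation at all, `erd` sits slightly above zero over electrodes that see
a narrowband source. For detecting *when* power drops this is harmless —
the offset is the same in every window, so the ordering of conditions is
untouched — but dividing `-erd` by the baseline misestimates the
*fractional* drop.

`erd_depth()` avoids the mismatch entirely by staying on one grid: it
compares mean band power between a window before the expected onset and a
window after it, both at the analysis resolution,

```
depth = 1 - mean(power[post]) / mean(power[pre])
```

For a source whose amplitude falls by a factor (1 − d), the expected value
is 1 − (1 − d)², diluted toward zero by whatever broadband background
power shares the band. Read fractional depth from `erd_depth()`, never
from `-erd / baseline`.

```{r}
erd_depth(bp, "mu", c("FC_L", "FC_R"), "vocal",
          pre_window = "w1", post_window = "w3")
```

## Onset estimation

The five windows `w1`–`w5` tile the 0–5 s span between stimulus onset and
the Go signal in 1-s steps. `erd_onset()` walks them in order and returns
the start time of the first window whose condition-mean ERD lies below −2
standard errors of zero (SE across trials); `Inf` means no window reached
criterion. Because the leakage offset is common to all windows, it only
costs sensitivity, not validity: a detected onset is still ordered
correctly between conditions.

```{r}
erd_onset(bp, "mu", c("FC_L", "FC_R"), "vocal")     # ~1 s
erd_onset(bp, "mu", c("FC_L", "FC_R"), "nonvocal")  # ~3 s or Inf
```

## Regions, mixing, and where to test what

The six regions of interest pair a left/right side with an
anteroposterior gradient: fronto-central (F1/F3/FC1 and F2/F4/FC2),
centro-parietal (C1/C3/CP1, C2/C4/CP2) and parieto-occipital (PO3/PO7/O1,
PO4/PO8/O2). The simulator gives each gradient's source a Gaussian scalp
footprint (SD 0.25 in montage units), so neighbouring regions mix: a deep
fronto-central desynchronization bleeds into centro-parietal electrodes
and can mask the much smaller posterior synchronization there. Recovery
claims about onset and depth are therefore made at the fronto-central
regions, where the driving source dominates its own electrodes; the
posterior ERS remains part of the simulation truth but is not a reliable
single-region readout at realistic noise levels.

## Statistics downstream

`run_pipeline()` feeds the region-averaged ERD values into fully
within-subject ANOVAs (condition × gradient × side for the main perception
window; condition × window for the fronto-central time course) with
Greenhouse-Geisser correction, Tukey HSD or Fisher LSD post-hocs on the
matching subject-by-effect error term, a permutation Spearman correlation
between each participant's sung-interval inaccuracy and their
vocal-minus-non-vocal fronto-central beta ERD difference, and a paired t
test on EMG band power (production vs perception) to document that the
perception epochs are free of overt vocalization.

```{r}
res <- run_pipeline(default_config(seed = 1L), "run-out")
res$recovery
res$stats$accuracy_effect_spearman
```
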