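# nirsgraph

Graph-closeness intersubject similarity analysis for multichannel fNIRS
recorded under **naturalistic stimulation** (movie watching, free play) —
paradigms with no event structure, hence no GLM design matrix, and far too
many channel × frame combinations for mass-univariate testing.

**Who it is for.** Researchers with frame-aligned multichannel hemodynamic
recordings from several participants who all received the same time-locked
naturalistic stimulus, asking: *did the stimulus drive participants into
similar cortical states, and if so, when and where?*

## The method

At every frame `t`, each participant contributes a state vector
`x_p(t) ∈ R^C` (their `C` long-channel values). The pairwise Euclidean
distances `d_ij(t) = ||x_i(t) − x_j(t)||` are the edge lengths of a
complete weighted graph with one node per participant. Freeman-normalised
closeness

```
c_i(t) = (N − 1) / Σ_j d_ij(t)
```

is high exactly when participant `i` is near everyone else; the mean over
nodes scores the frame, and the mean over frames is the single test
statistic `S`. Significance comes from a circular-permutation null: each
participant's whole multichannel series is rotated by an independent random
offset (preserving autocorrelation and cross-channel correlation exactly,
destroying stimulus alignment), the statistic is recomputed `B` times, and

```
p = (1 + #{S*_b ≥ S}) / (B + 1)       (one-sided; min p = 1/(B+1))
```

After rejection, two descriptive follow-ups: the top-5% closeness frames
(mapped back to stimulus time with a 5 s hemodynamic-delay correction) and
leave-one-channel-out relevance (channels whose removal most reduces
closeness, summarised as the frequency of being in the per-frame top-25%
set). A full preprocessing chain (modified Beer–Lambert, wavelet
despiking, 0.01–0.08 Hz zero-phase band-pass, short-separation channel
regression, variance-one scaling), a synthetic group generator with known
ground truth, plain-text and SNIRF readers, and a CLI are included. See
`vignettes/intersubject-similarity.Rmd` for models, assumptions and design
decisions.

## Worked example

Simulate a group with a shared response in channels 3 and 7 around two
stimulus events, then run the full analysis:

```r
library(nirsgraph)

cfg <- simulation_config(
  n_participants = 10, n_long_channels = 12, n_short_channels = 0,
  n_frames = 780, fs = 7.81,
  event_onsets = c(15, 55), event_duration = 10,
  responsive_channels = c(3, 7), effect_size = 3, seed = 42)
sim <- simulate_group(cfg)

res <- intersubject_similarity_test(sim$group, B = 999, seed = 1)
res
#> Intersubject similarity permutation test
#>   observed mean closeness: 0.218039
#>   null (999 circular permutations): mean 0.199411, max 0.205911
#>   p-value: 0.001  (minimum attainable 0.001)

frames <- top_frames(res$per_frame)        # top 5% closeness frames
head(frame_timestamps(frames), 3)          # 5 s HRF-delay-corrected
#>   frame  seconds  mmss
#> 1   160 15.48656 00:15
#> 2   164 15.99872 00:15
#> 3   169 16.63892 00:16

channel_relevance(sim$group)
#> <channel_relevance> 12 channels, 3 marked per frame (top 25%)
#>   ch3      in top set  46.9% of frames
#>   ch7      in top set  45.3% of frames
#>   ch12     in top set  31.7% of frames
#>   ch11     in top set  28.3% of frames
#>   ch4      in top set  24.4% of frames
```

Reading the output: the observed mean closeness (0.218) exceeds every one
of the 999 permuted statistics, so `p = 1/1000` — the finest p-value `B`
permutations can resolve; the earliest selected frames land at stimulus
times near the first event onset (15 s); and the two channels that truly
carry the shared response (ch3, ch7) top the relevance ranking. Here 82%
of the selected frames fall inside the ground-truth response windows
(`mean(frames$frames %in% sim$truth$response_frames)`).

## Command line

```sh
Rscript inst/cli/nirsgraph simulate --out sim --seed 11 --config sim.cfg
Rscript inst/cli/nirsgraph test --data sim --permutations 999 --seed 1 --out run1
Rscript inst/cli/nirsgraph map-channels --data sim --out run1
Rscript inst/cli/nirsgraph report --data sim --seed 1 --out report.json
```

(after installation the launcher also lives at
`system.file("cli", "nirsgraph", package = "nirsgraph")`). Every command
accepts `--seed`, `--config` and `--log-level`; results are byte-identical
under a fixed seed. Exit codes: 0 success, 1 data error, 2 usage error.

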