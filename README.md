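# emgdecomp

Decomposition of single-channel intramuscular EMG recordings into their
constituent motor unit action potential (MUAP) trains.

An intramuscular EMG signal is the sum of the spike trains of the motor
units (MUs) close to the needle electrode: each discharge of a unit adds a
stereotyped waveform, its MUAP, to the trace. Decomposition inverts that
process — it recovers each unit's template waveform and the times at which
it fired. Clinicians and motor-control researchers use the result to read
firing statistics and waveform morphology, both of which change in
neuropathies, myopathies and after stroke.

The pipeline has six stages, orchestrated by `decompose_emg()`:

1. **wavelet de-noising** — periodized db5 DWT; sub-bands outside
   30 Hz–8 kHz zeroed; retained details hard-thresholded at the universal
   threshold `σ̂·sqrt(2 ln N)`;
2. **segment detection** — amplitude threshold `T = k·σₙ` with the noise
   RMS `σₙ` taken from the quietest 1.25 ms window of the raw record;
   resting-epoch recognition extracts every active span, expanded 0.2 ms;
3. **phasic partition** — a phase is a baseline excursion reaching `T`;
   segments with ≤ 1 phase or < 1.5 ms are invalid, segments with more
   phases than the phase template (4 healthy / 6 stroke) are superimposed,
   the rest are isolated single MUAPs;
4. **alignment + features** — main-peak centring on a power-of-two support;
   features are db5 DWT detail coefficients, levels 3–6; similarity is the
   normalized error variance
   `d(s₁,s₂) = (E(e²) − E²(e)) / (E(s₁²) + E(s₂²))`, `e = s₁ − s₂`;
5. **MST clustering + refinement + supervised classification** —
   single-linkage clustering by cutting the largest minimum-spanning-tree
   edges; refinement deletes (< 3 members), splits (internal gap edge) and
   merges (sub-floor bridge) clusters; the pooled rest is assigned by a
   minimum-distance classifier with weighted-averaging template adaptation;
6. **peel-off superposition resolution** — pseudo-correlation
   `PsC_k = Σⱼ(xⱼy_{k+j} − |xⱼ−y_{k+j}|·max(|xⱼ|,|y_{k+j}|)) / Σⱼ max(|xⱼ|,|y_{k+j}|)²`
   scanned over all offsets; best match subtracted; stops on a non-positive
   score, a residual-energy increase, or after 3 peels.

A synthetic-signal generator (`simulate_emg()`) with known ground truth and
the three performance indices (`evaluate_decomposition()`: DR%, AR%, CCR%)
complete the toolkit. Everything is also reachable from a command-line
interface.

## Worked example

```r
library(emgdecomp)

sim <- simulate_emg(n_mus = 6, duration_s = 5, snr_db = 20, seed = 1)
sim$record
#> <emg_record> 150000 samples @ 30000 Hz (5.000 s), range [-753.6, 696.5] uV

res <- decompose_emg(sim$record, verbose = TRUE)
#> segments: 387 total, 197 isolated, 55 superimposed, 135 invalid
#> clustering: 12 initial clusters, 6 classes after refinement, 6 pooled
#> classification: threshold 2040, 4 of 6 pooled assigned
#> events: 333 assigned, 0 unassigned
res
#> <emg_decomposition> 6 trains, 333/333 events assigned (387 segments: 197 iso / 55 sup / 135 invalid)
#>   class 1: 45 firings, template 82 samples
#>   class 2: 56 firings, template 93 samples
#>   ...

evaluate_decomposition(res, sim$truth)
#> DR%  = 100.00  (333 of 333 true discharges covered; MU-level 100.0%)
#> AR%  = 100.00  (333 of 333 detected events assigned)
#> CCR% =  96.70  (322 of 333 detected events correct within tolerance)
```

Reading the output: all 333 true discharges fell inside detected active
segments (DR%), every detected MUAP event ended up in some train (AR%), and
96.7% of the events were assigned to the right unit within ±0.5 ms of the
true discharge time (CCR%); the per-MU table shows each recovered template
correlating with its true waveform at r ≥ 0.999. The 135 "invalid" segments
are sub-threshold noise blips excluded by the one-phase/1.5 ms validity
rule; the misses hide in near-coincident superpositions, the known failure
mode of template peel-off.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "emgdecomp.R", package = "emgdecomp"))')
Rscript $CLI simulate  --duration 5 --n-mus 6 --snr-db 20 --seed 1 \
                       --out signal.csv --truth truth.json
Rscript $CLI decompose --in signal.csv --out result.json
Rscript $CLI evaluate  --result result.json --truth truth.json
```

Signals travel as plain text (`# fs=<Hz>` header, one µV sample per line);
structured data (truth, results, segment lists, reports) as JSON.

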