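# mpquant

Quantitative analysis of micropatterned stem-cell colonies and the beating
cardiac microtissues they form.

When colonies of human induced pluripotent stem cells are geometrically
confined on circular adhesive micropatterns and pushed toward mesoderm,
they self-organize: cells condense into a dense, OCT4-positive annulus at
the pattern perimeter while centre cells migrate directionally outward, and
over two weeks the colony becomes a three-dimensional beating cardiac
microchamber. `mpquant` is the analysis layer for such experiments. It
covers three readouts, each exercisable end to end on synthetic inputs with
known ground truth:

* **Migration** — mean-square displacement (MSD) of single-cell tracks by
  the overlapping-interval method, persistent-random-walk (PRW) model fits,
  and per-cell "biased" vs "random" classification, split by
  centre/perimeter region.
* **Spatial patterning** — 15-µm annulus density maps of circular colonies,
  marker-positive fractions (OCT4, EdU, ...), nucleus shape index, spatial
  cell density ratio, and two-term power fits of intensity-vs-thickness
  profiles.
* **Contraction** — block-matching motion estimation on image stacks of
  beating tissue, motion waveforms, beat frequency, maximal contraction
  velocity, contraction heatmaps, and two-group condition comparisons.

## The model at the core

A persistently migrating cell has velocity correlation time *P* and
root-mean-square speed *S*; its MSD follows

    MSD(t) = 2 S² P [ t − P (1 − e^(−t/P)) ],

ballistic (∝ t²) for t ≪ P and diffusive (∝ t) for t ≫ P, with random
motility coefficient µ = S²P/n_d (n_d = 2 in the plane). `fit_prw()`
inverts this form from an MSD curve by weighted nonlinear least squares;
cells with a good fit and µ > 5 µm²/min (strict) are classified "biased".
Tracks whose initial position lies more than 100 µm from the centre of a
400-µm pattern count as perimeter cells.

## Worked example

Simulate a cohort of PRW tracks, pool their MSDs and recover the
parameters:

```r
library(mpquant)

tracks <- simulate_prw_cohort(50, persistence_time = 60, speed = 0.5, seed = 1)
curves <- lapply(tracks, compute_msd)
pooled <- curves[[1]]
pooled$msd <- rowMeans(sapply(curves, `[[`, "msd"))
fit_prw(pooled)
#> <prw_fit: P = 65.1 min, S = 0.503 um/min, mu = 8.25 um^2/min,
#>   rel. residual = 0.00294, converged = TRUE, class = NA>
```

The pooled fit lands within ~9% of the generating P = 60 min and within 1%
of S = 0.5 µm/min; µ = S²P/2 = 8.25 µm²/min would classify these cells
biased (µ > 5).

A condensed colony — 3× denser band at 150–200 µm, marker probabilities
0.9 in the band and 0.1 elsewhere — quantified with the default 400-µm,
15-µm-annulus geometry and 100-µm region boundary:

```r
col  <- simulate_colony(seed = 1)
dmap <- annulus_density_map(col, attr(col, "geometry"))
spatial_density_ratio(dmap)$ratio
#> [1] 2.015145
marker_positive_fraction(col, "OCT4", by_region = TRUE)[c("centre", "perimeter")]
#> $centre
#> [1] 0.09122807
#> $perimeter
#> [1] 0.7451895
```

The density ratio of 2.02 sits near its generative expectation of 2.17
(one 2000-cell colony; pooling colonies tightens it), and the perimeter
marker fraction reflects the band/off-band mixture within the perimeter
region.

Contraction analysis of a synthetic 1.2-Hz beating stack:

```r
st <- simulate_beating_stack(beat_frequency = 1.2, peak_velocity = 10,
                             n_frames = 200, image_size = 96, seed = 1)
detect_beats(motion_waveform(block_match_motion(st)))
#> <beat_summary: 1.2 Hz, max contraction velocity 9.76 um/s, 23 peaks>
```

Detected frequency is exact to the peak-time quantization and the peak
contraction velocity is within 3% of the configured 10 µm/s.

`run_pipeline()` chains the stages over CSV/TIFF inputs and writes one JSON
report with provenance; `inst/scripts/mpq.R` wraps the generators and the
pipeline for shell use.

## Documentation

The methods vignette (`vignettes/micropattern-quantification.Rmd`) explains
the PRW model and its estimator choices, the annulus and region
conventions, the block-matching design (including why the default cost is
SSD rather than SAD), what the synthetic generators do and do not emulate,
and known limitations.
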