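# File formats

Positions are always µm; track times are minutes; contraction times are
seconds.

## Track CSV (`write_tracks_csv` / `read_tracks_csv`)

One row per sample.

| column  | type    | meaning                                   |
|---------|---------|-------------------------------------------|
| cell_id | string  | cell identifier (one track per id)        |
| frame   | integer | 0-based frame index                       |
| t_min   | numeric | sample time, minutes, uniformly spaced    |
| x_um    | numeric | x position, µm, pattern-centred frame     |
| y_um    | numeric | y position, µm                            |
| region  | string  | `centre` / `perimeter` / `NA` (derived)   |

## Nuclei CSV (`write_nuclei_csv` / `read_nuclei_csv`)

One row per nucleus.

| column          | type    | meaning                                 |
|-----------------|---------|------------------------------------------|
| nucleus_id      | string  | identifier                               |
| x_um, y_um      | numeric | centroid, µm, pattern-centred frame      |
| major_um        | numeric | longest nucleus axis, µm                 |
| minor_um        | numeric | shortest nucleus axis, µm                |
| orientation_rad | numeric | major-axis orientation in [0, π)         |
| region          | string  | generator label (`inner`/`band`/`outer`) |
| `<marker>`      | logical | one column per marker flag (e.g. OCT4)   |

## Image stacks (`write_stack_tiff` / `read_stack_tiff`)

Multi-page grayscale TIFF, 16 bits per sample, intensities scaled by
`scale_max` (default 255) into [0, 1] on disk. Frame rate (frames/s) and
pixel size (µm/pixel) are not stored in the file and must be supplied on
read.

## Density map CSV (`write_density_csv`)

One row per annulus: `annulus` (1-based from the centre), `inner_um`,
`outer_um`, `count`, `area_um2`, `density` (cells/µm²). The terminal
annulus is truncated at the pattern radius; its true area is used.

## Waveform CSV (`write_waveform_csv`)

One row per inter-frame midpoint: `time_s`, `mean_speed` (µm/s over
confident blocks; `NA` when no block is confident), `n_confident`.

## Pipeline report (`run_pipeline(report_path = ...)`)

JSON with one object per executed stage (`tracks`, `spatial`,
`contraction`), a `provenance` object (package version, config MD5 hash,
seed) and `failed_stages`. Deterministic for fixed config, inputs and
seeds.

## Configuration YAML (`load_config` / `write_config`)

Sections `pattern` (`diameter`, `centre`, `annulus_width`), `tracks`
(`dt_min`, `n_frames`, `radial_threshold`, `mu_threshold`, `gof_threshold`,
`max_lag_fraction`), `contraction` (`frame_rate`, `n_frames`, `pixel_size`,
`block_size`, `search_radius`, `step`, `min_prominence`, `min_separation`),
plus `seed` and `output_dir`. Omitted fields take the documented defaults.
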