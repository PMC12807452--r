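# spotcoloc

Colocalization and randomization-null analysis of punctate fluorescence
images in R.

## What problem this addresses

Many questions in cell biology reduce to: *are the puncta in one fluorescence
channel closer to the puncta in another channel than chance would put them?*
Typical inputs are 2D rasters of labeled structures — proximity-ligation
puncta, single-molecule FISH transcript spots, or binarized super-resolution
localization maps of membrane-protein clusters — together with a traced cell
perimeter and, optionally, organelle masks (plasma-membrane band, ER, ER exit
sites, Golgi). `spotcoloc` implements the full quantification chain for such
data:

- **Particle extraction** — connected-component labeling (4- or
  8-connectivity) with physical-unit areas (nm²), densities per 10/100 µm²,
  and a minimum-area filter (conventionally 400 nm² for super-resolution
  maps, the imaging resolution limit).
- **Overlap colocalization** — the two binary channels are multiplied; a
  particle counts as colocalized when ≥ 1 of its pixels lies in the product
  mask. Object- and area-level percentages are reported in *both*
  directions, because the denominator channel matters.
- **Compartment classification** — each punctum is assigned inside/outside
  an organelle mask by centroid (default) or any-pixel overlap.
- **Proximity statistics** — exact edge-to-edge nearest-distance
  distributions (via an exact Euclidean distance transform), the fraction of
  particles within a distance *d* (e.g. 200 nm) of the partner channel, and
  the cumulative dilation ("ring") profile: channel A dilated by 20, 40, 60,
  80, 100, 200 nm, each dilation multiplied with channel B, and the captured
  B fraction normalized to the 200 nm value.
- **Randomization null** — a particle-preserving scrambler redraws every
  particle as a circle of equal area (radius √(area/π)) at a uniform random
  position inside the cell perimeter, keeping particle number exactly and
  total area to well under 1 % on average; colocalization of the scrambled
  channel against the genuine partner gives the chance baseline
  (conventionally averaged over three trials).
- **Synthetic scenes** — a generator produces polygonal cells, organelle
  masks, and coupled two-channel particle fields in which a fraction *f* of
  B particles is planted within an edge-to-edge distance δ of A particles,
  with full ground truth, so every statistic above can be validated against
  known answers.

## Worked example

```r
library(spotcoloc)

# a synthetic cell with two coupled channels (60% of B within 40 nm of A)
geom <- make_cell_geometry(seed = 11, radius_px = 400, irregularity = 0.2)
cfg  <- sim_config(pixel_size_nm = 25, density_A = 134, density_B = 33,
                   coupling_fraction = 0.6, coupling_distance_nm = 40,
                   area_median_nm2 = 30000, area_sigma = 0.4, seed = 13)
sim  <- simulate_coupled_particles(geom, cfg)

overlap_coloc(sim$A, sim$B)
#> <coloc_result> n_A = 361, n_B = 85
#>   object: A->B 16.3%, B->A 69.4%
#>   area:   A->B 7.2%, B->A 29.4%

bl <- scrambled_baseline(sim$A, rasterize(sim$B), geom,
                         n_trials = 3, base_seed = 41)
round(unname(bl$baseline["object_pct_A_to_B"]), 1)
#> [1] 3.5
```

Reading: 69.4 % of the sparser B puncta overlap an A punctum (most B puncta
were planted near A), while only 16.3 % of the abundant A puncta touch a B
punctum — the direction of the denominator changes the number, which is why
both are always reported. Scrambling A while preserving its particle number
and sizes drops its object colocalization to 3.5 %, so the genuine signal
far exceeds chance for these densities and sizes.

The numbered scripts under `analysis/` run this workflow end to end
(simulate → particle statistics → colocalization/compartments → scrambled
null → ring profiles) and write their tables under `results/`.

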