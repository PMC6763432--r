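# prismr

Quantitative analysis of probe-based sequential multiplexed (PRISM-style)
fluorescence imaging of neuronal cultures, and post-processing of DNA-PAINT
single-molecule localization data.

In PRISM-style multiplexed imaging, each antibody (or peptide) carries a
short single-stranded DNA docking strand, and targets are imaged one at a
time by sequential exchange of complementary fluorescent imaging probes —
high-affinity locked-nucleic-acid (LNA) probes for confocal imaging, or
transiently binding DNA probes for PAINT super-resolution. A dozen or more
synaptic and cytoskeletal proteins can thus be profiled in the same neurons,
yielding per-synapse protein co-expression profiles at scale. `prismr`
implements the computational side of that workflow:

* **Synthetic data with ground truth** — dendrite-localized synapse punctae
  with correlated lognormal per-channel intensities and sub-type mixtures,
  illumination vignetting, inter-round stage drift, Poisson + Gaussian
  camera noise, nuclei and intranuclear decoy punctae
  (`simulate_confocal_dataset`); PAINT-style localization streams with
  docking-site geometries, fiducial markers and smooth drift
  (`simulate_localization_dataset`); and a direct feature-table generator
  for the statistical stages (`simulate_synapse_table`). No public raw data
  exist for this assay, so every downstream stage is validated against
  these generators.
* **Preprocessing** — flat-field correction from morphological-opening
  backgrounds averaged per channel and plate
  (`estimate_background`, `estimate_illumination_profile`,
  `flat_field_correct`), and inter-round rigid registration by the peak of
  the normalized spatial cross-correlation of the MAP2 reference channel
  (`estimate_xy_drift`, `register_rounds`).
* **Segmentation** — percentile contrast stretch, adaptive 5×5 Wiener
  denoising and white top-hat enhancement (`enhance_punctae`), an
  object-count-maximizing threshold scan (`optimal_object_threshold`),
  watershed splitting of touching punctae (`split_touching`), synapse
  calling by the strict 0.42 µm² synapsin-area gate with nuclear exclusion
  (`detect_synapses`), and channel-to-synapse assignment by
  intensity-weighted centroid distance < 1 µm (`colocalize`).
* **Single-synapse statistics** — feature tables with the zero-fill rule
  for absent punctae (`extract_features`), two-stage image→well averaging
  (`summarize_wells`), batch-averaged Pearson correlation networks with a
  strict r > 0.35 edge rule (`pairwise_correlations`), two-tailed Student's
  t treatment comparisons (`compare_groups`), replicate-centered
  correlation-difference tests (`correlation_difference_test`), log/SD/min
  feature normalization, exact-method t-SNE with PCA initialization
  (`embed_tsne`), kernel-density sub-type maps (`density_regions`) and
  Ward/Euclidean hierarchical clustering (`cluster_profiles`).
* **PAINT post-processing** — fiducial track identification
  (`identify_fiducials`), LOESS drift estimation averaged over fiducials
  (`estimate_drift_loess`), drift correction (`correct_drift`), 5.4 nm 2D
  histogram rendering (`render_histogram`), angle-averaged normalized
  radial cross-correlation with a 1/e decay-length readout
  (`radial_cross_correlation`), and trans-synaptic 1D profiles with median
  and Gaussian-fit FWHM (`transsynaptic_profile`).
* **LNA probe design** — the empirical cross-hybridization cost optimizer:
  append the 3′ AA anchor, enumerate partially complementary regions
  against all docking strands, and exhaustively search all
  C(L, 3) LNA substitution schemes for the minimal-cost placement
  (`design_lna_scheme`).

## Worked example

Simulate a default 512 px, 11-channel, 4-round field with 200 planted
synapses and run the full profiling pipeline:

```r
library(prismr)
res <- run_pipeline(run_config(simulate = sim_config(seed = 7L), seed = 7L))

res$shifts
#  round dx dy       ncc
#      1  0  0 1.0000000
#      2  6  7 0.5062199
#      3  0 -3 0.5037174
#      4  1  4 0.5034843
```

The estimated per-round shifts (dx, dy, in pixels) reproduce the planted
stage drift exactly (`res$truth$drift`). After flat-field correction,
registration, segmentation and colocalization, the synapse table holds one
row per synapse with per-channel integrated intensity, area and mean
intensity — zeros mark channels with no colocalized punctum:

```r
res$synapse_table[1:3, c("synapse_id", "synapsin_intensity",
                         "PSD95_intensity", "PSD95_area_um2")]
#  synapse_id synapsin_intensity PSD95_intensity PSD95_area_um2
#           1           234530.5     155815.6130      10.001134
#           2           245462.2        448.7598       0.279752
#           3           170698.0     183993.9226      10.001134
```

The strongest correlation-network edges recover the planted block
structure (post-synaptic density proteins together, pre-synaptic proteins
together):

```r
head(res$network$edges[order(-res$network$edges$r), ], 5)
#        a       b         r
#   Homer1  SHANK3 0.8876240
#    PSD95  SHANK3 0.8868953
#    PSD95  Homer1 0.8760243
#  bassoon  VGLUT1 0.6990029
# synapsin bassoon 0.6555798
```

Design the LNA substitution scheme for an imaging probe against a docking
panel (the shipped panel is synthetic demo data):

```r
design_lna_scheme("ATACATCTAGT", demo_docking_panel(), cognate = "p1")
# lna_scheme: ATACATCTAGTAA
#   LNA at 0-based positions {0, 9, 10}, cost 16 (286 schemes searched)
```

A thin command-line wrapper over these functions ships at
`inst/cli/prism.R` (`Rscript prism.R simulate-confocal|flatfield|register|
segment|probe-design|paint-drift|paint-render|run ...`).

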