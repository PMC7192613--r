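# Shared synthetic-gel fixtures.  Study conditions: 24 Mb haploid genome,
# DNA sheared to ~50 kb pieces (480 molecules), 500 ribonucleotide-
# independent background breaks per genome, SYBR-scan noise dominated by a
# signal-dependent component with peak signal-to-noise 25 and a constant
# background at 1% of the peak signal.

exact_calibration <- function(a = 230, b = -20,
                              sizes = c(100, 1000, 10000)) {
  fit_ladder(data.frame(distance_mm = a + b * log(sizes), size_nt = sizes))
}

# Render a full lane set (sample, control, empty, ladder) for one strain.
sim_lane_set <- function(n_rnmp, seed, n_molecules = 480,
                         n_background = 500, snr = 25, bg_frac = 0.01,
                         band_sigma = 0.5, genome_size = 24e6) {
  frags <- simulate_fragments(genome_break_config(
    genome_size = genome_size, n_rnmp = n_rnmp,
    n_molecules = n_molecules, n_background = n_background, seed = seed))
  peak <- attr(render_lane(frags, gel_render_config(band_sigma = band_sigma)),
               "metadata")$signal_peak_au
  gel <- function(s) gel_render_config(
    band_sigma = band_sigma, background = bg_frac * peak,
    poisson_gain = peak / snr^2, seed = s)
  ctl_frags <- simulate_fragments(genome_break_config(
    genome_size = genome_size, n_rnmp = 0, n_molecules = n_molecules,
    n_background = n_background, seed = seed + 1L))
  list(frags = frags, ctl_frags = ctl_frags,
       lane = render_lane(frags, gel(seed + 2L), "sample"),
       control = render_lane(ctl_frags, gel(seed + 3L), "control"),
       empty = render_empty_lane(gel(seed + 4L)),
       ladder = render_ladder(gel(seed + 5L), band_mass = 3 * peak),
       gel_cfg = gel(seed + 2L))
}

# Full per-lane quantitation of a simulated lane set; returns the sample
# fit with the control subtracted.
quantify_set <- function(set, ...) {
  suppressWarnings({
    cfit <- rnmp_fit(set$control, ladder = set$ladder, empty = set$empty,
                     background = "empty_lane", ...)
    rnmp_fit(set$lane, ladder = set$ladder, empty = set$empty,
             background = "empty_lane", control = cfit, ...)
  })
}

# Recount oracle: a fragment-count table built from perfectly measured
# fragment sizes (one row per fragment), censored below sz_min.  Feeds the
# same normalization / correction code path with exact inputs.
table_from_sizes <- function(sizes, sz_min = 0, lane_id = "oracle") {
  structure(
    data.frame(mid_mm = NA_real_, size_nt = as.numeric(sizes),
               intensity_au = as.numeric(sizes), n_sz = 1,
               n_per_gb = NA_real_, excluded = sizes < sz_min),
    cutoff = list(d_max_mm = NA_real_, sz_min_nt = sz_min, manual = TRUE,
                  crossed = TRUE),
    lane_id = lane_id,
    class = c("fragment_count_table", "data.frame")
  )
}

# Minimal hand-built normalized table with a prescribed per-Gb spectrum.
table_from_per_gb <- function(size_nt, n_per_gb, sz_min = 0) {
  structure(
    data.frame(mid_mm = NA_real_, size_nt = size_nt,
               intensity_au = NA_real_, n_sz = n_per_gb,
               n_per_gb = n_per_gb, excluded = FALSE),
    cutoff = list(d_max_mm = NA_real_, sz_min_nt = sz_min, manual = TRUE,
                  crossed = TRUE),
    lane_id = "manual",
    class = c("fragment_count_table", "data.frame")
  )
}
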