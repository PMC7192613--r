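#' Configuration for random genome breakage
#'
#' Describes the alkali-fragmentation of a single-stranded genome carrying
#' embedded ribonucleotides.  Each embedded ribonucleotide is a break point;
#' the intact starting molecules (sheared chromosome pieces) contribute
#' end-terminated fragments as well.  Breaks can be placed uniformly along
#' the genome or concentrated in hotspots for robustness studies, and an
#' extra count of ribonucleotide-independent background breaks (the breakage
#' a control strain would show) can be added.
#'
#' @param genome_size genome length in nt (default 24e6, the haploid yeast
#'   genome).
#' @param n_rnmp number of embedded ribonucleotides, i.e. alkali break
#'   points.
#' @param placement `"uniform"` or `"clustered"`.
#' @param cluster_params list with `n_hotspots` (number of hotspot windows),
#'   `break_fraction` (fraction of breaks confined to the hotspots) and
#'   `span_fraction` (fraction of the genome the hotspots jointly cover).
#'   Used only when `placement = "clustered"`.
#' @param n_molecules number of starting DNA molecules loaded in the lane;
#'   their ends terminate fragments.  Default 16 (yeast chromosome count);
#'   sheared preparations are emulated with larger values.
#' @param n_background additional ribonucleotide-independent uniform breaks
#'   (default 0).
#' @param seed integer seed; all randomness in [simulate_fragments()] derives
#'   from it.
#'
#' @return An object of class `genome_break_config`.
#' @export
genome_break_config <- function(genome_size = 24e6, n_rnmp,
                                placement = c("uniform", "clustered"),
                                cluster_params = list(n_hotspots = 10,
                                                      break_fraction = 0.9,
                                                      span_fraction = 0.01),
                                n_molecules = 16, n_background = 0,
                                seed = NULL) {
  placement <- match.arg(placement)
  stop_if_not_scalar_pos(genome_size, "genome_size")
  if (n_rnmp < 0 || n_molecules < 1 || n_background < 0) {
    stop("n_rnmp and n_background must be >= 0, n_molecules >= 1",
         call. = FALSE)
  }
  structure(list(genome_size = as.numeric(genome_size),
                 n_rnmp = as.integer(n_rnmp),
                 placement = placement,
                 cluster_params = cluster_params,
                 n_molecules = as.integer(n_molecules),
                 n_background = as.integer(n_background),
                 seed = seed),
            class = "genome_break_config")
}

#' Simulate alkali fragmentation of a ribonucleotide-containing genome
#'
#' Places `n_rnmp + n_background` break points on the genome and cuts it,
#' together with the fixed molecule boundaries, into fragments.  Under
#' uniform placement the fragment-size distribution converges to an
#' exponential with mean `genome_size / n_breaks` as the break count grows.
#' Fragment sizes always partition the genome exactly.
#'
#' @param cfg a [genome_break_config()].
#' @return Integer-valued numeric vector of fragment sizes in nt, summing to
#'   `genome_size`.  The number of true break points actually placed (after
#'   removal of coinciding positions) is available as attribute `n_breaks`.
#' @export
simulate_fragments <- function(cfg) {
  stopifnot(inherits(cfg, "genome_break_config"))
  G <- cfg$genome_size
  nb <- cfg$n_rnmp + cfg$n_background
  if (G / (nb + cfg$n_molecules) < 1) {
    stop("expected fragment size below 1 nt: too many breaks for this genome",
         call. = FALSE)
  }
  with_seed(cfg$seed, {
    breaks <- if (nb == 0L) {
      integer(0)
    } else if (cfg$placement == "uniform") {
      sample.int(G - 1L, nb)
    } else {
      cp <- cfg$cluster_params
      n_hot <- round(cp$break_fraction * nb)
      width <- max(1, floor(cp$span_fraction * G / cp$n_hotspots))
      starts <- sort(sample.int(G - width - 1L, cp$n_hotspots))
      hot <- starts[sample.int(cp$n_hotspots, n_hot, replace = TRUE)] +
        sample.int(width, n_hot, replace = TRUE) - 1L
      cold <- if (nb - n_hot > 0L) sample.int(G - 1L, nb - n_hot) else integer(0)
      pmin(pmax(c(hot, cold), 1), G - 1)
    }
    # molecule ends from random shearing of the extracted DNA
    bounds <- if (cfg$n_molecules > 1L) {
      sample.int(G - 1L, cfg$n_molecules - 1L)
    } else numeric(0)
    cuts <- sort(unique(c(breaks, bounds)))
    sizes <- diff(c(0, cuts, G))
    structure(sizes, n_breaks = length(unique(breaks)))
  })
}

#' Band sizes of the 1 kb Plus DNA ladder
#'
#' @return Numeric vector of band sizes in nt, largest to smallest.
#' @export
ladder_1kb_plus <- function() {
  c(12000, 11000, 10000, 9000, 8000, 7000, 6000, 5000, 4000, 3000,
    2000, 1650, 1000, 850, 650, 500, 400, 300, 200, 100)
}

#' Configuration for rendering virtual gel lanes
#'
#' Forward model of the densitometry: a fragment of size `sz` migrates to
#' `d = a + b * log(sz)` mm from the well (b < 0 when larger fragments
#' migrate less), bands broaden as Gaussians of SD `band_sigma`, and the
#' staining intensity deposited by a fragment is proportional to its mass
#' (one mass unit per nt).  Fragments larger than the resolving range pile
#' up in a compression zone at `min_distance` from the well, as on a real
#' gel.  An additive polynomial background and detector noise complete the
#' model.  Detector noise has an additive Gaussian component (`noise_sd`)
#' and an optional signal-dependent component with variance
#' `poisson_gain * intensity`, emulating the shot-noise-like texture of
#' scanned gels that makes lane fluctuations scale with signal.
#'
#' @param a migration intercept in mm (`d` at `sz = 1` nt).
#' @param b migration slope in mm per ln(nt); typically negative.
#' @param band_sigma Gaussian band-broadening SD in mm.
#' @param lane_length scanned lane length in mm.
#' @param sample_step distance between densitometry samples in mm.
#' @param background polynomial coefficients (constant first) of the additive
#'   baseline in AU.
#' @param noise_sd SD of the additive Gaussian detector noise in AU.
#' @param poisson_gain variance of the signal-dependent noise per AU of
#'   clean intensity (0 disables it).
#' @param min_distance compression-zone distance in mm; no band center is
#'   rendered above the gel at smaller distances.
#' @param ladder_sizes band sizes (nt) used by [render_ladder()].
#' @param seed integer seed for the noise draws.
#' @return An object of class `gel_render_config`.
#' @export
gel_render_config <- function(a = 230, b = -20, band_sigma = 0.5,
                              lane_length = 150, sample_step = 0.25,
                              background = 0, noise_sd = 0,
                              poisson_gain = 0, min_distance = 2,
                              ladder_sizes = ladder_1kb_plus(),
                              seed = NULL) {
  stop_if_not_scalar_pos(sample_step, "sample_step")
  stop_if_not_scalar_pos(lane_length, "lane_length")
  if (band_sigma < 0) stop("band_sigma must be >= 0", call. = FALSE)
  if (b == 0) stop("migration slope b must be non-zero", call. = FALSE)
  structure(list(a = a, b = b, band_sigma = band_sigma,
                 lane_length = lane_length, sample_step = sample_step,
                 background = background, noise_sd = noise_sd,
                 poisson_gain = poisson_gain, min_distance = min_distance,
                 ladder_sizes = ladder_sizes, seed = seed),
            class = "gel_render_config")
}

# Render arbitrary (center, mass) bands into a sampled densitometry curve.
# Returns the clean signal (AU = mass density per mm) on the sample grid,
# plus the mass lost beyond the lane ends.
render_masses <- function(centers, masses, cfg) {
  d <- seq(0, cfg$lane_length, by = cfg$sample_step)
  centers <- pmax(centers, cfg$min_distance)
  total <- sum(masses)
  if (length(centers) == 0L) {
    return(list(distance = d, signal = numeric(length(d)), truncated = 0))
  }
  if (cfg$band_sigma == 0) {
    # delta bands: deposit each mass onto the nearest sample point
    keep <- centers >= 0 & centers <= cfg$lane_length
    sig <- numeric(length(d))
    if (any(keep)) {
      idx <- round(centers[keep] / cfg$sample_step) + 1L
      agg <- rowsum(masses[keep], idx)
      sig[as.integer(rownames(agg))] <- agg[, 1L] / cfg$sample_step
    }
    return(list(distance = d, signal = sig,
                truncated = total - sum(masses[keep])))
  }
  # aggregate centers on a fine grid, then evaluate the Gaussian mixture
  fine <- 0.02
  idx <- round(centers / fine)
  agg <- rowsum(masses, idx)
  cb <- as.numeric(rownames(agg)) * fine
  mb <- agg[, 1L]
  sig <- as.numeric(exp(-outer(d, cb, "-")^2 / (2 * cfg$band_sigma^2)) %*% mb) /
    (sqrt(2 * pi) * cfg$band_sigma)
  in_gel <- sum(mb * (stats::pnorm(cfg$lane_length, cb, cfg$band_sigma) -
                        stats::pnorm(0, cb, cfg$band_sigma)))
  list(distance = d, signal = sig, truncated = total - in_gel)
}

# Add background polynomial and detector noise to a clean signal.
finish_lane <- function(rend, cfg, lane_id, extra_meta = list()) {
  d <- rend$distance
  bg <- 0
  for (k in seq_along(cfg$background)) bg <- bg + cfg$background[k] * d^(k - 1)
  clean <- rend$signal + bg
  noisy <- with_seed(cfg$seed, {
    sdv <- sqrt(cfg$noise_sd^2 + cfg$poisson_gain * pmax(clean, 0))
    clean + stats::rnorm(length(d), 0, sdv)
  })
  meta <- c(list(config = cfg,
                 truncated_mass = rend$truncated,
                 signal_peak_au = max(rend$signal)),
            extra_meta)
  intensity_profile(d, noisy, lane_id = lane_id, metadata = meta)
}

#' Render a lane of fragmented DNA
#'
#' Converts a set of fragment sizes into the densitometry curve the gel
#' scanner would record: each fragment adds `size` mass units of staining at
#' `a + b * log(size)` mm, blurred by the band SD, on top of background and
#' noise.  Total band-attributable intensity is therefore proportional to
#' the total DNA mass loaded (before noise and background).
#'
#' @param fragments fragment sizes in nt (all >= 1).
#' @param cfg a [gel_render_config()].
#' @param lane_id label for the rendered lane.
#' @return An [intensity_profile()].  Metadata records the render config,
#'   the total mass lost beyond the lane ends (`truncated_mass`) and the
#'   peak clean signal (`signal_peak_au`).
#' @export
render_lane <- function(fragments, cfg, lane_id = "lane") {
  stopifnot(inherits(cfg, "gel_render_config"))
  if (length(fragments) && any(fragments < 1)) {
    stop("all fragment sizes must be >= 1 nt", call. = FALSE)
  }
  centers <- cfg$a + cfg$b * log(fragments)
  rend <- render_masses(centers, as.numeric(fragments), cfg)
  finish_lane(rend, cfg, lane_id,
              extra_meta = list(total_mass = sum(fragments)))
}

#' Render a DNA ladder lane
#'
#' Each ladder band receives the same mass (ladders are loaded at roughly
#' equal mass per band), centered at the migration distance of its size.
#'
#' @param cfg a [gel_render_config()]; band sizes come from
#'   `cfg$ladder_sizes`.
#' @param lane_id label.
#' @param band_mass mass units per band (AU x mm integrated intensity).
#' @return An [intensity_profile()]; metadata element `band_centers` holds
#'   the true (size -> center mm) map.
#' @export
render_ladder <- function(cfg, lane_id = "ladder", band_mass = 1e4) {
  stopifnot(inherits(cfg, "gel_render_config"))
  sizes <- cfg$ladder_sizes
  centers <- cfg$a + cfg$b * log(sizes)
  rend <- render_masses(centers, rep(band_mass, length(sizes)), cfg)
  finish_lane(rend, cfg, lane_id,
              extra_meta = list(band_centers = stats::setNames(centers,
                                                               sizes)))
}

#' Render an empty lane (background and noise only)
#'
#' Used by the signal-to-noise cutoff: an empty lane shows the fluctuation
#' level a loaded lane decays to where no DNA signal remains.
#'
#' @param cfg a [gel_render_config()].
#' @param lane_id label.
#' @return An [intensity_profile()].
#' @export
render_empty_lane <- function(cfg, lane_id = "empty") {
  stopifnot(inherits(cfg, "gel_render_config"))
  d <- seq(0, cfg$lane_length, by = cfg$sample_step)
  finish_lane(list(distance = d, signal = numeric(length(d)), truncated = 0),
              cfg, lane_id)
}
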