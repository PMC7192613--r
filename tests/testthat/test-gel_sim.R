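test_that("fragment sizes partition the genome for every placement and seed", {
  for (placement in c("uniform", "clustered")) {
    for (seed in 1:3) {
      cfg <- genome_break_config(n_rnmp = 5000, placement = placement,
                                 n_molecules = 16, seed = seed)
      sizes <- simulate_fragments(cfg)
      expect_equal(sum(sizes), 24e6)
      expect_true(all(sizes >= 1))
    }
  }
})

test_that("fragment count is breaks plus molecules when breaks are distinct", {
  sizes <- simulate_fragments(genome_break_config(n_rnmp = 0,
                                                  n_molecules = 16,
                                                  seed = 1))
  expect_length(sizes, 16)
  expect_equal(sum(sizes), 24e6)

  cfg <- genome_break_config(n_rnmp = 5000, n_molecules = 16, seed = 42)
  sizes <- simulate_fragments(cfg)
  expect_equal(length(sizes), attr(sizes, "n_breaks") + 16)
})

test_that("uniform breakage yields exponential fragment sizes", {
  n <- 20000
  sizes <- simulate_fragments(genome_break_config(n_rnmp = n,
                                                  n_molecules = 1,
                                                  seed = 7))
  ks <- suppressWarnings(
    stats::ks.test(sizes, "pexp", rate = n / 24e6))
  expect_lt(unname(ks$statistic), 0.05)
  expect_equal(mean(sizes), 24e6 / length(sizes))
})

test_that("clustered placement concentrates breaks into short fragments", {
  n <- 2000
  cl <- simulate_fragments(genome_break_config(
    n_rnmp = n, placement = "clustered",
    cluster_params = list(n_hotspots = 10, break_fraction = 0.9,
                          span_fraction = 0.01),
    n_molecules = 1, seed = 5))
  un <- simulate_fragments(genome_break_config(n_rnmp = n, n_molecules = 1,
                                               seed = 5))
  # 90% of breaks in 1% of the genome: most fragments far below the
  # uniform mean spacing
  expect_gte(mean(cl < 24e6 / n), 0.85)
  expect_lt(stats::median(cl), 0.2 * stats::median(un))
})

test_that("overfragmentation beyond 1 nt per fragment is rejected", {
  expect_error(
    simulate_fragments(genome_break_config(genome_size = 1000,
                                           n_rnmp = 2000, seed = 1)),
    "below 1 nt")
})

test_that("simulation and rendering are deterministic under a fixed seed", {
  cfg <- genome_break_config(n_rnmp = 3000, seed = 99)
  expect_identical(simulate_fragments(cfg), simulate_fragments(cfg))
  gel <- gel_render_config(noise_sd = 5, background = 10, seed = 3)
  f <- simulate_fragments(cfg)
  expect_identical(render_lane(f, gel)$intensity_au,
                   render_lane(f, gel)$intensity_au)
  expect_identical(render_empty_lane(gel)$intensity_au,
                   render_empty_lane(gel)$intensity_au)
})

test_that("rendering conserves mass and scales intensity with fragment size", {
  gel <- gel_render_config()  # no noise, no background
  f1 <- simulate_fragments(genome_break_config(n_rnmp = 5000,
                                               n_molecules = 100,
                                               seed = 2))
  lane <- render_lane(f1, gel)
  integral <- sum(lane$intensity_au) * gel$sample_step
  expect_equal(integral + attr(lane, "metadata")$truncated_mass,
               sum(f1), tolerance = 0.01)

  # two bands: integrated intensities in the 1:2 ratio of their masses
  two <- render_lane(c(500, 1000), gel)
  d <- two$distance_mm
  near <- function(sz) abs(d - (gel$a + gel$b * log(sz))) < 5
  r <- sum(two$intensity_au[near(1000)]) / sum(two$intensity_au[near(500)])
  expect_equal(r, 2, tolerance = 0.01)
})

test_that("a zero-width band is a single spike at a + b*log(size)", {
  gel <- gel_render_config(band_sigma = 0)
  lane <- render_lane(1000, gel)
  hit <- which(lane$intensity_au > 0)
  expect_length(hit, 1L)
  expect_equal(lane$distance_mm[hit], gel$a + gel$b * log(1000),
               tolerance = gel$sample_step)
  expect_equal(sum(lane$intensity_au) * gel$sample_step, 1000)
})

test_that("empty lanes carry only background and noise", {
  silent <- render_empty_lane(gel_render_config())
  expect_true(all(silent$intensity_au == 0))

  noisy <- render_empty_lane(gel_render_config(noise_sd = 4, seed = 8))
  expect_equal(stats::sd(noisy$intensity_au), 4, tolerance = 0.1 * 4)
  expect_gte(nrow(noisy), 500)
})
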