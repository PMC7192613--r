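make_series <- function(mid, I, cal = exact_calibration()) {
  structure(
    data.frame(mid_mm = mid, width_mm = 1, size_nt =
                 as.numeric(size_at(mid, cal)),
               intensity_au = I, excluded = FALSE),
    calibration = cal, lane_id = "test", cutoff = NULL,
    class = c("interval_series", "data.frame"))
}

test_that("molar counts are intensity over size", {
  cal <- exact_calibration()
  # I = 1000 AU at sz = 500 -> 2 molecules
  s <- make_series(distance_at(500, cal), 1000, cal)
  expect_equal(counts_from_intensity(s)$n_sz, 2)
  # equal intensity at sizes 100 and 1000 -> counts 10:1
  s2 <- make_series(sort(distance_at(c(100, 1000), cal)), c(300, 300), cal)
  n <- counts_from_intensity(s2)$n_sz
  big_first <- order(s2$size_nt, decreasing = TRUE)
  expect_equal(n[big_first][2] / n[big_first][1], 10)
})

test_that("per-Gb normalization fixes the included DNA mass at 1e9", {
  set.seed(1)
  cal <- exact_calibration()
  s <- make_series(seq(30.5, 120.5, by = 1),
                   stats::runif(91, 10, 1000), cal)
  tab <- normalize_per_gb(counts_from_intensity(s))
  expect_equal(sum(tab$size_nt * tab$n_per_gb), 1e9)

  # invariant under rescaling the lane intensities
  s7 <- s; s7$intensity_au <- s7$intensity_au * 7
  tab7 <- normalize_per_gb(counts_from_intensity(s7))
  expect_equal(tab7$n_per_gb, tab$n_per_gb, tolerance = 1e-12)

  # single interval at sz = 1000: exactly 1e6 fragments per Gb
  one <- normalize_per_gb(counts_from_intensity(
    make_series(distance_at(1000, cal), 123.4, cal)))
  expect_equal(one$n_per_gb, 1e6)

  zero <- make_series(c(10.5, 11.5), c(0, 0), cal)
  expect_error(normalize_per_gb(counts_from_intensity(zero)), "zero")
})

test_that("the genome total is the per-Gb sum rescaled to the genome", {
  tab <- table_from_per_gb(size_nt = c(500, 2000), n_per_gb = c(350125 / 2,
                                                                350125 / 2))
  est <- estimate_total(tab, genome_size = 24e6)
  expect_equal(round(est$N_prelim), 8403)
  expect_equal(estimate_total(tab, genome_size = 1e9)$N_prelim, 350125)
  empty <- table_from_per_gb(1000, 0)
  expect_equal(estimate_total(empty)$N_prelim, 0)
})

test_that("the truncation correction follows its closed form and bounds", {
  # sz_min = 0: no correction
  tab0 <- table_from_per_gb(1000, 5000, sz_min = 0)
  est0 <- correct_truncation(estimate_total(tab0), tab0)
  expect_equal(est0$N_corr, est0$N_prelim)

  # sz_min * sum(n_per_gb) / 1e9 = ln 2: correction is exactly 1.5x
  sumn <- 4e5
  tabl <- table_from_per_gb(1000, sumn, sz_min = log(2) * 1e9 / sumn)
  estl <- correct_truncation(estimate_total(tabl), tabl)
  expect_equal(estl$N_corr / estl$N_prelim, 1.5)

  # factor always in [1, 2], non-decreasing in sz_min
  fac <- vapply(seq(0, 5000, by = 500), function(szm) {
    tb <- table_from_per_gb(1000, sumn, sz_min = szm)
    e <- correct_truncation(estimate_total(tb), tb)
    e$N_corr / e$N_prelim
  }, numeric(1))
  expect_true(all(fac >= 1 & fac <= 2))
  expect_true(all(diff(fac) >= 0))
})

test_that("control subtraction nets out shared breakage and floors at 0", {
  mk <- function(n_per_gb) {
    tb <- table_from_per_gb(1000, n_per_gb, sz_min = 100)
    correct_truncation(estimate_total(tb), tb)
  }
  s <- mk(4e5); ctl <- mk(1e5)
  net <- subtract_control(s, ctl)
  expect_equal(net$N_net, s$N_corr - ctl$N_corr)

  zero_ctl <- mk(0 + 1e-9)
  expect_equal(subtract_control(s, zero_ctl)$N_net, s$N_corr,
               tolerance = 1e-6)

  expect_warning(fl <- subtract_control(ctl, s), "floored")
  expect_equal(fl$N_net, 0)
})

test_that("densities per Gb reproduce direct arithmetic", {
  expect_equal(density_per_gb(8403), 350125)
  expect_equal(density_per_gb(20136), 839000)
  expect_equal(density_per_gb(0), 0)
  expect_equal(format_density_k(350125), "350K")
})

test_that("per-interval counts match a direct recount of the simulation", {
  set <- sim_lane_set(8403, seed = 55)
  fit <- quantify_set(set)
  tab <- fit$counts
  cal <- fit$calibration
  inc <- !tab$excluded
  # true per-interval counts: fragments whose size falls in the interval
  hi <- as.numeric(size_at(tab$mid_mm - 0.5, cal))
  lo <- as.numeric(size_at(tab$mid_mm + 0.5, cal))
  truth <- vapply(seq_len(nrow(tab)), function(j)
    sum(set$frags >= lo[j] & set$frags < hi[j]), numeric(1))
  est <- tab$n_per_gb * 24e6 / 1e9
  check <- inc & truth >= 50
  expect_gt(sum(check), 20)
  # per-interval agreement is limited by the Poisson noise of the recount
  # itself (~10% SD at 100 counts), so judge the error distribution
  rel <- abs(est[check] - truth[check]) / truth[check]
  expect_lt(stats::median(rel), 0.1)
  expect_lt(unname(stats::quantile(rel, 0.9)), 0.25)
})

test_that("the whole pipeline is invariant to lane loading", {
  set <- sim_lane_set(8403, seed = 60)
  fit1 <- quantify_set(set)
  scale_profile <- function(p, f) intensity_profile(
    p$distance_mm, p$intensity_au * f, lane_id(p), attr(p, "metadata"))
  set2 <- set
  set2$lane <- scale_profile(set$lane, 7)
  set2$control <- scale_profile(set$control, 7)
  set2$empty <- scale_profile(set$empty, 7)
  fit7 <- quantify_set(set2)
  expect_equal(fit7$estimate$N_prelim, fit1$estimate$N_prelim,
               tolerance = 1e-10)
  expect_equal(fit7$estimate$N_corr, fit1$estimate$N_corr,
               tolerance = 1e-10)
  expect_equal(fit7$estimate$N_net, fit1$estimate$N_net,
               tolerance = 1e-10)
})

test_that("a full synthetic lane recovers its true ribonucleotide count", {
  set <- sim_lane_set(8403, seed = 11)
  fit <- quantify_set(set)
  expect_equal(fit$estimate$N_net, 8403, tolerance = 0.1)
  expect_true(fit$estimate$N_corr >= fit$estimate$N_prelim)
  expect_true(fit$estimate$N_corr <= 2 * fit$estimate$N_prelim)
})
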