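# Along-track wavelet machinery: resampling, the sustained-change
# statistic, scalograms, transition detection, scale correlation.

test_that("interpolation hits linear midpoints and is idempotent", {
  tr <- data.frame(distance_km = c(0, 10),
                   abundance_cells_per_ml = c(0, 100))
  segs <- interpolate_track(tr, spacing = 5, max_gap = 100)
  expect_length(segs, 1)
  expect_equal(segs[[1]]$abundance_cells_per_ml, c(0, 50, 100))
  uni <- make_segment(c(3, 1, 4, 1, 5), spacing = 5)
  again <- interpolate_track(uni, spacing = 5, max_gap = 100)[[1]]
  expect_equal(again$abundance_cells_per_ml, uni$abundance_cells_per_ml)
  expect_error(interpolate_track(tr, spacing = 0), "positive")
})

test_that("large raw gaps split the track instead of being interpolated", {
  tr <- data.frame(distance_km = c(0, 50, 100, 350, 400, 450),
                   abundance_cells_per_ml = c(1, 2, 3, 9, 8, 7))
  segs <- interpolate_track(tr, spacing = 50, max_gap = 100)
  expect_length(segs, 2)
  expect_equal(segs[[1]]$distance_km, c(0, 50, 100))
  expect_equal(segs[[2]]$distance_km, c(350, 400, 450))
})

test_that("Haar statistic is zero on constants and exact on ramps", {
  const <- make_segment(rep(4e4, 200))
  expect_true(all(haar_statistic(const, 150)$statistic == 0))
  for (m in c(7, -13.5, 0.002)) {
    x <- seq(0, 2000, by = 5)
    ramp <- make_segment(m * x)
    p <- haar_statistic(ramp, alpha = 150)
    expect_equal(p$statistic, rep(m, nrow(p)), tolerance = 1e-9)
    # brute-force window-mean oracle agrees everywhere
    o <- oracle_haar(ramp$distance_km, ramp$abundance_cells_per_ml, 150, 5)
    expect_equal(p$statistic, o$statistic)
  }
})

test_that("an ideal step yields the height/alpha closed form at the step", {
  x <- seq(0, 2000, by = 5)
  step <- make_segment(ifelse(x >= 1000, 1.5e5, 0))
  p <- haar_statistic(step, alpha = 150)
  peak <- which.max(abs(p$statistic))
  expect_equal(p$distance_km[peak], 1000)
  expect_equal(p$statistic[peak], 1.5e5 / 150)
})

test_that("Haar statistic is linear and shift-invariant, reversal negates", {
  set.seed(2)
  f <- rnorm(300, 5e4, 1e4); g <- rnorm(300, 2e4, 5e3)
  sf <- haar_statistic(make_segment(f), 100)$statistic
  sg <- haar_statistic(make_segment(g), 100)$statistic
  s_lin <- haar_statistic(make_segment(2 * f + 3 * g), 100)$statistic
  expect_equal(s_lin, 2 * sf + 3 * sg)
  s_shift <- haar_statistic(make_segment(f + 1e6), 100)$statistic
  expect_equal(s_shift, sf)
  s_rev <- haar_statistic(make_segment(rev(f)), 100)$statistic
  expect_equal(rev(s_rev), -sf)
})

test_that("profiles keep full window support and warn when too short", {
  seg <- make_segment(rnorm(100, 1e5, 1e3), spacing = 5)  # 495 km long
  p <- haar_statistic(seg, alpha = 150)
  expect_gte(min(p$distance_km), 150)
  expect_lte(max(p$distance_km), 495 - 150 + 5)
  expect_warning(haar_statistic(make_segment(1:10), alpha = 150), "shorter")
})

test_that("scalogram peak counts fall from noisy small scales to large", {
  x <- seq(0, 2000, by = 5)
  step <- make_segment(ifelse(x >= 800, 1.6e5, 0))
  sc <- scalogram(step, alphas = seq(10, 150, by = 20))
  expect_true(all(sc$peak_counts == 1))
  const <- make_segment(rep(1e5, 401))
  expect_true(all(scalogram(const, alphas = c(50, 150))$peak_counts == 0))
  set.seed(1)
  noisy <- make_segment(1e5 + rnorm(401, 0, 1e4))
  scn <- scalogram(noisy, alphas = c(5, 150))
  expect_gt(scn$peak_counts[1], scn$peak_counts[2])
})

test_that("detection recovers a planted noisy step and obeys separation", {
  g <- generate_cruise_track(
    cruise_track_cfg(boundaries_km = 500, means = c(5000, 155000),
                     transition_width_km = 30, noise_sd = 5000), seed = 7)
  d <- detect_transitions(g$track)
  crossing <- d[d$crosses_regime_threshold, ]
  expect_equal(nrow(crossing), 1)
  expect_lte(abs(crossing$distance_km - 500), 20)
  expect_gt(crossing$statistic, 0)  # abundance increases along track
  # below-filter noise yields nothing
  quiet <- generate_cruise_track(
    cruise_track_cfg(boundaries_km = numeric(0), means = 1e5, noise_sd = 100),
    seed = 1)
  expect_equal(nrow(detect_transitions(quiet$track)), 0)
  # two steps 80 km apart merge under the 100 km separation rule
  twostep <- generate_cruise_track(
    cruise_track_cfg(boundaries_km = c(900, 980), means = c(0, 8e4, 1.6e5),
                     noise_sd = 0), seed = 1)
  expect_equal(nrow(detect_transitions(twostep$track)), 1)
})

test_that("detected count is non-increasing in the filter threshold", {
  g <- generate_cruise_track(
    cruise_track_cfg(boundaries_km = c(500, 1200), means = c(0, 1.5e5, 2e4),
                     noise_sd = 8000), seed = 3)
  counts <- vapply(c(5, 10, 50, 200, 1500), function(th)
    nrow(detect_transitions(g$track, haar_params(filter_threshold = th))),
    integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("planted-step position is stable across alpha in 100-200 km", {
  g <- generate_cruise_track(
    cruise_track_cfg(boundaries_km = 1000, means = c(1e4, 1.6e5),
                     noise_sd = 5000), seed = 11)
  pos <- vapply(seq(100, 200, by = 25), function(a) {
    d <- detect_transitions(g$track, haar_params(alpha = a))
    d$distance_km[which.max(abs(d$statistic))]
  }, numeric(1))
  expect_lte(max(pos) - min(pos), 5)  # within one resample spacing
})

test_that("transitions colocalize against fields with retention flags", {
  g <- generate_cruise_track(
    cruise_track_cfg(boundaries_km = 500, means = c(5000, 155000)), seed = 7)
  d <- detect_transitions(g$track)
  const_field <- make_field(lat = seq(-2, 2, 1), lon = seq(0, 20, 0.5),
                            dates = as.Date("2017-06-01") + 0:5,
                            fill = function(dd, la, lo) 20)
  out <- colocalize_transitions(d, const_field, NULL)
  expect_true(all(out$temperature_C[out$colocalized] == 20))
  # a field with no overlapping dates keeps rows, flags them unmatched
  old <- make_field(dates = as.Date("2000-01-01"))
  out2 <- colocalize_transitions(d, old, NULL)
  expect_equal(nrow(out2), nrow(d))
  expect_true(all(!out2$colocalized))
  expect_true(all(is.na(out2$temperature_C)))
})

test_that("scale correlation is exact for proportional series", {
  x <- seq(0, 2000, by = 5)
  tr <- make_segment(1000 * (20 + sin(x / 200) + 0.3 * cos(x / 37)))
  tr$temperature_C <- tr$abundance_cells_per_ml / 1000
  cur <- scale_correlation(list(tr), scales = c(50, 200, 1000))
  ok <- !is.na(cur$r_squared)
  expect_true(any(ok))
  expect_equal(cur$r_squared[ok], rep(1, sum(ok)))
})

test_that("scale correlation is invariant to wavelet rescaling and to
           affine transforms of temperature", {
  set.seed(4)
  tr <- make_segment(1e5 + rnorm(401, 0, 1e4))
  tr$temperature_C <- 20 + 0.5 * sin(seq(0, 20, length.out = 401)) +
    rnorm(401, 0, 0.2)
  base <- scale_correlation(list(tr), scales = c(50, 400))
  scaled <- scale_correlation(list(tr), scales = c(50, 400),
                              normalization = 7.3)
  expect_equal(base$r_squared, scaled$r_squared, tolerance = 1e-12)
  tr2 <- tr; tr2$temperature_C <- -3 * tr$temperature_C + 100
  aff <- scale_correlation(list(tr2), scales = c(50, 400))
  expect_equal(aff$r_squared, base$r_squared)
})

test_that("scales without enough pooled points are undefined", {
  short <- make_segment(rnorm(30, 1e5, 1e3))
  short$temperature_C <- rnorm(30, 20, 1)
  cur <- scale_correlation(list(short), scales = c(10, 2000))
  expect_true(is.na(cur$r_squared[2]))
})
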