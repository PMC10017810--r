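# Surface filtering, PAR attenuation, gridded-field matching and
# along-track distances.

test_that("surface filter is inclusive at the depth boundary", {
  obs <- data.frame(depth_m = c(0, 50, 50.1), id = 1:3)
  kept <- filter_surface(obs)
  expect_equal(kept$id, c(1, 2))
  expect_equal(nrow(filter_surface(obs[0, , drop = FALSE])), 0)
  expect_equal(nrow(filter_surface(data.frame(depth_m = rep(1000, 3)))), 0)
})

test_that("PAR attenuation follows the exponential closed form", {
  expect_equal(attenuate_par(50, 0, 0.1), 50)
  expect_equal(attenuate_par(50, 10, 0.1), 50 * exp(-1))
  expect_equal(attenuate_par(50, 50, 0.1), 50 * exp(-5))
  expect_error(attenuate_par(50, -1, 0.1), "non-negative")
  expect_error(attenuate_par(50, 10, -0.1), "non-negative")
})

test_that("PAR attenuation is monotone in depth and identity at k = 0", {
  depths <- seq(0, 200, by = 5)
  out <- attenuate_par(37, depths, 0.1)
  expect_true(all(diff(out) <= 0))
  expect_equal(attenuate_par(37, depths, 0), rep(37, length(depths)))
})

test_that("an observation at a grid centre gets that cell's values", {
  sst <- make_field()
  par <- make_field("par", fill = function(d, la, lo) 40 + la)
  obs <- data.frame(lat = 1, lon = 12, depth_m = 0,
                    time_iso8601 = "2017-06-01T12:00:00Z")
  out <- colocalize_records(obs, sst, par)
  expect_equal(nrow(out), 1)
  expect_equal(out$temperature_C, 20 + 1 + 1.2)
  expect_equal(out$par, 41)  # depth 0: no attenuation
})

test_that("matched PAR is attenuated to the record depth", {
  par <- make_field("par", fill = function(d, la, lo) 40)
  obs <- data.frame(lat = 0, lon = 12, depth_m = 10,
                    time_iso8601 = "2017-06-01T12:00:00Z")
  out <- colocalize_records(obs, NULL, par, k = 0.1)
  expect_equal(out$par, 40 * exp(-1))
})

test_that("nearest-cell choice matches a brute-force scan, ties by (lat, lon)", {
  # 0.25-degree grid so several cells sit inside the tolerances
  sst <- make_field(lat = seq(-1, 1, by = 0.25), lon = seq(10, 12, by = 0.25),
                    fill = function(d, la, lo) la * 100 + lo)
  set.seed(31)
  for (i in 1:20) {
    lat <- runif(1, -0.9, 0.9); lon <- runif(1, 10.1, 11.9)
    obs <- data.frame(lat = lat, lon = lon, depth_m = 0,
                      time_iso8601 = "2017-06-01T00:00:00Z")
    got <- colocalize_records(obs, sst, NULL)$temperature_C
    want <- oracle_nearest(sst, "2017-06-01", lat, lon, lat_tol = 0.25)
    expect_equal(got, want)
  }
  # exactly equidistant between two cells: tie broken by ascending lat
  obs <- data.frame(lat = 0.125, lon = 10.5, depth_m = 0,
                    time_iso8601 = "2017-06-01T00:00:00Z")
  expect_equal(colocalize_records(obs, sst, NULL)$temperature_C,
               0 * 100 + 10.5)
})

test_that("records with no usable match are dropped and counted", {
  sst <- make_field()
  # PAR masked everywhere on day 1
  par <- make_field("par", fill = function(d, la, lo) if (d == 1) NA else 40)
  obs <- data.frame(lat = c(0, 0), lon = c(12, 12), depth_m = 0,
                    time_iso8601 = c("2017-06-01T12:00:00Z",
                                     "2017-06-02T12:00:00Z"))
  out <- colocalize_records(obs, sst, par)
  expect_equal(nrow(out), 1)
  expect_equal(attr(out, "dropped")[["no_par"]], 1L)
  # no overlapping dates at all: empty output with a warning, no error
  late <- data.frame(lat = 0, lon = 12, depth_m = 0,
                     time_iso8601 = "2019-01-01T00:00:00Z")
  expect_warning(out2 <- colocalize_records(late, sst, par), "colocalized")
  expect_equal(nrow(out2), 0)
})

test_that("matched cells always lie within the stated tolerances", {
  sst <- make_field(lat = seq(-3, 3, by = 0.25), lon = seq(8, 16, by = 0.25))
  par <- make_field("par", lat = seq(-3, 3, by = 0.0833),
                    lon = seq(8, 16, by = 0.0833),
                    fill = function(d, la, lo) 40 + la)
  set.seed(7)
  obs <- data.frame(lat = runif(30, -2, 2), lon = runif(30, 9, 15),
                    depth_m = 0, time_iso8601 = "2017-06-01T06:00:00Z")
  out <- colocalize_records(obs, sst, par)
  expect_gt(nrow(out), 0)
  # post-hoc audit: reconstruct each match's implied PAR cell distance
  for (i in seq_len(nrow(out))) {
    want <- oracle_nearest(par, "2017-06-01", out$lat[i], out$lon[i],
                           km_tol = 9)
    expect_equal(out$par[i], want)
  }
})

test_that("colocalization is idempotent on already-matched records", {
  sst <- make_field(); par <- make_field("par", fill = function(d, la, lo) 40)
  obs <- data.frame(lat = c(0.05, -1.03), lon = c(12.02, 13.01), depth_m = 0,
                    time_iso8601 = "2017-06-01T12:00:00Z")
  once <- colocalize_records(obs, sst, par)
  expect_equal(nrow(once), 2)
  twice <- colocalize_records(once, sst, par)
  attr(once, "dropped") <- NULL; attr(twice, "dropped") <- NULL
  rownames(once) <- rownames(twice) <- NULL
  expect_equal(twice, once)
})

test_that("along-track distance matches the haversine closed form", {
  expect_equal(along_track_distance(c(0, 0), c(0, 0)), c(0, 0))
  d <- along_track_distance(c(0, 0), c(0, 1))
  expect_equal(d[2], 6371 * pi / 180, tolerance = 1e-6)
  d3 <- along_track_distance(c(0, 0, 0), c(0, 1, 2))
  expect_equal(d3, c(0, 6371 * pi / 180, 2 * 6371 * pi / 180),
               tolerance = 1e-6)
  expect_true(all(diff(d3) >= 0))
  expect_error(along_track_distance(c(0, 91), c(0, 0)), "-90, 90")
})

test_that("gridded fields round-trip through long-format CSV", {
  f <- make_field(fill = function(d, la, lo) if (la == 0 && lo == 12) NA
                  else d * 100 + la + lo)
  path <- tempfile(fileext = ".csv")
  write_gridded_csv(f, path)
  back <- read_gridded_csv(path, "sst")
  expect_equal(back$values, f$values)
  expect_equal(back$lat, f$lat)
  expect_equal(back$dates, f$dates)
})
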