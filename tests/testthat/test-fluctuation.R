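# Station fluctuation stage: cruise means, monthly bins, deltas,
# bootstrap correlations, quadrants, two-predictor R^2.

station_records <- function(cruise_id, times, ab, temp = 25, par = 40,
                            depth = 5) {
  data.frame(cruise_id = cruise_id, time_iso8601 = times, depth_m = depth,
             temperature_C = temp, par = par, abundance_cells_per_ml = ab)
}

test_that("cruise means average non-missing values with median dates", {
  r <- rbind(
    station_records("c1", "1994-03-02T00:00:00Z", 1e5),
    station_records("c2", c("1994-03-10T00:00:00Z", "1994-03-12T00:00:00Z",
                            "1994-03-20T00:00:00Z"), c(10, 30, NA)))
  cm <- cruise_means(r)
  expect_equal(nrow(cm), 2)
  expect_equal(cm$abundance_cells_per_ml, c(1e5, 20))
  expect_equal(cm$date[2], as.Date("1994-03-12"))
})

test_that("deep records are rejected and empty cruises omitted", {
  deep <- station_records("c1", "1994-03-02T00:00:00Z", 1e5, depth = 100)
  expect_error(cruise_means(deep), "filter_surface")
  r <- rbind(station_records("c1", "1994-03-02T00:00:00Z", 1e5),
             station_records("c2", "1994-03-09T00:00:00Z",
                             NA, temp = NA, par = NA))
  expect_warning(cm <- cruise_means(r), "omitted")
  expect_equal(cm$cruise_id, "c1")
})

test_that("monthly binning averages cruises within a represented month", {
  cm <- data.frame(cruise_id = c("a", "b", "c"),
                   date = as.Date(c("1994-03-05", "1994-03-20", "1995-01-02")),
                   abundance_cells_per_ml = c(1e5, 2e5, 5e4))
  mb <- monthly_bin(cm)
  expect_equal(mb$year_month, c("1994-03", "1995-01"))
  expect_equal(mb$abundance_cells_per_ml, c(1.5e5, 5e4))
  expect_equal(mb$n_cruises, c(2L, 1L))
  expect_equal(nrow(monthly_bin(cm[0, ])), 0)
})

test_that("deltas pair only adjacent represented months, across year ends", {
  m <- data.frame(year_month = c("1994-01", "1994-02", "1994-04"),
                  temperature_C = c(20, 21, 25), par = c(30, 31, 35),
                  abundance_cells_per_ml = c(1, 2, 4))
  d <- consecutive_deltas(m)
  expect_equal(nrow(d), 1)
  expect_equal(d$from_month, "1994-01")
  expect_equal(d$dT, 1)
  yb <- data.frame(year_month = c("1995-12", "1996-01"),
                   temperature_C = c(20, 22), par = c(30, 29),
                   abundance_cells_per_ml = c(1, 5))
  expect_equal(nrow(consecutive_deltas(yb)), 1)
  run <- data.frame(year_month = sprintf("1994-%02d", 1:12),
                    temperature_C = 1:12, par = 1:12,
                    abundance_cells_per_ml = 1:12)
  expect_equal(nrow(consecutive_deltas(run)), 11)
  expect_lte(nrow(consecutive_deltas(run[c(1, 3, 5, 7), ])), 3)
})

test_that("pearson_boot recovers exact correlations and their signs", {
  x <- c(1, 3, 5, 7, 11, 13, 2, 8)
  r1 <- pearson_boot(x, x, n_boot = 200, seed = 1)
  expect_equal(r1$estimate, 1)
  expect_equal(r1$se, 0)
  expect_equal(pearson_boot(x, -2 * x, n_boot = 50, seed = 1)$estimate, -1)
  expect_error(pearson_boot(x, rep(1, 8)), "zero variance")
})

test_that("bootstrap coefficient is affine-invariant and sign-flips", {
  set.seed(21)
  x <- rnorm(60); y <- 0.5 * x + rnorm(60)
  a <- pearson_boot(x, y, n_boot = 100, seed = 2)
  b <- pearson_boot(3 * x + 7, 0.1 * y - 2, n_boot = 100, seed = 2)
  expect_equal(a$estimate, b$estimate)
  expect_equal(pearson_boot(-x, y, n_boot = 100, seed = 2)$estimate,
               -a$estimate)
})

test_that("bootstrap SE approximates the Fisher large-sample SE at null", {
  set.seed(11)
  x <- rnorm(500); y <- rnorm(500)
  r <- pearson_boot(x, y, n_boot = 1000, seed = 11)
  expect_lt(abs(r$estimate), 0.1)
  fisher <- 1 / sqrt(500 - 3)
  expect_lt(abs(r$se - fisher) / fisher, 0.3)
  rf <- pearson_boot(x, y, method = "fisher")
  expect_equal(rf$se, (1 - rf$estimate^2) / sqrt(497))
})

test_that("quadrant fractions recover a planted binomial rate", {
  set.seed(3)
  n <- 2000
  dT <- rnorm(n); dPAR <- rnorm(n)
  p_up <- ifelse(dT > 0 & dPAR < 0, 0.6, 0.4)
  deltas <- data.frame(from_month = "x", to_month = "y", dT = dT, dPAR = dPAR,
                       dPro = ifelse(runif(n) < p_up, 1, -1))
  qf <- quadrant_fractions(deltas, n_boot = 200, seed = 3)
  lr <- qf[qf$quadrant == "lower_right", ]
  ci <- qbinom(c(0.005, 0.995), lr$n, 0.6) / lr$n
  expect_gte(lr$fraction_increasing, ci[1])
  expect_lte(lr$fraction_increasing, ci[2])
  expect_lte(sum(qf$n[qf$quadrant != "overall"]), qf$n[qf$quadrant == "overall"])
})

test_that("degenerate quadrants are flagged, zeros unassigned", {
  d <- data.frame(from_month = "x", to_month = "y",
                  dT = c(1, 2, 0), dPAR = c(-1, -2, 1), dPro = c(1, 1, 1))
  qf <- quadrant_fractions(d, n_boot = 50, seed = 1)
  expect_equal(qf$fraction_increasing[qf$quadrant == "lower_right"], 1)
  ul <- qf[qf$quadrant == "upper_left", ]
  expect_equal(ul$n, 0L)
  expect_true(is.na(ul$fraction_increasing))
  # the (dT = 0, dPAR = 1) delta belongs to no quadrant
  expect_equal(sum(qf$n[qf$quadrant != "overall"]), 2L)
})

test_that("bivariate R^2 is exact for a noiseless linear relation", {
  set.seed(5)
  d <- data.frame(dT = rnorm(30), dPAR = rnorm(30))
  d$dPro <- 2 * d$dT - 3 * d$dPAR
  r <- bivariate_r2(d, n_boot = 50, seed = 5)
  expect_equal(r$r_squared, 1)
  # null simulation at larger n: R^2 should be near its E ~ 2/(n-1)
  dn <- data.frame(dT = rnorm(1000), dPAR = rnorm(1000))
  set.seed(5); dn$dPro <- rnorm(1000)
  expect_lt(bivariate_r2(dn, n_boot = 20, seed = 1)$r_squared, 0.02)
  dd <- data.frame(dT = rnorm(10), dPAR = 0, dPro = rnorm(10))
  dd$dPAR <- dd$dT
  expect_error(bivariate_r2(dd), "collinear")
})

test_that("bootstrap intervals cover a planted correlation at nominal rate", {
  rho <- 0.3; cover <- 0; reps <- 200
  for (k in seq_len(reps)) {
    set.seed(5000 + k)
    x <- rnorm(100); y <- rho * x + sqrt(1 - rho^2) * rnorm(100)
    r <- pearson_boot(x, y, n_boot = 400, seed = k)
    if (abs(r$estimate - rho) <= 2 * r$se) cover <- cover + 1
  }
  expect_gte(cover / reps, 0.90)
  expect_lte(cover / reps, 0.99)
})
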