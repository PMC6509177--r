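# Lambda model: DSRT integration, regression with outlier exclusion, TSRT.

test_that("DSRT is the traversed angle up to the EMG onset", {
  # constant 100 deg/s, onset 0.5 s after movement onset -> 50 degrees
  pt <- fake_pt(rep(100, 400), move_on = 101, move_off = 350,
                emg_onset = 1501)  # 1.5 s on the EMG base = sample 151 @100Hz
  expect_equal(compute_dsrt(pt), 50)
  # onset coincident with movement onset -> 0 degrees
  pt0 <- fake_pt(rep(100, 400), move_on = 101, move_off = 350,
                 emg_onset = 1001)
  expect_equal(compute_dsrt(pt0), 0)
  # no onset -> NA
  expect_true(is.na(compute_dsrt(fake_pt(rep(100, 400)))))
  # onset before movement onset -> NA with a warning
  ptb <- fake_pt(rep(100, 400), move_on = 201, move_off = 350,
                 emg_onset = 1001)
  expect_warning(d <- compute_dsrt(ptb), "precedes")
  expect_true(is.na(d))
})

test_that("triangular-profile DSRT matches a fine-grid Riemann oracle", {
  # triangular speed peaking at 200 deg/s, onset at the profile midpoint
  n <- 201
  up <- seq(0, 200, length.out = 101)
  speed <- c(up, rev(up)[-1])
  pt <- fake_pt(speed, move_on = 1, move_off = n,
                emg_onset = 1001)  # 1.0 s -> gyro sample 101 (the peak)
  got <- compute_dsrt(pt)
  # oracle: Riemann sum of the linearly interpolated profile at 10x resolution
  tt <- seq(0, 1, length.out = 10001)
  fine <- approx((0:(n - 1)) / 100, speed, xout = tt)$y
  oracle <- sum((fine[-1] + fine[-length(fine)]) / 2) * diff(tt)[1]
  expect_equal(got, oracle, tolerance = 1e-9)
})

test_that("exact points on the published example line are recovered exactly", {
  v <- c(30, 55, 80, 105, 130, 155)
  pts <- tibble::tibble(mean_speed = v, dsrt = -0.277 * v + 46.765)
  fit <- fit_lambda(pts)
  expect_equal(fit$slope, -0.277, tolerance = 1e-12)
  expect_equal(fit$intercept_tsrt, 46.765, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_false(any(fit$outlier_mask))
  expect_false(fit$fallback_used)
})

test_that("two points give the interpolating line without exclusion", {
  pts <- tibble::tibble(mean_speed = c(50, 150), dsrt = c(40, 10))
  fit <- fit_lambda(pts)
  expect_equal(fit$slope, -0.3)
  expect_equal(fit$intercept_tsrt, 55)
  expect_equal(fit$n_points, 2L)
})

test_that("a planted gross outlier is flagged, and only it", {
  set.seed(21)
  v <- seq(30, 170, length.out = 15)
  noise <- rnorm(15, 0, 1)
  dsrt <- 46.765 - 0.277 * v + noise
  dsrt[8] <- dsrt[8] + 25  # residual >> 5x the on-line noise
  fit <- fit_lambda(tibble::tibble(mean_speed = v, dsrt = dsrt))
  expect_identical(which(fit$outlier_mask), 8L)
  expect_equal(fit$n_points, 14L)
  # closed-form normal-equations oracle, with and without the planted point
  ne <- function(x, y) {
    b <- solve(cbind(1, x) |> crossprod(), crossprod(cbind(1, x), y))
    c(intercept = b[1], slope = b[2])
  }
  with_out <- ne(v, dsrt)
  without <- ne(v[-8], dsrt[-8])
  expect_equal(fit$intercept_tsrt, unname(without["intercept"]),
               tolerance = 1e-10)
  # exclusion moves the intercept towards the generative 46.765
  expect_lt(abs(without["intercept"] - 46.765),
            abs(with_out["intercept"] - 46.765))
  # r2 stored matches r2 recomputed from retained points
  keep <- !fit$outlier_mask
  expect_equal(fit$r2,
               summary(lm(dsrt[keep] ~ v[keep]))$r.squared,
               tolerance = 1e-9)
})

test_that("exclusion is one-shot: no cascade beyond the initial flags", {
  set.seed(33)
  for (rep in 1:10) {
    v <- runif(12, 30, 180)
    dsrt <- 50 - 0.25 * v + rnorm(12, 0, 4)
    fit <- fit_lambda(tibble::tibble(mean_speed = v, dsrt = dsrt))
    fit0 <- lm(dsrt ~ v)
    pi <- suppressWarnings(predict(fit0, interval = "prediction"))
    first_pass <- dsrt < pi[, "lwr"] | dsrt > pi[, "upr"]
    expect_identical(fit$outlier_mask, unname(first_pass))
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_lambda(tibble::tibble(mean_speed = 50, dsrt = 20)),
               class = "spastr_lambda_error")
  expect_error(
    fit_lambda(tibble::tibble(mean_speed = rep(80, 5),
                              dsrt = rnorm(5, 30))),
    "ill-conditioned", class = "spastr_lambda_error")
})

test_that("no-response sessions fall back to TSRT = 120", {
  p0 <- fixed_params("0", gain = 0.03)
  pts <- lapply(1:6, function(s) {
    preprocess_trial(quick_trial(p0, peak_velocity = 90 + 25 * s,
                                 seed = 70 + s))
  })
  fit <- extract_tsrt(pts)
  expect_true(fit$fallback_used)
  expect_equal(fit$intercept_tsrt, 120)
  expect_true(is.na(fit$slope))
})

test_that("the majority boundary is handled as documented (half -> fallback)", {
  mk <- function(onset) fake_pt(rep(100, 400), move_on = 101, move_off = 300,
                                emg_onset = onset)
  with_onsets <- lapply(c(1201, 1401, 1601), mk)
  without <- lapply(1:3, function(i) mk(NA_integer_))
  # exactly half the QC-passed trials have onsets: fraction == majority
  fit_half <- extract_tsrt(c(with_onsets, without))
  expect_true(fit_half$fallback_used)
  # strictly above half: regression path (needs distinct speeds)
  spd <- c(60, 100, 140, 180)
  ons <- c(1301, 1201, 1181, 1151)
  above <- c(purrr::map2(spd, ons, function(s, o)
    fake_pt(rep(s, 400), move_on = 101, move_off = 300, emg_onset = o)),
    list(mk(NA_integer_)))
  fit_above <- extract_tsrt(above)
  expect_false(fit_above$fallback_used)
  # zero QC-passed trials -> error
  bad <- list(fake_pt(rep(0, 400), qc_pass = FALSE))
  expect_error(extract_tsrt(bad), "empty session",
               class = "spastr_lambda_error")
})

test_that("TSRT recovery: known thresholds, noisy DSRT points", {
  # 20 subjects, 15 trials each, DSRT noise SD 3 degrees
  set.seed(123)
  tsrt_true <- runif(20, 25, 60)
  slopes <- runif(20, -0.3, -0.15)
  err <- vapply(1:20, function(i) {
    pts <- simulate_dsrt_points(tsrt_true[i], slopes[i], n_trials = 15,
                                noise_sd = 3, seed = 500 + i)
    fit_lambda(pts)$intercept_tsrt - tsrt_true[i]
  }, numeric(1))
  expect_lt(mean(abs(err)), 3)
})

test_that("fitted slope is negative whenever the generative slope is", {
  for (i in 1:6) {
    pts <- simulate_dsrt_points(40 + 5 * i, -0.1 - 0.03 * i, n_trials = 15,
                                noise_sd = 0, seed = i)
    expect_lt(fit_lambda(pts)$slope, 0)
  }
})

test_that("lambda_fit tidiers expose points and summary", {
  pts <- simulate_dsrt_points(48, -0.25, seed = 8)
  fit <- fit_lambda(pts)
  td <- tidy(fit)
  expect_equal(nrow(td), nrow(pts))
  expect_true("outlier" %in% names(td))
  gl <- glance(fit)
  expect_equal(gl$tsrt, fit$intercept_tsrt)
  expect_false(gl$fallback_used)
})
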