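test_that("spike duration at 25% matches triangles and Gaussians", {
  rate <- 24000
  # symmetric triangle of base width W: width at 25% is 0.75 W
  n <- 97                                 # odd: exact apex sample
  tri <- -c(seq(0, 1, length.out = (n + 1) / 2),
            seq(1, 0, length.out = (n + 1) / 2)[-1])
  W <- (n - 1) / rate * 1000
  expect_equal(spike_duration_at_25pct(tri, rate), 0.75 * W,
               tolerance = 1e-6)

  # Gaussian: width 2 sigma sqrt(2 ln 4)
  sigma_ms <- 0.12
  tt <- seq(-1, 1, by = 1000 / rate)
  g <- -exp(-tt^2 / (2 * sigma_ms^2))
  expect_equal(spike_duration_at_25pct(g, rate),
               2 * sigma_ms * sqrt(2 * log(4)), tolerance = 6e-3)

  expect_error(spike_duration_at_25pct(rep(0, 50), rate), "flat")
})

test_that("autocorrelation first moment: pairs, Poisson, oracle, reversal", {
  # isolated pairs 3 ms apart, pairs separated by 500 ms
  st <- as.vector(vapply(0:49, function(k) 0.5 * k + c(0, 0.003),
                         numeric(2)))
  expect_equal(autocorr_first_moment(st), 3, tolerance = 0.26)

  # long Poisson train: uniform lag density on (0, 25] -> mean 12.5 ms
  set.seed(15)
  pois <- cumsum(rexp(20000, 10))
  expect_lt(abs(autocorr_first_moment(pois) - 12.5), 0.5)

  for (i in 1:100) {
    st2 <- sort(runif(30, 0, 0.5))
    expect_equal(autocorr_first_moment(st2),
                 oracle_ac_first_moment(st2, 25, 0.5), tolerance = 1e-9)
  }

  # time reversal leaves the lag histogram unchanged
  st3 <- sort(runif(100, 0, 2))
  rev3 <- sort(1000 - st3)
  expect_equal(autocorr_first_moment(st3), autocorr_first_moment(rev3),
               tolerance = 1e-9)

  expect_error(autocorr_first_moment(c(0, 10)), "no lags")
})

test_that("template building is order-invariant and handles degeneracy", {
  set.seed(16)
  f <- gen_unit_population(n_pyramidal = 30, n_interneuron = 0, seed = 4)
  t1 <- build_template(f)
  t2 <- build_template(f[sample(nrow(f)), ])
  expect_equal(t1$mean, t2$mean)
  expect_equal(t1$cov, t2$cov)

  # identical units: singular covariance regularized, distances finite
  fid <- f[rep(1, 6), ]
  td <- build_template(fid)
  d <- template_distance(f[1:3, ], td)
  expect_true(all(is.finite(d)))

  expect_error(build_template(f[1:3, ]), "at least 4")
})

test_that("template mean estimates the cluster mean within 3 SE", {
  errs <- vapply(1:50, function(s) {
    f <- gen_unit_population(n_pyramidal = 25, n_interneuron = 0, seed = s)
    tm <- build_template(f)
    (tm$mean[["spike_duration"]] - 0.35) / (0.00345 / sqrt(25))
  }, numeric(1))
  expect_lt(mean(abs(errs) > 3), 0.05)
})

test_that("mahalanobis distance matches the solve-based oracle", {
  f <- gen_unit_population(seed = 6)
  tm <- build_template(f[f$class == "pyramidal", ])
  d <- template_distance(f, tm)
  expect_gt(unname(d[1]), 0)
  m <- as.matrix(f[, c("rate_feature", "ac_first_moment", "spike_duration")])
  d_oracle <- sqrt(stats::mahalanobis(m, tm$mean, tm$cov))
  expect_equal(unname(d), unname(d_oracle), tolerance = 1e-10)

  # x = mu -> 0; identity covariance unit offset -> 1
  t0 <- structure(list(mean = c(rate_feature = 0, ac_first_moment = 0,
                                spike_duration = 0), cov = diag(3)),
                  class = "pyramidal_template")
  probe <- tibble::tibble(unit_id = c("a", "b"),
                          rate_feature = c(0, 1), ac_first_moment = 0,
                          spike_duration = 0)
  expect_equal(unname(template_distance(probe, t0)), c(0, 1))
})

test_that("mahalanobis is invariant under joint affine transforms", {
  set.seed(17)
  f <- gen_unit_population(seed = 8)
  tm <- build_template(f[f$class == "pyramidal", ])
  d0 <- template_distance(f, tm)
  A <- matrix(rnorm(9), 3)
  while (abs(det(A)) < 0.1) A <- matrix(rnorm(9), 3)
  b <- rnorm(3)
  m <- as.matrix(f[, c("rate_feature", "ac_first_moment", "spike_duration")])
  mt <- sweep(m %*% t(A), 2, -b)
  f2 <- f
  f2$rate_feature <- mt[, 1]; f2$ac_first_moment <- mt[, 2]
  f2$spike_duration <- mt[, 3]
  tm2 <- list(mean = as.numeric(A %*% tm$mean + b),
              cov = A %*% tm$cov %*% t(A))
  names(tm2$mean) <- names(tm$mean)
  d1 <- template_distance(f2, structure(tm2, class = "pyramidal_template"))
  expect_equal(d0, d1, tolerance = 1e-8)
})

test_that("classification thresholds are exactly 20 and 40", {
  lab <- classify_units(c(10, 30, 50, 20, 40, 0, 19.999, 40.001))
  expect_equal(as.character(lab),
               c("pyramidal", "unclassified", "interneuron", "unclassified",
                 "unclassified", "pyramidal", "pyramidal", "interneuron"))
  expect_error(classify_units(-1), "non-negative")
})

test_that("isolation distance is the n-th smallest noise distance", {
  set.seed(18)
  # constant-distance noise: all at distance D
  cl <- matrix(rnorm(100 * 4), ncol = 4)
  mu <- colMeans(cl); S <- stats::cov(cl)
  # construct noise points at fixed Mahalanobis distance via Cholesky
  L <- chol(S)
  dirs <- matrix(rnorm(120 * 4), ncol = 4)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  D <- 3.7
  noise <- sweep(dirs %*% (L * D), 2, mu, "+")
  expect_equal(isolation_distance(cl, noise), D, tolerance = 1e-8)

  # explicit order statistic: n = 3, distances {1, 2, 5, 9} -> 5
  cl2 <- matrix(rnorm(6), ncol = 2)
  mu2 <- colMeans(cl2); S2 <- stats::cov(cl2)
  want <- c(1, 2, 5, 9)
  L2 <- chol(S2)
  noise2 <- t(vapply(want, function(dd) {
    v <- c(1, 0); as.numeric(mu2 + (v / sqrt(sum(v^2))) %*% (L2 * dd))
  }, numeric(2)))
  expect_equal(isolation_distance(cl2, noise2), 5, tolerance = 1e-8)

  # sort-based oracle on random clusters
  for (i in 1:20) {
    cl3 <- matrix(rnorm(40 * 3), ncol = 3)
    no3 <- matrix(rnorm(80 * 3, sd = 2), ncol = 3)
    d2 <- stats::mahalanobis(no3, colMeans(cl3), stats::cov(cl3))
    expect_equal(isolation_distance(cl3, no3), sqrt(sort(d2)[40]),
                 tolerance = 1e-10)
  }

  expect_warning(v <- isolation_distance(matrix(rnorm(40), 10),
                                         matrix(rnorm(20), 5)),
                 "undefined")
  expect_identical(v, Inf)
})

test_that("unit features land in the expected ranges for generated cells", {
  wf <- gen_waveform("pyramidal", jitter = 0)
  expect_lt(abs(spike_duration_at_25pct(wf$waveform, wf$rate) - 0.35), 0.05)
  wfi <- gen_waveform("interneuron", jitter = 0)
  expect_lt(abs(spike_duration_at_25pct(wfi$waveform, wfi$rate) - 0.15), 0.03)
})
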