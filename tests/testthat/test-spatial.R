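uniform_track <- function(dur = 300, seed = 1) {
  # lawnmower path with constant sweep speed: uniform coverage
  set.seed(seed)
  tt <- seq(0, dur, by = 0.04)
  x <- 35 + 34.9 * triangle_wave(tt, 7.3)
  y <- 35 + 34.9 * triangle_wave(tt + 17, 211)
  position_track(tt, x, y)
}

test_that("occupancy conserves time mass and needs moving samples", {
  tr <- uniform_track()
  sp <- compute_speed(tr)
  ar <- open_field_arena()
  occ <- occupancy_map(tr, sp, ar)
  expect_lt(abs(sum(occ$occupancy) / occ$total_time - 1), 0.001)

  # all time in one bin: mass conserved through smoothing at the edge
  tt <- seq(0, 10, by = 0.04)
  tr1 <- position_track(tt, rep(1, length(tt)), rep(1, length(tt)))
  sp1 <- tibble::tibble(time = tt, speed = rep(5, length(tt)), valid = TRUE)
  occ1 <- occupancy_map(tr1, sp1, ar)
  expect_lt(abs(sum(occ1$occupancy) / occ1$total_time - 1), 0.001)
  # the spot is a smoothed blob peaked at the corner bin
  expect_equal(which(occ1$occupancy == max(occ1$occupancy), arr.ind = TRUE),
               matrix(c(1L, 1L), 1, dimnames = list(NULL, c("row", "col"))))

  expect_error(occupancy_map(tr, sp, ar, min_speed = 1e6), "min_speed")
})

test_that("uniform dwell gives near-uniform smoothed occupancy", {
  tr <- uniform_track(600)
  sp <- compute_speed(tr)
  occ <- occupancy_map(tr, sp, open_field_arena())
  inner <- occ$occupancy[4:32, 4:32]
  expect_lt(max(abs(inner / mean(inner) - 1)), 0.5)
  # edge renormalization: border bins not systematically depressed
  expect_gt(mean(occ$occupancy[1, ]) / mean(inner), 0.5)
})

test_that("rate maps recover homogeneous and spatially confined firing", {
  set.seed(19)
  tr <- uniform_track(600)
  sp <- compute_speed(tr)
  ar <- open_field_arena()
  dur <- max(tr$time)
  # homogeneous Poisson at 4 Hz
  st <- sort(runif(round(4 * dur), 0, dur))
  m <- rate_map(st, tr, sp, ar)
  expect_lt(abs(mean(m$rate[m$visited]) - 4), 0.2)

  # zero spikes
  m0 <- rate_map(numeric(0), tr, sp, ar)
  expect_true(all(m0$rate[m0$visited] == 0))

  # left-half-only firing: right half beyond 3 kernel SDs is ~0
  xs <- approx(tr$time, tr$x, xout = st)$y
  stl <- st[xs < 35]
  ml <- rate_map(stl, tr, sp, ar)
  right <- ml$rate[ml$edges$x[-1] > 35 + 9, ]
  expect_lt(max(right, na.rm = TRUE), 0.2)
})

test_that("information and sparsity identities hold exactly", {
  # uniform rate: zero information, sparsity 1
  u <- make_map(matrix(5, 10, 10))
  expect_equal(spatial_information(u), 0, tolerance = 1e-12)
  expect_equal(sparsity(u), 1, tolerance = 1e-12)

  # firing in 1 of 4 equally occupied bins: log2(4) bits, sparsity 1/4
  m <- make_map(matrix(c(8, 0, 0, 0), 2, 2))
  expect_equal(spatial_information(m), 2, tolerance = 1e-12)
  expect_equal(sparsity(m), 0.25, tolerance = 1e-12)

  expect_error(spatial_information(make_map(matrix(0, 3, 3))), "zero")
})

test_that("information/sparsity match direct sums and scale invariance", {
  set.seed(20)
  for (i in 1:100) {
    r <- matrix(rexp(64, 1 / 3), 8, 8)
    occ <- matrix(runif(64, 0.5, 2), 8, 8)
    m <- make_map(r, occ)
    p <- occ / sum(occ)
    lam <- sum(p * r)
    info_oracle <- sum((p * (r / lam) * log2(r / lam))[r > 0])
    spars_oracle <- lam^2 / sum(p * r^2)
    expect_equal(spatial_information(m), info_oracle, tolerance = 1e-12)
    expect_equal(sparsity(m), spars_oracle, tolerance = 1e-12)
    # positive scaling changes neither
    m2 <- make_map(3.7 * r, occ)
    expect_equal(spatial_information(m2), info_oracle, tolerance = 1e-10)
    expect_equal(sparsity(m2), spars_oracle, tolerance = 1e-10)
    expect_gte(spatial_information(m), 0)
    expect_true(sparsity(m) > 0 && sparsity(m) <= 1)
  }
})

test_that("map stability equals the Pearson formula with common-bin masking", {
  set.seed(21)
  r1 <- matrix(rexp(100), 10, 10)
  m1 <- make_map(r1)
  expect_equal(map_stability(m1, m1), 1, tolerance = 1e-12)
  m2 <- make_map(max(r1) + 1 - r1)
  expect_equal(map_stability(m1, m2), -1, tolerance = 1e-12)
  for (i in 1:50) {
    a <- matrix(rexp(100), 10, 10); b <- matrix(rexp(100), 10, 10)
    expect_equal(map_stability(make_map(a), make_map(b)),
                 oracle_pearson(as.vector(a), as.vector(b)),
                 tolerance = 1e-12)
  }
  # too few common visited bins -> NA
  m3 <- make_map(r1)
  m3$visited[, ] <- FALSE
  m3$visited[1, 1:5] <- TRUE
  expect_true(is.na(map_stability(m1, m3)))
})

test_that("2D field detection obeys peak, extent and size rules", {
  # all sub-threshold: nothing
  low <- make_map(matrix(4.9, 12, 12))
  expect_equal(nrow(detect_fields_2d(low)), 0)

  # single Gaussian bump, peak 10 Hz, SD 6 cm on a flat background
  cx <- seq(1, 70, by = 2)
  g <- outer(cx, cx, function(a, b)
    10 * exp(-((a - 35)^2 + (b - 35)^2) / (2 * 6^2)))
  mg <- make_map(g)
  f <- detect_fields_2d(mg)
  expect_equal(nrow(f), 1)
  expect_equal(f$n_bins, oracle_flood_fields_2d(g))
  expect_lt(abs(f$centroid_x - 35), 2)

  # two bumps with a deep valley: two fields
  g2 <- outer(cx, cx, function(a, b)
    10 * exp(-((a - 18)^2 + (b - 35)^2) / (2 * 5^2)) +
      10 * exp(-((a - 52)^2 + (b - 35)^2) / (2 * 5^2)))
  f2 <- detect_fields_2d(make_map(g2))
  expect_equal(nrow(f2), 2)
  expect_equal(sort(f2$n_bins), sort(oracle_flood_fields_2d(g2)))
})

test_that("field detection matches the flood-fill oracle on random maps", {
  set.seed(22)
  for (i in 1:100) {
    r <- matrix(0, 15, 15)
    for (k in 1:sample(1:3, 1)) {
      cx <- runif(2, 3, 13); pk <- runif(1, 6, 12); s <- runif(1, 1, 2.5)
      r <- r + outer(1:15, 1:15, function(a, b)
        pk * exp(-((a - cx[1])^2 + (b - cx[2])^2) / (2 * s^2)))
    }
    f <- detect_fields_2d(make_map(r))
    expect_equal(sort(f$n_bins), sort(oracle_flood_fields_2d(r)))
  }
})

test_that("1D field extension stops at 20% of the peak", {
  edges1 <- seq(0, 100, by = 2)
  mk1 <- function(rate) {
    structure(list(rate = rate, occupancy = rep(1, length(rate)),
                   raw_occupancy = rep(1, length(rate)),
                   visited = rep(TRUE, length(rate)),
                   edges = list(x = edges1), dims = 1L,
                   n_spikes = NA_integer_, bin_size = 2,
                   direction = "northbound"),
              class = "rate_map")
  }
  expect_equal(nrow(detect_fields_1d(mk1(rep(1, 50)))), 0)

  # triangular bump peaking at 8 Hz: boundaries where rate crosses 1.6 Hz
  ctr <- (edges1[-1] + edges1[-51]) / 2
  tri <- pmax(0, 8 - abs(ctr - 50) / 2.5)
  f <- detect_fields_1d(mk1(tri))
  expect_equal(nrow(f), 1)
  # rate crosses 1.6 at |x-50| = 16 -> bins covering [34, 66]
  expect_lt(abs(f$start - 34), 2.1)
  expect_lt(abs(f$end - 66), 2.1)
  expect_equal(f$direction, "northbound")

  # valley at 30% of the lower peak separates two fields
  two <- 10 * exp(-(ctr - 30)^2 / 72) + 6 * exp(-(ctr - 70)^2 / 72)
  f2 <- detect_fields_1d(mk1(two))
  expect_equal(nrow(f2), 2)
})
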