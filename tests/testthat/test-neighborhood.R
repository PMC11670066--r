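# brute-force oracles: naive double loops, independent of the implementation
brute_dist <- function(col) {
  n <- nrow(col)
  d <- matrix(0, n, n, dimnames = list(col$colony_id, col$colony_id))
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sqrt((col$x[i] - col$x[j])^2 + (col$y[i] - col$y[j])^2)
  d
}

brute_metrics <- function(id, col, radius = NULL, lambda = NULL) {
  i <- which(col$colony_id == id)
  nn <- Inf; cnt <- 0; wa <- 0
  for (j in seq_len(nrow(col))) {
    if (j == i || !col$gravid[j]) next
    d <- sqrt((col$x[i] - col$x[j])^2 + (col$y[i] - col$y[j])^2)
    nn <- min(nn, d)
    if (!is.null(radius) && d <= radius) {
      cnt <- cnt + 1
      if (!is.null(lambda)) wa <- wa + col$planar_area[j] * exp(-d / lambda)
    }
  }
  list(nn = nn, count = cnt, wa = wa)
}

test_that("pairwise distances are Euclidean, symmetric, zero-diagonal", {
  col <- toy_colonies(c(0, 3), c(0, 4))
  d <- pairwise_distances(col)
  expect_equal(d[1, 2], 5)
  expect_equal(d[2, 1], 5)
  expect_equal(diag(d), c(T01 = 0, T02 = 0))
  expect_equal(unname(pairwise_distances(toy_colonies(2, 3))), matrix(0, 1, 1))

  set.seed(21)
  rc <- toy_colonies(runif(30, 0, 100), runif(30, 0, 60))
  expect_equal(pairwise_distances(rc), brute_dist(rc), tolerance = 1e-12)
})

test_that("nearest gravid neighbour ignores non-gravid colonies", {
  col <- toy_colonies(c(0, 1, 2, 0.5), c(0, 0, 0, 0),
                      gravid = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(nearest_gravid_neighbor("T01", col), 1)
  lone <- toy_colonies(c(0, 1), c(0, 0), gravid = c(TRUE, FALSE))
  expect_error(nearest_gravid_neighbor("T01", lone), "isolated")
})

test_that("density uses a closed radius boundary and is monotone in radius", {
  col <- toy_colonies(c(0, 1.9, 2.1), c(0, 0, 0))
  expect_equal(density_within("T01", col, 2), 1)
  expect_equal(density_within("T01", col, 2.1), 2)  # tie at r included

  set.seed(22)
  rc <- toy_colonies(runif(40, 0, 30), runif(40, 0, 30),
                     gravid = runif(40) < 0.8)
  for (id in rc$colony_id[rc$gravid][1:5]) {
    d2 <- density_within(id, rc, 2)
    d5 <- density_within(id, rc, 5)
    d10 <- density_within(id, rc, 10)
    expect_true(d2 <= d5 && d5 <= d10)
  }
})

test_that("neighbourhood metrics match the naive double-loop oracle", {
  set.seed(23)
  rc <- toy_colonies(runif(50, 0, 60), runif(50, 0, 40),
                     gravid = runif(50) < 0.7,
                     area = exp(rnorm(50, log(0.2), 0.5)))
  cfg <- run_config()
  targets <- rc$colony_id[rc$gravid]
  m <- compute_all_metrics(targets, rc, cfg)
  for (id in targets) {
    o <- brute_metrics(id, rc, radius = 10, lambda = cfg$lambda)
    r <- m[m$colony_id == id, ]
    expect_equal(r$nn_m, o$nn, tolerance = 1e-12)
    expect_equal(r$density_10m, o$count)
    expect_equal(r$weighted_area_10m_m2, o$wa, tolerance = 1e-12)
    o5 <- brute_metrics(id, rc, radius = 5)
    expect_equal(r$density_5m, o5$count)
  }
})

test_that("weighted area is bounded by the unweighted total and reaches it as
          the decay length grows", {
  col <- toy_colonies(c(0, 0), c(0, 0))  # neighbour at distance 0
  expect_equal(weighted_colony_area("T01", col, radius = 10), 1)

  set.seed(24)
  rc <- toy_colonies(runif(30, 0, 20), runif(30, 0, 20),
                     area = runif(30, 0.1, 2))
  d <- pairwise_distances(rc)
  id <- "T01"
  raw <- sum(rc$planar_area[-1][d[1, -1] <= 10])
  expect_lte(weighted_colony_area(id, rc, 10, lambda = 5), raw)
  expect_equal(weighted_colony_area(id, rc, 10, lambda = 1e9), raw,
               tolerance = 1e-6)
})

test_that("metrics are invariant under rigid motions of the map", {
  set.seed(25)
  rc <- toy_colonies(runif(40, 0, 50), runif(40, 0, 50),
                     gravid = runif(40) < 0.75,
                     area = runif(40, 0.05, 1))
  cfg <- run_config()
  m0 <- compute_all_metrics(colonies = rc, config = cfg)
  th <- 0.7
  rot <- rc
  rot$x <- cos(th) * rc$x - sin(th) * rc$y + 120
  rot$y <- sin(th) * rc$x + cos(th) * rc$y - 40
  m1 <- compute_all_metrics(colonies = rot, config = cfg)
  expect_equal(m0$nn_m, m1$nn_m, tolerance = 1e-9)
  expect_equal(m0$density_2m, m1$density_2m)
  expect_equal(m0$weighted_area_10m_m2, m1$weighted_area_10m_m2,
               tolerance = 1e-9)
})
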