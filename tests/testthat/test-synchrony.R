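test_that("pair construction enumerates same-night pairs with correct
          time differences", {
  col <- toy_colonies(c(0, 3, 6, 10, 20), c(0, 0, 0, 0, 0))
  d <- pairwise_distances(col)
  ev <- toy_events(col$colony_id[1:3], "n1", minute = c(4, 9, 1),
                   observer = c("a", "a", "b"))
  pr <- build_pairs(ev, d)
  expect_equal(nrow(pr), 3)  # C(3,2)
  r <- pr[pr$colony_a == "T01" & pr$colony_b == "T02", ]
  expect_equal(r$abs_dt_min, 5)
  expect_equal(r$distance_m, 3)
  expect_true(r$same_observer)

  # hand enumeration for five colonies over two nights
  ev5 <- rbind(toy_events(col$colony_id, "n1", c(1, 3, 6, 10, 2),
                          observer = c("a", "a", "b", "b", "a")),
               toy_events(col$colony_id[1:3], "n2", c(2, 2, 8)))
  pr5 <- build_pairs(ev5, d)
  expect_equal(nrow(pr5), choose(5, 2) + choose(3, 2))
  expect_equal(sort(pr5$abs_dt_min[pr5$night == "n2"]), c(0, 6, 6))

  # output independent of event row order
  perm <- ev5[sample(nrow(ev5)), ]
  expect_equal(build_pairs(perm, d), pr5)

  expect_error(build_pairs(toy_events("ZZ", "n1", 1), d), "missing from map")
})

test_that("the synchrony regression reports slope, naive and permutation
          p-values reproducibly", {
  fx <- make_study_fixture(seed = 6)
  d <- pairwise_distances(fx$colonies)
  pr <- build_pairs(fx$events, d)
  m1 <- sum(fx$events$night == "n1" & !is.na(fx$events$release_minute) &
              fx$events$extent != "none")
  m2 <- sum(fx$events$night == "n2" & !is.na(fx$events$release_minute) &
              fx$events$extent != "none")
  expect_equal(nrow(pr), choose(m1, 2) + choose(m2, 2))

  f1 <- fit_synchrony_model(pr, n_perm = 499, seed = 99)
  f2 <- fit_synchrony_model(pr, n_perm = 499, seed = 99)
  expect_identical(f1$perm_p, f2$perm_p)
  expect_true(is.finite(f1$slope) && is.finite(f1$naive_p))
  expect_s3_class(f1$per_night, "data.frame")

  # relabelling colony ids leaves the permutation p unchanged
  pr2 <- pr
  pr2$colony_a <- paste0("X", pr$colony_a)
  pr2$colony_b <- paste0("X", pr$colony_b)
  f3 <- fit_synchrony_model(pr2, n_perm = 499, seed = 99)
  expect_equal(f3$perm_p, f1$perm_p)
  expect_equal(f3$slope, f1$slope)
})

test_that("degenerate and collinear inputs are handled with notes", {
  col <- toy_colonies(c(0, 5, 9), c(0, 0, 0))
  d <- pairwise_distances(col)
  ev <- toy_events(col$colony_id, "n1", minute = c(3, 3, 3))
  f <- fit_synchrony_model(build_pairs(ev, d), n_perm = 99)
  expect_equal(f$slope, 0)
  expect_match(f$note, "degenerate")

  ev2 <- toy_events(col$colony_id, "n1", minute = c(1, 5, 9),
                    observer = "same")
  f2 <- fit_synchrony_model(build_pairs(ev2, d), n_perm = 99)
  expect_match(f2$note, "observer")
  expect_false("same_observer" %in% rownames(f2$coefficients))
})

test_that("the generator's distance-decaying synchrony is recovered by the
          regression", {
  set.seed(41)
  p <- gen_params()
  sl <- replicate(40, {
    col <- generate_colony_map(p)
    ev <- simulate_spawn_schedule(col, p)
    fit_synchrony_model(build_pairs(ev, pairwise_distances(col)),
                        n_perm = 9)$slope
  })
  expect_lt(abs(mean(sl) / p$synchrony_slope - 1), 0.5)
})

test_that("spawning intensity differs between nights as configured", {
  fx <- make_study_fixture(seed = 2)
  res <- compare_spawning_intensity(fx$events)
  expect_equal(nrow(res$table), 2)
  expect_true(all(res$table$prop_released >= res$table$prop_extensive))
  expect_true(is.finite(res$p_value))

  set.seed(42)
  pos <- replicate(40, {
    p2 <- gen_params(extensive_prob = c(n1 = 0.3, n2 = 0.6))
    col <- generate_colony_map(p2)
    ev <- simulate_spawn_schedule(col, p2)
    compare_spawning_intensity(ev)$night_effect > 0
  })
  expect_gte(sum(pos), 36)  # doubled extensive odds detected as positive

  fx$events$extent <- NA_character_
  expect_error(compare_spawning_intensity(fx$events), "assessed")
})

test_that("damage comparison recovers the configured night ratio", {
  fx <- make_study_fixture(seed = 13)
  res <- compare_damage(fx$samples)
  expect_gt(res$odds_ratio_n1_vs_n2, 1)
})
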