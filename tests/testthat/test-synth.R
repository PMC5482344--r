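test_that("degenerate status probabilities force single-color networks", {
  net <- generate_random_network(5, 4, 1, 0, 0, seed = 1)
  expect_true(all(net$status == "active"))
  expect_identical(drugs(net), paste0("d", 1:5))
  expect_identical(targets(net), paste0("t", 1:4))
})

test_that("generation is deterministic given the seed", {
  a <- generate_random_network(20, 10, 0.3, 0.3, 0.4, seed = 99)
  b <- generate_random_network(20, 10, 0.3, 0.3, 0.4, seed = 99)
  expect_identical(a$status, b$status)
  c <- generate_random_network(20, 10, 0.3, 0.3, 0.4, seed = 100)
  expect_false(identical(a$status, c$status))
})

test_that("empirical status fractions match the sampling distribution", {
  # two-sided 99% binomial interval for 10,000 draws at p = 0.3
  lo <- qbinom(0.005, 10000, 0.3) / 10000
  hi <- qbinom(0.995, 10000, 0.3) / 10000
  net <- generate_random_network(100, 100, 0.3, 0.5, 0.2, seed = 123)
  frac_active <- mean(net$status == "active")
  expect_gte(frac_active, lo)
  expect_lte(frac_active, hi)
})

test_that("invalid generator configurations are rejected", {
  expect_error(generate_random_network(5, 4, 0.5, 0.5, 0.5, seed = 1),
               class = "ternet_invalid_input")
  expect_error(generate_random_network(5, 4, -0.1, 0.6, 0.5, seed = 1),
               class = "ternet_invalid_input")
  expect_error(generate_random_network(0, 4, seed = 1),
               class = "ternet_invalid_input")
  expect_error(generate_random_network(5, 4, 0.2, 0.3, 0.5),
               class = "ternet_invalid_input")
})

test_that("masking hides exactly the requested number of pairs", {
  truth <- generate_random_network(20, 10, 0.4, 0.6, 0, seed = 7)
  masked <- mask_network(truth, hide_fraction = 0.3, seed = 8)
  expect_identical(sum(masked$status == "unknown"), 60L)
  expect_equal(completeness(masked)$c_dt, 0.7)

  same <- mask_network(truth, hide_fraction = 0, seed = 8)
  expect_identical(same$status, truth$status)
  gone <- mask_network(truth, hide_fraction = 1, seed = 8)
  expect_true(all(gone$status == "unknown"))
  expect_equal(completeness(gone)$c_dt, 0)
})

test_that("masking hides statuses but never flips them", {
  truth <- generate_random_network(15, 12, 0.5, 0.5, 0, seed = 21)
  for (hf in c(0.2, 0.5, 0.8)) {
    masked <- mask_network(truth, hide_fraction = hf, seed = 22)
    determined <- masked$status != "unknown"
    expect_identical(masked$status[determined], truth$status[determined])
  }
})

test_that("dropping inactives emulates actives-only databases", {
  truth <- generate_random_network(10, 8, 0.4, 0.6, 0, seed = 31)
  masked <- mask_network(truth, hide_fraction = 0, drop_inactives = TRUE,
                         seed = 32)
  expect_false(any(masked$status == "inactive"))
  expect_identical(masked$status == "active", truth$status == "active")
})

test_that("masking requires a fully determined ground truth", {
  with_unknown <- generate_random_network(5, 5, 0.3, 0.3, 0.4, seed = 41)
  expect_error(mask_network(with_unknown, 0.1, seed = 42),
               class = "ternet_invalid_input")
  truth <- generate_random_network(5, 5, 0.5, 0.5, 0, seed = 43)
  expect_error(mask_network(truth, 1.5, seed = 44),
               class = "ternet_invalid_input")
  expect_error(mask_network(truth, 0.5), class = "ternet_invalid_input")
})

test_that("Bernoulli masking hides approximately the requested fraction", {
  truth <- generate_random_network(60, 50, 0.5, 0.5, 0, seed = 51)
  masked <- mask_network(truth, hide_fraction = 0.3, seed = 52,
                         bernoulli = TRUE)
  lo <- qbinom(0.005, 3000, 0.3) / 3000
  hi <- qbinom(0.995, 3000, 0.3) / 3000
  frac <- mean(masked$status == "unknown")
  expect_gte(frac, lo)
  expect_lte(frac, hi)
})

test_that("masked-view bounds always bracket the true active degrees", {
  truths <- random_truths(20, 12, 8, base_seed = 1300)
  for (i in seq_along(truths)) {
    truth <- truths[[i]]
    true_active <- entity_profiles(truth)$active
    for (hf in c(0.2, 0.6)) {
      masked <- mask_network(truth, hide_fraction = hf, seed = 1400 + i)
      b <- degree_bounds(masked)
      expect_true(all(b$lower <= true_active))
      expect_true(all(true_active <= b$upper))
    }
  }
})

test_that("hiding more makes completeness fall and bounds widen", {
  truth <- generate_random_network(25, 15, 0.4, 0.6, 0, seed = 61)
  fractions <- c(0, 0.2, 0.4, 0.6, 0.8, 1)
  widths <- numeric(0)
  comps <- numeric(0)
  for (k in seq_along(fractions)) {
    # nested hiding: reuse one seed so larger fractions hide supersets
    masked <- mask_network(truth, hide_fraction = fractions[k], seed = 62)
    comps[k] <- completeness(masked)$c_dt
    b <- degree_bounds(masked)
    widths[k] <- sum(b$upper - b$lower)
  }
  expect_true(all(diff(comps) <= 0))
  expect_true(all(diff(widths) >= 0))
})
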