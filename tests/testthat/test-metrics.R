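test_that("colored degrees reproduce the fixture's published counts", {
  net <- load_worked_example()
  expect_identical(colored_degree(net, "d1", "drug", "active"), 3L)
  expect_identical(colored_degree(net, "t3", "target", "active"), 4L)
  expect_identical(colored_degree(net, "d6", "drug", "inactive"), 2L)
  expect_identical(colored_degree(net, "d3", "drug", "unknown"), 2L)
  expect_error(colored_degree(net, "d9", "drug", "active"),
               class = "ternet_lookup_error")
  expect_error(colored_degree(net, "d1", "target", "active"),
               class = "ternet_lookup_error")
})

test_that("profile vectors match the fixture and satisfy the sum identity", {
  net <- load_worked_example()
  d1 <- profile_vector(net, "d1", "drug")
  expect_identical(c(d1$active, d1$inactive, d1$unknown), c(3L, 0L, 1L))
  t4 <- profile_vector(net, "t4", "target")
  expect_identical(c(t4$active, t4$inactive, t4$unknown), c(5L, 3L, 0L))

  for (nw in random_networks(30, base_seed = 500)) {
    prof <- entity_profiles(nw)
    opp <- ifelse(prof$side == "drug", ncol(nw$status), nrow(nw$status))
    expect_true(all(prof$active + prof$inactive + prof$unknown == opp))
    expect_true(all(prof$active >= 0 & prof$inactive >= 0 & prof$unknown >= 0))
  }
})

test_that("polyspecificity equals polypharmacology on the transpose", {
  nets <- c(list(load_worked_example()), random_networks(100))
  for (nw in nets) {
    tr <- t(nw)
    for (tg in targets(nw)) {
      expect_identical(colored_degree(nw, tg, "target", "active"),
                       colored_degree(tr, tg, "drug", "active"))
    }
    for (d in drugs(nw)) {
      expect_identical(colored_degree(nw, d, "drug", "active"),
                       colored_degree(tr, d, "target", "active"))
    }
  }
})

test_that("global completeness counts determined pairs", {
  comp <- completeness(load_worked_example())
  expect_identical(c(comp$mu_plus, comp$mu_minus, comp$mu_star), c(19L, 7L, 6L))
  expect_equal(comp$c_dt, 26 / 32)
  expect_equal(round_half_up(comp$c_dt, 3), 0.813)

  none <- dtnet(matrix("unknown", 3, 3))
  expect_equal(completeness(none)$c_dt, 0)
  full <- dtnet(matrix(c("active", "inactive"), 2, 3))
  expect_equal(completeness(full)$c_dt, 1)

  for (nw in random_networks(30, base_seed = 600)) {
    comp <- completeness(nw)
    expect_identical(comp$mu_plus + comp$mu_minus + comp$mu_star,
                     as.integer(prod(dim(nw))))
    expect_gte(comp$c_dt, 0)
    expect_lte(comp$c_dt, 1)
  }
})

test_that("local uncertainty by rearrangement equals direct unknown counting", {
  nets <- c(list(load_worked_example()), random_networks(50, base_seed = 700))
  for (nw in nets) {
    lu <- local_uncertainty(nw)
    direct <- vapply(seq_len(nrow(lu)), function(i) {
      colored_degree(nw, lu$entity[i], lu$side[i], "unknown")
    }, integer(1))
    expect_identical(lu$uncertainty, direct)
  }
  expect_identical(local_uncertainty(load_worked_example(), "d3", "drug"), 2L)
  expect_identical(local_uncertainty(load_worked_example(), "t4", "target"), 0L)
  determined <- dtnet(matrix(c("active", "inactive"), 4, 3))
  expect_true(all(local_uncertainty(determined)$uncertainty == 0))
})

test_that("degree bounds reproduce the fixture's published intervals", {
  net <- load_worked_example()
  b <- degree_bounds(net)
  drugs_b <- b[b$side == "drug", ]
  expect_identical(drugs_b$lower, c(3L, 2L, 1L, 3L, 2L, 2L, 4L, 2L))
  expect_identical(drugs_b$upper, c(4L, 3L, 3L, 3L, 3L, 2L, 4L, 3L))
  targets_b <- b[b$side == "target", ]
  expect_identical(targets_b$lower, c(5L, 5L, 4L, 5L))
  expect_identical(targets_b$upper, c(7L, 6L, 7L, 5L))

  d3 <- degree_bounds(net, "d3", "drug")
  expect_identical(c(d3$lower, d3$upper), c(1L, 3L))
  expect_error(degree_bounds(net, "zzz", "drug"), class = "ternet_lookup_error")
})

test_that("bounds are ordered, capped, and collapse without unknowns", {
  for (nw in random_networks(30, base_seed = 800)) {
    b <- degree_bounds(nw)
    expect_true(all(b$lower >= 0))
    expect_true(all(b$lower <= b$upper))
    cap <- ifelse(b$side == "drug", ncol(nw$status), nrow(nw$status))
    expect_true(all(b$upper <= cap))
  }
  determined <- dtnet(matrix(c("active", "inactive"), 4, 3))
  b <- degree_bounds(determined)
  expect_identical(b$lower, b$upper)
})

test_that("determining an unknown pair never widens bounds nor drops completeness", {
  for (nw in random_networks(15, base_seed = 900)) {
    unknown_at <- which(nw$status == "unknown")
    if (!length(unknown_at)) next
    pick <- unknown_at[1]
    for (new_status in c("active", "inactive")) {
      upd <- nw
      upd$status[pick] <- new_status
      expect_gte(completeness(upd)$c_dt, completeness(nw)$c_dt)
      b0 <- degree_bounds(nw); b1 <- degree_bounds(upd)
      expect_true(all(b1$upper - b1$lower <= b0$upper - b0$lower))
      expect_true(all(b1$lower >= b0$lower))
      expect_true(all(b1$upper <= b0$upper))
    }
  }
})

test_that("profile distances behave like a metric and cosine like a similarity", {
  net <- load_worked_example()
  d2 <- profile_vector(net, "d2", "drug")
  d5 <- profile_vector(net, "d5", "drug")
  # both rows of the fixture give the profile (2, 1, 1)
  expect_equal(profile_distance(d2, d5, "euclidean"), 0)
  expect_equal(profile_distance(d2, d2, "cosine_similarity"), 1)
  expect_equal(profile_distance(c(3, 0, 1), c(6, 0, 2), "cosine_similarity"), 1)
  expect_equal(profile_distance(c(1, 0, 0), c(0, 1, 0), "cosine_similarity"), 0)
  expect_equal(profile_distance(c(3, 0, 0), c(0, 4, 0), "euclidean"), 5)

  expect_error(profile_distance(c(0, 0, 0), c(1, 1, 1), "cosine_similarity"),
               class = "ternet_invalid_input")
  t1 <- profile_vector(net, "t1", "target")
  expect_error(profile_distance(d2, t1), class = "ternet_invalid_input")

  dist_tab <- profile_distances(net, "drug", "cosine_similarity")
  expect_identical(nrow(dist_tab), 28L)
  expect_true(all(dist_tab$value >= 0 & dist_tab$value <= 1 + 1e-12))
})

test_that("the summary table combines degrees, bounds and completeness", {
  tab <- summary_table(load_worked_example())
  expect_identical(names(tab),
                   c("entity", "side", "active", "inactive", "unknown",
                     "lower_bound", "upper_bound"))
  expect_identical(tab$entity, c(fixture_drugs, fixture_targets))
  comp <- attr(tab, "completeness")
  expect_identical(c(comp$mu_plus, comp$mu_minus, comp$mu_star), c(19L, 7L, 6L))

  empty <- dt_network(
    tibble::tibble(drug = character(), target = character(),
                   status = character()),
    drugs = c("a", "b"), targets = c("x", "y")
  )
  tab0 <- summary_table(empty)
  expect_true(all(tab0$active == 0))
  expect_true(all(tab0$lower_bound == 0))
  expect_true(all(tab0$upper_bound == 2))
  expect_equal(attr(tab0, "completeness")$c_dt, 0)

  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_summary_tsv(tab, tmp)
  back <- readr::read_tsv(tmp, show_col_types = FALSE)
  expect_identical(nrow(back), 12L)
  expect_identical(back$lower_bound, as.double(tab$lower_bound))
})

test_that("fractional uncertainties appear only behind the normalize flag", {
  net <- load_worked_example()
  expect_false("frac_unknown" %in% names(entity_profiles(net)))
  prof <- entity_profiles(net, normalize = TRUE)
  expect_equal(prof$frac_unknown[prof$entity == "d3"], 2 / 4)
  expect_equal(prof$frac_unknown[prof$entity == "t3"], 3 / 8)
})
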