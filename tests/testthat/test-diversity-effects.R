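# Additive partition of the net diversity effect and proportional
# deviations.

test_that("expected biomass is monoculture mean times proportion", {
  expect_equal(expected_biomass(100, 0.5), 50)
  expect_equal(expected_biomass(100, 0), 0)
  expect_equal(expected_biomass(134.8, 0.2), 26.96)
  expect_error(expected_biomass(NA_real_, 0.5), "missing")
  expect_error(expected_biomass(100, 1.2))
})

test_that("worked two-species partitions reproduce exactly", {
  p1 <- additive_partition(c(a = 60, b = 120), c(a = 100, b = 200),
                           c(a = 0.5, b = 0.5))
  expect_equal(p1$net, 30)
  expect_equal(p1$complementarity, 30)
  expect_equal(p1$selection, 0)

  p2 <- additive_partition(c(a = 80, b = 80), c(a = 100, b = 200),
                           c(a = 0.5, b = 0.5))
  expect_equal(p2$net, 10)
  expect_equal(p2$complementarity, 30)
  expect_equal(p2$selection, -20)

  # observed equal to expected: all effects vanish
  p3 <- additive_partition(c(a = 50, b = 100), c(a = 100, b = 200),
                           c(a = 0.5, b = 0.5))
  expect_equal(c(p3$net, p3$complementarity, p3$selection), c(0, 0, 0))
})

test_that("net = complementarity + selection on 1000 random instances", {
  set.seed(2024)
  for (i in 1:1000) {
    inst <- random_partition_instance(sample(2:8, 1))
    p <- additive_partition(inst$observed, inst$mono, inst$prop)
    expect_equal(p$net, p$complementarity + p$selection,
                 tolerance = 1e-10)
  }
})

test_that("selection vanishes when all relative-yield deviations or all mono means are equal", {
  # equal delta-RY: observed = M * (p + c) so every dRY equals c
  m <- c(a = 120, b = 45, c = 210); p <- c(a = 0.3, b = 0.3, c = 0.4)
  obs <- m * (p + 0.25)
  pt <- additive_partition(obs, m, p)
  expect_equal(pt$selection, 0, tolerance = 1e-12)
  # equal mono means: covariance with a constant is zero
  m2 <- c(a = 100, b = 100, c = 100)
  obs2 <- c(a = 55, b = 20, c = 71)
  pt2 <- additive_partition(obs2, m2, p)
  expect_equal(pt2$selection, 0, tolerance = 1e-12)
})

test_that("partition is invariant to species order and scales linearly with biomass", {
  set.seed(5)
  inst <- random_partition_instance(5)
  pt <- additive_partition(inst$observed, inst$mono, inst$prop)
  shuf <- sample(names(inst$observed))
  pt_s <- additive_partition(inst$observed[shuf], inst$mono[shuf],
                             inst$prop[shuf])
  expect_equal(pt_s$net, pt$net, tolerance = 1e-12)
  expect_equal(pt_s$complementarity, pt$complementarity,
               tolerance = 1e-12)
  expect_equal(pt_s$selection, pt$selection, tolerance = 1e-12)
  pt_c <- additive_partition(3 * inst$observed, 3 * inst$mono, inst$prop)
  expect_equal(c(pt_c$net, pt_c$complementarity, pt_c$selection),
               3 * c(pt$net, pt$complementarity, pt$selection),
               tolerance = 1e-12)
})

test_that("degenerate partition inputs are rejected", {
  expect_error(additive_partition(c(a = 1), c(a = 2), c(a = 1)),
               "at least 2")
  expect_error(additive_partition(c(a = 1, b = 1), c(a = 0, b = 2),
                                  c(a = 0.5, b = 0.5)), "positive")
  # zero observed biomass is legal (delta RY = -p)
  pt <- additive_partition(c(a = 0, b = 100), c(a = 100, b = 100),
                           c(a = 0.5, b = 0.5))
  expect_equal(pt$delta_ry[["a"]], -0.5)
})

test_that("proportional deviations measure relative over/under-yielding", {
  expect_equal(proportional_deviation(100, 100), 0)
  expect_equal(proportional_deviation(150, 100), 0.5)
  expect_equal(proportional_deviation(50, 100), -0.5)
  expect_warning(d <- proportional_deviation(10, 0), "non-positive")
  expect_true(is.na(d))
})

test_that("group deviation pools biomass and closes with the net effect", {
  obs <- c(g1 = 60, g2 = 70, leg = 90)
  exp <- c(g1 = 50, g2 = 80, leg = 60)
  # full group: net = D_group * total expected
  d_all <- group_deviation(obs, exp, names(obs))
  expect_equal(d_all * sum(exp), sum(obs - exp), tolerance = 1e-12)
  # single-species group equals the species deviation
  expect_equal(group_deviation(obs, exp, "leg"),
               proportional_deviation(90, 60))
  # observed = expected within the group
  obs2 <- exp; obs2["leg"] <- 123
  expect_equal(group_deviation(obs2, exp, c("g1", "g2")), 0)
  expect_error(group_deviation(obs, exp, character(0)), "empty")
})

test_that("per-period partition on neutral synthetic data is all zeros", {
  d <- build_design(2, 2)
  sim <- simulate_biomass(d, ix = neutral_interactions())
  res <- partition_per_period(sim$biomass, d)
  expect_true(all(res$partition$net_g == 0))
  # CE/SE involve a division by the mono mean: zero to rounding error
  expect_lt(max(abs(res$partition$ce_g)), 1e-12)
  expect_lt(max(abs(res$partition$se_g)), 1e-12)
  expect_true(all(res$deviations$d == 0))
})

test_that("noise-free partition recovers the generator ground truth exactly", {
  d <- build_design()
  ix <- interaction_spec(facilitation_ramp = 0, legume_suppression = 1,
                         complementarity_amplitude = 0.3, noise_cv = 0)
  sim <- simulate_biomass(d, ix = ix)
  res <- partition_per_period(sim$biomass, d)
  key <- function(t) paste(t$composition, t$period)
  gt <- sim$ground_truth[match(key(res$partition),
                               key(sim$ground_truth)), ]
  expect_equal(res$partition$net_g, gt$net_g, tolerance = 1e-10)
  expect_equal(res$partition$ce_g, gt$ce_g, tolerance = 1e-10)
  expect_true(all(abs(res$partition$se_g) < 1e-10))
})

test_that("partition output has one row per mixture composition and period", {
  d <- build_design(2, 2, pool = tiny_pool())
  two_periods <- default_periods()[1:2, ]
  d$periods <- two_periods
  sim <- simulate_biomass(d, ix = neutral_interactions())
  sim$biomass <- sim$biomass[sim$biomass$period %in% two_periods$period, ]
  res <- partition_per_period(sim$biomass, d)
  expect_equal(nrow(res$partition), 1 * 2)   # one mixture, two periods
})

test_that("a mixture species without monoculture reference is an error", {
  d <- build_design(2, 2, pool = tiny_pool())
  sim <- simulate_biomass(d, ix = neutral_interactions())
  # drop all legume monoculture rows
  mono_leg <- d$pots$pot_id[d$pots$composition == "l1"]
  b <- sim$biomass[!sim$biomass$pot_id %in% mono_leg, ]
  expect_error(partition_per_period(b, d), "l1")
})
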