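# Design enumeration, biomass/water/trait simulation and their
# determinism and ground-truth guarantees.

test_that("default design reproduces the 53-pot layout with correct sward counts", {
  d <- build_design(4, 3)
  expect_equal(nrow(d$pots), 53)
  counts <- table(d$pots$sward_type)
  expect_equal(as.integer(counts[c("1-", "1+", "2-", "2+", "5+")]),
               c(16, 4, 18, 12, 3))
  # sown proportions sum to 1 per pot
  sums <- tapply(d$proportions$sown_proportion, d$proportions$pot_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("design enumeration covers monocultures, pairs and the full pool", {
  d <- build_design(1, 1, pool = tiny_pool())
  # 2 monocultures + 1 pair (full pool of two species is the pair)
  expect_equal(nrow(d$pots), 3)
  expect_setequal(unique(d$pots$composition), c("g1", "l1", "g1-l1"))
})

test_that("duplicate species ids are rejected", {
  p <- tiny_pool()
  p[[2]]$species_id <- "g1"
  expect_error(build_design(1, 1, pool = p), "duplicate")
})

test_that("neutral interactions yield exactly mono_yield x sown proportion", {
  d <- build_design(2, 2, pool = tiny_pool())
  sim <- simulate_biomass(d, ix = neutral_interactions())
  b <- merge(sim$biomass, d$proportions, by = c("pot_id", "species"))
  mono <- ifelse(b$species == "g1", 100, 80)
  expect_equal(b$biomass_g, mono * b$sown_proportion, tolerance = 1e-15)
  expect_true(all(sim$ground_truth$net_g == 0))
  expect_true(all(sim$ground_truth$ce_g == 0))
  expect_true(all(sim$ground_truth$se_g == 0))
})

test_that("complementarity-only interactions inject CE > 0 and SE = 0", {
  d <- build_design()
  ix <- interaction_spec(facilitation_ramp = 0, legume_suppression = 1,
                         complementarity_amplitude = 0.2, noise_cv = 0)
  gt <- simulate_biomass(d, ix = ix)$ground_truth
  expect_true(all(gt$ce_g > 0))
  expect_true(all(abs(gt$se_g) < 1e-10))
  expect_equal(gt$net_g, gt$ce_g, tolerance = 1e-12)
})

test_that("ground truth satisfies net = CE + SE for the default scenario", {
  gt <- simulate_biomass(build_design(),
                         ix = interaction_spec(seed = 11))$ground_truth
  expect_equal(gt$net_g, gt$ce_g + gt$se_g, tolerance = 1e-10)
})

test_that("identical seeds reproduce identical datasets; seeds differ otherwise", {
  d <- build_design(2, 2, pool = tiny_pool())
  ix <- interaction_spec(seed = 42, noise_cv = 0.2)
  s1 <- simulate_biomass(d, ix = ix)
  s2 <- simulate_biomass(d, ix = ix)
  expect_identical(s1, s2)
  s3 <- simulate_biomass(d, ix = interaction_spec(seed = 43, noise_cv = 0.2))
  expect_false(identical(s1$biomass$biomass_g, s3$biomass$biomass_g))
  t1 <- simulate_traits(d, ix = ix)
  t2 <- simulate_traits(d, ix = ix)
  expect_identical(t1, t2)
})

test_that("negative interaction multipliers are rejected", {
  expect_error(interaction_spec(facilitation_ramp = -0.1), ">= 0")
  expect_error(interaction_spec(complementarity_amplitude = -1), ">= 0")
  expect_error(interaction_spec(noise_cv = -0.5), ">= 0")
})

test_that("water simulation closes the mass balance for every pot", {
  d <- build_design(1, 1)
  w <- simulate_water(d, ix = interaction_spec(seed = 5))
  for (pid in unique(w$weights$pot_id)) {
    ww <- w$weights[w$weights$pot_id == pid, ]
    aa <- w$additions[w$additions$pot_id == pid, ]
    et <- daily_et_from_weights(ww, aa)
    resid <- sum(et$et_kg) -
      (sum(aa$addition_kg) - (ww$weight_kg[nrow(ww)] - ww$weight_kg[1]))
    expect_lt(abs(resid), 1e-9)
  }
})

test_that("zero leaf area gives constant moisture and zero ET", {
  p <- tiny_pool(grass_yield = 0, legume_yield = 0)
  d <- build_design(1, 1, pool = p)
  w <- simulate_water(d, ix = neutral_interactions())
  expect_equal(diff(range(w$moisture$sm)), 0)
  ww <- w$weights[w$weights$pot_id == "p01", ]
  aa <- w$additions[w$additions$pot_id == "p01", ]
  et <- daily_et_from_weights(ww, aa)
  expect_true(all(et$et_kg == 0))
})

test_that("cumulative ET is monotone in leaf area", {
  d_low <- build_design(1, 1, pool = tiny_pool(50, 40))
  d_high <- build_design(1, 1, pool = tiny_pool(200, 160))
  cum_et <- function(d) {
    w <- simulate_water(d, ix = neutral_interactions())
    ww <- w$weights[w$weights$pot_id == "p01", ]
    aa <- w$additions[w$additions$pot_id == "p01", ]
    sum(daily_et_from_weights(ww, aa)$et_kg)
  }
  expect_gte(cum_et(d_high), cum_et(d_low))
})

test_that("zero trait standard deviations make every draw equal its mean", {
  d <- build_design(1, 1, pool = tiny_pool())
  tr <- simulate_traits(d, ix = interaction_spec(seed = 2))
  sla <- tr$leaf_traits[tr$leaf_traits$trait == "SLA", ]
  expect_true(all(sla$value == 20))
  n_g <- tr$leaf_traits[tr$leaf_traits$trait == "N" &
                          tr$leaf_traits$species == "l1", ]
  expect_true(all(n_g$value == 4))
})

test_that("legume pots carry higher community N in expectation", {
  d <- build_design(2, 2)
  ds <- generate_dataset(d, interaction_spec(seed = 9))
  m <- period_metrics(ds)
  n_leg <- mean(m$N[m$sward_type %in% c("1+", "2+", "5+")])
  n_grass <- mean(m$N[m$sward_type %in% c("1-", "2-")])
  expect_gt(n_leg, n_grass)
})

test_that("written dataset files are hash-stable under a fixed seed", {
  d <- build_design(1, 1, pool = tiny_pool())
  ix <- interaction_spec(seed = 123, noise_cv = 0.1)
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  write_dataset(generate_dataset(d, ix), dir1)
  write_dataset(generate_dataset(d, ix), dir2)
  f1 <- list.files(dir1, full.names = TRUE)
  f2 <- file.path(dir2, basename(f1))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})
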