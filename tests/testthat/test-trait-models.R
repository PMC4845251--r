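# Best-subset regression under LOO-CV and relative importance
# decompositions.

make_instance <- function(n, p, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  y <- rnorm(n)
  list(X = X, y = y)
}

test_that("closed-form LOO-CV equals literal refitting on random instances", {
  set.seed(17)
  for (i in 1:50) {
    n <- sample(10:30, 1); p <- sample(2:4, 1)
    inst <- make_instance(n, p, seed = i)
    cols <- sort(sample(p, sample(1:p, 1)))
    expect_equal(loocv_mse(inst$X, inst$y, cols),
                 loocv_refit(inst$X, inst$y, cols), tolerance = 1e-10)
  }
})

test_that("an exact linear dependence is selected with near-zero CV error", {
  set.seed(3)
  n <- 25
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  y <- 2 * X[, "x1"]
  sel <- best_subset_by_loocv(X, y, max_size = 2)
  expect_equal(sel$best, "x1")
  expect_lt(sel$best_cv_mse, 1e-20)
  expect_equal(sel$best_r2, 1)
})

test_that("pure-noise responses yield CV error near the sample variance", {
  set.seed(8)
  n <- 60
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("x", 1:3)))
  y <- rnorm(n)
  sel <- best_subset_by_loocv(X, y, max_size = 2)
  expect_gt(min(sel$by_size$cv_mse), 0.5 * var(y))
  expect_lt(sel$best_r2, 0.3)
})

test_that("insufficient observations are rejected", {
  inst <- make_instance(6, 10)
  expect_error(best_subset_by_loocv(inst$X, inst$y, max_size = 5),
               "max_size")
})

test_that("the winner matches exhaustive literal-refit enumeration on a fixed instance", {
  set.seed(20)
  n <- 20
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- 1.5 * X[, 1] - 0.8 * X[, 3] + rnorm(n, 0, 0.7)
  # oracle: every nonempty subset, literal n-refit LOO
  subsets <- unlist(lapply(1:4, function(k)
    utils::combn(4, k, simplify = FALSE)), recursive = FALSE)
  oracle_mse <- vapply(subsets, function(cc) loocv_refit(X, y, cc),
                       numeric(1))
  oracle_best <- subsets[[which.min(oracle_mse)]]
  sel <- best_subset_by_loocv(X, y, max_size = 4)
  expect_equal(sel$best, colnames(X)[oracle_best])
  expect_equal(sel$best_cv_mse, min(oracle_mse), tolerance = 1e-10)
})

test_that("LMG shares sum to the model R2 and match the ordering-enumeration oracle", {
  set.seed(41)
  for (i in 1:10) {
    n <- 25; k <- sample(2:5, 1)
    X <- matrix(rnorm(n * 6), n, 6,
                dimnames = list(NULL, paste0("x", 1:6)))
    beta <- rnorm(6)
    y <- drop(X %*% beta) + rnorm(n)
    cols <- sort(sample(6, k))
    res <- lmg_importance(X, y, cols)
    expect_true(all(res$shares >= -1e-12))
    expect_equal(sum(res$shares), res$r2, tolerance = 1e-9)
    expect_equal(sum(res$shares_normalized), 1, tolerance = 1e-9)
    oracle <- lmg_orderings_oracle(X, y, cols)
    expect_equal(unname(res$shares), oracle, tolerance = 1e-10)
  }
})

test_that("LMG is invariant to predictor column order", {
  set.seed(50)
  X <- matrix(rnorm(30 * 4), 30, 4,
              dimnames = list(NULL, paste0("x", 1:4)))
  y <- X[, 1] + 0.5 * X[, 2] + rnorm(30)
  a <- lmg_importance(X, y, c("x1", "x2", "x3"))
  b <- lmg_importance(X[, c(3, 1, 4, 2)], y, c("x1", "x2", "x3"))
  expect_equal(a$shares[sort(names(a$shares))],
               b$shares[sort(names(b$shares))], tolerance = 1e-12)
})

test_that("orthogonal predictors get their marginal R2 under both LMG and PMVD", {
  n <- 64
  # mean-zero, mutually orthogonal columns (orthogonalized against the
  # intercept as well, so sequential R2 contributions are additive)
  set.seed(12)
  X <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, 2:4]
  colnames(X) <- paste0("x", 1:3)
  y <- 2 * X[, 1] + 1 * X[, 2] + rnorm(n, 0, 0.5)
  marg <- vapply(1:3, function(j) {
    f <- lm.fit(cbind(1, X[, j]), y)
    1 - sum(f$residuals^2) / sum((y - mean(y))^2)
  }, numeric(1))
  lmg <- lmg_importance(X, y, 1:3)
  pmvd <- pmvd_importance(X, y, 1:3)
  expect_equal(unname(lmg$shares), marg, tolerance = 1e-6)
  expect_equal(unname(pmvd$shares), marg, tolerance = 1e-6)
})

test_that("duplicate predictors share importance equally under LMG", {
  set.seed(13)
  n <- 40
  x <- rnorm(n)
  X <- cbind(x1 = x, x2 = x, x3 = rnorm(n))
  y <- x + rnorm(n, 0, 0.3)
  res <- lmg_importance(X, y, c("x1", "x2"))
  expect_equal(res$shares[["x1"]], res$shares[["x2"]], tolerance = 1e-10)
})

test_that("PMVD drives zero-partial predictors to zero share where LMG does not", {
  set.seed(14)
  n <- 200
  x1 <- rnorm(n)
  x2 <- 0.9 * x1 + 0.1 * rnorm(n)  # proxy: marginal R2 > 0, partial ~ 0
  y <- x1                          # x2 adds nothing given x1
  X <- cbind(x1 = x1, x2 = x2)
  lmg <- lmg_importance(X, y, 1:2)
  pmvd <- pmvd_importance(X, y, 1:2)
  expect_gt(lmg$shares[["x2"]], 0.1)     # LMG still credits the proxy
  expect_lt(pmvd$shares[["x2"]], 1e-6)   # PMVD does not
  expect_equal(sum(pmvd$shares), pmvd$r2, tolerance = 1e-9)
})

test_that("single-predictor importance equals the model R2", {
  inst <- make_instance(30, 3, seed = 5)
  y <- inst$X[, 1] + rnorm(30, 0, 0.5)
  r2 <- summary(lm(y ~ inst$X[, 1]))$r.squared
  expect_equal(unname(lmg_importance(inst$X, y, 1)$shares), r2,
               tolerance = 1e-10)
  expect_equal(unname(pmvd_importance(inst$X, y, 1)$shares), r2,
               tolerance = 1e-10)
})

test_that("subset sizes beyond enumeration capacity are refused", {
  inst <- make_instance(40, 10)
  expect_error(lmg_importance(inst$X, inst$y, 1:9), "k > 8")
  expect_error(pmvd_importance(inst$X, inst$y, 1:9), "k > 8")
})

test_that("planted two-trait signals are recovered with top importance ranks", {
  sim <- simulate_planted_signal(n = 30, active = c("L.area", "WUE"),
                                 r2 = 0.9, seed = 77)
  rep <- select_trait_model(sim$X, sim$y, max_size = 5,
                            response = "biomass")
  expect_true(all(sim$active %in% rep$selection$best))
  ranked <- names(sort(rep$pmvd$shares_normalized, decreasing = TRUE))
  expect_setequal(ranked[1:2], sim$active)
})

test_that("the importance table normalizes block percentages to 100", {
  sims <- lapply(c(1, 2, 3), function(s)
    simulate_planted_signal(seed = s))
  reports <- lapply(seq_along(sims), function(i)
    select_trait_model(sims[[i]]$X, sims[[i]]$y,
                       response = c("biomass", "net",
                                    "complementarity")[i]))
  tab <- importance_table(reports)
  expect_equal(nrow(tab), sum(vapply(reports, function(r)
    length(r$selection$best), integer(1))))
  for (resp in unique(tab$response)) {
    expect_equal(sum(tab$pct_r2[tab$response == resp]), 100,
                 tolerance = 0.1)
  }
})

test_that("matrix assembly averages periods and standardizes columns", {
  d <- build_design(2, 1)
  ds <- generate_dataset(d, interaction_spec(seed = 21))
  m <- period_metrics(ds)
  ct <- community_trait_table(ds)
  de <- partition_per_period(ds$biomass, d)
  am <- assemble_matrix(m, ct$cwm, de$partition, response = "net",
                        scope = "whole")
  expect_equal(ncol(am$X), 10)
  expect_equal(length(am$y), length(am$rows))
  expect_equal(unname(colMeans(am$X)), rep(0, 10), tolerance = 1e-12)
  expect_equal(unname(apply(am$X, 2, sd)), rep(1, 10), tolerance = 1e-12)
  # brute-force check of the whole-experiment mean for one cell
  comp <- am$rows[1]
  pots <- d$pots$pot_id[d$pots$composition == comp]
  manual <- mean(tapply(m$WUE[m$pot_id %in% pots],
                        m$period[m$pot_id %in% pots], mean))
  ctr <- attr(am$X, "center"); scl <- attr(am$X, "scale")
  expect_equal(am$X[comp, "WUE"] * scl[["WUE"]] + ctr[["WUE"]], manual,
               tolerance = 1e-12)
  # single-period scope has one row per mixture composition
  am1 <- assemble_matrix(m, ct$cwm, de$partition, response = "net",
                         scope = d$periods$period[1])
  expect_equal(length(am1$rows),
               length(unique(de$partition$composition)))
})

test_that("constant predictor columns cannot be standardized", {
  d <- build_design(2, 1)
  ds <- generate_dataset(d, interaction_spec(seed = 22))
  m <- period_metrics(ds)
  ct <- community_trait_table(ds)
  m$REW <- 0.5
  expect_error(assemble_matrix(m, ct$cwm, response = "biomass"),
               "constant")
})
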