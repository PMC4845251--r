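# Shared fixtures: small species pools and random-instance generators.

# a minimal two-species pool (one grass, one legume), constant yields
tiny_pool <- function(grass_yield = 100, legume_yield = 80) {
  tm <- c(SLA = 20, LDMC = 250, N = 2, d13C = -28, H.growth = 1,
          R.growth = 0.2, top_share = 50)
  zero_sd <- tm * 0
  p <- list(
    species_spec("g1", "grass", "tall", "deep",
                 rep(grass_yield, 6), tm, zero_sd),
    species_spec("l1", "legume", "short", "intermediate",
                 rep(legume_yield, 6),
                 replace(tm, "N", 4), zero_sd)
  )
  names(p) <- c("g1", "l1")
  class(p) <- "species_pool"
  p
}

# random partition instance: N species, positive monoculture means,
# arbitrary non-negative observed biomass
random_partition_instance <- function(n) {
  m <- stats::runif(n, 10, 300)
  p <- stats::runif(n, 0.2, 1); p <- p / sum(p)
  obs <- stats::runif(n, 0, 250)
  names(m) <- names(p) <- names(obs) <- paste0("s", seq_len(n))
  list(observed = obs, mono = m, prop = p)
}

# brute-force Rao quadratic entropy: explicit double loop over species,
# pairwise Gower distance computed scalar-wise
rao_bruteforce <- function(weights, tm) {
  weights <- unname(weights)
  rng <- unname(apply(tm, 2, function(x) diff(range(x))))
  use <- which(rng > 0)
  q <- 0
  for (i in seq_along(weights)) {
    for (j in seq_along(weights)) {
      if (length(use) == 0) next
      dij <- 0
      for (k in use) dij <- dij + abs(tm[i, k] - tm[j, k]) / rng[k]
      q <- q + weights[i] * weights[j] * dij / length(use)
    }
  }
  q
}

# literal leave-one-out cross-validation: refit n times
loocv_refit <- function(X, y, cols) {
  n <- length(y)
  errs <- vapply(seq_len(n), function(i) {
    Z <- cbind(1, X[-i, cols, drop = FALSE])
    fit <- stats::lm.fit(Z, y[-i])
    pred <- drop(c(1, X[i, cols]) %*% fit$coefficients)
    (y[i] - pred)^2
  }, numeric(1))
  mean(errs)
}

# LMG by literal enumeration of orderings with sequential R2 increments
lmg_orderings_oracle <- function(X, y, cols) {
  r2 <- function(cc) {
    if (length(cc) == 0) return(0)
    f <- stats::lm.fit(cbind(1, X[, cc, drop = FALSE]), y)
    1 - sum(f$residuals^2) / sum((y - mean(y))^2)
  }
  k <- length(cols)
  perms <- swardiv_permutations(k)
  shares <- numeric(k)
  for (r in seq_len(nrow(perms))) {
    prev <- 0
    for (i in seq_len(k)) {
      cur <- r2(cols[perms[r, seq_len(i)]])
      shares[perms[r, i]] <- shares[perms[r, i]] + (cur - prev)
      prev <- cur
    }
  }
  shares / nrow(perms)
}

# small standalone permutation enumerator for the oracle
swardiv_permutations <- function(k) {
  if (k == 1) return(matrix(1L))
  do.call(rbind, lapply(seq_len(k), function(first) {
    sub <- swardiv_permutations(k - 1L)
    cbind(first, matrix(setdiff(seq_len(k), first)[sub], nrow(sub)))
  }))
}
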