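#' Assemble the predictor matrix for trait-based models
#'
#' Builds the community x variable matrix feeding model selection: rows
#' are mixture communities (composition means by default, or pots),
#' columns are the ten community variables (Biom st1, d13C, H.growth,
#' L.area, LDMC, N, Nyield/ET, REW, R.growth, WUE), and the response is
#' community biomass, the net diversity effect, or the complementarity
#' effect. Whole-experiment scope averages each variable over periods
#' (responses biomass/net/CE are summed over periods); single-period
#' scope takes that period's values. Columns are standardized to zero
#' mean and unit variance; the constants are recorded in attributes.
#'
#' @param metrics a [period_metrics()] table.
#' @param cwm_table the `cwm` element of [community_trait_table()].
#' @param partition the `partition` element of [partition_per_period()]
#'   (needed for the `net` and `complementarity` responses; mixtures
#'   only).
#' @param response `"biomass"`, `"net"` or `"complementarity"`.
#' @param scope `"whole"` (default) or one period label.
#' @param unit `"composition"` (default; average pots of a composition)
#'   or `"pot"`.
#' @return list with `X` (standardized matrix), `y`, `rows` (community
#'   ids); `X` carries `"center"`/`"scale"` attributes.
#' @export
assemble_matrix <- function(metrics, cwm_table, partition = NULL,
                            response = c("biomass", "net",
                                         "complementarity"),
                            scope = "whole",
                            unit = c("composition", "pot")) {
  response <- match.arg(response)
  unit <- match.arg(unit)
  vars <- c("Biom.st1", "d13C", "H.growth", "L.area", "LDMC", "N",
            "Nyield.ET", "REW", "R.growth", "WUE")

  m <- metrics
  # merge CWM values of the weighted species-level traits over the
  # community-level metric columns (d13C, LDMC, and the CWM versions of
  # N, H.growth, Biom.st1 replace the metric-table variants)
  cw <- cwm_table
  for (trait in c("LDMC", "d13C", "N", "H.growth", "Biom.st1")) {
    sub <- cw[cw$trait == trait, c("pot_id", "period", "cwm")]
    names(sub)[3] <- paste0(".", trait)
    m <- merge(m, sub, by = c("pot_id", "period"), all.x = TRUE)
    m[[trait]] <- m[[paste0(".", trait)]]
    m[[paste0(".", trait)]] <- NULL
  }
  if (response != "biomass") {
    if (is.null(partition)) {
      stop("partition results required for response '", response, "'")
    }
    m <- m[m$composition %in% unique(partition$composition), ]
  }
  if (!identical(scope, "whole")) {
    if (!scope %in% m$period) stop("unknown period scope: ", scope)
    m <- m[m$period == scope, ]
  }

  key <- if (unit == "composition") m$composition else m$pot_id
  agg_var <- function(v, f) {
    a <- tapply(m[[v]], list(key, m$period), mean, na.rm = TRUE)
    apply(a, 1, f, na.rm = TRUE)
  }
  X <- sapply(vars, function(v) agg_var(v, mean))
  comm <- rownames(X)

  y <- switch(response,
    biomass = agg_var("biomass_g", sum)[comm],
    {
      p <- partition
      if (!identical(scope, "whole")) p <- p[p$period == scope, ]
      col <- if (response == "net") "net_g" else "ce_g"
      ag <- tapply(p[[col]], p$composition, sum)
      if (unit == "composition") ag[comm] else
        ag[m$composition[match(comm, m$pot_id)]]
    })
  if (anyNA(X) || anyNA(y)) {
    bad <- unique(c(colnames(X)[apply(is.na(X), 2, any)],
                    if (anyNA(y)) "response"))
    stop("missing cells after assembly: ", paste(bad, collapse = ", "))
  }
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0)) {
    stop("constant column(s) cannot be standardized: ",
         paste(colnames(X)[scl == 0], collapse = ", "))
  }
  Xs <- scale(X, ctr, scl)
  attr(Xs, "center") <- ctr; attr(Xs, "scale") <- scl
  list(X = Xs, y = unname(y), rows = comm, response = response,
       scope = scope)
}

# R-squared of an OLS fit of y on X columns `cols` (with intercept)
subset_r2 <- function(X, y, cols) {
  if (length(cols) == 0) return(0)
  f <- stats::lm.fit(cbind(1, X[, cols, drop = FALSE]), y)
  1 - sum(f$residuals^2) / sum((y - mean(y))^2)
}

#' Leave-one-out cross-validation error of an OLS subset
#'
#' Mean squared prediction error under exact leave-one-out, computed via
#' the hat-matrix identity `e_i / (1 - h_ii)` rather than n refits.
#' Observations with leverage numerically at 1 make the deleted residual
#' undefined; such subsets are reported as `Inf` (effectively excluded
#' from selection).
#'
#' @param X predictor matrix (no intercept column).
#' @param y response.
#' @param cols column indices or names of the subset.
#' @return LOO mean squared error.
#' @export
loocv_mse <- function(X, y, cols) {
  Z <- cbind(1, X[, cols, drop = FALSE])
  qr_z <- qr(Z)
  if (qr_z$rank < ncol(Z)) return(Inf)   # rank-deficient subset
  e <- stats::lm.fit(Z, y)$residuals
  h <- rowSums(qr.Q(qr_z)[, seq_len(qr_z$rank), drop = FALSE]^2)
  if (any(h > 1 - 1e-10)) return(Inf)
  mean((e / (1 - h))^2)
}

#' Exhaustive best-subset selection by leave-one-out cross-validation
#'
#' Enumerates every predictor subset up to `max_size`, fits ordinary
#' least squares, scores each subset by exact LOO-CV mean squared error,
#' and reports the CV-best subset per size and the overall winner. Ties
#' are broken in favour of the smaller subset, then lexicographic
#' predictor order. Rank-deficient subsets are skipped with a warning.
#'
#' @param X standardized predictor matrix with named columns.
#' @param y response vector; `length(y)` must exceed `max_size + 2`.
#' @param max_size largest subset size (default 5).
#' @return Object of class `subset_selection`: list with `best`
#'   (character vector of selected predictors), `best_cv_mse`,
#'   `best_r2`, `by_size` (data.frame per size: subset, CV-MSE, R2) and
#'   `n`.
#' @export
best_subset_by_loocv <- function(X, y, max_size = 5) {
  p <- ncol(X); n <- length(y)
  if (n <= max_size + 2) {
    stop("need n > max_size + 2 (n = ", n, ", max_size = ", max_size, ")")
  }
  vn <- colnames(X)
  by_size <- list()
  best <- NULL; best_mse <- Inf; n_skipped <- 0L
  for (k in seq_len(max_size)) {
    combos <- utils::combn(p, k, simplify = FALSE)
    mses <- vapply(combos, function(cc) loocv_mse(X, y, cc), numeric(1))
    n_skipped <- n_skipped + sum(is.infinite(mses))
    # lexicographic tie-break: combn emits subsets in lexicographic order
    kbest <- which(mses == min(mses))[1]
    by_size[[k]] <- data.frame(
      size = k, subset = paste(vn[combos[[kbest]]], collapse = "+"),
      cv_mse = mses[kbest],
      r2 = subset_r2(X, y, combos[[kbest]]), stringsAsFactors = FALSE)
    if (mses[kbest] < best_mse) {   # strict: ties keep the smaller size
      best_mse <- mses[kbest]
      best <- vn[combos[[kbest]]]
    }
  }
  if (n_skipped > 0) {
    warning(n_skipped, " rank-deficient subset(s) skipped")
  }
  structure(list(best = best, best_cv_mse = best_mse,
                 best_r2 = subset_r2(X, y, match(best, vn)),
                 by_size = do.call(rbind, by_size), n = n),
            class = "subset_selection")
}

#' @export
print.subset_selection <- function(x, ...) {
  cat(sprintf("<subset_selection> n = %d | best: %s (R2 %.3f, CV-MSE %.4g)\n",
              x$n, paste(x$best, collapse = " + "), x$best_r2,
              x$best_cv_mse))
  invisible(x)
}

# R2 of every sub-subset of `subset`, keyed by comma-joined sorted indices
all_subset_r2 <- function(X, y, subset) {
  k <- length(subset)
  cache <- new.env(parent = emptyenv())
  assign("s", 0, envir = cache)
  for (m in seq_len(k)) {
    for (cc in utils::combn(seq_len(k), m, simplify = FALSE)) {
      key <- paste0("s", paste(cc, collapse = ","))
      assign(key, subset_r2(X, y, subset[cc]), envir = cache)
    }
  }
  cache
}

#' LMG relative importance
#'
#' Allocates the full-model R-squared among the predictors of a subset
#' by averaging, over all k! orderings, the R-squared increase when each
#' predictor enters the model. Equivalently, a predictor's share is the
#' weighted mean of its marginal contribution to every sub-model, with
#' weights depending only on sub-model size. Shares are non-negative and
#' sum to the full-model R-squared.
#'
#' @param X standardized predictor matrix with named columns.
#' @param y response.
#' @param subset character vector (or indices) of predictors; at most 8.
#' @return list with `shares` (raw, summing to the model R2),
#'   `shares_normalized` (summing to 1), `r2`.
#' @export
lmg_importance <- function(X, y, subset) {
  cols <- if (is.character(subset)) match(subset, colnames(X)) else subset
  k <- length(cols)
  if (k > 8) {
    stop("subset too large for ordering enumeration (k > 8); ",
         "sample orderings instead")
  }
  cache <- all_subset_r2(X, y, cols)
  r2_of <- function(idx) get(paste0("s", paste(sort(idx), collapse = ",")),
                             envir = cache)
  shares <- numeric(k)
  for (j in seq_len(k)) {
    others <- setdiff(seq_len(k), j)
    # weight |S|! (k-|S|-1)! / k! over subsets S of the other predictors
    total <- 0
    for (m in 0:(k - 1)) {
      w <- factorial(m) * factorial(k - m - 1) / factorial(k)
      # combn() over positions: a scalar `others` must not expand to 1:x
      ss <- if (m == 0) list(integer(0)) else
        lapply(utils::combn(seq_along(others), m, simplify = FALSE),
               function(ii) others[ii])
      for (S in ss) {
        total <- total + w * (r2_of(c(S, j)) - r2_of(S))
      }
    }
    shares[j] <- total
  }
  names(shares) <- colnames(X)[cols]
  r2 <- r2_of(seq_len(k))
  list(shares = shares, shares_normalized = shares / sum(shares), r2 = r2)
}

#' Proportional marginal variance decomposition (PMVD)
#'
#' Like LMG, PMVD averages sequential R-squared contributions over
#' predictor orderings, but with data-dependent weights: an ordering's
#' weight is proportional to the product over its prefixes of the
#' reciprocal remaining contribution,
#' `w(r) ~ prod_i 1 / (R2_full - R2(r_1..r_i))`. Orderings that place
#' uninformative predictors late receive almost all the weight, so a
#' predictor with zero partial and zero marginal contribution gets share
#' tending to 0 (where LMG would still credit it). Denominators are
#' regularized with eps = 1e-12; if all weights degenerate to zero the
#' function falls back to LMG with a warning.
#'
#' @inheritParams lmg_importance
#' @return As [lmg_importance()].
#' @export
pmvd_importance <- function(X, y, subset) {
  cols <- if (is.character(subset)) match(subset, colnames(X)) else subset
  k <- length(cols)
  if (k > 8) {
    stop("subset too large for ordering enumeration (k > 8); ",
         "sample orderings instead")
  }
  cache <- all_subset_r2(X, y, cols)
  r2_of <- function(idx) get(paste0("s", paste(sort(idx), collapse = ",")),
                             envir = cache)
  r2_full <- r2_of(seq_len(k))
  if (k == 1) {
    shares <- stats::setNames(r2_full, colnames(X)[cols])
    return(list(shares = shares, shares_normalized = shares / sum(shares),
                r2 = r2_full))
  }
  eps <- 1e-12
  perms <- permutations(k)
  w <- numeric(nrow(perms))
  inc <- matrix(0, nrow(perms), k)
  for (r in seq_len(nrow(perms))) {
    ord <- perms[r, ]
    prev <- 0
    wr <- 1
    for (i in seq_len(k)) {
      cur <- r2_of(ord[seq_len(i)])
      inc[r, ord[i]] <- cur - prev
      if (i < k) wr <- wr / max(r2_full - cur, eps)
      prev <- cur
    }
    w[r] <- wr
  }
  if (!any(is.finite(w)) || sum(w) == 0) {
    warning("degenerate PMVD weights; falling back to LMG")
    return(lmg_importance(X, y, subset))
  }
  w <- w / sum(w)
  shares <- drop(t(inc) %*% w)
  names(shares) <- colnames(X)[cols]
  list(shares = shares, shares_normalized = shares / sum(shares),
       r2 = r2_full)
}

# all permutations of 1..k as rows (k small)
permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations(k - 1L)
  out <- matrix(0L, k * nrow(sub), k)
  row <- 0L
  for (pos in seq_len(k)) {
    for (r in seq_len(nrow(sub))) {
      row <- row + 1L
      out[row, ] <- append(sub[r, ], k, after = pos - 1L)
    }
  }
  out
}

#' Fit and rank trait models for one response
#'
#' Runs [best_subset_by_loocv()] and decorates the winner with LMG and
#' PMVD importance shares.
#'
#' @param X,y as in [best_subset_by_loocv()].
#' @param max_size subset-size cap (default 5).
#' @param response label carried into the report.
#' @return Object of class `selection_report`.
#' @export
select_trait_model <- function(X, y, max_size = 5, response = "response") {
  sel <- best_subset_by_loocv(X, y, max_size = max_size)
  lmg <- lmg_importance(X, y, sel$best)
  pmvd <- pmvd_importance(X, y, sel$best)
  structure(list(response = response, selection = sel,
                 r2 = sel$best_r2, lmg = lmg, pmvd = pmvd),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> %s: R2 = %.3f\n", x$response, x$r2))
  ord <- order(x$pmvd$shares_normalized, decreasing = TRUE)
  sh <- x$pmvd$shares_normalized[ord] * 100
  for (i in seq_along(sh)) {
    cat(sprintf("  %-10s %5.1f %% of R2\n", names(sh)[i], sh[i]))
  }
  invisible(x)
}

#' Trait-importance summary table
#'
#' One block per response: model R-squared and the selected traits ranked
#' by their share of explained variance (percentages of the model R2,
#' summing to 100 within a block), under the chosen importance metric.
#'
#' @param reports list of [select_trait_model()] results.
#' @param metric `"pmvd"` (default) or `"lmg"`.
#' @return data.frame `response`, `r2`, `rank`, `trait`, `pct_r2`.
#' @export
importance_table <- function(reports, metric = c("pmvd", "lmg")) {
  metric <- match.arg(metric)
  out <- lapply(reports, function(rep) {
    sh <- rep[[metric]]$shares_normalized
    ord <- order(sh, decreasing = TRUE)
    data.frame(response = rep$response, r2 = rep$r2,
               rank = seq_along(sh), trait = names(sh)[ord],
               pct_r2 = 100 * sh[ord], row.names = NULL,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
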