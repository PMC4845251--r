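#' Abundance weighting rule for a trait
#'
#' Community-weighted means use trait-specific abundance weights: species
#' proportion in total biomass for LDMC, in green-leaf biomass for N, and
#' in leaf area for d13C. Species-level traits without a stated rule
#' (H.growth, species-level Biom st1) default to total-biomass weights
#' and are flagged as such. Variables measured directly at the community
#' level (R.growth, community Biom st1, L.area, WUE, Nyield/ET, REW) are
#' pass-through: no weighting is applied.
#'
#' @param trait trait name (registered names: LDMC, N, d13C, SLA,
#'   H.growth, Biom.st1, top_share, R.growth, L.area, WUE, Nyield.ET,
#'   REW).
#' @return list with `rule` (one of `"total_biomass"`,
#'   `"green_leaf_biomass"`, `"leaf_area"`, `"pass_through"`) and
#'   `default_rule` (TRUE when the rule is the unstated-trait default).
#' @examples
#' resolve_weighting("LDMC")$rule  # "total_biomass"
#' resolve_weighting("WUE")$rule   # "pass_through"
#' @export
resolve_weighting <- function(trait) {
  stated <- c(LDMC = "total_biomass", N = "green_leaf_biomass",
              d13C = "leaf_area")
  default_rule <- c("SLA", "H.growth", "Biom.st1", "top_share")
  passthrough <- c("R.growth", "L.area", "WUE", "Nyield.ET", "REW")
  if (trait %in% names(stated)) {
    list(rule = unname(stated[trait]), default_rule = FALSE)
  } else if (trait %in% default_rule) {
    list(rule = "total_biomass", default_rule = TRUE)
  } else if (trait %in% passthrough) {
    list(rule = "pass_through", default_rule = FALSE)
  } else {
    stop("unknown trait: ", trait)
  }
}

#' Abundance weights under a named rule
#'
#' Normalizes a species abundance basis to proportions. The basis is
#' total biomass, green-leaf biomass, or leaf area (biomass x SLA),
#' depending on the rule; green-leaf biomass falls back to total biomass
#' when no green-leaf split is available.
#'
#' @param biomass_g named species biomass vector (g).
#' @param rule weighting rule from [resolve_weighting()].
#' @param green_g optional named green-leaf biomass (g).
#' @param sla optional named SLA (m^2 kg^-1), required for the
#'   leaf-area rule.
#' @return named proportions summing to 1.
#' @export
abundance_weights <- function(biomass_g,
                              rule = c("total_biomass",
                                       "green_leaf_biomass", "leaf_area"),
                              green_g = NULL, sla = NULL) {
  rule <- match.arg(rule)
  basis <- switch(rule,
    total_biomass = biomass_g,
    green_leaf_biomass = if (is.null(green_g)) biomass_g else
      green_g[names(biomass_g)],
    leaf_area = {
      if (is.null(sla)) stop("leaf_area weighting needs SLA values")
      biomass_g / 1000 * sla[names(biomass_g)]
    })
  if (any(basis < 0)) stop("abundance basis must be non-negative")
  tot <- sum(basis)
  if (tot <= 0) stop("abundance basis sums to zero")
  basis / tot
}

#' Community-weighted mean
#'
#' `CWM = sum_i p_i t_i` over the S species of the community, with
#' abundance weights p_i summing to one. The result is always bounded by
#' the species trait range.
#'
#' @param weights named abundance proportions (sum to 1 within 1e-6).
#' @param traits named species trait values covering every species with
#'   positive weight.
#' @return The community-weighted mean, in trait units.
#' @examples
#' cwm(c(a = 0.25, b = 0.75), c(a = 0, b = 4))  # 3
#' @export
cwm <- function(weights, traits) {
  if (abs(sum(weights) - 1) > 1e-6) {
    stop("abundance weights must sum to 1 (got ", sum(weights), ")")
  }
  if (any(weights < 0)) stop("abundance weights must be non-negative")
  pos <- names(weights)[weights > 0]
  if (!all(pos %in% names(traits)) || anyNA(traits[pos])) {
    stop("missing trait value for weighted species: ",
         paste(setdiff(pos, names(traits)[!is.na(traits)]),
               collapse = ", "))
  }
  sum(weights[pos] * traits[pos])
}

# Gower dissimilarity matrix on range-standardized numeric traits.
# Constant columns carry no information under range standardization and
# are dropped (with a warning upstream).
gower_distance <- function(trait_matrix) {
  rng <- apply(trait_matrix, 2, function(x) diff(range(x)))
  keep <- rng > 0
  dropped <- colnames(trait_matrix)[!keep]
  tm <- trait_matrix[, keep, drop = FALSE]
  n <- nrow(tm)
  d <- matrix(0, n, n, dimnames = list(rownames(tm), rownames(tm)))
  if (ncol(tm) > 0) {
    for (j in seq_len(ncol(tm))) {
      x <- tm[, j] / rng[keep][j]
      d <- d + abs(outer(x, x, "-"))
    }
    d <- d / ncol(tm)
  }
  attr(d, "dropped") <- dropped
  d
}

#' Functional diversity as Rao's quadratic entropy
#'
#' `FD_Q = sum_i sum_j p_i p_j d_ij`, the expected trait dissimilarity
#' between two randomly drawn individuals. Dissimilarities are Gower
#' distances on range-standardized traits (d in `[0, 1]`) by default;
#' alternatively half the squared Euclidean distance on z-scored traits.
#' The convention is recorded in the result. Monocultures have FD_Q = 0
#' by construction.
#'
#' @param weights named abundance proportions (sum to 1).
#' @param trait_matrix species x trait numeric matrix with rownames
#'   matching the weight names.
#' @param distance `"gower"` (default) or `"sq_euclid"`.
#' @return list with `fdq`, `distance` (convention label) and
#'   `dropped_traits` (constant columns removed).
#' @examples
#' tm <- matrix(c(0, 1), 2, 1, dimnames = list(c("a", "b"), "t"))
#' fd_rao(c(a = 0.5, b = 0.5), tm)$fdq  # 0.5
#' @export
fd_rao <- function(weights, trait_matrix,
                   distance = c("gower", "sq_euclid")) {
  distance <- match.arg(distance)
  if (length(weights) < 1) stop("need at least one species")
  if (abs(sum(weights) - 1) > 1e-6) stop("weights must sum to 1")
  if (length(weights) == 1) {
    return(list(fdq = 0, distance = distance, dropped_traits = character(0)))
  }
  trait_matrix <- trait_matrix[names(weights), , drop = FALSE]
  if (distance == "gower") {
    d <- gower_distance(trait_matrix)
  } else {
    z <- apply(trait_matrix, 2, function(x) {
      s <- stats::sd(x)
      if (s == 0) return(rep(NA_real_, length(x)))
      (x - mean(x)) / s
    })
    keep <- !apply(is.na(z), 2, any)
    zd <- as.matrix(stats::dist(z[, keep, drop = FALSE]))^2 / 2
    attr(zd, "dropped") <- colnames(trait_matrix)[!keep]
    d <- zd
  }
  dropped <- attr(d, "dropped")
  if (length(dropped) > 0) {
    warning("constant trait column(s) dropped: ",
            paste(dropped, collapse = ", "))
  }
  fdq <- drop(t(weights) %*% d %*% weights)
  list(fdq = fdq, distance = distance, dropped_traits = dropped)
}

#' Community-weighted means and functional diversity per pot and period
#'
#' Assembles, for every pot x period, the CWM of the species-level traits
#' under their trait-specific weightings and Rao's quadratic entropy over
#' the six species-level traits (Biom st1, d13C, H.growth, L.area, LDMC,
#' N; species leaf area enters as biomass x SLA).
#'
#' @param dataset a [generate_dataset()]-style list (needs `biomass`,
#'   `leaf_traits`, `heights`, `design`).
#' @param fd_distance distance convention for [fd_rao()].
#' @return list with `cwm` (long: `pot_id`, `period`, `trait`, `cwm`,
#'   `weighting`, `default_rule`) and `fdq` (`pot_id`, `period`, `fdq`,
#'   `distance`, `n_traits`).
#' @export
community_trait_table <- function(dataset, fd_distance = "gower") {
  design <- dataset$design
  periods <- design$periods
  lt <- dataset$leaf_traits
  lt$day <- abs_day(lt$year, lt$doy)

  species_trait <- function(pid, s, trait, day_ref) {
    m <- lt[lt$pot_id == pid & lt$species == s & lt$trait == trait, ]
    if (nrow(m) == 0) return(NA_real_)
    m$value[which.min(abs(m$day - day_ref))]
  }

  cwm_rows <- list(); fdq_rows <- list()
  for (i in seq_len(nrow(design$pots))) {
    pid <- design$pots$pot_id[i]
    sp <- composition_species(design$pots$composition[i])
    b_pot <- dataset$biomass[dataset$biomass$pot_id == pid, ]
    h_pot <- dataset$heights[dataset$heights$pot_id == pid, ]
    for (k in seq_len(nrow(periods))) {
      per <- periods$period[k]
      d0 <- periods$day_start[k]; d1 <- periods$day_end[k]
      bp <- b_pot[b_pot$period == per, ]
      if (nrow(bp) == 0) next
      biom <- stats::setNames(bp$biomass_g, bp$species)[sp]
      sla <- vapply(sp, species_trait, numeric(1), pid = pid,
                    trait = "SLA", day_ref = d1)
      tvals <- list(
        LDMC = vapply(sp, species_trait, numeric(1), pid = pid,
                      trait = "LDMC", day_ref = d1),
        N = vapply(sp, species_trait, numeric(1), pid = pid,
                   trait = "N", day_ref = d1),
        d13C = vapply(sp, species_trait, numeric(1), pid = pid,
                      trait = "d13C", day_ref = d1),
        H.growth = vapply(sp, function(s) {
          hs <- h_pot[h_pot$species == s, ]
          hs <- hs[order(abs_day(hs$year, hs$doy)), ]
          if (nrow(hs) < 2) return(NA_real_)
          rt <- growth_rate_series(abs_day(hs$year, hs$doy), hs$height_cm)
          max_rate_per_period(rt, d0, d1)
        }, numeric(1)),
        Biom.st1 = stats::setNames(
          100 * bp$biomass_top_g / bp$biomass_g, bp$species)[sp]
      )
      for (trait in names(tvals)) {
        w <- resolve_weighting(trait)
        wt <- abundance_weights(biom, w$rule, sla = sla)
        cwm_rows[[length(cwm_rows) + 1L]] <- data.frame(
          pot_id = pid, period = per, trait = trait,
          cwm = cwm(wt, tvals[[trait]]), weighting = w$rule,
          default_rule = w$default_rule, stringsAsFactors = FALSE)
      }
      # FD_Q over the six species-level traits
      la_sp <- biom / 1000 * sla
      tm <- cbind(Biom.st1 = tvals$Biom.st1, d13C = tvals$d13C,
                  H.growth = tvals$H.growth, L.area = la_sp,
                  LDMC = tvals$LDMC, N = tvals$N)
      rownames(tm) <- sp
      ok <- !apply(is.na(tm), 2, any)
      wt <- abundance_weights(biom, "total_biomass")
      fq <- suppressWarnings(
        fd_rao(wt, tm[, ok, drop = FALSE], distance = fd_distance))
      fdq_rows[[length(fdq_rows) + 1L]] <- data.frame(
        pot_id = pid, period = per, fdq = fq$fdq, distance = fq$distance,
        n_traits = sum(ok) - length(fq$dropped_traits),
        stringsAsFactors = FALSE)
    }
  }
  list(cwm = do.call(rbind, cwm_rows), fdq = do.call(rbind, fdq_rows))
}
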