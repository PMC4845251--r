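#' Expected biomass of a species in mixture
#'
#' The null expectation under no interaction: monoculture biomass scaled
#' by the species' proportion in the mixture. By default the sown
#' proportion is used (the standard convention for the additive
#' partition, since pots are established with equal species shares).
#'
#' @param mono_mean monoculture mean biomass M_i (g pot^-1), > 0.
#' @param proportion species proportion p_i in `[0, 1]`.
#' @return Expected biomass M_i * p_i (g pot^-1).
#' @examples
#' expected_biomass(100, 0.5)  # 50
#' @export
expected_biomass <- function(mono_mean, proportion) {
  stopifnot(all(proportion >= 0), all(proportion <= 1))
  if (any(is.na(mono_mean))) {
    stop("monoculture mean is missing")
  }
  mono_mean * proportion
}

#' Additive partition of the net diversity effect
#'
#' Splits the net diversity effect of a mixture into complementarity and
#' selection components. With observed species biomass Y_i, monoculture
#' mean M_i and expected proportion p_i, the relative-yield deviation is
#' dRY_i = Y_i / M_i - p_i, and
#' \deqn{net = \sum_i (Y_i - M_i p_i),}
#' \deqn{CE = N \, \overline{dRY} \, \overline{M},\qquad
#'       SE = N \, \mathrm{cov}(dRY, M),}
#' with the covariance taken with divisor N (population form), which makes
#' net = CE + SE an algebraic identity. A positive complementarity effect
#' means species yield more, on average, than their monocultures predict;
#' the selection effect is positive when high-yielding species
#' over-perform disproportionately.
#'
#' @param observed named numeric vector of observed species biomass in the
#'   mixture (g pot^-1); zeros allowed.
#' @param mono_means named numeric vector of monoculture means (g pot^-1),
#'   all > 0.
#' @param proportions named numeric vector of expected proportions,
#'   summing to 1.
#' @return An object of class `partition`: list with `net`,
#'   `complementarity`, `selection` (g pot^-1), plus per-species
#'   `expected`, `delta_ry` and the inputs.
#' @examples
#' p <- additive_partition(c(a = 60, b = 120), c(a = 100, b = 200),
#'                         c(a = 0.5, b = 0.5))
#' p$net; p$complementarity; p$selection  # 30, 30, 0
#' @export
additive_partition <- function(observed, mono_means, proportions) {
  n <- length(observed)
  if (n < 2) stop("additive partition needs at least 2 species")
  if (length(mono_means) != n || length(proportions) != n) {
    stop("observed, mono_means and proportions must have equal length")
  }
  if (!is.null(names(observed)) && !is.null(names(mono_means))) {
    mono_means <- mono_means[names(observed)]
    proportions <- proportions[names(observed)]
  }
  if (any(is.na(mono_means)) || any(mono_means <= 0)) {
    bad <- names(mono_means)[is.na(mono_means) | mono_means <= 0]
    stop("monoculture means must be positive; offending species: ",
         paste(bad, collapse = ", "))
  }
  if (abs(sum(proportions) - 1) > 1e-6) {
    stop("expected proportions must sum to 1 (got ", sum(proportions), ")")
  }
  expected <- mono_means * proportions
  delta_ry <- observed / mono_means - proportions
  net <- sum(observed - expected)
  ce <- n * mean(delta_ry) * mean(mono_means)
  # population covariance (divisor N) keeps net = CE + SE exact
  se <- n * mean((delta_ry - mean(delta_ry)) * (mono_means - mean(mono_means)))
  structure(list(net = net, complementarity = ce, selection = se,
                 expected = expected, delta_ry = delta_ry,
                 observed = observed, mono_means = mono_means,
                 proportions = proportions, n_species = n),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf(paste0("<partition> N = %d | net %.3f = ",
                     "complementarity %.3f + selection %.3f (g pot^-1)\n"),
              x$n_species, x$net, x$complementarity, x$selection))
  invisible(x)
}

#' Proportional deviation from expected biomass
#'
#' D = (observed - expected) / expected: the sign and relative magnitude
#' of the interaction effect on one species (or group). D = 0 means the
#' species produced exactly its monoculture-based expectation; D = 0.5
#' means 50% over-yielding.
#'
#' @param observed observed biomass (g).
#' @param expected expected biomass (g); non-positive values yield NA
#'   with a warning.
#' @return Dimensionless deviation(s).
#' @export
proportional_deviation <- function(observed, expected) {
  bad <- !is.na(expected) & expected <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive expected value(s); returning NA")
  }
  d <- (observed - expected) / expected
  d[bad] <- NA_real_
  d
}

#' Pooled proportional deviation of a species group
#'
#' Group-level deviation computed on pooled biomass:
#' D_group = (sum observed - sum expected) / sum expected over the group.
#' Used for the grass share (D_Grass) and the legume share (D_Leg) of a
#' mixture's net effect.
#'
#' @param observed,expected named numeric vectors over species.
#' @param group character vector of species ids to pool; must be
#'   non-empty and present in the names.
#' @return A single dimensionless deviation.
#' @export
group_deviation <- function(observed, expected, group) {
  if (length(group) == 0) stop("group is empty")
  if (!all(group %in% names(observed)) || !all(group %in% names(expected))) {
    stop("group species missing from observed/expected: ",
         paste(setdiff(group, intersect(names(observed), names(expected))),
               collapse = ", "))
  }
  tot_exp <- sum(expected[group])
  if (tot_exp <= 0) {
    warning("group expected biomass is non-positive; returning NA")
    return(NA_real_)
  }
  (sum(observed[group]) - tot_exp) / tot_exp
}

#' Monoculture reference means
#'
#' Per species x period mean above-ground biomass over the monoculture
#' replicate pots, the reference for all expected-biomass calculations.
#'
#' @param biomass_table long data.frame with columns `pot_id`, `period`,
#'   `species`, `biomass_g`.
#' @param design a [build_design()] object.
#' @return data.frame `species`, `period`, `mono_mean_g`, `n_reps`.
#' @export
monoculture_reference <- function(biomass_table, design) {
  mono_pots <- design$pots[design$pots$n_species == 1, ]
  b <- biomass_table[biomass_table$pot_id %in% mono_pots$pot_id, ]
  if (nrow(b) == 0) stop("no monoculture pots found in biomass table")
  agg <- stats::aggregate(biomass_g ~ species + period, data = b,
                          FUN = mean)
  n <- stats::aggregate(biomass_g ~ species + period, data = b,
                        FUN = length)
  names(agg)[names(agg) == "biomass_g"] <- "mono_mean_g"
  agg$n_reps <- n$biomass_g
  agg
}

#' Partition diversity effects for every mixture and period
#'
#' For each mixture composition and period: averages observed species
#' biomass over replicate pots, computes the expected biomass from the
#' monoculture reference, runs the additive partition, and computes
#' proportional deviations per species and pooled over the grass and
#' legume groups. Sward-type aggregates (means over compositions within
#' `2-`, `2+`, `5+`, ...) are appended.
#'
#' @param biomass_table long biomass table (see
#'   [monoculture_reference()]).
#' @param design a [build_design()] object.
#' @param proportion `"sown"` (default) to use sown proportions as the
#'   expectation, or `"observed"` to use each species' realized share of
#'   mixture biomass.
#' @return list with `partition` (one row per composition x period:
#'   `composition`, `period`, `sward_type`, `n_species`, `net_g`, `ce_g`,
#'   `se_g`, `proportion_convention`), `deviations` (rows per species and
#'   per group unit) and `sward_means` (partition columns averaged by
#'   sward type).
#' @export
partition_per_period <- function(biomass_table, design,
                                 proportion = c("sown", "observed")) {
  proportion <- match.arg(proportion)
  mono <- monoculture_reference(biomass_table, design)
  mix_pots <- design$pots[design$pots$n_species >= 2, ]
  legumes <- pool_legume_ids(design$pool)

  part_rows <- list(); dev_rows <- list()
  for (comp in unique(mix_pots$composition)) {
    sp <- composition_species(comp)
    pots_c <- mix_pots$pot_id[mix_pots$composition == comp]
    sward <- mix_pots$sward_type[mix_pots$composition == comp][1]
    b <- biomass_table[biomass_table$pot_id %in% pots_c, ]
    for (per in unique(design$periods$period)) {
      bp <- b[b$period == per, ]
      if (nrow(bp) == 0) next
      obs <- vapply(sp, function(s)
        mean(bp$biomass_g[bp$species == s]), numeric(1))
      if (any(is.na(obs))) {
        stop("species without biomass records in composition ", comp,
             ", period ", per)
      }
      m <- vapply(sp, function(s) {
        v <- mono$mono_mean_g[mono$species == s & mono$period == per]
        if (length(v) == 0) {
          stop("no monoculture reference for species ", s,
               " in period ", per)
        }
        v
      }, numeric(1))
      p <- if (proportion == "sown") {
        rep(1 / length(sp), length(sp))
      } else {
        obs / sum(obs)
      }
      names(p) <- sp
      pt <- additive_partition(obs, m, p)
      part_rows[[length(part_rows) + 1L]] <- data.frame(
        composition = comp, period = per, sward_type = sward,
        n_species = length(sp), net_g = pt$net,
        ce_g = pt$complementarity, se_g = pt$selection,
        proportion_convention = proportion, stringsAsFactors = FALSE)

      d_sp <- proportional_deviation(obs, pt$expected)
      units <- data.frame(unit = sp, d = unname(d_sp),
                          stringsAsFactors = FALSE)
      gr <- setdiff(sp, legumes)
      if (length(gr) > 0) {
        units <- rbind(units, data.frame(
          unit = "grass-group",
          d = group_deviation(obs, pt$expected, gr)))
      }
      lg <- intersect(sp, legumes)
      if (length(lg) > 0) {
        units <- rbind(units, data.frame(
          unit = "legume-group",
          d = group_deviation(obs, pt$expected, lg)))
      }
      units$composition <- comp; units$period <- per
      units$sward_type <- sward
      dev_rows[[length(dev_rows) + 1L]] <- units
    }
  }
  partition <- do.call(rbind, part_rows)
  deviations <- do.call(rbind, dev_rows)
  sward_means <- stats::aggregate(
    cbind(net_g, ce_g, se_g) ~ sward_type + period, data = partition,
    FUN = mean)
  list(partition = partition, deviations = deviations,
       sward_means = sward_means)
}
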