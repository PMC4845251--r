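#' Daily evapotranspiration from pot weights
#'
#' Recovers daily ET from a weighed-pot series by mass balance:
#' `ET_t = (W_(t-1) - W_t) + additions_t`, where additions are watering
#' or rain inputs logged on day t. Negative corrected ET (condensation or
#' weighing error) is clipped to zero; the number of clipped days is
#' returned as the `"n_clipped"` attribute so pipelines can report it.
#'
#' @param weights data.frame with columns `year`, `doy`, `weight_kg`,
#'   at least two rows, strictly increasing in time.
#' @param additions data.frame with columns `year`, `doy`,
#'   `addition_kg` (may be empty or NULL).
#' @return data.frame `year`, `doy`, `et_kg` (one row per day from the
#'   second weighing onward), with attribute `n_clipped`.
#' @examples
#' w <- data.frame(year = 1, doy = 1:3, weight_kg = c(190, 188, 187))
#' a <- data.frame(year = 1, doy = 2, addition_kg = 1)
#' daily_et_from_weights(w, a)$et_kg  # 3, 1
#' @export
daily_et_from_weights <- function(weights, additions = NULL) {
  if (nrow(weights) < 2) stop("need at least 2 weight records")
  day <- abs_day(weights$year, weights$doy)
  if (any(diff(day) <= 0)) stop("weight dates must be strictly increasing")
  add <- rep(0, nrow(weights))
  if (!is.null(additions) && nrow(additions) > 0) {
    aday <- abs_day(additions$year, additions$doy)
    idx <- match(aday, day)
    if (anyNA(idx)) stop("addition on a day without a weight record")
    add[idx] <- add[idx] + additions$addition_kg
  }
  et <- (weights$weight_kg[-nrow(weights)] - weights$weight_kg[-1]) +
    add[-1]
  n_clipped <- sum(et < 0)
  et[et < 0] <- 0
  out <- data.frame(year = weights$year[-1], doy = weights$doy[-1],
                    et_kg = et)
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Relative extractable water
#'
#' Rescales gravimetric soil moisture between a drought minimum and a
#' well-watered maximum:
#' `REW_t = (SM_t - SM_min) / (SM_max - SM_min)`, clipped to `[0, 1]`.
#' The default bounds (0.054, 0.379) are the drought and field-capacity
#' gravimetric moistures of a granitic brown grassland soil in 100 L
#' pots; because the minimum is calibrated externally, observed moisture
#' can fall outside the bounds, hence clipping with a warning rather than
#' an error.
#'
#' @param sm numeric vector of gravimetric soil moisture (fraction).
#' @param sm_min,sm_max calibration bounds; `sm_max` must exceed
#'   `sm_min`.
#' @return REW values in `[0, 1]`.
#' @examples
#' compute_rew(c(0.054, 0.2165, 0.379))  # 0, 0.5, 1
#' @export
compute_rew <- function(sm, sm_min = 0.054, sm_max = 0.379) {
  if (sm_max <= sm_min) stop("sm_max must be greater than sm_min")
  rew <- (sm - sm_min) / (sm_max - sm_min)
  n_clip <- sum(rew < 0 | rew > 1, na.rm = TRUE)
  if (n_clip > 0) {
    warning(n_clip, " REW value(s) outside [0,1] clipped")
  }
  pmin(pmax(rew, 0), 1)
}

#' Integrated water-use efficiency
#'
#' Above-ground biomass produced per unit of evapotranspired water,
#' `WUE = biomass / ET` (g dry mass per kg water), over any integration
#' window (period or year).
#'
#' @param biomass_g above-ground biomass (g), >= 0.
#' @param et_kg evapotranspiration (kg), > 0.
#' @return WUE in g kg^-1.
#' @export
compute_wue <- function(biomass_g, et_kg) {
  if (any(et_kg <= 0)) stop("evapotranspiration must be positive")
  if (any(biomass_g < 0)) stop("biomass must be non-negative")
  biomass_g / et_kg
}

#' Shoot nitrogen yield and its water cost
#'
#' `compute_nyield()` converts leaf N concentration (%) and biomass (g)
#' to nitrogen yield in gN: `Nyield = N/100 * biomass`.
#' `nyield_per_et()` expresses the water cost of shoot N production,
#' gN per kg water.
#'
#' @param n_pct leaf nitrogen concentration, percent of dry mass.
#' @param biomass_g above-ground biomass (g).
#' @param nyield_gn nitrogen yield (gN).
#' @param et_kg evapotranspiration (kg), > 0.
#' @return gN (yield) or gN kg^-1 (ratio).
#' @export
compute_nyield <- function(n_pct, biomass_g) {
  if (any(n_pct < 0) || any(biomass_g < 0)) {
    stop("nitrogen concentration and biomass must be non-negative")
  }
  n_pct / 100 * biomass_g
}

#' @rdname compute_nyield
#' @export
nyield_per_et <- function(nyield_gn, et_kg) {
  if (any(et_kg <= 0)) stop("evapotranspiration must be positive")
  if (any(nyield_gn < 0)) stop("nitrogen yield must be non-negative")
  nyield_gn / et_kg
}

#' Community leaf area
#'
#' Sums species leaf area from biomass and specific leaf area:
#' `L.area = sum_i biomass_i/1000 * SLA_i` (biomass g -> kg conversion
#' explicit), in m^2 per pot.
#'
#' @param biomass_g named numeric vector of species biomass (g).
#' @param sla named numeric vector of specific leaf area (m^2 kg^-1)
#'   covering the same species.
#' @return Leaf area in m^2 pot^-1.
#' @export
community_leaf_area <- function(biomass_g, sla) {
  if (is.null(names(biomass_g)) || is.null(names(sla)) ||
      !all(names(biomass_g) %in% names(sla))) {
    stop("species mismatch between biomass and SLA: ",
         paste(setdiff(names(biomass_g), names(sla)), collapse = ", "))
  }
  sum(biomass_g / 1000 * sla[names(biomass_g)])
}

#' Growth rate series from repeated size measurements
#'
#' Converts an ordered series of size measurements (plant height, or
#' cumulative root length on a minirhizotron tube) into per-interval
#' growth rates `rate = dvalue / ddays`. For cumulative root length,
#' negative increments (root disappearance between images) are floored
#' at zero before dividing, since the variable measures growth; height
#' increments may be negative (lodging, senescence) and are kept.
#'
#' @param day absolute day index of each measurement (see [abs_day()]),
#'   strictly increasing; at least 2 values.
#' @param value measured size at each day.
#' @param cumulative logical; TRUE floors negative increments at 0
#'   (root-length convention).
#' @return data.frame `day_start`, `day_end`, `rate` (units of `value`
#'   per day).
#' @examples
#' growth_rate_series(c(0, 2, 5), c(10, 12, 15))$rate  # 1, 1
#' @export
growth_rate_series <- function(day, value, cumulative = FALSE) {
  if (length(day) < 2) stop("need at least 2 measurements")
  if (any(diff(day) <= 0)) stop("measurement days must be strictly increasing")
  inc <- diff(value)
  if (cumulative) inc <- pmax(inc, 0)
  data.frame(day_start = day[-length(day)], day_end = day[-1],
             rate = inc / diff(day))
}

#' Maximum growth rate within a period
#'
#' The per-period statistic is the maximum rate over the intervals
#' assigned to that period; an interval belongs to the period containing
#' its end day (growth is realized by the time it is measured). Periods
#' with no assigned interval get NA, not an error.
#'
#' @param rates a [growth_rate_series()] result.
#' @param day_start,day_end period bounds as absolute day indices.
#' @return Maximum rate in the period, or NA if no interval ends in it.
#' @export
max_rate_per_period <- function(rates, day_start, day_end) {
  sel <- rates$day_end >= day_start & rates$day_end <= day_end
  if (!any(sel)) return(NA_real_)
  max(rates$rate[sel])
}

#' Top canopy layer biomass fraction
#'
#' Percentage of biomass in the top canopy layer (the layer absorbing
#' roughly half the photosynthetically active radiation):
#' `100 * top / total`. Zero total biomass gives NA (undefined), not an
#' error.
#'
#' @param biomass_top_g biomass in the top layer (g).
#' @param biomass_total_g total biomass (g), >= top.
#' @return Percentage in `[0, 100]` or NA.
#' @export
top_layer_fraction <- function(biomass_top_g, biomass_total_g) {
  if (any(biomass_top_g < 0, na.rm = TRUE)) stop("top biomass must be >= 0")
  if (any(biomass_top_g > biomass_total_g, na.rm = TRUE)) {
    stop("top-layer biomass cannot exceed total biomass")
  }
  out <- 100 * biomass_top_g / biomass_total_g
  out[biomass_total_g == 0] <- NA_real_
  out
}

#' Per-pot per-period resource-use metrics
#'
#' Assembles the community-level variable set from the raw tables of a
#' dataset: total biomass, ET (summed daily ET in the period), WUE,
#' community leaf area (year-matched SLA), community N (biomass-weighted
#' species N at the cut date), Nyield and Nyield/ET, mean REW, maximum
#' height growth rate (biomass-weighted over species maxima), maximum
#' deep-root growth rate, and the top-layer biomass percentage.
#'
#' @param dataset a [generate_dataset()] result or a list with the same
#'   tables (`biomass`, `leaf_traits`, `heights`, `roots`, `weights`,
#'   `additions`, `moisture`) and `design`.
#' @param sm_min,sm_max REW calibration bounds (see [compute_rew()]).
#' @return data.frame with one row per pot x period and columns
#'   `pot_id`, `period`, `sward_type`, `composition`, `biomass_g`,
#'   `et_kg`, `WUE`, `L.area`, `N`, `Nyield`, `Nyield.ET`, `REW`,
#'   `H.growth`, `R.growth`, `Biom.st1`.
#' @export
period_metrics <- function(dataset, sm_min = 0.054, sm_max = 0.379) {
  design <- dataset$design
  periods <- design$periods
  pots <- design$pots

  et_all <- do.call(rbind, lapply(split(dataset$weights,
                                        dataset$weights$pot_id),
    function(w) {
      a <- dataset$additions[dataset$additions$pot_id == w$pot_id[1], ]
      e <- daily_et_from_weights(w[order(abs_day(w$year, w$doy)), ], a)
      e$pot_id <- w$pot_id[1]
      e
    }))
  et_all$day <- abs_day(et_all$year, et_all$doy)

  moist <- dataset$moisture
  moist$day <- abs_day(moist$year, moist$doy)
  moist$rew <- compute_rew(moist$sm, sm_min, sm_max)

  lt <- dataset$leaf_traits
  lt$day <- abs_day(lt$year, lt$doy)

  rows <- list()
  for (i in seq_len(nrow(pots))) {
    pid <- pots$pot_id[i]
    sp <- composition_species(pots$composition[i])
    b_pot <- dataset$biomass[dataset$biomass$pot_id == pid, ]
    h_pot <- dataset$heights[dataset$heights$pot_id == pid, ]
    r_pot <- dataset$roots[dataset$roots$pot_id == pid, ]
    r_pot <- r_pot[order(abs_day(r_pot$year, r_pot$doy)), ]
    root_rates <- if (nrow(r_pot) >= 2) {
      growth_rate_series(abs_day(r_pot$year, r_pot$doy),
                         r_pot$root_length_mm_cm2, cumulative = TRUE)
    } else NULL
    for (k in seq_len(nrow(periods))) {
      per <- periods$period[k]
      d0 <- periods$day_start[k]; d1 <- periods$day_end[k]
      bp <- b_pot[b_pot$period == per, ]
      if (nrow(bp) == 0) next
      biomass <- sum(bp$biomass_g)
      biom_sp <- stats::setNames(bp$biomass_g, bp$species)

      et <- sum(et_all$et_kg[et_all$pot_id == pid &
                               et_all$day >= d0 & et_all$day <= d1])
      rew <- mean(moist$rew[moist$pot_id == pid &
                              moist$day >= d0 & moist$day <= d1])

      # year-matched SLA: measurement closest to the period end
      sla <- vapply(sp, function(s) {
        m <- lt[lt$pot_id == pid & lt$species == s & lt$trait == "SLA", ]
        m$value[which.min(abs(m$day - d1))]
      }, numeric(1))
      larea <- community_leaf_area(biom_sp[sp], sla)

      # community N: biomass-weighted species N at the cut date
      n_sp <- vapply(sp, function(s) {
        m <- lt[lt$pot_id == pid & lt$species == s & lt$trait == "N", ]
        m$value[which.min(abs(m$day - d1))]
      }, numeric(1))
      n_comm <- sum(biom_sp[sp] * n_sp) / sum(biom_sp[sp])
      nyield <- compute_nyield(n_comm, biomass)

      # maximum height growth rate, biomass-weighted over species
      hg_sp <- vapply(sp, function(s) {
        hs <- h_pot[h_pot$species == s, ]
        hs <- hs[order(abs_day(hs$year, hs$doy)), ]
        if (nrow(hs) < 2) return(NA_real_)
        rt <- growth_rate_series(abs_day(hs$year, hs$doy), hs$height_cm)
        max_rate_per_period(rt, d0, d1)
      }, numeric(1))
      ok <- !is.na(hg_sp)
      hgrowth <- if (any(ok)) {
        sum(biom_sp[sp][ok] * hg_sp[ok]) / sum(biom_sp[sp][ok])
      } else NA_real_

      rgrowth <- if (!is.null(root_rates)) {
        max_rate_per_period(root_rates, d0, d1)
      } else NA_real_

      biom_st1 <- top_layer_fraction(sum(bp$biomass_top_g), biomass)

      rows[[length(rows) + 1L]] <- data.frame(
        pot_id = pid, period = per, sward_type = pots$sward_type[i],
        composition = pots$composition[i], biomass_g = biomass,
        et_kg = et, WUE = compute_wue(biomass, et), L.area = larea,
        N = n_comm, Nyield = nyield,
        Nyield.ET = nyield_per_et(nyield, et), REW = rew,
        H.growth = hgrowth, R.growth = rgrowth, Biom.st1 = biom_st1,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
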