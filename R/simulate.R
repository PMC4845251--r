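#' Interaction specification for the synthetic generator
#'
#' Encodes the species-interaction structure injected into synthetic
#' biomass: a time-ramped facilitation of grasses growing with the legume
#' (the legume's N fixation benefits its neighbours increasingly as it
#' establishes), an early suppression of the legume in mixtures (slow
#' establishment under grass competition for light and shallow soil
#' resources), and a symmetric relative-yield surplus common to all
#' mixture members (resource-use complementarity). Multipliers act on the
#' relative yield: species biomass in mixture is
#' `mono_yield * p * (1 + complementarity) * (1 + ramp[t])^grass-with-legume
#' * suppression[t]^legume * lognormal noise`.
#'
#' @param facilitation_ramp numeric vector (recycled to the number of
#'   periods) of non-negative per-period additions to the grass relative
#'   yield when grown with the legume; the default ramps linearly from
#'   the third period onward, reproducing the late onset of legume
#'   effects.
#' @param legume_suppression per-period multiplier (<= 1 early) on the
#'   legume relative yield in mixtures.
#' @param complementarity_amplitude scalar relative-yield surplus applied
#'   to every species in every mixture.
#' @param noise_cv lognormal coefficient of variation of pot-level
#'   species biomass (0 = noise-free).
#' @param seed master integer seed; per-pot child streams are derived
#'   deterministically from it.
#' @return Object of class `interaction_spec`.
#' @export
interaction_spec <- function(facilitation_ramp = c(0, 0, 0.10, 0.30, 0.45, 0.60),
                             legume_suppression = c(0.35, 0.50, 0.65, 0.80, 0.90, 1.00),
                             complementarity_amplitude = 0.15,
                             noise_cv = 0.15,
                             seed = 1L) {
  if (any(facilitation_ramp < 0)) stop("facilitation_ramp must be >= 0")
  if (any(legume_suppression < 0)) stop("legume_suppression must be >= 0")
  if (complementarity_amplitude < 0) {
    stop("complementarity_amplitude must be >= 0")
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  structure(list(facilitation_ramp = facilitation_ramp,
                 legume_suppression = legume_suppression,
                 complementarity_amplitude = complementarity_amplitude,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "interaction_spec")
}

#' Neutral interaction specification
#'
#' No facilitation, no suppression, no complementarity, no noise: every
#' mixture species produces exactly `mono_yield * sown proportion`, so all
#' diversity effects downstream are exactly zero.
#' @param seed master seed (irrelevant at zero noise, kept for symmetry).
#' @return An `interaction_spec`.
#' @export
neutral_interactions <- function(seed = 1L) {
  interaction_spec(facilitation_ramp = 0, legume_suppression = 1,
                   complementarity_amplitude = 0, noise_cv = 0,
                   seed = seed)
}

# deterministic 32-bit child seed per (master, stream index)
child_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + index * 69621) %% 2147483647)
}

# lognormal multiplier with mean 1 and coefficient of variation cv
rlnorm_cv1 <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

# interaction multiplier for one species in a pot, per period
interaction_multiplier <- function(species, pot_species, pool, ix,
                                   n_periods) {
  ramp <- rep_len(ix$facilitation_ramp, n_periods)
  supp <- rep_len(ix$legume_suppression, n_periods)
  mult <- rep(1 + ix$complementarity_amplitude, n_periods)
  if (length(pot_species) == 1) return(rep(1, n_periods))
  legumes <- pool_legume_ids(pool)
  has_leg <- any(pot_species %in% legumes)
  is_leg <- species %in% legumes
  if (!is_leg && has_leg) mult <- mult * (1 + ramp)
  if (is_leg) {
    # in the full-pool mixture the legume's early suppression deepens:
    # establishment is slower under competition from four grasses
    pw <- if (length(pot_species) > 2) 2 else 1
    mult <- mult * supp^pw
  }
  mult
}

#' Simulate per-pot per-period species biomass
#'
#' Species biomass in each pot is the monoculture baseline scaled by the
#' sown proportion and the interaction multipliers of `ix`, with
#' multiplicative mean-one lognormal noise. A top-canopy-layer split is
#' emitted from each species' top-layer share trait. Ground truth is the
#' additive partition computed from the noise-free means against the true
#' monoculture baselines (not the realized monoculture pots).
#'
#' @param design a [build_design()] object.
#' @param pool the species pool used to build the design.
#' @param ix an [interaction_spec()].
#' @return list with `biomass` (long table: `pot_id`, `period`,
#'   `species`, `biomass_g`, `biomass_top_g`) and `ground_truth` (per
#'   mixture composition x period: noise-free `net_g`, `ce_g`, `se_g`).
#' @export
simulate_biomass <- function(design, pool = design$pool,
                             ix = interaction_spec()) {
  validate_pool(pool)
  periods <- design$periods$period
  np <- length(periods)
  rows <- vector("list", nrow(design$pots))
  for (i in seq_len(nrow(design$pots))) {
    pot <- design$pots[i, ]
    sp <- composition_species(pot$composition)
    set.seed(child_seed(ix$seed, i))
    pot_rows <- lapply(sp, function(s) {
      mono <- rep_len(pool[[s]]$mono_yield, np)
      mult <- interaction_multiplier(s, sp, pool, ix, np)
      noise <- rlnorm_cv1(np, ix$noise_cv)
      b <- mono * (1 / length(sp)) * mult * noise
      data.frame(pot_id = pot$pot_id, period = periods, species = s,
                 biomass_g = b,
                 biomass_top_g = b * pool[[s]]$trait_means[["top_share"]] / 100,
                 stringsAsFactors = FALSE)
    })
    rows[[i]] <- do.call(rbind, pot_rows)
  }
  biomass <- do.call(rbind, rows)
  rownames(biomass) <- NULL

  # noise-free ground truth per mixture composition x period
  mixes <- unique(design$pots$composition[design$pots$n_species >= 2])
  gt <- list()
  for (comp in mixes) {
    sp <- composition_species(comp)
    for (k in seq_len(np)) {
      m <- vapply(sp, function(s) rep_len(pool[[s]]$mono_yield, np)[k],
                  numeric(1))
      mult <- vapply(sp, function(s)
        interaction_multiplier(s, sp, pool, ix, np)[k], numeric(1))
      p <- rep(1 / length(sp), length(sp)); names(p) <- sp
      obs <- m * p * mult
      pt <- additive_partition(obs, m, p)
      gt[[length(gt) + 1L]] <- data.frame(
        composition = comp, period = periods[k], n_species = length(sp),
        net_g = pt$net, ce_g = pt$complementarity, se_g = pt$selection,
        stringsAsFactors = FALSE)
    }
  }
  list(biomass = biomass, ground_truth = do.call(rbind, gt))
}

#' Simulate daily pot water dynamics
#'
#' A bucket model per pot: gravimetric soil water is drawn down daily in
#' proportion to the pot's (noise-free) community leaf area and refilled
#' to the 80%-of-field-capacity setpoint on watering days. Pot weight is
#' tare plus soil water mass; every watering addition is logged, so the
#' series close the water balance exactly and daily evapotranspiration is
#' recoverable from weights and additions alone. Sensor soil water
#' content is emitted at three depths; legume-containing pots shift their
#' uptake toward the deep layer as the experiment progresses (deep
#' rooting of established clover).
#'
#' @param design,pool,ix as in [simulate_biomass()].
#' @param soil_dry_mass_kg dry soil mass per pot (default 130 kg: a
#'   100 L pot at bulk density 1.3).
#' @param tare_kg non-water pot mass (pot, casing, dry soil; default 155).
#' @param sm_max field-capacity gravimetric moisture (default 0.379).
#' @param setpoint_frac watering setpoint as fraction of field capacity
#'   (default 0.8).
#' @param et_rate_kg_m2 transpiration per unit leaf area per day
#'   (default 0.5 kg m^-2 day^-1, which puts integrated water-use
#'   efficiency near 3 g dry mass per kg water, typical for temperate
#'   grassland mesocosms).
#' @param refill_every watering interval in days (default 2).
#' @return list of data.frames: `weights` (`pot_id`, `year`, `doy`,
#'   `weight_kg`), `additions` (`pot_id`, `year`, `doy`,
#'   `addition_kg`), `moisture` (`pot_id`, `year`, `doy`, `sm`, plus
#'   sensor `swc_15`, `swc_30`, `swc_50` in m^3 m^-3).
#' @export
simulate_water <- function(design, pool = design$pool,
                           ix = interaction_spec(),
                           soil_dry_mass_kg = 130, tare_kg = 155,
                           sm_max = 0.379, setpoint_frac = 0.8,
                           et_rate_kg_m2 = 0.5, refill_every = 2) {
  periods <- design$periods
  days <- seq(min(periods$day_start) - 1L, max(periods$day_end))
  np <- nrow(periods)

  # noise-free community leaf area per pot x period (m^2): biomass x SLA
  la_pot <- matrix(0, nrow(design$pots), np,
                   dimnames = list(design$pots$pot_id, periods$period))
  for (i in seq_len(nrow(design$pots))) {
    sp <- composition_species(design$pots$composition[i])
    for (k in seq_len(np)) {
      b <- vapply(sp, function(s) {
        rep_len(pool[[s]]$mono_yield, np)[k] / length(sp) *
          interaction_multiplier(s, sp, pool, ix, np)[k]
      }, numeric(1))
      sla <- vapply(sp, function(s) pool[[s]]$trait_means[["SLA"]],
                    numeric(1))
      la_pot[i, k] <- sum(b / 1000 * sla)
    }
  }

  setpoint <- sm_max * setpoint_frac
  w_list <- a_list <- m_list <- vector("list", nrow(design$pots))
  for (i in seq_len(nrow(design$pots))) {
    pot_id <- design$pots$pot_id[i]
    has_leg <- design$pots$has_legume[i] && design$pots$n_species[i] >= 1
    water <- setpoint * soil_dry_mass_kg
    nd <- length(days)
    weight <- addition <- sm <- numeric(nd)
    swc <- matrix(0, nd, 3)
    weight[1] <- tare_kg + water
    sm[1] <- water / soil_dry_mass_kg
    frac0 <- c(0.45, 0.35, 0.20)  # uptake shares at 15/30/50 cm
    swc[1, ] <- sm[1] * 1.3       # volumetric ~ gravimetric x bulk density
    for (t in 2:nd) {
      per_idx <- match(period_of_day(days[t], periods), periods$period)
      if (is.na(per_idx)) per_idx <- if (days[t] < periods$day_start[1]) 1L else np
      # leaf area regrows linearly from the cut at period start
      span <- periods$day_end[per_idx] - periods$day_start[per_idx]
      fgrow <- min(1, max(0.1, (days[t] - periods$day_start[per_idx]) / span))
      la_t <- la_pot[i, per_idx] * fgrow
      et <- min(et_rate_kg_m2 * la_t, water)  # cannot extract below zero
      water <- water - et
      add <- 0
      if ((t %% refill_every) == 0) {
        add <- setpoint * soil_dry_mass_kg - water
        water <- water + add
      }
      weight[t] <- tare_kg + water
      addition[t] <- add
      sm[t] <- water / soil_dry_mass_kg
      # depth profile: legume pots shift uptake to 50 cm over time
      prog <- (t - 1) / (nd - 1)
      shift <- if (has_leg) 0.15 * prog else 0
      frac <- frac0 + c(-shift / 2, -shift / 2, shift)
      deficit <- (setpoint - sm[t]) / setpoint
      swc[t, ] <- pmax(0, (sm[t] * 1.3) * (1 - deficit * (frac / frac0 - 1)))
    }
    yr <- (days - 1L) %/% 365L + 1L
    dy <- days - (yr - 1L) * 365L
    w_list[[i]] <- data.frame(pot_id = pot_id, year = yr, doy = dy,
                              weight_kg = weight, stringsAsFactors = FALSE)
    keep <- which(addition > 0)
    a_list[[i]] <- data.frame(pot_id = rep(pot_id, length(keep)),
                              year = yr[keep], doy = dy[keep],
                              addition_kg = addition[keep],
                              stringsAsFactors = FALSE)
    m_list[[i]] <- data.frame(pot_id = pot_id, year = yr, doy = dy,
                              sm = sm, swc_15 = swc[, 1], swc_30 = swc[, 2],
                              swc_50 = swc[, 3], stringsAsFactors = FALSE)
  }
  list(weights = do.call(rbind, w_list),
       additions = do.call(rbind, a_list),
       moisture = do.call(rbind, m_list))
}

#' Simulate trait measurements and growth time series
#'
#' Leaf traits (SLA, LDMC at two spring dates; N and d13C at each cutting
#' date) are drawn per species x pot around the pool trait means. Height
#' is recorded at ~18 dates per species x pot, growing from the last cut
#' at the species' height growth rate; deep root length (minirhizotron,
#' pot level) accumulates monthly at the community-weighted root growth
#' rate, amplified by the facilitation ramp in legume-containing pots.
#'
#' @param design,pool,ix as in [simulate_biomass()].
#' @return list of data.frames: `leaf_traits` (`pot_id`, `species`,
#'   `year`, `doy`, `trait`, `value`), `heights` (`pot_id`, `species`,
#'   `year`, `doy`, `height_cm`), `roots` (`pot_id`, `year`, `doy`,
#'   `root_length_mm_cm2`).
#' @export
simulate_traits <- function(design, pool = design$pool,
                            ix = interaction_spec()) {
  periods <- design$periods
  np <- nrow(periods)
  cut_dates <- data.frame(year = periods$year_end, doy = periods$doy_end)
  sla_dates <- data.frame(year = c(1L, 2L), doy = c(136L, 157L))

  # height measurement dates: every ~20 days across the experiment
  hd <- seq(min(periods$day_start) + 10L, max(periods$day_end), by = 20L)
  # root imaging dates: fortnightly, so every period spans >= 1 interval
  rd <- seq(min(periods$day_start) + 10L, max(periods$day_end), by = 15L)

  lt <- hh <- rr <- list()
  ramp <- rep_len(ix$facilitation_ramp, np)
  for (i in seq_len(nrow(design$pots))) {
    pot <- design$pots[i, ]
    sp <- composition_species(pot$composition)
    set.seed(child_seed(ix$seed, 10000L + i))
    for (s in sp) {
      tm <- pool[[s]]$trait_means; ts <- pool[[s]]$trait_sds
      draw <- function(trait, n) stats::rnorm(n, tm[[trait]], ts[[trait]])
      for (j in seq_len(nrow(sla_dates))) {
        lt[[length(lt) + 1L]] <- data.frame(
          pot_id = pot$pot_id, species = s, year = sla_dates$year[j],
          doy = sla_dates$doy[j],
          trait = c("SLA", "LDMC"),
          value = pmax(c(draw("SLA", 1), draw("LDMC", 1)), 0),
          stringsAsFactors = FALSE)
      }
      for (j in seq_len(nrow(cut_dates))) {
        lt[[length(lt) + 1L]] <- data.frame(
          pot_id = pot$pot_id, species = s, year = cut_dates$year[j],
          doy = cut_dates$doy[j],
          trait = c("N", "d13C"),
          value = c(max(draw("N", 1), 0), draw("d13C", 1)),
          stringsAsFactors = FALSE)
      }
      # heights: linear regrowth from last cut at species rate + noise
      rate <- pmax(stats::rnorm(length(hd), tm[["H.growth"]],
                                ts[["H.growth"]]), 0)
      h_yr <- (hd - 1L) %/% 365L + 1L
      h_dy <- hd - (h_yr - 1L) * 365L
      since_cut <- vapply(hd, function(d) {
        starts <- periods$day_start[periods$day_start <= d]
        if (length(starts) == 0) 0 else d - max(starts)
      }, numeric(1))
      hh[[length(hh) + 1L]] <- data.frame(
        pot_id = pot$pot_id, species = s, year = h_yr, doy = h_dy,
        height_cm = 5 + rate * since_cut, stringsAsFactors = FALSE)
    }
    # pot-level deep root length: cumulative community growth
    per_idx <- match(period_of_day(rd, periods), periods$period)
    per_idx[is.na(per_idx)] <- 1L
    rg_mean <- mean(vapply(sp, function(s)
      pool[[s]]$trait_means[["R.growth"]], numeric(1)))
    amp <- if (pot$has_legume && length(sp) >= 2) 1 + ramp[per_idx] else
      rep(1, length(rd))
    inc <- pmax(stats::rnorm(length(rd), rg_mean, 0.05 * rg_mean), 0) *
      amp * c(diff(c(min(periods$day_start), rd)))
    r_yr <- (rd - 1L) %/% 365L + 1L
    rr[[length(rr) + 1L]] <- data.frame(
      pot_id = pot$pot_id, year = r_yr, doy = rd - (r_yr - 1L) * 365L,
      root_length_mm_cm2 = cumsum(inc), stringsAsFactors = FALSE)
  }
  list(leaf_traits = do.call(rbind, lt), heights = do.call(rbind, hh),
       roots = do.call(rbind, rr))
}

#' Generate a complete synthetic dataset
#'
#' Runs [simulate_biomass()], [simulate_water()] and [simulate_traits()]
#' under one master seed and bundles the tables with the design and the
#' noise-free ground-truth partition.
#'
#' @param design a [build_design()] object (default: the 53-pot layout).
#' @param ix an [interaction_spec()].
#' @param ... passed to [simulate_water()].
#' @return Object of class `sward_dataset`: list of tables `biomass`,
#'   `leaf_traits`, `heights`, `roots`, `weights`, `additions`,
#'   `moisture`, `ground_truth`, plus `design` and `ix`.
#' @export
generate_dataset <- function(design = build_design(),
                             ix = interaction_spec(), ...) {
  b <- simulate_biomass(design, design$pool, ix)
  w <- simulate_water(design, design$pool, ix, ...)
  tr <- simulate_traits(design, design$pool, ix)
  structure(c(list(biomass = b$biomass, ground_truth = b$ground_truth),
              tr, w, list(design = design, ix = ix)),
            class = "sward_dataset")
}

#' @export
print.sward_dataset <- function(x, ...) {
  cat(sprintf(paste0("<sward_dataset> %d pots x %d periods; %d biomass ",
                     "rows, %d weight days\n"),
              nrow(x$design$pots), nrow(x$design$periods),
              nrow(x$biomass), nrow(x$weights) / nrow(x$design$pots)))
  invisible(x)
}

#' Write a synthetic dataset to tab-separated files
#'
#' Writes `design.tsv`, `biomass.tsv`, `traits.tsv`, `heights.tsv`,
#' `roots.tsv`, `weights.tsv`, `additions.tsv`, `moisture.tsv` and
#' `ground_truth.tsv` (UTF-8, tab-separated, header row, '.' decimal).
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory, created if absent.
#' @return Invisibly, the named vector of file paths.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  design_tab <- merge(dataset$design$pots, dataset$design$proportions,
                      by = "pot_id")
  per <- dataset$design$periods
  tabs <- list(design = design_tab,
               periods = per[, c("period", "year_start", "doy_start",
                                 "year_end", "doy_end")],
               biomass = dataset$biomass,
               traits = dataset$leaf_traits, heights = dataset$heights,
               roots = dataset$roots, weights = dataset$weights,
               additions = dataset$additions, moisture = dataset$moisture,
               ground_truth = dataset$ground_truth)
  paths <- vapply(names(tabs), function(nm) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    write_tsv(tabs[[nm]], p)
    p
  }, character(1))
  invisible(paths)
}

# plain TSV writer: tab-separated, '.' decimal, no quoting, no row names
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
}

#' Simulate a planted linear trait signal
#'
#' Generates a community-by-trait predictor matrix over the ten standard
#' community variables and a response driven by a chosen subset of them
#' at a target population R-squared -- the recovery benchmark for
#' best-subset selection and importance decomposition.
#'
#' @param n number of communities (rows).
#' @param active character vector of the truly active predictors.
#' @param r2 target population R-squared of the linear signal.
#' @param seed integer seed.
#' @param beta coefficients for the active predictors (default all 1).
#' @return list with `X` (n x 10 matrix, standard-normal columns), `y`,
#'   `active`, `beta`, `r2`.
#' @export
simulate_planted_signal <- function(n = 30, active = c("L.area", "WUE"),
                                    r2 = 0.9, seed = 1L,
                                    beta = rep(1, length(active))) {
  stopifnot(r2 > 0, r2 < 1, n > length(active) + 2)
  vars <- c("Biom.st1", "d13C", "H.growth", "L.area", "LDMC", "N",
            "Nyield.ET", "REW", "R.growth", "WUE")
  if (!all(active %in% vars)) {
    stop("active predictors must be among: ", paste(vars, collapse = ", "))
  }
  set.seed(seed)
  X <- matrix(stats::rnorm(n * length(vars)), n, length(vars),
              dimnames = list(NULL, vars))
  signal <- drop(X[, active, drop = FALSE] %*% beta)
  # independent columns: signal variance = sum(beta^2); scale noise to r2
  noise_sd <- sqrt(sum(beta^2) * (1 - r2) / r2)
  y <- signal + stats::rnorm(n, 0, noise_sd)
  list(X = X, y = y, active = active, beta = beta, r2 = r2)
}
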