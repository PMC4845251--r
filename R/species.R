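#' Species specifications for the synthetic mesocosm generator
#'
#' A species specification records the identity, functional group and
#' stature of one species together with its baseline monoculture yield per
#' production period and the means and standard deviations of its
#' measurable traits. The default pool holds four perennial grasses and one
#' legume (white clover), the classic composition of a temperate fertile
#' grassland mixture experiment.
#'
#' Trait slots (units): `SLA` specific leaf area (m^2 kg^-1), `LDMC` leaf
#' dry matter content (mg g^-1), `N` leaf nitrogen (% dry mass), `d13C`
#' leaf carbon isotopic composition (per mil), `H.growth` height growth
#' rate (cm day^-1), `R.growth` deep root length growth rate
#' (mm cm^-2 day^-1), `top_share` share of biomass in the top canopy
#' layer (%).
#'
#' @param species_id short code, e.g. `"dg"`.
#' @param functional_group `"grass"` or `"legume"`.
#' @param stature `"tall"` or `"short"`.
#' @param rooting `"deep"`, `"shallow"` or `"intermediate"`.
#' @param mono_yield named or unnamed numeric vector of mean monoculture
#'   above-ground biomass (g pot^-1) for each production period, in
#'   calendar order.
#' @param trait_means,trait_sds named numeric vectors over the trait slots
#'   listed above; standard deviations must be non-negative.
#' @return An object of class `species_spec`.
#' @export
species_spec <- function(species_id, functional_group, stature, rooting,
                         mono_yield, trait_means, trait_sds) {
  functional_group <- match.arg(functional_group, c("grass", "legume"))
  stature <- match.arg(stature, c("tall", "short"))
  rooting <- match.arg(rooting, c("deep", "shallow", "intermediate"))
  if (any(mono_yield < 0)) {
    stop("monoculture yields must be non-negative for species ", species_id)
  }
  slots <- c("SLA", "LDMC", "N", "d13C", "H.growth", "R.growth", "top_share")
  if (!all(slots %in% names(trait_means)) ||
      !all(slots %in% names(trait_sds))) {
    stop("trait_means and trait_sds must cover: ",
         paste(slots, collapse = ", "))
  }
  if (any(trait_sds[slots] < 0)) {
    stop("trait standard deviations must be non-negative")
  }
  structure(
    list(species_id = species_id, functional_group = functional_group,
         stature = stature, rooting = rooting,
         mono_yield = as.numeric(mono_yield),
         trait_means = trait_means[slots], trait_sds = trait_sds[slots]),
    class = "species_spec"
  )
}

#' @export
print.species_spec <- function(x, ...) {
  cat(sprintf("<species_spec> %s (%s, %s, %s-rooted)\n", x$species_id,
              x$functional_group, x$stature, x$rooting))
  cat("  mono yield (g pot^-1):", paste(round(x$mono_yield, 1),
                                        collapse = ", "), "\n")
  invisible(x)
}

#' Default five-species pool
#'
#' Four grasses -- two tall deep-rooted (cocksfoot `dg`, tall fescue `fa`)
#' and two short shallow-rooted (smooth meadow-grass `pp`, yellow
#' oat-grass `tf`) -- plus the legume white clover (`tr`). Monoculture
#' yield profiles follow the published treatment means of a 53-pot
#' mesocosm trial: grass monocultures peak in early summer of year 1 and
#' decline, while the clover monoculture establishes slowly and overtakes
#' the grasses from autumn of year 1 onward. Trait means are typical
#' species-level values for fertile upland grassland; the legume carries
#' higher leaf N, lower LDMC and more negative d13C than the grasses.
#'
#' @return A list of [species_spec()] objects of class `species_pool`.
#' @export
default_species_pool <- function() {
  # per-period monoculture means; grass profile scaled per species around
  # the grass-monoculture treatment mean, clover uses the legume profile
  grass_profile  <- c(92.6, 149.6, 85.3, 74.1, 59.1, 54.6)
  legume_profile <- c(31.2, 159.7, 120.4, 134.8, 100.3, 118.3)
  mk <- function(id, fg, st, ro, scale, profile, tm, ts) {
    species_spec(id, fg, st, ro, profile * scale, tm, ts)
  }
  tm <- function(sla, ldmc, n, d13c, hg, rg, top) {
    c(SLA = sla, LDMC = ldmc, N = n, d13C = d13c,
      H.growth = hg, R.growth = rg, top_share = top)
  }
  rel_sd <- c(SLA = 0.08, LDMC = 0.06, N = 0.08, d13C = 0.015,
              H.growth = 0.15, R.growth = 0.20, top_share = 0.10)
  ts <- function(m) abs(m) * rel_sd
  pool <- list(
    mk("dg", "grass", "tall", "deep", 1.10, grass_profile,
       tm(22, 250, 2.0, -28.5, 1.20, 0.20, 60), ts(tm(22, 250, 2.0, -28.5, 1.20, 0.20, 60))),
    mk("fa", "grass", "tall", "deep", 1.05, grass_profile,
       tm(18, 280, 1.8, -28.0, 1.10, 0.22, 55), ts(tm(18, 280, 1.8, -28.0, 1.10, 0.22, 55))),
    mk("pp", "grass", "short", "shallow", 0.90, grass_profile,
       tm(24, 300, 1.9, -27.5, 0.60, 0.10, 35), ts(tm(24, 300, 1.9, -27.5, 0.60, 0.10, 35))),
    mk("tf", "grass", "short", "shallow", 0.95, grass_profile,
       tm(26, 270, 2.0, -27.8, 0.70, 0.12, 40), ts(tm(26, 270, 2.0, -27.8, 0.70, 0.12, 40))),
    mk("tr", "legume", "short", "intermediate", 1.00, legume_profile,
       tm(28, 180, 3.8, -29.5, 0.80, 0.25, 45), ts(tm(28, 180, 3.8, -29.5, 0.80, 0.25, 45)))
  )
  names(pool) <- vapply(pool, `[[`, "", "species_id")
  class(pool) <- "species_pool"
  pool
}

#' @export
print.species_pool <- function(x, ...) {
  cat(sprintf("<species_pool> %d species: %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

pool_legume_ids <- function(pool) {
  names(pool)[vapply(pool, function(s) s$functional_group == "legume",
                     logical(1))]
}

validate_pool <- function(pool) {
  ids <- vapply(pool, `[[`, "", "species_id")
  if (anyDuplicated(ids)) stop("duplicate species ids in pool")
  if (length(pool) == 0) stop("species pool is empty")
  invisible(pool)
}
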