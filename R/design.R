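#' Build the pot design of a mixture experiment
#'
#' Enumerates all monocultures, all unordered two-species mixtures and the
#' single full-pool mixture over a species pool, replicated, and labels
#' each pot with its sward type (richness crossed with legume presence:
#' `1-`, `1+`, `2-`, `2+`, `5+` for the default five-species pool). With
#' the default pool and 4 monoculture / 3 mixture replicates this yields
#' the canonical 53-pot layout: 5 monocultures x 4 + 10 pairs x 3 + 1
#' five-species mixture x 3.
#'
#' Sown proportions are equal within a pot (each pot is planted with the
#' same number of individuals split evenly among its species).
#'
#' @param n_reps_mono replicates per monoculture (default 4).
#' @param n_reps_mix replicates per mixture (default 3).
#' @param pool a `species_pool`; default [default_species_pool()].
#' @param periods period calendar data.frame; default [default_periods()].
#' @return An object of class `sward_design`: a list with `pots` (one row
#'   per pot: `pot_id`, `composition`, `sward_type`, `replicate`,
#'   `n_species`, `has_legume`), `proportions` (long pot x species sown
#'   proportions), `periods` and the `pool`.
#' @examples
#' d <- build_design()
#' nrow(d$pots)            # 53
#' table(d$pots$sward_type)
#' @export
build_design <- function(n_reps_mono = 4, n_reps_mix = 3,
                         pool = default_species_pool(),
                         periods = default_periods()) {
  validate_pool(pool)
  stopifnot(n_reps_mono >= 1, n_reps_mix >= 1)
  ids <- names(pool)
  legumes <- pool_legume_ids(pool)

  comps <- c(as.list(ids),                                  # monocultures
             if (length(ids) >= 2)
               utils::combn(ids, 2, simplify = FALSE),      # all pairs
             if (length(ids) >= 3) list(ids))               # full pool
  pots <- list()
  pot_id <- 0L
  for (comp in comps) {
    n_sp <- length(comp)
    reps <- if (n_sp == 1) n_reps_mono else n_reps_mix
    for (r in seq_len(reps)) {
      pot_id <- pot_id + 1L
      pots[[pot_id]] <- data.frame(
        pot_id = sprintf("p%02d", pot_id),
        composition = paste(comp, collapse = "-"),
        replicate = r,
        n_species = n_sp,
        has_legume = any(comp %in% legumes),
        stringsAsFactors = FALSE
      )
    }
  }
  pots <- do.call(rbind, pots)
  pots$sward_type <- paste0(pots$n_species,
                            ifelse(pots$has_legume, "+", "-"))

  prop <- do.call(rbind, lapply(seq_len(nrow(pots)), function(i) {
    sp <- strsplit(pots$composition[i], "-", fixed = TRUE)[[1]]
    data.frame(pot_id = pots$pot_id[i], species = sp,
               sown_proportion = 1 / length(sp), stringsAsFactors = FALSE)
  }))

  structure(list(pots = pots, proportions = prop, periods = periods,
                 pool = pool),
            class = "sward_design")
}

#' @export
print.sward_design <- function(x, ...) {
  cat(sprintf("<sward_design> %d pots, %d species, %d periods\n",
              nrow(x$pots), length(x$pool), nrow(x$periods)))
  print(table(sward_type = x$pots$sward_type))
  invisible(x)
}

# species of one composition string
composition_species <- function(composition) {
  strsplit(composition, "-", fixed = TRUE)[[1]]
}
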