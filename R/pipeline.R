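#' Default run configuration
#'
#' The configuration object fully determines a pipeline run: the
#' synthetic scenario (or paths to user tables in the same schema), REW
#' calibration bounds, the community-trait and partition conventions,
#' model scope and subset cap, output directory and master seed.
#'
#' @param seed master seed for synthetic generation.
#' @param output_dir where tables and the manifest are written.
#' @param scenario `"synthetic"` or a directory of user TSV tables
#'   (schema of [write_dataset()]).
#' @param n_reps_mono,n_reps_mix design replication.
#' @param interactions an [interaction_spec()]; its seed is overridden
#'   by `seed`.
#' @param sm_min,sm_max REW bounds.
#' @param fd_distance `"gower"` or `"sq_euclid"`.
#' @param proportion partition expectation convention, `"sown"` or
#'   `"observed"`.
#' @param model_scope `"whole"` or a period label.
#' @param max_subset_size subset cap for model selection.
#' @param importance_metric `"pmvd"` or `"lmg"`.
#' @return A `run_config` list.
#' @export
default_config <- function(seed = 1L, output_dir = tempfile("swardiv_run_"),
                           scenario = "synthetic",
                           n_reps_mono = 4, n_reps_mix = 3,
                           interactions = interaction_spec(),
                           sm_min = 0.054, sm_max = 0.379,
                           fd_distance = "gower",
                           proportion = "sown",
                           model_scope = "whole",
                           max_subset_size = 5,
                           importance_metric = "pmvd") {
  cfg <- list(seed = as.integer(seed), output_dir = output_dir,
              scenario = scenario, n_reps_mono = n_reps_mono,
              n_reps_mix = n_reps_mix, interactions = interactions,
              sm_min = sm_min, sm_max = sm_max,
              fd_distance = fd_distance, proportion = proportion,
              model_scope = model_scope,
              max_subset_size = max_subset_size,
              importance_metric = importance_metric)
  class(cfg) <- "run_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (!cfg$fd_distance %in% c("gower", "sq_euclid")) {
    stop("unknown fd_distance: ", cfg$fd_distance)
  }
  if (!cfg$proportion %in% c("sown", "observed")) {
    stop("unknown proportion convention: ", cfg$proportion)
  }
  if (!cfg$importance_metric %in% c("pmvd", "lmg")) {
    stop("unknown importance metric: ", cfg$importance_metric)
  }
  if (cfg$sm_max <= cfg$sm_min) stop("sm_max must exceed sm_min")
  if (identical(cfg$scenario, "synthetic") && is.null(cfg$seed)) {
    stop("synthetic runs require a seed")
  }
  invisible(cfg)
}

#' Read a run configuration from YAML
#'
#' Reads the scalar fields of [default_config()] plus an optional
#' `interactions` block (fields of [interaction_spec()]).
#'
#' @param path YAML file.
#' @return A validated `run_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ix_args <- raw$interactions
  raw$interactions <- NULL
  cfg <- do.call(default_config, c(raw,
    if (!is.null(ix_args)) list(interactions = do.call(interaction_spec,
                                                       ix_args))))
  cfg
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory holding the TSV tables.
#' @return A `sward_dataset`-style list (without an interaction spec).
#' @export
read_dataset <- function(dir) {
  rd <- function(nm) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    if (!file.exists(p)) stop("missing table: ", p)
    utils::read.delim(p, stringsAsFactors = FALSE)
  }
  design_tab <- rd("design")
  periods <- rd("periods")
  periods$day_start <- abs_day(periods$year_start, periods$doy_start)
  periods$day_end <- abs_day(periods$year_end, periods$doy_end)
  pots <- unique(design_tab[, c("pot_id", "composition", "replicate",
                                "n_species", "has_legume", "sward_type")])
  prop <- design_tab[, c("pot_id", "species", "sown_proportion")]
  design <- structure(list(pots = pots, proportions = prop,
                           periods = periods,
                           pool = default_species_pool()),
                      class = "sward_design")
  structure(list(biomass = rd("biomass"), leaf_traits = rd("traits"),
                 heights = rd("heights"), roots = rd("roots"),
                 weights = rd("weights"), additions = rd("additions"),
                 moisture = rd("moisture"),
                 ground_truth = tryCatch(rd("ground_truth"),
                                         error = function(e) NULL),
                 design = design),
            class = "sward_dataset")
}

#' Run the full analysis pipeline
#'
#' Orchestrates generate (or load) -> resource metrics -> community
#' traits -> diversity-effect partition -> trait models, writing
#' `period_metrics.tsv`, `cwm.tsv`, `fdq.tsv`, `diversity_effects.tsv`,
#' `deviations.tsv`, `model_selection.tsv`, `importance.tsv` and
#' `manifest.json` to the configured output directory. Any stage failure
#' aborts with an error naming the stage. Warnings raised inside stages
#' (REW clipping, dropped FD traits, PMVD fallback) are counted in the
#' manifest.
#'
#' @param config a [default_config()] object.
#' @return Invisibly, a `run_manifest` list (config echo, package
#'   version, per-file md5 checksums, warning counts).
#' @export
run_pipeline <- function(config = default_config()) {
  validate_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- new.env(parent = emptyenv())
  stage <- function(name, expr) {
    n_before <- length(ls(warnings_log))
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)
      }),
      warning = function(w) {
        key <- paste0(name, ":", length(ls(warnings_log)) + 1L)
        assign(key, conditionMessage(w), envir = warnings_log)
        invokeRestart("muffleWarning")
      })
  }

  dataset <- stage("generate", {
    if (identical(config$scenario, "synthetic")) {
      ix <- config$interactions
      ix$seed <- config$seed
      generate_dataset(build_design(config$n_reps_mono,
                                    config$n_reps_mix), ix)
    } else {
      read_dataset(config$scenario)
    }
  })
  metrics <- stage("resource_metrics",
                   period_metrics(dataset, config$sm_min, config$sm_max))
  ct <- stage("community_traits",
              community_trait_table(dataset, config$fd_distance))
  de <- stage("diversity_effects",
              partition_per_period(dataset$biomass, dataset$design,
                                   proportion = config$proportion))
  reports <- stage("trait_models", {
    lapply(c("biomass", "net", "complementarity"), function(resp) {
      am <- assemble_matrix(metrics, ct$cwm,
                            partition = de$partition, response = resp,
                            scope = config$model_scope)
      select_trait_model(am$X, am$y,
                         max_size = config$max_subset_size,
                         response = resp)
    })
  })

  sel_tab <- do.call(rbind, lapply(reports, function(r) {
    cbind(response = r$response, r$selection$by_size)
  }))
  imp_tab <- importance_table(reports, metric = config$importance_metric)

  out <- config$output_dir
  files <- c(period_metrics = "period_metrics.tsv", cwm = "cwm.tsv",
             fdq = "fdq.tsv", diversity_effects = "diversity_effects.tsv",
             deviations = "deviations.tsv",
             model_selection = "model_selection.tsv",
             importance = "importance.tsv")
  write_tsv(metrics, file.path(out, files["period_metrics"]))
  write_tsv(ct$cwm, file.path(out, files["cwm"]))
  write_tsv(ct$fdq, file.path(out, files["fdq"]))
  write_tsv(de$partition, file.path(out, files["diversity_effects"]))
  write_tsv(de$deviations, file.path(out, files["deviations"]))
  write_tsv(sel_tab, file.path(out, files["model_selection"]))
  write_tsv(imp_tab, file.path(out, files["importance"]))

  checksums <- tools::md5sum(file.path(out, files))
  names(checksums) <- files
  wkeys <- ls(warnings_log)
  warn_counts <- table(sub(":.*$", "", wkeys))
  manifest <- list(
    seed = config$seed,
    scenario = config$scenario,
    conventions = list(proportion = config$proportion,
                       fd_distance = config$fd_distance,
                       importance_metric = config$importance_metric,
                       rew_bounds = c(config$sm_min, config$sm_max)),
    package_version = as.character(utils::packageVersion("swardiv")),
    checksums = as.list(checksums),
    warning_counts = as.list(warn_counts),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(structure(list(manifest = manifest, metrics = metrics,
                           community_traits = ct, diversity_effects = de,
                           reports = reports, dataset = dataset),
                      class = "run_result"))
}

#' Validate a directory of input tables
#'
#' Schema and consistency checks on tables in the [write_dataset()]
#' layout: required columns, key uniqueness of (pot, period, species)
#' biomass rows, sown proportions summing to 1 per pot, strictly
#' increasing weight dates per pot, non-negative moisture. Returns a
#' machine-readable issue list rather than stopping at the first
#' problem.
#'
#' @param dir directory of TSV tables.
#' @return data.frame with columns `file`, `check`, `detail`; zero rows
#'   when everything passes.
#' @export
validate_tables <- function(dir) {
  issues <- list()
  note <- function(file, check, detail) {
    issues[[length(issues) + 1L]] <<- data.frame(
      file = file, check = check, detail = detail,
      stringsAsFactors = FALSE)
  }
  required <- list(
    design = c("pot_id", "composition", "species", "sown_proportion"),
    biomass = c("pot_id", "period", "species", "biomass_g"),
    weights = c("pot_id", "year", "doy", "weight_kg"),
    moisture = c("pot_id", "year", "doy", "sm"))
  tabs <- list()
  for (nm in names(required)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    if (!file.exists(p)) { note(nm, "missing_file", p); next }
    t <- tryCatch(utils::read.delim(p, stringsAsFactors = FALSE),
                  error = function(e) NULL)
    if (is.null(t)) { note(nm, "unreadable", p); next }
    miss <- setdiff(required[[nm]], names(t))
    if (length(miss) > 0) {
      note(nm, "missing_columns", paste(miss, collapse = ","))
      next
    }
    tabs[[nm]] <- t
  }
  if (!is.null(tabs$biomass)) {
    key <- with(tabs$biomass, paste(pot_id, period, species))
    dup <- unique(key[duplicated(key)])
    for (d in dup) note("biomass", "duplicate_key", d)
    if (any(tabs$biomass$biomass_g < 0, na.rm = TRUE)) {
      note("biomass", "negative_biomass",
           sum(tabs$biomass$biomass_g < 0, na.rm = TRUE))
    }
  }
  if (!is.null(tabs$design)) {
    ps <- tapply(tabs$design$sown_proportion, tabs$design$pot_id, sum)
    bad <- names(ps)[abs(ps - 1) > 1e-6]
    for (b in bad) {
      note("design", "proportion_sum",
           sprintf("%s sums to %.4f", b, ps[[b]]))
    }
  }
  if (!is.null(tabs$weights)) {
    for (pid in unique(tabs$weights$pot_id)) {
      w <- tabs$weights[tabs$weights$pot_id == pid, ]
      d <- abs_day(w$year, w$doy)
      if (any(diff(d[order(seq_along(d))]) <= 0) && any(diff(d) <= 0)) {
        note("weights", "dates_not_increasing", pid)
      }
    }
  }
  if (!is.null(tabs$moisture) &&
      any(tabs$moisture$sm < 0, na.rm = TRUE)) {
    note("moisture", "negative_moisture",
         sum(tabs$moisture$sm < 0, na.rm = TRUE))
  }
  if (length(issues) == 0) {
    data.frame(file = character(0), check = character(0),
               detail = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, issues)
  }
}
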