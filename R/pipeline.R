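# End-to-end driver: ingest -> metrics -> per-clade model fits / PGLS /
# multivariate PGLS -> supertree ancestral states -> ANOVA -> hypervolumes,
# from a single configuration with structured logging and provenance.

#' Prune a tree and a metric table to their common species
#'
#' @param metric_table data.frame with a `species` column.
#' @param tree a `phylo`.
#' @return list: `tree` (pruned), `table` (subset, in tip order),
#'   `dropped_from_table`, `dropped_from_tree` (counts).
#' @export
species_tree_intersect <- function(metric_table, tree) {
  common <- intersect(metric_table$species, tree$tip.label)
  if (length(common) < 4L) {
    stop("fewer than 4 species shared between table and tree (",
         length(common), ")")
  }
  drop_tree <- setdiff(tree$tip.label, common)
  pruned <- if (length(drop_tree)) ape::drop.tip(tree, drop_tree) else tree
  tab <- metric_table[match(pruned$tip.label, metric_table$species), , drop = FALSE]
  rownames(tab) <- NULL
  list(tree = pruned, table = tab,
       dropped_from_table = nrow(metric_table) - length(common),
       dropped_from_tree = length(drop_tree))
}

#' Pipeline run configuration
#'
#' Collects all inputs and options of [run_pipeline()]. Either file paths
#' (trait tables, per-clade Newick trees, divergence CSV) or in-memory
#' objects (a [generate_trait_database()] bundle) can be supplied.
#'
#' @param traits_primary,traits_supplement trait tables (data.frames or
#'   CSV paths); supplement may be NULL.
#' @param trees named list of `phylo` objects or Newick file paths, one
#'   per clade.
#' @param divergences divergence-age data.frame or CSV path (see
#'   [read_divergence_table()]); NULL skips supertree stages.
#' @param clades clade labels to analyse.
#' @param nesting clade order for supertree stitching, outermost first;
#'   the default encodes the tetrapod backbone
#'   (Amphibia,(Mammalia,(Reptilia,Aves))).
#' @param subgroups optional named list of extra hypervolume groups
#'   (e.g. `list(Chiroptera = <species vector>)`).
#' @param adult_lifespan_mode,amphibian_mass_mode,allometry metric options
#'   (see [build_metric_table()]).
#' @param models trait-evolution models to fit to log body mass.
#' @param n_permutations permutations for the signal test; 0 skips
#'   p-values (lambda estimates only).
#' @param estimate_error estimate measurement error in the multivariate
#'   fit?
#' @param hv hypervolume options, an [hv_config()] (its seed is
#'   overridden by the run seed fan-out); NULL skips hypervolumes.
#' @param stages character vector of stages to run, a subset of
#'   `c("models", "signal", "pgls", "mvpgls", "asr", "anova", "hypervolume")`.
#' @param output_dir directory for result files; NULL keeps results in
#'   memory only.
#' @param seed master seed; per-stage seeds are derived by a fixed
#'   counter scheme so stages are individually reproducible.
#' @return a `run_config` list.
#' @export
run_config <- function(traits_primary, traits_supplement = NULL,
                       trees, divergences = NULL,
                       clades = c("Amphibia", "Reptilia", "Mammalia", "Aves"),
                       nesting = c("Amphibia", "Mammalia", "Reptilia", "Aves"),
                       subgroups = NULL,
                       adult_lifespan_mode = "longevity_minus_maturity",
                       amphibian_mass_mode = "max_mass",
                       allometry = NULL,
                       models = c("BM", "lambda", "kappa", "OU"),
                       n_permutations = 999,
                       estimate_error = FALSE,
                       hv = hv_config(),
                       stages = c("models", "signal", "pgls", "mvpgls",
                                  "asr", "anova", "hypervolume"),
                       output_dir = NULL,
                       seed = 1L) {
  structure(list(
    traits_primary = traits_primary, traits_supplement = traits_supplement,
    trees = trees, divergences = divergences, clades = clades,
    nesting = nesting, subgroups = subgroups,
    adult_lifespan_mode = adult_lifespan_mode,
    amphibian_mass_mode = amphibian_mass_mode, allometry = allometry,
    models = models, n_permutations = n_permutations,
    estimate_error = estimate_error, hv = hv, stages = stages,
    output_dir = output_dir, seed = as.integer(seed)
  ), class = "run_config")
}

.load_traits <- function(x) {
  if (is.character(x)) read_trait_table(x) else .check_trait_table(x)
}

.load_tree <- function(x) {
  if (is.character(x)) read_newick(x) else x
}

.stage_log <- function(log, stage, t0, ...) {
  log[[stage]] <- c(list(seconds = round(as.numeric(Sys.time()) - t0, 3)),
                    list(...))
  log
}

#' Run the full comparative life-history pipeline
#'
#' Executes, per clade: metric computation with completeness counts,
#' model selection for log body-mass evolution (AIC over BM / lambda /
#' kappa / OU), Pagel's-lambda signal tests for mass and the three
#' metrics, PGLS of each log metric on log mass under the best mass
#' model, and multivariate PGLS yielding evolutionary correlations. Then,
#' across clades: supertree stitching and Brownian ancestral states per
#' metric, one-way ANOVA with Tukey HSD per metric, and the per-clade
#' hypervolume / Sorensen overlap report. Any stage failure aborts with
#' the stage name; results computed so far are returned with an
#' `incomplete` marker. All randomness derives from the run seed.
#'
#' @param config a [run_config()].
#' @return a result bundle (list) with one element per stage plus
#'   `manifest` (config hash, seeds, counts, per-stage wall time).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  res <- list()
  log <- list()
  stage <- "ingest"
  out <- tryCatch({
    t0 <- as.numeric(Sys.time())
    primary <- .load_traits(config$traits_primary)
    merged <- if (!is.null(config$traits_supplement)) {
      merge_trait_sources(primary, .load_traits(config$traits_supplement))
    } else primary
    trees <- lapply(config$trees, .load_tree)
    log <- .stage_log(log, stage, t0, n_primary = nrow(primary),
                      n_merged = nrow(merged))

    stage <- "metrics"
    t0 <- as.numeric(Sys.time())
    mt <- build_metric_table(merged,
                             adult_lifespan_mode = config$adult_lifespan_mode,
                             amphibian_mass_mode = config$amphibian_mass_mode,
                             allometry = config$allometry)
    metrics <- mt$metrics[mt$metrics$clade %in% config$clades, , drop = FALSE]
    res$metrics <- metrics
    res$completeness <- mt$report
    counts <- table(factor(metrics$clade, levels = config$clades))
    log <- .stage_log(log, stage, t0, species_per_clade = as.list(counts))

    per_clade_data <- list()
    for (cl in config$clades) {
      if (!cl %in% names(trees)) next
      sub <- metrics[metrics$clade == cl, , drop = FALSE]
      if (nrow(sub) < 4L) next
      per_clade_data[[cl]] <- species_tree_intersect(sub, trees[[cl]])
    }

    if ("models" %in% config$stages) {
      stage <- "models"
      t0 <- as.numeric(Sys.time())
      sel_tab <- list()
      best_fit <- list()
      for (cl in names(per_clade_data)) {
        pc <- per_clade_data[[cl]]
        x <- setNames(pc$table$log_mass, pc$table$species)
        fits <- lapply(config$models, function(mod) fit_model(pc$tree, x, mod))
        best <- select_model(fits)
        best_fit[[cl]] <- best
        sel_tab[[cl]] <- data.frame(
          clade = cl,
          model = vapply(fits, `[[`, character(1), "model"),
          logLik = vapply(fits, `[[`, numeric(1), "logLik"),
          AIC = vapply(fits, `[[`, numeric(1), "AIC"),
          param = vapply(fits, `[[`, numeric(1), "param"),
          selected = vapply(fits, function(f) f$model == best$model, logical(1)),
          stringsAsFactors = FALSE
        )
      }
      res$mass_model_selection <- do.call(rbind, sel_tab)
      res$mass_model_best <- best_fit
      log <- .stage_log(log, stage, t0)
    }

    if ("signal" %in% config$stages) {
      stage <- "signal"
      t0 <- as.numeric(Sys.time())
      traits <- c(mass = "log_mass", lre = "log_lre", rrl = "log_rrl",
                  ros = "log_ros")
      rows <- list()
      i <- 0L
      for (cl in names(per_clade_data)) {
        pc <- per_clade_data[[cl]]
        for (tn in names(traits)) {
          i <- i + 1L
          x <- setNames(pc$table[[traits[[tn]]]], pc$table$species)
          if (config$n_permutations > 0) {
            sig <- phylo_signal_lambda(pc$tree, x, config$n_permutations,
                                       seed = .stage_seed(config$seed, 10L, i))
            rows[[i]] <- data.frame(clade = cl, trait = tn,
                                    lambda = sig$lambda, p = sig$p_value,
                                    stringsAsFactors = FALSE)
          } else {
            f <- fit_model(pc$tree, x, "lambda")
            rows[[i]] <- data.frame(clade = cl, trait = tn,
                                    lambda = f$param, p = NA_real_,
                                    stringsAsFactors = FALSE)
          }
        }
      }
      res$signal <- do.call(rbind, rows)
      log <- .stage_log(log, stage, t0)
    }

    if ("pgls" %in% config$stages) {
      stage <- "pgls"
      t0 <- as.numeric(Sys.time())
      rows <- list()
      for (cl in names(per_clade_data)) {
        pc <- per_clade_data[[cl]]
        xmass <- setNames(pc$table$log_mass, pc$table$species)
        trans <- if (!is.null(res$mass_model_best[[cl]])) {
          res$mass_model_best[[cl]]
        } else "BM"
        for (met in c("lre", "rrl", "ros")) {
          y <- setNames(pc$table[[paste0("log_", met)]], pc$table$species)
          fit <- pgls(pc$tree, y, xmass, trans)
          sl <- fit$coefficients[fit$coefficients$term == "slope", ]
          rows[[paste(cl, met)]] <- data.frame(
            clade = cl, metric = met, slope = sl$estimate, se = sl$se,
            t = sl$t, p = sl$p, transform = fit$transform, n = fit$n,
            stringsAsFactors = FALSE
          )
        }
      }
      res$pgls <- do.call(rbind, rows)
      rownames(res$pgls) <- NULL
      log <- .stage_log(log, stage, t0)
    }

    if ("mvpgls" %in% config$stages) {
      stage <- "mvpgls"
      t0 <- as.numeric(Sys.time())
      fits <- list()
      rows <- list()
      for (cl in names(per_clade_data)) {
        pc <- per_clade_data[[cl]]
        Y <- as.matrix(pc$table[, c("log_lre", "log_rrl", "log_ros")])
        colnames(Y) <- c("lre", "rrl", "ros")
        rownames(Y) <- pc$table$species
        xmass <- setNames(pc$table$log_mass, pc$table$species)
        fit <- mv_pgls(pc$tree, Y, xmass,
                       estimate_error = config$estimate_error)
        fits[[cl]] <- fit
        cc <- fit$correlations
        rows[[cl]] <- data.frame(
          clade = cl,
          lre_rrl = cc["lre", "rrl"], lre_ros = cc["lre", "ros"],
          rrl_ros = cc["rrl", "ros"], lambda = fit$lambda,
          stringsAsFactors = FALSE
        )
      }
      res$mvpgls <- fits
      res$evolutionary_correlations <- do.call(rbind, rows)
      rownames(res$evolutionary_correlations) <- NULL
      log <- .stage_log(log, stage, t0)
    }

    if ("asr" %in% config$stages && !is.null(config$divergences) &&
        length(per_clade_data) >= 2L) {
      stage <- "asr"
      t0 <- as.numeric(Sys.time())
      div <- if (is.character(config$divergences)) {
        read_divergence_table(config$divergences)
      } else config$divergences
      ord <- intersect(config$nesting, names(per_clade_data))
      clade_trees <- lapply(per_clade_data[ord], `[[`, "tree")
      supertree <- stitch_trees(clade_trees, div)
      res$supertree <- supertree
      asr <- list()
      for (met in c("log_mass", "log_lre", "log_rrl", "log_ros")) {
        x <- setNames(metrics[[met]], metrics$species)[supertree$tip.label]
        asr[[met]] <- asr_bm(supertree, x)
      }
      res$asr <- asr
      log <- .stage_log(log, stage, t0, n_supertree_tips = ape::Ntip(supertree))
    }

    if ("anova" %in% config$stages) {
      stage <- "anova"
      t0 <- as.numeric(Sys.time())
      res$anova <- lapply(
        c(lre = "log_lre", rrl = "log_rrl", ros = "log_ros"),
        function(col) class_anova(metrics[[col]], metrics$clade)
      )
      log <- .stage_log(log, stage, t0)
    }

    if ("hypervolume" %in% config$stages && !is.null(config$hv)) {
      stage <- "hypervolume"
      t0 <- as.numeric(Sys.time())
      hv_cfg <- config$hv
      hv_cfg$seed <- .stage_seed(config$seed, 20L)
      groups <- split(seq_len(nrow(metrics)), metrics$clade)
      if (!is.null(config$subgroups)) {
        for (g in names(config$subgroups)) {
          groups[[g]] <- which(metrics$species %in% config$subgroups[[g]])
        }
      }
      res$hypervolumes <- clade_hypervolume_report(metrics, hv_cfg,
                                                   groups = groups)
      log <- .stage_log(log, stage, t0)
    }

    res$manifest <- list(
      seed = config$seed,
      clades = config$clades,
      stages_run = intersect(config$stages, names(log)),
      species_per_clade = log$metrics$species_per_clade,
      stage_log = log,
      config_hash = .config_hash(config),
      r_version = as.character(getRversion()),
      incomplete = FALSE
    )
    res
  }, error = function(e) {
    res$manifest <- list(incomplete = TRUE, failed_stage = stage,
                         error = conditionMessage(e), stage_log = log)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(config$output_dir)) .write_pipeline_outputs(out, config)
  out
}

.config_hash <- function(config) {
  ser <- config
  ser$traits_primary <- ser$traits_supplement <- ser$trees <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(ser, auto_unbox = TRUE, digits = 10,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

.write_pipeline_outputs <- function(res, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$output_dir, f)
  write.csv(res$metrics, p("metrics.csv"), row.names = FALSE)
  jsonlite::write_json(res$completeness, p("completeness.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(res$mass_model_selection)) {
    write.csv(res$mass_model_selection, p("mass_model_selection.csv"),
              row.names = FALSE)
  }
  if (!is.null(res$signal)) write.csv(res$signal, p("signal.csv"), row.names = FALSE)
  if (!is.null(res$pgls)) write.csv(res$pgls, p("pgls.csv"), row.names = FALSE)
  if (!is.null(res$evolutionary_correlations)) {
    write.csv(res$evolutionary_correlations, p("evolutionary_correlations.csv"),
              row.names = FALSE)
  }
  if (!is.null(res$supertree)) write_newick_file(res$supertree, p("supertree.nwk"))
  if (!is.null(res$anova)) {
    jsonlite::write_json(
      lapply(res$anova, function(a) list(F = a$F, df_between = a$df_between,
                                         df_within = a$df_within,
                                         p = a$p_value, tukey = a$tukey)),
      p("anova.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(res$hypervolumes)) {
    write.csv(res$hypervolumes$volumes, p("hypervolume_volumes.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(res$hypervolumes$sorensen), p("sorensen.csv"))
    write.csv(as.data.frame(res$hypervolumes$unique_fraction),
              p("unique_fractions.csv"))
  }
  jsonlite::write_json(res$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  invisible(config$output_dir)
}
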