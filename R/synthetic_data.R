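# Seeded generators for trees, traits and raw trait-database fixtures with
# known ground truth, so every pipeline stage can be exercised and checked
# without any external downloads.

#' Simulate an ultrametric Yule (pure-birth) tree
#'
#' Starts from two crown lineages; while k lineages exist the waiting time
#' to the next speciation is Exp(k * birth_rate) and a uniformly chosen
#' lineage splits. After the n-th tip appears the tree grows for one final
#' Exp(n * birth_rate) stretch, so the expected crown height is
#' `sum_{k=2}^{n} 1 / (k * birth_rate)`. Deterministic given the seed.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate, per Myr.
#' @param seed integer seed.
#' @param tip_prefix prefix for tip labels (`t1 ... tn` by default).
#' @return an ultrametric `phylo` with exactly `n_tips` tips.
#' @export
simulate_yule <- function(n_tips, birth_rate = 1, seed = 1L, tip_prefix = "t") {
  if (n_tips < 2L) stop("n_tips must be >= 2")
  if (birth_rate <= 0) stop("birth_rate must be > 0")
  set.seed(seed)
  # lineage bookkeeping: birth time, children (0 = pendant), split time
  birth <- c(0, 0)
  child1 <- child2 <- c(NA_integer_, NA_integer_)
  split_t <- c(NA_real_, NA_real_)
  active <- c(1L, 2L)
  t <- 0
  k <- 2L
  while (k < n_tips) {
    t <- t + rexp(1L, k * birth_rate)
    who <- active[sample.int(k, 1L)]
    id1 <- length(birth) + 1L
    id2 <- length(birth) + 2L
    birth <- c(birth, t, t)
    child1 <- c(child1, NA_integer_, NA_integer_)
    child2 <- c(child2, NA_integer_, NA_integer_)
    split_t <- c(split_t, NA_real_, NA_real_)
    child1[who] <- id1
    child2[who] <- id2
    split_t[who] <- t
    active <- c(setdiff(active, who), id1, id2)
    k <- k + 1L
  }
  T_end <- t + rexp(1L, n_tips * birth_rate)

  tip_counter <- 0L
  nwk <- function(id) {
    if (is.na(child1[id])) {
      tip_counter <<- tip_counter + 1L
      sprintf("%s%d:%.12f", tip_prefix, tip_counter, T_end - birth[id])
    } else {
      sprintf("(%s,%s):%.12f", nwk(child1[id]), nwk(child2[id]),
              split_t[id] - birth[id])
    }
  }
  parse_newick(paste0("(", nwk(1L), ",", nwk(2L), ");"))
}

#' Rescale a tree to a target crown age
#'
#' @param tree a `phylo`.
#' @param crown_age target root-to-tip height, Myr.
#' @return rescaled tree.
#' @export
rescale_tree_height <- function(tree, crown_age) {
  h <- .tree_height(tree)
  tree$edge.length <- tree$edge.length * (crown_age / h)
  tree
}

# Symmetric PSD square root via eigendecomposition (tolerates rank
# deficiency, unlike chol).
.psd_sqrt <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

#' Simulate correlated traits under multivariate Brownian motion
#'
#' Tip values are drawn from the matrix normal with row covariance the
#' lambda-transformed tree covariance and column covariance `R`: each
#' trait evolves as Brownian motion at its own rate, with instantaneous
#' cross-trait correlations given by `R`'s off-diagonals.
#'
#' @param tree a `phylo`.
#' @param R trait covariance matrix (m x m, PSD; rates per Myr).
#' @param roots root state per trait (recycled).
#' @param lambda Pagel's lambda applied to the tree covariance.
#' @param seed integer seed.
#' @return n x m matrix of tip values, rows named by tip label.
#' @export
simulate_mvbm <- function(tree, R, roots = 0, lambda = 1, seed = 1L) {
  R <- as.matrix(R)
  m <- ncol(R)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1)) stop("R must be positive semi-definite")
  roots <- rep_len(roots, m)
  C <- transform_lambda(vcv_matrix(tree), lambda)
  n <- nrow(C)
  set.seed(seed)
  Z <- matrix(rnorm(n * m), n, m)
  X <- .psd_sqrt(C) %*% Z %*% .psd_sqrt(R)
  X <- sweep(X, 2L, roots, `+`)
  dimnames(X) <- list(rownames(C), colnames(R))
  X
}

#' Configuration for the synthetic trait-database generator
#'
#' Defaults emulate the compiled tetrapod study system: four clades at the
#' published per-clade species counts, crown ages in the range of the
#' dated timetrees, a high-signal model of log body-mass evolution per
#' clade (OU for the ectotherm clades, Pagel's lambda for the endotherms),
#' metric-on-mass regression slopes at the reported magnitudes (e.g. ROS
#' on mass about -0.4 in squamates), and an evolutionary correlation
#' structure among metric residuals with a strong LRE-RRL correlation
#' (0.6), moderate LRE-ROS (0.5) and null RRL-ROS.
#'
#' @param n_tips named integer vector: species per clade.
#' @param crown_ages named numeric vector: crown age per clade, Myr.
#' @param birth_rate Yule speciation rate used before rescaling.
#' @param mass_model named list per clade: `model` ("BM", "OU", "lambda"),
#'   `sigma2`, `z0`, and `param` (alpha or lambda).
#' @param slopes named numeric: regression slope of each log metric
#'   (lre, rrl, ros) on log mass.
#' @param intercepts named numeric: intercept of each log metric.
#' @param R_metrics 3 x 3 evolutionary covariance of metric residuals
#'   (per Myr; order lre, rrl, ros).
#' @param lambda_metrics shared Pagel's lambda of the metric residuals.
#' @param maturity_meanlog,maturity_sdlog lognormal parameters for the
#'   age at female maturity used by the inverse construction, years.
#' @param missingness named numeric: per-field masking probability.
#' @param supplement_fill probability that a value masked from the primary
#'   table appears in the supplement.
#' @param supplement_only_rate fraction of species present only in the
#'   supplement table.
#' @param seed integer master seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(
    n_tips = c(Amphibia = 113, Reptilia = 491, Mammalia = 842, Aves = 171),
    crown_ages = c(Amphibia = 310, Reptilia = 190, Mammalia = 170, Aves = 110),
    birth_rate = 1,
    mass_model = list(
      Amphibia = list(model = "OU", sigma2 = 0.05, z0 = 3.5, param = 0.01),
      Reptilia = list(model = "OU", sigma2 = 0.08, z0 = 4.0, param = 0.01),
      Mammalia = list(model = "lambda", sigma2 = 0.05, z0 = 6.0, param = 0.99),
      Aves = list(model = "lambda", sigma2 = 0.04, z0 = 4.5, param = 0.99)
    ),
    slopes = c(lre = -0.17, rrl = 0.01, ros = -0.38),
    intercepts = c(lre = 1.0, rrl = 1.2, ros = -2.5),
    R_metrics = NULL,
    lambda_metrics = 0.9,
    maturity_meanlog = log(2), maturity_sdlog = 0.5,
    missingness = c(adult_body_mass = 0, litter_size = 0.1,
                    litters_per_year = 0.1, mass_at_independence = 0.1,
                    max_longevity = 0.1, female_maturity_age = 0.1),
    supplement_fill = 0.5,
    supplement_only_rate = 0.05,
    seed = 1L) {
  if (is.null(R_metrics)) {
    # correlations calibrated to the reported evolutionary correlations
    corr <- matrix(c(1, 0.6, 0.5,
                     0.6, 1, 0.0,
                     0.5, 0.0, 1), 3, 3)
    rates <- c(lre = 0.02, rrl = 0.01, ros = 0.015)
    R_metrics <- corr * tcrossprod(sqrt(rates))
    dimnames(R_metrics) <- list(names(rates), names(rates))
  }
  ev <- eigen(R_metrics, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stop("R_metrics must be positive semi-definite")
  dimnames(R_metrics) <- list(c("lre", "rrl", "ros"), c("lre", "rrl", "ros"))
  if (any(missingness < 0 | missingness > 1)) stop("missingness rates in [0, 1]")
  structure(list(
    n_tips = n_tips, crown_ages = crown_ages, birth_rate = birth_rate,
    mass_model = mass_model, slopes = slopes, intercepts = intercepts,
    R_metrics = R_metrics, lambda_metrics = lambda_metrics,
    maturity_meanlog = maturity_meanlog, maturity_sdlog = maturity_sdlog,
    missingness = missingness, supplement_fill = supplement_fill,
    supplement_only_rate = supplement_only_rate, seed = as.integer(seed)
  ), class = "sim_config")
}

# Per-stage seed fan-out: deterministic, collision-free offsets from the
# master seed, kept within 32-bit integer range.
.stage_seed <- function(seed, stage, i = 0L) {
  s <- (as.numeric(seed) * 101 + stage * 1009 + i * 13) %% 2147483647
  as.integer(s)
}

#' Generate a synthetic trait database with known ground truth
#'
#' For each clade: simulates a Yule tree rescaled to the clade crown age,
#' simulates natural-log body mass under the configured model, simulates
#' metric residuals under correlated Brownian motion with shared lambda,
#' forms `log metric = intercept + slope * log mass + residual`, and then
#' inverts the metric formulas back to raw life-history fields. The
#' inverse construction fixes litters_per_year = 1 and draws the age at
#' female maturity from a lognormal, after which longevity, litter size
#' and mass at independence are determined exactly:
#' `longevity = maturity * (1 + RRL)`, `mass_indep = ROS * mass`,
#' `litter = LRE / (ROS * lifespan)`. Raw fields are split into a primary
#' and a supplement table with configured missingness, emulating the
#' multi-source compilation the real analysis starts from.
#'
#' @param config a [sim_config()].
#' @param output_dir optional directory; when given, writes per-clade
#'   Newick trees, primary/supplement CSVs, ground-truth CSV and a
#'   ground_truth.json.
#' @return list: `trees` (named list of `phylo`), `primary`, `supplement`
#'   (trait data.frames), `ground_truth` (metric data.frame with the
#'   generating values), `config`.
#' @export
generate_trait_database <- function(config = sim_config(), output_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  clades <- names(config$n_tips)
  trees <- list()
  truth <- list()
  raw <- list()
  for (ci in seq_along(clades)) {
    cl <- clades[ci]
    n <- config$n_tips[[cl]]
    sd_tree <- .stage_seed(config$seed, 1L, ci)
    tree <- simulate_yule(n, config$birth_rate, seed = sd_tree,
                          tip_prefix = paste0(substr(cl, 1, 3), "_sp"))
    tree <- rescale_tree_height(tree, config$crown_ages[[cl]])
    trees[[cl]] <- tree

    mm <- config$mass_model[[cl]]
    Cm <- model_vcv(tree, mm$model,
                    if (mm$model == "BM") NULL else mm$param)
    set.seed(.stage_seed(config$seed, 2L, ci))
    z <- drop(.psd_sqrt(mm$sigma2 * Cm) %*% rnorm(n))
    log_mass <- mm$z0 + z
    names(log_mass) <- rownames(Cm)

    E <- simulate_mvbm(tree, config$R_metrics, roots = 0,
                       lambda = config$lambda_metrics,
                       seed = .stage_seed(config$seed, 3L, ci))
    log_met <- sapply(c("lre", "rrl", "ros"), function(k) {
      config$intercepts[[k]] + config$slopes[[k]] * log_mass + E[, k]
    })
    rownames(log_met) <- names(log_mass)

    mass <- exp(log_mass)
    lre <- exp(log_met[, "lre"])
    rrl <- exp(log_met[, "rrl"])
    ros <- exp(log_met[, "ros"])

    set.seed(.stage_seed(config$seed, 4L, ci))
    maturity <- exp(rnorm(n, config$maturity_meanlog, config$maturity_sdlog))
    lifespan <- maturity * rrl
    longevity <- maturity + lifespan
    mass_indep <- ros * mass
    litter <- lre / (ros * lifespan)
    if (any(!is.finite(litter)) || any(litter <= 0)) {
      stop("configuration implies impossible records (non-positive litter size)")
    }

    truth[[cl]] <- data.frame(
      species = names(log_mass), clade = cl,
      mass_g = mass, lre = lre, rrl = rrl, ros = ros,
      log_mass = log_mass, log_lre = log_met[, "lre"],
      log_rrl = log_met[, "rrl"], log_ros = log_met[, "ros"],
      stringsAsFactors = FALSE, row.names = NULL
    )
    raw[[cl]] <- data.frame(
      species = names(log_mass), clade = cl,
      adult_body_mass = mass, litter_size = litter,
      litters_per_year = rep(1, n), mass_at_independence = mass_indep,
      max_longevity = longevity, female_maturity_age = maturity,
      svl_min = NA_real_, svl_max = NA_real_,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  truth <- do.call(rbind, truth)
  raw <- do.call(rbind, raw)
  rownames(truth) <- rownames(raw) <- NULL

  # split into primary + supplement with configured missingness
  set.seed(.stage_seed(config$seed, 5L))
  ns <- nrow(raw)
  sup_only <- runif(ns) < config$supplement_only_rate
  primary <- raw[!sup_only, , drop = FALSE]
  supplement <- raw[sup_only, , drop = FALSE]
  fields <- names(config$missingness)
  for (f in fields) {
    rate <- config$missingness[[f]]
    if (rate <= 0) next
    mask <- runif(nrow(primary)) < rate
    recover <- mask & (runif(nrow(primary)) < config$supplement_fill)
    if (any(recover)) {
      add <- primary[recover, , drop = FALSE]
      for (g in setdiff(fields, f)) add[[g]] <- NA_real_
      supplement <- rbind(supplement, add)
    }
    primary[[f]][mask] <- NA_real_
  }
  # collapse duplicate supplement rows per species (union of fields)
  if (nrow(supplement) > 0L) {
    supplement <- do.call(rbind, lapply(split(supplement, supplement$species), function(g) {
      out <- g[1L, , drop = FALSE]
      for (f in fields) {
        v <- g[[f]][!is.na(g[[f]])]
        out[[f]] <- if (length(v)) v[1L] else NA_real_
      }
      out
    }))
    rownames(supplement) <- NULL
  }

  bundle <- list(trees = trees, primary = primary, supplement = supplement,
                 ground_truth = truth, config = config)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    for (cl in names(trees)) {
      write_newick_file(trees[[cl]], file.path(output_dir, paste0(cl, ".nwk")))
    }
    write.csv(primary, file.path(output_dir, "traits_primary.csv"), row.names = FALSE)
    write.csv(supplement, file.path(output_dir, "traits_supplement.csv"),
              row.names = FALSE)
    write.csv(truth, file.path(output_dir, "ground_truth.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(seed = config$seed, n_tips = as.list(config$n_tips),
           slopes = as.list(config$slopes),
           lambda_metrics = config$lambda_metrics,
           correlations = stats::cov2cor(config$R_metrics)),
      file.path(output_dir, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  bundle
}
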