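# Pruning-based Gaussian likelihood machinery for trait evolution models.
#
# The engine computes, in one post-order pass over the edges, the four
# quadratic forms needed for GLS under a tree-structured covariance C:
# log|C|, 1'C^-1 1, 1'C^-1 x and x'C^-1 x. This avoids ever forming or
# inverting C (O(n) per evaluation) and handles polytomies and zero-length
# internal branches. Shape-parameter transforms (lambda, kappa, OU) are
# expressed as edge-length substitutions on the same topology, so a single
# engine serves all four models.

# Precompute the topology-dependent quantities reused across likelihood
# evaluations: post-order edge list, tip depths, node heights.
.tree_data <- function(tree, x = NULL) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n <- ape::Ntip(tree)
  depths <- .node_depths(tree)        # root-to-node path lengths
  list(
    tree = tree,
    n = n,
    n_node = n + tree$Nnode,
    edge = tree$edge,
    len = tree$edge.length,
    depths = depths,
    height = max(depths[seq_len(n)]),
    ultrametric = (max(depths[seq_len(n)]) - min(depths[seq_len(n)])) <=
      1e-6 * max(depths[seq_len(n)]),
    x = if (!is.null(x)) x[tree$tip.label] else NULL
  )
}

# Edge lengths realizing the model covariance on the fixed topology.
# lambda: scale all edges by lambda, extend terminal edges so tip depths
#   (the diagonal of C) are unchanged.
# kappa: raise each edge to kappa, 0^0 := 0.
# OU (ultrametric): remap node heights h -> g(h) with
#   g(h) = (exp(-2a(T-h)) - exp(-2aT)) / (2a), monotone increasing, which
#   realizes C_ij = g(s_ij) on the same topology.
.model_edge_lengths <- function(td, model, param) {
  switch(model,
    BM = td$len,
    lambda = {
      el <- param * td$len
      tip_edge <- td$edge[, 2] <= td$n
      el[tip_edge] <- el[tip_edge] + (1 - param) * td$depths[td$edge[tip_edge, 2]]
      el
    },
    kappa = {
      el <- td$len^param
      el[td$len == 0] <- 0
      el
    },
    OU = {
      if (!td$ultrametric) stop("OU model requires an ultrametric tree")
      if (param == 0) return(td$len)
      a2 <- 2 * param
      g <- exp(-a2 * (td$height - td$depths)) * (-expm1(-a2 * td$depths)) / a2
      g[td$edge[, 2]] - g[td$edge[, 1]]
    },
    stop("unknown model: ", model)
  )
}

# One post-order pass: returns log|C|, p = 1'C^-1 1, u = 1'C^-1 x,
# s = x'C^-1 x for covariance C implied by edge lengths `len`.
.threepoint <- function(td, len, x) {
  n <- td$n
  edge <- td$edge
  p <- u <- s <- ld <- numeric(td$n_node)
  for (k in seq_len(nrow(edge))) {
    par <- edge[k, 1]
    ch <- edge[k, 2]
    t <- len[k]
    if (ch <= n) {
      if (t <= 0) stop("zero-length terminal branch: likelihood undefined for tip '",
                       td$tree$tip.label[ch], "'")
      p[par] <- p[par] + 1 / t
      u[par] <- u[par] + x[ch] / t
      s[par] <- s[par] + x[ch]^2 / t
      ld[par] <- ld[par] + log(t)
    } else {
      denom <- 1 + t * p[ch]
      p[par] <- p[par] + p[ch] / denom
      u[par] <- u[par] + u[ch] / denom
      s[par] <- s[par] + s[ch] - t * u[ch]^2 / denom
      ld[par] <- ld[par] + ld[ch] + log(denom)
    }
  }
  root <- edge[nrow(edge), 1]
  list(logdet = ld[root], p = p[root], u = u[root], s = s[root])
}

# Log-likelihood at given (sigma2, z0) from three-point quantities.
.ll_at <- function(tp, n, sigma2, z0) {
  -(n / 2) * log(2 * pi * sigma2) - tp$logdet / 2 -
    (tp$s - 2 * z0 * tp$u + z0^2 * tp$p) / (2 * sigma2)
}

# Profile out z0 (GLS mean) and sigma2 (mean squared GLS residual).
.ll_profiled <- function(tp, n) {
  z0 <- tp$u / tp$p
  rss <- tp$s - tp$u^2 / tp$p
  sigma2 <- max(rss / n, .Machine$double.xmin)
  list(
    logLik = -(n / 2) * (log(2 * pi * sigma2) + 1) - tp$logdet / 2,
    z0 = z0, sigma2 = sigma2
  )
}

.check_tip_match <- function(tree, x) {
  if (is.null(names(x))) stop("trait vector must be named by species")
  miss <- setdiff(tree$tip.label, names(x))
  extra <- setdiff(names(x), tree$tip.label)
  if (length(miss) > 0L || length(extra) > 0L) {
    stop("tip/trait name mismatch; missing from traits: ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(extra)) paste0("; extra traits: ",
                                   paste(utils::head(extra, 5), collapse = ", ")))
  }
}

#' Brownian-motion log-likelihood of a trait vector on a tree
#'
#' Log density of tip values under multivariate normal with mean `z0` and
#' covariance `sigma2 * C(tree)`, evaluated by a linear-time pruning pass
#' (never forming C). Identical, to numerical precision, to the dense
#' multivariate-normal density.
#'
#' @param tree a `phylo`.
#' @param x named trait vector (names = tip labels).
#' @param sigma2 Brownian rate (> 0).
#' @param z0 root state.
#' @return log-likelihood (scalar).
#' @export
bm_loglik <- function(tree, x, sigma2, z0) {
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  .check_tip_match(tree, x)
  td <- .tree_data(tree, x)
  tp <- .threepoint(td, td$len, td$x)
  .ll_at(tp, td$n, sigma2, z0)
}

.shape_bounds <- function(model, height) {
  switch(model,
    lambda = c(0, 1),
    kappa = c(0, 3),
    OU = log(c(1e-8, 100) / height),   # bounds on log(alpha)
    NULL
  )
}

#' Fit an evolutionary model to a continuous trait by maximum likelihood
#'
#' Fits one of Brownian motion (BM), Ornstein-Uhlenbeck (OU), Pagel's
#' lambda or kappa. The root state and rate are profiled in closed form
#' (GLS mean; mean squared GLS residual) given the shape parameter, which
#' is optimized by bounded one-dimensional search (Brent, tolerance 1e-8)
#' over lambda in [0, 1], kappa in [0, 3], or log(alpha) in
#' [log(1e-8/T), log(100/T)] for a tree of height T. ML (not REML)
#' throughout, for AIC comparability.
#'
#' @param tree a `phylo` with >= 4 tips.
#' @param x named trait vector.
#' @param model one of "BM", "OU", "lambda", "kappa".
#' @return object of class `evo_model_fit`: model, sigma2, z0, shape
#'   parameter (`param`, NA for BM), logLik, n_params, AIC, and a
#'   `note` field flagging boundary/identifiability issues.
#' @export
fit_model <- function(tree, x, model = c("BM", "OU", "lambda", "kappa")) {
  model <- match.arg(model)
  .check_tip_match(tree, x)
  if (ape::Ntip(tree) < 4L) stop("need >= 4 tips to fit a trait model")
  if (any(!is.finite(x))) stop("trait values must be finite")
  td <- .tree_data(tree, x)

  obj <- function(par) {
    param <- if (model == "OU") exp(par) else par
    tp <- .threepoint(td, .model_edge_lengths(td, model, param), td$x)
    .ll_profiled(tp, td$n)$logLik
  }

  note <- NULL
  if (model == "BM") {
    param <- NA_real_
    tp <- .threepoint(td, td$len, td$x)
    prof <- .ll_profiled(tp, td$n)
    n_params <- 2L
  } else {
    b <- .shape_bounds(model, td$height)
    opt <- optimize(obj, interval = b, maximum = TRUE, tol = 1e-8)
    # compare against the bounds themselves: Brent can miss boundary optima
    cand_par <- c(opt$maximum, b)
    cand_ll <- c(opt$objective, obj(b[1]), obj(b[2]))
    best <- which.max(cand_ll)
    par <- cand_par[best]
    if (!is.finite(cand_ll[best])) {
      stop("optimizer failed for model ", model,
           "; best log-likelihood non-finite")
    }
    param <- if (model == "OU") exp(par) else par
    tp <- .threepoint(td, .model_edge_lengths(td, model, param), td$x)
    prof <- .ll_profiled(tp, td$n)
    n_params <- 3L
    if (model == "kappa" && all(abs(td$len[td$len > 0] - 1) < 1e-12)) {
      note <- "kappa unidentifiable: all branch lengths equal 1"
    }
  }

  structure(list(
    model = model,
    sigma2 = prof$sigma2,
    z0 = prof$z0,
    param = param,
    logLik = prof$logLik,
    n_params = n_params,
    AIC = 2 * n_params - 2 * prof$logLik,
    n = td$n,
    note = note,
    data_hash = .data_hash(tree, x)
  ), class = "evo_model_fit")
}

.data_hash <- function(tree, x) {
  x <- x[sort(names(x))]
  paste0(ape::Ntip(tree), ":", signif(sum(tree$edge.length), 12), ":",
         signif(sum(x), 12), ":", signif(sum(x^2), 12))
}

#' @export
print.evo_model_fit <- function(x, ...) {
  cat("Trait-evolution model fit (", x$model, ")\n", sep = "")
  cat("  n tips  :", x$n, "\n")
  cat("  sigma2  :", signif(x$sigma2, 6), "\n")
  cat("  root z0 :", signif(x$z0, 6), "\n")
  if (!is.na(x$param)) {
    lab <- switch(x$model, OU = "alpha", lambda = "lambda", kappa = "kappa", "param")
    cat("  ", lab, "  :", signif(x$param, 6), "\n")
  }
  cat("  logLik  :", signif(x$logLik, 8), "  AIC:", signif(x$AIC, 8), "\n")
  if (!is.null(x$note)) cat("  note    :", x$note, "\n")
  invisible(x)
}

#' Select the best-fitting evolutionary model by AIC
#'
#' Returns the fit with the lowest AIC. Exact ties are broken toward the
#' fit with fewer parameters, then by the fixed order BM < lambda <
#' kappa < OU, so the result is invariant to the ordering of the input
#' list.
#'
#' @param fits list of `evo_model_fit` objects on identical data.
#' @return the selected `evo_model_fit`.
#' @export
select_model <- function(fits) {
  if (length(fits) < 2L) stop("need at least two fits to select among")
  stopifnot(all(vapply(fits, inherits, logical(1), "evo_model_fit")))
  hashes <- vapply(fits, function(f) f$data_hash, character(1))
  if (length(unique(hashes)) > 1L) {
    stop("fits were made on different data; cannot compare AIC")
  }
  order_rank <- c(BM = 1L, lambda = 2L, kappa = 3L, OU = 4L)
  aic <- vapply(fits, function(f) f$AIC, numeric(1))
  npar <- vapply(fits, function(f) f$n_params, integer(1))
  rank <- order_rank[vapply(fits, function(f) f$model, character(1))]
  best <- order(round(aic, 10), npar, rank)[1L]
  fits[[best]]
}

#' Permutation test of phylogenetic signal via Pagel's lambda
#'
#' Estimates lambda by ML and tests it against lambda = 0 (star phylogeny)
#' with a permutation test: tip values are shuffled across the fixed tree
#' `n_permutations` times and the likelihood-ratio statistic
#' `LR = 2 (logLik(lambda_hat) - logLik(lambda = 0))` recomputed for each;
#' `p = (1 + #{LR_perm >= LR_obs}) / (n_permutations + 1)`. The smallest
#' attainable p with 999 permutations is therefore 0.001.
#'
#' @param tree a `phylo`.
#' @param x named trait vector.
#' @param n_permutations number of permutations (>= 1).
#' @param seed integer seed for the permutation stream.
#' @return object of class `signal_result`: lambda, p_value,
#'   n_permutations, logLik at the ML lambda and at lambda = 0, LR, and a
#'   `degenerate` flag (TRUE, with NA estimates, for constant traits).
#' @export
phylo_signal_lambda <- function(tree, x, n_permutations = 999, seed = 1L) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  .check_tip_match(tree, x)
  if (var(x) == 0) {
    return(structure(list(lambda = NA_real_, p_value = NA_real_,
                          n_permutations = n_permutations,
                          logLik_hat = NA_real_, logLik_0 = NA_real_,
                          LR = NA_real_, degenerate = TRUE),
                     class = "signal_result"))
  }
  td <- .tree_data(tree, x)
  lr_stat <- function(xv) {
    obj <- function(lam) {
      tp <- .threepoint(td, .model_edge_lengths(td, "lambda", lam), xv)
      .ll_profiled(tp, td$n)$logLik
    }
    opt <- optimize(obj, interval = c(0, 1), maximum = TRUE, tol = 1e-8)
    ll1 <- max(opt$objective, obj(1))
    lam <- if (obj(1) > opt$objective) 1 else opt$maximum
    ll0 <- obj(0)
    list(lambda = lam, ll1 = ll1, ll0 = ll0, LR = 2 * (ll1 - ll0))
  }
  obs <- lr_stat(td$x)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_permutations)) {
    xp <- sample(td$x)
    if (lr_stat(xp)$LR >= obs$LR - 1e-12) exceed <- exceed + 1L
  }
  structure(list(
    lambda = obs$lambda,
    p_value = (1 + exceed) / (n_permutations + 1),
    n_permutations = n_permutations,
    logLik_hat = obs$ll1, logLik_0 = obs$ll0, LR = obs$LR,
    degenerate = FALSE
  ), class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("Phylogenetic signal: degenerate (constant trait), lambda undefined\n")
  } else {
    cat("Pagel's lambda =", signif(x$lambda, 4),
        " (p =", format(x$p_value, digits = 3),
        "from", x$n_permutations, "permutations)\n")
  }
  invisible(x)
}
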