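#' Phylogenetic generalized least squares
#'
#' Regresses `y` on `x` with error covariance proportional to the tip
#' covariance of a fitted evolutionary model (typically the best-AIC model
#' of body-mass evolution): `beta = (X' V^-1 X)^-1 X' V^-1 y`, residual
#' variance `RSS_V / (n - 2)`, standard errors from the GLS information
#' matrix, two-sided t tests. The overall scale of V is profiled out, so
#' only its correlation structure matters. With a lambda = 0 transform on
#' an ultrametric tree, PGLS reduces exactly to OLS.
#'
#' @param tree a `phylo`.
#' @param y named response vector.
#' @param x named predictor vector.
#' @param transform either an `evo_model_fit` (its model and shape
#'   parameter define V), a model name ("BM" for the untransformed tree),
#'   or NULL for BM.
#' @return object of class `pgls_fit` with a coefficient table
#'   (estimate, SE, t, p), `sigma2_resid`, `transform`, `n`, `df`.
#' @export
pgls <- function(tree, y, x, transform = NULL) {
  .check_tip_match(tree, y)
  .check_tip_match(tree, x)
  tips <- tree$tip.label
  y <- y[tips]
  x <- x[tips]
  n <- length(tips)

  if (is.null(transform)) transform <- "BM"
  if (inherits(transform, "evo_model_fit")) {
    V <- model_vcv(tree, transform$model, transform$param)
    tname <- if (is.na(transform$param)) transform$model else {
      sprintf("%s(%.4g)", transform$model, transform$param)
    }
  } else if (is.character(transform) && transform == "BM") {
    V <- vcv_matrix(tree)
    tname <- "BM"
  } else {
    stop("transform must be NULL, \"BM\" or an evo_model_fit")
  }
  V <- V[tips, tips]

  X <- cbind(`(Intercept)` = 1, slope = x)
  L <- tryCatch(chol(V), error = function(e) {
    stop("model covariance is not positive definite: ", conditionMessage(e))
  })
  Xs <- backsolve(L, X, transpose = TRUE)
  ys <- backsolve(L, y, transpose = TRUE)
  XtX <- crossprod(Xs)
  if (rcond(XtX) < 1e-12) stop("singular design matrix in PGLS")
  XtXi <- solve(XtX)
  beta <- drop(XtXi %*% crossprod(Xs, ys))
  resid_s <- ys - Xs %*% beta
  rss <- sum(resid_s^2)
  df <- n - 2L
  sigma2 <- rss / df
  se <- sqrt(diag(XtXi) * sigma2)
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df)

  structure(list(
    coefficients = data.frame(
      term = c("(Intercept)", "slope"),
      estimate = unname(beta), se = unname(se),
      t = unname(tval), p = unname(pval),
      stringsAsFactors = FALSE
    ),
    sigma2_resid = sigma2,
    transform = tname,
    n = n, df = df
  ), class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS fit (correlation: ", x$transform, ", n = ", x$n, ")\n", sep = "")
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Ancestral state reconstruction under Brownian motion
#'
#' For each internal node, the generalized-least-squares (ML) ancestral
#' estimate: the conditional expectation of the node state given the tip
#' values, with the root state set to the GLS phylogenetic mean. On a star
#' tree the root estimate equals the arithmetic mean of the tips.
#'
#' @param tree a `phylo`.
#' @param x named trait vector.
#' @return object of class `ancestral_states`: `node_estimates` (named by
#'   node number), `root`, and the tip states passed through.
#' @export
asr_bm <- function(tree, x) {
  .check_tip_match(tree, x)
  n <- ape::Ntip(tree)
  x <- x[tree$tip.label]
  depths <- .node_depths(tree)
  # covariance between any two nodes = depth of their MRCA
  M <- ape::mrca(tree, full = TRUE)
  Cfull <- matrix(depths[M], nrow(M), nrow(M))
  tipi <- seq_len(n)
  nodei <- (n + 1L):(n + tree$Nnode)
  Ct <- Cfull[tipi, tipi]
  Cnt <- Cfull[nodei, tipi, drop = FALSE]

  L <- chol(Ct)
  one_s <- backsolve(L, rep(1, n), transpose = TRUE)
  x_s <- backsolve(L, x, transpose = TRUE)
  z0 <- sum(one_s * x_s) / sum(one_s^2)
  w <- backsolve(L, backsolve(L, x - z0, transpose = TRUE))
  est <- drop(z0 + Cnt %*% w)
  names(est) <- as.character(nodei)

  structure(list(
    node_estimates = est,
    root = est[[1L]],
    tip_states = x
  ), class = "ancestral_states")
}

#' @export
print.ancestral_states <- function(x, ...) {
  cat("Brownian ancestral states for", length(x$node_estimates),
      "internal nodes; root =", signif(x$root, 6), "\n")
  invisible(x)
}

#' One-way ANOVA with Tukey HSD across clades
#'
#' Treats each clade as phylogenetically independent and compares a
#' (typically natural-log) metric across groups: overall F test plus
#' Tukey honest-significant-difference pairwise comparisons with
#' studentized-range adjustment.
#'
#' @param values numeric vector of metric values.
#' @param groups factor or character vector of group labels, same length.
#' @return object of class `clade_anova`: `F`, `df_between`, `df_within`,
#'   `p_value`, and `tukey` (data.frame of pairwise mean differences and
#'   adjusted p-values).
#' @export
class_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  sizes <- table(groups)
  if (any(sizes < 2L)) {
    stop("groups with < 2 observations: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  fit <- aov(values ~ groups)
  an <- summary(fit)[[1L]]
  tk <- TukeyHSD(fit)$groups
  structure(list(
    F = an[["F value"]][1L],
    df_between = an[["Df"]][1L],
    df_within = an[["Df"]][2L],
    p_value = an[["Pr(>F)"]][1L],
    tukey = data.frame(
      pair = rownames(tk),
      diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
      p_adj = tk[, "p adj"],
      row.names = NULL, stringsAsFactors = FALSE
    )
  ), class = "clade_anova")
}

#' @export
print.clade_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.4g on (%d, %d) df, p = %.3g\n",
              x$F, x$df_between, x$df_within, x$p_value))
  print(x$tukey, row.names = FALSE, digits = 4)
  invisible(x)
}
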