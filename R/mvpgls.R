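# Multivariate phylogenetic regression under a shared Pagel's lambda, with
# optional per-response measurement error estimated as a nuisance
# parameter. The model for responses Y (n tips x m traits) and design X:
#   cov(y_k, y_l) = R[k,l] * C_lambda + (k == l) * e_k * I
# i.e. an evolutionary covariance R scaled by the lambda-transformed tree
# covariance, plus independent error variance on each response's diagonal.
# Without error the likelihood is matrix-normal and B, R have closed
# forms given lambda; with error we rotate by the eigenvectors of
# C_lambda, which makes rows independent with covariance d_i * R + E and
# keeps each likelihood evaluation O(n m^3).

.mv_closed_form <- function(C, Y, X) {
  n <- nrow(Y); m <- ncol(Y)
  L <- chol(C)
  Xs <- backsolve(L, X, transpose = TRUE)
  Ys <- backsolve(L, Y, transpose = TRUE)
  XtXi <- solve(crossprod(Xs))
  B <- XtXi %*% crossprod(Xs, Ys)
  Rs <- Ys - Xs %*% B
  R <- crossprod(Rs) / n
  logdetC <- 2 * sum(log(diag(L)))
  ldR <- determinant(R, logarithm = TRUE)$modulus
  ll <- -(n * m / 2) * log(2 * pi) - (m / 2) * logdetC - (n / 2) * ldR - n * m / 2
  list(B = B, R = R, logLik = as.numeric(ll))
}

# Likelihood with measurement error, in the eigenbasis of C_lambda.
# d: eigenvalues, Ys/Xs: rotated data/design, R: evolutionary covariance,
# e: error variances. Profiles B by GLS across the independent rows.
.mv_error_loglik <- function(d, Ys, Xs, R, e) {
  n <- nrow(Ys); m <- ncol(Ys); p <- ncol(Xs)
  E <- diag(e, m)
  A <- matrix(0, m * p, m * p)
  b <- numeric(m * p)
  Winv <- vector("list", n)
  ok <- TRUE
  for (i in seq_len(n)) {
    Sig <- d[i] * R + E
    W <- tryCatch(chol2inv(chol(Sig)), error = function(err) NULL)
    if (is.null(W)) return(list(logLik = -Inf))
    Winv[[i]] <- W
    xo <- tcrossprod(Xs[i, ])
    for (k in seq_len(m)) {
      rk <- ((k - 1) * p + 1):(k * p)
      for (l in seq_len(m)) {
        rl <- ((l - 1) * p + 1):(l * p)
        A[rk, rl] <- A[rk, rl] + W[k, l] * xo
      }
      b[rk] <- b[rk] + Xs[i, ] * sum(W[k, ] * Ys[i, ])
    }
  }
  beta <- tryCatch(solve(A, b), error = function(err) NULL)
  if (is.null(beta)) return(list(logLik = -Inf))
  B <- matrix(beta, nrow = p, ncol = m)
  ll <- -(n * m / 2) * log(2 * pi)
  for (i in seq_len(n)) {
    Sig <- d[i] * R + E
    r <- Ys[i, ] - drop(Xs[i, ] %*% B)
    ld <- determinant(Sig, logarithm = TRUE)$modulus
    ll <- ll - ld / 2 - drop(r %*% Winv[[i]] %*% r) / 2
  }
  list(logLik = as.numeric(ll), B = B)
}

.chol_from_par <- function(theta, m) {
  L <- matrix(0, m, m)
  diag(L) <- exp(theta[seq_len(m)])
  if (m > 1) L[lower.tri(L)] <- theta[-seq_len(m)]
  L
}

.par_from_chol <- function(R) {
  L <- t(chol(R))
  c(log(diag(L)), L[lower.tri(L)])
}

#' Multivariate phylogenetic regression with evolutionary correlations
#'
#' Jointly fits the three log metrics (or any response matrix) on a
#' predictor under a shared Pagel's lambda: the tip covariance of response
#' k is `R[k,k] * C_lambda (+ e_k * I)` and the cross-response covariance
#' `R[k,l] * C_lambda`. Coefficients are estimated by GLS given the
#' covariance parameters; the evolutionary covariance R of the residuals
#' yields the evolutionary correlation matrix
#' `r[k,l] = R[k,l] / sqrt(R[k,k] R[l,l])`, i.e. the correlated-evolution
#' signal among responses after controlling for the predictor. With
#' `estimate_error = TRUE` a per-response independent error variance is
#' estimated as a nuisance parameter (recommended for empirical data);
#' with it off, lambda is profiled with B and R in closed form.
#'
#' @param tree a `phylo`.
#' @param Y numeric matrix, rows named by species, columns by response.
#' @param x named predictor vector (e.g. natural-log body mass).
#' @param estimate_error estimate per-response error variances?
#' @return object of class `mv_pgls_fit`: `B` (coefficients, predictors x
#'   responses), `R` (evolutionary covariance), `correlations`, `lambda`,
#'   `error_variances`, `logLik`, `n`.
#' @export
mv_pgls <- function(tree, Y, x, estimate_error = TRUE) {
  if (is.null(rownames(Y))) stop("Y must have species rownames")
  .check_tip_match(tree, x)
  .check_tip_match(tree, setNames(Y[, 1], rownames(Y)))
  tips <- tree$tip.label
  Y <- as.matrix(Y[tips, , drop = FALSE])
  if (any(!is.finite(Y))) stop("mv_pgls requires complete cases (finite Y)")
  x <- x[tips]
  n <- nrow(Y); m <- ncol(Y)
  if (n < m + 2L) stop("too few species for ", m, " responses")
  X <- cbind(1, x)
  C <- vcv_matrix(tree)[tips, tips]

  prof <- function(lam) .mv_closed_form(transform_lambda(C, lam), Y, X)
  opt <- optimize(function(l) prof(l)$logLik, c(0, 1), maximum = TRUE, tol = 1e-8)
  lam0 <- opt$maximum
  if (prof(1)$logLik > opt$objective) lam0 <- 1
  if (prof(0)$logLik > max(opt$objective, prof(1)$logLik)) lam0 <- 0
  fit0 <- prof(lam0)

  if (!estimate_error) {
    R <- fit0$R
    out <- list(B = fit0$B, R = R, lambda = lam0,
                error_variances = rep(0, m), logLik = fit0$logLik)
  } else {
    # theta = (lambda, e_1..e_m, chol-parameters of R)
    ecur <- rep(1e-4 * mean(diag(fit0$R)) * mean(diag(C)), m)
    th0 <- c(lam0, ecur, .par_from_chol(fit0$R))
    ed <- eigen(transform_lambda(C, lam0), symmetric = TRUE)
    cache <- list(lambda = lam0, ed = ed)
    negll <- function(th) {
      lam <- th[1]
      e <- th[2:(m + 1)]
      L <- .chol_from_par(th[-(1:(m + 1))], m)
      R <- tcrossprod(L)
      if (abs(lam - cache$lambda) > 1e-12) {
        cache$ed <<- eigen(transform_lambda(C, lam), symmetric = TRUE)
        cache$lambda <<- lam
      }
      ed <- cache$ed
      Ys <- crossprod(ed$vectors, Y)
      Xs <- crossprod(ed$vectors, X)
      ll <- .mv_error_loglik(pmax(ed$values, 0), Ys, Xs, R, e)$logLik
      if (!is.finite(ll)) 1e10 else -ll
    }
    # bounds: lambda in [0,1]; e >= 0; chol log-diagonals kept finite
    lower <- c(0, rep(0, m), rep(-20, m), rep(-1e3, m * (m - 1) / 2))
    upper <- c(1, rep(Inf, m), rep(20, m), rep(1e3, m * (m - 1) / 2))
    o <- optim(th0, negll, method = "L-BFGS-B", lower = lower, upper = upper,
               control = list(maxit = 500))
    th <- o$par
    lam <- th[1]
    e <- th[2:(m + 1)]
    L <- .chol_from_par(th[-(1:(m + 1))], m)
    R <- tcrossprod(L)
    ed <- eigen(transform_lambda(C, lam), symmetric = TRUE)
    Ys <- crossprod(ed$vectors, Y)
    Xs <- crossprod(ed$vectors, X)
    fin <- .mv_error_loglik(pmax(ed$values, 0), Ys, Xs, R, e)
    if (!is.finite(fin$logLik)) stop("mv_pgls did not converge to a finite likelihood")
    out <- list(B = fin$B, R = R, lambda = lam,
                error_variances = e, logLik = fin$logLik)
  }

  ev <- eigen(out$R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    stop("estimated evolutionary covariance is not positive semi-definite; ",
         "eigenvalues: ", paste(signif(ev, 4), collapse = ", "))
  }
  s <- sqrt(diag(out$R))
  corr <- out$R / tcrossprod(s)
  diag(corr) <- 1
  dimnames(out$B) <- list(c("(Intercept)", "slope"), colnames(Y))
  dimnames(out$R) <- dimnames(corr) <- list(colnames(Y), colnames(Y))
  structure(c(out, list(correlations = corr, n = n,
                        estimate_error = estimate_error)),
            class = "mv_pgls_fit")
}

#' @export
print.mv_pgls_fit <- function(x, ...) {
  cat("Multivariate PGLS (shared Pagel's lambda = ", signif(x$lambda, 4),
      ", n = ", x$n, ")\n", sep = "")
  cat("Coefficients:\n"); print(round(x$B, 4))
  cat("Evolutionary correlations:\n"); print(round(x$correlations, 3))
  if (any(x$error_variances > 0)) {
    cat("Error variances:", signif(x$error_variances, 4), "\n")
  }
  cat("logLik:", signif(x$logLik, 8), "\n")
  invisible(x)
}
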