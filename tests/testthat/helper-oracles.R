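# Shared fixtures and independent oracles, built in code.

# Dense multivariate-normal log-density oracle (independent of the
# package's pruning engine): x ~ N(z0, sigma2 * C).
dense_bm_loglik <- function(C, x, sigma2, z0) {
  C <- C[names(x), names(x)]
  L <- chol(sigma2 * C)
  r <- backsolve(L, x - z0, transpose = TRUE)
  -length(x) / 2 * log(2 * pi) - sum(log(diag(L))) - sum(r^2) / 2
}

# Random non-ultrametric rooted tree with positive branch lengths.
random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + 0.05  # keep terminal branches off zero
  tr
}

# Simulate BM tip values by walking the edges with independent normal
# increments -- a covariance-free simulation path, used as the oracle for
# vcv_matrix and the contrasts checks.
bm_edge_walk <- function(tree, nrep, sigma2 = 1, seed = 1) {
  set.seed(seed)
  tree <- ape::reorder.phylo(tree, "postorder")
  n <- ape::Ntip(tree)
  vals <- matrix(0, n + tree$Nnode, nrep)
  for (k in rev(seq_len(nrow(tree$edge)))) {  # preorder: root -> tips
    par <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    vals[ch, ] <- vals[par, ] +
      rnorm(nrep, 0, sqrt(sigma2 * tree$edge.length[k]))
  }
  out <- vals[seq_len(n), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

# Star phylogeny with unit branch lengths.
star_tree <- function(n, depth = 1) {
  tips <- paste0("t", seq_len(n))
  parse_newick(paste0("(", paste0(tips, ":", depth, collapse = ","), ");"))
}

# Small complete trait table for metric tests.
toy_traits <- function() {
  data.frame(
    species = c("Aa_aa", "Bb_bb", "Cc_cc"),
    clade = c("Mammalia", "Mammalia", "Aves"),
    adult_body_mass = c(100, 200, 50),
    litter_size = c(2, 3, 1),
    litters_per_year = c(1, 2, 1),
    mass_at_independence = c(10, 30, 25),
    max_longevity = c(12, 8, 6),
    female_maturity_age = c(2, 1, 1),
    svl_min = NA_real_, svl_max = NA_real_,
    stringsAsFactors = FALSE
  )
}

# Dense log-likelihood of the multivariate measurement-error model:
# vec(Y - XB) ~ N(0, R %x% C_lambda + diag-blocks e_k I), responses
# stacked column by column. Plain Kronecker algebra, no rotation tricks.
dense_mv_loglik <- function(C, Y, X, B, R, e, lambda) {
  n <- nrow(Y); m <- ncol(Y)
  Cl <- transform_lambda(C, lambda)
  V <- kronecker(R, Cl)
  for (k in seq_len(m)) {
    idx <- ((k - 1) * n + 1):(k * n)
    V[idx, idx] <- V[idx, idx] + diag(e[k], n)
  }
  r <- as.vector(Y - X %*% B)
  L <- tryCatch(chol(V), error = function(err) NULL)
  if (is.null(L)) return(-Inf)
  w <- backsolve(L, r, transpose = TRUE)
  -(n * m / 2) * log(2 * pi) - sum(log(diag(L))) - sum(w^2) / 2
}
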