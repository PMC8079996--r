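#' Parse a Newick string into a phylogeny
#'
#' Thin validating wrapper around [ape::read.tree()]: requires branch
#' lengths, unique tip labels and a well-formed string.
#'
#' @param text Newick string (single tree, terminated by `;`).
#' @return an object of class `phylo`.
#' @export
parse_newick <- function(text) {
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) stop("malformed Newick string: ", substr(text, 1, 60))
  if (is.null(tree$edge.length)) stop("Newick string lacks branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup) > 0L) stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  tree
}

#' Serialize a phylogeny to Newick
#'
#' @param tree a `phylo` object.
#' @param digits significant digits for branch lengths.
#' @return a Newick string.
#' @export
write_newick <- function(tree, digits = 12) {
  ape::write.tree(tree, digits = digits)
}

#' Read / write Newick files
#'
#' @param path file path.
#' @return `read_newick`: a `phylo`; `write_newick_file`: the path, invisibly.
#' @export
read_newick <- function(path) {
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' @rdname read_newick
#' @param tree a `phylo` object.
#' @export
write_newick_file <- function(tree, path) {
  writeLines(write_newick(tree), path)
  invisible(path)
}

#' Phylogenetic variance-covariance matrix
#'
#' `C[i, j]` is the shared path length from the root to the most recent
#' common ancestor of tips i and j; the diagonal holds root-to-tip
#' distances. Under Brownian motion with rate `sigma2` the tip values are
#' multivariate normal with covariance `sigma2 * C`.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @return symmetric PSD matrix with tip labels as dimnames.
#' @export
vcv_matrix <- function(tree) {
  ape::vcv.phylo(tree)
}

#' Pagel's lambda transformation of a phylogenetic covariance
#'
#' Multiplies off-diagonal covariances by `lambda`, leaving the diagonal
#' unchanged. `lambda = 1` is Brownian motion on the original tree;
#' `lambda = 0` a star phylogeny (no phylogenetic signal).
#'
#' @param C covariance matrix from [vcv_matrix()].
#' @param lambda signal multiplier in `[0, 1]`.
#' @return transformed covariance matrix.
#' @export
transform_lambda <- function(C, lambda) {
  if (!is.numeric(lambda) || lambda < 0) stop("lambda must be >= 0")
  if (lambda > 1) stop("lambda must be <= 1")
  d <- diag(C)
  out <- lambda * C
  diag(out) <- d
  out
}

#' Pagel's kappa transformation of a tree
#'
#' Raises every branch length to the power `kappa` (with `0^0` defined as
#' 0, so zero-length branches stay zero). `kappa = 0` approximates
#' speciational evolution; `kappa = 1` is the identity.
#'
#' @param tree a `phylo`.
#' @param kappa exponent, `>= 0`.
#' @return tree with transformed branch lengths.
#' @export
transform_kappa <- function(tree, kappa) {
  if (!is.numeric(kappa) || kappa < 0) stop("kappa must be >= 0")
  el <- tree$edge.length
  new <- el^kappa
  new[el == 0] <- 0
  tree$edge.length <- new
  tree
}

.node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

.tree_height <- function(tree) {
  max(.node_depths(tree)[seq_len(ape::Ntip(tree))])
}

.is_ultrametric <- function(tree, tol = 1e-6) {
  d <- .node_depths(tree)[seq_len(ape::Ntip(tree))]
  (max(d) - min(d)) <= tol * max(d)
}

#' Ornstein-Uhlenbeck covariance on an ultrametric tree
#'
#' Stationary-form OU covariance: for tips i, j with shared path length
#' `s_ij` on a tree of height T,
#' `C_ij = (1 / (2 alpha)) * exp(-2 alpha (T - s_ij)) * (1 - exp(-2 alpha s_ij))`.
#' As `alpha -> 0` this converges to the Brownian covariance `s_ij`.
#'
#' @param tree an ultrametric `phylo`.
#' @param alpha pull strength towards the optimum, per Myr, `>= 0`.
#' @return covariance matrix over tips.
#' @export
transform_ou <- function(tree, alpha) {
  if (!is.numeric(alpha) || alpha < 0) stop("alpha must be >= 0")
  if (!.is_ultrametric(tree)) stop("OU transform requires an ultrametric tree")
  C <- vcv_matrix(tree)
  if (alpha == 0) return(C)
  T_ <- max(diag(C))
  # -expm1 form avoids cancellation as alpha -> 0
  (1 / (2 * alpha)) * exp(-2 * alpha * (T_ - C)) * (-expm1(-2 * alpha * C))
}

#' Model-specific tip covariance matrix
#'
#' Dispatches on the evolutionary model to build the (unit-rate) tip
#' covariance used by GLS machinery: BM uses the tree covariance, lambda
#' rescales off-diagonals, kappa exponentiates branch lengths, OU applies
#' the stationary transform.
#'
#' @param tree a `phylo`.
#' @param model one of "BM", "lambda", "kappa", "OU".
#' @param param shape parameter (ignored for BM).
#' @return covariance matrix over tips.
#' @export
model_vcv <- function(tree, model = c("BM", "lambda", "kappa", "OU"),
                      param = NULL) {
  model <- match.arg(model)
  switch(model,
    BM = vcv_matrix(tree),
    lambda = transform_lambda(vcv_matrix(tree), param),
    kappa = vcv_matrix(transform_kappa(tree, param)),
    OU = transform_ou(tree, param)
  )
}

.crown_age <- function(tree) .tree_height(tree)

.strip_newick <- function(tree) {
  sub(";$", "", write_newick(tree))
}

#' Stitch dated clade trees into a supertree from divergence ages
#'
#' Joins ultrametric clade trees along a ladder backbone given by the
#' order of `trees`: the last two clades join first, then each earlier
#' clade attaches to the growing group. The age of each attachment comes
#' from `divergences`; the stem branch of a clade is its attachment age
#' minus its crown age, so within-clade structure and all within-clade
#' distances are preserved and the supertree is ultrametric.
#'
#' @param trees named list of ultrametric `phylo` objects, ordered from
#'   outermost to innermost clade (e.g. Amphibia, Mammalia, Reptilia, Aves).
#' @param divergences data.frame with columns `cladeA`, `cladeB`,
#'   `age_myr`: stem divergence ages for clade pairs. The attachment age of
#'   clade i is the maximum tabulated age between it and any clade deeper
#'   in the nesting.
#' @return an ultrametric supertree (`phylo`).
#' @export
stitch_trees <- function(trees, divergences) {
  if (length(trees) < 2L) stop("need at least two clade trees")
  if (is.null(names(trees)) || any(names(trees) == "")) {
    stop("trees must be a named list")
  }
  for (nm in names(trees)) {
    if (!.is_ultrametric(trees[[nm]])) stop("clade tree not ultrametric: ", nm)
  }
  pair_age <- function(a, b) {
    hit <- (divergences$cladeA == a & divergences$cladeB == b) |
      (divergences$cladeA == b & divergences$cladeB == a)
    if (!any(hit)) return(NA_real_)
    max(divergences$age_myr[hit])
  }
  nms <- names(trees)
  n <- length(nms)
  # innermost clade: subtree newick + its crown age
  cur_nwk <- .strip_newick(trees[[n]])
  cur_age <- .crown_age(trees[[n]])
  cur_members <- nms[n]
  for (i in rev(seq_len(n - 1L))) {
    ages <- vapply(cur_members, function(m) pair_age(nms[i], m), numeric(1))
    ages <- ages[!is.na(ages)]
    if (length(ages) == 0L) {
      stop("no divergence age linking clade ", nms[i], " to {",
           paste(cur_members, collapse = ","), "}")
    }
    att <- max(ages)
    crown_i <- .crown_age(trees[[i]])
    if (crown_i >= att) {
      stop("crown age of clade ", nms[i], " (", signif(crown_i, 6),
           ") >= attachment age (", signif(att, 6), ")")
    }
    if (cur_age >= att) {
      stop("crown age of group {", paste(cur_members, collapse = ","),
           "} (", signif(cur_age, 6), ") >= attachment age (", signif(att, 6), ")")
    }
    stem_i <- att - crown_i
    stem_cur <- att - cur_age
    cur_nwk <- sprintf("(%s:%.10f,%s:%.10f)",
                       .strip_newick(trees[[i]]), stem_i, cur_nwk, stem_cur)
    cur_age <- att
    cur_members <- c(cur_members, nms[i])
  }
  parse_newick(paste0(cur_nwk, ";"))
}

#' Read a divergence-age table
#'
#' CSV with columns `cladeA`, `cladeB`, `age_myr` (stem divergence ages in
#' Myr, as tabulated by timetree calibration resources).
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_divergence_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cladeA", "cladeB", "age_myr")
  if (!all(need %in% names(tab))) {
    stop("divergence table must have columns ", paste(need, collapse = ", "))
  }
  if (any(tab$age_myr <= 0)) stop("divergence ages must be positive")
  tab
}
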