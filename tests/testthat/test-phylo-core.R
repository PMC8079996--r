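test_that("Newick parsing validates and round-trips", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  expect_equal(ape::Ntip(tr), 3L)
  expect_equal(max(ape::node.depth.edgelength(tr)), 2)
  expect_error(parse_newick("((A:1,A:1):1);"), "duplicate tip")
  expect_error(parse_newick("((A:1,B:1:1,C:2);"), "malformed|Newick")

  yule <- simulate_yule(40, 1, seed = 5)
  rt <- parse_newick(write_newick(yule))
  expect_equal(rt$tip.label, yule$tip.label)
  d1 <- ape::cophenetic.phylo(yule); d2 <- ape::cophenetic.phylo(rt)
  expect_lt(max(abs(d1 - d2[rownames(d1), colnames(d1)])), 1e-9)
})

test_that("phylogenetic covariance holds shared root-to-MRCA path lengths", {
  C <- vcv_matrix(parse_newick("((A:1,B:1):1,C:2);"))
  expect_equal(C[c("A", "B", "C"), c("A", "B", "C")],
               matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3, 3,
                      dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  Cs <- vcv_matrix(star_tree(4))
  expect_equal(unname(Cs), diag(4))
})

test_that("covariance matches edge-walk Brownian simulation", {
  tr <- random_tree(6, seed = 3)
  C <- vcv_matrix(tr)
  sims <- bm_edge_walk(tr, nrep = 4e4, seed = 11)
  emp <- tcrossprod(sims) / ncol(sims)  # mean-zero covariance
  # Monte-Carlo tolerance: SE of a covariance entry ~ C_ii/sqrt(nrep)
  expect_lt(max(abs(emp - C[rownames(emp), rownames(emp)])),
            5 * max(diag(C)) / sqrt(4e4))
})

test_that("lambda transform scales off-diagonals only and preserves PSD", {
  C <- vcv_matrix(parse_newick("((A:1,B:1):1,C:2);"))
  expect_equal(transform_lambda(C, 1), C)
  expect_equal(unname(transform_lambda(C, 0)), diag(diag(C)))
  C5 <- transform_lambda(C, 0.5)
  expect_equal(unname(C5[c("A", "B", "C"), c("A", "B", "C")]),
               matrix(c(2, 0.5, 0, 0.5, 2, 0, 0, 0, 2), 3, 3))
  expect_error(transform_lambda(C, -0.1), ">= 0")
  for (s in 1:5) {
    tr <- random_tree(8, seed = s)
    lam <- runif(1)
    ev <- eigen(transform_lambda(vcv_matrix(tr), lam), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gt(min(ev), -1e-9)
  }
})

test_that("kappa transform exponentiates branch lengths with 0^0 = 0", {
  tr <- parse_newick("((A:4,B:1):0,C:2);")
  expect_equal(transform_kappa(tr, 1)$edge.length, tr$edge.length)
  k0 <- transform_kappa(tr, 0)
  expect_equal(sort(k0$edge.length), c(0, 1, 1, 1))  # zero branch stays zero
  expect_equal(sort(transform_kappa(tr, 0.5)$edge.length), c(0, 1, sqrt(2), 2))
})

test_that("OU covariance has the stationary closed form and the BM limit", {
  tr2 <- parse_newick("(A:1,B:1);")
  Cou <- transform_ou(tr2, alpha = 1)
  expect_equal(Cou["A", "B"], 0)
  expect_equal(Cou["A", "A"], (1 - exp(-2)) / 2)

  yule <- simulate_yule(20, 1, seed = 2)
  C <- vcv_matrix(yule)
  T_ <- max(diag(C))
  lim <- transform_ou(yule, alpha = 1e-12)
  expect_lt(max(abs(lim - C) / max(C)), 1e-6)

  big <- transform_ou(yule, alpha = 1e4)
  expect_lt(max(abs(big - diag(1 / (2 * 1e4), nrow(C)))), 1e-8)

  nonult <- random_tree(6, seed = 1)
  expect_error(transform_ou(nonult, 1), "ultrametric")
})

test_that("stitching joins clade trees at the tabulated ages and stays ultrametric", {
  tA <- parse_newick("(a1:10,a2:10);")
  tB <- parse_newick("(b1:20,b2:20);")
  div <- data.frame(cladeA = "A", cladeB = "B", age_myr = 30)
  st <- stitch_trees(list(A = tA, B = tB), div)
  d <- ape::node.depth.edgelength(st)
  expect_equal(max(d[1:4]), 30)
  expect_true(ape::is.ultrametric(st, tol = 1e-9))
  # stems: attachment age minus crown ages
  el <- st$edge.length
  expect_true(any(abs(el - 20) < 1e-9) && any(abs(el - 10) < 1e-9))

  # within-clade distances preserved exactly
  dd <- ape::cophenetic.phylo(st)
  expect_equal(dd["a1", "a2"], 20)
  expect_equal(dd["b1", "b2"], 40)
  expect_equal(dd["a1", "b1"], 60)
})

test_that("four clades with nested ages form a ladder backbone", {
  trees <- list(
    Amphibia = parse_newick("(p1:50,p2:50);"),
    Mammalia = parse_newick("(m1:40,m2:40);"),
    Reptilia = parse_newick("(r1:30,r2:30);"),
    Aves = parse_newick("(v1:20,v2:20);")
  )
  div <- data.frame(
    cladeA = c("Amphibia", "Mammalia", "Reptilia"),
    cladeB = c("Aves", "Aves", "Aves"),
    age_myr = c(352, 312, 280)
  )
  st <- stitch_trees(trees, div)
  expect_true(ape::is.ultrametric(st, tol = 1e-9))
  dd <- ape::cophenetic.phylo(st)
  expect_equal(dd["p1", "v1"] / 2, 352)
  expect_equal(dd["m1", "v1"] / 2, 312)
  expect_equal(dd["r1", "v1"] / 2, 280)
  expect_equal(dd["r1", "r2"] / 2, 30)

  bad <- div; bad$age_myr[3] <- 25  # younger than the avian crown
  expect_error(stitch_trees(trees, bad), "Reptilia|crown age")
})
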