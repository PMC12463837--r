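test_that("classical MDS reproduces Euclidean geometry", {
  # equilateral: all pairwise distances 1
  v <- matrix(1, 3, 3) - diag(3)
  dimnames(v) <- list(c("A", "B", "C"), c("A", "B", "C"))
  e <- classical_mds(dist_matrix(v), 2)
  expect_equal(as.matrix(dist(e$coords)), v, tolerance = 1e-9,
               ignore_attr = TRUE)

  # collinear points 0, 1, 2, 4: 1-D structure, second eigenvalue ~ 0
  x <- c(0, 1, 2, 4)
  v2 <- abs(outer(x, x, "-"))
  dimnames(v2) <- list(letters[1:4], letters[1:4])
  e2 <- classical_mds(dist_matrix(v2), 2)
  expect_lt(abs(e2$eigenvalues[2]), 1e-9)
  expect_equal(as.matrix(dist(e2$coords)), v2, tolerance = 1e-9,
               ignore_attr = TRUE)

  # random point sets, n up to 12, both k: distances reproduced to 1e-9
  set.seed(301)
  for (k in 2:3) for (i in 1:10) {
    n <- sample((k + 1):12, 1)
    d <- random_euclidean_dm(n, k)
    e <- classical_mds(d, k)
    expect_equal(as.matrix(dist(e$coords)), d$values, tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_true(all(abs(colSums(e$coords)) < 1e-9 * n))
    expect_equal(e$eigenvalues, sort(e$eigenvalues, decreasing = TRUE))
  }
})

test_that("MDS orientation is deterministic and degeneracy is flagged", {
  set.seed(302)
  d <- random_euclidean_dm(6)
  e1 <- classical_mds(d, 2)
  e2 <- classical_mds(d, 2)
  expect_identical(e1$coords, e2$coords)
  ref <- order(d$labels)[1]
  expect_true(all(e1$coords[ref, ] <= 0))

  # 3 collinear points asked for k = 2 -> zero-padded second axis
  x <- c(0, 1, 3)
  v <- abs(outer(x, x, "-"))
  dimnames(v) <- list(c("a", "b", "c"), c("a", "b", "c"))
  e3 <- classical_mds(dist_matrix(v), 2)
  expect_true(e3$degenerate)
  expect_equal(unname(e3$coords[, 2]), rep(0, 3))
})

test_that("agglomerative clustering recovers separated clouds and respects
           linkage conventions", {
  set.seed(303)
  X <- rbind(matrix(rnorm(10, sd = 0.05), 5, 2),
             matrix(rnorm(10, mean = 10, sd = 0.05), 5, 2))
  D <- as.matrix(dist(X))
  dimnames(D) <- list(sprintf("x%02d", 1:10), sprintf("x%02d", 1:10))
  d <- dist_matrix(D)
  truth <- rep(1:2, each = 5)
  for (linkage in c("average", "ward")) {
    part <- cut_tree(agglomerative(d, linkage), 2)
    expect_equal(adjusted_rand(part, truth), 1)
  }

  # n = 2, average linkage: single merge at the sole distance
  v <- matrix(c(0, 0.7, 0.7, 0), 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  h <- agglomerative(dist_matrix(v))
  expect_equal(h$height, 0.7)
  # merge heights are monotone non-decreasing
  sim <- simulate_wordlist(sim_config(seed = 9))
  hh <- agglomerative(pairwise_ldn(sim$wordlist))
  expect_true(all(diff(hh$height) >= 0))
})

test_that("average-linkage cophenetics reproduce ultrametric input", {
  set.seed(304)
  for (i in 1:10) {
    u <- random_ultrametric(sample(4:10, 1))
    h <- agglomerative(dist_matrix(u), "average")
    cop <- as.matrix(stats::cophenetic(h))
    expect_equal(cop[rownames(u), colnames(u)], u)
    # cophenetic matrix is ultrametric: d(i,k) <= max(d(i,j), d(j,k))
    n <- nrow(cop)
    for (j in 1:n)
      expect_true(all(outer(cop[, j], cop[j, ], pmax) - cop >= -1e-12))
  }
})

test_that("cut_tree boundary cases and 3-family recovery", {
  sim <- simulate_wordlist(sim_config(seed = 12))
  h <- agglomerative(pairwise_ldn(sim$wordlist))
  n <- length(h$labels)
  expect_equal(length(unique(cut_tree(h, n))), n)   # singletons
  expect_equal(length(unique(cut_tree(h, 1))), 1)   # one group
  expect_error(cut_tree(h, 0))
  expect_error(cut_tree(h, n + 1))
  expect_equal(adjusted_rand(cut_tree(h, 3), sim$partition), 1)
})

test_that("neighbor joining is exact on additive matrices", {
  # 3 taxa: closed-form star branch lengths
  v <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(dist_matrix(v))
  pl <- ape::cophenetic.phylo(tr)
  expect_equal(pl[c("A", "B", "C"), c("A", "B", "C")], v)
  # x_A = (d_AB + d_AC - d_BC)/2 = 1
  edge_a <- tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "A")]
  expect_equal(edge_a, 1)

  set.seed(305)
  for (i in 1:20) {
    ad <- random_additive_dm(sample(4:8, 1))
    tr <- neighbor_joining(ad$dm)
    pl <- ape::cophenetic.phylo(tr)
    labs <- ad$dm$labels
    expect_equal(pl[labs, labs], ad$dm$values, tolerance = 1e-9)
  }
  expect_error(neighbor_joining(dist_matrix(v[1:2, 1:2])), "at least 3")
})

test_that("trees serialize to Newick and round-trip", {
  v <- matrix(c(0, 0.6, 0.6, 0), 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  nwk <- to_newick(agglomerative(dist_matrix(v)))
  expect_match(nwk, "^\\(A:0\\.3,B:0\\.3\\);$")

  set.seed(306)
  ad <- random_additive_dm(6)
  tr <- neighbor_joining(ad$dm)
  tr2 <- read_newick(to_newick(tr))
  labs <- ad$dm$labels
  expect_equal(ape::cophenetic.phylo(tr2)[labs, labs], ad$dm$values,
               tolerance = 1e-9)

  # metacharacter labels are quoted and survive
  v2 <- matrix(c(0, 0.4, 0.4, 0), 2,
               dimnames = list(c("A(1)", "B"), c("A(1)", "B")))
  nwk2 <- to_newick(agglomerative(dist_matrix(v2)))
  tr3 <- read_newick(nwk2)
  expect_true("A(1)" %in% tr3$tip.label)
})

test_that("structure operations are invariant to label order", {
  set.seed(307)
  d <- random_euclidean_dm(8)
  perm <- sample(8)
  dp <- dist_matrix(d$values[perm, perm])
  labs <- d$labels

  e <- classical_mds(d, 2); ep <- classical_mds(dp, 2)
  expect_equal(ep$coords[labs, ], e$coords[labs, ], tolerance = 1e-9)

  cop <- as.matrix(stats::cophenetic(agglomerative(d)))
  copp <- as.matrix(stats::cophenetic(agglomerative(dp)))
  expect_equal(copp[labs, labs], cop[labs, labs], tolerance = 1e-12)

  pj <- ape::cophenetic.phylo(neighbor_joining(d))
  pjp <- ape::cophenetic.phylo(neighbor_joining(dp))
  expect_equal(pjp[labs, labs], pj[labs, labs], tolerance = 1e-9)
})
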