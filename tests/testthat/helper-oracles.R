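# Independent oracles and fixture builders used across the suite.

# Pure recursion over edit scripts: no memoization, no DP.  Exponential, so
# only usable on very short strings; serves as the from-first-principles
# definition of the edit distance.
lev_recursive <- function(a, b) {
  if (nchar(a) == 0) return(nchar(b))
  if (nchar(b) == 0) return(nchar(a))
  a1 <- substr(a, 1, 1); b1 <- substr(b, 1, 1)
  ar <- substr(a, 2, nchar(a)); br <- substr(b, 2, nchar(b))
  min(lev_recursive(ar, br) + (a1 != b1),   # substitute / match
      lev_recursive(ar, b) + 1,             # delete from a
      lev_recursive(a, br) + 1)             # insert into a
}

# Memoized variant of the same recursion, usable on slightly longer strings.
lev_memo <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0) return(j)
    if (j == 0) return(i)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    cost <- substr(a, i, i) != substr(b, j, j)
    v <- min(rec(i - 1, j - 1) + cost, rec(i - 1, j) + 1, rec(i, j - 1) + 1)
    memo[[key]] <- v
    v
  }
  rec(nchar(a), nchar(b))
}

rand_string <- function(maxlen, alphabet = letters[1:4]) {
  n <- sample(0:maxlen, 1)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Distance matrix of n random points in R^k, labeled P01, P02, ...
random_euclidean_dm <- function(n, k = 2) {
  X <- matrix(rnorm(n * k), n)
  D <- as.matrix(dist(X))
  dimnames(D) <- list(sprintf("P%02d", 1:n), sprintf("P%02d", 1:n))
  dist_matrix(D)
}

# Random ultrametric matrix: cophenetic distances of an average-linkage
# dendrogram over random points (any dendrogram's cophenetic matrix is
# ultrametric by construction).
random_ultrametric <- function(n) {
  X <- matrix(rnorm(n * 3), n)
  h <- hclust(dist(X), method = "average")
  u <- as.matrix(stats::cophenetic(h))
  dimnames(u) <- list(sprintf("U%02d", 1:n), sprintf("U%02d", 1:n))
  u
}

# Path-length (additive) matrix of a random tree with labels sorted.
random_additive_dm <- function(n) {
  tr <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
  pm <- ape::cophenetic.phylo(tr)
  labs <- sort(rownames(pm))
  list(tree = tr, dm = dist_matrix(pm[labs, labs]))
}

toy_wordlist_path <- function() {
  system.file("extdata", "toy_wordlist.csv", package = "lexstrat")
}
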