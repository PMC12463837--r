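#' Classical (Torgerson) multidimensional scaling
#'
#' Projects a distance matrix into `k` = 2 or 3 dimensions by
#' eigendecomposition of the double-centered squared-distance matrix, with
#' coordinates scaled by the square root of each eigenvalue.  Negative
#' eigenvalues (expected for non-Euclidean inputs such as averaged LDN) are
#' never used for coordinates but are visible through the returned
#' eigenvalue spectrum so distortion can be assessed; when fewer than `k`
#' eigenvalues are positive, the missing coordinates are zero-padded and the
#' embedding is flagged degenerate.
#'
#' The reflection indeterminacy of MDS is resolved deterministically: every
#' axis is flipped, if necessary, so that the variety with the
#' lexicographically smallest identifier has a nonpositive coordinate.
#'
#' @param d a [dist_matrix()].
#' @param k number of dimensions, 2 or 3.
#' @return An object of class `"lex_mds"`: list with `labels`, `coords`
#'   (n-by-k matrix), `eigenvalues` (the k leading eigenvalues, sorted
#'   descending), `stress` (residual sum of squared distance
#'   discrepancies) and `degenerate` flag.
#' @export
classical_mds <- function(d, k = 2) {
  validate_dist_matrix(d)
  k <- as.integer(k)
  if (!k %in% c(2L, 3L)) stop("`k` must be 2 or 3")
  n <- length(d$labels)
  if (n < k + 1) stop("need at least k + 1 = ", k + 1, " varieties")
  fit <- suppressWarnings(cmdscale(d$values, k = k, eig = TRUE))
  pts <- fit$points
  coords <- matrix(0, n, k, dimnames = list(d$labels, paste0("dim", 1:k)))
  if (ncol(pts) > 0) coords[, seq_len(ncol(pts))] <- pts
  # axes whose eigenvalue is numerically zero carry no structure: zero them
  ev <- sort(fit$eig, decreasing = TRUE)[1:k]
  eps <- max(abs(fit$eig)) * 1e-12
  dead <- (seq_len(k) > ncol(pts)) | (ev <= eps)
  coords[, dead] <- 0
  degenerate <- any(dead)
  ref <- order(d$labels)[1]   # lexicographically smallest identifier
  for (j in seq_len(k))
    if (coords[ref, j] > 0) coords[, j] <- -coords[, j]
  emb_d <- as.matrix(stats::dist(coords))
  lo <- lower.tri(emb_d)
  structure(list(labels = d$labels, coords = coords,
                 eigenvalues = sort(fit$eig, decreasing = TRUE)[1:k],
                 stress = sum((d$values[lo] - emb_d[lo])^2),
                 degenerate = degenerate),
            class = "lex_mds")
}

#' @export
print.lex_mds <- function(x, ...) {
  cat("Classical MDS embedding: ", length(x$labels), " varieties in ",
      ncol(x$coords), "D", if (x$degenerate) " (degenerate)", "\n",
      sep = "")
  cat("Leading eigenvalues:", signif(x$eigenvalues, 5), "\n")
  cat("Stress (residual SSQ):", signif(x$stress, 5), "\n")
  invisible(x)
}

#' Write MDS coordinates as TSV
#'
#' One row per variety: `variety<TAB>dim1<TAB>dim2[<TAB>dim3]`.
#'
#' @param e a `"lex_mds"` embedding.
#' @param path output path.
#' @export
write_embedding <- function(e, path) {
  stopifnot(inherits(e, "lex_mds"))
  df <- data.frame(variety = e$labels, e$coords, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Agglomerative hierarchical clustering of a distance matrix
#'
#' Standard Lance-Williams agglomeration via [stats::hclust()].  Both
#' linkages the pipeline uses are exposed: `"average"` (UPGMA) and `"ward"`
#' (Ward's minimum-variance criterion applied to squared distances, the
#' `ward.D2` convention, so merge heights stay in distance units).
#'
#' @param d a [dist_matrix()].
#' @param linkage `"average"` (default) or `"ward"`.
#' @return An [stats::hclust] dendrogram with a `linkage` attribute.
#' @export
agglomerative <- function(d, linkage = c("average", "ward")) {
  linkage <- match.arg(linkage)
  validate_dist_matrix(d)
  if (length(d$labels) < 2) stop("need at least 2 varieties")
  h <- hclust(as.dist(d$values),
              method = if (linkage == "ward") "ward.D2" else "average")
  attr(h, "linkage") <- linkage
  h
}

#' Cut a dendrogram into k groups
#'
#' Removes the `k - 1` highest merges of a rooted dendrogram, yielding the
#' induced partition of the leaves.
#'
#' @param t an [stats::hclust] tree (as returned by [agglomerative()]).
#' @param k number of groups, between 1 and the number of leaves.
#' @return Named integer vector of group memberships.
#' @export
cut_tree <- function(t, k) {
  stopifnot(inherits(t, "hclust"))
  n <- length(t$labels)
  k <- as.integer(k)
  if (k < 1 || k > n) stop("`k` must be between 1 and ", n)
  cutree(t, k = k)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]): an unrooted tree with
#' branch lengths, exact on additive distance matrices.  Negative branch
#' lengths — which NJ can produce on non-additive input — are clamped to
#' zero with a warning; the indices of clamped edges are kept in the
#' `clamped_edges` attribute of the returned tree.
#'
#' @param d a [dist_matrix()] over at least 3 labels.
#' @return An [ape::phylo] tree.
#' @export
neighbor_joining <- function(d) {
  validate_dist_matrix(d)
  if (length(d$labels) < 3) stop("neighbor joining needs at least 3 taxa")
  tr <- ape::nj(as.dist(d$values))
  neg <- which(tr$edge.length < 0)
  if (length(neg)) {
    warning(length(neg), " negative branch length(s) clamped to 0")
    tr$edge.length[neg] <- 0
  }
  attr(tr, "clamped_edges") <- neg
  tr
}

#' Serialize a tree as Newick
#'
#' Dendrograms ([stats::hclust]) are written rooted, with branch lengths
#' derived from merge heights; NJ trees are written unrooted (trifurcating
#' root).  Labels containing Newick metacharacters are single-quoted.
#' Branch lengths are kept at full double precision so a round trip through
#' [read_newick()] is lossless to near machine precision.
#'
#' @param t an [stats::hclust] or [ape::phylo] tree.
#' @return A single Newick string, semicolon-terminated.
#' @export
to_newick <- function(t) {
  if (inherits(t, "hclust")) t <- ape::as.phylo(t)
  if (!inherits(t, "phylo")) stop("`t` must be an hclust or phylo tree")
  labs <- t$tip.label
  meta <- grepl("[][():,;'[:space:]]", labs)
  final <- ifelse(meta, paste0("'", gsub("'", "''", labs), "'"), labs)
  # serialize with placeholder tips, then splice in the (quoted) labels:
  # ape sanitizes metacharacters instead of quoting them
  ph <- sprintf("zq%04dqz", seq_along(labs))
  t$tip.label <- ph
  nwk <- ape::write.tree(t, digits = 15)
  for (i in seq_along(ph)) nwk <- sub(ph[i], final[i], nwk, fixed = TRUE)
  nwk
}

#' Parse a Newick string
#'
#' @param text Newick string.
#' @return An [ape::phylo] tree, with single-quoted labels unquoted.
#' @export
read_newick <- function(text) {
  t <- ape::read.tree(text = text)
  q <- grepl("^'.*'$", t$tip.label)
  t$tip.label[q] <- gsub("''", "'",
                         sub("^'(.*)'$", "\\1", t$tip.label[q]))
  t
}
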