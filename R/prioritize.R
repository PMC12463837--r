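#' Maximin (farthest-point) panel selection
#'
#' Greedy selection of `k` varieties that maximize captured diversity with
#' minimal redundancy: start from the pair attaining the matrix maximum
#' (or from a given variety), then repeatedly add the variety whose minimum
#' distance to the current panel is largest.  The classic greedy guarantee
#' applies: the final covering radius is within a factor 2 of the optimal
#' maximin radius.  Ties are broken by lexicographic label order.
#'
#' @param d a [dist_matrix()].
#' @param k panel size, between 1 and the number of labels.
#' @param start optional variety identifier to seed the panel with instead
#'   of the maximum-distance pair.
#' @return An object of class `"sampling_panel"`: list with `selected`
#'   (ordered identifiers), `coverage` (per step, the distance from the
#'   newly selected variety to the nearest earlier selection; `NA` for the
#'   seed) and `method = "maximin"`.
#' @export
select_maximin <- function(d, k, start = NULL) {
  validate_dist_matrix(d)
  n <- length(d$labels)
  k <- as.integer(k)
  if (k < 1 || k > n) stop("`k` must be between 1 and ", n)
  v <- d$values
  ord <- order(d$labels)          # lexicographic preference for ties
  selected <- integer(0)
  coverage <- numeric(0)
  if (!is.null(start)) {
    i0 <- match(start, d$labels)
    if (is.na(i0)) stop("unknown start variety: ", start)
    selected <- i0
    coverage <- NA_real_
  } else {
    # maximum-distance pair; among ties the lexicographically first pair
    best <- -Inf; pick <- NULL
    for (a in ord) for (b in ord) if (a != b && d$labels[a] < d$labels[b]) {
      if (v[a, b] > best) { best <- v[a, b]; pick <- c(a, b) }
    }
    selected <- pick[seq_len(min(k, 2))]
    coverage <- c(NA_real_, if (k >= 2) best)
  }
  while (length(selected) < k) {
    cand <- setdiff(seq_len(n), selected)
    mind <- apply(v[cand, selected, drop = FALSE], 1, min)
    best <- max(mind)
    tied <- cand[mind == best]
    nxt <- tied[order(d$labels[tied])[1]]
    selected <- c(selected, nxt)
    coverage <- c(coverage, best)
  }
  structure(list(selected = d$labels[selected], coverage = coverage,
                 method = "maximin"),
            class = "sampling_panel")
}

#' Cluster-medoid panel selection
#'
#' One representative per cluster: the medoid, i.e. the member minimizing
#' the sum of distances to its cluster co-members.  Ties are broken by
#' lexicographic label order.
#'
#' @param d a [dist_matrix()].
#' @param partition cluster assignment: vector (factor, integer or
#'   character) named by label, or in label order, covering every label.
#' @return A `"sampling_panel"` with one medoid per cluster, clusters in
#'   sorted order; `coverage` holds each medoid's mean distance to its
#'   co-members (`0` for singletons).
#' @export
select_medoids <- function(d, partition) {
  validate_dist_matrix(d)
  part <- check_partition(partition, d$labels)
  cl <- sort(unique(part))
  selected <- character(0)
  coverage <- numeric(0)
  for (g in cl) {
    members <- names(part)[part == g]
    if (length(members) == 0) stop("empty cluster: ", g)
    members <- sort(members)
    sums <- vapply(members, function(m)
      sum(d$values[m, members]), numeric(1))
    med <- members[which.min(sums)]   # which.min is first-match: lexicographic
    selected <- c(selected, med)
    coverage <- c(coverage,
                  if (length(members) > 1)
                    sums[med] / (length(members) - 1) else 0)
  }
  structure(list(selected = selected, coverage = unname(coverage),
                 method = "medoid"),
            class = "sampling_panel")
}

check_partition <- function(partition, labs) {
  part <- partition
  if (is.factor(part)) part <- as.character(part)
  if (is.null(names(part))) {
    if (length(part) != length(labs))
      stop("`partition` must be named by label or have one entry per label")
    names(part) <- labs
  }
  missing <- setdiff(labs, names(part))
  if (length(missing))
    stop("partition does not cover: ", paste(missing, collapse = ", "))
  out <- as.character(part[labs])
  names(out) <- labs
  out
}

#' @export
print.sampling_panel <- function(x, ...) {
  cat("Sampling panel (", x$method, "): ", length(x$selected),
      " varieties\n", sep = "")
  print(data.frame(variety = x$selected,
                   coverage = signif(x$coverage, 5)))
  invisible(x)
}

#' Bridge scores: lexical intermediacy between clusters
#'
#' For each variety, let `d_nearest <= d_second` be the ordered pair of (a)
#' its mean distance to the other members of its own cluster and (b) its
#' mean distance to the members of the closest foreign cluster.  The score
#' `s = 1 - d_nearest / d_second` lies in \[0, 1\]: `s` near 1 means the
#' variety is well nested inside a cluster, while `s` near 0 flags a
#' "bridge" variety positioned between clusters — the lexical signature of
#' sustained contact or admixture.  Varieties with `s` below `threshold`
#' are marked as bridges.  A variety alone in its cluster has no
#' within-cluster distance; its score is reported as `NA` and flagged.
#'
#' @param d a [dist_matrix()].
#' @param partition cluster assignment over the labels (at least 2
#'   clusters).
#' @param threshold bridge flag threshold on `s` (default 0.15).
#' @return A data frame of class `"bridge_scores"` sorted by decreasing
#'   `s`, with columns `variety`, `s`, `nearest`, `second`, `singleton`,
#'   `bridge`.
#' @export
bridge_scores <- function(d, partition, threshold = 0.15) {
  validate_dist_matrix(d)
  part <- check_partition(partition, d$labels)
  names(part) <- d$labels
  cl <- sort(unique(part))
  if (length(cl) < 2) stop("need at least 2 clusters")
  rows <- lapply(d$labels, function(v) {
    own <- setdiff(names(part)[part == part[v]], v)
    singleton <- length(own) == 0
    d_own <- if (singleton) 0 else mean(d$values[v, own])
    foreign <- setdiff(cl, part[v])
    fmeans <- vapply(foreign, function(g)
      mean(d$values[v, names(part)[part == g]]), numeric(1))
    fbest <- foreign[which.min(fmeans)]
    pair <- c(d_own, min(fmeans))
    labs2 <- c(part[[v]], fbest)
    o <- order(pair)
    s <- if (singleton || pair[o[2]] == 0) NA_real_
         else 1 - pair[o[1]] / pair[o[2]]
    data.frame(variety = v, s = s, nearest = labs2[o[1]],
               second = labs2[o[2]], singleton = singleton,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$bridge <- !is.na(out$s) & out$s < threshold
  out <- out[order(-out$s, out$variety, na.last = TRUE), ]
  rownames(out) <- NULL
  class(out) <- c("bridge_scores", "data.frame")
  out
}
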