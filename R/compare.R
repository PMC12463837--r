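lower_vec <- function(m) m[lower.tri(m)]

harmonize <- function(d1, d2) {
  common <- sort(intersect(d1$labels, d2$labels))
  dropped <- setdiff(union(d1$labels, d2$labels), common)
  if (length(dropped))
    warning("labels absent from one matrix dropped: ",
            paste(dropped, collapse = ", "))
  list(m1 = d1$values[common, common, drop = FALSE],
       m2 = d2$values[common, common, drop = FALSE],
       labels = common, dropped = dropped)
}

#' Mantel permutation test between two distance matrices
#'
#' Computes the Mantel correlation `r` — the Pearson correlation of the
#' vectorized strict lower triangles — between two distance matrices over
#' the same labels, and a permutation p-value obtained by jointly permuting
#' the rows and columns of the second matrix.  The p-value uses the
#' add-one convention `p = (#extreme + 1) / (n_perm + 1)`, with "extreme"
#' meaning `|r*| >= |r|` for the two-sided test and `r* >= r` for
#' `tail = "greater"`.  With few labels the permutation distribution is
#' coarse (n = 3 has only 6 permutations), so small p-values are
#' unattainable regardless of effect size.
#'
#' Matrices with unequal label sets are reduced to the sorted intersection,
#' with a warning naming the dropped labels.
#'
#' @param d1,d2 [dist_matrix()] objects over at least 3 common labels.
#' @param n_perm number of random permutations (default 9999).
#' @param seed integer seed for the permutation stream (required).
#' @param tail `"two-sided"` (default) or `"greater"`.
#' @return An object of class `"mantel_test"`: list with `r`, `p`,
#'   `n_perm`, `tail`, `seed`, `n`, `labels`, `dropped`, and `ci_low` /
#'   `ci_high` slots (`NA` until filled by [mantel_ci()]).
#' @examples
#' fst <- matrix(c(0, .01, .17, .01, 0, .1, .17, .1, 0), 3,
#'               dimnames = list(c("Luhya","Kikuyu","Maasai"),
#'                               c("Luhya","Kikuyu","Maasai")))
#' ldn <- matrix(c(0, .67, .82, .67, 0, .85, .82, .85, 0), 3,
#'               dimnames = dimnames(fst))
#' mantel(dist_matrix(fst, "genetic"), dist_matrix(ldn, "lexical"),
#'        n_perm = 999, seed = 1)
#' @export
mantel <- function(d1, d2, n_perm = 9999, seed,
                   tail = c("two-sided", "greater")) {
  tail <- match.arg(tail)
  validate_dist_matrix(d1); validate_dist_matrix(d2)
  if (missing(seed)) stop("a permutation `seed` is required")
  h <- harmonize(d1, d2)
  n <- length(h$labels)
  if (n < 3) stop("need at least 3 common labels, have ", n)
  x <- lower_vec(h$m1)
  y <- lower_vec(h$m2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant lower triangle: Pearson correlation undefined")
  r <- cor(x, y)
  ij <- which(lower.tri(h$m1), arr.ind = TRUE)
  set.seed(as.integer(seed))
  rs <- vapply(seq_len(n_perm), function(b) {
    p <- sample.int(n)
    cor(x, h$m2[cbind(p[ij[, 1]], p[ij[, 2]])])
  }, numeric(1))
  eps <- 1e-12
  extreme <- if (tail == "two-sided") sum(abs(rs) >= abs(r) - eps)
             else sum(rs >= r - eps)
  structure(list(r = r, p = (extreme + 1) / (n_perm + 1),
                 n_perm = n_perm, tail = tail,
                 ci_low = NA_real_, ci_high = NA_real_,
                 seed = as.integer(seed), n = n,
                 labels = h$labels, dropped = h$dropped),
            class = "mantel_test")
}

#' @export
print.mantel_test <- function(x, ...) {
  cat("Mantel test (", x$tail, ", ", x$n_perm, " permutations, n = ",
      x$n, ")\n", sep = "")
  cat("r =", signif(x$r, 4), " p =", signif(x$p, 4), "\n")
  if (!is.na(x$ci_low))
    cat("bootstrap 95% CI: (", signif(x$ci_low, 4), ", ",
        signif(x$ci_high, 4), ")\n", sep = "")
  invisible(x)
}

#' Gloss-bootstrap confidence interval for a Mantel correlation
#'
#' The sampling unit of a lexical distance matrix is the gloss, so
#' uncertainty in the Mantel `r` between a lexical matrix and a second
#' matrix is assessed by resampling glosses with replacement: for each
#' replicate the LDN matrix is recomputed from the resampled wordlist and
#' the correlation with `d2` recomputed, and the percentile interval of the
#' replicate correlations is reported.  A replicate in which some variety
#' pair retains no shared gloss is discarded and counted.
#'
#' @param d1 the lexical [dist_matrix()] derived from `w` (used for label
#'   harmonization and sanity checks).
#' @param d2 the comparison [dist_matrix()] (e.g. genetic F_ST).
#' @param w the [wordlist()] from which `d1` derives.
#' @param n_boot number of bootstrap replicates (default 1000; fewer than
#'   100 draws a warning).
#' @param seed integer seed (required).
#' @param conf confidence level (default 0.95).
#' @return List with `ci_low`, `ci_high`, `n_boot`, `n_discarded`, `seed`.
#' @export
mantel_ci <- function(d1, d2, w, n_boot = 1000, seed, conf = 0.95) {
  stopifnot(inherits(w, "wordlist"))
  validate_dist_matrix(d1); validate_dist_matrix(d2)
  if (d1$kind != "lexical")
    stop("`d1` must be a lexical matrix derived from `w`")
  if (!all(d1$labels %in% w$varieties))
    stop("`d1` has labels not present in the wordlist")
  if (missing(seed)) stop("a bootstrap `seed` is required")
  if (n_boot < 100) warning("fewer than 100 bootstrap replicates")
  common <- sort(intersect(d1$labels, d2$labels))
  if (length(common) < 3) stop("need at least 3 common labels")
  m2 <- d2$values[common, common]
  y <- lower_vec(m2)
  g <- length(w$glosses)
  set.seed(as.integer(seed))
  rs <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(g, g, replace = TRUE)
    forms <- w$forms[common, idx, drop = FALSE]
    colnames(forms) <- make.unique(colnames(forms))
    wb <- wordlist(forms, normalize = FALSE)
    mb <- tryCatch(pairwise_ldn(wb), error = function(e) NULL)
    if (is.null(mb)) next                     # pair lost all shared glosses
    xb <- lower_vec(mb$values[common, common])
    if (stats::sd(xb) == 0 || stats::sd(y) == 0) next
    rs[b] <- cor(xb, y)
  }
  ok <- !is.na(rs)
  if (!any(ok)) stop("all bootstrap replicates were discarded")
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(rs[ok], c(alpha, 1 - alpha), type = 7))
  list(ci_low = ci[1], ci_high = ci[2], n_boot = n_boot,
       n_discarded = sum(!ok), seed = as.integer(seed))
}

#' Great-circle distance matrix from homeland coordinates
#'
#' Haversine distances between population centroid coordinates, on a sphere
#' of mean Earth radius 6371.0088 km.
#'
#' @param g data frame with columns `variety` (or `label`), `lat`, `lon` in
#'   decimal degrees.
#' @return A [dist_matrix()] of kind `"geographic"` (units km).
#' @export
geo_matrix <- function(g) {
  g <- as.data.frame(g)
  labcol <- intersect(c("variety", "label"), names(g))[1]
  if (is.na(labcol) || !all(c("lat", "lon") %in% names(g)))
    stop("`g` needs columns variety (or label), lat, lon")
  lab <- as.character(g[[labcol]])
  check_ids(lab, "label")
  lat <- as.numeric(g$lat); lon <- as.numeric(g$lon)
  if (anyNA(lat) || anyNA(lon) || any(abs(lat) > 90) || any(abs(lon) > 180))
    stop("coordinates out of range: lat in [-90, 90], lon in [-180, 180]")
  n <- length(lab)
  phi <- lat * pi / 180
  lam <- lon * pi / 180
  values <- matrix(0, n, n, dimnames = list(lab, lab))
  R <- 6371.0088
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    a <- sin((phi[j] - phi[i]) / 2)^2 +
      cos(phi[i]) * cos(phi[j]) * sin((lam[j] - lam[i]) / 2)^2
    d <- 2 * R * asin(min(1, sqrt(a)))
    values[i, j] <- values[j, i] <- d
  }
  dist_matrix(values, kind = "geographic")
}
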