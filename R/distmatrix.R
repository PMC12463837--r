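#' Construct a labeled distance matrix
#'
#' The universal currency of the pipeline: a square symmetric nonnegative
#' matrix over variety/population labels, tagged with the kind of distance
#' it holds.  Lexical (LDN) and genetic (F_ST) distances must lie in
#' \[0, 1\]; geographic distances are in kilometers.
#'
#' @param values square numeric matrix with identical row and column names.
#' @param kind one of `"lexical"`, `"genetic"`, `"geographic"`, `"other"`.
#' @param units measurement units; defaults to `"dimensionless"` except
#'   `"km"` for geographic matrices.
#' @param support optional integer matrix of the number of shared glosses
#'   behind each lexical entry (same shape as `values`).
#' @return An object of class `"dist_matrix"`: list with elements `labels`,
#'   `values`, `kind`, `units` and `support`.
#' @export
dist_matrix <- function(values, kind = c("other", "lexical", "genetic",
                                         "geographic"),
                        units = NULL, support = NULL) {
  kind <- match.arg(kind)
  if (is.null(units))
    units <- if (kind == "geographic") "km" else "dimensionless"
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  labels <- rownames(values)
  if (is.null(labels) || is.null(colnames(values)) ||
      !identical(labels, colnames(values)))
    stop("`values` must have identical row and column labels")
  check_ids(labels, "label")
  x <- structure(list(labels = labels, values = values, kind = kind,
                      units = units, support = support),
                 class = "dist_matrix")
  validate_dist_matrix(x)
}

#' Validate distance-matrix invariants
#'
#' Checks squareness, exact symmetry, zero diagonal, nonnegativity, the
#' \[0, 1\] range for lexical and genetic matrices, and (for lexical
#' matrices with a support matrix) that every defined entry is backed by at
#' least one shared gloss.  Errors on the first violation.
#'
#' @param x a [dist_matrix()].
#' @return `x`, invisibly, if valid.
#' @export
validate_dist_matrix <- function(x) {
  stopifnot(inherits(x, "dist_matrix"))
  v <- x$values
  if (nrow(v) != ncol(v)) stop("matrix is not square")
  if (anyNA(v)) stop("matrix contains NA values")
  if (!all(v == t(v))) {
    bad <- which(v != t(v), arr.ind = TRUE)[1, ]
    stop("matrix is not symmetric: [", x$labels[bad[1]], ", ",
         x$labels[bad[2]], "]")
  }
  if (any(diag(v) != 0)) stop("diagonal is not zero")
  if (any(v < 0)) stop("negative distances present")
  if (x$kind %in% c("lexical", "genetic") && any(v > 1))
    stop(x$kind, " distances must lie in [0, 1]")
  if (!is.null(x$support)) {
    s <- x$support
    if (!identical(dim(s), dim(v))) stop("support matrix shape mismatch")
    off <- upper.tri(v) | lower.tri(v)
    if (x$kind == "lexical" && any(s[off] < 1 & !is.na(v[off])))
      stop("lexical entries defined with zero shared glosses")
  }
  invisible(x)
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat("Distance matrix (", x$kind, ", ", x$units, "): ",
      length(x$labels), " x ", length(x$labels), "\n", sep = "")
  print(round(x$values, 4))
  invisible(x)
}

#' @export
as.matrix.dist_matrix <- function(x, ...) x$values

#' @export
labels.dist_matrix <- function(object, ...) object$labels

fmt_full <- function(x) sprintf("%.17g", x)

csv_quote <- function(x) {
  need <- grepl('[",\n]', x)
  x[need] <- paste0('"', gsub('"', '""', x[need]), '"')
  x
}

#' Write a distance matrix to disk
#'
#' `"csv"` writes a square labeled table (header row and first column of
#' labels) at full double precision, so a read/write round trip is exact.
#' `"phylip"` writes the lower-triangle PHYLIP distance format (count line,
#' then one row per taxon with distances to itself and all previous taxa)
#' with at least 10 significant digits; labels containing whitespace or the
#' delimiter are rejected because the format cannot quote them.
#'
#' @param m a [dist_matrix()].
#' @param path output path.
#' @param format `"csv"` or `"phylip"`.
#' @export
write_matrix <- function(m, path, format = c("csv", "phylip")) {
  format <- match.arg(format)
  validate_dist_matrix(m)
  v <- m$values
  if (format == "csv") {
    lab <- csv_quote(m$labels)
    lines <- c(paste(c("", lab), collapse = ","),
               vapply(seq_along(lab), function(i)
                 paste(c(lab[i], fmt_full(v[i, ])), collapse = ","),
                 character(1)))
  } else {
    if (any(grepl("[][(),;:[:space:]]", m$labels)))
      stop("phylip format cannot represent labels containing ",
           "whitespace or separator characters")
    lines <- c(as.character(nrow(v)),
               vapply(seq_len(nrow(v)), function(i)
                 paste(c(m$labels[i], sprintf("%.12g", v[i, seq_len(i)])),
                       collapse = " "), character(1)))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a distance matrix from disk
#'
#' Three layouts are supported. `"csv"`: a square labeled table as written
#' by [write_matrix()].  `"phylip"`: lower-triangle PHYLIP.  `"pairs"`: a
#' pair list with one row per unordered pair (`labelA,labelB,value`, header
#' optional) from which the full square matrix is assembled; every pair of
#' the implied label set must be present, and a pair listed twice with
#' conflicting values is a symmetry error.  Published pairwise F_ST tables
#' are typically in pair-list form.
#'
#' @param path input path.
#' @param format `"auto"` (default: sniff the layout), `"csv"`, `"phylip"`
#'   or `"pairs"`.
#' @param kind distance kind tag for the result (see [dist_matrix()]).
#' @param keep optional character vector: restrict a pair list to pairs
#'   whose two labels both belong to `keep` before assembly.
#' @return A [dist_matrix()].
#' @export
read_matrix <- function(path, format = c("auto", "csv", "phylip", "pairs"),
                        kind = "other", keep = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "auto") {
    first <- scan(text = lines[1], what = character(), sep = ",",
                  quiet = TRUE)
    format <- if (grepl("^[0-9]+$", trimws(lines[1]))) "phylip"
      else if (length(first) == 3 || (length(lines) > 1 &&
        length(scan(text = lines[2], what = character(), sep = ",",
                    quiet = TRUE)) == 3)) "pairs"
      else "csv"
  }
  values <- switch(format,
    csv = read_matrix_csv(lines),
    phylip = read_matrix_phylip(lines),
    pairs = read_matrix_pairs(lines, keep))
  dist_matrix(values, kind = kind)
}

read_matrix_csv <- function(lines) {
  tab <- utils::read.csv(text = lines, check.names = FALSE,
                         row.names = 1, stringsAsFactors = FALSE)
  values <- as.matrix(tab)
  if (!is.numeric(values)) stop("non-numeric entries in matrix CSV")
  rownames(values) <- rownames(tab)
  values
}

read_matrix_phylip <- function(lines) {
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || length(lines) != n + 1)
    stop("malformed phylip file: expected ", n, " taxon rows")
  labs <- character(n)
  values <- matrix(0, n, n)
  for (i in seq_len(n)) {
    f <- scan(text = lines[i + 1], what = character(), quiet = TRUE)
    if (length(f) != i + 1)
      stop("phylip row ", i, ": expected ", i + 1, " fields")
    labs[i] <- f[1]
    values[i, seq_len(i)] <- as.numeric(f[-1])
    values[seq_len(i), i] <- values[i, seq_len(i)]
  }
  dimnames(values) <- list(labs, labs)
  values
}

read_matrix_pairs <- function(lines, keep = NULL) {
  rows <- lapply(lines, function(l)
    scan(text = l, what = character(), sep = ",", quote = "\"",
         quiet = TRUE))
  if (any(lengths(rows) != 3))
    stop("pair list rows must have exactly 3 fields (labelA,labelB,value)")
  tab <- do.call(rbind, rows)
  if (is.na(suppressWarnings(as.numeric(tab[1, 3]))))
    tab <- tab[-1, , drop = FALSE]             # header row
  a <- trimws(tab[, 1]); b <- trimws(tab[, 2])
  val <- as.numeric(tab[, 3])
  if (anyNA(val)) stop("non-numeric pair value in pair list")
  if (!is.null(keep)) {
    sel <- a %in% keep & b %in% keep
    a <- a[sel]; b <- b[sel]; val <- val[sel]
  }
  labs <- sort(unique(c(a, b)))
  n <- length(labs)
  if (n < 2) stop("pair list implies fewer than 2 labels")
  values <- matrix(NA_real_, n, n, dimnames = list(labs, labs))
  diag(values) <- 0
  for (r in seq_along(val)) {
    i <- match(a[r], labs); j <- match(b[r], labs)
    if (i == j) stop("self-pair in pair list: ", a[r])
    prev <- values[i, j]
    if (!is.na(prev) && prev != val[r])
      stop("conflicting values for pair ", a[r], " / ", b[r], ": ",
           prev, " vs ", val[r])
    values[i, j] <- values[j, i] <- val[r]
  }
  if (anyNA(values)) {
    miss <- which(is.na(values) & upper.tri(values), arr.ind = TRUE)
    stop("pair list is incomplete; absent pairs: ",
         paste(labs[miss[, 1]], labs[miss[, 2]], sep = "-",
               collapse = ", "))
  }
  values
}
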