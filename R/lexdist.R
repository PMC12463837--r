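enc_utf8_int <- function(x) lapply(x, function(s)
  if (is.na(s)) NULL else utf8ToInt(enc2utf8(s)))

#' Levenshtein edit distance
#'
#' Minimal number of single-character insertions, deletions and
#' substitutions (all unit cost, no transposition) transforming one string
#' into the other.  Characters are Unicode code points; no grapheme
#' clustering or digraph tokenization is applied, so the measure is
#' deterministic across platforms.
#'
#' @param a,b character vectors, recycled to a common length.
#' @return integer vector of edit distances.
#' @examples
#' levenshtein("kitten", "sitting")  # 3
#' @export
levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  if (anyNA(a) || anyNA(b)) stop("NA strings are not allowed")
  ea <- enc_utf8_int(a)
  eb <- enc_utf8_int(b)
  vapply(seq_len(n), function(i) lev_int(ea[[i]], eb[[i]]), integer(1))
}

#' Normalized Levenshtein distance (LDN)
#'
#' `levenshtein(a, b) / max(nchar(a), nchar(b))`, with lengths counted in
#' Unicode code points.  LDN lies in \[0, 1\]: 0 for identical strings, 1
#' when no aligned character is shared (e.g. equal-length strings differing
#' everywhere).  Undefined when both strings are empty.
#'
#' @inheritParams levenshtein
#' @return numeric vector in \[0, 1\].
#' @examples
#' ldn("ab", "abcd")  # 0.5
#' @export
ldn <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  la <- nchar(a, type = "chars")
  lb <- nchar(b, type = "chars")
  lmax <- pmax(la, lb)
  if (any(lmax == 0))
    stop("ldn is undefined for two empty strings")
  levenshtein(a, b) / lmax
}

#' Pairwise lexical distance matrix from a wordlist
#'
#' For every pair of varieties, the LDN is computed for each gloss at which
#' *both* varieties have a form, and the per-gloss distances are averaged
#' (missing entries are excluded pairwise, so each pair uses its own set of
#' shared glosses).  The number of shared glosses behind each entry is
#' returned as the `support` matrix.
#'
#' @param w a [wordlist()].
#' @param min_shared minimum number of shared glosses a pair must have
#'   (default 1); a pair below the threshold is an error, since its distance
#'   would be undefined or unreliably estimated.
#' @return A [dist_matrix()] of kind `"lexical"` with a `support` matrix.
#' @examples
#' f <- rbind(A = c(g1 = "aa", g2 = "ab"),
#'            B = c(g1 = "ab", g2 = "bb"))
#' pairwise_ldn(wordlist(f))$values["A", "B"]  # 0.5
#' @export
pairwise_ldn <- function(w, min_shared = 1L) {
  stopifnot(inherits(w, "wordlist"))
  if (length(w$varieties) < 2) stop("need at least 2 varieties")
  min_shared <- as.integer(min_shared)
  if (min_shared < 1) stop("`min_shared` must be >= 1")
  enc <- lapply(w$varieties, function(v) enc_utf8_int(w$forms[v, ]))
  res <- pairwise_ldn_core(enc)
  m <- res$mean
  s <- res$support
  dimnames(m) <- dimnames(s) <- list(w$varieties, w$varieties)
  off <- upper.tri(s)
  if (any(s[off] < min_shared)) {
    bad <- which(s < min_shared & off, arr.ind = TRUE)[1, ]
    stop("pair ", w$varieties[bad[1]], "-", w$varieties[bad[2]],
         " has only ", s[bad[1], bad[2]], " shared glosses (need ",
         min_shared, ")")
  }
  dist_matrix(m, kind = "lexical", support = s)
}
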