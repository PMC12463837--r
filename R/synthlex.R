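#' Configuration for the synthetic wordlist generator
#'
#' Defines a balanced family structure: `n_families` lineages split at the
#' root, each carrying `varieties_per_family` varieties.  For every gloss a
#' single root word is drawn; each family's ancestral form evolves from it
#' along a branch of length `between_family_depth`, and each variety's form
#' evolves from its family's ancestor along a branch of length
#' `within_family_depth`.  Evolution is a per-character i.i.d. edit process
#' (substitution, plus rarer insertion/deletion) at probability
#' `edit_prob` per character per unit branch length — intentionally simple:
#' it creates rate-controlled divergence, not phonological realism.
#'
#' The defaults emulate a three-family landscape (three well-separated
#' language families, a handful of varieties each, a Swadesh-scale gloss
#' count, light missingness) on which family structure is unambiguously
#' recoverable.
#'
#' @param n_families number of language families (default 3).
#' @param varieties_per_family varieties per family (default 4).
#' @param n_glosses number of glosses (default 60).
#' @param root_word_length length of root words in characters (default 6).
#' @param edit_prob per-character edit probability per unit branch length
#'   (default 0.12).
#' @param within_family_depth branch length from family ancestor to each
#'   variety (default 0.3).
#' @param between_family_depth branch length from root to each family
#'   ancestor (default 3.0); must exceed `within_family_depth`.
#' @param missing_rate probability that any (variety, gloss) cell is
#'   missing (default 0.05).
#' @param hybrid optional list `list(variety =, donors = c(f1, f2), mix =)`
#'   adding one admixed variety that takes each gloss from a lineage of
#'   donor family `f1` with probability `mix`, else from `f2`.
#' @param genetic_coupling coupling in \[0, 1\] used by
#'   [simulate_coupled_fst()] (default 0.9).
#' @param seed integer seed (required; same seed, same wordlist).
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_families = 3, varieties_per_family = 4,
                       n_glosses = 60, root_word_length = 6,
                       edit_prob = 0.12, within_family_depth = 0.3,
                       between_family_depth = 3.0, missing_rate = 0.05,
                       hybrid = NULL, genetic_coupling = 0.9, seed) {
  if (missing(seed)) stop("a `seed` is required")
  if (root_word_length < 1) stop("root words must have length >= 1")
  for (p in c(edit_prob, missing_rate, genetic_coupling))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  if (between_family_depth <= within_family_depth)
    stop("`between_family_depth` must exceed `within_family_depth`")
  if (!is.null(hybrid)) {
    stopifnot(is.list(hybrid),
              all(c("variety", "donors", "mix") %in% names(hybrid)),
              length(hybrid$donors) == 2,
              hybrid$mix >= 0, hybrid$mix <= 1)
  }
  structure(list(n_families = as.integer(n_families),
                 varieties_per_family = as.integer(varieties_per_family),
                 n_glosses = as.integer(n_glosses),
                 root_word_length = as.integer(root_word_length),
                 edit_prob = edit_prob,
                 within_family_depth = within_family_depth,
                 between_family_depth = between_family_depth,
                 missing_rate = missing_rate, hybrid = hybrid,
                 genetic_coupling = genetic_coupling,
                 seed = as.integer(seed)),
            class = "sim_config")
}

rand_word <- function(len) paste(sample(letters, len, replace = TRUE),
                                 collapse = "")

# Evolve a word along a branch: each character independently substituted
# with probability p and deleted or followed by an insertion with
# probability p/4 each (indels rarer than substitutions keeps word lengths
# stable).  A word is never reduced below one character.
evolve_word <- function(word, depth, rate) {
  p <- min(1, rate * depth)
  chars <- strsplit(word, "", fixed = TRUE)[[1]]
  out <- character(0)
  for (ch in chars) {
    u <- runif(3)
    keep <- ch
    if (u[1] < p) keep <- sample(letters, 1)
    if (u[2] < p / 4) keep <- character(0)         # deletion
    out <- c(out, keep)
    if (u[3] < p / 4) out <- c(out, sample(letters, 1))  # insertion
  }
  if (length(out) == 0) out <- sample(letters, 1)
  paste(out, collapse = "")
}

#' Generate a synthetic wordlist with known family structure
#'
#' Draws word forms by edit-process divergence along the balanced family
#' tree described by the configuration (see [sim_config()]), applies
#' uniform missingness, and optionally adds one hybrid variety mixing two
#' donor families gloss by gloss.  Fully deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return List with `wordlist` (a [wordlist()] with family labels),
#'   `tree` (the generating [ape::phylo] tree with branch lengths; the
#'   hybrid, if any, is attached to its first donor's ancestor) and
#'   `partition` (named character vector variety -> family; the hybrid is
#'   assigned to its first donor family).
#' @export
simulate_wordlist <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  c0 <- config
  set.seed(c0$seed)
  fams <- paste0("F", seq_len(c0$n_families))
  vnames <- as.vector(t(outer(fams, seq_len(c0$varieties_per_family),
                              function(f, i) paste0(f, "_V", i))))
  hyb <- c0$hybrid
  all_names <- c(vnames, if (!is.null(hyb)) hyb$variety)
  forms <- matrix(NA_character_, length(all_names), c0$n_glosses,
                  dimnames = list(all_names,
                                  paste0("g", seq_len(c0$n_glosses))))
  for (g in seq_len(c0$n_glosses)) {
    root <- rand_word(c0$root_word_length)
    anc <- vapply(fams, function(f)
      evolve_word(root, c0$between_family_depth, c0$edit_prob),
      character(1))
    for (f in fams) for (i in seq_len(c0$varieties_per_family)) {
      forms[paste0(f, "_V", i), g] <-
        evolve_word(anc[[f]], c0$within_family_depth, c0$edit_prob)
    }
    if (!is.null(hyb)) {
      lineages <- vapply(hyb$donors, function(f)
        evolve_word(anc[[f]], c0$within_family_depth, c0$edit_prob),
        character(1))
      pick <- if (runif(1) < hyb$mix) 1 else 2
      forms[hyb$variety, g] <- lineages[pick]
    }
  }
  if (c0$missing_rate > 0) {
    drop <- runif(length(forms)) < c0$missing_rate
    forms[drop] <- NA_character_
  }
  partition <- rep(fams, each = c0$varieties_per_family)
  names(partition) <- vnames
  if (!is.null(hyb)) {
    partition[hyb$variety] <- hyb$donors[1]
  }
  w <- wordlist(forms, family = partition[all_names], normalize = FALSE)
  list(wordlist = w, tree = balanced_tree(c0), partition = partition)
}

# Balanced generating tree as an ape phylo: root -> family ancestors
# (branch = between_family_depth) -> varieties (branch =
# within_family_depth); a hybrid leaf hangs off its first donor's ancestor.
balanced_tree <- function(c0) {
  fams <- paste0("F", seq_len(c0$n_families))
  sub <- vapply(fams, function(f) {
    tips <- paste0(f, "_V", seq_len(c0$varieties_per_family), ":",
                   c0$within_family_depth)
    if (!is.null(c0$hybrid) && c0$hybrid$donors[1] == f)
      tips <- c(tips, paste0(c0$hybrid$variety, ":",
                             c0$within_family_depth))
    paste0("(", paste(tips, collapse = ","), "):",
           c0$between_family_depth)
  }, character(1))
  ape::read.tree(text = paste0("(", paste(sub, collapse = ","), ");"))
}

#' Pseudo-genetic differentiation matrix coupled to a tree
#'
#' Produces an F_ST-like matrix for testing matrix-comparison machinery:
#' pairwise path lengths of the tree are rescaled to \[0, 0.2\] (a
#' realistic F_ST range for human populations) and mixed with independent
#' uniform noise on the same scale, `F = coupling * scaled_path +
#' (1 - coupling) * noise`.  It is a rescaled tree metric plus noise, not a
#' coalescent quantity.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param coupling mixing weight in \[0, 1\]; 1 = pure tree metric,
#'   0 = pure noise.
#' @param seed integer seed for the noise (required).
#' @return A [dist_matrix()] of kind `"genetic"`.
#' @export
simulate_coupled_fst <- function(tree, coupling, seed) {
  stopifnot(inherits(tree, "phylo"))
  if (coupling < 0 || coupling > 1) stop("`coupling` must be in [0, 1]")
  if (missing(seed)) stop("a noise `seed` is required")
  path <- ape::cophenetic.phylo(tree)
  labs <- sort(rownames(path))
  path <- path[labs, labs]
  scaled <- if (max(path) > 0) 0.2 * path / max(path) else path
  set.seed(as.integer(seed))
  n <- nrow(path)
  noise <- matrix(0, n, n)
  noise[upper.tri(noise)] <- runif(sum(upper.tri(noise)), 0, 0.2)
  noise <- noise + t(noise)
  values <- coupling * scaled + (1 - coupling) * noise
  diag(values) <- 0
  dimnames(values) <- list(labs, labs)
  dist_matrix(values, kind = "genetic")
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two partitions of the same items:
#' 1 for identical partitions (up to relabeling), approximately 0 for
#' independent ones.
#'
#' @param a,b partitions: vectors of cluster labels over the same items
#'   (matched by name when both are named, by position otherwise).
#' @return The adjusted Rand index (a single number, at most 1).
#' @export
adjusted_rand <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  if (length(a) != length(b)) stop("partitions differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  ncomb <- comb2(sum(tab))
  expected <- sum_a * sum_b / ncomb
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(1)
  (sum_ij - expected) / (maxidx - expected)
}
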