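test_that("maximin selection starts from the maximum pair and greedily
           maximizes the minimum distance", {
  set.seed(501)
  d <- random_euclidean_dm(8)
  # k = 2: exactly the pair attaining the matrix maximum
  p2 <- select_maximin(d, 2)
  expect_equal(sort(unname(d$values[p2$selected[1], p2$selected[2]])),
               max(d$values))
  # k = n: all varieties
  pn <- select_maximin(d, 8)
  expect_setequal(pn$selected, d$labels)
  expect_false(anyDuplicated(pn$selected) > 0)
  # coverage non-increasing after the seed
  cov <- pn$coverage[-1]
  expect_true(all(diff(cov) <= 1e-12))
  # coverage value = min distance of the new pick to earlier picks
  for (i in 3:8) {
    expect_equal(pn$coverage[i],
                 min(d$values[pn$selected[i], pn$selected[1:(i - 1)]]))
  }
  expect_error(select_maximin(d, 0))
  expect_error(select_maximin(d, 9))
  # given-start policy
  ps <- select_maximin(d, 3, start = d$labels[4])
  expect_equal(ps$selected[1], d$labels[4])
})

test_that("maximin k = 3 on a 3-family wordlist picks one variety per
           family", {
  sim <- simulate_wordlist(sim_config(seed = 31))
  m <- pairwise_ldn(sim$wordlist)
  p <- select_maximin(m, 3)
  fams <- unname(sim$partition[p$selected])
  expect_setequal(fams, c("F1", "F2", "F3"))
})

test_that("greedy maximin radius is within factor 2 of the optimum", {
  set.seed(502)
  for (i in 1:8) {
    n <- sample(6:10, 1)
    k <- sample(2:4, 1)
    d <- random_euclidean_dm(n)
    pk <- select_maximin(d, k)
    greedy_radius <- pk$coverage[k]
    # exhaustive optimum of the maximin objective
    best <- -Inf
    for (sel in utils::combn(n, k, simplify = FALSE)) {
      sub <- d$values[sel, sel]
      best <- max(best, min(sub[lower.tri(sub)]))
    }
    expect_gte(greedy_radius * 2 + 1e-12, best)
  }
})

test_that("medoids minimize within-cluster distance sums", {
  # hand case: AB=1, AC=1, BC=2 -> medoid A
  v <- matrix(c(0, 1, 1, 1, 0, 2, 1, 2, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  p <- select_medoids(dist_matrix(v), c(A = "g", B = "g", C = "g"))
  expect_equal(p$selected, "A")

  # singleton clusters are their own medoids
  p2 <- select_medoids(dist_matrix(v), c(A = "x", B = "y", C = "z"))
  expect_equal(p2$selected, c("A", "B", "C"))
  expect_equal(p2$coverage, c(0, 0, 0))

  expect_error(select_medoids(dist_matrix(v), c(A = "x", B = "x")),
               "cover")

  # brute-force oracle on random inputs
  set.seed(503)
  for (i in 1:10) {
    n <- sample(5:12, 1)
    d <- random_euclidean_dm(n)
    part <- sample(c("c1", "c2"), n, replace = TRUE)
    names(part) <- d$labels
    if (length(unique(part)) < 2) next
    p <- select_medoids(d, part)
    for (g in sort(unique(part))) {
      members <- names(part)[part == g]
      sums <- vapply(members, function(m) sum(d$values[m, members]),
                     numeric(1))
      med <- p$selected[match(g, sort(unique(part)))]
      expect_equal(sums[[med]], min(sums))
    }
  }
})

test_that("bridge scores quantify intermediacy between clusters", {
  # equidistant variety: s = 0; well-nested variety: s near 1
  v <- matrix(0, 5, 5,
              dimnames = list(c("a1", "a2", "b1", "b2", "mid"),
                              c("a1", "a2", "b1", "b2", "mid")))
  pairs <- list(c("a1", "a2", 0.1), c("b1", "b2", 0.1),
                c("a1", "b1", 1), c("a1", "b2", 1),
                c("a2", "b1", 1), c("a2", "b2", 1),
                c("a1", "mid", 0.5), c("a2", "mid", 0.5),
                c("b1", "mid", 0.5), c("b2", "mid", 0.5))
  for (p in pairs) {
    v[p[1], p[2]] <- v[p[2], p[1]] <- as.numeric(p[3])
  }
  part <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", mid = "A")
  b <- bridge_scores(dist_matrix(v), part)
  expect_equal(b$s[b$variety == "mid"], 0)      # exactly between clusters
  # a1's own-cluster mean (0.1 with a2, 0.5 with mid) vs 1 to cluster B
  expect_true(all(abs(b$s[b$variety %in% c("a1", "a2")] - 0.7) < 1e-12))
  expect_true(b$bridge[b$variety == "mid"])
  # sorted descending by s
  expect_true(all(diff(b$s[!is.na(b$s)]) <= 0))

  # single-cluster input is an error; singleton cluster flagged NA
  expect_error(bridge_scores(dist_matrix(v), rep("A", 5)), "2 clusters")
  part2 <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", mid = "C")
  b2 <- bridge_scores(dist_matrix(v), part2)
  expect_true(is.na(b2$s[b2$variety == "mid"]))
  expect_true(b2$singleton[b2$variety == "mid"])
})

test_that("a lexically admixed variety attains the minimum bridge score
           and s tracks mixing proportion", {
  cfg <- sim_config(seed = 41, hybrid = list(variety = "HYB",
                                             donors = c("F1", "F2"),
                                             mix = 0.5))
  sim <- simulate_wordlist(cfg)
  m <- pairwise_ldn(sim$wordlist)
  b <- bridge_scores(m, sim$partition)
  expect_equal(b$variety[which.min(b$s)], "HYB")

  # monotone: the closer the mix to 0.5, the lower s (Spearman check)
  mixes <- c(0.5, 0.65, 0.8, 0.95)
  s_at <- vapply(seq_along(mixes), function(i) {
    cfg <- sim_config(seed = 600 + i,
                      hybrid = list(variety = "HYB",
                                    donors = c("F1", "F2"),
                                    mix = mixes[i]))
    sim <- simulate_wordlist(cfg)
    m <- pairwise_ldn(sim$wordlist)
    b <- bridge_scores(m, sim$partition)
    b$s[b$variety == "HYB"]
  }, numeric(1))
  expect_true(cor(mixes, s_at, method = "spearman") > 0.7)
})

test_that("panels are invariant to label order", {
  set.seed(504)
  d <- random_euclidean_dm(9)
  perm <- sample(9)
  dp <- dist_matrix(d$values[perm, perm])
  expect_identical(select_maximin(d, 4)$selected,
                   select_maximin(dp, 4)$selected)
  part <- setNames(sample(c("x", "y"), 9, replace = TRUE), d$labels)
  part[1] <- "x"; part[2] <- "y"
  expect_identical(select_medoids(d, part)$selected,
                   select_medoids(dp, part[dp$labels])$selected)
})
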