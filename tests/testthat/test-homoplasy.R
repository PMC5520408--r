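# helpers to build substitution tables by hand
sub_row <- function(site, edge, B, A, pB = 1, pA = 1) {
  data.table::data.table(site = site, edge = edge, B = B, A = A,
                         post_B = pB, post_A = pA)
}

test_that("pair enumeration classifies and excludes correctly", {
  tree <- fixture_tree()
  a <- tree$tip_index[["A"]]; b <- tree$tip_index[["B"]]
  c_ <- tree$tip_index[["C"]]; e_ <- tree$tip_index[["E"]]

  # two parallel L->F on sibling edges
  p <- enumerate_pairs(rbind(sub_row(1, a, "L", "F"), sub_row(1, b, "L", "F")),
                       tree)
  expect_equal(nrow(p), 1L)
  expect_equal(p$kind, "parallel")
  expect_equal(p$dist, mid_edge_distance(tree, a, b))

  # {B->A, B->X, C->A}: one divergent pair; convergent pair never emitted
  p2 <- enumerate_pairs(rbind(sub_row(1, a, "L", "F"), sub_row(1, b, "L", "V"),
                              sub_row(1, c_, "K", "F")), tree)
  expect_equal(nrow(p2), 1L)
  expect_equal(p2$kind, "divergent")
  expect_equal(sort(c(p2$A1, p2$A2)), c("F", "V"))

  # nested edges are not independent -> no pair
  ab <- tree$parent[a]
  p3 <- enumerate_pairs(rbind(sub_row(1, a, "L", "F"), sub_row(1, ab, "L", "F")),
                        tree)
  expect_equal(nrow(p3), 0L)

  expect_error(enumerate_pairs(rbind(sub_row(1, a, "L", "F"),
                                     sub_row(2, b, "L", "F")), tree),
               "single site")
  # multi-site version handles both sites
  p4 <- enumerate_all_pairs(rbind(sub_row(1, a, "L", "F"),
                                  sub_row(1, b, "L", "F"),
                                  sub_row(2, a, "K", "R"),
                                  sub_row(2, e_, "K", "Q")), tree)
  expect_equal(nrow(p4), 2L)
  expect_setequal(p4$kind, c("parallel", "divergent"))
})

test_that("pair enumeration agrees exactly with the brute-force enumerator", {
  for (seed in 1:6) {
    tree <- random_calibration_tree(sample(10:30, 1), 6, seed = seed)
    set.seed(seed * 100)
    n <- 25
    subs <- data.table::data.table(
      site = sample(1:3, n, TRUE),
      edge = sample(tree$edges, n, TRUE),
      B = sample(c("L", "K"), n, TRUE),
      A = sample(c("F", "V", "R"), n, TRUE),
      post_B = 1, post_A = 1)
    subs <- subs[B != A]
    subs <- unique(subs, by = c("site", "edge"))
    got <- enumerate_all_pairs(subs, tree)
    want <- bf_pairs(subs, tree)
    expect_equal(nrow(got), if (is.null(nrow(want))) 0L else nrow(want))
    if (nrow(got)) {
      # canonical unordered-edge key for row alignment
      ge <- cbind(pmin(got$e1, got$e2), pmax(got$e1, got$e2))
      got_k <- got[order(got$site, got$B, ge[, 1], ge[, 2])]
      want_k <- want[order(want$site, want$B, want$e1, want$e2), ]
      expect_equal(got_k$kind, want_k$kind)
      expect_equal(got_k$dist, want_k$dist, tolerance = 1e-9)
    }
  }
})

test_that("homoplasy-informative site rule", {
  tree <- fixture_tree()
  a <- tree$tip_index[["A"]]; b <- tree$tip_index[["B"]]
  c_ <- tree$tip_index[["C"]]; d <- tree$tip_index[["D"]]
  e_ <- tree$tip_index[["E"]]

  # parallel and divergent from the same B
  p <- enumerate_all_pairs(rbind(sub_row(1, a, "L", "F"),
                                 sub_row(1, b, "L", "F"),
                                 sub_row(1, e_, "L", "V")), tree)
  expect_true(homoplasy_informative(p))

  # parallel from L, divergent from K only -> not informative
  q <- enumerate_all_pairs(rbind(sub_row(1, a, "L", "F"),
                                 sub_row(1, b, "L", "F"),
                                 sub_row(1, c_, "K", "R"),
                                 sub_row(1, d, "K", "Q")), tree)
  expect_false(homoplasy_informative(q))
  expect_false(homoplasy_informative(empty <- q[0]))
  expect_equal(informative_sites(p), 1L)
})

test_that("matched subsampling: min rule, balance, determinism", {
  tree <- fixture_tree()
  tips <- tree$tip_index
  # site 1, B=L: 2 parallel pairs (3 L->F subs would give 3; use 2 subs on
  # A,B plus divergent L->V on C,D,E edges)
  subs <- rbind(sub_row(1, tips[["A"]], "L", "F"),
                sub_row(1, tips[["B"]], "L", "F"),
                sub_row(1, tips[["C"]], "L", "V"),
                sub_row(1, tips[["D"]], "L", "W"),
                sub_row(1, tips[["E"]], "L", "Y"))
  pairs <- enumerate_all_pairs(subs, tree)
  cnt <- pair_counts(pairs)
  m <- min(cnt$n_paral, cnt$n_diverg)
  sub1 <- matched_subsample(pairs, seed = 7)
  c1 <- pair_counts(sub1)
  expect_equal(c1$n_paral, m)
  expect_equal(c1$n_diverg, m)
  expect_identical(matched_subsample(pairs, seed = 7), sub1)
  expect_false(identical(matched_subsample(pairs, seed = 8), sub1) &&
               identical(matched_subsample(pairs, seed = 9), sub1))

  # when counts already match, sampling is a no-op up to order
  pp <- pairs[kind == "parallel"][1]
  dd <- pairs[kind == "divergent"][1]
  eq <- rbind(pp, dd)
  expect_equal(nrow(matched_subsample(eq, seed = 1)), 2L)
})

test_that("matched subsampling balances per (site, B) for random pair sets", {
  set.seed(42)
  for (rep in 1:50) {
    n <- sample(5:60, 1)
    pairs <- data.table::data.table(
      site = sample(1:6, n, TRUE), B = sample(c("L", "K", "G"), n, TRUE),
      A1 = "F", A2 = "F",
      kind = sample(c("parallel", "divergent"), n, TRUE),
      e1 = 1L, e2 = 2L, dist = runif(n), ndist = NA_real_,
      post_B1 = 1, post_A1 = 1, post_B2 = 1, post_A2 = 1)
    sub <- matched_subsample(pairs, seed = rep)
    cnt <- pair_counts(sub)
    expect_true(all(cnt$n_paral == cnt$n_diverg))
    expect_equal(sum(sub$kind == "parallel"), sum(sub$kind == "divergent"))
    # subsample is a subset of the input
    expect_true(all(sub$dist %in% pairs$dist))
  }
})

test_that("P/D curve: bins, edge cases, totals", {
  mk <- function(kind, dist) data.table::data.table(
    site = 1L, B = "L", A1 = "F", A2 = if (kind == "parallel") "F" else "V",
    kind = kind, e1 = 1L, e2 = 2L, dist = dist, ndist = NA_real_,
    post_B1 = 1, post_A1 = 1, post_B2 = 1, post_A2 = 1)
  p <- rbind(mk("parallel", 0.1), mk("divergent", 0.1))
  cv <- pd_curve(p, breaks = c(-4, -3), min_divergent = 1)
  expect_equal(cv$pd, 1.0)

  p2 <- rbind(mk("parallel", 0.1), mk("parallel", 0.1),
              mk("divergent", 0.3), mk("divergent", 0.3))
  cv2 <- pd_curve(p2, breaks = c(-4, -3, -1), min_divergent = 1)
  expect_true(is.na(cv2$pd[1]))     # no divergent pairs -> undefined
  expect_equal(cv2$pd[2], 0.0)

  # zero-distance pairs land in the smallest bin
  p3 <- rbind(mk("parallel", 0), mk("divergent", 0.2))
  cv3 <- pd_curve(p3)
  expect_equal(cv3$n_paral[1], 1L)

  # matched totals are preserved across bins
  set.seed(3)
  p4 <- do.call(rbind, lapply(1:40, function(i)
    mk(sample(c("parallel", "divergent"), 1), runif(1, 0.01, 2))))
  cv4 <- pd_curve(p4)
  expect_equal(sum(cv4$n_paral), sum(p4$kind == "parallel"))
  expect_equal(sum(cv4$n_diverg), sum(p4$kind == "divergent"))
  expect_equal(nrow(pd_curve(p4[0])), 0L)
})

test_that("mean distance ratio: arithmetic and label-swap inversion", {
  mk <- function(kind, dist) data.table::data.table(
    site = 1L, B = "L", A1 = "F", A2 = "X", kind = kind, e1 = 1L, e2 = 2L,
    dist = dist, ndist = NA_real_, post_B1 = 1, post_A1 = 1, post_B2 = 1,
    post_A2 = 1)
  p <- rbind(mk("parallel", 0.4), mk("divergent", 0.5))
  expect_equal(mean_distance_ratio(p), 0.8)
  same <- rbind(mk("parallel", 0.2), mk("parallel", 0.6),
                mk("divergent", 0.2), mk("divergent", 0.6))
  expect_equal(mean_distance_ratio(same), 1.0)
  # swapping labels inverts the ratio
  set.seed(8)
  p2 <- do.call(rbind, lapply(1:30, function(i)
    mk(sample(c("parallel", "divergent"), 1), runif(1))))
  swapped <- data.table::copy(p2)
  swapped[, kind := ifelse(kind == "parallel", "divergent", "parallel")]
  expect_equal(mean_distance_ratio(swapped), 1 / mean_distance_ratio(p2))
  expect_error(mean_distance_ratio(p2[kind == "parallel"]), "at least one")
})

test_that("site bootstrap: determinism, single-site degeneracy", {
  tree <- fixture_tree()
  tips <- tree$tip_index
  subs <- rbind(sub_row(1, tips[["A"]], "L", "F"),
                sub_row(1, tips[["B"]], "L", "F"),
                sub_row(1, tips[["C"]], "L", "V"))
  pairs <- enumerate_all_pairs(subs, tree)
  b1 <- bootstrap_sites(pairs, "ratio", reps = 50, seed = 3)
  b2 <- bootstrap_sites(pairs, "ratio", reps = 50, seed = 3)
  expect_identical(b1$replicates, b2$replicates)
  expect_s3_class(b1, "ratio_estimate")
  expect_true(b1$ci[1] <= b1$median && b1$median <= b1$ci[2])

  # one site with balanced counts: statistic constant under resampling
  subs1 <- rbind(sub_row(1, tips[["A"]], "L", "F"),
                 sub_row(1, tips[["B"]], "L", "F"))
  one <- enumerate_all_pairs(rbind(subs1, sub_row(1, tips[["C"]], "L", "V"),
                                   sub_row(1, tips[["D"]], "L", "V")), tree)
  # keep exactly 1 parallel + 1 divergent so every draw is identical
  one <- one[c(which(one$kind == "parallel")[1],
               which(one$kind == "divergent")[1])]
  bc <- bootstrap_sites(one, "ratio", reps = 30, seed = 1)
  expect_equal(diff(bc$ci), 0)
})

test_that("crossing distance: interpolation and boundary conventions", {
  mk_curve <- function(pd, mids, stable = TRUE) {
    data.table::data.table(bin_lo = 2^(mids - 0.5), bin_hi = 2^(mids + 0.5),
                           mid_log2 = mids, n_paral = 10L, n_diverg = 10L,
                           pd = pd, stable = stable)
  }
  # hand interpolation: pd 2.0 at log2 mid log2(0.1), 0.5 at log2(0.4)
  mids <- log2(c(0.1, 0.4))
  cr <- crossing_distance(mk_curve(c(2, 0.5), mids))
  x_expect <- mids[1] + (mids[2] - mids[1]) * (2 - 1) / (2 - 0.5)
  expect_equal(cr$distance, 2^x_expect, tolerance = 1e-12)
  expect_true(cr$crossed)

  cr2 <- crossing_distance(mk_curve(c(2, 1.5, 1.2), log2(c(0.1, 0.2, 0.4))))
  expect_identical(cr2$distance, Inf)
  expect_false(cr2$crossed)

  cr3 <- crossing_distance(mk_curve(c(1, 1), mids))
  expect_equal(cr3$distance, 0.1)

  cr4 <- crossing_distance(mk_curve(c(0.8, 0.5), mids))
  expect_false(cr4$crossed)
  expect_false(cr4$start_above)
  expect_true(is.na(cr4$distance))
})

test_that("rate normalization", {
  expect_equal(normalize_by_site_rate(0.5, 2), 1.0)
  expect_equal(normalize_by_site_rate(0.37, 1), 0.37)
  expect_error(normalize_by_site_rate(0.5, 0), "positive")
})
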