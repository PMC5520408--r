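test_that("discrete-gamma rates: limits and quadrature oracle", {
  expect_equal(discrete_gamma_rates(0.7, 1), 1)
  expect_true(all(abs(discrete_gamma_rates(1e6, 4) - 1) < 1e-2))
  for (alpha in c(0.2, 0.5, 1.3)) for (K in c(2, 4, 8)) {
    r <- discrete_gamma_rates(alpha, K)
    expect_equal(r, quad_gamma_rates(alpha, K), tolerance = 1e-6)
    expect_true(all(diff(r) > 0))
    expect_equal(mean(r), 1)
  }
  expect_error(discrete_gamma_rates(-1, 4), "positive")
})

test_that("rate model construction: scaling, reversibility, PAML order", {
  m <- fixture_model()
  expect_equal(rowSums(m$Q), rep(0, 20), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(-sum(m$pi * diag(m$Q)), 1, tolerance = 1e-12)
  P <- transition_matrix(m, 0.37)
  expect_equal(rowSums(P), rep(1, 20), tolerance = 1e-9, ignore_attr = TRUE)
  # detailed balance of a reversible model
  expect_lt(max(abs(m$pi * P - t(m$pi * P))), 1e-12)
  expect_equal(transition_matrix(m, 0), diag(20))

  # 190-vector input is row-major lower triangle (PAML file convention)
  v <- numeric(190); v[1] <- 7   # S[R, A] in row-major order
  m2 <- rate_model(v + 1, rep(0.05, 20), alpha = 1, K = 1)
  expect_equal(m2$S["R", "A"], 8)
  expect_equal(m2$S["A", "R"], 8)
})

test_that("site likelihood: trivial cases and enumeration oracle", {
  m <- fixture_model(alpha = 0.9, K = 2)
  # degenerate: two leaves at zero distance
  t0 <- read_tree_newick("(A:0,B:0)R;")
  col <- c(A = "L", B = "L")
  expect_equal(site_log_likelihood(t0, col, m),
               log(m$pi[["L"]]), tolerance = 1e-9)

  t3 <- read_tree_newick("((A:0.3,B:0.5)I:0.2,C:0.8)R;")
  for (column in list(c(A = "L", B = "F", C = "V"),
                      c(A = "K", B = "K", C = "K"),
                      c(A = "W", B = "C", C = "W"))) {
    o <- enum_site(t3, column, m)
    expect_equal(site_log_likelihood(t3, column, m), o$loglik,
                 tolerance = 1e-9)
  }
  expect_error(site_log_likelihood(t3, c(A = "L", B = "F"), m), "missing")
})

test_that("marginal posteriors equal enumeration on 3- and 4-leaf trees", {
  m <- fixture_model(alpha = 0.6, K = 3)
  t3 <- read_tree_newick("((A:0.3,B:0.5)I:0.2,C:0.8)R;")
  aln <- matrix(c("L", "F", "V"), 3, 1, dimnames = list(c("A", "B", "C"), NULL))
  st <- reconstruct_ancestral(t3, aln, m)
  o <- enum_site(t3, aln[, 1], m)
  for (ii in seq_along(o$internals))
    expect_equal(st$post[, 1, o$internals[ii]], o$post[, ii],
                 tolerance = 1e-9, ignore_attr = TRUE)

  t4 <- read_tree_newick("((A:0.2,B:0.4)I:0.3,(C:0.6,D:0.1)J:0.5)R;")
  aln4 <- matrix(c("K", "K", "R", "E"), 4, 1,
                 dimnames = list(c("A", "B", "C", "D"), NULL))
  st4 <- reconstruct_ancestral(t4, aln4, m)
  o4 <- enum_site(t4, aln4[, 1], m)
  for (ii in seq_along(o4$internals))
    expect_equal(st4$post[, 1, o4$internals[ii]], o4$post[, ii],
                 tolerance = 1e-9, ignore_attr = TRUE)
  # posteriors sum to 1 at every node and site
  expect_equal(apply(st4$post, c(2, 3), sum),
               matrix(1, 1, t4$n_node), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("closed form on a two-leaf tree with K = 1", {
  m <- fixture_model(alpha = 1, K = 1)
  t2 <- read_tree_newick("(A:0.4,B:0.9)R;")
  aln <- matrix(c("H", "Q"), 2, 1, dimnames = list(c("A", "B"), NULL))
  st <- reconstruct_ancestral(t2, aln, m)
  P1 <- transition_matrix(m, 0.4); P2 <- transition_matrix(m, 0.9)
  h <- match("H", AA20); q <- match("Q", AA20)
  expected <- m$pi * P1[, h] * P2[, q]
  expect_equal(st$post[, 1, t2$root], expected / sum(expected),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("reconstruction sanity: invariant columns, star trees, missing data", {
  m <- fixture_model()
  tree <- fixture_tree()
  aln <- matrix("L", 6, 2, dimnames = list(names(tree$tip_index), NULL))
  st <- reconstruct_ancestral(tree, aln, m)
  internal <- (tree$n_tip + 1):tree$n_node
  expect_true(all(st$map[internal, ] == "L"))
  expect_true(all(st$post["L", , internal] > m$pi[["L"]]))

  star <- suppressWarnings(as_pd_tree(ape::read.tree(text = "(A:0,B:0,C:0,D:0);")))
  alns <- matrix("K", 4, 1, dimnames = list(c("A", "B", "C", "D"), NULL))
  sts <- reconstruct_ancestral(star, alns, m)
  expect_true(all(sts$post["K", 1, star$root] >= sts$post[, 1, star$root]))

  # missing leaf data: uniform posterior, NA MAP, no fabricated substitution
  aln[1, 1] <- "-"
  stm <- reconstruct_ancestral(tree, aln, m)
  expect_equal(stm$post[, 1, 1], rep(1 / 20, 20), ignore_attr = TRUE)
  expect_true(is.na(stm$map[1, 1]))
  subs <- map_substitutions(tree, stm)
  expect_false(any(subs$edge == 1 & subs$site == 1))
})

test_that("likelihood is invariant to rerooting along a zero-length edge", {
  m <- fixture_model(alpha = 0.8, K = 2)
  # same unrooted tree, two rootings separated by a zero-length edge
  ta <- read_tree_newick("((A:0.3,B:0.5)I:0.0,(C:0.6,D:0.2)J:0.4)R;")
  tb <- read_tree_newick("(((C:0.6,D:0.2)J:0.4,B:0.5)I2:0.0,A:0.3)R;")
  stop_col <- function(tr) {
    aln <- matrix(c("A", "C", "D", "E"), 4, 1,
                  dimnames = list(c("A", "B", "C", "D"), NULL))
    site_log_likelihood(tr, aln, m)
  }
  expect_equal(stop_col(ta), stop_col(tb), tolerance = 1e-9)
})

test_that("substitution mapping from MAP states", {
  tree <- fixture_tree()
  m <- fixture_model()
  aln <- matrix("G", 6, 3, dimnames = list(names(tree$tip_index), NULL))
  st <- reconstruct_ancestral(tree, aln, m)
  expect_equal(nrow(map_substitutions(tree, st)), 0L)

  # force a clean substitution: A,B carry L; everyone else F at site 2
  aln[, 2] <- "F"; aln[c("A", "B"), 2] <- "L"
  st2 <- reconstruct_ancestral(tree, aln, m)
  subs <- map_substitutions(tree, st2)
  expect_true(all(subs$site == 2))
  expect_true(all(subs$B != subs$A))
  # posteriors recorded are the states' own node posteriors
  expect_true(all(subs$post_B >= 0 & subs$post_B <= 1))
})

test_that("MAP recovery: most true single-event edges are found", {
  tree <- random_calibration_tree(40, 8, seed = 5)
  m <- default_rate_model(alpha = 1, K = 2)
  sim <- simulate_evolution(sim_config(tree, m, n_sites = 60, mode = "null",
                                       seed = 4))
  st <- reconstruct_ancestral(tree, sim$aln, m)
  subs <- map_substitutions(tree, st)
  ev <- sim$truth$events
  one <- ev[, .N, by = .(site, edge)][N == 1]
  ev1 <- ev[one, on = c("site", "edge")]
  hit <- subs[ev1, on = c("site", "edge"), nomatch = NULL]
  expect_gte(nrow(hit) / nrow(ev1), 0.8)
})

test_that("PAML-style matrix files are parsed and feed the model", {
  f <- tempfile(fileext = ".dat")
  set.seed(12)
  vals <- round(runif(190, 0.1, 10), 4)
  freqs <- round(runif(20, 1, 5), 4); freqs <- freqs / sum(freqs)
  writeLines(c("# comment line",
               paste(vals, collapse = " "),
               paste(round(freqs, 6), collapse = " ")), f)
  got <- read_paml_matrix(f)
  expect_equal(got$exchangeabilities, vals)
  expect_length(got$freqs, 20L)
  m <- rate_model(got$exchangeabilities, got$freqs, alpha = 1, K = 2)
  expect_equal(-sum(m$pi * diag(m$Q)), 1, tolerance = 1e-12)
  # truncated file is rejected
  writeLines(paste(vals[1:100], collapse = " "), f)
  expect_error(read_paml_matrix(f), "190")
})

test_that("ancestral TSV round-trip preserves MAP states and rates", {
  tree <- fixture_tree()
  m <- fixture_model()
  aln <- matrix(sample(c("L", "F", "V"), 18, TRUE), 6, 3,
                dimnames = list(names(tree$tip_index), NULL))
  st <- reconstruct_ancestral(tree, aln, m)
  f <- tempfile(fileext = ".tsv")
  write_ancestral_tsv(st, f)
  st2 <- read_ancestral_tsv(f, n_tip = tree$n_tip)
  expect_equal(st2$map, st$map)
  expect_equal(st2$map_post, st$map_post, tolerance = 1e-6)
  expect_equal(st2$site_rate, st$site_rate, tolerance = 1e-6)
  expect_equal(map_substitutions(tree, st2), map_substitutions(tree, st))
})
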