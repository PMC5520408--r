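# Independent brute-force oracles used to freeze expected values.  These
# deliberately avoid the package's cached LCA tables and pruning code.

# path to root as (node, parent-edge-length) pairs, by climbing
climb_path <- function(tree, v) {
  nodes <- integer(0); lens <- numeric(0)
  while (v != tree$root) {
    nodes <- c(nodes, v); lens <- c(lens, tree$edge_len[v])
    v <- tree$parent[v]
  }
  list(nodes = nodes, lens = lens)
}

bf_patristic <- function(tree, a, b) {
  pa <- climb_path(tree, a); pb <- climb_path(tree, b)
  # drop the shared tail of the two root paths
  ka <- pa$nodes; kb <- pb$nodes
  common <- intersect(ka, kb)
  sum(pa$lens[!ka %in% common]) + sum(pb$lens[!kb %in% common])
}

bf_is_ancestral_edge <- function(tree, e1, e2) {
  # TRUE if edge e1 lies on the root path of e2 or vice versa, or identical
  if (e1 == e2) return(TRUE)
  e1 %in% climb_path(tree, e2)$nodes || e2 %in% climb_path(tree, e1)$nodes
}

# shortest path between edge midpoints through the tree graph (igraph)
bf_mid_edge <- function(tree, e1, e2) {
  N <- tree$n_node
  from <- tree$parent[tree$edges]
  to <- tree$edges
  w <- tree$edge_len[tree$edges]
  # split e1 and e2 with midpoint vertices N+1, N+2
  keep <- !(to %in% c(e1, e2))
  ed <- cbind(from[keep], to[keep]); ww <- w[keep]
  ed <- rbind(ed,
              c(tree$parent[e1], N + 1L), c(N + 1L, e1),
              c(tree$parent[e2], N + 2L), c(N + 2L, e2))
  ww <- c(ww, tree$edge_len[e1] / 2, tree$edge_len[e1] / 2,
          tree$edge_len[e2] / 2, tree$edge_len[e2] / 2)
  g <- igraph::graph_from_edgelist(apply(ed, 2, as.character), directed = FALSE)
  igraph::E(g)$weight <- ww
  igraph::distances(g, as.character(N + 1L), as.character(N + 2L))[1, 1]
}

# triple-loop pair enumeration from a substitution table
bf_pairs <- function(subs, tree) {
  out <- list()
  n <- nrow(subs)
  if (n < 2) return(data.frame())
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (subs$site[i] != subs$site[j]) next
    if (subs$B[i] != subs$B[j]) next
    if (bf_is_ancestral_edge(tree, subs$edge[i], subs$edge[j])) next
    out[[length(out) + 1L]] <- data.frame(
      site = subs$site[i], B = subs$B[i],
      kind = if (subs$A[i] == subs$A[j]) "parallel" else "divergent",
      e1 = min(subs$edge[i], subs$edge[j]),
      e2 = max(subs$edge[i], subs$edge[j]),
      dist = bf_mid_edge(tree, subs$edge[i], subs$edge[j]))
  }
  do.call(rbind, out)
}

# full enumeration likelihood/posteriors for small trees (any K)
enum_site <- function(tree, column, model) {
  internals <- setdiff(seq_len(tree$n_node), seq_len(tree$n_tip))
  leaf_state <- match(column[names(tree$tip_index)], AA20)
  combos <- as.matrix(expand.grid(rep(list(1:20), length(internals))))
  lik_k <- matrix(0, nrow(combos), model$K)
  for (k in seq_len(model$K)) {
    P <- lapply(seq_len(tree$n_node), function(e)
      if (e == tree$root) NULL
      else transition_matrix(model, model$rates[k] * tree$edge_len[e]))
    state_of <- function(v, row) {
      if (v <= tree$n_tip) leaf_state[v] else combos[row, match(v, internals)]
    }
    for (row in seq_len(nrow(combos))) {
      p <- model$pi[state_of(tree$root, row)]
      for (e in tree$edges)
        p <- p * P[[e]][state_of(tree$parent[e], row), state_of(e, row)]
      lik_k[row, k] <- p
    }
  }
  lik <- rowMeans(lik_k)   # equal category priors
  post <- sapply(seq_along(internals), function(ii)
    vapply(1:20, function(a) sum(lik[combos[, ii] == a]), 0) / sum(lik))
  list(loglik = log(sum(lik)), post = post, internals = internals)
}

# mean-within-quantile gamma rates by numerical quadrature
quad_gamma_rates <- function(alpha, K) {
  q <- qgamma(seq(0, 1, length.out = K + 1), shape = alpha, rate = alpha)
  r <- vapply(seq_len(K), function(i)
    integrate(function(x) x * dgamma(x, alpha, rate = alpha),
              q[i], q[i + 1], rel.tol = 1e-10)$value * K, 0)
  r / mean(r)
}

# accessibility by independent scan over all codon pairs
bf_accessible <- function(code, mode = "every") {
  codons <- names(code)
  nt <- function(x) strsplit(x, "")[[1]]
  one_step <- outer(codons, codons, Vectorize(function(a, b)
    sum(nt(a) != nt(b)) == 1L))
  dimnames(one_step) <- list(codons, codons)
  acc <- matrix(FALSE, 20, 20, dimnames = list(AA20, AA20))
  for (B in AA20) for (A in AA20) {
    if (A == B) next
    bc <- codons[code == B]; ac <- codons[code == A]
    if (!length(bc) || !length(ac)) next
    hit <- vapply(bc, function(cb) any(one_step[cb, ac]), TRUE)
    acc[B, A] <- if (mode == "every") all(hit) else any(hit)
  }
  acc
}

# Spearman rho with midranks, by hand
bf_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# small fixture: a 6-leaf tree with supports and varied branch lengths
fixture_tree <- function() {
  read_tree_newick(
    "(((A:0.10,B:0.20)100:0.30,(C:0.15,D:0.05)95:0.25)80:0.40,(E:0.50,F:0.60)100:0.10)R;")
}

# tiny model with fewer frequencies asymmetries, quick to exponentiate
fixture_model <- function(alpha = 0.7, K = 2) {
  set.seed(99)
  S <- matrix(runif(400, 0.2, 2), 20, 20); S <- (S + t(S)) / 2; diag(S) <- 0
  f <- runif(20, 0.5, 2); f <- f / sum(f)
  rate_model(S, f, alpha = alpha, K = K)
}
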