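# Marginal maximum likelihood ancestral reconstruction by the pruning
# algorithm, with empirical-Bayes averaging over discrete-gamma rate
# categories.  This plays the role codeml's marginal reconstruction plays in
# the original analysis pipeline.

# per-category transition matrices for every edge
edge_transition_matrices <- function(tree, model) {
  lapply(seq_len(model$K), function(k) {
    r <- model$rates[k]
    out <- vector("list", tree$n_node)
    for (e in tree$edges) out[[e]] <- transition_matrix(model, r * tree$edge_len[e])
    out
  })
}

# postorder node order (children before parents)
postorder_nodes <- function(tree) {
  ord <- integer(0)
  stack <- tree$root
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    ord <- c(v, ord)
    kids <- tree$children[[v]]
    if (length(kids)) stack <- c(kids, stack)
  }
  ord   # reversed preorder = valid postorder
}

# leaf partial likelihoods: 20 x S, 1s for missing data
leaf_partials <- function(states_row) {
  S <- length(states_row)
  F <- matrix(0, 20L, S)
  miss <- is.na(states_row)
  if (any(miss)) F[, miss] <- 1
  if (any(!miss)) F[cbind(states_row[!miss], which(!miss))] <- 1
  F
}

#' Site log-likelihoods of an alignment on a tree
#'
#' Felsenstein pruning under a [rate_model()], averaging transition
#' probabilities over the discrete-gamma categories with equal prior weight.
#'
#' @param tree a `pd_tree`.
#' @param aln character matrix (taxa x sites) or a single named character
#'   vector for one column; names must match the tree's leaf names exactly.
#' @param model a `rate_model`.
#' @return numeric vector of per-site log-likelihoods.
#' @export
site_log_likelihood <- function(tree, aln, model) {
  tree <- as_pd_tree(tree)
  if (is.null(dim(aln))) aln <- matrix(aln, ncol = 1, dimnames = list(names(aln), NULL))
  fit <- prune_all(tree, aln, model)
  fit$loglik
}

# core machinery: down (partials) and up (outside) passes for all categories.
# Returns per-category partials, scalers and root likelihoods.
prune_all <- function(tree, aln, model, want_up = FALSE) {
  miss <- setdiff(names(tree$tip_index), rownames(aln))
  extra <- setdiff(rownames(aln), names(tree$tip_index))
  if (length(miss)) stopf("leaves missing from alignment: %s",
                          paste(utils::head(miss, 5), collapse = ", "))
  if (length(extra)) stopf("alignment rows not in tree: %s",
                           paste(utils::head(extra, 5), collapse = ", "))
  st <- encode_alignment(aln)
  S <- ncol(st)
  K <- model$K
  N <- tree$n_node
  Ps <- edge_transition_matrices(tree, model)
  post_ord <- postorder_nodes(tree)

  Fk <- vector("list", K)     # Fk[[k]][[v]]: 20 x S partials (rescaled)
  logfk <- vector("list", K)  # logfk[[k]]: N x S log scalers
  Xk <- vector("list", K)     # Xk[[k]][[v]]: P_v %*% F_v, cached for the up pass
  logLk <- matrix(0, K, S)    # per-category per-site log-likelihood

  for (k in seq_len(K)) {
    F <- vector("list", N)
    X <- vector("list", N)
    logf <- matrix(0, N, S)
    for (v in post_ord) {
      kids <- tree$children[[v]]
      if (!length(kids)) {
        F[[v]] <- leaf_partials(st[names(tree$tip_index)[v], ])
      } else {
        acc <- matrix(1, 20L, S)
        for (c in kids) {
          X[[c]] <- Ps[[k]][[c]] %*% F[[c]]
          acc <- acc * X[[c]]
          logf[v, ] <- logf[v, ] + logf[c, ]
        }
        mx <- apply(acc, 2L, max)
        mx[mx == 0] <- 1   # all-zero column would mean impossible data
        F[[v]] <- acc / rep(mx, each = 20L)
        logf[v, ] <- logf[v, ] + log(mx)
      }
      if (v == tree$root) {
        Lroot <- colSums(model$pi * F[[v]])
        logLk[k, ] <- log(Lroot) + logf[v, ]
      }
    }
    Fk[[k]] <- F; logfk[[k]] <- logf; Xk[[k]] <- X
  }
  # total log-likelihood per site: log mean_k exp(logLk)
  mx <- apply(logLk, 2L, max)
  loglik <- mx + log(colMeans(exp(sweep(logLk, 2L, mx))))

  out <- list(states = st, S = S, K = K, Ps = Ps, Fk = Fk, logfk = logfk,
              logLk = logLk, loglik = loglik, post_ord = post_ord)
  if (!want_up) return(out)

  Gk <- vector("list", K)     # outside messages, 20 x S per node
  loggk <- vector("list", K)
  pre_ord <- rev(post_ord)
  for (k in seq_len(K)) {
    G <- vector("list", N)
    logg <- matrix(0, N, S)
    G[[tree$root]] <- matrix(model$pi, 20L, S)
    for (v in pre_ord) {
      kids <- tree$children[[v]]
      if (length(kids) == 0) next
      # prefix/suffix products of sibling messages around each child
      nk <- length(kids)
      for (ci in seq_len(nk)) {
        c <- kids[ci]
        W <- G[[v]]
        lg <- logg[v, ]
        for (s in kids[-ci]) {
          W <- W * Xk[[k]][[s]]
          lg <- lg + logfk[[k]][s, ]
        }
        Gc <- crossprod(Ps[[k]][[c]], W)   # t(P) %*% W
        mx2 <- apply(Gc, 2L, max)
        mx2[mx2 == 0] <- 1
        G[[c]] <- Gc / rep(mx2, each = 20L)
        logg[c, ] <- lg + log(mx2)
      }
    }
    Gk[[k]] <- G; loggk[[k]] <- logg
  }
  out$Gk <- Gk; out$loggk <- loggk
  out
}

#' Marginal ancestral state reconstruction
#'
#' Computes, for every node and site, the marginal posterior distribution
#' over the 20 amino acids given the leaf data, integrating over the
#' discrete-gamma rate categories with their posterior weights
#' (empirical Bayes).  Also returns the maximum a posteriori (MAP) state per
#' node and site (ties broken alphabetically by one-letter code) and the
#' posterior-mean relative rate of each site.
#'
#' Leaf posteriors are point masses on the observed state; fully missing
#' leaf states get a uniform posterior and an `NA` MAP so that no
#' substitution is ever fabricated on their pendant edge.
#'
#' @param tree a `pd_tree`.
#' @param aln character matrix (taxa x sites), rownames matching leaf names.
#' @param model a `rate_model`; when NULL, [default_rate_model()] with
#'   alignment-derived frequencies.
#' @return object of class `ancestral_states`: list with `post`
#'   (20 x sites x nodes array), `map` (nodes x sites character), `map_post`
#'   (nodes x sites, posterior of the MAP state), `site_rate` (posterior-mean
#'   rate per site), `cat_post` (K x sites), `loglik` (per site).
#' @export
reconstruct_ancestral <- function(tree, aln, model = NULL) {
  tree <- as_pd_tree(tree)
  if (is.null(model)) model <- default_rate_model(freqs = aln)
  fit <- prune_all(tree, aln, model, want_up = TRUE)
  S <- fit$S; K <- fit$K; N <- tree$n_node

  post <- array(0, dim = c(20L, S, N),
                dimnames = list(AA20, NULL, NULL))
  # per-category site weights on the common log scale
  mxL <- apply(fit$logLk, 2L, max)
  wk <- exp(sweep(fit$logLk, 2L, mxL))          # K x S, relative likelihoods
  wk <- sweep(wk, 2L, colSums(wk), "/")         # P(category | site)

  internal <- setdiff(seq_len(N), seq_len(tree$n_tip))
  for (v in internal) {
    acc <- matrix(0, 20L, S)
    # combine categories on a per-site common scale
    lsc <- sapply(seq_len(K), function(k) fit$logfk[[k]][v, ] + fit$loggk[[k]][v, ])
    if (S == 1L) lsc <- matrix(lsc, nrow = 1L)
    mxv <- apply(lsc, 1L, max)                  # per site
    for (k in seq_len(K)) {
      raw <- fit$Fk[[k]][[v]] * fit$Gk[[k]][[v]]
      acc <- acc + raw * rep(exp(lsc[, k] - mxv), each = 20L)
    }
    post[, , v] <- sweep(acc, 2L, colSums(acc), "/")
  }
  # leaves: point masses; missing -> uniform
  for (v in seq_len(tree$n_tip)) {
    row <- fit$states[names(tree$tip_index)[v], ]
    P <- matrix(0, 20L, S)
    isna <- is.na(row)
    if (any(isna)) P[, isna] <- 1 / 20
    if (any(!isna)) P[cbind(row[!isna], which(!isna))] <- 1
    post[, , v] <- P
  }

  # MAP with alphabetical tie-break
  alpha_rank <- order(order(AA20))   # rank of each AA20 entry alphabetically
  map <- matrix(NA_character_, N, S)
  map_post <- matrix(NA_real_, N, S)
  for (v in seq_len(N)) {
    P <- post[, , v]
    if (S == 1L) P <- matrix(P, ncol = 1L)
    mx <- apply(P, 2L, max)
    # add a tiny alphabetical bonus to break exact ties deterministically
    tie <- P >= rep(mx, each = 20L) - 1e-12
    pick <- apply(tie, 2L, function(z) which(z)[which.min(alpha_rank[which(z)])])
    map[v, ] <- AA20[pick]
    map_post[v, ] <- P[cbind(pick, seq_len(S))]
  }
  # missing leaves: MAP is undefined, not 'A'
  for (v in seq_len(tree$n_tip)) {
    row <- fit$states[names(tree$tip_index)[v], ]
    map[v, is.na(row)] <- NA_character_
  }

  structure(list(post = post, map = map, map_post = map_post,
                 site_rate = as.numeric(model$rates %*% wk),
                 cat_post = wk, loglik = fit$loglik,
                 n_tip = tree$n_tip, model = model),
            class = "ancestral_states")
}

#' @export
print.ancestral_states <- function(x, ...) {
  cat(sprintf("ancestral_states: %d nodes x %d sites, logL = %.3f\n",
              dim(x$post)[3], dim(x$post)[2], sum(x$loglik)))
  invisible(x)
}

#' Map substitutions onto edges from MAP states
#'
#' One substitution per (edge, site) where the MAP state changes between the
#' parent and the child node.  Multiple hits within one edge are invisible
#' by construction, exactly as in a MAP-to-MAP reconstruction.  Edges whose
#' child is a leaf with missing data at a site contribute nothing there.
#'
#' @param tree a `pd_tree`.
#' @param states an `ancestral_states`.
#' @return `data.table` with columns `site`, `edge` (child node id),
#'   `B` (ancestral), `A` (derived), `post_B` (parent-node posterior of B),
#'   `post_A` (child-node posterior of A).
#' @export
map_substitutions <- function(tree, states) {
  tree <- as_pd_tree(tree)
  S <- ncol(states$map)
  rows <- list()
  for (e in tree$edges) {
    p <- tree$parent[e]
    diffs <- which(states$map[p, ] != states$map[e, ])  # NA-safe: NA drops out
    if (!length(diffs)) next
    B <- states$map[p, diffs]; A <- states$map[e, diffs]
    rows[[length(rows) + 1L]] <- data.table::data.table(
      site = diffs, edge = e, B = B, A = A,
      post_B = states$post[cbind(match(B, AA20), diffs, p)],
      post_A = states$post[cbind(match(A, AA20), diffs, e)])
  }
  if (!length(rows))
    return(data.table::data.table(site = integer(), edge = integer(),
                                  B = character(), A = character(),
                                  post_B = numeric(), post_A = numeric()))
  out <- data.table::rbindlist(rows)
  data.table::setorder(out, site, edge)
  out[]
}

#' Write / read ancestral MAP states as TSV
#'
#' The table holds one row per (node, site): node id, 1-based site, MAP
#' state, and its posterior probability; per-site rates are included as
#' extra rows with `node = 0` and the rate in the `map_post` column so a
#' single flat file round-trips everything external tools need.
#'
#' @param states an `ancestral_states`.
#' @param path output TSV path.
#' @export
write_ancestral_tsv <- function(states, path) {
  N <- nrow(states$map); S <- ncol(states$map)
  tab <- data.table::data.table(
    node = rep(seq_len(N), S),
    site = rep(seq_len(S), each = N),
    map = as.vector(states$map),
    map_post = as.vector(states$map_post))
  rates <- data.table::data.table(node = 0L, site = seq_len(S),
                                  map = "", map_post = states$site_rate)
  data.table::fwrite(rbind(tab, rates), path, sep = "\t")
  invisible(path)
}

#' @rdname write_ancestral_tsv
#' @param n_tip number of leaves in the matching tree (leaf rows are point
#'   masses when importing).
#' @return for the reader: an `ancestral_states` with degenerate posteriors
#'   (mass `map_post` on the MAP state, remainder uniform), suitable for
#'   substitution mapping and the high-confidence filter.
#' @export
read_ancestral_tsv <- function(path, n_tip) {
  tab <- data.table::fread(path, sep = "\t")
  rates <- tab[tab$node == 0L, ]
  tab <- tab[tab$node > 0L, ]
  N <- max(tab$node); S <- max(tab$site)
  map <- matrix(NA_character_, N, S)
  map_post <- matrix(NA_real_, N, S)
  map[cbind(tab$node, tab$site)] <- ifelse(nzchar(tab$map), tab$map, NA)
  map_post[cbind(tab$node, tab$site)] <- tab$map_post
  post <- array(NA_real_, dim = c(20L, S, N), dimnames = list(AA20, NULL, NULL))
  for (v in seq_len(N)) for (s in seq_len(S)) {
    if (is.na(map[v, s])) { post[, s, v] <- 1 / 20; next }
    p <- map_post[v, s]
    post[, s, v] <- (1 - p) / 19
    post[match(map[v, s], AA20), s, v] <- p
  }
  site_rate <- rep(1, S)
  if (nrow(rates)) site_rate[rates$site] <- rates$map_post
  structure(list(post = post, map = map, map_post = map_post,
                 site_rate = site_rate, cat_post = NULL, loglik = NULL,
                 n_tip = n_tip, model = NULL, imported = TRUE),
            class = "ancestral_states")
}
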