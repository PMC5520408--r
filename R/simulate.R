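# Event-level (Gillespie) amino acid sequence simulator with truth logging.
#
# Three modes:
#   null          - one time-homogeneous rate matrix everywhere
#   clade_matrices- a different rate matrix for each clade of the tree
#   spfl_switch   - the positive control: each site carries a set of k
#                   "permitted" amino acids (its single-position fitness
#                   landscape); at Poisson switch points along branches one
#                   permitted member is swapped for one prohibited one, so
#                   the landscape drifts gradually, the way a two-state
#                   permitted/prohibited fitness process behaves.
#                   Substitutions into non-permitted states have rate zero
#                   (total rate shrinks, no renormalization); when the
#                   current state is the member swapped out, the site jumps
#                   immediately to a random permitted state (logged as a
#                   forced event)
#
# Every (site, edge) consumes its own RNG substream derived from the master
# seed by stable hashing, so adding sites or reordering edges never perturbs
# the realization of earlier sites.

#' Simulation configuration
#'
#' @param tree a `pd_tree` (or `phylo`).
#' @param model a `rate_model` (root frequencies, rate matrix, gamma rates).
#' @param n_sites number of independent sites.
#' @param mode `"null"`, `"clade_matrices"` or `"spfl_switch"`.
#' @param lambda switch rate per unit branch length (spfl_switch only, >= 0).
#' @param k_permitted size of the permitted amino acid set (2..20).
#' @param clade_models named list of `rate_model`s keyed by subtree-root node
#'   id (clade_matrices only); each edge uses the model of its nearest
#'   ancestral key, and every edge must be covered.
#' @param seed master seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(tree, model, n_sites = 300L,
                       mode = c("null", "clade_matrices", "spfl_switch"),
                       lambda = 0, k_permitted = 5L, clade_models = NULL,
                       seed = 1L) {
  mode <- match.arg(mode)
  tree <- as_pd_tree(tree)
  if (lambda < 0) stopf("lambda must be >= 0")
  k_permitted <- as.integer(k_permitted)
  if (mode == "spfl_switch" && (k_permitted < 2L || k_permitted > 20L))
    stopf("k_permitted must be in 2..20")
  if (mode == "clade_matrices") {
    if (is.null(clade_models) || is.null(names(clade_models)))
      stopf("clade_matrices mode needs a named list of clade models")
    cov <- clade_model_index(tree, as.integer(names(clade_models)))
    if (any(is.na(cov))) stopf("clade keys do not cover edge(s): %s",
                               paste(utils::head(tree$edges[is.na(cov)], 5), collapse = ", "))
  }
  structure(list(tree = tree, model = model, n_sites = as.integer(n_sites),
                 mode = mode, lambda = lambda, k_permitted = k_permitted,
                 clade_models = clade_models, seed = as.integer(seed)),
            class = "sim_config")
}

# for each edge (child id), which clade key governs it: the nearest
# ancestor-or-self key of the child node
clade_model_index <- function(tree, keys) {
  out <- rep(NA_integer_, tree$n_node)
  for (e in tree$edges) {
    path <- tree$anc_path[[e]]
    hit <- path[path %in% keys]
    if (length(hit)) out[e] <- match(hit[1], keys)
  }
  out[tree$edges]
}

# one Gillespie pass along one edge; returns final state/permitted set and
# event log rows.  All randomness comes from the caller's current RNG state.
evolve_edge <- function(state, permitted, len, Q, r, lambda, spfl, k) {
  events <- list()
  tau <- 0
  repeat {
    rates <- Q[state, ] * r
    rates[state] <- 0
    if (spfl) rates[!permitted] <- 0
    tot <- sum(rates)
    t_sub <- if (tot > 0) rexp(1L, tot) else Inf
    t_sw <- if (spfl && lambda > 0) rexp(1L, lambda) else Inf
    dt <- min(t_sub, t_sw)
    if (tau + dt > len) break
    tau <- tau + dt
    if (t_sub <= t_sw) {
      to <- sample.int(20L, 1L, prob = rates)
      events[[length(events) + 1L]] <- c(pos = tau, from = state, to = to,
                                         forced = 0, switch = 0)
      state <- to
    } else {
      # landscape update: swap one permitted member for one prohibited one
      inn <- which(permitted); out <- which(!permitted)
      if (!length(out)) next   # k = 20: the landscape has nothing to change
      drop_aa <- inn[sample.int(length(inn), 1L)]
      add_aa <- out[sample.int(length(out), 1L)]
      permitted[drop_aa] <- FALSE
      permitted[add_aa] <- TRUE
      events[[length(events) + 1L]] <- c(pos = tau, from = state, to = state,
                                         forced = 0, switch = 1)
      if (!permitted[state]) {
        to <- sample.int(20L, 1L, prob = as.numeric(permitted))
        events[[length(events) + 1L]] <- c(pos = tau, from = state, to = to,
                                           forced = 1, switch = 0)
        state <- to
      }
    }
  }
  list(state = state, permitted = permitted, events = events)
}

#' Simulate amino acid evolution with truth logging
#'
#' Draws a rate category and a root state per site, then evolves each site
#' down the tree by event-level sampling under the configured mode.  The
#' returned truth log records every true event (including multiple hits on
#' one edge, which a MAP reconstruction cannot see) with its position along
#' the edge, plus all permitted-set switches.
#'
#' @param config a [sim_config()].
#' @return list with `aln` (leaf character matrix), `truth` (list:
#'   `node_states` nodes x sites character matrix, `events` data.table with
#'   `site`, `edge`, `pos` (distance from the parent node), `from`, `to`,
#'   `forced`, `switches` data.table, `site_rate`, `site_category`), and the
#'   echoed `config`.
#' @export
simulate_evolution <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tree <- config$tree; model <- config$model
  S <- config$n_sites; N <- tree$n_node
  spfl <- config$mode == "spfl_switch"
  K <- model$K; rates <- model$rates
  pre <- rev(postorder_nodes(tree))

  Qs <- list(model$Q)
  qidx <- rep(1L, N)
  if (config$mode == "clade_matrices") {
    Qs <- lapply(config$clade_models, function(m) m$Q)
    qidx_e <- clade_model_index(tree, as.integer(names(config$clade_models)))
    qidx <- rep(NA_integer_, N); qidx[tree$edges] <- qidx_e
  } else {
    qidx <- rep(1L, N)
  }

  node_states <- matrix(NA_integer_, N, S)
  ev_rows <- list()
  sw_rows <- list()
  site_cat <- integer(S)

  old_rng <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_rng)) assign(".Random.seed", old_rng, globalenv()))

  for (s in seq_len(S)) {
    set.seed(hash_seed(config$seed, s, 0L))
    site_cat[s] <- sample.int(K, 1L)
    r <- rates[site_cat[s]]
    permitted <- rep(TRUE, 20L)
    if (spfl) {
      permitted[] <- FALSE
      permitted[sample.int(20L, config$k_permitted)] <- TRUE
      p0 <- model$pi * permitted
      root_state <- sample.int(20L, 1L, prob = p0 / sum(p0))
    } else {
      root_state <- sample.int(20L, 1L, prob = model$pi)
    }
    node_states[tree$root, s] <- root_state
    perm_at <- vector("list", N)
    perm_at[[tree$root]] <- permitted

    for (v in pre) {
      if (v == tree$root) next
      set.seed(hash_seed(config$seed, s, v))
      res <- evolve_edge(node_states[tree$parent[v], s],
                         perm_at[[tree$parent[v]]],
                         tree$edge_len[v], Qs[[qidx[v]]], r,
                         config$lambda, spfl, config$k_permitted)
      node_states[v, s] <- res$state
      perm_at[[v]] <- res$permitted
      for (ev in res$events) {
        if (ev[["switch"]] == 1) {
          sw_rows[[length(sw_rows) + 1L]] <-
            c(site = s, edge = v, pos = ev[["pos"]])
        } else {
          ev_rows[[length(ev_rows) + 1L]] <-
            c(site = s, edge = v, pos = ev[["pos"]], from = ev[["from"]],
              to = ev[["to"]], forced = ev[["forced"]])
        }
      }
    }
  }

  events <- if (length(ev_rows)) {
    m <- do.call(rbind, ev_rows)
    data.table::data.table(site = as.integer(m[, "site"]),
                           edge = as.integer(m[, "edge"]),
                           pos = m[, "pos"],
                           from = AA20[m[, "from"]], to = AA20[m[, "to"]],
                           forced = m[, "forced"] == 1)
  } else data.table::data.table(site = integer(), edge = integer(),
                                pos = numeric(), from = character(),
                                to = character(), forced = logical())
  switches <- if (length(sw_rows)) {
    m <- do.call(rbind, sw_rows)
    data.table::data.table(site = as.integer(m[, "site"]),
                           edge = as.integer(m[, "edge"]), pos = m[, "pos"])
  } else data.table::data.table(site = integer(), edge = integer(),
                                pos = numeric())

  aln <- matrix(AA20[node_states[seq_len(tree$n_tip), , drop = FALSE]],
                tree$n_tip, S)
  rownames(aln) <- names(tree$tip_index)

  list(aln = aln,
       truth = list(node_states = matrix(AA20[node_states], N, S),
                    events = events, switches = switches,
                    site_rate = rates[site_cat], site_category = site_cat),
       config = config)
}

#' Substitution pairs from the simulator truth log
#'
#' Applies the same classification rules as [enumerate_all_pairs()] to the
#' true events: same site, same source amino acid, phylogenetically
#' independent edges; parallel when the targets agree.  Distances are
#' measured between the actual event positions on their edges (not the edge
#' midpoints).
#'
#' @param truth the `truth` element returned by [simulate_evolution()].
#' @param tree the simulated-on `pd_tree`.
#' @param include_forced include forced (post-switch) jump events.
#' @return pair table with the same core columns as [enumerate_all_pairs()]
#'   (posterior columns set to 1).
#' @export
truth_substitution_pairs <- function(truth, tree, include_forced = TRUE) {
  tree <- as_pd_tree(tree)
  ev <- data.table::as.data.table(truth$events)
  if (!include_forced) ev <- ev[forced == FALSE]
  if (nrow(ev) == 0L) return(empty_pairs())
  ev[, id := .I]
  g <- ev[, .(i = list(.I)), by = .(site, from)]
  ii <- integer(0); jj <- integer(0)
  for (idx in g$i) {
    if (length(idx) < 2L) next
    cmb <- utils::combn(idx, 2L)
    ii <- c(ii, cmb[1L, ]); jj <- c(jj, cmb[2L, ])
  }
  if (!length(ii)) return(empty_pairs())
  e1 <- ev$edge[ii]; e2 <- ev$edge[jj]
  keep <- e1 != e2 & is_independent_safe(tree, e1, e2)
  ii <- ii[keep]; jj <- jj[keep]
  if (!length(ii)) return(empty_pairs())
  e1 <- ev$edge[ii]; e2 <- ev$edge[jj]
  p1 <- tree$parent[e1]; p2 <- tree$parent[e2]
  dl <- tree$lca_depth[cbind(e1, e2)]
  d <- (tree$depth[p1] + ev$pos[ii] - dl) + (tree$depth[p2] + ev$pos[jj] - dl)
  A1 <- ev$to[ii]; A2 <- ev$to[jj]
  swap <- A2 < A1
  tmp <- A1[swap]; A1[swap] <- A2[swap]; A2[swap] <- tmp
  out <- data.table::data.table(
    site = ev$site[ii], B = ev$from[ii], A1 = A1, A2 = A2,
    kind = ifelse(A1 == A2, "parallel", "divergent"),
    e1 = e1, e2 = e2, dist = d, ndist = NA_real_,
    post_B1 = 1, post_A1 = 1, post_B2 = 1, post_A2 = 1)
  data.table::setorder(out, site, B, e1, e2)
  out[]
}

# vectorized independence without the same-edge error path (same-edge pairs
# are simply FALSE here: two events on one edge are not independent)
is_independent_safe <- function(tree, e1, e2) {
  l <- tree$lca_node[cbind(e1, e2)]
  e1 != e2 & l != e1 & l != e2
}

#' Write simulator output to plain-text files
#'
#' FASTA alignment, newick tree, and TSV truth tables, with the
#' configuration echoed as `#` header lines in the truth file.
#'
#' @param sim result of [simulate_evolution()].
#' @param dir output directory (created if needed).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta_alignment(sim$aln, file.path(dir, "alignment.fasta"))
  write_tree_newick(sim$config$tree, file.path(dir, "tree.nwk"))
  hdr <- sprintf("# mode=%s n_sites=%d lambda=%g k_permitted=%d seed=%d",
                 sim$config$mode, sim$config$n_sites, sim$config$lambda,
                 sim$config$k_permitted, sim$config$seed)
  ef <- file.path(dir, "truth_events.tsv")
  writeLines(hdr, ef)
  suppressWarnings(utils::write.table(sim$truth$events, ef, sep = "\t",
                                      row.names = FALSE, quote = FALSE,
                                      append = TRUE))
  invisible(dir)
}
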