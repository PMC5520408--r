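# End-to-end orchestration: reconstruction -> substitution mapping ->
# filters -> pair enumeration -> matched subsampling -> P/D statistics,
# with TSV outputs and a reproducible run log.

#' Load a flat key=value run configuration
#'
#' Recognized keys: `tree`, `alignment`, `states` (optional precomputed
#' ancestral-state TSV), `site_mask` (optional TSV), `gap_threshold`,
#' `accessibility` (true/false), `code_table`, `high_confidence`,
#' `support_min`, `posterior_min`, `normalize_rates`, `alpha`, `gamma_categories`,
#' `matrix` (optional PAML-style file), `bootstrap_reps`, `min_divergent`,
#' `seed`, `out_dir`.  Lines starting with `#` are ignored.
#'
#' @param path config file path.
#' @return named list of class `run_config`.
#' @export
load_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stopf("malformed config line: %s", lines[bad][1])
  cfg <- setNames(lapply(kv, `[[`, 2L), vapply(kv, `[[`, "", 1L))
  for (k in c("tree", "alignment", "states", "site_mask", "matrix"))
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]]))
      stopf("config path does not exist: %s = %s", k, cfg[[k]])
  num <- function(k, d) if (is.null(cfg[[k]])) d else as.numeric(cfg[[k]])
  flag <- function(k, d) if (is.null(cfg[[k]])) d else tolower(cfg[[k]]) %in% c("true", "1", "yes")
  out <- list(tree = cfg$tree, alignment = cfg$alignment, states = cfg$states,
              site_mask = cfg$site_mask, matrix = cfg$matrix,
              gap_threshold = num("gap_threshold", 0.01),
              accessibility = flag("accessibility", FALSE),
              code_table = as.integer(num("code_table", 2)),
              high_confidence = flag("high_confidence", FALSE),
              support_min = num("support_min", 100),
              posterior_min = num("posterior_min", 1),
              normalize_rates = flag("normalize_rates", FALSE),
              alpha = num("alpha", 0.5),
              gamma_categories = as.integer(num("gamma_categories", 4)),
              bootstrap_reps = as.integer(num("bootstrap_reps", 1000)),
              min_divergent = as.integer(num("min_divergent", 5)),
              seed = as.integer(num("seed", 1)),
              out_dir = cfg$out_dir)
  if (out$bootstrap_reps < 1L) stopf("bootstrap_reps must be >= 1")
  class(out) <- "run_config"
  out
}

#' Run the full homoplasy-clustering pipeline
#'
#' Reconstruction (unless precomputed states are supplied), substitution
#' mapping, site filters, pair enumeration, matched subsampling, binned P/D
#' curve, mean distance ratio and crossing distance with site-bootstrap CIs.
#' Identical inputs and seed give identical outputs.
#'
#' @param tree a `pd_tree` (or newick path).
#' @param aln alignment character matrix (or FASTA path).
#' @param model optional `rate_model` (default: mtREV24 + alignment
#'   frequencies, alpha/K from the arguments).
#' @param states optional precomputed `ancestral_states`.
#' @param gap_threshold gap-fraction filter threshold (NULL disables).
#' @param site_mask optional extra logical site mask.
#' @param accessibility restrict analysis to genetic-code-accessible
#'   (B, derived) pairs.
#' @param code_table NCBI translation table for the accessibility filter.
#' @param high_confidence apply the support/posterior pair filter.
#' @param support_min,posterior_min high-confidence thresholds.
#' @param normalize_rates use rate-normalized distances in the statistics.
#' @param alpha,gamma_categories model parameters when `model` is NULL.
#' @param breaks,min_divergent binning parameters, see [pd_curve()].
#' @param bootstrap_reps bootstrap replicate count.
#' @param seed master seed for subsampling and bootstrap.
#' @param out_dir optional directory for TSV outputs and the run log.
#' @return list of class `pd_report`: `substitutions`, `pairs`,
#'   `informative_sites`, `subsampled`, `curve` (with CIs), `ratio`
#'   (`ratio_estimate`), `crossing` (`ratio_estimate`), `summary`,
#'   `counts` (filter-stage log), `seed`.
#' @export
run_pipeline <- function(tree, aln, model = NULL, states = NULL,
                         gap_threshold = 0.01, site_mask = NULL,
                         accessibility = FALSE, code_table = 2L,
                         high_confidence = FALSE, support_min = 100,
                         posterior_min = 1, normalize_rates = FALSE,
                         alpha = 0.5, gamma_categories = 4L,
                         breaks = NULL, min_divergent = 5L,
                         bootstrap_reps = 1000L, seed = 1L, out_dir = NULL) {
  if (is.character(tree) && !inherits(tree, "pd_tree"))
    tree <- read_tree_newick(file = tree)
  tree <- as_pd_tree(tree)
  if (is.character(aln) && !is.matrix(aln)) aln <- read_fasta_alignment(aln)
  counts <- list(sites_total = ncol(aln))

  mask <- rep(TRUE, ncol(aln))
  if (!is.null(gap_threshold)) mask <- mask & gap_mask(aln, gap_threshold)
  if (!is.null(site_mask)) mask <- mask & site_mask
  counts$sites_pass_mask <- sum(mask)

  if (is.null(states)) {
    if (is.null(model))
      model <- default_rate_model(freqs = aln, alpha = alpha, K = gamma_categories)
    states <- reconstruct_ancestral(tree, aln, model)
  }
  subs <- map_substitutions(tree, states)
  subs <- subs[subs$site %in% which(mask)]
  counts$substitutions <- nrow(subs)

  pairs <- enumerate_all_pairs(subs, tree, site_rate = states$site_rate)
  counts$pairs_enumerated <- nrow(pairs)

  if (accessibility) {
    acc <- accessible_pairs(genetic_code(code_table))
    ok <- acc[cbind(pairs$B, pairs$A1)] & acc[cbind(pairs$B, pairs$A2)]
    pairs <- pairs[ok]
    counts$pairs_accessible <- nrow(pairs)
  }
  if (high_confidence) {
    pairs <- high_confidence_filter(pairs, tree, support_min, posterior_min)
    counts$pairs_high_confidence <- nrow(pairs)
  }

  inf <- informative_sites(pairs)
  counts$sites_informative <- length(inf)
  if (!length(inf)) {
    rep_obj <- structure(list(substitutions = subs, pairs = pairs,
                              informative_sites = integer(),
                              subsampled = empty_pairs(), curve = NULL,
                              ratio = NULL, crossing = NULL,
                              summary = summary_stats(aln[, mask, drop = FALSE], subs),
                              counts = counts, seed = seed, empty = TRUE),
                         class = "pd_report")
    if (!is.null(out_dir)) write_report(rep_obj, out_dir)
    return(rep_obj)
  }

  subsampled <- matched_subsample(pairs, seed = hash_seed(seed, 0L))
  boot <- bootstrap_sites(pairs, c("ratio", "curve", "crossing"),
                          reps = bootstrap_reps, seed = seed, breaks = breaks,
                          min_divergent = min_divergent,
                          use_ndist = normalize_rates)

  rep_obj <- structure(list(substitutions = subs, pairs = pairs,
                            informative_sites = inf, subsampled = subsampled,
                            curve = boot$curve, ratio = boot$ratio,
                            crossing = boot$crossing,
                            summary = summary_stats(aln[, mask, drop = FALSE], subs),
                            counts = counts, seed = seed, empty = FALSE),
                       class = "pd_report")
  if (!is.null(out_dir)) write_report(rep_obj, out_dir)
  rep_obj
}

#' @export
print.pd_report <- function(x, ...) {
  cat("P/D homoplasy-clustering report\n")
  cat(sprintf("  sites: %d total, %d analyzed, %d homoplasy-informative\n",
              x$counts$sites_total, x$counts$sites_pass_mask,
              x$counts$sites_informative))
  cat(sprintf("  substitutions: %d; pairs: %d\n",
              x$counts$substitutions, x$counts$pairs_enumerated))
  if (!x$empty) {
    cat(sprintf("  mean distance ratio: %.3f [%.3f, %.3f]\n",
                x$ratio$point, x$ratio$ci[1], x$ratio$ci[2]))
    cr <- x$crossing$point
    cat(sprintf("  crossing distance: %s\n",
                if (is.na(cr)) "undefined (curve starts below 1)"
                else if (is.infinite(cr)) "never reaches 1" else sprintf("%.3g", cr)))
  }
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fw <- function(x, f) data.table::fwrite(x, file.path(out_dir, f), sep = "\t")
  fw(report$pairs, "pairs.tsv")
  if (!is.null(report$curve)) fw(report$curve, "curve.tsv")
  scal <- data.table::data.table(
    statistic = c("mean_distance_ratio", "crossing_distance"),
    point = c(report$ratio$point %||% NA_real_, report$crossing$point %||% NA_real_),
    median = c(report$ratio$median %||% NA_real_, report$crossing$median %||% NA_real_),
    ci_lo = c(report$ratio$ci[1] %||% NA_real_, report$crossing$ci[1] %||% NA_real_),
    ci_hi = c(report$ratio$ci[2] %||% NA_real_, report$crossing$ci[2] %||% NA_real_))
  fw(scal, "scalars.tsv")
  log <- c(sprintf("seed=%d", report$seed),
           sprintf("%s=%s", names(report$counts), unlist(report$counts)))
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Per-gene summary statistics
#'
#' Mean number of distinct amino acids per analyzed column (over leaf
#' sequences, gaps ignored) and mean number of mapped substitutions per
#' column, plus species/site counts.
#'
#' @param aln alignment character matrix (analyzed columns only).
#' @param subs substitution table from [map_substitutions()].
#' @return one-row `data.frame`.
#' @export
summary_stats <- function(aln, subs) {
  aa_per_site <- mean(apply(aln, 2L, function(col)
    length(unique(col[col %in% AA20]))))
  data.frame(species = nrow(aln), sites = ncol(aln),
             aa_per_site = aa_per_site,
             subs_per_site = nrow(subs) / ncol(aln))
}

#' Distribution of branch pairs by parallel-substitution count
#'
#' Counts unordered pairs of phylogenetically independent branches by how
#' many parallel substitution pairs they carry.  When the tree is given, the
#' zero class (independent branch pairs with no parallel pair) is included.
#'
#' @param pairs pair table.
#' @param tree optional `pd_tree` for the zero class.
#' @return `data.frame` with `n_parallel` and `n_branch_pairs`.
#' @export
branch_pair_distribution <- function(pairs, tree = NULL) {
  pairs <- data.table::as.data.table(pairs)
  par <- pairs[kind == "parallel"]
  tab <- if (nrow(par)) par[, .N, by = .(e1, e2)] else
    data.table::data.table(e1 = integer(), e2 = integer(), N = integer())
  hist <- table(factor(tab$N, levels = seq_len(max(tab$N, 1L))))
  out <- data.frame(n_parallel = as.integer(names(hist)),
                    n_branch_pairs = as.integer(hist))
  if (!is.null(tree)) {
    tree <- as_pd_tree(tree)
    E <- tree$edges
    L <- tree$lca_node[E, E]
    indep <- sum(L != matrix(E, length(E), length(E)) &
                 L != matrix(E, length(E), length(E), byrow = TRUE)) / 2
    out <- rbind(data.frame(n_parallel = 0L,
                            n_branch_pairs = as.integer(indep - nrow(tab))), out)
  }
  out[out$n_branch_pairs > 0 | out$n_parallel == 0, , drop = FALSE]
}

#' Rank correlation of crossing distance with gene evolutionary rate
#'
#' Spearman correlation (midrank ties, two-sided p from the t approximation)
#' between per-gene P/D crossing distances and a per-gene rate proxy such as
#' the patristic distance between two reference species.
#'
#' @param crossing numeric vector of per-gene crossing distances.
#' @param rate numeric vector of per-gene rate proxies (same length, >= 3
#'   finite pairs).
#' @return list with `rho`, `p_value`, `n`, and the scatter `table`.
#' @export
gene_rate_trend <- function(crossing, rate) {
  ok <- is.finite(crossing) & is.finite(rate)
  if (sum(ok) < 3L) stopf("need at least 3 genes with both values")
  ct <- suppressWarnings(cor.test(crossing[ok], rate[ok], method = "spearman",
                                  exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = sum(ok),
       table = data.frame(crossing = crossing[ok], rate = rate[ok]))
}

#' Plot a P/D curve
#'
#' Base-graphics rendering of a bootstrapped [pd_curve()]: point estimate,
#' CI band when present, and the neutral expectation P/D = 1.
#'
#' @param x a `pd_curve`.
#' @param ... passed to [plot()].
#' @export
plot.pd_curve <- function(x, ...) {
  use <- !is.na(x$pd)
  plot(x$mid_log2[use], x$pd[use], type = "b", pch = 16,
       xlab = "log2 distance (subst/site)", ylab = "P/D", ...)
  if (!is.null(x$ci_lo)) {
    graphics::arrows(x$mid_log2[use], x$ci_lo[use], x$mid_log2[use],
                     x$ci_hi[use], angle = 90, code = 3, length = 0.03,
                     col = "grey50")
  }
  graphics::abline(h = 1, col = "red")
  invisible(x)
}

#' Clade partition and perturbed clade models
#'
#' Splits a tree into `n_clades` subtrees (largest-first traversal) that
#' together with a root "background" clade cover every edge, and builds a
#' perturbed copy of a base model for each: exchangeabilities are jittered
#' by independent lognormal factors with standard deviation `sdlog`.
#' Used by the clade-specific-matrix simulation control.
#'
#' @param tree a `pd_tree`.
#' @param model base `rate_model`.
#' @param n_clades number of non-root clades.
#' @param sdlog lognormal jitter of the exchangeabilities (0 = identical
#'   matrices).
#' @param seed RNG seed for clade choice and jitter.
#' @return named list of `rate_model`s keyed by subtree-root node id,
#'   suitable for [sim_config()]'s `clade_models`.
#' @export
make_clade_models <- function(tree, model, n_clades = 3L, sdlog = 0.3,
                              seed = 1L) {
  tree <- as_pd_tree(tree)
  # split the tree into n_clades subtrees by repeatedly breaking the largest
  # clade into its children (edges above the clade roots keep the base model)
  sizes <- vapply(seq_len(tree$n_node), function(v)
    sum(tree$lca_node[seq_len(tree$n_tip), v] == v), 1L)
  picked <- tree$children[[tree$root]]
  while (length(picked) < n_clades) {
    big <- picked[which.max(sizes[picked])]
    kids <- tree$children[[big]]
    if (!length(kids)) break
    picked <- c(setdiff(picked, big), kids)
  }
  keys <- c(tree$root, picked)
  with_seed(seed, {
    models <- lapply(seq_along(keys), function(i) {
      S <- model$S
      if (sdlog > 0 && i > 1L) {
        jit <- matrix(0, 20, 20)
        jit[lower.tri(jit)] <- stats::rlnorm(190, 0, sdlog)
        jit <- jit + t(jit)
        S <- S * jit
      }
      rate_model(S, model$pi, alpha = model$alpha, K = model$K)
    })
    names(models) <- as.character(keys)
    models
  })
}
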