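# Parallel / divergent substitution pairs and the P/D distance statistics.
#
# A pair is two substitutions at the same site sharing the ancestral amino
# acid B, located on phylogenetically independent edges.  Same derived state
# -> parallel; different derived states -> divergent.  Convergent pairs
# (same derived, different ancestral state) are never formed: pooling them
# with parallel pairs is exactly the bias this statistic avoids.

#' @import data.table
NULL

empty_pairs <- function() {
  data.table::data.table(site = integer(), B = character(),
                         A1 = character(), A2 = character(),
                         kind = character(), e1 = integer(), e2 = integer(),
                         dist = numeric(), ndist = numeric(),
                         post_B1 = numeric(), post_A1 = numeric(),
                         post_B2 = numeric(), post_A2 = numeric())
}

#' Enumerate independent substitution pairs
#'
#' All unordered pairs of substitutions with the same ancestral amino acid on
#' independent edges, classified as parallel or divergent, with their
#' mid-edge distances.  `enumerate_pairs` handles the substitutions of one
#' site; `enumerate_all_pairs` is the vectorized version over a full
#' substitution table (the two agree exactly).
#'
#' @param subs `data.table` of substitutions as produced by
#'   [map_substitutions()] (for `enumerate_pairs`, all rows from one site).
#' @param tree a `pd_tree`.
#' @param site_rate optional per-site rates; when given, the rate-normalized
#'   distance column `ndist = dist * r_s` is filled (otherwise `NA`).
#' @return `data.table` with columns `site`, `B`, `A1`, `A2`, `kind`
#'   (`"parallel"` or `"divergent"`), edge refs `e1`, `e2`, `dist`, `ndist`,
#'   and the four node-state posteriors of the two substitutions.
#' @export
enumerate_pairs <- function(subs, tree, site_rate = NULL) {
  if (length(unique(subs$site)) > 1L)
    stopf("enumerate_pairs expects substitutions from a single site")
  enumerate_all_pairs(subs, tree, site_rate)
}

#' @rdname enumerate_pairs
#' @export
enumerate_all_pairs <- function(subs, tree, site_rate = NULL) {
  tree <- as_pd_tree(tree)
  subs <- data.table::as.data.table(subs)
  if (nrow(subs) == 0L) return(empty_pairs())
  # index pairs within each (site, B) group
  g <- subs[, .(i = list(.I)), by = .(site, B)]
  ii <- integer(0); jj <- integer(0)
  for (idx in g$i) {
    n <- length(idx)
    if (n < 2L) next
    cmb <- utils::combn(idx, 2L)
    ii <- c(ii, cmb[1L, ]); jj <- c(jj, cmb[2L, ])
  }
  if (!length(ii)) return(empty_pairs())
  e1 <- subs$edge[ii]; e2 <- subs$edge[jj]
  keep <- is_independent(tree, e1, e2)
  if (!any(keep)) return(empty_pairs())
  ii <- ii[keep]; jj <- jj[keep]; e1 <- e1[keep]; e2 <- e2[keep]
  A1 <- subs$A[ii]; A2 <- subs$A[jj]
  swap <- A2 < A1   # canonical order of derived states in the pair
  tmp <- A1[swap]; A1[swap] <- A2[swap]; A2[swap] <- tmp
  i1 <- ifelse(swap, jj, ii); i2 <- ifelse(swap, ii, jj)
  out <- data.table::data.table(
    site = subs$site[ii], B = subs$B[ii], A1 = A1, A2 = A2,
    kind = ifelse(A1 == A2, "parallel", "divergent"),
    e1 = subs$edge[i1], e2 = subs$edge[i2],
    dist = mid_edge_distance(tree, e1, e2),
    post_B1 = subs$post_B[i1], post_A1 = subs$post_A[i1],
    post_B2 = subs$post_B[i2], post_A2 = subs$post_A[i2])
  out[, ndist := if (is.null(site_rate)) NA_real_ else dist * site_rate[site]]
  data.table::setcolorder(out, c("site", "B", "A1", "A2", "kind", "e1", "e2",
                                 "dist", "ndist"))
  data.table::setorder(out, site, B, e1, e2)
  out[]
}

#' Per-(site, B) parallel and divergent pair counts
#'
#' @param pairs a pair table from [enumerate_all_pairs()].
#' @return `data.table` with `site`, `B`, `n_paral`, `n_diverg`.
#' @export
pair_counts <- function(pairs) {
  pairs <- data.table::as.data.table(pairs)
  if (nrow(pairs) == 0L)
    return(data.table::data.table(site = integer(), B = character(),
                                  n_paral = integer(), n_diverg = integer()))
  pairs[, .(n_paral = sum(kind == "parallel"),
            n_diverg = sum(kind == "divergent")), by = .(site, B)]
}

#' Is a site homoplasy-informative?
#'
#' True iff some ancestral amino acid at the site has at least one parallel
#' and at least one divergent pair.
#'
#' @param pairs pair table for one site (or any subset).
#' @return logical scalar.
#' @export
homoplasy_informative <- function(pairs) {
  cnt <- pair_counts(pairs)
  any(cnt$n_paral >= 1L & cnt$n_diverg >= 1L)
}

#' Sites that are homoplasy-informative
#'
#' @param pairs full pair table.
#' @return sorted integer vector of site indices.
#' @export
informative_sites <- function(pairs) {
  cnt <- pair_counts(pairs)
  sort(unique(cnt$site[cnt$n_paral >= 1L & cnt$n_diverg >= 1L]))
}

#' Matched subsampling of parallel and divergent pairs
#'
#' Per (site, ancestral amino acid) at homoplasy-informative sites, draws
#' `m = min(n_paral, n_diverg)` parallel and `m` divergent pairs uniformly
#' without replacement, so the pooled parallel and divergent samples are
#' matched in size within every group.  Deterministic given `seed`.
#'
#' @param pairs full pair table.
#' @param seed integer seed (a private RNG stream is used).
#' @return subsampled pair table.
#' @export
matched_subsample <- function(pairs, seed = 1L) {
  pairs <- data.table::as.data.table(pairs)
  if (nrow(pairs) == 0L) return(empty_pairs())
  inf_sites <- informative_sites(pairs)
  pairs <- pairs[site %in% inf_sites]
  if (nrow(pairs) == 0L) return(empty_pairs())
  # keep, per (site, B, kind), the m rows with the smallest random keys,
  # where m = min(n_paral, n_diverg) of the (site, B) group: a vectorized
  # uniform draw without replacement
  key <- with_seed(seed, runif(nrow(pairs)))
  grp <- pairs[, .(site, B, kind)]
  grp[, key := key]
  grp[, m := min(sum(kind == "parallel"), sum(kind == "divergent")),
      by = .(site, B)]
  grp[, rk := data.table::frank(key, ties.method = "first"),
      by = .(site, B, kind)]
  pairs[grp$rk <= grp$m]
}

#' Distance-binned P/D ratio curve
#'
#' Pools the (subsampled) pairs and, within bins of log2(distance) with
#' integer boundaries, counts parallel and divergent pairs and their ratio.
#' Zero-distance pairs fall into the smallest bin.  Bins with fewer divergent
#' pairs than `min_divergent` are flagged unstable; a bin with no divergent
#' pairs has an undefined (`NA`) ratio.
#'
#' @param pairs pooled pair table (normally after [matched_subsample()]).
#' @param breaks optional integer log2 bin boundaries (e.g. `-6:3`); default
#'   covers the observed distance range.
#' @param min_divergent stability threshold on the divergent count per bin.
#' @param use_ndist use rate-normalized distances instead of raw ones.
#' @return `data.table` of class `pd_curve`: `bin_lo`, `bin_hi` (natural
#'   scale), `mid_log2`, `n_paral`, `n_diverg`, `pd`, `stable`.
#' @export
pd_curve <- function(pairs, breaks = NULL, min_divergent = 5L,
                     use_ndist = FALSE) {
  pairs <- data.table::as.data.table(pairs)
  d <- if (use_ndist) pairs$ndist else pairs$dist
  if (nrow(pairs) == 0L) {
    out <- data.table::data.table(bin_lo = numeric(), bin_hi = numeric(),
                                  mid_log2 = numeric(), n_paral = integer(),
                                  n_diverg = integer(), pd = numeric(),
                                  stable = logical())
    data.table::setattr(out, "class", c("pd_curve", class(out)))
    return(out)
  }
  if (any(is.na(d))) stopf("distances contain NA (did you ask for ndist without site rates?)")
  if (is.null(breaks)) {
    pos <- d[d > 0]
    if (!length(pos)) pos <- 1e-3
    breaks <- floor(min(log2(pos))):ceiling(max(log2(max(d, 1e-3))))
    if (length(breaks) < 2L) breaks <- c(breaks[1] - 1L, breaks)
  }
  breaks <- sort(unique(as.numeric(breaks)))
  lg <- log2(pmax(d, 2^breaks[1]))          # zero distances -> smallest bin
  lg <- pmin(pmax(lg, breaks[1]), breaks[length(breaks)] - 1e-12)
  bin <- findInterval(lg, breaks, rightmost.closed = TRUE)
  nb <- length(breaks) - 1L
  np <- tabulate(bin[pairs$kind == "parallel"], nb)
  nd <- tabulate(bin[pairs$kind == "divergent"], nb)
  out <- data.table::data.table(
    bin_lo = 2^breaks[-length(breaks)], bin_hi = 2^breaks[-1],
    mid_log2 = (breaks[-length(breaks)] + breaks[-1]) / 2,
    n_paral = np, n_diverg = nd,
    pd = ifelse(nd > 0, np / nd, NA_real_),
    stable = nd >= min_divergent)
  data.table::setattr(out, "class", c("pd_curve", class(out)))
  out[]
}

#' Mean parallel-to-divergent distance ratio
#'
#' Mean mid-edge distance of parallel pairs divided by that of divergent
#' pairs, over a pooled (normally matched-subsampled) pair set.  Values
#' below 1 mean parallel substitutions are phylogenetically closer.
#'
#' @param pairs pooled pair table.
#' @param use_ndist use rate-normalized distances.
#' @return scalar ratio.
#' @export
mean_distance_ratio <- function(pairs, use_ndist = FALSE) {
  pairs <- data.table::as.data.table(pairs)
  d <- if (use_ndist) pairs$ndist else pairs$dist
  dp <- d[pairs$kind == "parallel"]; dd <- d[pairs$kind == "divergent"]
  if (!length(dp) || !length(dd))
    stopf("need at least one parallel and one divergent pair")
  mean(dp) / mean(dd)
}

#' Site bootstrap of the homoplasy statistics
#'
#' Resamples sites with replacement; inside each replicate the entire
#' matched-subsampling procedure is redone with a fresh derived seed, and the
#' statistic recomputed.  A site drawn twice contributes two independent
#' subsampling draws.
#'
#' @param pairs full (pre-subsampling) pair table.
#' @param statistic `"ratio"` (mean distance ratio), `"curve"` (per-bin P/D)
#'   or `"crossing"` (distance where the P/D curve reaches 1).
#' @param reps number of bootstrap replicates.
#' @param seed master seed; replicate and subsample seeds are derived from it.
#' @param breaks,min_divergent,use_ndist passed to [pd_curve()]
#'   (curve/crossing statistics).  When `breaks` is NULL they are fixed from
#'   the point-estimate curve so all replicates share bins.
#' @return for `"ratio"`/`"crossing"`: a `ratio_estimate` list with `point`,
#'   `median`, `ci` (2.5/97.5 percentiles), `reps`, `replicates`; for
#'   `"curve"`: the point-estimate curve with `pd_median`, `ci_lo`, `ci_hi`
#'   columns added.  When several statistics are requested they share one
#'   set of bootstrap replicates and a named list is returned.
#' @export
bootstrap_sites <- function(pairs, statistic = c("ratio", "curve", "crossing"),
                            reps = 1000L, seed = 1L, breaks = NULL,
                            min_divergent = 5L, use_ndist = FALSE) {
  statistic <- match.arg(statistic, several.ok = TRUE)
  single <- length(statistic) == 1L
  pairs <- data.table::as.data.table(pairs)
  sites <- informative_sites(pairs)
  if (!length(sites)) stopf("no homoplasy-informative sites")
  pairs <- pairs[site %in% sites]

  point_sub <- matched_subsample(pairs, seed = hash_seed(seed, 0L))
  curve0 <- pd_curve(point_sub, breaks = breaks, min_divergent = min_divergent,
                     use_ndist = use_ndist)
  if (is.null(breaks)) breaks <- log2(c(curve0$bin_lo, curve0$bin_hi[nrow(curve0)]))

  # --- precomputed flat structures for the replicate loop -----------------
  # group id per (site, B); per-row kind flag, distance, and fixed bin
  wk <- data.table::copy(pairs)
  wk[, gid := .GRP, by = .(site, B)]
  G <- max(wk$gid)
  d_all <- if (use_ndist) wk$ndist else wk$dist
  nb <- nrow(curve0)
  lg <- log2(pmax(d_all, 2^breaks[1]))
  lg <- pmin(pmax(lg, breaks[1]), breaks[length(breaks)] - 1e-12)
  bin_all <- findInterval(lg, breaks, rightmost.closed = TRUE)
  par_all <- wk$kind == "parallel"
  gid_all <- wk$gid
  idx_by_site <- split(seq_len(nrow(wk)), wk$site)
  site_n <- lengths(idx_by_site)
  site_key <- names(idx_by_site)
  curve_stub <- list(mid_log2 = curve0$mid_log2)

  rep_ratio <- rep(NA_real_, reps)
  rep_cross <- rep(NA_real_, reps)
  rep_curve <- matrix(NA_real_, reps, nb)
  for (r in seq_len(reps)) {
    rs <- hash_seed(seed, r, 1L)
    nsite <- length(site_key)
    pick <- with_seed(rs, {
      p <- sample.int(nsite, nsite, replace = TRUE)
      list(p = p, key = runif(sum(site_n[p])))
    })
    rows <- unlist(idx_by_site[pick$p], use.names = FALSE)
    inst <- rep(seq_len(nsite), site_n[pick$p])
    g2 <- (inst - 1L) * G + gid_all[rows]          # per-instance group id
    par <- par_all[rows]
    # matched subsampling: per group keep the m = min(#par, #div) rows with
    # the smallest random keys within each kind
    npar <- tabulate(g2[par], nsite * G)
    ndiv <- tabulate(g2[!par], nsite * G)
    m <- pmin(npar, ndiv)
    lab <- g2 * 2L + par
    rk <- integer(length(rows))
    o <- order(pick$key)
    rk[o] <- data.table::rowidv(lab[o])
    keep <- rk <= m[g2]
    if (!any(keep)) next
    dk <- d_all[rows[keep]]; pk <- par[keep]
    if (any(statistic != "ratio")) {
      np <- tabulate(bin_all[rows[keep]][pk], nb)
      nd <- tabulate(bin_all[rows[keep]][!pk], nb)
      pd <- ifelse(nd > 0, np / nd, NA_real_)
      rep_curve[r, ] <- pd
      curve_stub$pd <- pd
      curve_stub$stable <- nd >= min_divergent
      rep_cross[r] <- crossing_distance(curve_stub)$distance
    }
    if ("ratio" %in% statistic && any(pk) && any(!pk))
      rep_ratio[r] <- mean(dk[pk]) / mean(dk[!pk])
  }

  mk_est <- function(point, v, what) {
    ci <- if (all(is.na(v))) c(NA_real_, NA_real_) else
      quantile(v, c(0.025, 0.975), na.rm = TRUE, names = FALSE, type = 7)
    structure(list(point = point,
                   median = if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE),
                   ci = ci, reps = reps, replicates = v, statistic = what),
              class = "ratio_estimate")
  }
  out <- list()
  if ("curve" %in% statistic) {
    cv <- data.table::copy(curve0)
    cv[, pd_median := apply(rep_curve, 2L, median, na.rm = TRUE)]
    cv[, ci_lo := apply(rep_curve, 2L, quantile, 0.025, na.rm = TRUE, names = FALSE)]
    cv[, ci_hi := apply(rep_curve, 2L, quantile, 0.975, na.rm = TRUE, names = FALSE)]
    out$curve <- cv[]
  }
  if ("ratio" %in% statistic)
    out$ratio <- mk_est(mean_distance_ratio(point_sub, use_ndist = use_ndist),
                        rep_ratio, "ratio")
  if ("crossing" %in% statistic)
    out$crossing <- mk_est(crossing_distance(curve0)$distance, rep_cross,
                           "crossing")
  if (single) out[[statistic]] else out
}

#' @export
print.ratio_estimate <- function(x, ...) {
  cat(sprintf("%s: point %.4g, bootstrap median %.4g, 95%% CI [%.4g, %.4g] (%d reps)\n",
              x$statistic, x$point, x$median, x$ci[1], x$ci[2], x$reps))
  invisible(x)
}

#' Distance at which the P/D curve reaches 1
#'
#' First crossing of the per-bin P/D point estimates through 1, linearly
#' interpolated between adjacent bin midpoints on the log2 axis and reported
#' on the natural scale.  Only stable bins with a defined ratio are used.
#'
#' @param curve a `pd_curve`.
#' @return list with `distance` (natural scale; `Inf` when the curve never
#'   reaches 1), `crossed` (logical) and `start_above` (whether the first
#'   usable bin exceeds 1; when FALSE the result is flagged, not an error).
#' @export
crossing_distance <- function(curve) {
  use <- !is.na(curve$pd) & curve$stable
  pd <- curve$pd[use]; mid <- curve$mid_log2[use]
  if (!length(pd))
    return(list(distance = NA_real_, crossed = FALSE, start_above = NA))
  if (pd[1] <= 1) {
    return(list(distance = if (pd[1] == 1) 2^mid[1] else NA_real_,
                crossed = pd[1] == 1, start_above = FALSE))
  }
  for (i in seq_along(pd)[-1]) {
    if (pd[i] <= 1) {
      x <- mid[i - 1] + (mid[i] - mid[i - 1]) * (pd[i - 1] - 1) / (pd[i - 1] - pd[i])
      return(list(distance = 2^x, crossed = TRUE, start_above = TRUE))
    }
  }
  list(distance = Inf, crossed = FALSE, start_above = TRUE)
}

#' Rate-normalized distance
#'
#' Multiplies a phylogenetic distance by the site-specific relative rate, a
#' proxy for site-specific evolutionary distance.
#'
#' @param dist distance(s) in substitutions per site.
#' @param r_s site rate(s) (> 0).
#' @return normalized distance(s).
#' @export
normalize_by_site_rate <- function(dist, r_s) {
  if (any(r_s <= 0)) stopf("site rate must be positive")
  dist * r_s
}
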