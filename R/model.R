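#' @importFrom stats qgamma pgamma rexp runif quantile median cor.test setNames rlnorm
#' @importFrom graphics plot arrows abline
NULL

#' One-letter amino acid codes in PAML matrix order
#'
#' The row/column order (`ARNDCQEGHILKMFPSTWYV`) used by all 20x20 matrices
#' in this package, matching the convention of PAML-style rate files.
#' @export
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Discrete-gamma rate categories
#'
#' Mean rates of the `K` equal-probability categories of a gamma
#' distribution with shape `alpha` and mean 1 (the usual discretization for
#' among-site rate variation).  Rates are renormalized to have mean exactly 1.
#'
#' @param alpha gamma shape parameter (> 0); small values mean strong
#'   rate heterogeneity between sites.
#' @param K number of categories (>= 1).
#' @return numeric vector of `K` strictly increasing rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, K = 4L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stopf("alpha must be a positive number")
  K <- as.integer(K)
  if (K < 1L) stopf("K must be >= 1")
  if (K == 1L) return(1)
  q <- qgamma(seq(0, 1, length.out = K + 1L), shape = alpha, rate = alpha)
  # mean of a mean-1 gamma within each inter-quantile slice
  r <- K * diff(pgamma(q, shape = alpha + 1, rate = alpha))
  r / mean(r)
}

#' Amino acid substitution model
#'
#' Builds a reversible 20-state rate model from a symmetric exchangeability
#' matrix `S`, equilibrium frequencies `pi`, and a discrete-gamma description
#' of among-site rate variation.  The instantaneous rate matrix is
#' `Q[i,j] = S[i,j] * pi[j]`, with the diagonal set so rows sum to zero, and
#' the whole matrix scaled so the expected number of substitutions per site
#' per unit branch length at equilibrium is 1.
#'
#' @param exchangeabilities either a symmetric 20x20 matrix (diagonal
#'   ignored) or the 190 sub-diagonal entries in row-wise lower-triangle
#'   order (PAML convention, `AA20` ordering).
#' @param freqs equilibrium frequencies, length 20, in `AA20` order; they are
#'   floored at `1e-4` and renormalized so the model stays well conditioned
#'   when some residue is unobserved.
#' @param alpha gamma shape for site rates.
#' @param K number of discrete-gamma categories.
#' @return an object of class `rate_model` with elements `S`, `pi`, `Q`,
#'   `alpha`, `K`, `rates` (category rates), and a cached eigendecomposition
#'   used for transition probabilities.
#' @export
rate_model <- function(exchangeabilities, freqs, alpha = 0.5, K = 4L) {
  S <- exchangeabilities
  if (is.null(dim(S))) {
    if (length(S) != 190L) stopf("expected 190 lower-triangle exchangeabilities")
    M <- matrix(0, 20, 20)
    M[lower.tri(M)] <- unlist_lower_triangle(S)
    S <- M + t(M)
  } else {
    S <- as.matrix(S)
    if (!all(dim(S) == c(20L, 20L))) stopf("exchangeability matrix must be 20x20")
    if (max(abs(S - t(S))) > 1e-8 * max(abs(S), 1))
      stopf("exchangeability matrix must be symmetric")
    diag(S) <- 0
  }
  if (any(S < 0)) stopf("exchangeabilities must be non-negative")
  if (length(freqs) != 20L) stopf("freqs must have length 20")
  if (any(freqs < 0)) stopf("freqs must be non-negative")
  pi <- pmax(as.numeric(freqs), 1e-4)
  pi <- pi / sum(pi)
  dimnames(S) <- list(AA20, AA20)
  names(pi) <- AA20

  Q <- S * rep(pi, each = 20L)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  if (scale <= 0) stopf("degenerate model: zero total substitution rate")
  Q <- Q / scale

  # reversible Q: symmetrize with sqrt(pi) and eigendecompose once
  sp <- sqrt(pi)
  B <- Q * (sp %o% (1 / sp))
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  U <- eig$vectors / sp           # diag(1/sp) %*% V
  Uinv <- t(eig$vectors * sp)     # t(V) %*% diag(sp)

  structure(list(S = S, pi = pi, Q = Q, alpha = alpha, K = as.integer(K),
                 rates = discrete_gamma_rates(alpha, K),
                 eig_values = eig$values, eig_U = U, eig_Uinv = Uinv),
            class = "rate_model")
}

# accept lower-triangle input given row-wise (PAML files list row i entries
# j < i); R's lower.tri fills column-wise, so reorder
unlist_lower_triangle <- function(x) {
  idx <- which(lower.tri(matrix(0, 20, 20)), arr.ind = TRUE)
  # column-major order of lower.tri; the input is row-major (i major)
  ord <- order(idx[, "row"], idx[, "col"])
  out <- numeric(190L)
  out[ord] <- as.numeric(x)
  out
}

#' Transition probability matrix P(t) = exp(Q t)
#'
#' @param model a `rate_model`.
#' @param t branch length (expected substitutions per site, >= 0).
#' @return 20x20 stochastic matrix, rows = ancestral state.
#' @export
transition_matrix <- function(model, t) {
  if (t < 0) stopf("branch length must be >= 0")
  if (t == 0) return(diag(20L))
  P <- model$eig_U %*% (exp(model$eig_values * t) * model$eig_Uinv)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Default mitochondrial rate model
#'
#' The mtREV24 empirical exchangeability set (taken at run time from the
#' model collection shipped with \pkg{phangorn}) combined with either its own
#' equilibrium frequencies or frequencies estimated from an alignment
#' ("+F" style), which is the standard choice when analyzing a new protein.
#'
#' @param freqs optional length-20 frequency vector in `AA20` order; if an
#'   alignment character matrix is given instead, frequencies are counted
#'   from it (with a small floor, see [rate_model()]).
#' @param alpha,K discrete-gamma parameters.
#' @param exchangeabilities optional replacement 190-vector or 20x20 matrix
#'   (e.g. from [read_paml_matrix()]).
#' @return a `rate_model`.
#' @export
default_rate_model <- function(freqs = NULL, alpha = 0.5, K = 4L,
                               exchangeabilities = NULL) {
  mt <- utils::getFromNamespace(".mtREV24", "phangorn")
  # phangorn stores the lower triangle in R's column-major order
  M <- matrix(0, 20, 20)
  M[lower.tri(M)] <- mt$Q
  exch <- exchangeabilities %||% (M + t(M))
  if (is.null(freqs)) {
    pi <- as.numeric(mt$bf)
  } else if (is.matrix(freqs) && is.character(freqs)) {
    pi <- alignment_frequencies(freqs)
  } else {
    pi <- as.numeric(freqs)
  }
  rate_model(exch, pi, alpha = alpha, K = K)
}

#' Amino acid frequencies observed in an alignment
#'
#' @param aln character matrix (taxa x sites); gap/ambiguity symbols ignored.
#' @return length-20 numeric vector in `AA20` order, summing to 1.
#' @export
alignment_frequencies <- function(aln) {
  counts <- table(factor(toupper(as.vector(aln)), levels = AA20))
  n <- sum(counts)
  if (n == 0) stopf("alignment contains no amino acid characters")
  as.numeric(counts) / n
}

#' Read a PAML-style exchangeability file
#'
#' Expects the 190 lower-triangle exchangeabilities (row-wise, `AA20` order)
#' as free-format whitespace-separated numbers, optionally followed by 20
#' equilibrium frequencies.  Lines starting with `#` are skipped.
#'
#' @param path file path.
#' @return list with `exchangeabilities` (length 190) and `freqs`
#'   (length 20 or NULL).
#' @export
read_paml_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  x <- suppressWarnings(as.numeric(unlist(strsplit(paste(lines, collapse = " "),
                                                   "\\s+"))))
  x <- x[!is.na(x)]
  if (length(x) == 190L) return(list(exchangeabilities = x, freqs = NULL))
  if (length(x) == 210L)
    return(list(exchangeabilities = x[1:190], freqs = x[191:210]))
  stopf("expected 190 exchangeabilities (+ optional 20 frequencies), found %d numbers",
        length(x))
}

#' @export
print.rate_model <- function(x, ...) {
  cat("Amino acid rate model (20 states)\n")
  cat(sprintf("  gamma shape alpha = %g, %d categories (rates %s)\n",
              x$alpha, x$K, paste(signif(x$rates, 3), collapse = ", ")))
  cat(sprintf("  frequency range [%.4f, %.4f]\n", min(x$pi), max(x$pi)))
  invisible(x)
}
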