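# Site and pair filters: gap fraction, genetic-code accessibility,
# high-confidence (support + posterior) pairs, and generic site masks.

#' Gap-fraction site mask
#'
#' A column passes when its gap fraction is strictly below `threshold`
#' (default 1\%, the usual deep-alignment criterion).
#'
#' @param aln character matrix (taxa x sites).
#' @param threshold gap-fraction threshold in (0, 1].
#' @param gap_chars characters counted as gaps.
#' @return logical vector of length `ncol(aln)` with a `provenance`
#'   attribute.
#' @export
gap_mask <- function(aln, threshold = 0.01, gap_chars = "-") {
  if (!is.matrix(aln) || ncol(aln) == 0L) stopf("empty alignment")
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stopf("threshold must lie in (0, 1]")
  frac <- colMeans(matrix(aln %in% gap_chars, nrow(aln)))
  structure(frac < threshold, provenance = sprintf("gap<%g", threshold))
}

#' Read a site mask from a two-column TSV
#'
#' Columns: 1-based position, label.  Positions present in the file are TRUE.
#'
#' @param path TSV path.
#' @param n_sites alignment length.
#' @return logical vector with `provenance` = the most common label.
#' @export
read_site_mask <- function(path, n_sites) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("pos", "label"))
  if (any(tab$pos < 1 | tab$pos > n_sites)) stopf("mask positions out of range")
  mask <- rep(FALSE, n_sites)
  mask[tab$pos] <- TRUE
  structure(mask, provenance = names(sort(table(tab$label), decreasing = TRUE))[1])
}

#' Genetic code table
#'
#' Codon to amino acid map for an NCBI translation table, via
#' \pkg{Biostrings}.  The default, table 2, is the vertebrate mitochondrial
#' code; 5 is invertebrate mitochondrial and 1 the standard code.
#'
#' @param table NCBI translation table number (1, 2, 5, ...).
#' @return object of class `genetic_code`: named character vector of length
#'   64 (codon -> one-letter amino acid, `*` = stop) with attribute `table`.
#' @export
genetic_code <- function(table = 2L) {
  gc <- Biostrings::getGeneticCode(as.character(table))
  if (length(gc) != 64L) stopf("malformed genetic code")
  structure(as.character(gc), names = names(gc), table = as.integer(table),
            class = "genetic_code")
}

codon_neighbors <- function(codon) {
  nts <- c("A", "C", "G", "T")
  s <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (p in 1:3) for (n in setdiff(nts, s[p])) {
    x <- s; x[p] <- n
    out <- c(out, paste(x, collapse = ""))
  }
  out
}

#' Accessible amino acid pairs under a genetic code
#'
#' An ordered pair (B, A), B != A, is accessible when A can be reached by a
#' single nucleotide change from B's codons.  In the default strict mode
#' ("every"), every codon of B must have a one-step neighbor coding A, so
#' accessibility cannot depend on which codon a lineage happens to use; the
#' permissive mode ("some") requires only one such codon and is provided for
#' sensitivity analysis.  Stop codons never count as sources or targets.
#'
#' @param code a [genetic_code()].
#' @param mode `"every"` (default) or `"some"`.
#' @return 20x20 logical matrix (rows = B, cols = A, `AA20` order); diagonal
#'   is FALSE.
#' @export
accessible_pairs <- function(code, mode = c("every", "some")) {
  mode <- match.arg(mode)
  codons <- names(code)
  acc <- matrix(FALSE, 20L, 20L, dimnames = list(AA20, AA20))
  for (B in AA20) {
    bc <- codons[code == B]
    if (!length(bc)) next
    # which amino acids are reachable from each codon of B
    reach <- lapply(bc, function(cd) {
      aa <- code[codon_neighbors(cd)]
      unique(aa[aa != "*" & aa != B])
    })
    targets <- if (mode == "every") Reduce(intersect, reach) else unique(unlist(reach))
    acc[B, targets] <- TRUE
  }
  diag(acc) <- FALSE
  acc
}

#' High-confidence pair filter
#'
#' Keeps a pair only when (a) at least one node strictly on the path between
#' the two edge centers -- the edges' parent nodes up to and including their
#' last common ancestor -- has bootstrap support at or above `support_min`,
#' and (b) all four reconstructed node states involved (ancestral state at
#' each parent, derived state at each child) have posterior probability at
#' least `posterior_min` (within 1e-6).
#'
#' @param pairs pair table from [enumerate_all_pairs()] (it carries the four
#'   posteriors).
#' @param tree a `pd_tree` with support labels.
#' @param support_min minimum support in [0, 100].
#' @param posterior_min minimum posterior in [0, 1].
#' @return filtered pair table.
#' @export
high_confidence_filter <- function(pairs, tree, support_min = 100,
                                   posterior_min = 1) {
  tree <- as_pd_tree(tree)
  pairs <- data.table::as.data.table(pairs)
  if (nrow(pairs) == 0L) return(pairs)
  post_ok <- pairs$post_B1 >= posterior_min - 1e-6 &
             pairs$post_A1 >= posterior_min - 1e-6 &
             pairs$post_B2 >= posterior_min - 1e-6 &
             pairs$post_A2 >= posterior_min - 1e-6
  sup_ok <- vapply(seq_len(nrow(pairs)), function(i) {
    if (support_min <= 0) return(TRUE)
    e1 <- pairs$e1[i]; e2 <- pairs$e2[i]
    L <- tree$lca_node[e1, e2]
    path1 <- tree$anc_path[[tree$parent[e1]]]
    path2 <- tree$anc_path[[tree$parent[e2]]]
    nodes <- unique(c(path1[seq_len(match(L, path1))],
                      path2[seq_len(match(L, path2))]))
    sup <- tree$support[nodes]
    if (any(is.na(sup)))
      stopf("node %d on a needed path has no support label", nodes[which(is.na(sup))[1]])
    any(sup >= support_min)
  }, logical(1))
  pairs[post_ok & sup_ok]
}
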