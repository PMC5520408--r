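# Protein alignment I/O.  The working container is a plain character matrix
# (taxa x sites, rownames = taxon names, uppercase one-letter codes), the
# lightest structure the pruning code can index directly.

MISSING_CHARS <- c("-", "X", "?", ".", "*")

#' Read a protein alignment from FASTA
#'
#' @param path FASTA file (uncompressed).
#' @return character matrix, taxa x sites, rownames = sequence names.
#' @export
read_fasta_alignment <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) stopf("no sequences in %s", path)
  w <- Biostrings::width(seqs)
  if (length(unique(w)) != 1L)
    stopf("sequences have unequal lengths; not an alignment")
  m <- do.call(rbind, strsplit(toupper(as.character(seqs)), ""))
  rownames(m) <- sub("\\s.*$", "", names(seqs))
  if (any(duplicated(rownames(m)))) stopf("duplicate sequence names")
  m
}

#' Write a protein alignment to FASTA
#'
#' @param aln character matrix (taxa x sites).
#' @param path output path.
#' @export
write_fasta_alignment <- function(aln, path) {
  seqs <- Biostrings::AAStringSet(apply(aln, 1L, paste, collapse = ""))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

# validate symbols; returns matrix of integer state codes 1..20, NA = missing
encode_alignment <- function(aln) {
  aln <- toupper(aln)
  bad <- setdiff(unique(as.vector(aln)), c(AA20, MISSING_CHARS))
  if (length(bad))
    stopf("non-amino-acid symbols in alignment: %s", paste(bad, collapse = " "))
  s <- match(aln, AA20)
  dim(s) <- dim(aln)
  rownames(s) <- rownames(aln)
  s
}
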