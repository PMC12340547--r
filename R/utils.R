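DNA_BASES <- c("A", "C", "G", "T")

## Integer-encode equal-length sequences: 1..4 for A,C,G,T, NA for N.
## Returns an n x L integer matrix.
encode_seqs <- function(seqs) {
  n <- length(seqs)
  if (n == 0L) return(matrix(integer(0), nrow = 0, ncol = 0))
  L <- unique(nchar(seqs))
  if (length(L) != 1L)
    stop("sequences must all have the same length for matrix encoding")
  m <- matrix(match(unlist(strsplit(seqs, "", fixed = TRUE)), DNA_BASES),
              nrow = n, ncol = L, byrow = TRUE)
  m
}

decode_seq <- function(idx) {
  out <- DNA_BASES[idx]
  out[is.na(idx)] <- "N"
  paste(out, collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Row-wise log-sum-exp of cbind(a0, A) where a0 is a scalar.
logsumexp_rows <- function(a0, A) {
  rmax <- do.call(pmax, c(as.data.frame(A), list(a0)))
  rmax + log(exp(a0 - rmax) + rowSums(exp(A - rmax)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Extract the sequence column from a windows data.frame or pass through a
## character vector.
window_seqs <- function(windows) {
  if (is.character(windows)) return(windows)
  if (is.data.frame(windows) && "seq" %in% names(windows))
    return(as.character(windows$seq))
  stop("expected a character vector or a windows data.frame with a 'seq' column")
}

window_ids <- function(windows) {
  if (is.data.frame(windows) && "gene_id" %in% names(windows))
    return(as.character(windows$gene_id))
  paste0("seq_", seq_along(window_seqs(windows)))
}
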