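## Hand-built two-gene contig with fully known coordinates:
##   pos (0-based):  0..79 upstream pad | 80..99 = upstream of gene+ |
##   gene+ [100,200) starting ATG | gap | gene- [300,400) whose coding
##   strand starts at fwd position 399 (fwd bases 397..399 = CAT -> ATG)
tiny_genome <- function() {
  set.seed(42)
  bases <- sample(c("A", "C", "G", "T"), 500, replace = TRUE)
  bases[101:103] <- c("A", "T", "G")          # gene+ start codon
  bases[398:400] <- c("C", "A", "T")          # gene- start codon (revcomp ATG)
  contigs <- Biostrings::DNAStringSet(
    stats::setNames(paste(bases, collapse = ""), "chr"))
  genes <- data.frame(
    gene_id = c("gplus", "gminus"),
    contig = "chr", strand = c("+", "-"),
    start = c(100L, 300L), end = c(200L, 400L),
    start_codon = "ATG", stringsAsFactors = FALSE)
  list(contigs = contigs, genes = genes, bases = bases)
}

## Random column-stochastic PWM, away from degenerate columns.
random_pwm <- function(w, alpha = 1) {
  theta <- matrix(stats::rgamma(4 * w, shape = alpha), nrow = 4)
  theta <- sweep(theta, 2, colSums(theta), "/")
  rownames(theta) <- c("A", "C", "G", "T")
  theta
}

## Independent brute-force oracle for the exact p-value machinery:
## enumerates all 4^w words, discretizes per-column scores the same way,
## and accumulates the survival function by direct summation.
brute_force_survival <- function(int_scores, background) {
  w <- ncol(int_scores)
  grids <- rep(list(1:4), w)
  words <- as.matrix(expand.grid(grids))
  score <- integer(nrow(words))
  prob <- rep(1, nrow(words))
  for (j in seq_len(w)) {
    score <- score + int_scores[words[, j] + (j - 1L) * 4L]
    prob <- prob * background[words[, j]]
  }
  agg <- rowsum(prob, score)                  # prob mass per achievable score
  sc <- as.integer(rownames(agg))
  ord <- order(sc, decreasing = TRUE)
  surv <- cumsum(agg[ord])
  data.frame(score = sc[ord], survival = as.numeric(surv))
}

## Windows with a planted site in a given fraction of GC-rich sequences.
## The site is either a fixed word or, when `pwm` is given, sampled per
## window from that position probability matrix.
planted_windows <- function(n, frac, word = "TACACT", L = 20, gc = 0.65,
                            seed = 1, offset = NULL, pwm = NULL) {
  set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = p),
          collapse = ""), character(1))
  planted <- seq_len(n) <= round(frac * n)
  wlen <- if (is.null(pwm)) nchar(word) else ncol(pwm)
  pos <- if (is.null(offset)) sample(L - wlen + 1L, n, replace = TRUE)
         else rep(offset, n)
  for (i in which(planted)) {
    site <- if (is.null(pwm)) word else
      paste(vapply(seq_len(wlen), function(j)
        sample(c("A", "C", "G", "T"), 1, prob = pwm[, j]), character(1)),
        collapse = "")
    substr(seqs[i], pos[i], pos[i] + wlen - 1L) <- site
  }
  attr(seqs, "planted") <- planted
  attr(seqs, "pos") <- pos
  seqs
}
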