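#' Build a log-odds scoring matrix from a motif model
#'
#' `log_odds[b, j] = log2(theta'[b, j] / background[b])` with
#' `theta' = (theta + 0.001)` renormalized, so every entry is finite even
#' for near-one-hot columns.
#'
#' @param model a [motif_model()].
#' @param granularity score discretization step used for the exact p-value
#'   lattice (default 1e-3 bits).
#' @return object of class `scoring_matrix`: list with `w`, `log_odds`
#'   (4 x w), `int_scores` (discretized integer scores), `granularity`,
#'   `background`.
#' @export
make_scoring_matrix <- function(model, granularity = 1e-3) {
  stopifnot(granularity > 0)
  thp <- model$theta + 0.001
  thp <- sweep(thp, 2, colSums(thp), "/")
  lo <- log2(sweep(thp, 1, model$background, "/"))
  structure(list(w = model$w, log_odds = lo,
                 int_scores = round(lo / granularity),
                 granularity = granularity,
                 background = model$background),
            class = "scoring_matrix")
}

#' Exact null score distribution of a scoring matrix
#'
#' Discretizes the log-odds scores to multiples of `granularity` and builds
#' the distribution of the total score of a random background w-mer by
#' positional convolution over the columns. The survival function
#' `P(score >= s)` is what converts an observed site score into an exact
#' p-value, as in FIMO-style scanning.
#'
#' @param matrix a `scoring_matrix` from [make_scoring_matrix()].
#' @param background background probabilities; defaults to the matrix's own.
#' @param granularity override of the matrix's granularity.
#' @return object of class `score_distribution`: list with `granularity`,
#'   `min_int`/`max_int` (achievable integer score range) and `survival`
#'   (vector over the lattice, `survival[s - min_int + 1] = P(score >= s)`).
#' @export
exact_pvalues <- function(matrix, background = matrix$background,
                          granularity = matrix$granularity) {
  stopifnot(granularity > 0)
  I <- round(matrix$log_odds / granularity)
  bg <- as.numeric(background)
  w <- matrix$w
  mins <- apply(I, 2, min); maxs <- apply(I, 2, max)
  size <- sum(maxs - mins) + 1
  if (size > 5e7)
    stop("score lattice of ", size,
         " cells; increase granularity (coarser discretization)")
  pmf <- 1
  for (j in seq_len(w)) {
    oldlen <- length(pmf)
    new <- numeric(oldlen + maxs[j] - mins[j])
    for (b in 1:4) {
      sh <- I[b, j] - mins[j]
      rng <- (1 + sh):(oldlen + sh)
      new[rng] <- new[rng] + pmf * bg[b]
    }
    pmf <- new
  }
  surv <- rev(cumsum(rev(pmf)))
  structure(list(granularity = granularity,
                 min_int = sum(mins), max_int = sum(maxs),
                 survival = surv),
            class = "score_distribution")
}

#' p-value of an integer-lattice score
#' @param dist a `score_distribution`.
#' @param score_int integer score(s) on the distribution's lattice.
#' @return survival probabilities `P(score >= score_int)`.
#' @export
score_pvalue <- function(dist, score_int) {
  idx <- score_int - dist$min_int + 1L
  idx <- pmin(pmax(idx, 1L), length(dist$survival))
  p <- dist$survival[idx]
  p[score_int < dist$min_int] <- 1
  p[score_int > dist$max_int] <- dist$survival[length(dist$survival)]
  p
}

## Integer scores of every w-mer start in an encoded sequence matrix.
## Returns an n x m matrix; NA where the word contains N.
score_matrix_int <- function(X, matrix) {
  w <- matrix$w
  n <- nrow(X); L <- ncol(X)
  m <- L - w + 1L
  if (m < 1L) return(base::matrix(integer(0), n, 0))
  Imat <- matrix$int_scores
  S <- base::matrix(0, n, m)
  for (k in seq_len(w)) {
    idx <- X[, k:(k + m - 1L), drop = FALSE]
    S <- S + base::matrix(Imat[as.vector(idx) + (k - 1L) * 4L], n, m)
  }
  S
}

#' Scan one sequence with a scoring matrix
#'
#' Reports every start position whose w-mer has exact p-value at or below
#' the threshold, given strand only (no reverse-complement scanning:
#' promoter elements are strand-specific). Words containing N are skipped.
#' The reported score is the discretized score (`int * granularity`), so
#' score order and p-value order always agree.
#'
#' @param seq a single character sequence.
#' @param matrix a `scoring_matrix`.
#' @param dist matching `score_distribution` from [exact_pvalues()].
#' @param p_threshold report sites with `p_value <= p_threshold`.
#' @return data.frame with `pos` (1-based start in `seq`), `word`, `score`,
#'   `p_value`; empty when the sequence is shorter than the motif.
#' @export
scan_sequence <- function(seq, matrix, dist, p_threshold = 0.015) {
  stopifnot(length(seq) == 1L, p_threshold > 0, p_threshold <= 1)
  empty <- data.frame(pos = integer(0), word = character(0),
                      score = numeric(0), p_value = numeric(0))
  if (nchar(seq) < matrix$w) return(empty)
  X <- encode_seqs(seq)
  S <- score_matrix_int(X, matrix)
  p <- score_pvalue(dist, as.vector(S))
  keep <- which(!is.na(S[1, ]) & p <= p_threshold)
  if (!length(keep)) return(empty)
  data.frame(pos = keep,
             word = substring(seq, keep, keep + matrix$w - 1L),
             score = S[1, keep] * dist$granularity,
             p_value = p[keep])
}

#' Scan gene windows and report start-codon-relative motif sites
#'
#' Applies [scan_sequence()] to every window and converts in-window hits to
#' start-codon-relative coordinates using the windows' offset bookkeeping:
#' `offset` is the position of the site's first base relative to the first
#' base of the start codon (negative = upstream), and
#' `spacer = -offset - w` counts the bases strictly between the site's last
#' base and the start codon (defined for upstream sites only).
#'
#' @param windows windows data.frame from [extract_scan_window()] (or
#'   [extract_upstream()]).
#' @inheritParams scan_sequence
#' @return data.frame of motif sites: `gene_id`, `offset`, `word`, `score`,
#'   `p_value`, `spacer` (NA for sites starting at or inside the ORF).
#' @export
scan_gene_windows <- function(windows, matrix, dist, p_threshold = 0.015) {
  stopifnot(p_threshold > 0, p_threshold <= 1)
  seqs <- window_seqs(windows)
  ids <- window_ids(windows)
  offL <- windows$offset_of_last_base
  Ls <- nchar(seqs)
  w <- matrix$w

  scan_one_len <- function(sel) {
    X <- encode_seqs(seqs[sel])
    S <- score_matrix_int(X, matrix)
    if (ncol(S) == 0)
      return(NULL)
    P <- base::matrix(score_pvalue(dist, as.vector(S)), nrow(S), ncol(S))
    hit <- which(!is.na(S) & P <= p_threshold, arr.ind = TRUE)
    if (!nrow(hit)) return(NULL)
    i <- sel[hit[, 1]]; pos <- hit[, 2]
    data.frame(gene_id = ids[i],
               offset = offL[i] - Ls[i] + pos,
               word = substring(seqs[i], pos, pos + w - 1L),
               score = S[hit] * dist$granularity,
               p_value = P[hit],
               stringsAsFactors = FALSE)
  }
  parts <- lapply(split(seq_along(seqs), Ls), scan_one_len)
  sites <- do.call(rbind, parts)
  if (is.null(sites))
    sites <- data.frame(gene_id = character(0), offset = integer(0),
                        word = character(0), score = numeric(0),
                        p_value = numeric(0))
  sites$spacer <- ifelse(sites$offset < 0, -sites$offset - w, NA_integer_)
  sites <- sites[order(sites$gene_id, sites$offset), , drop = FALSE]
  rownames(sites) <- NULL
  attr(sites, "w") <- w
  attr(sites, "p_threshold") <- p_threshold
  sites
}

#' Best site per gene
#'
#' Keeps, for every gene with at least one passing site, the site with the
#' smallest p-value; ties go to the most 3' site (closest to / furthest into
#' the ORF), since the biological question concerns the proximal element.
#'
#' @param sites site table from [scan_gene_windows()].
#' @return one-row-per-gene site table.
#' @export
best_site_per_gene <- function(sites) {
  if (!nrow(sites)) return(sites)
  ord <- order(sites$gene_id, sites$p_value, -sites$offset)
  out <- sites[ord, , drop = FALSE]
  out <- out[!duplicated(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "w") <- attr(sites, "w")
  out
}

#' Write sites as a FIMO-like TSV
#'
#' Columns `gene_id`, `start`, `stop`, `score`, `p-value`,
#' `matched_sequence`, with `start`/`stop` 1-based inclusive in
#' start-codon-relative coordinates (the first base of the start codon is
#' +1; -1 is the base immediately upstream).
#'
#' @param sites site table from [scan_gene_windows()].
#' @param path output TSV path.
#' @export
write_sites_tsv <- function(sites, path) {
  w <- attr(sites, "w") %||% nchar(sites$word[1])
  to1 <- function(o) ifelse(o >= 0, o + 1L, o)   # no position 0 in 1-based
  out <- data.frame(gene_id = sites$gene_id,
                    start = to1(sites$offset),
                    stop = to1(sites$offset + w - 1L),
                    score = sites$score,
                    `p-value` = sites$p_value,
                    matched_sequence = sites$word,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
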