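#' Construct a motif model
#'
#' A motif model couples a position probability matrix (PPM) with a 0-order
#' background and the ZOOPS site prior `gamma` (the probability that a
#' training sequence contains one site).
#'
#' @param theta 4 x w column-stochastic matrix, rows A,C,G,T.
#' @param background length-4 probability vector (A,C,G,T).
#' @param gamma ZOOPS occurrence prior in `[0, 1]`.
#' @param log_likelihood observed-data ZOOPS log likelihood at the fit.
#' @param n_training_sequences number of sequences the model was fitted on.
#' @return an object of class `motif_model`.
#' @export
motif_model <- function(theta, background, gamma = NA_real_,
                        log_likelihood = NA_real_,
                        n_training_sequences = NA_integer_) {
  theta <- as.matrix(theta)
  stopifnot(nrow(theta) == 4, length(background) == 4)
  if (any(abs(colSums(theta) - 1) > 1e-9))
    stop("theta columns must each sum to 1")
  if (abs(sum(background) - 1) > 1e-9)
    stop("background must sum to 1")
  if (!is.na(gamma) && (gamma < 0 || gamma > 1))
    stop("gamma must lie in [0, 1]")
  rownames(theta) <- DNA_BASES
  structure(list(w = ncol(theta), theta = theta,
                 background = stats::setNames(as.numeric(background), DNA_BASES),
                 gamma = gamma, log_likelihood = log_likelihood,
                 n_training_sequences = n_training_sequences),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat("motif_model: width", x$w, "consensus", consensus_string(x), "\n")
  cat("  gamma =", format(x$gamma, digits = 4),
      " logLik =", format(x$log_likelihood, digits = 8),
      " n =", x$n_training_sequences, "\n")
  print(round(x$theta, 3))
  invisible(x)
}

#' Consensus (argmax base per column) of a motif model
#' @param model a `motif_model`.
#' @return single character string of length `w`.
#' @export
consensus_string <- function(model) {
  paste(DNA_BASES[apply(model$theta, 2, which.max)], collapse = "")
}

#' Estimate the 0-order background from a window set
#'
#' Mononucleotide frequencies over all window bases; N bases are excluded.
#' Frequencies are floored at 1e-6 and renormalized so log-odds stay finite.
#'
#' @param windows windows data.frame or character vector of sequences.
#' @return named numeric vector (A,C,G,T) summing to 1.
#' @export
estimate_background <- function(windows) {
  seqs <- window_seqs(windows)
  if (!length(seqs)) stop("need at least one window")
  counts <- Biostrings::letterFrequency(
    Biostrings::DNAStringSet(seqs), DNA_BASES, collapse = TRUE)
  if (sum(counts) == 0) stop("windows contain no A/C/G/T bases")
  f <- pmax(counts / sum(counts), 1e-6)
  stats::setNames(as.numeric(f / sum(f)), DNA_BASES)
}

## All w-mers of a set of sequences (N-containing words excluded), counted.
count_wmers <- function(seqs, w) {
  L <- nchar(seqs)
  words <- unlist(lapply(seq_len(max(L) - w + 1L), function(j) {
    s <- seqs[L >= j + w - 1L]
    substr(s, j, j + w - 1L)
  }))
  words <- words[!grepl("N", words, fixed = TRUE)]
  if (!length(words)) return(integer(0))
  tab <- table(words)
  stats::setNames(as.integer(tab), names(tab))
}

wmer_to_theta <- function(word, eps = 0.05) {
  idx <- match(strsplit(word, "")[[1]], DNA_BASES)
  theta <- matrix(eps, nrow = 4, ncol = length(idx),
                  dimnames = list(DNA_BASES, NULL))
  theta[cbind(idx, seq_along(idx))] <- 1 - 3 * eps
  theta
}

#' Seed PPMs from over-represented words
#'
#' One-pass count of every w-mer in the windows, ranked by
#' over-representation against the background (`count / P_bg(word)`), ties
#' broken lexicographically. The top words are converted to seed PPMs with
#' probability `1 - 3*eps` on the matching base and `eps` elsewhere.
#'
#' @param windows windows data.frame or character vector.
#' @param w motif width.
#' @param n_seeds number of seed matrices to return.
#' @param background background vector; estimated from the windows if NULL.
#' @param eps per-mismatch-base seed probability (default 0.05).
#' @return named list of 4 x w seed matrices (names are the seed words,
#'   in rank order).
#' @export
seed_candidates <- function(windows, w, n_seeds, background = NULL,
                            eps = 0.05) {
  seqs <- window_seqs(windows)
  if (w > min(nchar(seqs)))
    stop("w exceeds the shortest window length")
  if (is.null(background)) background <- estimate_background(seqs)
  counts <- count_wmers(seqs, w)
  if (!length(counts)) stop("no N-free w-mers available for seeding")
  lp_bg <- vapply(names(counts), function(word) {
    sum(log(background[match(strsplit(word, "")[[1]], DNA_BASES)]))
  }, numeric(1))
  score <- log(counts) - lp_bg
  ord <- order(-score, names(counts))
  top <- names(counts)[ord][seq_len(min(n_seeds, length(counts)))]
  out <- lapply(top, wmer_to_theta, eps = eps)
  names(out) <- top
  attr(out, "scores") <- score[ord][seq_along(top)]
  out
}

#' ZOOPS expectation-maximization for a single motif
#'
#' Fits the zero-or-one-occurrence-per-sequence model: each sequence carries
#' one motif site with prior probability `gamma`, its position uniform over
#' the valid offsets, or no site (probability `1 - gamma`); non-site bases
#' follow the 0-order background. The E-step computes per-sequence site
#' posteriors; the M-step re-estimates the PPM from posterior-weighted
#' counts (pseudocount `0.01 * background` per column) and `gamma` from the
#' mean site posterior. Iterates until the observed-data log likelihood
#' changes by less than `tol` or `max_iter` is reached.
#'
#' Masked positions (N) contribute a likelihood ratio of 1, so previously
#' erased sites are invisible to subsequent fits.
#'
#' @param windows windows data.frame or character vector (equal lengths).
#' @param theta0 initial 4 x w PPM (e.g. from [seed_candidates()]).
#' @param background length-4 background vector.
#' @param max_iter maximum EM iterations.
#' @param tol absolute convergence tolerance on the log likelihood.
#' @param gamma0 initial occurrence prior.
#' @return list with `model` (a [motif_model()]; its `log_likelihood` is
#'   the observed-data ZOOPS log likelihood at the fit), `posteriors` (list
#'   with matrix `Z` of per-offset site posteriors, vector `no_site`, and
#'   `gene_id`), and `ll_trace` — the EM objective per iteration (observed
#'   log likelihood plus the Dirichlet smoothing term the M-step
#'   pseudocount corresponds to), which ascends monotonically.
#' @export
zoops_em <- function(windows, theta0, background, max_iter = 200L,
                     tol = 1e-6, gamma0 = 0.5) {
  seqs <- window_seqs(windows)
  ids <- window_ids(windows)
  w <- ncol(theta0)
  X <- encode_seqs(seqs)
  n <- nrow(X); L <- ncol(X)
  if (w > L) stop("motif width ", w, " exceeds window length ", L)
  m <- L - w + 1L
  bg <- as.numeric(background)

  ## per-sequence background log likelihood (masked bases contribute 0)
  lbg <- log(bg)[X]
  lbg[is.na(lbg)] <- 0
  log_pbg <- rowSums(matrix(lbg, n, L))

  ## per-column index caches: idx_cache[[k]] are the linear lookups into a
  ## 4 x w matrix for motif column k at every offset; mask_cache[[k]][[b]]
  ## are the positions where that base equals b (for the M-step)
  idx_cache <- vector("list", w)
  mask_cache <- vector("list", w)
  for (k in seq_len(w)) {
    B <- as.vector(X[, k:(k + m - 1L), drop = FALSE])
    idx_cache[[k]] <- B + (k - 1L) * 4L
    mask_cache[[k]] <- lapply(1:4, function(b) which(!is.na(B) & B == b))
  }

  theta <- theta0
  gamma <- gamma0
  ll_trace <- numeric(0)
  ll_prev <- -Inf
  ll_final <- NA_real_
  Z <- NULL; z0 <- NULL

  for (iter in seq_len(max_iter)) {
    lr <- log(theta) - log(bg)           # 4 x w log likelihood ratios
    LR <- matrix(0, n, m)
    for (k in seq_len(w)) {
      v <- lr[idx_cache[[k]]]
      v[is.na(v)] <- 0
      LR <- LR + v
    }
    a0 <- log(1 - gamma)
    A <- LR + log(gamma / m)
    rmax <- A[, 1L]
    if (m > 1L) for (j in 2:m) rmax <- pmax(rmax, A[, j])
    rmax <- pmax(rmax, a0)
    lse <- rmax + log(exp(a0 - rmax) + rowSums(exp(A - rmax)))
    ll <- sum(log_pbg) + sum(lse)
    ## the EM objective includes the Dirichlet term the pseudocount
    ## corresponds to; it (not the bare likelihood) ascends monotonically
    obj <- ll + 0.01 * sum(bg * log(theta))
    if (!is.finite(ll))
      stop("non-finite ZOOPS log likelihood at iteration ", iter)
    ll_trace <- c(ll_trace, obj)
    Z <- exp(A - lse)
    z0 <- exp(a0 - lse)
    ll_final <- ll
    if (abs(obj - ll_prev) < tol) break
    ll_prev <- obj
    if (iter == max_iter) break

    ## M-step
    counts <- matrix(0, 4, w, dimnames = list(DNA_BASES, NULL))
    for (k in seq_len(w)) {
      for (b in 1:4) counts[b, k] <- sum(Z[mask_cache[[k]][[b]]])
    }
    counts <- counts + 0.01 * bg          # per-column background pseudocount
    theta <- sweep(counts, 2, colSums(counts), "/")
    gamma <- min(max(mean(1 - z0), 1e-6), 1 - 1e-6)
  }

  model <- motif_model(theta, bg, gamma = gamma,
                       log_likelihood = ll_final,
                       n_training_sequences = n)
  list(model = model,
       posteriors = list(Z = Z, no_site = z0, gene_id = ids),
       ll_trace = ll_trace)
}

#' De novo ZOOPS motif discovery with seeded restarts
#'
#' For each motif, a short pilot EM is run from a pool of word seeds, the
#' `n_refine` highest-likelihood pilots are continued to convergence, and
#' the best fit is kept. Before discovering the next motif, the
#' maximum-a-posteriori site of every sequence with site posterior > 0.5 is
#' erased (masked to N), so successive motifs describe different signals.
#'
#' The seed pool is the `5 * n_seeds` most over-represented words; from it,
#' `n_seeds` restarts are drawn without replacement with probability
#' proportional to over-representation, deterministically under `seed`
#' (seed 0 and a pool no larger than `n_seeds` reduce to the plain top-n
#' ranking).
#'
#' @inheritParams zoops_em
#' @param w motif width (default 6, the classical -10 hexamer).
#' @param nmotifs number of motifs to discover in sequence.
#' @param n_seeds restarts per motif.
#' @param seed integer seed controlling the restart draw.
#' @param pilot_iters EM iterations in the pilot stage.
#' @param n_refine pilots continued to convergence.
#' @return list of fitted [motif_model()] objects in discovery order; each
#'   carries the erasure-stage posteriors in attribute `posteriors`.
#' @export
discover_motifs <- function(windows, w = 6L, nmotifs = 2L, n_seeds = 50L,
                            seed = 0L, max_iter = 200L, tol = 1e-6,
                            pilot_iters = 5L, n_refine = 3L) {
  stopifnot(nmotifs >= 1L)
  seqs <- window_seqs(windows)
  ids <- window_ids(windows)
  background <- estimate_background(seqs)
  models <- vector("list", nmotifs)

  for (mi in seq_len(nmotifs)) {
    pool <- seed_candidates(seqs, w, 5L * n_seeds, background)
    take <- min(n_seeds, length(pool))
    if (length(pool) > take) {
      sc <- attr(pool, "scores")
      prob <- exp(sc - max(sc))
      pick <- withr::with_seed(seed + mi,
        sample.int(length(pool), take, prob = prob))
      pool <- pool[sort(pick)]
    }
    ## two-stage restarts: a short pilot EM for every seed, then full EM
    ## continued from the few most promising fits
    pilots <- lapply(pool, function(theta0)
      zoops_em(seqs, theta0, background, max_iter = pilot_iters, tol = tol))
    lls <- vapply(pilots, function(f) f$model$log_likelihood, numeric(1))
    best <- NULL
    for (pi in utils::head(order(-lls), n_refine)) {
      fit <- zoops_em(seqs, pilots[[pi]]$model$theta, background,
                      max_iter = max_iter, tol = tol,
                      gamma0 = pilots[[pi]]$model$gamma)
      if (is.null(best) ||
          fit$model$log_likelihood > best$model$log_likelihood)
        best <- fit
    }
    attr(best$model, "posteriors") <- best$posteriors
    models[[mi]] <- best$model

    if (mi < nmotifs) {   # erase MAP sites before the next round
      site_post <- rowSums(best$posteriors$Z)
      map_off <- max.col(best$posteriors$Z, ties.method = "first")
      for (i in which(site_post > 0.5)) {
        substr(seqs[i], map_off[i], map_off[i] + w - 1L) <-
          strrep("N", w)
      }
    }
  }
  names(models) <- paste0("motif_", seq_len(nmotifs))
  models
}

#' Consensus and site-variant table of a fitted motif
#'
#' The consensus is the argmax base per column. The variant table counts the
#' exact word found at each sequence's maximum-a-posteriori site (site
#' posterior > 0.5), sorted by decreasing count.
#'
#' @param model fitted `motif_model`.
#' @param windows the windows the model was fitted on.
#' @param posteriors posteriors as returned by [zoops_em()]; recomputed with
#'   one E-step when NULL.
#' @return list with `consensus` (string) and `variants` (data.frame with
#'   `word`, `count`).
#' @export
consensus_and_variants <- function(model, windows, posteriors = NULL) {
  seqs <- window_seqs(windows)
  if (is.null(posteriors))
    posteriors <- attr(model, "posteriors") %||%
      site_posteriors(model, seqs)
  site_post <- rowSums(posteriors$Z)
  map_off <- max.col(posteriors$Z, ties.method = "first")
  hit <- which(site_post > 0.5)
  words <- substr(seqs[hit], map_off[hit], map_off[hit] + model$w - 1L)
  words <- words[!grepl("N", words, fixed = TRUE)]
  tab <- sort(table(words), decreasing = TRUE)
  list(consensus = consensus_string(model),
       variants = data.frame(word = names(tab), count = as.integer(tab),
                             stringsAsFactors = FALSE))
}

#' One E-step of the ZOOPS model at fixed parameters
#' @inheritParams consensus_and_variants
#' @param windows windows data.frame or character vector.
#' @return posterior list as in [zoops_em()].
#' @export
site_posteriors <- function(model, windows) {
  zoops_em(windows, model$theta, model$background, max_iter = 1L,
           gamma0 = if (is.na(model$gamma)) 0.5 else model$gamma)$posteriors
}

#' Fraction of training windows carrying a ZOOPS site
#'
#' The share of windows whose posterior probability of containing a motif
#' site exceeds 0.5 under the fitted ZOOPS model. On short upstream windows
#' this is the model-based estimate of the motif-carrying fraction of the
#' genome: the short window leaves little room for chance matches, so —
#' unlike a best-site count over a long scan window at a fixed p-value
#' threshold — it is not diluted by background hits.
#'
#' @param model fitted `motif_model` (posteriors recomputed if it does not
#'   carry them).
#' @param windows the training windows, required when posteriors are
#'   recomputed.
#' @return fraction in `[0, 1]`.
#' @export
zoops_site_fraction <- function(model, windows = NULL) {
  post <- attr(model, "posteriors")
  if (is.null(post)) {
    if (is.null(windows)) stop("windows required to recompute posteriors")
    post <- site_posteriors(model, windows)
  }
  mean(rowSums(post$Z) > 0.5)
}

#' Per-column information content of a motif
#'
#' `IC_j = sum_b theta[b,j] * log2(theta[b,j] / background[b])` — the
#' Kullback-Leibler divergence of each column from the background, in bits.
#'
#' @param model a `motif_model`.
#' @return numeric vector of length `w`.
#' @export
information_content <- function(model) {
  th <- model$theta
  bg <- model$background
  term <- th * log2(th / bg)
  term[th == 0] <- 0
  colSums(term)
}
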