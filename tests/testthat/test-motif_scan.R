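test_that("scoring matrix matches direct per-word evaluation", {
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  m <- motif_model(matrix(0.25, 4, 6), bg)
  sm <- make_scoring_matrix(m)
  expect_true(all(abs(sm$log_odds) < 1e-9))      # theta == background
  set.seed(3)
  theta <- random_pwm(6)
  bg2 <- c(0.2, 0.3, 0.3, 0.2)
  m2 <- motif_model(theta, bg2)
  sm2 <- make_scoring_matrix(m2)
  ## brute-force: every 4-mer prefix word score equals column sum
  words <- as.matrix(expand.grid(rep(list(1:4), 6)))
  direct <- numeric(nrow(words))
  thp <- sweep(theta + 0.001, 2, colSums(theta + 0.001), "/")
  for (j in 1:6) direct <- direct + log2(thp[cbind(words[, j], j)] / bg2[words[, j]])
  viasm <- numeric(nrow(words))
  for (j in 1:6) viasm <- viasm + sm2$log_odds[cbind(words[, j], j)]
  expect_equal(viasm, direct, tolerance = 1e-12)
  ## consensus word attains the maximum
  expect_equal(max(viasm), sum(apply(sm2$log_odds, 2, max)), tolerance = 1e-12)
})

test_that("exact p-values match brute-force enumeration", {
  set.seed(11)
  for (rep in 1:5) {
    theta <- random_pwm(6, alpha = if (rep %% 2) 1 else 0.3)
    bg <- as.numeric(random_pwm(1)[, 1])
    m <- motif_model(theta, bg)
    sm <- make_scoring_matrix(m)
    dist <- exact_pvalues(sm, bg)
    oracle <- brute_force_survival(sm$int_scores, bg)
    got <- score_pvalue(dist, oracle$score)
    expect_lt(max(abs(got - oracle$survival)), 1e-12)
  }
})

test_that("survival function boundary values behave", {
  bg <- rep(0.25, 4)
  idx <- match(strsplit("TACACT", "")[[1]], c("A", "C", "G", "T"))
  hot <- matrix(0, 4, 6); hot[cbind(idx, 1:6)] <- 1
  m <- motif_model(hot, bg)
  sm <- make_scoring_matrix(m)
  dist <- exact_pvalues(sm, bg)
  expect_equal(score_pvalue(dist, dist$min_int), 1, tolerance = 1e-12)
  ## the maximum is achieved only by the consensus word
  expect_equal(score_pvalue(dist, dist$max_int), 0.25^6, tolerance = 1e-12)
  ## survival non-increasing
  expect_true(all(diff(dist$survival) <= 0))
})

test_that("scanning respects strand, N handling and degenerate input", {
  w <- planted_windows(60, frac = 1, offset = 7, seed = 6)
  mods <- discover_motifs(w, w = 6, nmotifs = 1, n_seeds = 5, seed = 0)
  sm <- make_scoring_matrix(mods[[1]])
  dist <- exact_pvalues(sm)
  expect_equal(nrow(scan_sequence("ACG", sm, dist)), 0L)
  hits <- scan_sequence("GGGGGGTACACTGGGGGG", sm, dist, 0.015)
  expect_true(7 %in% hits$pos)
  ## site only on the reverse strand is invisible (given-strand semantics)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("GGGGGGTACACTGGGGGG")))
  hits_rc <- scan_sequence(rc, sm, dist, 0.015)
  expect_false(any(hits_rc$word == "TACACT"))
  ## N-containing words are skipped, flanking hits survive
  hits_n <- scan_sequence("TACACTNNTACACT", sm, dist, 0.5)
  expect_false(any(grepl("N", hits_n$word)))
  expect_true(all(c(1, 9) %in% hits_n$pos))
})

test_that("planted consensus in a 450-bp scan window is recovered at its offset", {
  spec <- synthetic_spec(n_genes = 120, rng_seed = 14)
  g <- gen_genome(spec)
  up <- extract_upstream(g$genes, g$contigs)
  mods <- discover_motifs(up, w = 6, nmotifs = 1, n_seeds = 10, seed = 0)
  sm <- make_scoring_matrix(mods[[1]])
  dist <- exact_pvalues(sm)
  sw <- extract_scan_window(g$genes, g$contigs)
  expect_true(all(nchar(sw$seq) == 450))
  sites <- scan_gene_windows(sw, sm, dist)
  tr <- g$truth[g$truth$has_motif, ]
  found <- vapply(seq_len(nrow(tr)), function(i)
    any(sites$gene_id == tr$gene_id[i] & sites$offset == tr$motif_offset[i]),
    logical(1))
  ## exact-consensus words always pass (maximal score); words with all three
  ## near-invariant bases intact pass unless their middle bases are so
  ## unfavorable that the exact p-value exceeds the threshold
  expect_true(all(found[tr$motif_word == "TACACT"]))
  intact <- with(tr, substr(motif_word, 1, 1) == "T" &
                   substr(motif_word, 2, 2) == "A" &
                   substr(motif_word, 6, 6) == "T")
  expect_gte(mean(found[intact]), 0.9)
  ## spacer bookkeeping: offset -> spacer identity for upstream sites
  upstream <- sites$offset < 0
  expect_equal(sites$spacer[upstream], -sites$offset[upstream] - 6)
})

test_that("threshold monotonicity and score/p consistency hold", {
  spec <- synthetic_spec(n_genes = 60, rng_seed = 15)
  g <- gen_genome(spec)
  up <- extract_upstream(g$genes, g$contigs)
  mods <- discover_motifs(up, w = 6, nmotifs = 1, n_seeds = 8, seed = 0)
  sm <- make_scoring_matrix(mods[[1]])
  dist <- exact_pvalues(sm)
  sw <- extract_scan_window(g$genes, g$contigs, up = 100, down = 50)
  loose <- scan_gene_windows(sw, sm, dist, p_threshold = 0.05)
  strict <- scan_gene_windows(sw, sm, dist, p_threshold = 0.005)
  key <- function(s) paste(s$gene_id, s$offset)
  expect_true(all(key(strict) %in% key(loose)))
  expect_true(all(strict$p_value <= 0.005))
  ## within a scan: higher score implies lower-or-equal p
  ord <- order(loose$score)
  expect_true(all(diff(loose$p_value[ord]) <= 1e-15))
})

test_that("best-site selection breaks p-value ties toward the 3' site", {
  win <- data.frame(gene_id = "g1",
                    seq = "GGGGGTACACTGGGGGGGGGGTACACTGGGGG",
                    offset_of_last_base = -1L)
  w <- planted_windows(80, frac = 1, offset = 7, seed = 19)
  mods <- discover_motifs(w, w = 6, nmotifs = 1, n_seeds = 5, seed = 0)
  sm <- make_scoring_matrix(mods[[1]])
  dist <- exact_pvalues(sm)
  sites <- scan_gene_windows(win, sm, dist, p_threshold = 0.05)
  both <- sites[sites$word == "TACACT", ]
  expect_equal(nrow(both), 2L)
  best <- best_site_per_gene(sites)
  expect_equal(best$offset, max(both$offset))
  ## a gene with no passing site is absent from the site table
  null_win <- data.frame(gene_id = "g2", seq = strrep("G", 40),
                         offset_of_last_base = -1L)
  s2 <- scan_gene_windows(null_win, sm, dist)
  expect_equal(nrow(s2), 0L)
})

test_that("null passing-site counts match the binomial expectation", {
  set.seed(23)
  theta <- random_pwm(6)
  bg <- rep(0.25, 4)
  m <- motif_model(theta, bg)
  sm <- make_scoring_matrix(m)
  dist <- exact_pvalues(sm, bg)
  alpha_eff <- max(dist$survival[dist$survival <= 0.015])
  L <- 450; nrep <- 300
  seqs <- vapply(seq_len(nrep), function(i)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  wins <- data.frame(gene_id = paste0("r", seq_len(nrep)), seq = seqs,
                     offset_of_last_base = -1L)
  sites <- scan_gene_windows(wins, sm, dist, p_threshold = 0.015)
  n_off <- (L - 6 + 1) * nrep
  expected <- n_off * alpha_eff
  sd3 <- 3 * sqrt(n_off * alpha_eff * (1 - alpha_eff))
  expect_lt(abs(nrow(sites) - expected), sd3 + 1)
})
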