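test_that("background estimation floors, renormalizes and recovers GC content", {
  bg <- estimate_background(c("AAAAAAAA", "AAAA"))
  expect_equal(sum(bg), 1)
  expect_gt(bg["A"], 0.99)
  expect_true(all(bg[c("C", "G", "T")] > 0))   # floored, never zero
  bg2 <- estimate_background("ACGTACGT")
  expect_equal(as.numeric(bg2), rep(0.25, 4))
  w <- planted_windows(1000, frac = 0, gc = 0.65, seed = 9)
  bg3 <- estimate_background(w)
  expect_lt(abs(sum(bg3[c("C", "G")]) - 0.65), 0.01)
})

test_that("seeding ranks planted and over-represented words on top", {
  w <- planted_windows(200, frac = 1, word = "TACACT", seed = 4)
  seeds <- seed_candidates(w, 6, 5)
  expect_true("TACACT" %in% names(seeds))
  th <- seeds[["TACACT"]]
  expect_equal(unname(colSums(th)), rep(1, 6))
  expect_equal(unname(th["T", 1]), 0.85)
  expect_equal(unname(th["A", 2]), 0.85)
  ## all windows identical: seeds are that window's own w-mers
  same <- rep("ACGTACGTACGT", 5)
  s2 <- seed_candidates(same, 6, 3)
  expect_true(all(names(s2) %in% c("ACGTAC", "CGTACG", "GTACGA", "GTACGT",
                                   "TACGTA")))
})

test_that("ZOOPS EM converges to the planted word on a toy fixture", {
  ## two sequences sharing one exact 6-mer on random background
  set.seed(7)
  seqs <- c("GGCGGTACACTGCGCC", "CCGCGTACACTGGGCG")
  seeds <- seed_candidates(seqs, 6, 1)
  fit <- zoops_em(seqs, seeds[[1]], estimate_background(seqs))
  idx <- match(strsplit("TACACT", "")[[1]], c("A", "C", "G", "T"))
  probs <- fit$model$theta[cbind(idx, 1:6)]
  expect_true(all(probs > 0.95))
  expect_gt(fit$model$gamma, 0.95)
})

test_that("EM log likelihood is monotone and posteriors normalize", {
  w <- planted_windows(150, frac = 0.4, seed = 12)
  seeds <- seed_candidates(w, 6, 8)
  bg <- estimate_background(w)
  for (th in seeds) {
    fit <- zoops_em(w, th, bg, max_iter = 60)
    expect_true(all(diff(fit$ll_trace) >= -1e-9))
    norm <- rowSums(fit$posteriors$Z) + fit$posteriors$no_site
    expect_true(all(abs(norm - 1) < 1e-9))
  }
})

test_that("degenerate one-sequence input reaches a stable fixed point", {
  fit <- zoops_em("TACACT", seed_candidates("TACACT", 6, 1)[[1]],
                  rep(0.25, 4), max_iter = 100)
  expect_lt(length(fit$ll_trace), 100)            # converged before cap
  expect_equal(consensus_string(fit$model), "TACACT")
})

test_that("pure-noise windows carry far less motif signal than planted ones", {
  ## on noise, ZOOPS converges to a rare chance pattern: the occurrence
  ## prior gamma collapses even when the column IC of that pattern is
  ## moderate, so the per-sequence expected information (gamma x mean IC)
  ## is the quantity that separates noise from a planted motif
  null_w <- planted_windows(800, frac = 0, gc = 0.5, seed = 21)
  null_m <- discover_motifs(null_w, w = 6, nmotifs = 1, n_seeds = 10,
                            seed = 0)[[1]]
  null_signal <- null_m$gamma * mean(information_content(null_m))
  pl_w <- planted_windows(800, frac = 0.3, gc = 0.5, seed = 21,
                          pwm = default_planted_pwm())
  pl_m <- discover_motifs(pl_w, w = 6, nmotifs = 1, n_seeds = 10,
                          seed = 0)[[1]]
  pl_signal <- pl_m$gamma * mean(information_content(pl_m))
  expect_lt(null_signal, 0.2)
  expect_lt(null_signal, pl_signal / 2)
})

test_that("two disjointly planted motifs are both recovered in order", {
  set.seed(31)
  w <- planted_windows(400, frac = 0, gc = 0.5, seed = 31)
  i1 <- 1:160; i2 <- 161:320                       # disjoint 40% / 40%
  for (i in i1) substr(w[i], 8, 13) <- "TACACT"
  for (i in i2) substr(w[i], 8, 13) <- "GGAGGA"
  mods <- discover_motifs(w, w = 6, nmotifs = 2, n_seeds = 15, seed = 0)
  cons <- vapply(mods, consensus_string, character(1))
  expect_setequal(cons, c("TACACT", "GGAGGA"))
  ## single-motif request: one model, no erasure pass
  one <- discover_motifs(w, w = 6, nmotifs = 1, n_seeds = 15, seed = 0)
  expect_length(one, 1L)
})

test_that("variant table reflects planted variant ratios", {
  set.seed(8)
  w <- planted_windows(400, frac = 0, gc = 0.5, seed = 8)
  variant <- ifelse(seq_len(400) %% 4 == 0, "TAGACT", "TACACT")  # 3:1
  for (i in 1:400) substr(w[i], 9, 14) <- variant[i]
  mods <- discover_motifs(w, w = 6, nmotifs = 1, n_seeds = 10, seed = 0)
  cv <- consensus_and_variants(mods[[1]], w)
  expect_equal(cv$consensus, "TACACT")
  expect_equal(cv$variants$word[1], "TACACT")
  ratio <- cv$variants$count[cv$variants$word == "TACACT"] /
    cv$variants$count[cv$variants$word == "TAGACT"]
  expect_gt(ratio, 2.2); expect_lt(ratio, 4.2)     # 3:1 within binomial error
  ## degenerate: identical sites give a single variant
  same <- planted_windows(50, frac = 1, offset = 7, seed = 2)
  m2 <- discover_motifs(same, w = 6, nmotifs = 1, n_seeds = 5, seed = 0)
  cv2 <- consensus_and_variants(m2[[1]], same)
  expect_equal(cv2$variants$word[1], "TACACT")
  expect_gt(cv2$variants$count[1], 45)
})

test_that("information content matches closed forms", {
  unif <- matrix(0.25, 4, 6)
  m <- motif_model(unif, rep(0.25, 4))
  expect_equal(information_content(m), rep(0, 6))
  idx <- match(strsplit("TACACT", "")[[1]], c("A", "C", "G", "T"))
  hot <- matrix(0, 4, 6); hot[cbind(idx, 1:6)] <- 1  # exact one-hot
  m2 <- motif_model(hot, rep(0.25, 4))
  expect_equal(information_content(m2), rep(2, 6))
})

test_that("the EM core is symmetric under reverse complement", {
  w <- planted_windows(120, frac = 0.5, seed = 17)
  bg <- estimate_background(w)
  th0 <- seed_candidates(w, 6, 1)[[1]]
  fit <- zoops_em(w, th0, bg)
  wrc <- vapply(w, function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s))), character(1), USE.NAMES = FALSE)
  th0rc <- th0[4:1, 6:1]; rownames(th0rc) <- c("A", "C", "G", "T")
  fitrc <- zoops_em(wrc, th0rc, rev(bg))
  expect_equal(fit$model$log_likelihood, fitrc$model$log_likelihood,
               tolerance = 1e-8)
  threv <- fitrc$model$theta[4:1, 6:1]
  expect_equal(unname(fit$model$theta), unname(threv), tolerance = 1e-6)
})

test_that("MEME minimal format round-trips motif matrices", {
  w <- planted_windows(100, frac = 0.6, seed = 5)
  mods <- discover_motifs(w, w = 6, nmotifs = 1, n_seeds = 5, seed = 0)
  path <- tempfile(fileext = ".txt")
  write_meme(mods, path)
  back <- read_meme(path)
  expect_equal(names(back), "motif_1")
  expect_equal(unname(back[[1]]$theta), unname(mods[[1]]$theta),
               tolerance = 1e-4)
  expect_equal(as.numeric(back[[1]]$background),
               as.numeric(mods[[1]]$background), tolerance = 1e-4)
})
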