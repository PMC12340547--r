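test_that("depth accumulation and the gap/inversion filter follow the rules", {
  clen <- c(chr = 100L)
  iv <- data.frame(contig = "chr", start = 10L, end = 20L,
                   has_gap = FALSE, is_inverted = FALSE)
  tr <- depth_from_alignments(iv, clen)
  expect_equal(tr$chr[11:20], rep(1L, 10))
  expect_equal(sum(tr$chr), 10)
  ## gapped interval contributes nothing but is counted
  iv2 <- rbind(iv, data.frame(contig = "chr", start = 30L, end = 40L,
                              has_gap = TRUE, is_inverted = FALSE))
  tr2 <- depth_from_alignments(iv2, clen)
  expect_equal(sum(tr2$chr), 10)
  expect_equal(attr(tr2, "n_excluded"), 1L)
  expect_equal(attr(tr2, "n_gap"), 1L)
  ## out-of-bounds interval is an error
  bad <- data.frame(contig = "chr", start = 95L, end = 105L)
  expect_error(depth_from_alignments(bad, clen), "beyond contig")
})

test_that("depth from 500 random intervals equals brute-force membership", {
  set.seed(77)
  clen <- c(c1 = 300L, c2 = 200L)
  n <- 500
  ctg <- sample(names(clen), n, replace = TRUE)
  s <- vapply(ctg, function(cn) sample.int(clen[[cn]] - 20L, 1L) - 1L,
              integer(1))
  e <- s + sample(1:20, n, replace = TRUE)
  iv <- data.frame(contig = ctg, start = s, end = e)
  tr <- depth_from_alignments(iv, clen)
  for (cn in names(clen)) {
    brute <- integer(clen[[cn]])
    for (i in which(ctg == cn)) {
      rng <- (s[i] + 1L):e[i]
      brute[rng] <- brute[rng] + 1L
    }
    expect_equal(tr[[cn]], brute)
  }
  ## conservation: total depth equals summed interval lengths
  expect_equal(total_depth(tr), sum(e - s))
})

test_that("bedGraph round-trips a coverage track", {
  set.seed(5)
  tr <- structure(list(chr = as.integer(rpois(400, 2))),
                  class = "coverage_track")
  path <- tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, path)
  back <- read_bedgraph(path, c(chr = 400L))
  expect_equal(back$chr, tr$chr)
})

test_that("region selection is strand-aware with correct arithmetic", {
  gene <- data.frame(gene_id = "g", contig = "chr", strand = "+",
                     start = 1000L, end = 1900L)
  r <- region_selection(gene[1, ], up = 400, down = 400)
  expect_equal(r$end - r$start, 1700L)            # 900-nt gene + 2*400
  gm <- gene; gm$strand <- "-"
  rm_ <- region_selection(gm[1, ], up = 400, down = 400)
  expect_equal(rm_$start, 600L); expect_equal(rm_$end, 2300L)
  ## edge gene dropped with warning
  ge <- gene; ge$start <- 100L; ge$end <- 400L
  expect_warning(expect_null(
    region_selection(ge[1, ], up = 400, down = 400,
                     contig_lengths = c(chr = 5000L))), "dropped")
})

test_that("gene profiles are coding-strand oriented", {
  v <- integer(500); v[201:300] <- 5L            # depth 5 on [200,300)
  tr <- structure(list(chr = v), class = "coverage_track")
  gene <- data.frame(gene_id = "g", contig = "chr", strand = "+",
                     start = 200L, end = 300L)
  p <- gene_profile(tr, gene[1, ], flank = 50)
  expect_length(p$depth, 200L)
  expect_equal(unname(profile_zoom(p, 0, 9)), rep(5, 10))
  expect_equal(unname(profile_zoom(p, -10, -1)), rep(0, 10))
  ## minus-strand profile is the reverse of the forward slice
  gm <- gene; gm$strand <- "-"
  pm <- gene_profile(tr, gm[1, ], flank = 50)
  expect_equal(pm$depth, rev(p$depth))
  ## flat track gives a constant profile
  trc <- structure(list(chr = rep(7L, 500)), class = "coverage_track")
  pc <- gene_profile(trc, gene[1, ], flank = 20)
  expect_true(all(pc$depth == 7L))
})

test_that("step statistic classifies flat, zero and stepped profiles", {
  gene <- data.frame(gene_id = "g", contig = "chr", strand = "+",
                     start = 100L, end = 400L)
  flat <- structure(list(chr = rep(5L, 600)), class = "coverage_track")
  p <- gene_profile(flat, gene[1, ], flank = 100)
  call <- step_statistic(p, motif_end_offset = -7L)
  expect_equal(call$class, "flat")
  expect_lt(abs(call$ratio - 5 / 5.5), 1e-9)
  zero <- structure(list(chr = integer(600)), class = "coverage_track")
  p0 <- gene_profile(zero, gene[1, ], flank = 100)
  expect_equal(step_statistic(p0, -7L)$class, "low-coverage")
  ## sharp synthetic step at the motif end
  v <- integer(600); v[94:400] <- 10L            # step at 0-based 93 = rel -7+1
  stepped <- structure(list(chr = v), class = "coverage_track")
  ps <- gene_profile(stepped, gene[1, ], flank = 100)
  expect_equal(step_statistic(ps, -8L)$class, "step-increase")
})

test_that("Poisson step genes are detected with high sensitivity", {
  set.seed(9)
  nrep <- 200
  calls <- character(nrep)
  for (i in seq_len(nrep)) {
    depth <- c(rpois(120, 1), rpois(180, 10))    # step at index 121
    p <- structure(list(gene_id = "g", depth = depth, flank = 100L,
                        gene_length = 100L), class = "gene_profile")
    ## motif end at rel offset 19 => index 121 starts the downstream window
    calls[i] <- step_statistic(p, motif_end_offset = 19L)$class
  }
  expect_gte(mean(calls == "step-increase"), 0.95)
})

test_that("trend aggregation counts classes and localizes the mean step", {
  set.seed(13)
  profiles <- list(); calls <- NULL
  for (i in 1:40) {
    depth <- c(rpois(110, 1), rpois(190, 10))
    p <- structure(list(gene_id = paste0("g", i), depth = depth,
                        flank = 100L, gene_length = 100L),
                   class = "gene_profile")
    profiles[[i]] <- p
    ## first high base at index 111 = rel +10; motif end at rel +9 puts the
    ## planted step at motif-anchored position +1
    calls <- rbind(calls, step_statistic(p, motif_end_offset = 9L))
  }
  agg <- aggregate_trends(calls, profiles)
  expect_equal(unname(agg$counts["step-increase"]), 40L)
  expect_equal(step_gradient_position(agg$curve), 1L)
  ## identical step profiles average to the same step shape
  same <- lapply(profiles[1], identity)
  agg1 <- aggregate_trends(calls[1, ], same)
  expect_equal(agg1$curve$mean_depth,
               profiles[[1]]$depth[(-50:100) + 9 + 101] /
                 mean(profiles[[1]]$depth))
})

test_that("raising tau never increases the step-increase count", {
  set.seed(19)
  profiles <- lapply(1:60, function(i) {
    depth <- c(rpois(110, 2), rpois(190, 2 + (i %% 3) * 4))
    structure(list(gene_id = paste0("g", i), depth = depth, flank = 100L,
                   gene_length = 100L), class = "gene_profile")
  })
  counts <- vapply(c(1.5, 2, 3, 5), function(tau) {
    sum(vapply(profiles, function(p)
      step_statistic(p, 10L, tau = tau)$class == "step-increase",
      logical(1)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})
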