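#' Default planted -10-like position probability matrix
#'
#' Consensus TACACT: the first T, second A and sixth T are near-invariant
#' (probability 0.97), while the middle three positions weakly favor C, A
#' and C (0.4 on the favored base, 0.2 elsewhere) — the TANNNT shape with a
#' most-frequent TACACT variant.
#'
#' @return 4 x 6 column-stochastic matrix, rows A,C,G,T.
#' @export
default_planted_pwm <- function() {
  inv <- function(b) { v <- rep(0.01, 4); v[match(b, DNA_BASES)] <- 0.97; v }
  mid <- function(b) { v <- rep(0.2, 4); v[match(b, DNA_BASES)] <- 0.4; v }
  theta <- cbind(inv("T"), inv("A"), mid("C"), mid("A"), mid("C"), inv("T"))
  rownames(theta) <- DNA_BASES
  theta
}

#' Specification of a synthetic genome benchmark
#'
#' Collects the parameters of the generator: a GC-rich background genome
#' with alternating-strand genes, a -10-like word planted a few bases
#' upstream of the start codon in a configurable fraction of genes, and
#' Poisson coverage with a step at the motif 3' end for leaderless genes.
#'
#' @param n_genes number of genes.
#' @param gene_length_range inclusive range of gene lengths (rounded to
#'   codon multiples).
#' @param intergenic_length_range inclusive range of intergenic gaps. The
#'   default lower bound of 120 keeps the benchmark geometry
#'   non-interfering: a neighboring leadered gene's coverage extends
#'   `|leadered_promoter_offset|` (80) bases beyond its ORF, and the step
#'   statistic's upstream window reaches ~33 bases out from a gene's start
#'   codon, so gaps of at least 80 + 33 bases guarantee that no gene's
#'   step windows overlap a neighbor's transcript or CDS.
#' @param gc_content background G+C fraction (default 0.65, a high-GC
#'   Deinococcus-Thermus-like genome).
#' @param planted_pwm PWM the planted words are sampled from.
#' @param planted_fraction fraction of genes receiving a planted site.
#' @param planted_count exact number of planted genes (overrides the
#'   binomial draw implied by `planted_fraction` when non-NULL).
#' @param spacer_distribution named probability vector over spacer values
#'   (bases between motif 3' end and start codon).
#' @param lambda_low,lambda_high Poisson depth before/after the coverage
#'   step.
#' @param leadered_promoter_offset start-codon-relative position at which
#'   leadered (5'-UTR-carrying) genes' coverage steps up.
#' @param leadered_fraction fraction of non-planted genes that are
#'   leadered (the rest stay at baseline coverage).
#' @param leadered_count exact count of leadered genes (optional).
#' @param gap_fraction fraction of emitted alignment intervals flagged as
#'   gapped/inverted, to exercise the exclusion filter.
#' @param rng_seed integer seed; all outputs are deterministic under it.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 1000L,
                           gene_length_range = c(300L, 900L),
                           intergenic_length_range = c(120L, 250L),
                           gc_content = 0.65,
                           planted_pwm = default_planted_pwm(),
                           planted_fraction = 0.30,
                           planted_count = NULL,
                           spacer_distribution = c("6" = 0.5, "7" = 0.5),
                           lambda_low = 1,
                           lambda_high = 10,
                           leadered_promoter_offset = -80L,
                           leadered_fraction = 0.5,
                           leadered_count = NULL,
                           gap_fraction = 0,
                           rng_seed = 0L) {
  stopifnot(n_genes >= 1L,
            planted_fraction >= 0, planted_fraction <= 1,
            all(abs(colSums(planted_pwm) - 1) < 1e-9),
            all(as.integer(names(spacer_distribution)) >= 0L),
            abs(sum(spacer_distribution) - 1) < 1e-9,
            intergenic_length_range[1] >= 40L,
            gap_fraction >= 0, gap_fraction < 1)
  structure(as.list(environment()), class = "synthetic_spec")
}

## Forward-strand 1-based positions and characters of a word placed at
## coding-strand positions rel_from..(rel_from + nchar - 1) of a gene.
overlay_positions <- function(start, end, strand, rel_from, word) {
  wlen <- nchar(word)
  if (strand == "+") {
    list(pos = start + rel_from + seq_len(wlen),    # 1-based fwd
         chars = strsplit(word, "")[[1]])
  } else {
    at <- end - rel_from - seq_len(wlen) + 1L       # descending fwd span
    list(pos = rev(at), chars = strsplit(revcomp_chr(word), "")[[1]])
  }
}

## In-place-style overlay for one-off edits (small genomes).
overlay_coding <- function(bases, start, end, strand, rel_from, word) {
  o <- overlay_positions(start, end, strand, rel_from, word)
  bases[o$pos] <- o$chars
  bases
}

#' Generate a synthetic genome, annotation and truth table
#'
#' Genes alternate strands along one contig. Every gene gets a start codon
#' (ATG) and stop codon (TAA) on its coding strand; planted genes
#' additionally receive a PWM-sampled word whose last base sits `spacer`
#' bases before the start codon. A spacer is drawn for every gene (planted
#' or not) so downstream benchmarks have a motif anchor for all genes. The
#' contig carries 500 bp of padding at both ends so flanked windows for
#' edge genes stay on-contig.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `contigs` ([Biostrings::DNAStringSet]), `genes` (gene
#'   table in [load_genome()] layout), `truth` (per-gene data.frame:
#'   `gene_id`, `strand`, `start`, `end`, `has_motif`, `motif_word`,
#'   `spacer`, `motif_offset`, `motif_end_offset`, `expr_class`,
#'   `is_leaderless`, `step_offset`), and `spec`.
#' @export
gen_genome <- function(spec) {
  withr::with_seed(spec$rng_seed, {
    n <- spec$n_genes
    glr <- spec$gene_length_range
    lens <- 3L * sample(seq(ceiling(glr[1] / 3), floor(glr[2] / 3)),
                        n, replace = TRUE)
    gaps <- sample(seq(spec$intergenic_length_range[1],
                       spec$intergenic_length_range[2]),
                   n + 1L, replace = TRUE)
    gaps[1] <- gaps[1] + 500L
    gaps[n + 1L] <- gaps[n + 1L] + 500L
    strand <- rep(c("+", "-"), length.out = n)

    starts <- cumsum(gaps[seq_len(n)]) + c(0L, cumsum(lens))[seq_len(n)]
    ends <- starts + lens
    G <- ends[n] + gaps[n + 1L]

    at <- (1 - spec$gc_content) / 2
    gc <- spec$gc_content / 2
    bases <- sample(DNA_BASES, G, replace = TRUE, prob = c(at, gc, gc, at))

    has_motif <- if (!is.null(spec$planted_count)) {
      v <- rep(FALSE, n); v[sample.int(n, spec$planted_count)] <- TRUE; v
    } else stats::runif(n) < spec$planted_fraction
    spacer <- as.integer(sample(names(spec$spacer_distribution), n,
                                replace = TRUE,
                                prob = spec$spacer_distribution))
    w <- ncol(spec$planted_pwm)
    words <- vapply(seq_len(n), function(i) {
      paste(DNA_BASES[vapply(seq_len(w), function(j)
        sample.int(4L, 1L, prob = spec$planted_pwm[, j]), integer(1))],
        collapse = "")
    }, character(1))

    nonplanted <- which(!has_motif)
    leadered <- rep(FALSE, n)
    if (!is.null(spec$leadered_count)) {
      leadered[sample(nonplanted,
                      min(spec$leadered_count, length(nonplanted)))] <- TRUE
    } else {
      leadered[nonplanted] <-
        stats::runif(length(nonplanted)) < spec$leadered_fraction
    }
    expr_class <- ifelse(has_motif, "leaderless",
                         ifelse(leadered, "leadered", "silent"))

    overlays <- vector("list", 3L * n)
    for (i in seq_len(n)) {
      overlays[[3L * i - 2L]] <-
        overlay_positions(starts[i], ends[i], strand[i], 0L, "ATG")
      overlays[[3L * i - 1L]] <-
        overlay_positions(starts[i], ends[i], strand[i], lens[i] - 3L, "TAA")
      if (has_motif[i])
        overlays[[3L * i]] <-
          overlay_positions(starts[i], ends[i], strand[i],
                            -(spacer[i] + w), words[i])
    }
    overlays <- overlays[!vapply(overlays, is.null, logical(1))]
    bases[unlist(lapply(overlays, `[[`, "pos"))] <-
      unlist(lapply(overlays, `[[`, "chars"))

    contigs <- Biostrings::DNAStringSet(
      stats::setNames(paste(bases, collapse = ""), "chr"))
    gene_id <- sprintf("gene_%04d", seq_len(n))
    genes <- data.frame(gene_id = gene_id, contig = "chr", strand = strand,
                        start = starts, end = ends, start_codon = "ATG",
                        stringsAsFactors = FALSE)
    truth <- data.frame(
      gene_id = gene_id, strand = strand, start = starts, end = ends,
      has_motif = has_motif,
      motif_word = ifelse(has_motif, words, NA_character_),
      spacer = spacer,
      motif_offset = -(spacer + w),
      motif_end_offset = -(spacer + 1L),
      expr_class = expr_class,
      is_leaderless = expr_class == "leaderless",
      step_offset = ifelse(expr_class == "leaderless", -spacer,
                    ifelse(expr_class == "leadered",
                           spec$leadered_promoter_offset, NA_integer_)),
      stringsAsFactors = FALSE)
    list(contigs = contigs, genes = genes, truth = truth, spec = spec)
  })
}

#' Generate synthetic coverage with a step at the motif 3' end
#'
#' Per-base depth is drawn independently as Poisson with a baseline rate
#' `lambda_low` over the whole contig; leaderless genes raise the rate to
#' `lambda_high` from the first base after the planted motif through the
#' ORF end (on the coding strand), leadered genes from
#' `leadered_promoter_offset`, and silent genes stay at baseline.
#' Optionally the drawn track is decomposed into stacked alignment
#' intervals (so that rebuilding depth from the intervals reproduces the
#' track exactly), with a configurable fraction of additional
#' gapped/inverted flagged intervals that carry no depth.
#'
#' @param spec a [synthetic_spec()].
#' @param truth,genes from [gen_genome()].
#' @param contigs contig set from [gen_genome()].
#' @param make_intervals also emit the alignment-interval table (quadratic
#'   in depth; intended for modest genomes).
#' @return list with `track` (a `coverage_track`), `intervals` (data.frame
#'   or NULL), `n_flagged`.
#' @export
gen_coverage <- function(spec, truth, genes, contigs,
                         make_intervals = FALSE) {
  withr::with_seed(spec$rng_seed + 1L, {
    clen <- contig_length_vec(contigs)
    G <- clen[["chr"]]
    rate <- rep(spec$lambda_low, G)
    for (i in seq_len(nrow(truth))) {
      so <- truth$step_offset[i]
      if (is.na(so)) next
      glen <- truth$end[i] - truth$start[i]
      if (truth$strand[i] == "+") {
        a <- truth$start[i] + so + 1L; b <- truth$end[i]      # 1-based fwd
      } else {
        a <- truth$start[i] + 1L; b <- truth$end[i] - so
      }
      a <- max(a, 1L); b <- min(b, G)
      rate[a:b] <- spec$lambda_high
    }
    depth <- stats::rpois(G, rate)
    track <- structure(list(chr = as.integer(depth)),
                       class = "coverage_track")

    intervals <- NULL
    n_flagged <- 0L
    if (make_intervals) {
      parts <- lapply(seq_len(max(depth)), function(k) {
        r <- rle(depth >= k)
        ends <- cumsum(r$lengths)
        s <- ends - r$lengths
        keep <- r$values
        if (!any(keep)) return(NULL)
        data.frame(contig = "chr", start = s[keep], end = ends[keep])
      })
      intervals <- do.call(rbind, parts)
      intervals$has_gap <- FALSE
      intervals$is_inverted <- FALSE
      if (spec$gap_fraction > 0) {
        n_flagged <- round(spec$gap_fraction / (1 - spec$gap_fraction) *
                             nrow(intervals))
        if (n_flagged > 0) {
          fs <- sample.int(G - 100L, n_flagged)
          fl <- sample(30:100, n_flagged, replace = TRUE)
          flagged <- data.frame(contig = "chr", start = fs - 1L,
                                end = pmin(fs - 1L + fl, G),
                                has_gap = FALSE, is_inverted = FALSE)
          half <- seq_len(n_flagged) <= n_flagged / 2
          flagged$has_gap[half] <- TRUE
          flagged$is_inverted[!half] <- TRUE
          intervals <- rbind(intervals, flagged)
        }
      }
      intervals <- intervals[sample.int(nrow(intervals)), , drop = FALSE]
      rownames(intervals) <- NULL
    }
    list(track = track, intervals = intervals, n_flagged = n_flagged)
  })
}

#' Write a complete synthetic input set to a directory
#'
#' One call produces everything the pipeline consumes — genome FASTA, GFF3
#' annotation, bedGraph coverage, alignment-interval TSV and the
#' ground-truth TSV — plus the in-memory objects.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @param make_intervals forwarded to [gen_coverage()].
#' @return invisible list with the generated objects and file `paths`.
#' @export
end_to_end_fixture <- function(spec, dir, make_intervals = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- gen_genome(spec)
  cov <- gen_coverage(spec, g$truth, g$genes, g$contigs,
                      make_intervals = make_intervals)
  paths <- list(fasta = file.path(dir, "genome.fna"),
                gff3 = file.path(dir, "genes.gff3"),
                bedgraph = file.path(dir, "coverage.bedgraph"),
                truth = file.path(dir, "truth.tsv"))
  Biostrings::writeXStringSet(g$contigs, paths$fasta, width = 60L)
  gr <- GenomicRanges::GRanges(
    g$genes$contig,
    IRanges::IRanges(g$genes$start + 1L, g$genes$end),
    strand = g$genes$strand)
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$phase <- 0L
  S4Vectors::mcols(gr)$ID <- g$genes$gene_id
  S4Vectors::mcols(gr)$locus_tag <- g$genes$gene_id
  rtracklayer::export(gr, paths$gff3, format = "gff3")
  write_bedgraph(cov$track, paths$bedgraph)
  utils::write.table(g$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(cov$intervals)) {
    paths$intervals <- file.path(dir, "intervals.tsv")
    utils::write.table(cov$intervals, paths$intervals, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(c(g, cov, list(paths = paths)))
}

#' Generate reannotation benchmark genes
#'
#' Builds a genome whose genes carry the planted consensus word inside the
#' annotated ORF (at coding position `motif_rel`), followed after
#' `spacer_after` bases by an in-frame start codon — the situation where
#' the annotated start overshoots the true leaderless start. Bases between
#' motif end and the planted codon are filled with C so no competing
#' initiator codon precedes it, and chance duplicate consensus words more
#' 3' in the scan window are disrupted so the planted site is always the
#' best-scoring one.
#'
#' @param n_genes number of genes.
#' @param motif_rel coding-strand position of the planted motif's first
#'   base relative to the annotated start (must be a positive multiple not
#'   required; default 30).
#' @param spacer_after bases between motif end and planted codon; drawn per
#'   gene from this set, constrained so the codon is in frame.
#' @param codon planted start codon (default GTG, the classic
#'   immediately-after-the-motif case).
#' @param rng_seed seed.
#' @return list as [gen_genome()] with `truth` columns `planted_rel_start`
#'   (coding-relative proposed start) and `planted_codon`.
#' @export
gen_reannotation_cases <- function(n_genes = 50L, motif_rel = 30L,
                                   spacer_after = c(0L, 3L, 6L),
                                   codon = "GTG", rng_seed = 0L) {
  w <- 6L
  word <- "TACACT"
  stopifnot((motif_rel + w) %% 3L == 0L, all(spacer_after %% 3L == 0L))
  spec <- synthetic_spec(n_genes = n_genes, planted_fraction = 0,
                         gene_length_range = c(300L, 600L),
                         rng_seed = rng_seed)
  g <- gen_genome(spec)
  withr::with_seed(rng_seed + 7L, {
    bases <- strsplit(as.character(g$contigs[[1]]), "")[[1]]
    d <- sample(spacer_after, n_genes, replace = TRUE)
    rel_start <- motif_rel + w + d
    for (i in seq_len(n_genes)) {
      gi <- g$genes[i, ]
      ins <- paste0(word, strrep("C", d[i]), codon)
      bases <- overlay_coding(bases, gi$start, gi$end, gi$strand,
                              motif_rel, ins)
    }
    seqchr <- paste(bases, collapse = "")
    ## disrupt chance duplicates of the consensus word so the planted site
    ## is the unique top-scoring hit in every gene's scan window
    for (str in c("+", "-")) {
      pat <- if (str == "+") word else revcomp_chr(word)
      hits <- gregexpr(pat, seqchr, fixed = TRUE)[[1]]
      hits <- hits[hits > 0]
      for (h in hits) {
        planted <- vapply(seq_len(n_genes), function(i) {
          gi <- g$genes[i, ]
          if (gi$strand != str) return(FALSE)
          p0 <- if (str == "+") gi$start + motif_rel + 1L
                else gi$end - motif_rel - w + 1L
          h == p0
        }, logical(1))
        if (!any(planted))
          substr(seqchr, h + 2L, h + 2L) <- "G"   # TACACT -> TAGACT etc.
      }
    }
    g$contigs <- Biostrings::DNAStringSet(stats::setNames(seqchr, "chr"))
    g$truth$has_motif <- TRUE
    g$truth$motif_word <- word
    g$truth$motif_offset <- motif_rel
    g$truth$motif_end_offset <- motif_rel + w - 1L
    g$truth$spacer <- NA_integer_
    g$truth$planted_rel_start <- rel_start
    g$truth$planted_codon <- codon
    g
  })
}
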