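#' Build a per-base coverage track from alignment intervals
#'
#' Each retained interval increments depth by one over `[start, end)`
#' (0-based half-open, forward strand). Intervals flagged as containing
#' gaps or inversions are excluded from the track and counted — mirroring
#' the exclusion of gapped/inverted alignments from transcript
#' quantification.
#'
#' @param intervals data.frame with `contig`, `start`, `end` and optional
#'   logical `has_gap`, `is_inverted`.
#' @param contig_lengths named integer vector of contig lengths, or a
#'   [Biostrings::DNAStringSet].
#' @return object of class `coverage_track`: named list of integer depth
#'   vectors, with attributes `n_excluded`, `n_gap`, `n_inverted`.
#' @export
depth_from_alignments <- function(intervals, contig_lengths) {
  clen <- contig_length_vec(contig_lengths)
  unknown <- setdiff(unique(intervals$contig), names(clen))
  if (length(unknown))
    stop("intervals reference unknown contig(s): ",
         paste(unknown, collapse = ", "))
  if (any(intervals$start < 0L) ||
      any(intervals$end > clen[intervals$contig]))
    stop("interval beyond contig bounds")
  if (any(intervals$start >= intervals$end))
    stop("intervals must satisfy start < end")
  gap <- if ("has_gap" %in% names(intervals))
    isTRUE_vec(intervals$has_gap) else rep(FALSE, nrow(intervals))
  inv <- if ("is_inverted" %in% names(intervals))
    isTRUE_vec(intervals$is_inverted) else rep(FALSE, nrow(intervals))
  keep <- !gap & !inv
  track <- lapply(names(clen), function(cn) {
    len <- clen[[cn]]
    sel <- keep & intervals$contig == cn
    if (!any(sel)) return(integer(len))
    s <- intervals$start[sel]; e <- intervals$end[sel]
    delta <- tabulate(s + 1L, nbins = len + 1L) -
      tabulate(e + 1L, nbins = len + 1L)
    as.integer(cumsum(delta[seq_len(len)]))
  })
  names(track) <- names(clen)
  structure(track, class = "coverage_track",
            n_excluded = sum(!keep), n_gap = sum(gap), n_inverted = sum(inv))
}

contig_length_vec <- function(x) {
  if (inherits(x, "DNAStringSet"))
    return(stats::setNames(Biostrings::width(x), names(x)))
  if (inherits(x, "coverage_track"))
    return(stats::setNames(lengths(x), names(x)))
  if (is.null(names(x))) stop("contig lengths must be named")
  x
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Total depth mass of a coverage track
#' @param track a `coverage_track`.
#' @return sum of depth over all contigs.
#' @export
total_depth <- function(track) sum(vapply(track, function(v) sum(as.numeric(v)),
                                          numeric(1)))

#' Read/write coverage tracks as bedGraph
#'
#' Zero-depth runs are omitted on write, as is conventional for bedGraph.
#'
#' @param path bedGraph file path.
#' @param contig_lengths named lengths (or DNAStringSet) defining the full
#'   track extent on read.
#' @param track a `coverage_track` on write.
#' @return `read_bedgraph` returns a `coverage_track`.
#' @export
read_bedgraph <- function(path, contig_lengths) {
  clen <- contig_length_vec(contig_lengths)
  gr <- rtracklayer::import(path, format = "bedGraph")
  track <- lapply(names(clen), function(cn) {
    v <- integer(clen[[cn]])
    sel <- gr[as.character(GenomicRanges::seqnames(gr)) == cn]
    if (length(sel)) {
      s <- GenomicRanges::start(sel); e <- GenomicRanges::end(sel)
      sc <- as.integer(S4Vectors::mcols(sel)$score)
      for (i in seq_along(sel)) v[s[i]:e[i]] <- sc[i]
    }
    v
  })
  names(track) <- names(clen)
  structure(track, class = "coverage_track")
}

#' @rdname read_bedgraph
#' @export
write_bedgraph <- function(track, path) {
  parts <- lapply(names(track), function(cn) {
    r <- rle(track[[cn]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != 0L
    if (!any(keep)) return(NULL)
    GenomicRanges::GRanges(cn,
                           IRanges::IRanges(starts[keep], ends[keep]),
                           score = r$values[keep])
  })
  gr <- do.call(c, parts[!vapply(parts, is.null, logical(1))])
  if (is.null(gr))
    gr <- GenomicRanges::GRanges(score = integer(0))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Quantification region around a gene
#'
#' The ORF plus `up`/`down` flanking bases, oriented to the coding strand
#' (so "upstream" is 3' on the forward strand for minus-strand genes).
#'
#' @param gene one gene-table row.
#' @param up,down flank sizes in bp.
#' @param contig_lengths optional; when given, genes whose region leaves
#'   the contig are dropped (NULL return) with a warning.
#' @return one-row data.frame `contig`, `start`, `end`, `strand` (forward
#'   0-based half-open), or NULL.
#' @export
region_selection <- function(gene, up = 400L, down = 400L,
                             contig_lengths = NULL) {
  if (gene$strand == "+") {
    s <- gene$start - up; e <- gene$end + down
  } else {
    s <- gene$start - down; e <- gene$end + up
  }
  if (!is.null(contig_lengths)) {
    clen <- contig_length_vec(contig_lengths)
    if (s < 0L || e > clen[[gene$contig]]) {
      warning("region for ", gene$gene_id, " leaves contig; dropped")
      return(NULL)
    }
  }
  data.frame(contig = gene$contig, start = s, end = e,
             strand = gene$strand, stringsAsFactors = FALSE)
}

#' Coding-strand depth profile of a gene
#'
#' Depth over coding-strand positions `-flank .. gene_length + flank - 1`
#' relative to the first base of the start codon (the profile is reversed
#' for minus-strand genes). Genes whose flanked span leaves the contig are
#' dropped (NULL).
#'
#' @param track a `coverage_track`.
#' @param gene one gene-table row.
#' @param flank flank size in bp (default 100).
#' @return object of class `gene_profile`: list with `gene_id`, `depth`,
#'   `flank`, `gene_length`; or NULL at a contig edge.
#' @export
gene_profile <- function(track, gene, flank = 100L) {
  v <- track[[gene$contig]]
  if (is.null(v)) stop("no coverage for contig ", gene$contig)
  s <- gene$start - flank; e <- gene$end + flank
  if (s < 0L || e > length(v)) return(NULL)
  depth <- v[(s + 1L):e]
  if (gene$strand == "-") depth <- rev(depth)
  structure(list(gene_id = gene$gene_id, depth = depth,
                 flank = as.integer(flank),
                 gene_length = gene$end - gene$start),
            class = "gene_profile")
}

#' Slice of a profile in start-codon-relative coordinates
#'
#' The default -20..+60 slice is the zoomed view used for per-gene bar
#' charts of transcript levels around the start codon.
#'
#' @param profile a `gene_profile`.
#' @param from,to inclusive start-codon-relative positions (0 = first base
#'   of the start codon).
#' @return named numeric vector of depths.
#' @export
profile_zoom <- function(profile, from = -20L, to = 60L) {
  idx <- (from:to) + profile$flank + 1L
  if (any(idx < 1L) || any(idx > length(profile$depth)))
    stop("zoom range outside the profiled span")
  stats::setNames(profile$depth[idx], from:to)
}

#' Step statistic around a motif site
#'
#' Compares mean depth over the `up_window` bases ending at the motif's
#' last base with the `down_window` bases after it:
#' `R = downstream_mean / (upstream_mean + eps)`. Classes:
#' `low-coverage` when `downstream_mean < min_cov`; `step-increase` when
#' `R >= tau`; `decrease` when `R <= 1/tau`; otherwise `flat`.
#'
#' @param profile a `gene_profile`.
#' @param motif_end_offset start-codon-relative offset of the motif's last
#'   base (e.g. `site$offset + w - 1`).
#' @param up_window,down_window window sizes in bp.
#' @param tau ratio threshold for calling a step.
#' @param min_cov minimum downstream mean depth for a confident call.
#' @param eps denominator guard.
#' @return one-row data.frame: `gene_id`, `upstream_mean`,
#'   `downstream_mean`, `ratio`, `class`, `motif_end_offset`.
#' @export
step_statistic <- function(profile, motif_end_offset, up_window = 20L,
                           down_window = 60L, tau = 2, min_cov = 1,
                           eps = 0.5) {
  iend <- motif_end_offset + profile$flank + 1L
  up_idx <- (iend - up_window + 1L):iend
  down_idx <- (iend + 1L):(iend + down_window)
  if (up_idx[1] < 1L || down_idx[length(down_idx)] > length(profile$depth))
    stop("step windows fall outside the profiled span for ",
         profile$gene_id)
  um <- mean(profile$depth[up_idx])
  dm <- mean(profile$depth[down_idx])
  R <- dm / (um + eps)
  cls <- if (dm < min_cov) "low-coverage"
         else if (R >= tau) "step-increase"
         else if (R <= 1 / tau) "decrease"
         else "flat"
  data.frame(gene_id = profile$gene_id, upstream_mean = um,
             downstream_mean = dm, ratio = R, class = cls,
             motif_end_offset = motif_end_offset,
             stringsAsFactors = FALSE)
}

#' Aggregate trend calls and the motif-anchored mean coverage curve
#'
#' Counts calls per class and averages per-gene profiles on motif-anchored
#' coordinates (position 0 = motif's last base) after normalizing each
#' profile by its own mean depth; zero-mean profiles are excluded.
#'
#' @param calls row-bound [step_statistic()] output (needs
#'   `motif_end_offset`).
#' @param profiles list of `gene_profile` objects, matched to `calls` by
#'   `gene_id`.
#' @param curve_from,curve_to motif-anchored extent of the mean curve.
#' @return list with `counts` (named integer vector) and `curve`
#'   (data.frame `pos`, `mean_depth`, `n`).
#' @export
aggregate_trends <- function(calls, profiles, curve_from = -50L,
                             curve_to = 100L) {
  counts <- table(factor(calls$class,
                         levels = c("step-increase", "flat", "decrease",
                                    "low-coverage")))
  ids <- vapply(profiles, function(p) p$gene_id, character(1))
  pos <- curve_from:curve_to
  acc <- matrix(NA_real_, nrow(calls), length(pos))
  for (i in seq_len(nrow(calls))) {
    p <- profiles[[match(calls$gene_id[i], ids)]]
    if (is.null(p)) next
    mu <- mean(p$depth)
    if (mu == 0) next
    idx <- pos + calls$motif_end_offset[i] + p$flank + 1L
    ok <- idx >= 1L & idx <= length(p$depth)
    acc[i, ok] <- p$depth[idx[ok]] / mu
  }
  curve <- data.frame(pos = pos,
                      mean_depth = colMeans(acc, na.rm = TRUE),
                      n = colSums(!is.na(acc)))
  list(counts = c(counts), curve = curve)
}

#' Position of the steepest rise in a mean coverage curve
#'
#' Returns the motif-anchored coordinate of the base at which the largest
#' single-base increase of the mean curve lands (a planted coverage step at
#' the first base after the motif end gives +1).
#'
#' @param curve curve data.frame from [aggregate_trends()].
#' @return integer position.
#' @export
step_gradient_position <- function(curve) {
  d <- diff(curve$mean_depth)
  curve$pos[which.max(d) + 1L]
}
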