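#' Spacer-distance distribution of best motif sites
#'
#' Histogram of the spacer (bases strictly between the motif's last base and
#' the start codon's first base) over each gene's best site. Sites starting
#' at or inside the ORF have no spacer and are excluded from the histogram
#' but counted in `n_no_spacer`. The mode reports the most frequent spacer;
#' ties go to the smaller spacer.
#'
#' @param sites site table ([scan_gene_windows()] output); reduced to one
#'   best site per gene internally.
#' @return object of class `spacer_histogram`: list with `counts`
#'   (data.frame `spacer`, `count`), `mode`, `n`, `n_no_spacer`.
#' @export
spacer_distribution <- function(sites) {
  best <- best_site_per_gene(sites)
  sp <- best$spacer[!is.na(best$spacer)]
  counts <- if (length(sp)) {
    tab <- table(sp)
    data.frame(spacer = as.integer(names(tab)), count = as.integer(tab))
  } else data.frame(spacer = integer(0), count = integer(0))
  mode <- if (nrow(counts)) {
    counts$spacer[counts$count == max(counts$count)][1]  # rows sorted by spacer
  } else NA_integer_
  structure(list(counts = counts, mode = mode, n = length(sp),
                 n_no_spacer = sum(is.na(best$spacer))),
            class = "spacer_histogram")
}

#' @export
print.spacer_histogram <- function(x, ...) {
  cat("spacer histogram over", x$n, "best sites (mode =", x$mode, "bp)\n")
  print(utils::head(x$counts[order(-x$counts$count), ], 10))
  invisible(x)
}

#' Classify each gene's motif location relative to its ORF
#'
#' Per gene (best site governs): sites starting at or after the start codon
#' are `within-ORF`; upstream sites with spacer greater than `far_min` are
#' `far-upstream`; all other upstream sites (including those overlapping the
#' start codon) are `proximal-upstream`; genes without a passing site are
#' `none`.
#'
#' @param genes gene table; every gene receives exactly one class.
#' @param sites site table from [scan_gene_windows()].
#' @param proximal_max upper spacer bound reported for the proximal band
#'   (kept for band bookkeeping; see Details).
#' @param far_min spacers strictly greater than this are far-upstream.
#' @return data.frame `gene_id`, `class`.
#' @export
classify_locations <- function(genes, sites, proximal_max = 20L,
                               far_min = 50L) {
  best <- best_site_per_gene(sites)
  idx <- match(genes$gene_id, best$gene_id)
  offset <- best$offset[idx]
  spacer <- best$spacer[idx]
  cls <- ifelse(is.na(offset), "none",
         ifelse(offset >= 0, "within-ORF",
         ifelse(!is.na(spacer) & spacer > far_min, "far-upstream",
                "proximal-upstream")))
  data.frame(gene_id = genes$gene_id, class = cls,
             stringsAsFactors = FALSE)
}

#' Motif-carrying fraction of a genome
#'
#' A gene counts as motif-carrying when its best site's spacer lies in
#' `band` (inclusive). With the default band of 0-20 bp this captures the
#' proximal promoter-like placement ~6-7 bp upstream of the start codon.
#'
#' @param genes gene table.
#' @param sites site table from [scan_gene_windows()].
#' @param band length-2 inclusive spacer band.
#' @param genome_id label carried into the summary.
#' @return object of class `genome_summary`: list with `genome_id`,
#'   `n_genes`, `n_motif_genes`, `fraction`, `top_variants` (data.frame),
#'   `spacer_mode`.
#' @export
motif_fraction <- function(genes, sites, band = c(0L, 20L),
                           genome_id = "genome") {
  stopifnot(length(band) == 2L, band[1] <= band[2])
  best <- best_site_per_gene(sites)
  best <- best[best$gene_id %in% genes$gene_id, , drop = FALSE]
  carrying <- !is.na(best$spacer) &
    best$spacer >= band[1] & best$spacer <= band[2]
  words <- best$word[carrying]
  tab <- sort(table(words), decreasing = TRUE)
  top <- data.frame(word = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  hist <- spacer_distribution(best[carrying, , drop = FALSE])
  structure(list(genome_id = genome_id,
                 n_genes = nrow(genes),
                 n_motif_genes = sum(carrying),
                 fraction = sum(carrying) / nrow(genes),
                 top_variants = utils::head(top, 10),
                 spacer_mode = hist$mode),
            class = "genome_summary")
}

#' @export
print.genome_summary <- function(x, ...) {
  cat(sprintf("%s: %d / %d genes motif-carrying (%.1f%%), spacer mode %s bp\n",
              x$genome_id, x$n_motif_genes, x$n_genes, 100 * x$fraction,
              x$spacer_mode))
  invisible(x)
}

#' Aggregate genome summaries by group
#'
#' For each group (e.g. a phylum): the proportion of genomes in which the
#' motif is detected (ORF-level fraction at or above
#' `detect_min_fraction`), and the mean ORF-level fraction among the
#' detected genomes.
#'
#' @param summaries list of `genome_summary` objects.
#' @param grouping character/factor of group labels, one per summary.
#' @param detect_min_fraction minimum ORF-level fraction for a genome to
#'   count as motif-positive (default 0.1, well above the chance rate of a
#'   best site landing in the proximal band).
#' @return data.frame with `group`, `n_genomes`, `prop_motif_genomes`,
#'   `mean_fraction`.
#' @export
aggregate_genomes <- function(summaries, grouping,
                              detect_min_fraction = 0.1) {
  stopifnot(length(summaries) == length(grouping))
  fr <- vapply(summaries, function(s) s$fraction, numeric(1))
  res <- lapply(split(fr, grouping), function(f) {
    det <- f >= detect_min_fraction
    c(n_genomes = length(f),
      prop_motif_genomes = mean(det),
      mean_fraction = if (any(det)) mean(f[det]) else NA_real_)
  })
  out <- data.frame(group = names(res),
                    do.call(rbind, res), row.names = NULL)
  out
}
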