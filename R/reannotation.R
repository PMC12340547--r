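#' Propose a corrected start codon downstream of a misplaced motif
#'
#' When a gene's best -10-like site lies inside the annotated ORF (or far
#' upstream of it), the promoter-at-the-start-codon model suggests the
#' annotated start is wrong: a leaderless transcript should begin just
#' after the motif, so a true start codon is expected within a few bases of
#' the motif's 3' end. This scans the coding strand from the base after the
#' motif for a start codon, preferring the nearest one in frame with the
#' annotated ORF; if only out-of-frame codons exist, the nearest is
#' returned flagged `in_frame_with_annotation = FALSE` (frame shifts may
#' reflect sequencing errors and are advisory only).
#'
#' @param gene one row of a gene table.
#' @param best_site one row of a best-site table (needs `offset`, `word`).
#' @param contigs contig [Biostrings::DNAStringSet].
#' @param max_spacer furthest scanned distance (bases) between motif end
#'   and candidate codon.
#' @param codons allowed initiator codons.
#' @param min_orf_nt proposals leaving an ORF shorter than this are
#'   suppressed with a warning.
#' @return one-row data.frame (`gene_id`, `original_start`,
#'   `proposed_start`, `proposed_codon`, `spacer_after_motif`,
#'   `in_frame_with_annotation`, `trimmed_nterm_length`) or NULL. Start
#'   coordinates are 0-based forward-strand positions of the codon's first
#'   coding-strand base. `trimmed_nterm_length` is the number of codons
#'   removed from the N terminus (negative = extended; NA when out of
#'   frame).
#' @export
propose_start <- function(gene, best_site, contigs, max_spacer = 15L,
                          codons = c("ATG", "GTG", "TTG"),
                          min_orf_nt = 30L) {
  w <- nchar(best_site$word)
  motif_end_rel <- best_site$offset + w - 1L
  cs <- coding_subseq(contigs, gene, motif_end_rel + 1L,
                      motif_end_rel + max_spacer + 3L)
  if (is.na(cs)) return(NULL)

  d <- 0:max_spacer
  cand <- substring(cs, d + 1L, d + 3L)
  rel_start <- motif_end_rel + 1L + d
  ok <- cand %in% codons
  if (!any(ok)) return(NULL)
  in_frame <- rel_start %% 3L == 0L
  pick <- if (any(ok & in_frame)) which(ok & in_frame)[1] else which(ok)[1]

  rs <- rel_start[pick]
  new_len <- (gene$end - gene$start) - rs
  if (new_len < min_orf_nt) {
    warning("proposal for ", gene$gene_id, " suppressed: ORF would be ",
            new_len, " nt")
    return(NULL)
  }
  orig0 <- if (gene$strand == "+") gene$start else gene$end - 1L
  prop0 <- if (gene$strand == "+") gene$start + rs else gene$end - 1L - rs
  data.frame(gene_id = gene$gene_id,
             original_start = orig0,
             proposed_start = prop0,
             proposed_codon = cand[pick],
             spacer_after_motif = d[pick],
             in_frame_with_annotation = in_frame[pick],
             trimmed_nterm_length = if (in_frame[pick]) rs %/% 3L
                                    else NA_integer_,
             stringsAsFactors = FALSE)
}

#' Propose corrected starts for all eligible genes
#'
#' Genes are eligible when their best site classifies as `within-ORF` or
#' `far-upstream` (see [classify_locations()]); proximally placed motifs
#' need no correction, which also makes the procedure idempotent on an
#' annotation that already uses the proposed starts.
#'
#' @param genes gene table.
#' @param sites site table from [scan_gene_windows()].
#' @param contigs contig [Biostrings::DNAStringSet].
#' @param locations optional precomputed [classify_locations()] output.
#' @inheritParams propose_start
#' @return data.frame of proposals (zero rows if none).
#' @export
propose_starts <- function(genes, sites, contigs, locations = NULL,
                           max_spacer = 15L,
                           codons = c("ATG", "GTG", "TTG"),
                           min_orf_nt = 30L) {
  if (is.null(locations)) locations <- classify_locations(genes, sites)
  best <- best_site_per_gene(sites)
  eligible <- locations$gene_id[locations$class %in%
                                  c("within-ORF", "far-upstream")]
  out <- lapply(eligible, function(id) {
    g <- genes[genes$gene_id == id, , drop = FALSE]
    s <- best[best$gene_id == id, , drop = FALSE]
    if (!nrow(g) || !nrow(s)) return(NULL)
    propose_start(g[1, ], s[1, ], contigs, max_spacer = max_spacer,
                  codons = codons, min_orf_nt = min_orf_nt)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), original_start = integer(0),
                      proposed_start = integer(0),
                      proposed_codon = character(0),
                      spacer_after_motif = integer(0),
                      in_frame_with_annotation = logical(0),
                      trimmed_nterm_length = integer(0))
  out
}

#' Apply in-frame start proposals to a gene table
#'
#' Returns a copy of the gene table whose eligible genes use the proposed
#' (in-frame) starts; out-of-frame proposals are never applied. Useful for
#' idempotence checks and for exporting a corrected annotation.
#'
#' @param genes gene table.
#' @param proposals output of [propose_starts()].
#' @param contigs contig set, used to refresh `start_codon`.
#' @return updated gene table.
#' @export
apply_proposals <- function(genes, proposals, contigs) {
  proposals <- proposals[proposals$in_frame_with_annotation, , drop = FALSE]
  for (i in seq_len(nrow(proposals))) {
    j <- match(proposals$gene_id[i], genes$gene_id)
    if (is.na(j)) next
    if (genes$strand[j] == "+") {
      genes$start[j] <- proposals$proposed_start[i]
    } else {
      genes$end[j] <- proposals$proposed_start[i] + 1L
    }
    genes$start_codon[j] <- coding_subseq(contigs, genes[j, ], 0L, 2L)
  }
  genes
}
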