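#' Load a genome and its gene annotation
#'
#' Reads a (multi-)FASTA genome and a GFF3 (or GenBank flat-file) annotation
#' and returns the contigs together with one record per protein-coding gene.
#' Coordinates are normalized to 0-based half-open intervals on the forward
#' strand; the start codon is read off the coding strand so that minus-strand
#' genes report the reverse complement of the forward-strand bases at their
#' 3' end. Non-ACGT IUPAC codes in the genome are mapped to N on load.
#'
#' Only CDS features are kept; features flagged as pseudogenes are excluded,
#' and CDS shorter than 3 nt are skipped with a warning.
#'
#' @param fasta_path path to the genome FASTA.
#' @param annotation_path path to a GFF3 file (`.gff`/`.gff3`) or a GenBank
#'   flat file (`.gb`/`.gbk`/`.gbff`).
#' @return a list with `contigs` (a [Biostrings::DNAStringSet]) and `genes`
#'   (a data.frame with columns `gene_id`, `contig`, `strand`, `start`,
#'   `end`, `start_codon`; `start`/`end` are 0-based half-open).
#' @export
load_genome <- function(fasta_path, annotation_path) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  if (!file.exists(annotation_path))
    stop("annotation file not found: ", annotation_path)

  contigs <- tryCatch(
    Biostrings::readDNAStringSet(fasta_path),
    error = function(e) stop("malformed FASTA '", fasta_path, "': ",
                             conditionMessage(e), call. = FALSE))
  ## keep only the first whitespace-delimited token of each header
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  contigs <- Biostrings::replaceAmbiguities(contigs, new = "N")

  ext <- tolower(tools::file_ext(annotation_path))
  feats <- if (ext %in% c("gb", "gbk", "gbff", "genbank")) {
    parse_genbank_cds(annotation_path)
  } else {
    parse_gff3_cds(annotation_path)
  }

  unknown <- setdiff(unique(feats$contig), names(contigs))
  if (length(unknown))
    stop("annotation references unknown contig(s): ",
         paste(unknown, collapse = ", "))

  short <- (feats$end - feats$start) < 3L
  if (any(short)) {
    warning(sum(short), " CDS feature(s) shorter than 3 nt skipped")
    feats <- feats[!short, , drop = FALSE]
  }
  clen <- stats::setNames(Biostrings::width(contigs), names(contigs))
  bad <- feats$start < 0L | feats$end > clen[feats$contig]
  if (any(bad))
    stop("CDS coordinates outside contig bounds for: ",
         paste(utils::head(feats$gene_id[bad], 5), collapse = ", "))

  feats$start_codon <- extract_coding_batch(contigs, feats, 0L, 2L)
  rownames(feats) <- NULL
  list(contigs = contigs, genes = feats)
}

parse_gff3_cds <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path),
    error = function(e) stop("malformed GFF3 '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  meta <- S4Vectors::mcols(gr)
  if (!"type" %in% names(meta))
    stop("malformed GFF3 '", path, "': no feature type column")
  keep <- as.character(meta$type) == "CDS"
  if ("pseudo" %in% names(meta))
    keep <- keep & is.na(meta$pseudo)
  if ("gene_biotype" %in% names(meta))
    keep <- keep & !(meta$gene_biotype %in% "pseudogene")
  gr <- gr[keep]
  meta <- S4Vectors::mcols(gr)
  id <- if ("ID" %in% names(meta) && !all(is.na(meta$ID))) {
    as.character(meta$ID)
  } else if ("locus_tag" %in% names(meta)) {
    as.character(meta$locus_tag)
  } else if ("Name" %in% names(meta)) {
    as.character(meta$Name)
  } else {
    paste0("cds_", seq_along(gr))
  }
  if (anyDuplicated(id))
    stop("duplicate CDS identifiers in '", path, "': ",
         paste(utils::head(unique(id[duplicated(id)]), 5), collapse = ", "))
  data.frame(gene_id = id,
             contig = as.character(GenomicRanges::seqnames(gr)),
             strand = as.character(GenomicRanges::strand(gr)),
             start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

## Minimal GenBank flat-file CDS reader: handles `a..b` and
## `complement(a..b)` locations; joined (spliced) locations are skipped with
## a warning since prokaryotic gene models are the target here.
parse_genbank_cds <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines)
  if (!length(locus))
    stop("malformed GenBank file '", path, "': no LOCUS line (line 1)")
  recs <- list()
  contig <- NA_character_
  i <- 1L
  n_skip <- 0L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^LOCUS", ln)) contig <- strsplit(trimws(ln), "\\s+")[[1]][2]
    if (grepl("^\\s{5}CDS\\s", ln)) {
      loc <- trimws(sub("^\\s{5}CDS\\s+", "", ln))
      j <- i + 1L
      tag <- NA_character_
      while (j <= length(lines) && grepl("^\\s{21}", lines[j]) &&
             !grepl("^\\s{5}\\S", lines[j])) {
        m <- regmatches(lines[j],
                        regexec("/locus_tag=\"([^\"]+)\"", lines[j]))[[1]]
        if (length(m) == 2 && is.na(tag)) tag <- m[2]
        j <- j + 1L
      }
      if (grepl("join", loc)) {
        n_skip <- n_skip + 1L
      } else {
        strand <- if (grepl("complement", loc)) "-" else "+"
        nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
        if (length(nums) == 2) {
          recs[[length(recs) + 1L]] <- data.frame(
            gene_id = if (is.na(tag)) paste0("cds_", length(recs) + 1L) else tag,
            contig = contig, strand = strand,
            start = nums[1] - 1L, end = nums[2],
            stringsAsFactors = FALSE)
        }
      }
      i <- j
    } else {
      i <- i + 1L
    }
  }
  if (n_skip) warning(n_skip, " joined CDS location(s) skipped")
  if (!length(recs)) stop("no CDS features found in '", path, "'")
  out <- do.call(rbind, recs)
  out$gene_id <- make.unique(out$gene_id, sep = "_")
  out
}

## Coding-strand subsequence of a gene over positions [rel_from, rel_to]
## (inclusive) relative to the first base of the start codon. Returns NA when
## the range falls outside the contig.
coding_subseq <- function(contigs, gene, rel_from, rel_to) {
  len <- length(contigs[[gene$contig]])
  if (gene$strand == "+") {
    f0 <- gene$start + rel_from
    f1 <- gene$start + rel_to
    if (f0 < 0L || f1 >= len) return(NA_character_)
    as.character(Biostrings::subseq(contigs[[gene$contig]], f0 + 1L, f1 + 1L))
  } else {
    f0 <- gene$end - 1L - rel_to
    f1 <- gene$end - 1L - rel_from
    if (f0 < 0L || f1 >= len) return(NA_character_)
    revcomp_chr(as.character(
      Biostrings::subseq(contigs[[gene$contig]], f0 + 1L, f1 + 1L)))
  }
}

## Batch coding-strand extraction over a fixed relative range for many
## genes; returns a character vector with NA where the range leaves the
## contig.
extract_coding_batch <- function(contigs, genes, rel_from, rel_to) {
  clen <- stats::setNames(Biostrings::width(contigs), names(contigs))
  plus <- genes$strand == "+"
  f0 <- ifelse(plus, genes$start + rel_from, genes$end - 1L - rel_to)
  f1 <- ifelse(plus, genes$start + rel_to, genes$end - 1L - rel_from)
  ok <- f0 >= 0L & f1 < clen[genes$contig]
  out <- rep(NA_character_, nrow(genes))
  for (cn in unique(genes$contig)) {
    sel <- which(ok & genes$contig == cn)
    if (!length(sel)) next
    frag <- Biostrings::extractAt(contigs[[cn]],
                                  IRanges::IRanges(f0[sel] + 1L, f1[sel] + 1L))
    minus <- !plus[sel]
    if (any(minus))
      frag[minus] <- Biostrings::reverseComplement(frag[minus])
    out[sel] <- as.character(frag)
  }
  out
}

## Shared engine for window extraction over a coding-strand-relative range.
extract_windows <- function(genes, contigs, rel_from, rel_to,
                            max_n_fraction = 0.5) {
  stopifnot(rel_to >= rel_from)
  seqs <- extract_coding_batch(contigs, genes, rel_from, rel_to)
  n_frac <- ifelse(is.na(seqs), 1,
                   lengths(regmatches(seqs, gregexpr("N", seqs))) / nchar(seqs))
  keep <- !is.na(seqs) & n_frac <= max_n_fraction
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " gene(s) dropped (contig edge or >",
            round(100 * max_n_fraction), "% N)")
  out <- data.frame(gene_id = genes$gene_id[keep],
                    seq = seqs[keep],
                    offset_of_last_base = rel_to,
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- n_dropped
  attr(out, "n_input") <- nrow(genes)
  out
}

#' Extract fixed-length upstream windows
#'
#' Takes the `length` bases immediately 5' of each gene's start codon on the
#' coding strand. Genes closer than `length` to a contig edge (and windows
#' with more than 50% N) are dropped and counted in the `n_dropped`
#' attribute.
#'
#' @param genes gene table as returned by [load_genome()].
#' @param contigs [Biostrings::DNAStringSet] of contig sequences.
#' @param length window length in bp (default 20).
#' @return data.frame with columns `gene_id`, `seq`, `offset_of_last_base`
#'   (always -1: the base immediately adjacent to the start codon), with
#'   attributes `n_dropped` and `n_input`.
#' @export
extract_upstream <- function(genes, contigs, length = 20L) {
  stopifnot(length >= 1L)
  extract_windows(genes, contigs, -as.integer(length), -1L)
}

#' Extract scan windows spanning the start codon
#'
#' Extracts the coding-strand window from `up` bases upstream of the start
#' codon through `down` bases into the gene (positions `-up .. down-1`
#' relative to the first base of the start codon). The default 300/150 gives
#' the 450-bp window used for proximal-element scanning.
#'
#' @inheritParams extract_upstream
#' @param up,down bases upstream / downstream of the start-codon first base.
#' @return as [extract_upstream()]; `offset_of_last_base` is `down - 1`.
#' @export
extract_scan_window <- function(genes, contigs, up = 300L, down = 150L) {
  stopifnot(up >= 0L, down >= 0L, up + down >= 1L)
  extract_windows(genes, contigs, -as.integer(up), as.integer(down) - 1L)
}

#' Write/read window sets as FASTA
#'
#' Round-trippable FASTA serialization of a windows table; the header line
#' carries the gene identifier and the start-codon-relative offset of the
#' window's last base (`>gene offset_of_last_base=K`).
#'
#' @param windows data.frame from [extract_upstream()] or
#'   [extract_scan_window()].
#' @param path output/input file path.
#' @return `read_windows_fasta` returns a windows data.frame.
#' @export
write_windows_fasta <- function(windows, path) {
  if (anyDuplicated(windows$gene_id))
    stop("duplicate gene_id in window set: ",
         windows$gene_id[duplicated(windows$gene_id)][1])
  x <- Biostrings::DNAStringSet(windows$seq)
  if (nrow(windows) > 0)
    names(x) <- paste0(windows$gene_id,
                       " offset_of_last_base=", windows$offset_of_last_base)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' @rdname write_windows_fasta
#' @export
read_windows_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  hdr <- names(x)
  id <- sub("\\s.*$", "", hdr)
  off <- suppressWarnings(as.integer(
    sub(".*offset_of_last_base=(-?[0-9]+).*", "\\1", hdr)))
  if (anyDuplicated(id))
    stop("duplicate gene_id in '", path, "'")
  data.frame(gene_id = id, seq = as.character(x),
             offset_of_last_base = off, stringsAsFactors = FALSE)
}
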