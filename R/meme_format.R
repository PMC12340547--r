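#' Write motifs in MEME minimal motif text format
#'
#' Serializes motif models in the minimal motif format (version 4) so that
#' third-party scanners can consume them. `nsites` is taken as
#' `round(gamma * n_training_sequences)` when both are available.
#'
#' @param models a `motif_model` or list of them.
#' @param path output file.
#' @param names motif names; defaults to list names or `motif_1`, ...
#' @export
write_meme <- function(models, path, names = NULL) {
  if (inherits(models, "motif_model")) models <- list(models)
  if (is.null(names))
    names <- base::names(models) %||% paste0("motif_", seq_along(models))
  bg <- models[[1]]$background
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: +", "",
               "Background letter frequencies",
               paste(sprintf("%s %.6f", DNA_BASES, bg), collapse = " "),
               ""), con)
  for (i in seq_along(models)) {
    m <- models[[i]]
    nsites <- if (!is.na(m$gamma) && !is.na(m$n_training_sequences))
      max(1L, round(m$gamma * m$n_training_sequences)) else 20L
    writeLines(c(paste("MOTIF", names[i]),
                 sprintf(
                   "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                   m$w, nsites)), con)
    for (j in seq_len(m$w))
      writeLines(paste(sprintf("%.6f", m$theta[, j]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read motifs from MEME minimal motif text format
#'
#' @param path a MEME-format motif file.
#' @return named list of [motif_model()] objects (`gamma` reconstructed from
#'   `nsites` when possible is not attempted; `gamma` is NA).
#' @export
read_meme <- function(path) {
  lines <- readLines(path, warn = FALSE)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bgl <- grep("^Background letter frequencies", lines)
  if (length(bgl)) {
    toks <- strsplit(trimws(lines[bgl[1] + 1L]), "\\s+")[[1]]
    vals <- as.numeric(toks[seq(2, length(toks), 2)])
    names(vals) <- toks[seq(1, length(toks), 2)]
    bg <- vals[DNA_BASES]
  }
  starts <- grep("^MOTIF", lines)
  if (!length(starts)) stop("no MOTIF blocks in '", path, "'")
  models <- list()
  for (s in starts) {
    name <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    hl <- s + which(grepl("^letter-probability matrix:",
                          lines[(s + 1):min(s + 5, length(lines))]))[1]
    w <- as.integer(sub(".*w= *([0-9]+).*", "\\1", lines[hl]))
    n <- suppressWarnings(as.integer(
      sub(".*nsites= *([0-9]+).*", "\\1", lines[hl])))
    rows <- lines[(hl + 1):(hl + w)]
    theta <- t(vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]]), numeric(4)))
    theta <- sweep(t(theta), 2, colSums(t(theta)), "/")  # renormalize 4 x w
    models[[name]] <- motif_model(theta, bg / sum(bg),
                                  n_training_sequences = n)
  }
  models
}
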