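# Readers and writers for the per-residue feature file formats:
# PSI-BLAST ASCII PSSM, HHsuite HHM profile, single-sequence FASTA-like
# secondary-structure strings, and two-column ASA TSV.

PSSM_AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
HHM_AA_ORDER <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the first 20 score columns (log-odds in PSI-BLAST output; this
#' package's synthetic profiles print real values in the same layout).
#' Header lines and the trailing statistics block are skipped.
#'
#' @param path PSSM file.
#' @return list with `sequence` (one-letter string) and `scores`
#'   (`n x 20` matrix, columns in PSI-BLAST amino-acid order).
#' @export
read_pssm <- function(path) {
  lines <- readLines(path)
  rows <- list()
  seqv <- character(0)
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(tok) < 22L) next
    idx <- suppressWarnings(as.integer(tok[1L]))
    if (is.na(idx) || !tok[2L] %in% c(LETTERS)) next
    vals <- suppressWarnings(as.numeric(tok[3:22]))
    if (anyNA(vals)) next
    rows[[length(rows) + 1L]] <- vals
    seqv <- c(seqv, tok[2L])
  }
  if (!length(rows)) stop("read_pssm: no residue rows found in ", path)
  scores <- do.call(rbind, rows)
  colnames(scores) <- PSSM_AA_ORDER
  list(sequence = paste(seqv, collapse = ""), scores = scores)
}

#' Write a PSSM in PSI-BLAST ASCII layout
#'
#' @param sequence one-letter sequence string.
#' @param scores `n x 20` numeric matrix (PSI-BLAST amino-acid order).
#' @param path output file.
#' @param digits decimal places for the scores (PSI-BLAST itself prints
#'   integers; the default keeps synthetic real-valued profiles exact to
#'   3 decimals).
#' @export
write_pssm <- function(sequence, scores, path, digits = 3L) {
  seqv <- strsplit(sequence, "")[[1L]]
  stopifnot(nrow(scores) == length(seqv), ncol(scores) == 20L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
               "Last position-specific scoring matrix computed",
               paste(" ", paste(sprintf("%6s", PSSM_AA_ORDER), collapse = ""))),
             con)
  for (i in seq_along(seqv))
    writeLines(paste0(sprintf("%5d %s ", i, seqv[i]),
                      paste(sprintf(paste0("%8.", digits, "f"), scores[i, ]),
                            collapse = "")), con)
  writeLines(c("", "                      K         Lambda"), con)
  invisible(path)
}

#' Read an HHsuite HHM profile
#'
#' Extracts the 20 match-emission columns of each residue and converts them
#' from the format's negative-log representation (`v = -1000*log2(f)`) to
#' frequencies; `*` entries decode to frequency 0.
#'
#' @param path HHM file.
#' @return list with `sequence` and `freq` (`n x 20` matrix, columns in
#'   HHsuite amino-acid order).
#' @export
read_hhm <- function(path) {
  lines <- readLines(path)
  start <- grep("^#", lines)[1L]
  if (is.na(start)) stop("read_hhm: malformed file (no '#' line): ", path)
  body <- lines[(start + 1L):length(lines)]
  rows <- list()
  seqv <- character(0)
  i <- 1L
  while (i <= length(body)) {
    ln <- body[i]
    if (startsWith(ln, "//")) break
    tok <- strsplit(trimws(ln), "\\s+")[[1L]]
    # residue match line: "<AA> <pos> <20 values> <pos>"
    if (length(tok) >= 22L && tok[1L] %in% c(LETTERS, "-") &&
        !is.na(suppressWarnings(as.integer(tok[2L])))) {
      v <- tok[3:22]
      f <- ifelse(v == "*", 0, 2^(-suppressWarnings(as.numeric(v)) / 1000))
      rows[[length(rows) + 1L]] <- f
      seqv <- c(seqv, tok[1L])
      i <- i + 2L  # skip the transition line
    }
    i <- i + 1L
  }
  if (!length(rows)) stop("read_hhm: no match-state rows found in ", path)
  freq <- do.call(rbind, rows)
  colnames(freq) <- HHM_AA_ORDER
  list(sequence = paste(seqv, collapse = ""), freq = freq)
}

#' Write an HHsuite-style HHM profile
#'
#' Frequencies are encoded as `round(-1000*log2(f))`, `*` for zero.
#'
#' @param sequence one-letter sequence string.
#' @param freq `n x 20` matrix of match-emission frequencies.
#' @param path output file.
#' @export
write_hhm <- function(sequence, freq, path) {
  seqv <- strsplit(sequence, "")[[1L]]
  stopifnot(nrow(freq) == length(seqv), ncol(freq) == 20L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("HHsearch 1.5", paste("NAME ", "synthetic"), "#",
               paste("NULL  ", paste(rep("3000", 20L), collapse = " ")),
               paste("HMM   ", paste(HHM_AA_ORDER, collapse = "\t"))), con)
  enc <- function(f) ifelse(f <= 0, "*", as.character(round(-1000 * log2(f))))
  for (i in seq_along(seqv)) {
    writeLines(paste(seqv[i], i, paste(enc(freq[i, ]), collapse = " "), i), con)
    writeLines(paste("      ", paste(rep("0", 7L), collapse = " ")), con)
    writeLines("", con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read a FASTA-like single-sequence file
#'
#' Used for both amino-acid sequences and 8-state secondary-structure
#' strings (one record; multi-line bodies are concatenated).
#'
#' @param path input file.
#' @return list with `id` (header text) and `sequence`.
#' @export
read_fasta_like <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !startsWith(lines[1L], ">"))
    stop("read_fasta_like: expected a '>' header in ", path)
  list(id = sub("^>\\s*", "", lines[1L]),
       sequence = paste(trimws(lines[-1L]), collapse = ""))
}

#' Write a FASTA-like single-sequence file
#'
#' @param id header text.
#' @param sequence sequence string.
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_fasta_like <- function(id, sequence, path, width = 60L) {
  n <- nchar(sequence)
  starts <- seq(1L, n, by = width)
  body <- substring(sequence, starts, pmin(starts + width - 1L, n))
  writeLines(c(paste0(">", id), body), path)
  invisible(path)
}

#' Read a per-residue ASA file
#'
#' Two-column TSV: `residue_index`, `asa`.
#'
#' @param path input file.
#' @return numeric vector of ASA values ordered by residue index.
#' @export
read_asa <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("residue_index", "asa") %in% names(df)))
  df <- df[order(df$residue_index), ]
  if (!identical(as.integer(df$residue_index), seq_len(nrow(df))))
    stop("read_asa: residue_index must be 1..n in ", path)
  as.numeric(df$asa)
}

#' Write a per-residue ASA file
#'
#' @param asa numeric vector.
#' @param path output file.
#' @export
write_asa <- function(asa, path) {
  utils::write.table(
    data.frame(residue_index = seq_along(asa),
               asa = formatC(asa, format = "f", digits = 4)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
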