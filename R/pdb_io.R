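# PDB input/output for backbone chains, delegated to bio3d.

aa_three_to_one <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
                     GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
                     LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
                     SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
aa_one_to_three <- structure(names(aa_three_to_one), names = aa_three_to_one)

#' Read a backbone chain from a PDB file
#'
#' Uses ATOM records of the first model only; for alternate locations the
#' first one is kept. Residues missing any of N/CA/C keep NA coordinates for
#' the missing atoms and their dependent angles become undefined downstream.
#'
#' @param path PDB file.
#' @param chain chain identifier; default the first chain in the file.
#' @return a [backbone_chain].
#' @export
read_pdb_chain <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("read_pdb_chain: no ATOM records in ", path)
  if (is.null(chain)) chain <- at$chain[1L]
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("read_pdb_chain: chain '", chain, "' not found")
  # first alternate location per (resno, insert, elety)
  alt <- at$alt
  alt[is.na(alt)] <- ""
  key <- paste(at$resno, at$insert, at$elety)
  at <- at[!duplicated(key), , drop = FALSE]
  resk <- paste(at$resno, ifelse(is.na(at$insert), "", at$insert))
  resnos <- unique(resk)
  n <- length(resnos)
  arr <- array(NA_real_, dim = c(n, 4L, 3L),
               dimnames = list(NULL, c("N", "CA", "C", "CB"), c("x", "y", "z")))
  seqv <- character(n)
  for (i in seq_len(n)) {
    rows <- at[resk == resnos[i], , drop = FALSE]
    seqv[i] <- aa_three_to_one[rows$resid[1L]]
    if (is.na(seqv[i])) seqv[i] <- "X"
    for (atom in c("N", "CA", "C", "CB")) {
      r <- rows[rows$elety == atom, , drop = FALSE]
      if (nrow(r) >= 1L) arr[i, atom, ] <- c(r$x[1L], r$y[1L], r$z[1L])
    }
  }
  backbone_chain(paste(seqv, collapse = ""), arr, chain_id = chain)
}

#' Write a backbone chain to a PDB file
#'
#' @param chain a [backbone_chain].
#' @param path output file.
#' @export
write_pdb_chain <- function(chain, path) {
  stopifnot(inherits(chain, "backbone_chain"))
  n <- length(chain)
  seqv <- strsplit(chain$sequence, "")[[1L]]
  xyz <- NULL
  elety <- character(0)
  resid <- character(0)
  resno <- integer(0)
  for (i in seq_len(n)) {
    for (atom in c("N", "CA", "C", "CB")) {
      p <- chain$coords[i, atom, ]
      if (anyNA(p)) next
      xyz <- c(xyz, p)
      elety <- c(elety, atom)
      res3 <- aa_one_to_three[seqv[i]]
      resid <- c(resid, if (is.na(res3)) "UNK" else res3)
      resno <- c(resno, i)
    }
  }
  bio3d::write.pdb(file = path, xyz = as.numeric(xyz), type = "ATOM",
                   eleno = seq_along(elety), elety = elety, resid = resid,
                   chain = chain$chain_id, resno = resno)
  invisible(path)
}
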