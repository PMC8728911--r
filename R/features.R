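# Per-residue feature assembly, sliding-window encoding and normalization.

#' Eight-state secondary-structure alphabet
#'
#' Fixed one-hot position order for the 8-state secondary-structure codes:
#' H (alpha helix), G (3-10 helix), I (pi helix), E (strand), B (bridge),
#' T (turn), S (bend), C (coil/other). All encodings and mappings in the
#' package reference this declared order.
#'
#' @export
SS8_ALPHABET <- c("H", "G", "I", "E", "B", "T", "S", "C")

#' One-hot encode an 8-state secondary-structure code
#'
#' @param state character vector of single-letter 8-state codes.
#' @return if `length(state) == 1`, a named length-8 0/1 vector; otherwise a
#'   `length(state) x 8` matrix, columns in [SS8_ALPHABET] order.
#' @examples
#' one_hot_ss8("H")
#' @export
one_hot_ss8 <- function(state) {
  idx <- match(state, SS8_ALPHABET)
  if (anyNA(idx))
    stop("one_hot_ss8: invalid state '",
         paste(state[is.na(idx)], collapse = "','"),
         "'; alphabet is ", paste(SS8_ALPHABET, collapse = ""))
  m <- matrix(0, length(state), 8L, dimnames = list(NULL, SS8_ALPHABET))
  m[cbind(seq_along(state), idx)] <- 1
  if (length(state) == 1L) m[1L, ] else m
}

#' Seven physicochemical property constants per amino acid
#'
#' A 20 x 7 matrix of per-amino-acid constants following the standard
#' physicochemical parameter set used for sequence-based structure
#' prediction: steric parameter (graph shape index), polarizability, volume,
#' hydrophobicity, isoelectric point, helix propensity and sheet propensity.
#'
#' @return numeric matrix, rows named by one-letter amino acid, columns
#'   `steric`, `polarizability`, `volume`, `hydrophobicity`, `isoelectric`,
#'   `helix_prob`, `sheet_prob`.
#' @export
pcp7_table <- function() {
  tab <- rbind(
    A = c(1.28, 0.05, 1.00, 0.31, 6.11, 0.42, 0.23),
    C = c(1.77, 0.13, 2.43, 1.54, 6.35, 0.17, 0.41),
    D = c(1.60, 0.11, 2.78, -0.77, 2.95, 0.25, 0.20),
    E = c(1.56, 0.15, 3.78, -0.64, 3.09, 0.42, 0.21),
    F = c(2.94, 0.29, 5.89, 1.79, 5.67, 0.30, 0.38),
    G = c(0.00, 0.00, 0.00, 0.00, 6.07, 0.13, 0.15),
    H = c(2.99, 0.23, 4.66, 0.13, 7.69, 0.27, 0.30),
    I = c(4.19, 0.19, 4.00, 1.80, 6.04, 0.30, 0.45),
    K = c(1.89, 0.22, 4.77, -0.99, 9.99, 0.32, 0.27),
    L = c(2.59, 0.19, 4.00, 1.70, 6.04, 0.39, 0.31),
    M = c(2.35, 0.22, 4.43, 1.23, 5.71, 0.38, 0.32),
    N = c(1.60, 0.13, 2.95, -0.60, 6.52, 0.21, 0.22),
    P = c(2.67, 0.00, 2.72, 0.72, 6.80, 0.13, 0.34),
    Q = c(1.56, 0.18, 3.95, -0.22, 5.65, 0.36, 0.25),
    R = c(2.34, 0.29, 6.13, -1.01, 10.74, 0.36, 0.25),
    S = c(1.31, 0.06, 1.60, -0.04, 5.70, 0.20, 0.28),
    T = c(3.03, 0.11, 2.60, 0.26, 5.60, 0.21, 0.36),
    V = c(3.67, 0.14, 3.00, 1.22, 6.02, 0.27, 0.49),
    W = c(3.21, 0.41, 8.08, 2.25, 5.94, 0.32, 0.42),
    Y = c(2.94, 0.30, 6.47, 0.96, 5.66, 0.25, 0.41))
  colnames(tab) <- c("steric", "polarizability", "volume", "hydrophobicity",
                     "isoelectric", "helix_prob", "sheet_prob")
  tab
}

#' Parse a four-character feature-setting name
#'
#' A setting name `AHIW` encodes four configuration axes: `A` in Y/N turns
#' the accessible-surface-area feature on/off, `H` in Y/N turns the 20
#' HMM-profile features on/off, `I` in R/Z selects range ([0,1]) or Z-score
#' input normalization, and `W` in 5/9 is the sliding-window size. For
#' example `"YNR5"` uses ASA, no HMM, range normalization and window 5.
#'
#' @param name 4-character setting string.
#' @return object of class `ahiw`: list with `use_asa`, `use_hmm`,
#'   `encoding` ("range"/"zscore"), `window`, and the `name` itself.
#' @export
parse_ahiw <- function(name) {
  if (inherits(name, "ahiw")) return(name)
  stopifnot(is.character(name), length(name) == 1L)
  if (nchar(name) != 4L)
    stop("parse_ahiw: setting name must have 4 characters, got '", name, "'")
  ch <- strsplit(toupper(name), "")[[1L]]
  if (!ch[1L] %in% c("Y", "N") || !ch[2L] %in% c("Y", "N") ||
      !ch[3L] %in% c("R", "Z") || !ch[4L] %in% c("5", "9"))
    stop("parse_ahiw: invalid setting '", name,
         "' (expected [YN][YN][RZ][59])")
  structure(list(name = toupper(name),
                 use_asa = ch[1L] == "Y",
                 use_hmm = ch[2L] == "Y",
                 encoding = if (ch[3L] == "R") "range" else "zscore",
                 window = as.integer(ch[4L])),
            class = "ahiw")
}

#' @export
format.ahiw <- function(x, ...) x$name

#' @export
print.ahiw <- function(x, ...) {
  cat(sprintf("setting %s: ASA=%s HMM=%s encoding=%s window=%d\n", x$name,
              x$use_asa, x$use_hmm, x$encoding, x$window))
  invisible(x)
}

# per-residue feature width for a setting: 8 + 20 + 7 (+20 HMM) (+1 ASA)
ahiw_width <- function(setting) {
  setting <- parse_ahiw(setting)
  35L + (if (setting$use_hmm) 20L else 0L) + (if (setting$use_asa) 1L else 0L)
}

#' Assemble the per-residue feature block matrix of one protein
#'
#' Concatenates, in fixed order, the one-hot 8-state secondary structure
#' (8), PSSM profile (20), physicochemical constants (7), then the optional
#' HMM profile (20) and ASA (1) blocks enabled by the setting — at most 56
#' features per residue.
#'
#' @param ss8 character vector of predicted 8-state codes (one per residue).
#' @param pssm numeric `n x 20` PSSM matrix.
#' @param pcp7 numeric `n x 7` physicochemical matrix (or NULL to derive it
#'   from `sequence`).
#' @param hmm numeric `n x 20` HMM match-emission matrix, or NULL.
#' @param asa numeric length-n ASA vector, or NULL.
#' @param setting an `ahiw` setting or its 4-character name.
#' @param sequence one-letter sequence, used when `pcp7` is NULL.
#' @return numeric `n x width` matrix with block-labelled column names.
#' @export
assemble_residue_features <- function(ss8, pssm, pcp7 = NULL, hmm = NULL,
                                      asa = NULL, setting = "YYR9",
                                      sequence = NULL) {
  setting <- parse_ahiw(setting)
  n <- length(ss8)
  stopifnot(is.matrix(pssm), nrow(pssm) == n, ncol(pssm) == 20L)
  if (is.null(pcp7)) {
    if (is.null(sequence))
      stop("assemble_residue_features: need pcp7 or sequence")
    seqv <- if (length(sequence) == 1L) strsplit(sequence, "")[[1L]] else sequence
    pcp7 <- pcp7_table()[seqv, , drop = FALSE]
  }
  stopifnot(nrow(pcp7) == n, ncol(pcp7) == 7L)
  blocks <- list(ss8 = one_hot_ss8(ss8), pssm = pssm, pcp7 = as.matrix(pcp7))
  if (setting$use_hmm) {
    if (is.null(hmm))
      stop("assemble_residue_features: setting ", setting$name,
           " requires the hmm block")
    stopifnot(nrow(hmm) == n, ncol(hmm) == 20L)
    blocks$hmm <- hmm
  }
  if (setting$use_asa) {
    if (is.null(asa))
      stop("assemble_residue_features: setting ", setting$name,
           " requires the asa block")
    stopifnot(length(asa) == n)
    blocks$asa <- matrix(asa, ncol = 1L)
  }
  out <- do.call(cbind, blocks)
  colnames(out) <- unlist(lapply(names(blocks), function(b)
    paste0(b, ".", seq_len(ncol(blocks[[b]])))))
  out
}

#' Sliding-window encode per-residue features
#'
#' Row i of the result concatenates the per-residue vectors at positions
#' `i - floor(W/2) ... i + floor(W/2)`; positions beyond either chain end
#' contribute all-zero blocks.
#'
#' @param features numeric `n x p` per-residue feature matrix.
#' @param W odd window size (5 or 9 in the shipped settings).
#' @return numeric `n x (p*W)` matrix.
#' @export
window_encode <- function(features, W) {
  stopifnot(is.matrix(features), nrow(features) >= 1L)
  W <- as.integer(W)
  if (W < 1L || W %% 2L == 0L) stop("window_encode: W must be odd and >= 1")
  n <- nrow(features)
  p <- ncol(features)
  half <- W %/% 2L
  out <- matrix(0, n, p * W)
  for (k in seq_len(W)) {
    off <- k - 1L - half
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    out[ok, (k - 1L) * p + seq_len(p)] <- features[src[ok], , drop = FALSE]
  }
  cn <- colnames(features)
  if (!is.null(cn))
    colnames(out) <- paste0("w", rep(seq_len(W) - 1L - half, each = p),
                            ".", rep(cn, W))
  out
}

#' Fit per-column normalization statistics
#'
#' Range mode records each column's training minimum and maximum (the
#' transform is `(x - min) / (max - min)`); Z-score mode records the mean
#' and population standard deviation (divide by n) — the transform is
#' `(x - mu) / sigma`. Statistics come from the supplied (training) rows
#' only.
#'
#' @param x numeric training matrix.
#' @param mode `"range"` or `"zscore"`.
#' @return object of class `norm_stats`.
#' @export
fit_normalization <- function(x, mode = c("range", "zscore")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(x), nrow(x) >= 1L)
  if (mode == "range") {
    st <- list(mode = mode, ncol = ncol(x),
               min = apply(x, 2L, min), max = apply(x, 2L, max))
  } else {
    mu <- colMeans(x)
    sg <- sqrt(colMeans(sweep(x, 2L, mu)^2))  # population convention
    st <- list(mode = mode, ncol = ncol(x), mu = mu, sigma = sg)
  }
  structure(st, class = "norm_stats")
}

#' Apply fitted normalization statistics
#'
#' Columns that were constant in training (max == min, or sigma == 0) map
#' to 0. Values outside the training range are transformed as-is (range
#' mode does not clip).
#'
#' @param x numeric matrix with the layout the statistics were fitted on.
#' @param stats a `norm_stats` object from [fit_normalization()].
#' @return transformed matrix of the same shape.
#' @export
apply_normalization <- function(x, stats) {
  stopifnot(inherits(stats, "norm_stats"), is.matrix(x))
  if (ncol(x) != stats$ncol)
    stop("apply_normalization: column layout mismatch (", ncol(x),
         " vs fitted ", stats$ncol, ")")
  if (stats$mode == "range") {
    span <- stats$max - stats$min
    out <- sweep(x, 2L, stats$min)
    const <- span == 0
    span[const] <- 1
    out <- sweep(out, 2L, span, "/")
    if (any(const)) out[, const] <- 0
  } else {
    sg <- stats$sigma
    const <- sg == 0
    sg[const] <- 1
    out <- sweep(sweep(x, 2L, stats$mu), 2L, sg, "/")
    if (any(const)) out[, const] <- 0
  }
  out
}

#' Encode a protein (or set of proteins) under a setting
#'
#' Builds the windowed, un-normalized feature matrix for one or more
#' proteins together with per-row provenance (protein id, residue index,
#' predicted and actual 3-state class, angle targets).
#'
#' @param proteins a `bap_protein` or list of them (see
#'   [generate_protein()] / [read_protein_dir()]).
#' @param setting an `ahiw` setting or name.
#' @return object of class `feature_matrix`: list with `x` (numeric matrix,
#'   `rows = residues`, `cols = width * W`), `meta` (data frame with
#'   `protein`, `residue_index`, `ss3_pred`, `ss3_true`, `phi`, `psi`,
#'   `theta`, `tau`), and the `setting`.
#' @export
encode_proteins <- function(proteins, setting = "YYR9") {
  setting <- parse_ahiw(setting)
  if (inherits(proteins, "bap_protein")) proteins <- list(proteins)
  xs <- vector("list", length(proteins))
  metas <- vector("list", length(proteins))
  for (j in seq_along(proteins)) {
    p <- proteins[[j]]
    per <- assemble_residue_features(
      ss8 = p$ss8_pred, pssm = p$pssm, hmm = p$hmm, asa = p$asa,
      setting = setting, sequence = p$sequence)
    xs[[j]] <- window_encode(per, setting$window)
    ang <- p$angles
    metas[[j]] <- data.frame(
      protein = p$id,
      residue_index = seq_len(nrow(per)),
      ss3_pred = map_ss8_to_ss3(p$ss8_pred),
      ss3_true = map_ss8_to_ss3(p$ss8_true),
      phi = ang$phi, psi = ang$psi, theta = ang$theta, tau = ang$tau,
      stringsAsFactors = FALSE)
  }
  structure(list(x = do.call(rbind, xs),
                 meta = do.call(rbind, metas),
                 setting = setting),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d residues x %d features (setting %s)\n",
              nrow(x$x), ncol(x$x), x$setting$name))
  invisible(x)
}

#' Write a feature matrix as TSV
#'
#' Emits the provenance columns followed by the encoded features, with a
#' header naming each windowed column block and offset.
#'
#' @param fm a `feature_matrix`.
#' @param path output file.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  out <- cbind(fm$meta, as.data.frame(fm$x))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
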