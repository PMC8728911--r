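# Self-contained synthetic protein generator with planted class-conditional
# angle distributions and angle-informative feature profiles, so the whole
# train/predict/evaluate/build pipeline can be rehearsed without external
# databases.

#' Synthetic-dataset generator configuration
#'
#' The generator emulates the statistical shape of the real inputs: 8-state
#' secondary structure drawn as segments whose stationary class composition
#' approximates the roughly 38/23/39 helix/sheet/coil split of natural
#' proteins; helix and sheet phi/psi concentrated (about a 20-degree range)
#' in their respective Ramachandran basins; coil a broad multi-basin
#' mixture; PSSM- and HMM-like profiles that are smooth trigonometric
#' functions of the residue's (sin phi, cos phi, sin psi, cos psi) plus
#' noise — a planted, learnable, non-linear signal; ASA a noisy
#' class-dependent scalar; and predicted 8-state labels equal to the true
#' ones corrupted at a configurable per-residue error rate.
#'
#' @param n_proteins number of proteins.
#' @param length_range integer range of chain lengths (uniform).
#' @param target_fractions stationary helix/sheet/coil residue fractions.
#' @param mean_segment_length mean secondary-structure segment length per
#'   class (geometric lengths).
#' @param angle_model per-class phi/psi distributions; see defaults.
#' @param feature_noise standard deviation of the noise added to the
#'   planted profile signal.
#' @param ss_error_rate per-residue probability that the predicted 8-state
#'   label differs from the true one (in \[0, 1)).
#' @param class_specific_link if TRUE, each 3-state class gets its own
#'   independently drawn feature link, so the same profile values map to
#'   different angles in different classes — the divergent-map scenario in
#'   which class-specialised models have an information advantage over a
#'   pooled one.
#' @param asa_model per-class mean ASA and common noise sd.
#' @param seed integer seed; the same configuration and seed reproduce the
#'   dataset exactly.
#' @return object of class `gen_config`.
#' @export
gen_config <- function(n_proteins = 60L,
                       length_range = c(40L, 100L),
                       target_fractions = c(helix = 0.38, sheet = 0.23,
                                            coil = 0.39),
                       mean_segment_length = c(helix = 10, sheet = 6,
                                               coil = 8),
                       angle_model = default_angle_model(),
                       feature_noise = 0.1,
                       ss_error_rate = 0.08,
                       asa_model = list(mean = c(helix = 35, sheet = 25,
                                                 coil = 60), sd = 8),
                       class_specific_link = FALSE,
                       seed = 1L) {
  stopifnot(n_proteins >= 1L, length(length_range) == 2L,
            length_range[1L] >= 5L, length_range[2L] >= length_range[1L],
            abs(sum(target_fractions) - 1) < 1e-8,
            all(mean_segment_length > 0),
            feature_noise >= 0, ss_error_rate >= 0, ss_error_rate < 1)
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 target_fractions = target_fractions,
                 mean_segment_length = mean_segment_length,
                 angle_model = angle_model,
                 feature_noise = feature_noise,
                 ss_error_rate = ss_error_rate,
                 asa_model = asa_model,
                 class_specific_link = isTRUE(class_specific_link),
                 seed = as.integer(seed)),
            class = "gen_config")
}

#' Default class-conditional phi/psi model
#'
#' Helix and sheet are tight Gaussians (sd 5 degrees, so about a 20-degree
#' range) centred in the alpha and beta Ramachandran basins; coil is a
#' broad four-component mixture spanning the alpha, beta and left-handed
#' basins plus a uniform background. These are generator parameters, not
#' estimates from any dataset.
#'
#' @return nested list keyed by class.
#' @export
default_angle_model <- function() {
  list(
    helix = list(type = "gaussian", phi_mean = -63, phi_sd = 5,
                 psi_mean = -42, psi_sd = 5),
    sheet = list(type = "gaussian", phi_mean = -120, phi_sd = 5,
                 psi_mean = 135, psi_sd = 5),
    coil = list(type = "mixture",
                weights = c(0.35, 0.40, 0.15, 0.10),
                phi_mean = c(-70, -110, 60, 0),
                psi_mean = c(-35, 130, 45, 0),
                phi_sd = c(15, 20, 10, NA),  # NA = uniform component
                psi_sd = c(15, 20, 10, NA)))
}

.ss8_letters <- list(
  helix = c(H = 0.85, G = 0.10, I = 0.05),
  sheet = c(E = 0.90, B = 0.10),
  coil = c(C = 0.50, T = 0.30, S = 0.20))

sample_class_angles <- function(class, n, model) {
  m <- model[[class]]
  if (m$type == "gaussian") {
    phi <- stats::rnorm(n, m$phi_mean, m$phi_sd)
    psi <- stats::rnorm(n, m$psi_mean, m$psi_sd)
  } else {
    comp <- sample.int(length(m$weights), n, replace = TRUE, prob = m$weights)
    phi <- psi <- numeric(n)
    for (i in seq_len(n)) {
      k <- comp[i]
      if (is.na(m$phi_sd[k])) {
        phi[i] <- stats::runif(1, -180, 180)
        psi[i] <- stats::runif(1, -180, 180)
      } else {
        phi[i] <- stats::rnorm(1, m$phi_mean[k], m$phi_sd[k])
        psi[i] <- stats::rnorm(1, m$psi_mean[k], m$psi_sd[k])
      }
    }
  }
  list(phi = wrap_angle(phi), psi = wrap_angle(psi))
}

# segment-class draw weights giving the configured stationary residue
# fractions: weight_c proportional to fraction_c / mean_length_c
segment_class_weights <- function(cfg) {
  w <- cfg$target_fractions[SS3_CLASSES] / cfg$mean_segment_length[SS3_CLASSES]
  w / sum(w)
}

sample_ss_segments <- function(cfg, L) {
  w <- segment_class_weights(cfg)
  cls <- character(0)
  ss8 <- character(0)
  while (length(cls) < L) {
    cl <- sample(SS3_CLASSES, 1L, prob = w)
    len <- 1L + stats::rgeom(1L, 1 / cfg$mean_segment_length[[cl]])
    lets <- .ss8_letters[[cl]]
    letter <- sample(names(lets), 1L, prob = lets)
    cls <- c(cls, rep(cl, len))
    ss8 <- c(ss8, rep(letter, len))
  }
  list(class = cls[seq_len(L)], ss8 = ss8[seq_len(L)])
}

# trig basis of the planted feature link
angle_basis <- function(phi, psi) {
  pr <- phi * pi / 180
  qr <- psi * pi / 180
  cbind(sin(pr), cos(pr), sin(qr), cos(qr),
        sin(pr) * cos(qr), cos(pr) * sin(qr))
}

# deterministic link coefficients derived from the config seed without
# disturbing the caller's RNG stream
plant_link <- function(cfg) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed((cfg$seed + 90017L) %% .Machine$integer.max)
  draw <- function() list(pssm = matrix(stats::rnorm(6L * 20L, sd = 2), 6L, 20L),
                          hmm = matrix(stats::rnorm(6L * 20L, sd = 1.5), 6L, 20L))
  if (isTRUE(cfg$class_specific_link))
    lapply(stats::setNames(SS3_CLASSES, SS3_CLASSES), function(cl) draw())
  else draw()
}

# per-residue planted profile blocks under a shared or class-specific link
link_features <- function(link, basis, class, noise_sd) {
  L <- nrow(basis)
  emit <- function(lk, rows) {
    list(pssm = basis[rows, , drop = FALSE] %*% lk$pssm * 3,
         hmm_raw = basis[rows, , drop = FALSE] %*% lk$hmm * 2)
  }
  pssm <- matrix(0, L, 20L)
  hmm_raw <- matrix(0, L, 20L)
  if (is.null(link$pssm)) {  # class-specific
    for (cl in SS3_CLASSES) {
      rows <- which(class == cl)
      if (!length(rows)) next
      e <- emit(link[[cl]], rows)
      pssm[rows, ] <- e$pssm
      hmm_raw[rows, ] <- e$hmm_raw
    }
  } else {
    e <- emit(link, seq_len(L))
    pssm <- e$pssm
    hmm_raw <- e$hmm_raw
  }
  pssm <- pssm + matrix(stats::rnorm(L * 20L, sd = noise_sd), L, 20L)
  hmm_raw <- hmm_raw + matrix(stats::rnorm(L * 20L, sd = noise_sd), L, 20L)
  list(pssm = pssm, hmm = row_softmax(hmm_raw))
}

row_softmax <- function(x) {
  e <- exp(x - apply(x, 1L, max))
  e / rowSums(e)
}

#' Generate one synthetic protein
#'
#' Draws secondary structure as segments, samples phi/psi from the
#' class-conditional distributions, reconstructs coordinates with
#' [build_backbone()] (so theta and tau are geometric consequences of the
#' sampled torsions), and derives the feature blocks from the planted
#' angle link. Consumes the caller's RNG stream: seed the session (or use
#' [generate_dataset()]) for reproducibility.
#'
#' @param cfg a [gen_config()].
#' @param id protein identifier.
#' @param link planted link coefficients; defaults to the configuration's
#'   deterministic link.
#' @return object of class `bap_protein`: list with `id`, `sequence`,
#'   `ss8_true`, `ss8_pred`, `angles` (an `angle_table`), `chain`
#'   (a `backbone_chain`), `pssm`, `hmm`, `asa`.
#' @export
generate_protein <- function(cfg, id = "P001", link = plant_link(cfg)) {
  stopifnot(inherits(cfg, "gen_config"))
  L <- sample(seq(cfg$length_range[1L], cfg$length_range[2L]), 1L)
  seg <- sample_ss_segments(cfg, L)
  sequence <- paste(sample(names(aa_one_to_three), L, replace = TRUE),
                    collapse = "")
  phi <- psi <- numeric(L)
  for (cl in SS3_CLASSES) {
    idx <- which(seg$class == cl)
    if (!length(idx)) next
    draw <- sample_class_angles(cl, length(idx), cfg$angle_model)
    phi[idx] <- draw$phi
    psi[idx] <- draw$psi
  }
  chain <- build_backbone(sequence, phi, psi, chain_id = "A")
  angles <- compute_backbone_angles(chain)
  basis <- angle_basis(phi, psi)
  lf <- link_features(link, basis, seg$class, cfg$feature_noise)
  pssm <- lf$pssm
  colnames(pssm) <- PSSM_AA_ORDER
  hmm <- lf$hmm
  colnames(hmm) <- HHM_AA_ORDER
  asa <- cfg$asa_model$mean[seg$class] +
    stats::rnorm(L, sd = cfg$asa_model$sd)
  ss8_pred <- seg$ss8
  if (cfg$ss_error_rate > 0) {
    flip <- stats::runif(L) < cfg$ss_error_rate
    for (i in which(flip))
      ss8_pred[i] <- sample(setdiff(SS8_ALPHABET, seg$ss8[i]), 1L)
  }
  structure(list(id = id, sequence = sequence,
                 ss8_true = seg$ss8, ss8_pred = ss8_pred,
                 angles = angles, chain = chain,
                 pssm = pssm, hmm = hmm, asa = as.numeric(asa)),
            class = "bap_protein")
}

#' @export
print.bap_protein <- function(x, ...) {
  cat(sprintf("bap_protein %s: %d residues\n", x$id, nchar(x$sequence)))
  invisible(x)
}

#' Generate a full train/validation/test dataset
#'
#' Draws `cfg$n_proteins` synthetic proteins from one seeded stream and
#' splits them into disjoint train/validation/test sets by the given
#' fractions (rounded down for validation and test, remainder to train).
#' When `dir` is given the proteins and a JSON manifest (seed,
#' configuration fingerprint, split ids, per-file MD5 digests) are written
#' to disk in the package's interchange formats; rerunning with the same
#' configuration reproduces the files byte for byte.
#'
#' @param cfg a [gen_config()].
#' @param fractions named train/validation/test fractions summing to 1.
#' @param dir optional output directory.
#' @return list with `train`, `validation`, `test` (lists of
#'   `bap_protein`) and `manifest`.
#' @export
generate_dataset <- function(cfg,
                             fractions = c(train = 0.8, validation = 0.1,
                                           test = 0.1),
                             dir = NULL) {
  stopifnot(inherits(cfg, "gen_config"),
            all(c("train", "validation", "test") %in% names(fractions)))
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("generate_dataset: split fractions must sum to 1")
  set.seed(cfg$seed)
  link <- plant_link(cfg)
  n <- cfg$n_proteins
  ids <- sprintf("P%04d", seq_len(n))
  proteins <- lapply(seq_len(n), function(i)
    generate_protein(cfg, id = ids[i], link = link))
  n_val <- floor(fractions[["validation"]] * n)
  n_test <- floor(fractions[["test"]] * n)
  n_train <- n - n_val - n_test
  if (n_train < 1L) stop("generate_dataset: no training proteins left")
  splits <- list(train = proteins[seq_len(n_train)],
                 validation = proteins[n_train + seq_len(n_val)],
                 test = proteins[n_train + n_val + seq_len(n_test)])
  manifest <- list(seed = cfg$seed, n_proteins = n,
                   fractions = as.list(fractions),
                   counts = lapply(splits, length),
                   ids = lapply(splits, function(s)
                     vapply(s, function(p) p$id, "")))
  if (!is.null(dir)) {
    files <- character(0)
    for (sp in names(splits)) {
      spdir <- file.path(dir, sp)
      dir.create(spdir, showWarnings = FALSE, recursive = TRUE)
      for (p in splits[[sp]])
        files <- c(files, write_protein(p, spdir))
    }
    digests <- tools::md5sum(files)
    names(digests) <- sub(paste0("^", gsub("([][{}()+*^$|\\\\.?])",
                                           "\\\\\\1", dir), "/?"), "",
                          names(digests))
    manifest$md5 <- as.list(digests)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  c(splits, list(manifest = manifest))
}

#' Write one protein's interchange files
#'
#' Emits, under `dir`: `<id>.fasta` (sequence), `<id>.ss8_true` and
#' `<id>.ss8_pred` (FASTA-like 8-state strings), `<id>.pssm` (PSI-BLAST
#' ASCII layout), `<id>.hhm` (HHsuite layout), `<id>.asa.tsv`, `<id>.pdb`
#' and `<id>.angles.tsv`.
#'
#' @param p a `bap_protein`.
#' @param dir output directory.
#' @return character vector of the files written.
#' @export
write_protein <- function(p, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(ext) file.path(dir, paste0(p$id, ext))
  write_fasta_like(p$id, p$sequence, f(".fasta"))
  write_fasta_like(p$id, paste(p$ss8_true, collapse = ""), f(".ss8_true"))
  write_fasta_like(p$id, paste(p$ss8_pred, collapse = ""), f(".ss8_pred"))
  write_pssm(p$sequence, p$pssm, f(".pssm"))
  write_hhm(p$sequence, p$hmm, f(".hhm"))
  write_asa(p$asa, f(".asa.tsv"))
  write_pdb_chain(p$chain, f(".pdb"))
  write_angle_table(p$angles, f(".angles.tsv"))
  vapply(c(".fasta", ".ss8_true", ".ss8_pred", ".pssm", ".hhm", ".asa.tsv",
           ".pdb", ".angles.tsv"), f, "")
}

#' Read a protein from its interchange files
#'
#' Counterpart of [write_protein()].
#'
#' @param dir directory containing the files.
#' @param id protein identifier (file stem).
#' @return a `bap_protein`.
#' @export
read_protein <- function(dir, id) {
  f <- function(ext) file.path(dir, paste0(id, ext))
  sequence <- read_fasta_like(f(".fasta"))$sequence
  ss8_true <- strsplit(read_fasta_like(f(".ss8_true"))$sequence, "")[[1L]]
  ss8_pred <- strsplit(read_fasta_like(f(".ss8_pred"))$sequence, "")[[1L]]
  pssm <- read_pssm(f(".pssm"))$scores
  hmm <- read_hhm(f(".hhm"))$freq
  asa <- read_asa(f(".asa.tsv"))
  chain <- read_pdb_chain(f(".pdb"))
  angles <- read_angle_table(f(".angles.tsv"))
  structure(list(id = id, sequence = sequence, ss8_true = ss8_true,
                 ss8_pred = ss8_pred, angles = angles, chain = chain,
                 pssm = pssm, hmm = hmm, asa = asa),
            class = "bap_protein")
}

#' Load a dataset directory written by [generate_dataset()]
#'
#' @param dir dataset root containing `manifest.json`.
#' @return list with `train`, `validation`, `test` and `manifest`.
#' @export
load_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  out <- list()
  for (sp in c("train", "validation", "test")) {
    ids <- manifest$ids[[sp]]
    out[[sp]] <- lapply(ids, function(id) read_protein(file.path(dir, sp), id))
  }
  out$manifest <- manifest
  out
}
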