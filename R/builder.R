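# Backbone reconstruction from torsions via sequential internal-coordinate
# (NeRF-style) placement, plus superposition RMSD.

# canonical peptide geometry used at inter-residue junctions; the C-N length
# and the 180-degree omega are fixed by construction, the junction bond
# angles are standard peptide values.
.peptide_geom <- list(
  b_CN = 1.33,       # C(i-1)-N(i) peptide bond, Angstrom
  ang_CA_C_N = 116.2,
  ang_C_N_CA = 121.7,
  omega = 180
)

# idealized intra-residue geometry for the bundled template library
.template_geom <- list(
  b_N_CA = 1.458,
  b_CA_C = 1.525,
  ang_N_CA_C = 111.2,
  b_CA_CB = 1.53,
  ang_N_CA_CB = 110.5,
  tor_C_N_CA_CB = -122.55  # improper fixing L-chirality
)

#' Place an atom from internal coordinates
#'
#' NeRF-style placement: the new atom D is positioned at distance `bond`
#' from C, with angle B-C-D equal to `angle` and dihedral A-B-C-D equal to
#' `torsion` (IUPAC sign convention, consistent with [dihedral()]).
#'
#' @param a,b,c numeric length-3 coordinates of the three reference atoms.
#' @param bond C-D distance (Angstrom).
#' @param angle B-C-D angle (degrees).
#' @param torsion A-B-C-D dihedral (degrees).
#' @return numeric length-3 coordinate of the new atom.
#' @export
place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- angle * pi / 180
  ch <- torsion * pi / 180
  d_local <- c(-bond * cos(th),
               bond * sin(th) * cos(ch),
               bond * sin(th) * sin(ch))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc)
  nn <- sqrt(sum(n^2))
  if (nn < .degeneracy_tol)
    stop("place_atom: degenerate reference geometry")
  n <- n / nn
  m <- cross3(n, bc)
  c + d_local[1L] * bc + d_local[2L] * m + d_local[3L] * n
}

make_template <- function(aa) {
  g <- .template_geom
  N <- c(-g$b_N_CA, 0, 0)
  CA <- c(0, 0, 0)
  ang <- g$ang_N_CA_C * pi / 180
  C <- g$b_CA_C * c(-cos(ang), sin(ang), 0)
  coords <- rbind(N = N, CA = CA, C = C, CB = c(NA_real_, NA_real_, NA_real_))
  colnames(coords) <- c("x", "y", "z")
  if (aa != "G") {
    # place CB off the N-CA-C plane with L-chirality
    coords["CB", ] <- place_atom(C, N, CA, g$b_CA_CB,
                                 g$ang_N_CA_CB, g$tor_C_N_CA_CB)
  }
  list(aa = aa, coords = coords)
}

#' Bundled residue template library
#'
#' One local-frame template per standard amino acid (20 in total) holding
#' N, CA, C and (except glycine) CB coordinates. The bundled library uses
#' idealized canonical bond lengths and angles; it is synthetic, not taken
#' from any deposited structure. A library extracted from a real structure
#' can be loaded with [residue_library_from_pdb()].
#'
#' @return object of class `residue_library`: named list of templates.
#' @export
residue_library <- function() {
  aas <- names(aa_one_to_three)
  lib <- lapply(aas, make_template)
  names(lib) <- aas
  structure(lib, class = "residue_library")
}

#' Build a residue template library from a PDB file
#'
#' Takes, for each amino-acid type, the first residue in the file with
#' complete N/CA/C (and CB where applicable) and stores it in a local frame
#' (CA at the origin, N on the negative x-axis, C in the xy-plane with
#' positive y). Amino acids absent from the file fall back to the idealized
#' template.
#'
#' @param path PDB file.
#' @param chain chain identifier passed to [read_pdb_chain()].
#' @return a `residue_library`.
#' @export
residue_library_from_pdb <- function(path, chain = NULL) {
  bb <- read_pdb_chain(path, chain)
  lib <- residue_library()
  seqv <- strsplit(bb$sequence, "")[[1L]]
  for (aa in names(lib)) {
    idx <- which(seqv == aa)
    for (i in idx) {
      N <- res_atom(bb, i, "N"); CA <- res_atom(bb, i, "CA")
      C <- res_atom(bb, i, "C"); CB <- res_atom(bb, i, "CB")
      if (is.null(N) || is.null(CA) || is.null(C)) next
      if (aa != "G" && is.null(CB)) next
      loc <- to_local_frame(N, CA, C, CB)
      lib[[aa]]$coords <- loc
      break
    }
  }
  lib
}

# express N/CA/C/CB in the canonical local frame (CA origin, N on -x,
# C in xy with y > 0)
to_local_frame <- function(N, CA, C, CB = NULL) {
  ex <- (CA - N); ex <- ex / sqrt(sum(ex^2))
  v <- C - CA
  ez <- cross3(ex, v); ez <- ez / sqrt(sum(ez^2))
  ey <- cross3(ez, ex)
  R <- rbind(ex, ey, ez)
  tr <- function(p) as.numeric(R %*% (p - CA))
  coords <- rbind(N = tr(N), CA = c(0, 0, 0), C = tr(C),
                  CB = if (is.null(CB)) c(NA_real_, NA_real_, NA_real_) else tr(CB))
  colnames(coords) <- c("x", "y", "z")
  coords
}

template_internal <- function(tpl) {
  co <- tpl$coords
  out <- list(
    b_N_CA = sqrt(sum((co["N", ] - co["CA", ])^2)),
    b_CA_C = sqrt(sum((co["CA", ] - co["C", ])^2)),
    ang_N_CA_C = planar_angle(co["N", ], co["CA", ], co["C", ])
  )
  if (!anyNA(co["CB", ])) {
    out$b_CA_CB <- sqrt(sum((co["CA", ] - co["CB", ])^2))
    out$ang_C_CA_CB <- planar_angle(co["C", ], co["CA", ], co["CB", ])
    out$tor_C_N_CA_CB <- dihedral(co["C", ], co["N", ], co["CA", ], co["CB", ])
  }
  out
}

#' Reconstruct a backbone from phi/psi torsions
#'
#' Extends the chain residue by residue with internal-coordinate placement:
#' each atom is positioned from the bond length, bond angle and torsion of
#' the three previously placed atoms. Inter-residue junctions use a C-N
#' peptide bond of 1.33 Angstrom and a fixed omega of 180 degrees; the
#' supplied psi_i places N_{i+1} and phi_{i+1} places C_{i+1}. Intra-residue
#' geometry (N-CA, CA-C, the N-CA-C angle and CB placement) comes from the
#' residue library template of each amino acid, so extracting angles from
#' the built chain returns the prescription exactly (to numerical noise).
#'
#' phi at residue 1 and psi at the last residue do not correspond to any
#' torsion of the chain and may be NA; interior NAs are an error.
#'
#' @param sequence one-letter amino-acid string.
#' @param phi,psi numeric vectors of torsions in degrees, one per residue.
#' @param library a `residue_library`; default the bundled idealized one.
#' @param chain_id chain identifier for the result.
#' @return a [backbone_chain] with N, CA, C and CB (non-glycine) coordinates.
#' @export
build_backbone <- function(sequence, phi, psi, library = residue_library(),
                           chain_id = "A") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  n <- nchar(sequence)
  if (n < 1L) stop("build_backbone: empty sequence")
  if (length(phi) != n || length(psi) != n)
    stop("build_backbone: phi/psi length must equal sequence length")
  seqv <- strsplit(sequence, "")[[1L]]
  bad <- setdiff(seqv, names(library))
  if (length(bad))
    stop("build_backbone: unknown amino acid(s): ", paste(unique(bad), collapse = ", "))
  if (n >= 2L && (anyNA(phi[-1L]) || anyNA(psi[-n])))
    stop("build_backbone: interior phi/psi must be defined")
  pg <- .peptide_geom
  internals <- lapply(seqv, function(a) template_internal(library[[a]]))
  arr <- array(NA_real_, dim = c(n, 4L, 3L),
               dimnames = list(NULL, c("N", "CA", "C", "CB"), c("x", "y", "z")))
  # residue 1 in the canonical frame
  g1 <- internals[[1L]]
  arr[1L, "N", ] <- c(0, 0, 0)
  arr[1L, "CA", ] <- c(g1$b_N_CA, 0, 0)
  a1 <- g1$ang_N_CA_C * pi / 180
  arr[1L, "C", ] <- arr[1L, "CA", ] + g1$b_CA_C * c(-cos(a1), sin(a1), 0)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      gi1 <- internals[[i + 1L]]
      arr[i + 1L, "N", ] <- place_atom(arr[i, "N", ], arr[i, "CA", ], arr[i, "C", ],
                                       pg$b_CN, pg$ang_CA_C_N, psi[i])
      arr[i + 1L, "CA", ] <- place_atom(arr[i, "CA", ], arr[i, "C", ], arr[i + 1L, "N", ],
                                        gi1$b_N_CA, pg$ang_C_N_CA, pg$omega)
      arr[i + 1L, "C", ] <- place_atom(arr[i, "C", ], arr[i + 1L, "N", ], arr[i + 1L, "CA", ],
                                       gi1$b_CA_C, gi1$ang_N_CA_C, phi[i + 1L])
    }
  }
  for (i in seq_len(n)) {
    gi <- internals[[i]]
    if (!is.null(gi$b_CA_CB))
      arr[i, "CB", ] <- place_atom(arr[i, "C", ], arr[i, "N", ], arr[i, "CA", ],
                                   gi$b_CA_CB, gi$ang_C_CA_CB, gi$tor_C_N_CA_CB)
  }
  backbone_chain(sequence, arr, chain_id = chain_id)
}

chain_xyz <- function(chain, atoms = "CA") {
  sel <- if (identical(atoms, "backbone") || identical(atoms, "bb"))
    c("N", "CA", "C") else toupper(atoms)
  out <- NULL
  for (i in seq_len(length(chain)))
    for (a in sel) {
      p <- chain$coords[i, a, ]
      out <- rbind(out, p)
    }
  rownames(out) <- NULL
  out
}

#' Optimal-superposition RMSD between two chains
#'
#' Least-squares rigid superposition (rotation plus translation, no
#' reflection) of the selected atoms, then root-mean-square deviation.
#' Superposition uses bio3d's Kabsch least-squares fit (`bio3d::fit.xyz`);
#' the deviation is computed from the fitted coordinates at full
#' precision.
#'
#' @param a,b [backbone_chain] objects with equal residue counts.
#' @param atoms `"CA"` (default) or `"backbone"` (N, CA, C).
#' @return RMSD in Angstrom.
#' @export
superpose_rmsd <- function(a, b, atoms = c("CA", "backbone")) {
  atoms <- match.arg(atoms)
  if (length(a) != length(b))
    stop("superpose_rmsd: chains have different residue counts")
  xa <- chain_xyz(a, atoms)
  xb <- chain_xyz(b, atoms)
  if (anyNA(xa) || anyNA(xb))
    stop("superpose_rmsd: selected atoms missing in one of the chains")
  va <- as.numeric(t(xa))
  fit <- bio3d::fit.xyz(fixed = va, mobile = as.numeric(t(xb)),
                        fixed.inds = seq_along(va),
                        mobile.inds = seq_along(va))
  sqrt(mean(rowSums(matrix(va - as.numeric(fit), ncol = 3L, byrow = TRUE)^2)))
}
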