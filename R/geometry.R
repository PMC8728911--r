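#' Wrap an angle into (-180, 180] degrees
#'
#' Periodic angles are reported on the half-open interval (-180, 180]:
#' 360 is subtracted from (added to) any value above 180 (at or below -180)
#' until the value falls in range. The upper endpoint +180 is kept so that
#' the wrap is a function (exactly one representative per equivalence class).
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector of the same length, each element congruent to the
#'   input modulo 360 and lying in (-180, 180].
#' @examples
#' wrap_angle(c(190, -190, 180, 0, 540))
#' @export
wrap_angle <- function(x) {
  stopifnot(is.numeric(x))
  if (any(!is.finite(x) & !is.na(x)))
    stop("wrap_angle: non-finite angle")
  r <- x %% 360
  r[!is.na(r) & r > 180] <- r[!is.na(r) & r > 180] - 360
  r
}

# cross product of two length-3 vectors
cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# triples whose cross-product norm falls below this are treated as collinear
.degeneracy_tol <- 1e-10

#' Signed dihedral angle of four points
#'
#' Returns the torsion about the p2-p3 axis under the IUPAC sign convention:
#' looking from p2 towards p3, a clockwise rotation of p4 relative to p1 is
#' positive. This is the convention under which an alpha-helical phi is
#' approximately -60 degrees.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (Angstrom).
#' @return dihedral angle in degrees, in (-180, 180].
#' @examples
#' dihedral(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0))   # cis, 0
#' dihedral(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(-1, 0, 0))  # trans, 180
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < .degeneracy_tol || sqrt(sum(n2^2)) < .degeneracy_tol)
    stop("dihedral: degenerate geometry (collinear or coincident points)")
  u2 <- b2 / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * u2)
  wrap_angle(atan2(y, x) * 180 / pi)
}

#' Planar (bond) angle of three points
#'
#' Interior angle at `p2` formed by the rays towards `p1` and `p3`.
#'
#' @param p1,p2,p3 numeric length-3 coordinate vectors (Angstrom).
#' @return angle in degrees, in \[0, 180\].
#' @examples
#' planar_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))  # 90
#' @export
planar_angle <- function(p1, p2, p3) {
  v1 <- p1 - p2
  v2 <- p3 - p2
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 < .degeneracy_tol || n2 < .degeneracy_tol)
    stop("planar_angle: degenerate geometry (coincident points)")
  ct <- sum(v1 * v2) / (n1 * n2)
  ct <- min(1, max(-1, ct))
  acos(ct) * 180 / pi
}

#' Backbone chain container
#'
#' Holds per-residue backbone atom coordinates (N, CA, C and optionally CB)
#' together with the amino-acid sequence. Coordinates are stored as an
#' `n x 4 x 3` array; missing atoms are NA.
#'
#' @param sequence character scalar, one-letter amino-acid sequence.
#' @param coords numeric array `n x 4 x 3` with atom dimension named
#'   `c("N","CA","C","CB")`, or a list with matrices `N`, `CA`, `C` and
#'   optionally `CB` (each `n x 3`).
#' @param chain_id chain identifier (single character).
#' @return object of class `backbone_chain`.
#' @export
backbone_chain <- function(sequence, coords, chain_id = "A") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  n <- nchar(sequence)
  atoms <- c("N", "CA", "C", "CB")
  if (is.list(coords) && !is.array(coords)) {
    arr <- array(NA_real_, dim = c(n, 4L, 3L),
                 dimnames = list(NULL, atoms, c("x", "y", "z")))
    for (a in intersect(atoms, names(coords))) arr[, a, ] <- coords[[a]]
    coords <- arr
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3L,
            dim(coords)[2L] == 4L, dim(coords)[3L] == 3L)
  if (dim(coords)[1L] != n)
    stop("backbone_chain: sequence length and coordinate rows differ")
  dimnames(coords) <- list(NULL, atoms, c("x", "y", "z"))
  structure(list(sequence = sequence, coords = coords, chain_id = chain_id),
            class = "backbone_chain")
}

#' @export
length.backbone_chain <- function(x) nchar(x$sequence)

#' @export
print.backbone_chain <- function(x, ...) {
  n <- length(x)
  cat(sprintf("backbone_chain: %d residues, chain '%s'\n", n, x$chain_id))
  cat(" ", substr(x$sequence, 1L, min(60L, n)),
      if (n > 60L) "..." else "", "\n", sep = "")
  invisible(x)
}

res_atom <- function(chain, i, atom) {
  if (i < 1L || i > length(chain)) return(NULL)
  p <- chain$coords[i, atom, ]
  if (anyNA(p)) NULL else as.numeric(p)
}

#' Extract backbone angles from a chain
#'
#' Computes per-residue phi, psi, theta and tau:
#' \itemize{
#'   \item phi_i  = dihedral(C_{i-1}, N_i, CA_i, C_i)
#'   \item psi_i  = dihedral(N_i, CA_i, C_i, N_{i+1})
#'   \item theta_i = planar_angle(CA_{i-1}, CA_i, CA_{i+1})
#'   \item tau_i  = dihedral(CA_{i-1}, CA_i, CA_{i+1}, CA_{i+2})
#' }
#' Angles whose defining atoms fall outside the chain (phi at residue 1, psi
#' at the last residue, theta/tau near both termini) or touch a missing atom
#' are NA, mirroring the convention that undefined terminal angles are
#' excluded from every loss and metric.
#'
#' @param chain a [backbone_chain].
#' @return an `angle_table` data frame with columns `residue_index`, `aa`,
#'   `phi`, `psi`, `theta`, `tau`.
#' @export
compute_backbone_angles <- function(chain) {
  stopifnot(inherits(chain, "backbone_chain"))
  n <- length(chain)
  if (n == 0L) stop("compute_backbone_angles: empty chain")
  phi <- psi <- theta <- tau <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    Cp <- res_atom(chain, i - 1L, "C")
    Ni <- res_atom(chain, i, "N")
    CAi <- res_atom(chain, i, "CA")
    Ci <- res_atom(chain, i, "C")
    Nn <- res_atom(chain, i + 1L, "N")
    if (!is.null(Cp) && !is.null(Ni) && !is.null(CAi) && !is.null(Ci))
      phi[i] <- dihedral(Cp, Ni, CAi, Ci)
    if (!is.null(Ni) && !is.null(CAi) && !is.null(Ci) && !is.null(Nn))
      psi[i] <- dihedral(Ni, CAi, Ci, Nn)
    ca_m <- res_atom(chain, i - 1L, "CA")
    ca_p <- res_atom(chain, i + 1L, "CA")
    ca_pp <- res_atom(chain, i + 2L, "CA")
    if (!is.null(ca_m) && !is.null(CAi) && !is.null(ca_p))
      theta[i] <- planar_angle(ca_m, CAi, ca_p)
    if (i >= 2L && i <= n - 2L &&
        !is.null(ca_m) && !is.null(CAi) && !is.null(ca_p) && !is.null(ca_pp))
      tau[i] <- dihedral(ca_m, CAi, ca_p, ca_pp)
  }
  angle_table(residue_index = seq_len(n),
              aa = strsplit(chain$sequence, "")[[1L]],
              phi = phi, psi = psi, theta = theta, tau = tau)
}

#' Per-residue angle table
#'
#' @param residue_index 1-based residue indices.
#' @param aa one-letter amino acids.
#' @param phi,psi,theta,tau angles in degrees; NA marks undefined.
#' @return data frame of class `angle_table`.
#' @export
angle_table <- function(residue_index, aa, phi, psi, theta, tau) {
  df <- data.frame(residue_index = as.integer(residue_index),
                   aa = as.character(aa),
                   phi = as.numeric(phi), psi = as.numeric(psi),
                   theta = as.numeric(theta), tau = as.numeric(tau),
                   stringsAsFactors = FALSE)
  class(df) <- c("angle_table", "data.frame")
  df
}

#' Write an angle table as TSV
#'
#' Columns: residue_index, aa, phi, psi, theta, tau; undefined angles are
#' written as "NA".
#'
#' @param x an `angle_table`.
#' @param path output file.
#' @export
write_angle_table <- function(x, path) {
  stopifnot(inherits(x, "angle_table"))
  out <- as.data.frame(x)
  for (col in c("phi", "psi", "theta", "tau"))
    out[[col]] <- ifelse(is.na(out[[col]]), "NA",
                         formatC(out[[col]], format = "f", digits = 6))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an angle table TSV written by [write_angle_table()]
#'
#' @param path input file.
#' @return an `angle_table`.
#' @export
read_angle_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("integer", "character", rep("numeric", 4L)))
  angle_table(df$residue_index, df$aa, df$phi, df$psi, df$theta, df$tau)
}
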