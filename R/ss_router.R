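# 8-state to 3-state secondary-structure mapping and per-class routing.

#' Default 8-state to 3-state mapping
#'
#' DSSP-convention collapse: H, G, I to helix; E, B to sheet; T, S, C to
#' coil.
#'
#' @export
SS3_DEFAULT_MAP <- c(H = "helix", G = "helix", I = "helix",
                     E = "sheet", B = "sheet",
                     T = "coil", S = "coil", C = "coil")

#' The three secondary-structure classes
#' @export
SS3_CLASSES <- c("helix", "sheet", "coil")

#' Map 8-state secondary-structure codes to 3-state classes
#'
#' @param state character vector of 8-state codes.
#' @param map named character vector giving the class of each 8-state code;
#'   defaults to the DSSP-style collapse [SS3_DEFAULT_MAP].
#' @return character vector over `helix`/`sheet`/`coil`.
#' @examples
#' map_ss8_to_ss3(c("H", "B", "S"))
#' @export
map_ss8_to_ss3 <- function(state, map = SS3_DEFAULT_MAP) {
  out <- unname(map[state])
  if (anyNA(out))
    stop("map_ss8_to_ss3: invalid state '",
         paste(unique(state[is.na(out)]), collapse = "','"),
         "'; alphabet is ", paste(names(map), collapse = ""))
  out
}

#' Partition an encoded dataset by 3-state class
#'
#' Splits the rows of a [encode_proteins()] feature matrix into the three
#' disjoint class subsets according to each residue's *predicted* 3-state
#' class (the same track used to route residues to class-specific models at
#' inference). Row order and the feature/target alignment are preserved
#' within each subset.
#'
#' @param fm a `feature_matrix`.
#' @param by `"pred"` (default; routing track) or `"true"` (evaluation
#'   stratification track).
#' @return named list `helix`/`sheet`/`coil` of `feature_matrix` objects.
#' @export
partition_by_ss <- function(fm, by = c("pred", "true")) {
  stopifnot(inherits(fm, "feature_matrix"))
  by <- match.arg(by)
  if (nrow(fm$x) != nrow(fm$meta))
    stop("partition_by_ss: misaligned features and metadata")
  lab <- if (by == "pred") fm$meta$ss3_pred else fm$meta$ss3_true
  out <- lapply(SS3_CLASSES, function(cl) {
    keep <- lab == cl
    structure(list(x = fm$x[keep, , drop = FALSE],
                   meta = fm$meta[keep, , drop = FALSE],
                   setting = fm$setting),
              class = "feature_matrix")
  })
  names(out) <- SS3_CLASSES
  out
}

#' Class-composition summary of one or more protein sets
#'
#' Residue counts and percentages per 3-state class for each named split,
#' on both the actual and the predicted label track.
#'
#' @param splits named list of protein lists (e.g. train/validation/test).
#' @return data frame with columns `split`, `track`, `class`, `residues`,
#'   `percent`.
#' @export
ss3_summary <- function(splits) {
  rows <- list()
  for (sp in names(splits)) {
    prot <- splits[[sp]]
    for (track in c("true", "pred")) {
      lab <- unlist(lapply(prot, function(p)
        map_ss8_to_ss3(if (track == "true") p$ss8_true else p$ss8_pred)))
      tab <- table(factor(lab, levels = SS3_CLASSES))
      for (cl in SS3_CLASSES)
        rows[[length(rows) + 1L]] <- data.frame(
          split = sp, track = track, class = cl,
          residues = as.integer(tab[[cl]]),
          percent = 100 * as.integer(tab[[cl]]) / sum(tab))
    }
  }
  do.call(rbind, rows)
}
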