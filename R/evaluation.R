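# Accuracy metrics and report tables: periodic MAE, Spearman rank
# correlation, improvement and relative-difference percentages,
# threshold-coverage curves and length-group reports.

#' Periodic absolute error between two angles
#'
#' `AE = min(D, |360 - D|)` with `D = |P - A|`: the absolute angular
#' separation on the circle, in \[0, 180\].
#'
#' @param predicted,actual numeric vectors in degrees (recycled).
#' @return numeric vector of absolute errors.
#' @examples
#' absolute_error(179, -179)  # 2
#' absolute_error(90, -90)    # 180
#' @export
absolute_error <- function(predicted, actual) {
  d <- abs(predicted - actual) %% 360
  pmin(d, abs(360 - d))
}

# per-residue AE vectors for one angle over aligned tables
paired_ae <- function(pred, actual, angle) {
  stopifnot(inherits(pred, "angle_table"), inherits(actual, "angle_table"),
            nrow(pred) == nrow(actual))
  p <- pred[[angle]]
  a <- actual[[angle]]
  keep <- !is.na(p) & !is.na(a)
  list(ae = absolute_error(p[keep], a[keep]), keep = keep)
}

#' Periodic mean absolute error for one angle type
#'
#' Mean AE over residues with the angle defined in both tables, optionally
#' restricted to a stratum (e.g. residues of one *actual* 3-state class,
#' the stratification used in class-wise report tables).
#'
#' @param pred,actual aligned `angle_table`s.
#' @param angle one of `"phi"`, `"psi"`, `"theta"`, `"tau"`.
#' @param stratum optional logical vector (length = rows) selecting the
#'   stratum.
#' @return list with `mae` and residue `count`; an empty stratum yields
#'   `mae = NA` and `count = 0` (absent, not zero).
#' @export
mae_angle <- function(pred, actual, angle = ANGLE_TYPES, stratum = NULL) {
  angle <- match.arg(angle)
  p <- pred[[angle]]
  a <- actual[[angle]]
  keep <- !is.na(p) & !is.na(a)
  if (!is.null(stratum)) {
    stopifnot(length(stratum) == nrow(pred))
    keep <- keep & stratum
  }
  if (!any(keep)) return(list(mae = NA_real_, count = 0L))
  list(mae = mean(absolute_error(p[keep], a[keep])), count = sum(keep))
}

#' Relative improvement over competing errors
#'
#' When `ours` is the best (smallest) MAE the improvement is
#' `(second_best - ours) / ours * 100` (positive); when some competitor is
#' better it is `(best - ours) / ours * 100` (negative, a degradation).
#'
#' @param ours our MAE (> 0).
#' @param others numeric vector of competing MAEs (> 0, non-empty).
#' @return signed percentage.
#' @examples
#' improvement(8.73, c(9.00, 11.99))           # +3.09
#' improvement(16.48, c(15.93, 16.43, 17.22))  # -3.34
#' @export
improvement <- function(ours, others) {
  if (!length(others)) stop("improvement: empty comparison list")
  stopifnot(ours > 0, all(others > 0))
  best <- min(others)
  (best - ours) / ours * 100
}

#' Relative MAE difference of a method versus a reference
#'
#' `(method - reference) / reference * 100`: positive when the method is
#' worse than the reference.
#'
#' @param method the method's MAE.
#' @param reference the reference MAE (> 0).
#' @return percentage.
#' @examples
#' delta_percent(16.30, 15.59)  # +4.55
#' @export
delta_percent <- function(method, reference) {
  stopifnot(reference > 0)
  (method - reference) / reference * 100
}

#' Spearman rank correlation between predicted and actual angles
#'
#' Rank correlation with average ranks for ties, over pairs defined in
#' both vectors. A constant vector has no defined rank correlation and
#' yields NA (reported as absent).
#'
#' @param pred,actual numeric vectors; NAs dropped pairwise.
#' @return correlation in \[-1, 1\], or NA.
#' @export
spearman_rho <- function(pred, actual) {
  keep <- !is.na(pred) & !is.na(actual)
  p <- pred[keep]
  a <- actual[keep]
  if (length(p) < 2L) stop("spearman_rho: need at least 2 defined pairs")
  if (stats::sd(p) == 0 || stats::sd(a) == 0) return(NA_real_)
  stats::cor(p, a, method = "spearman")
}

#' Threshold-coverage curves
#'
#' For each threshold t, the curve point (x, y) gives the percentage y of
#' proteins for which at least x percent of their defined angles have
#' `AE <= t` ("within" is inclusive). x runs over 0..100 in steps of 10.
#'
#' @param protein_aes list of numeric per-protein AE vectors.
#' @param thresholds AE thresholds in degrees (default 6 and 12).
#' @param grid percentage grid.
#' @return data frame with columns `threshold`, `pct_angles` (x) and
#'   `pct_proteins` (y).
#' @export
threshold_coverage <- function(protein_aes, thresholds = c(6, 12),
                               grid = seq(0, 100, by = 10)) {
  if (!length(protein_aes)) stop("threshold_coverage: empty protein set")
  rows <- list()
  for (t in thresholds) {
    frac <- vapply(protein_aes, function(ae) {
      ae <- ae[!is.na(ae)]
      if (!length(ae)) return(NA_real_)
      100 * mean(ae <= t)
    }, 0)
    frac <- frac[!is.na(frac)]
    for (x in grid)
      rows[[length(rows) + 1L]] <- data.frame(
        threshold = t, pct_angles = x,
        pct_proteins = 100 * mean(frac >= x))
  }
  do.call(rbind, rows)
}

#' Per-length-group MAE report
#'
#' Groups proteins by residue count into the standard bins (1-100, 101-200,
#' ..., 501-800, plus an overflow bin when needed) and reports per-bin
#' protein counts and per-angle MAE over the residues of the bin's
#' proteins.
#'
#' @param pred_list,actual_list aligned named lists of `angle_table`s, one
#'   per protein.
#' @param breaks upper bin edges.
#' @return data frame: `group`, `count`, and one MAE column per angle; a
#'   final `Overall` row aggregates everything.
#' @export
length_group_report <- function(pred_list, actual_list,
                                breaks = c(100, 200, 300, 400, 500, 800)) {
  stopifnot(length(pred_list) == length(actual_list))
  lens <- vapply(actual_list, nrow, 0L)
  lower <- c(1, utils::head(breaks, -1) + 1)
  labels <- sprintf("%03d-%03d", lower, breaks)
  bin <- findInterval(lens, c(lower, max(breaks) + 1), left.open = FALSE)
  bin[lens > max(breaks)] <- length(breaks) + 1L
  labels <- c(labels, sprintf(">%d", max(breaks)))
  rows <- list()
  groups <- sort(unique(bin))
  for (g in c(groups, 0L)) {  # 0 sentinel = overall
    sel <- if (g == 0L) seq_along(lens) else which(bin == g)
    if (!length(sel)) next
    row <- data.frame(group = if (g == 0L) "Overall" else labels[g],
                      count = length(sel))
    for (ang in ANGLE_TYPES) {
      aes <- unlist(lapply(sel, function(i)
        paired_ae(pred_list[[i]], actual_list[[i]], ang)$ae))
      row[[paste0("mae_", ang)]] <- if (length(aes)) mean(aes) else NA_real_
    }
    rows[[length(rows) + 1L]] <- row
  }
  do.call(rbind, rows)
}

#' Full evaluation report
#'
#' Computes, over a set of proteins: per-angle overall MAE and Spearman
#' rank correlation; per-(actual 3-state class, angle) MAE; per-angle
#' threshold-coverage curves at 6 and 12 degrees; and the per-length-group
#' MAE table.
#'
#' @param pred_list named list of predicted `angle_table`s.
#' @param actual_list aligned list of actual `angle_table`s.
#' @param ss3_actual optional list of per-residue actual 3-state labels
#'   (character vectors aligned with the tables); enables the class
#'   stratification.
#' @return object of class `eval_report`: list of data frames `overall`,
#'   `by_class` (or NULL), `coverage`, `length_groups`.
#' @export
evaluate_predictions <- function(pred_list, actual_list, ss3_actual = NULL) {
  stopifnot(length(pred_list) == length(actual_list))
  overall <- list()
  by_class <- list()
  coverage <- list()
  for (ang in ANGLE_TYPES) {
    ps <- unlist(lapply(seq_along(pred_list), function(i) {
      k <- paired_ae(pred_list[[i]], actual_list[[i]], ang)$keep
      pred_list[[i]][[ang]][k]
    }))
    as_ <- unlist(lapply(seq_along(pred_list), function(i) {
      k <- paired_ae(pred_list[[i]], actual_list[[i]], ang)$keep
      actual_list[[i]][[ang]][k]
    }))
    overall[[ang]] <- data.frame(
      angle = ang, count = length(ps),
      mae = if (length(ps)) mean(absolute_error(ps, as_)) else NA_real_,
      spearman = if (length(ps) >= 2L) spearman_rho(ps, as_) else NA_real_)
    per_prot <- lapply(seq_along(pred_list), function(i)
      paired_ae(pred_list[[i]], actual_list[[i]], ang)$ae)
    cov <- threshold_coverage(per_prot)
    cov$angle <- ang
    coverage[[ang]] <- cov
    if (!is.null(ss3_actual)) {
      for (cl in SS3_CLASSES) {
        res <- lapply(seq_along(pred_list), function(i)
          mae_angle(pred_list[[i]], actual_list[[i]], ang,
                    stratum = ss3_actual[[i]] == cl))
        cnt <- sum(vapply(res, `[[`, 0L, "count"))
        m <- if (cnt > 0L)
          sum(vapply(res, function(r)
            if (r$count) r$mae * r$count else 0, 0)) / cnt else NA_real_
        by_class[[paste(cl, ang)]] <- data.frame(
          class = cl, angle = ang, count = cnt, mae = m)
      }
    }
  }
  structure(list(overall = do.call(rbind, overall),
                 by_class = if (length(by_class)) do.call(rbind, by_class) else NULL,
                 coverage = do.call(rbind, coverage),
                 length_groups = length_group_report(pred_list, actual_list)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Overall per-angle performance:\n")
  print(x$overall, row.names = FALSE, digits = 4)
  if (!is.null(x$by_class)) {
    cat("\nMAE by actual 3-state class:\n")
    print(x$by_class, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Write an evaluation report as TSV tables
#'
#' Emits `overall.tsv`, `by_class.tsv` (when stratified), `coverage.tsv`
#' and `length_groups.tsv` under a directory.
#'
#' @param report an `eval_report`.
#' @param dir output directory (created if missing).
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(report$overall, "overall.tsv")
  if (!is.null(report$by_class)) wt(report$by_class, "by_class.tsv")
  wt(report$coverage, "coverage.tsv")
  wt(report$length_groups, "length_groups.tsv")
  invisible(dir)
}
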