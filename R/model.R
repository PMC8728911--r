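# Per-(class, angle) model bundle: training, routed inference, persistence.

ANGLE_TYPES <- c("phi", "psi", "theta", "tau")

#' Default per-(class, angle) feature settings
#'
#' The shipped assignment of feature settings to the twelve
#' (3-state class, angle) model slots: helix uses `YYR9` for all four
#' angles; sheet uses `YYR9` for phi, theta and tau and `YYZ9` for psi;
#' coil uses `YYR5` for phi and theta and `YYR9` for psi and tau.
#'
#' @return data frame with columns `class`, `angle`, `setting`.
#' @export
default_settings <- function() {
  data.frame(
    class = rep(SS3_CLASSES, each = 4L),
    angle = rep(ANGLE_TYPES, times = 3L),
    setting = c("YYR9", "YYR9", "YYR9", "YYR9",
                "YYR9", "YYZ9", "YYR9", "YYR9",
                "YYR5", "YYR9", "YYR5", "YYR9"),
    stringsAsFactors = FALSE)
}

settings_lookup <- function(settings, class, angle) {
  row <- settings$setting[settings$class == class & settings$angle == angle]
  if (length(row) != 1L)
    stop("no setting defined for (", class, ", ", angle, ")")
  row
}

#' Train the full per-class model bundle
#'
#' Trains one regressor per (3-state class, angle type) slot — twelve by
#' default — each on the residues whose *predicted* class matches the slot,
#' encoded under the slot's feature setting and normalized with statistics
#' fitted on that training subset (`normalization = "class"`; use
#' `"global"` to fit on all training residues instead). With
#' `by_class = FALSE` a single pooled model per angle is trained on all
#' residues with the same architecture and schedule, which serves as the
#' equal-capacity baseline that class specialisation is measured against.
#'
#' @param train,validation lists of `bap_protein` objects.
#' @param settings data frame as from [default_settings()]; for pooled
#'   training only the per-angle setting of the `"all"` rows or a single
#'   setting string is needed.
#' @param schedule a [training_schedule()]; each slot trains with a seed
#'   derived deterministically from `schedule$seed`.
#' @param normalization `"class"` or `"global"` scope for the fitted
#'   statistics.
#' @param by_class route residues to class-specific models (TRUE, default)
#'   or train pooled per-angle models (FALSE).
#' @param angles subset of angle types to train; default all four.
#' @param hidden hidden-layer sizes for every model; default the canonical
#'   three layers of 150.
#' @param verbose print one line per trained slot.
#' @return object of class `model_bundle`.
#' @export
train_bundle <- function(train, validation, settings = default_settings(),
                         schedule = training_schedule(),
                         normalization = c("class", "global"),
                         by_class = TRUE, angles = ANGLE_TYPES,
                         hidden = c(150L, 150L, 150L), verbose = FALSE) {
  normalization <- match.arg(normalization)
  if (is.character(settings) && length(settings) == 1L)
    settings <- data.frame(class = rep(if (by_class) SS3_CLASSES else "all",
                                       each = length(ANGLE_TYPES)),
                           angle = rep(ANGLE_TYPES,
                                       times = if (by_class) 3L else 1L),
                           setting = settings, stringsAsFactors = FALSE)
  classes <- if (by_class) SS3_CLASSES else "all"
  used <- unique(settings$setting[settings$class %in% classes &
                                    settings$angle %in% angles])
  enc_train <- lapply(stats::setNames(used, used), encode_proteins,
                      proteins = train)
  enc_val <- lapply(stats::setNames(used, used), encode_proteins,
                    proteins = validation)
  models <- list()
  idx <- 0L
  for (cl in classes) {
    for (ang in angles) {
      idx <- idx + 1L
      sname <- settings_lookup(settings, cl, ang)
      setting <- parse_ahiw(sname)
      ft <- enc_train[[sname]]
      fv <- enc_val[[sname]]
      rows_t <- if (cl == "all") rep(TRUE, nrow(ft$x)) else ft$meta$ss3_pred == cl
      rows_v <- if (cl == "all") rep(TRUE, nrow(fv$x)) else fv$meta$ss3_pred == cl
      if (!any(rows_t))
        stop("train_bundle: empty training class '", cl, "'")
      if (!any(rows_v))
        stop("train_bundle: empty validation class '", cl, "'")
      fit_rows <- if (normalization == "class") rows_t else rep(TRUE, nrow(ft$x))
      stats_cl <- fit_normalization(ft$x[fit_rows, , drop = FALSE],
                                    mode = setting$encoding)
      xt <- apply_normalization(ft$x[rows_t, , drop = FALSE], stats_cl)
      xv <- apply_normalization(fv$x[rows_v, , drop = FALSE], stats_cl)
      yt <- ft$meta[[ang]][rows_t]
      yv <- fv$meta[[ang]][rows_v]
      sched <- schedule
      sched$seed <- (schedule$seed + 101L * idx) %% .Machine$integer.max
      fit <- train_model(xt, yt, xv, yv,
                         config = fcnn_config(ncol(xt), hidden = hidden),
                         schedule = sched)
      if (verbose)
        message(sprintf("  [%s %s %s] epochs=%d best val MAE=%.3f deg",
                        cl, ang, sname, nrow(fit$history), fit$best_loss))
      models[[paste(cl, ang, sep = ".")]] <-
        list(class = cl, angle = ang, setting = setting,
             stats = stats_cl, fit = fit)
    }
  }
  structure(list(models = models, settings = settings, schedule = schedule,
                 normalization = normalization, by_class = by_class),
            class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("model_bundle: %d models (%s)\n", length(x$models),
              if (x$by_class) "class-routed" else "pooled"))
  for (k in names(x$models))
    cat(sprintf("  %-12s %s  best %.3f deg\n", k,
                x$models[[k]]$setting$name, x$models[[k]]$fit$best_loss))
  invisible(x)
}

#' Predict the four backbone angles of a protein
#'
#' Each residue is routed, by its predicted 3-state class, to the bundle's
#' (class, angle) model; raw network outputs are wrapped to (-180, 180] and
#' theta is additionally clamped to \[0, 180\] (theta is a planar, not a
#' periodic, angle). Angles that are undefined at the termini (phi at
#' residue 1, psi at the last residue, theta outside 2..L-1, tau outside
#' 2..L-2) are NA. The returned table carries a `models_used` attribute
#' counting the residues each model slot served, which makes routing
#' auditable.
#'
#' @param bundle a `model_bundle`.
#' @param protein a `bap_protein` (sequence, predicted SS8, feature blocks).
#' @return an `angle_table` of predictions.
#' @export
predict_angles <- function(bundle, protein) {
  stopifnot(inherits(bundle, "model_bundle"))
  n <- nchar(protein$sequence)
  ss3 <- map_ss8_to_ss3(protein$ss8_pred)
  used_settings <- unique(vapply(bundle$models, function(m) m$setting$name, ""))
  enc <- lapply(stats::setNames(used_settings, used_settings),
                encode_proteins, proteins = protein)
  out <- list(phi = rep(NA_real_, n), psi = rep(NA_real_, n),
              theta = rep(NA_real_, n), tau = rep(NA_real_, n))
  used <- integer(0)
  for (key in names(bundle$models)) {
    m <- bundle$models[[key]]
    rows <- if (m$class == "all") seq_len(n) else which(ss3 == m$class)
    if (!length(rows)) next
    x <- apply_normalization(enc[[m$setting$name]]$x[rows, , drop = FALSE],
                             m$stats)
    raw <- predict(m$fit, x)
    pred <- wrap_angle(raw)
    if (m$angle == "theta") pred <- pmin(180, pmax(0, pred))
    out[[m$angle]][rows] <- pred
    used[key] <- length(rows)
  }
  # terminal angles are undefined
  out$phi[1L] <- NA_real_
  out$psi[n] <- NA_real_
  out$theta[c(1L, n)] <- NA_real_
  out$tau[unique(c(1L, n - 1L, n))] <- NA_real_
  res <- angle_table(seq_len(n), strsplit(protein$sequence, "")[[1L]],
                     out$phi, out$psi, out$theta, out$tau)
  attr(res, "models_used") <- used
  res
}

#' Predict angles for a list of proteins
#'
#' @param bundle a `model_bundle`.
#' @param proteins list of `bap_protein` objects.
#' @return named list of `angle_table` predictions.
#' @export
predict_angles_set <- function(bundle, proteins) {
  out <- lapply(proteins, function(p) predict_angles(bundle, p))
  names(out) <- vapply(proteins, function(p) p$id, "")
  out
}

#' Save a model bundle as portable JSON
#'
#' Weights, normalization statistics, settings and schedule are written to
#' one JSON file with full numeric precision, so a reloaded bundle
#' reproduces predictions bit for bit.
#'
#' @param bundle a `model_bundle`.
#' @param path output file.
#' @export
save_bundle <- function(bundle, path) {
  ser <- list(settings = as.list(bundle$settings),
              schedule = unclass(bundle$schedule),
              normalization = bundle$normalization,
              by_class = bundle$by_class,
              models = lapply(bundle$models, function(m) {
                # numeric payloads as %.17g strings: doubles survive the
                # text round-trip exactly
                st <- unclass(m$stats)
                for (f in setdiff(names(st), c("mode", "ncol")))
                  st[[f]] <- sprintf("%.17g", st[[f]])
                list(class = m$class, angle = m$angle,
                     setting = m$setting$name,
                     stats = st,
                     config = unclass(m$fit$config),
                     history = as.list(m$fit$history),
                     best_loss = m$fit$best_loss,
                     W = lapply(m$fit$par$W, function(w)
                       list(dim = dim(w),
                            data = sprintf("%.17g", as.numeric(w)))),
                     b = lapply(m$fit$par$b, function(v)
                       sprintf("%.17g", v)))
              }))
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a model bundle saved by [save_bundle()]
#'
#' @param path JSON file.
#' @return a `model_bundle`.
#' @export
load_bundle <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  sched <- do.call(training_schedule, ser$schedule[
    setdiff(names(ser$schedule), character(0))])
  models <- lapply(ser$models, function(m) {
    st <- m$stats
    stats_obj <- structure(
      c(list(mode = st$mode, ncol = as.integer(st$ncol)),
        lapply(st[setdiff(names(st), c("mode", "ncol"))], as.numeric)),
      class = "norm_stats")
    cfg <- fcnn_config(as.integer(m$config$input_width),
                       as.integer(m$config$hidden))
    par <- list(W = lapply(m$W, function(w) {
      d <- as.integer(unlist(w$dim))
      matrix(as.numeric(unlist(w$data)), d[1L], d[2L])
    }),
                b = lapply(m$b, function(v) as.numeric(unlist(v))))
    fit <- structure(list(par = par, history = as.data.frame(m$history),
                          config = cfg, schedule = sched,
                          best_loss = m$best_loss),
                     class = "fcnn_fit")
    list(class = m$class, angle = m$angle, setting = parse_ahiw(m$setting),
         stats = stats_obj, fit = fit)
  })
  structure(list(models = models, settings = as.data.frame(ser$settings),
                 schedule = sched, normalization = ser$normalization,
                 by_class = ser$by_class),
            class = "model_bundle")
}
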