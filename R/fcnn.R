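# Fully-connected regressor for one (class, angle) pair: 3 hidden layers of
# 150 sigmoid units, a single linear output emitting the angle in degrees,
# trained by minibatch SGD with momentum on the periodic mean absolute
# error.

#' Network architecture configuration
#'
#' @param input_width number of input features (per-residue width times
#'   window size).
#' @param hidden integer vector of hidden-layer sizes; the canonical
#'   architecture is three layers of 150.
#' @return object of class `fcnn_config`.
#' @export
fcnn_config <- function(input_width, hidden = c(150L, 150L, 150L)) {
  stopifnot(input_width >= 1L, all(hidden >= 1L))
  structure(list(input_width = as.integer(input_width),
                 hidden = as.integer(hidden),
                 output_width = 1L),
            class = "fcnn_config")
}

#' Training schedule
#'
#' Minibatch stochastic gradient descent with momentum 0.9 and initial
#' learning rate 0.01. After `patience` (3) consecutive epochs without
#' improvement of the monitored loss, the learning rate is halved; training
#' stops when the rate falls below `lr_floor` (1e-15) or `max_epochs` is
#' reached. Weights are initialised with scaled-uniform (Glorot) draws.
#'
#' @param lr_initial initial learning rate.
#' @param lr_factor multiplicative decay factor.
#' @param patience consecutive non-improving epochs before a decay step.
#' @param lr_floor training stops once the rate would fall below this.
#' @param momentum classical momentum coefficient.
#' @param batch_size minibatch size.
#' @param max_epochs epoch budget.
#' @param monitor `"val"` (default) or `"train"`: which loss drives the
#'   schedule.
#' @param seed integer seed controlling initialisation and shuffling.
#' @return object of class `training_schedule`.
#' @export
training_schedule <- function(lr_initial = 0.01, lr_factor = 0.5,
                              patience = 3L, lr_floor = 1e-15,
                              momentum = 0.9, batch_size = 64L,
                              max_epochs = 300L,
                              monitor = c("val", "train"), seed = 1L) {
  monitor <- match.arg(monitor)
  stopifnot(lr_initial > 0, lr_factor > 0, lr_factor < 1,
            patience >= 1L, lr_floor > 0, momentum >= 0, momentum < 1,
            batch_size >= 1L, max_epochs >= 1L)
  structure(list(lr_initial = lr_initial, lr_factor = lr_factor,
                 patience = as.integer(patience), lr_floor = lr_floor,
                 momentum = momentum, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), monitor = monitor,
                 seed = as.integer(seed)),
            class = "training_schedule")
}

glorot_uniform <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

fcnn_init <- function(config) {
  sizes <- c(config$input_width, config$hidden, config$output_width)
  L <- length(sizes) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- glorot_uniform(sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  list(W = W, b = b)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

fcnn_forward <- function(par, x, keep_activations = FALSE) {
  L <- length(par$W)
  act <- if (keep_activations) vector("list", L) else NULL
  a <- x
  for (l in seq_len(L - 1L)) {
    a <- sigmoid(sweep(a %*% par$W[[l]], 2L, par$b[[l]], "+"))
    if (keep_activations) act[[l]] <- a
  }
  out <- sweep(a %*% par$W[[L]], 2L, par$b[[L]], "+")
  if (keep_activations) list(out = out, act = act) else out
}

#' Periodic mean absolute error loss
#'
#' Mean over defined entries of `AE = min(D, |360 - D|)` with
#' `D = |predicted - actual|` — the absolute angular separation on the
#' circle. Entries flagged undefined (terminal angles) are excluded.
#'
#' @param predicted,actual numeric vectors of angles in degrees.
#' @param defined logical vector; NA targets are additionally excluded.
#' @return non-negative scalar in \[0, 180\].
#' @examples
#' periodic_mae_loss(179, -179)  # 2
#' @export
periodic_mae_loss <- function(predicted, actual,
                              defined = rep(TRUE, length(actual))) {
  stopifnot(length(predicted) == length(actual),
            length(defined) == length(actual))
  keep <- defined & !is.na(actual) & !is.na(predicted)
  if (!any(keep)) stop("periodic_mae_loss: no defined entries")
  mean(absolute_error(predicted[keep], actual[keep]))
}

# subgradient of the periodic absolute error with respect to the
# prediction: sign of the residual wrapped to (-180, 180]
periodic_ae_grad <- function(predicted, actual) {
  sign(wrap_angle(predicted - actual))
}

#' Train one fully-connected angle regressor
#'
#' Runs the minibatch SGD-with-momentum loop under the step-halving
#' learning-rate schedule, monitoring the validation periodic MAE (by
#' default). The returned model carries the weights of the best monitored
#' epoch and a per-epoch history of train loss, validation loss and
#' learning rate. With a fixed schedule seed the history is reproducible
#' bit for bit.
#'
#' @param x_train,y_train training features (matrix) and angle targets
#'   (degrees); rows with NA targets are dropped.
#' @param x_val,y_val validation features and targets.
#' @param config an [fcnn_config()]; defaults to the canonical 3 x 150
#'   architecture for `ncol(x_train)` inputs.
#' @param schedule a [training_schedule()].
#' @return object of class `fcnn_fit` with elements `par` (best weights),
#'   `history` (data frame: epoch, train_loss, val_loss, lr), `config`,
#'   `schedule`.
#' @export
train_model <- function(x_train, y_train, x_val, y_val,
                        config = fcnn_config(ncol(x_train)),
                        schedule = training_schedule()) {
  stopifnot(is.matrix(x_train), is.matrix(x_val),
            ncol(x_train) == ncol(x_val),
            ncol(x_train) == config$input_width)
  keep <- !is.na(y_train)
  x_train <- x_train[keep, , drop = FALSE]
  y_train <- y_train[keep]
  keepv <- !is.na(y_val)
  x_val <- x_val[keepv, , drop = FALSE]
  y_val <- y_val[keepv]
  if (nrow(x_train) == 0L)
    stop("train_model: empty training subset")
  if (nrow(x_val) == 0L)
    stop("train_model: empty validation subset")

  # all RNG happens here: initial weights, then one shuffle per epoch
  set.seed(schedule$seed)
  par <- fcnn_init(config)
  n <- nrow(x_train)
  orders <- matrix(0L, n, schedule$max_epochs)
  for (ep in seq_len(schedule$max_epochs)) orders[, ep] <- sample.int(n)

  res <- .cpp_fcnn_train(x_train, y_train, x_val, y_val,
                         par$W, par$b, orders,
                         as.integer(schedule$batch_size),
                         schedule$lr_initial, schedule$lr_factor,
                         as.integer(schedule$patience), schedule$lr_floor,
                         schedule$momentum,
                         as.integer(schedule$max_epochs),
                         schedule$monitor == "val")
  history <- data.frame(epoch = seq_along(res$train_loss),
                        train_loss = res$train_loss,
                        val_loss = res$val_loss, lr = res$lr)
  best_par <- list(W = res$W, b = res$b)
  structure(list(par = best_par, history = history, config = config,
                 schedule = schedule, best_loss = res$best),
            class = "fcnn_fit")
}

#' @export
print.fcnn_fit <- function(x, ...) {
  cat(sprintf("fcnn_fit: %d-%s-1, %d epochs, best monitored loss %.4f deg\n",
              x$config$input_width,
              paste(x$config$hidden, collapse = "-"),
              nrow(x$history), x$best_loss))
  invisible(x)
}

#' Predict with a trained regressor
#'
#' @param object an `fcnn_fit`.
#' @param newdata feature matrix with the fitted input width.
#' @param ... unused.
#' @return numeric vector of raw (unwrapped) angle outputs in degrees.
#' @export
predict.fcnn_fit <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  if (ncol(newdata) != object$config$input_width)
    stop("predict.fcnn_fit: feature width ", ncol(newdata),
         " does not match model input width ", object$config$input_width)
  fcnn_forward(object$par, newdata)[, 1L]
}
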