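#' Focal-loss parameters
#'
#' The focal loss down-weights well-classified (overwhelmingly background)
#' examples by the modulating factor `(1 - p_t)^gamma`, concentrating the
#' training signal on hard, minority examples such as the relatively small
#' pneumonia-consistent regions in a chest X-ray. `gamma = 2` is the value
#' found to give the best detection performance in this setting; at
#' `gamma = 0` the loss reduces exactly to cross-entropy. `alpha_t` is the
#' conventional class-balancing weight; 0.25 is the usual companion of
#' `gamma = 2` in dense detection, but no single value is canonical and it
#' is fully exposed.
#'
#' @param gamma Focusing exponent, `>= 0`; default 2.
#' @param alpha_t Class weight in `[0, 1]`; default 0.25.
#' @return A list of class `"focal_params"`.
#' @export
focal_params <- function(gamma = 2, alpha_t = 0.25) {
  if (!is.finite(gamma) || gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  if (!is.finite(alpha_t) || alpha_t < 0 || alpha_t > 1) {
    stop("alpha_t must lie in [0, 1]", call. = FALSE)
  }
  structure(list(gamma = gamma, alpha_t = alpha_t), class = "focal_params")
}

#' Tversky / focal-Tversky parameters
#'
#' The Tversky index generalizes the Dice overlap by weighting false
#' positives by `alpha` and false negatives by `beta`; pushing `beta` above
#' `alpha` emphasizes recall, which matters when the positive (lesion)
#' pixels are a small minority. The focal Tversky loss raises `1 - TI` to
#' the exponent `gamma_ft` to keep gradient flowing on hard examples.
#' Defaults are the empirically fixed values `alpha = 0.7`, `beta = 0.75`,
#' `gamma_ft = 4/3`; `epsilon` only guards the ratio against 0/0.
#'
#' @param alpha False-positive weight, `>= 0`.
#' @param beta False-negative weight, `>= 0`.
#' @param gamma_ft Focal exponent, `> 0`.
#' @param epsilon Stability constant, `> 0`.
#' @return A list of class `"tversky_params"`.
#' @export
tversky_params <- function(alpha = 0.7, beta = 0.75, gamma_ft = 4 / 3,
                           epsilon = 1e-7) {
  if (alpha < 0 || beta < 0) stop("alpha and beta must be >= 0", call. = FALSE)
  if (gamma_ft <= 0) stop("gamma_ft must be > 0", call. = FALSE)
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, gamma_ft = gamma_ft,
                 epsilon = epsilon), class = "tversky_params")
}

LOG_EPS <- 1e-12

reduce_loss <- function(x, reduction) {
  switch(reduction, mean = mean(x), sum = sum(x), none = x)
}

#' Categorical cross-entropy loss
#'
#' `-sum(y * log(y_hat))` over the classes, natural logarithm, for a
#' one-hot target `y` and a predicted probability vector `y_hat` summing to
#' one. Predicted probabilities are clamped below at `1e-12` so a zero
#' probability on the true class yields a large finite loss rather than
#' `Inf`.
#'
#' @param y One-hot target vector.
#' @param y_hat Predicted probability vector of the same length.
#' @return Non-negative scalar.
#' @examples
#' cce_loss(c(0, 1, 0), c(0.2, 0.7, 0.1)) # -log(0.7)
#' @export
cce_loss <- function(y, y_hat) {
  if (length(y) != length(y_hat)) {
    stop("y and y_hat must have the same length", call. = FALSE)
  }
  if (!all(y %in% c(0, 1)) || sum(y) != 1) {
    stop("y must be one-hot", call. = FALSE)
  }
  if (abs(sum(y_hat) - 1) > 1e-6) {
    stop("y_hat must sum to 1", call. = FALSE)
  }
  -sum(y * log(pmax(y_hat, LOG_EPS)))
}

#' Focal loss
#'
#' `-alpha_t * (1 - p_t)^gamma * log(p_t)` for the probability `p_t` the
#' model assigns to the true class, vectorized over `p_t`. With
#' `gamma = 0` and `alpha_t = 1` this is exactly the cross-entropy of the
#' true class. A `p_t` of zero is clamped to `1e-12` with a warning.
#'
#' @param p_t Probabilities in `(0, 1]` (zero is clamped).
#' @param params A [focal_params()].
#' @param reduction `"mean"` (default), `"sum"` or `"none"`.
#' @return Non-negative scalar (or vector for `reduction = "none"`).
#' @examples
#' focal_loss(0.9, focal_params(gamma = 2, alpha_t = 0.25))
#' @export
focal_loss <- function(p_t, params = focal_params(),
                       reduction = c("mean", "sum", "none")) {
  reduction <- match.arg(reduction)
  stopifnot(inherits(params, "focal_params"))
  if (any(!is.finite(p_t)) || any(p_t < 0) || any(p_t > 1)) {
    stop("p_t must lie in [0, 1]", call. = FALSE)
  }
  if (any(p_t == 0)) {
    warning("p_t of 0 clamped to ", LOG_EPS, call. = FALSE)
    p_t <- pmax(p_t, LOG_EPS)
  }
  loss <- -params$alpha_t * (1 - p_t)^params$gamma * log(p_t)
  reduce_loss(loss, reduction)
}

#' Tversky index of a pixel labeling
#'
#' For per-pixel ground-truth indicators `g` (0/1) and predicted
#' probabilities `t`, with `t_hat = 1 - t` and `g_hat = 1 - g`:
#' `TI = (sum(t g) + eps) / (sum(t g) + alpha sum(t_hat g) +
#' beta sum(t g_hat) + eps)`. Equals 1 for a perfect labeling, and for the
#' all-empty labeling (the epsilon guard).
#'
#' @param g Ground-truth indicator vector (values 0/1).
#' @param t Predicted probability vector in `[0, 1]`, same length.
#' @param params A [tversky_params()].
#' @return Scalar in `(0, 1]`.
#' @export
tversky_index <- function(g, t, params = tversky_params()) {
  stopifnot(inherits(params, "tversky_params"))
  if (length(g) == 0) stop("empty labeling", call. = FALSE)
  if (length(g) != length(t)) {
    stop("g and t must have the same length", call. = FALSE)
  }
  if (!all(g %in% c(0, 1))) stop("g must be 0/1", call. = FALSE)
  if (any(t < 0) || any(t > 1)) stop("t must lie in [0, 1]", call. = FALSE)
  num <- sum(t * g) + params$epsilon
  den <- sum(t * g) + params$alpha * sum((1 - t) * g) +
    params$beta * sum(t * (1 - g)) + params$epsilon
  num / den
}

#' Focal Tversky loss
#'
#' `(1 - TI)^gamma_ft` for the single-class Tversky index of the labeling
#' (summation over classes is trivial here: the detection task has one
#' foreground class). Zero, up to the epsilon guard, when `t` equals `g`.
#'
#' @inheritParams tversky_index
#' @return Non-negative scalar.
#' @examples
#' focal_tversky_loss(c(1, 0), c(0.8, 0.3))
#' @export
focal_tversky_loss <- function(g, t, params = tversky_params()) {
  ti <- tversky_index(g, t, params)
  (1 - ti)^params$gamma_ft
}

#' Smooth-L1 loss
#'
#' The bounding-box regression loss: quadratic near zero, linear in the
#' tails — `0.5 x^2 / delta` scaled form is not used; with the standard
#' `delta = 1` transition the loss is `0.5 x^2` for `|x| < delta` and
#' `|x| - 0.5 delta` otherwise, elementwise over the coordinate residuals.
#'
#' @param residual Finite numeric vector of coordinate residuals.
#' @param delta Quadratic-to-linear transition point; default 1.
#' @param reduction `"sum"` (default, the box-regression convention),
#'   `"mean"` or `"none"`.
#' @return Non-negative scalar (or vector for `reduction = "none"`).
#' @export
smooth_l1 <- function(residual, delta = 1,
                      reduction = c("sum", "mean", "none")) {
  reduction <- match.arg(reduction)
  if (any(!is.finite(residual))) stop("residual must be finite", call. = FALSE)
  a <- abs(residual)
  loss <- ifelse(a < delta, 0.5 * residual^2, a - 0.5 * delta)
  reduce_loss(loss, reduction)
}
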