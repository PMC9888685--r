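#' Kaplan-Meier (Stute) weights
#'
#' Jump weights of the Kaplan-Meier estimator of the event-time distribution,
#' attached to the observations so that weighted least squares consistently
#' estimates a regression of the log time under random right censoring.
#' With observations ordered by increasing `y` (events before censorings at
#' tied values), the weights are
#' `d_(1) = delta_(1)/n` and
#' `d_(i) = delta_(i)/(n-i+1) * prod_{j<i} ((n-j)/(n-j+1))^delta_(j)`.
#' Censored observations receive weight zero; the weights sum to 1 exactly
#' when the largest ordered observation is an event, and to less than 1
#' otherwise.
#'
#' @param y numeric vector of observed (log) times.
#' @param delta 0/1 event indicators, same length.
#' @return list with `d` (weights aligned to the input order) and `order`
#'   (the permutation sorting `y` ascending, events first at ties).
#' @examples
#' stute_weights(c(1, 2, 3), c(0, 1, 1))$d  # 0, 1/2, 1/2
#' @export
stute_weights <- function(y, delta) {
  n <- length(y)
  if (n == 0L) stop("empty input")
  if (length(delta) != n) stop("y and delta lengths differ")
  if (!all(delta %in% c(0, 1))) stop("delta must be 0/1")
  ord <- order(y, -delta)
  ds <- delta[ord]
  d <- numeric(n)
  prod <- 1
  for (i in seq_len(n)) {
    if (ds[i] == 1) {
      d[i] <- prod / (n - i + 1)
      prod <- prod * (n - i) / (n - i + 1)
    }
  }
  out <- numeric(n)
  out[ord] <- d
  list(d = out, order = ord)
}

#' Fit a node model by Stute-weighted least squares
#'
#' Estimates the within-node regression of log survival time on the focus
#' variable (and, for HPRISM, the focus-by-contextual interaction):
#' minimises `sum_i d_i (y_i - theta0 - theta1 x_i [- theta2 x_i w_i])^2`
#' with `d` the node's own Kaplan-Meier weights.
#'
#' When `w` is supplied but does not vary among positively weighted `x = 1`
#' rows, the interaction column is collinear and is dropped: `theta2` is
#' returned as 0 with `used_w = FALSE` (downstream disparity estimates then
#' treat theta2 as 0).
#'
#' @param y log observed times.
#' @param delta 0/1 event indicators.
#' @param x binary focus values.
#' @param w contextual values per record, or `NULL` for the PRISM model.
#' @param weights optionally a precomputed [stute_weights()] result.
#' @return list of class `"prism_node_model"`: `theta0`, `theta1`, `theta2`,
#'   `used_w`, `rss` (weighted residual sum of squares), `n`, `n_events`,
#'   `mean_log_surv`.
#' @export
fit_node_model <- function(y, delta, x, w = NULL, weights = NULL) {
  n <- length(y)
  stopifnot(length(delta) == n, length(x) == n)
  if (!is.null(w)) stopifnot(length(w) == n)
  sw <- weights %||% stute_weights(y, delta)
  d <- sw$d
  pos <- d > 0
  if (!any(pos)) stop("no events: node model unfittable")
  use_w <- !is.null(w)
  if (use_w) {
    w1 <- w[pos & x == 1]
    if (length(w1) == 0L || diff(range(w1)) <= 1e-10 * (1 + max(abs(w1))))
      use_w <- FALSE
  }
  X <- if (use_w) cbind(1, x, x * w) else cbind(1, x)
  fit <- lm.wfit(X[pos, , drop = FALSE], y[pos], d[pos])
  if (fit$rank < ncol(X)) {
    bad <- colnames(X)[is.na(fit$coefficients)] %||% "focus"
    stop("rank-deficient node design (degenerate column: ",
         paste(which(is.na(fit$coefficients)), collapse = ","), ")")
  }
  th <- fit$coefficients
  theta0 <- th[1]; theta1 <- th[2]
  theta2 <- if (use_w) th[3] else 0
  res <- y - theta0 - theta1 * x - if (use_w) theta2 * x * w else 0
  structure(list(theta0 = unname(theta0), theta1 = unname(theta1),
                 theta2 = unname(theta2), used_w = use_w,
                 rss = sum(d * res^2), n = n, n_events = sum(delta == 1),
                 mean_log_surv = sum(d * y) / sum(d)),
            class = "prism_node_model")
}

#' Impute censored residuals
#'
#' Computes node-model residuals
#' `r_i = y_i - theta0 - theta1 x_i - theta2 x_i w_i` and replaces each
#' censored residual by an estimate of `E(e | e > r_i)`: the mean of the
#' uncensored residuals strictly greater than `r_i`.  When no uncensored
#' residual exceeds `r_i` the raw value is kept (conservative fallback).
#' Event residuals are returned unchanged.
#'
#' @param model a [fit_node_model()] result.
#' @param y,delta,x observed log times, indicators, focus values.
#' @param w contextual values (ignored unless the model used them).
#' @return list with `r` (raw residuals), `r_hat` (imputed) and `delta`.
#' @export
impute_residuals <- function(model, y, delta, x, w = NULL) {
  res <- y - model$theta0 - model$theta1 * x -
    if (model$used_w) model$theta2 * x * w else 0
  u <- sort(res[delta == 1])
  m <- length(u)
  cs <- rev(cumsum(rev(u)))  # suffix sums
  r_hat <- res
  cens <- which(delta == 0)
  for (i in cens) {
    k <- findInterval(res[i], u) + 1L  # first index with u[k] > res[i]
    while (k <= m && u[k] <= res[i]) k <- k + 1L
    if (k <= m) r_hat[i] <- cs[k] / (m - k + 1L)
  }
  list(r = res, r_hat = r_hat, delta = delta)
}
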