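# Independent oracles used across the suite.  These deliberately avoid the
# package's computational path: Kaplan-Meier jumps come from survival::survfit,
# split search is exhaustive enumeration over R-level model fits, concordance
# is a literal double loop, and the multinomial log odds ratios are closed
# form.

# Kaplan-Meier jump size at each event time, from survfit.
km_jump_oracle <- function(y, delta) {
  sf <- survival::survfit(survival::Surv(y, delta) ~ 1)
  surv_before <- c(1, head(sf$surv, -1))
  jumps <- surv_before - sf$surv
  data.frame(time = sf$time, jump = jumps)[jumps > 0 & sf$n.event > 0, ]
}

# Random survival instance on the log scale.
random_instance <- function(n, censor = 0.3) {
  y <- round(rnorm(n, 1, 1), 2)  # rounding creates ties
  delta <- rbinom(n, 1, 1 - censor)
  if (sum(delta) == 0) delta[sample(n, 1)] <- 1L
  list(y = y, delta = delta)
}

# Weighted-normal-equations solution for the node model.
wls_oracle <- function(y, delta, x, w = NULL) {
  d <- stute_weights(y, delta)$d
  X <- if (is.null(w)) cbind(1, x) else cbind(1, x, x * w)
  A <- t(X) %*% (d * X)
  b <- t(X) %*% (d * y)
  as.vector(solve(A, b))
}

# R-level evaluation of one binary partition with the same admissibility
# rules as the engine; returns the daughters' imputed RSS sum or NA.
bf_eval_partition <- function(ds, left, contextual = NULL,
                              min_node = 20, min_events_per_group = 1) {
  w <- if (!is.null(contextual)) ds$W[[contextual]] else NULL
  req2 <- !is.null(contextual)
  side <- function(sel) {
    if (sum(sel) < min_node) return(NA_real_)
    for (g in 0:1) {
      ev <- sel & ds$delta == 1 & ds$x == g
      if (sum(ev) < min_events_per_group) return(NA_real_)
      if (req2 && length(unique(ds$tract[ev])) < 2) return(NA_real_)
    }
    fit <- tryCatch(
      fit_node_model(ds$y[sel], ds$delta[sel], ds$x[sel],
                     if (is.null(w)) NULL else w[sel]),
      error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    ir <- impute_residuals(fit, ds$y[sel], ds$delta[sel], ds$x[sel],
                           if (is.null(w)) NULL else w[sel])
    sum(ir$r_hat^2)
  }
  a <- side(left); b <- side(!left)
  if (is.na(a) || is.na(b)) NA_real_ else a + b
}

# Exhaustive best split over midpoint candidates of numeric covariates
# (sufficient for the oracle instances, which use numeric z only).
bf_best_split <- function(ds, contextual = NULL,
                          min_node = 20, min_events_per_group = 1) {
  w <- if (!is.null(contextual)) ds$W[[contextual]] else NULL
  parent <- fit_node_model(ds$y, ds$delta, ds$x, w)
  parent_irss <- sum(impute_residuals(parent, ds$y, ds$delta, ds$x, w)$r_hat^2)
  best <- NULL
  for (v in names(ds$Z)) {
    zv <- ds$Z[[v]]
    uv <- sort(unique(zv))
    if (length(uv) < 2) next
    for (s in (uv[-1] + uv[-length(uv)]) / 2) {
      tot <- bf_eval_partition(ds, zv < s, contextual,
                               min_node, min_events_per_group)
      if (is.na(tot)) next
      drss <- parent_irss - tot
      if (is.null(best) || drss > best$delta_rss)
        best <- list(variable = v, s = s, delta_rss = drss)
    }
  }
  best
}

# Recursive brute-force grower mirroring the Cp acceptance rule.
bf_grow_splits <- function(ds, contextual = NULL, cp = 0.01,
                           min_node = 20, min_events_per_group = 1) {
  w <- if (!is.null(contextual)) ds$W[[contextual]] else NULL
  root <- fit_node_model(ds$y, ds$delta, ds$x, w)
  root_irss <- sum(impute_residuals(root, ds$y, ds$delta, ds$x, w)$r_hat^2)
  out <- list()
  rec <- function(idx) {
    if (length(idx) < 2 * min_node) return(invisible())
    sub <- prismsurv:::prism_data_subset(ds, idx)
    rule <- bf_best_split(sub, contextual, min_node, min_events_per_group)
    if (is.null(rule) || rule$delta_rss < cp * root_irss) return(invisible())
    out[[length(out) + 1]] <<- rule[c("variable", "s")]
    left <- idx[sub$Z[[rule$variable]] < rule$s]
    rec(left)
    rec(setdiff(idx, left))
    invisible()
  }
  rec(seq_len(ds$n))
  out
}

# Literal double-loop concordance.
harrell_oracle <- function(pred, y, delta) {
  num <- 0; den <- 0
  n <- length(y)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- i; b <- j
    usable <- FALSE
    if (y[a] != y[b]) {
      if (y[b] < y[a]) { a <- j; b <- i }
      usable <- delta[a] == 1          # shorter time is an event
    } else if (delta[i] + delta[j] == 1) {
      if (delta[j] == 1) { a <- j; b <- i }
      usable <- TRUE                    # tie: the event member died first
    }
    if (!usable) next
    den <- den + 1
    if (pred[a] < pred[b]) num <- num + 1
    else if (pred[a] == pred[b]) num <- num + 0.5
  }
  num / den
}

# Saturated-model multinomial log odds ratios.
mlogit_oracle <- function(counts, ref = 1) {
  K <- ncol(counts)
  ks <- setdiff(seq_len(K), ref)
  out <- log((counts[2, ks] / counts[2, ref]) / (counts[1, ks] / counts[1, ref]))
  names(out) <- colnames(counts)[ks]
  out
}

# Small helper: write a prism_data-ready CSV and its schema.
demo_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}
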