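#' Local variable importance by permutation with full tree rebuild
#'
#' For each terminal node and each individual-level covariate: permute
#' ("noise up") that covariate's column across the whole dataset, rebuild the
#' entire tree with the identical configuration, send the node's original
#' member records down the rebuilt tree, and compare their Stute-weighted
#' squared prediction error with the error under the original tree.  The
#' importance value is `mean(noised error) - original error`, averaged over
#' `n_perm` permutation replicates; values at or below zero indicate a
#' variable that is not important for that node.
#'
#' Prediction error for a member set is the weighted mean squared error of
#' predicted vs observed log time, with weights the node members' own
#' Kaplan-Meier weights.  Ranks are assigned within each node, descending by
#' value, ties sharing the minimum rank (set `rank_abs = TRUE` to rank by
#' absolute value instead).
#'
#' @param tree a fitted [prism()] tree.
#' @param data training data (defaults to the data stored in the tree).
#' @param n_perm permutation replicates per variable (default 10; 1
#'   reproduces the single-pass procedure).
#' @param seed integer seed for the permutation stream.
#' @param variables covariates to score (default: all individual-level).
#' @param nodes terminal-node ids to score (default: all).
#' @param rank_abs rank by absolute value instead of signed value.
#' @return An object of class `"lvimp"`: list with `values` and `ranks`
#'   (node x variable matrices), `n_perm`, `seed`.
#' @export
lvimp <- function(tree, data = NULL, n_perm = 10, seed = 1,
                  variables = NULL, nodes = NULL, rank_abs = FALSE) {
  stopifnot(inherits(tree, "prism"), n_perm >= 1)
  data <- data %||% tree$data
  variables <- variables %||% names(data$Z)
  nodes <- nodes %||% terminal_nodes(tree)
  bad <- setdiff(nodes, terminal_nodes(tree))
  if (length(bad)) stop("not terminal node(s): ", paste(bad, collapse = ", "))

  cfg <- tree$config
  refit <- function(ds) prism(ds, contextual = cfg$contextual,
                              criterion = cfg$criterion, cp = cfg$cp,
                              min_node = cfg$min_node,
                              min_events_per_group = cfg$min_events_per_group,
                              max_depth = cfg$max_depth,
                              daughter_residuals = cfg$daughter_residuals)

  # node-specific weights and baseline error
  wts <- lapply(nodes, function(id) {
    m <- tree$nodes[[id]]$members
    d <- stute_weights(data$y[m], data$delta[m])$d
    d / sum(d)
  })
  names(wts) <- as.character(nodes)
  err_for <- function(pred, id) {
    m <- tree$nodes[[id]]$members
    sum(wts[[as.character(id)]] * (data$y[m] - pred[m])^2)
  }
  base_pred <- predict(tree, data)
  base_err <- vapply(nodes, function(id) err_for(base_pred, id), numeric(1))

  vals <- matrix(0, nrow = length(nodes), ncol = length(variables),
                 dimnames = list(as.character(nodes), variables))
  with_seed(seed, {
    for (vi in seq_along(variables)) {
      v <- variables[[vi]]
      acc <- numeric(length(nodes))
      for (p in seq_len(n_perm)) {
        noised <- data
        noised$Z[[v]] <- data$Z[[v]][sample.int(data$n)]
        rebuilt <- refit(noised)
        pred <- predict(rebuilt, noised)
        acc <- acc + vapply(nodes, function(id) err_for(pred, id), numeric(1))
      }
      vals[, vi] <- acc / n_perm - base_err
    }
  })
  key <- if (rank_abs) -abs(vals) else -vals
  ranks <- t(apply(key, 1, rank, ties.method = "min"))
  dimnames(ranks) <- dimnames(vals)
  structure(list(values = vals, ranks = ranks, n_perm = n_perm, seed = seed,
                 rank_abs = rank_abs),
            class = "lvimp")
}

#' @export
print.lvimp <- function(x, digits = 4, ...) {
  cat("Local variable importance (", x$n_perm, " permutation replicate(s))\n",
      sep = "")
  disp <- matrix(sprintf("%.*f (%d)", digits, t(x$values), t(x$ranks)),
                 nrow = ncol(x$values),
                 dimnames = list(colnames(x$values),
                                 paste0("node ", rownames(x$values))))
  print(disp, quote = FALSE)
  invisible(x)
}

#' Andrews curves
#'
#' Embeds each row of `x` into the finite Fourier series
#' `f(t) = c1/sqrt(2) + c2 sin(t) + c3 cos(t) + c4 sin(2t) + c5 cos(2t) + ...`
#' evaluated on a grid over `[-pi, pi]`, the classical device for visually
#' comparing multivariate points -- here, per-terminal-node vectors of
#' rank-ordered importance values.
#'
#' @param x numeric vector (one curve) or matrix (one curve per row, e.g.
#'   the `values` of an [lvimp()] object with columns ordered by rank).
#' @param n_grid number of grid points (default 101).
#' @return An object of class `"andrews"`: data frame with columns `curve`,
#'   `t`, `f`.
#' @examples
#' andrews_curves(c(1, 0, 0))$f[1]  # 1/sqrt(2)
#' @export
andrews_curves <- function(x, n_grid = 101) {
  if (inherits(x, "lvimp")) {
    v <- x$values
    x <- t(vapply(seq_len(nrow(v)),
                  function(i) v[i, order(x$ranks[i, ])], numeric(ncol(v))))
    rownames(x) <- rownames(v)
  }
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  stopifnot(ncol(x) >= 1, n_grid >= 2)
  tt <- seq(-pi, pi, length.out = n_grid)
  basis <- matrix(0, nrow = n_grid, ncol = ncol(x))
  basis[, 1] <- 1 / sqrt(2)
  if (ncol(x) > 1) {
    for (j in 2:ncol(x)) {
      k <- (j %/% 2)
      basis[, j] <- if (j %% 2 == 0) sin(k * tt) else cos(k * tt)
    }
  }
  fm <- basis %*% t(x)
  nm <- rownames(x) %||% as.character(seq_len(nrow(x)))
  out <- data.frame(curve = rep(nm, each = n_grid),
                    t = rep(tt, times = nrow(x)),
                    f = as.vector(fm))
  class(out) <- c("andrews", "data.frame")
  out
}

#' @export
plot.andrews <- function(x, col = NULL, ...) {
  curves <- unique(x$curve)
  col <- col %||% seq_along(curves)
  plot(NA, xlim = range(x$t), ylim = range(x$f),
       xlab = "t", ylab = "f(t)", ...)
  for (i in seq_along(curves)) {
    sel <- x$curve == curves[i]
    lines(x$t[sel], x$f[sel], col = col[i])
  }
  legend("topright", legend = curves, col = col, lty = 1, cex = 0.7)
  invisible(x)
}
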