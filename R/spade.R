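#' Node-level disparity
#'
#' The predicted focus-group difference in mean log survival within one
#' terminal node, evaluated at a contextual value `w`:
#' `d = theta1 + theta2 * w` (for PRISM models, `d = theta1`).  On the log
#' scale this is the log of the survival-time ratio between the focus = 1
#' and focus = 0 groups.
#'
#' @param theta1 focus coefficient.
#' @param theta2 focus-by-contextual coefficient (0 for PRISM).
#' @param w contextual value(s).
#' @return numeric disparity value(s).
#' @export
node_disparity <- function(theta1, theta2 = 0, w = 0) theta1 + theta2 * w

#' Specific area-level disparity estimates (SPADE)
#'
#' For each tract m: gather its records from every terminal node l, compute
#' the node disparity at the tract's own contextual value,
#' `d_lm = theta1_l + theta2_l * w_m`, and average with weights
#' `eta_lm = (records of tract m in node l) / (records of tract m overall)`,
#' giving `d_hat_m = sum_l eta_lm d_lm`.  The weights sum to one within each
#' tract; tracts with no records receive no estimate.  Because the terminal
#' nodes pool patients across tracts, sparse tracts borrow strength from
#' tracts sharing their nodes and still receive estimates.
#'
#' @param tree a fitted [prism()] tree (HPRISM for contextual moderation;
#'   a PRISM tree yields `theta2 = 0` everywhere).
#' @param data training data (defaults to the data stored in the tree).
#' @return An object of class `"spade"`: list with `estimates` (data frame
#'   `tract_id`, `d_hat`, `robust_z`, `n_contributing`), `eta` (long data
#'   frame `tract_id`, `node`, `eta`, `d_node`), and `contextual`.  The
#'   robust z column is `NA` when the tract disparities are degenerate
#'   (zero median absolute deviation).
#' @export
spade <- function(tree, data = NULL) {
  stopifnot(inherits(tree, "prism"))
  data <- data %||% tree$data
  ctx_name <- tree$config$contextual
  tn <- terminal_nodes(tree)

  node_of <- integer(data$n)
  for (id in tn) node_of[tree$nodes[[id]]$members] <- id
  tract <- as.character(data$tract)
  w_by_tract <- if (!is.null(ctx_name)) {
    tapply(data$W[[ctx_name]], tract, function(u) u[1])
  } else NULL

  th <- vapply(tree$nodes, function(nd) nd$model$theta, numeric(3))
  used <- vapply(tree$nodes, function(nd) isTRUE(nd$model$used_w), logical(1))

  tab <- table(tract, factor(node_of, levels = tn))
  tracts <- rownames(tab)
  n_m <- rowSums(tab)
  eta <- sweep(tab, 1, n_m, "/")

  d_lm <- function(m) {
    wm <- if (is.null(w_by_tract)) 0 else w_by_tract[[m]]
    th1 <- th[2, tn]
    th2 <- ifelse(used[tn], th[3, tn], 0)
    node_disparity(th1, th2, wm)
  }
  d_hat <- vapply(tracts, function(m) sum(eta[m, ] * d_lm(m)), numeric(1))

  rz <- tryCatch(robust_z(d_hat), error = function(e) rep(NA_real_, length(d_hat)))

  eta_long <- do.call(rbind, lapply(tracts, function(m) {
    keep <- eta[m, ] > 0
    data.frame(tract_id = m, node = tn[keep],
               eta = as.numeric(eta[m, keep]),
               d_node = d_lm(m)[keep], row.names = NULL)
  }))

  structure(list(
    estimates = data.frame(tract_id = tracts, d_hat = unname(d_hat),
                           robust_z = unname(rz),
                           n_contributing = as.integer(n_m),
                           row.names = NULL),
    eta = eta_long,
    contextual = ctx_name %||% NA_character_
  ), class = "spade")
}

#' Composite SPADE
#'
#' Combines SPADE estimates across contextual variables by per-tract
#' summation (the simple composite).  Tracts present in only some estimates
#' are summed over those present, with the source count recorded.
#'
#' @param ... two or more [spade()] objects, or a single list of them.
#' @return A `"spade"` object with `contextual = "composite"` and an
#'   `n_sources` column.
#' @export
composite_spade <- function(...) {
  ests <- list(...)
  if (length(ests) == 1L && !inherits(ests[[1]], "spade")) ests <- ests[[1]]
  if (length(ests) == 0L) stop("no SPADE estimates supplied")
  stopifnot(all(vapply(ests, inherits, logical(1), "spade")))
  all_df <- do.call(rbind, lapply(ests, function(e)
    e$estimates[c("tract_id", "d_hat", "n_contributing")]))
  agg <- aggregate(cbind(d_hat = all_df$d_hat) ~ tract_id, data = all_df, FUN = sum)
  cnt <- aggregate(cbind(n_sources = all_df$d_hat) ~ tract_id, data = all_df,
                   FUN = length)
  nc <- aggregate(cbind(n_contributing = all_df$n_contributing) ~ tract_id,
                  data = all_df, FUN = max)
  out <- merge(merge(agg, cnt, by = "tract_id"), nc, by = "tract_id")
  rz <- tryCatch(robust_z(setNames(out$d_hat, out$tract_id)),
                 error = function(e) rep(NA_real_, nrow(out)))
  structure(list(
    estimates = data.frame(tract_id = out$tract_id, d_hat = out$d_hat,
                           robust_z = unname(rz),
                           n_contributing = out$n_contributing,
                           n_sources = out$n_sources, row.names = NULL),
    eta = NULL, contextual = "composite"), class = "spade")
}

#' Robust z-scores
#'
#' Standardizes heavy-tailed values as
#' `z = (v - median(v)) / (1.4826 * MAD(v))`, with 1.4826 the constant
#' making the median absolute deviation consistent for a normal scale.
#'
#' @param values numeric vector (optionally named, e.g. by tract).
#' @return numeric vector of the same shape; its median is 0.
#' @export
robust_z <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 2)
  if (length(unique(values)) < 2L)
    stop("degenerate input: all values equal (", values[1], ")")
  md <- median(values)
  s <- mad(values, center = md)  # 1.4826 * median(|v - median|)
  if (s == 0)
    stop("zero median absolute deviation: distribution too concentrated at ",
         md)
  (values - md) / s
}

#' @export
print.spade <- function(x, ...) {
  cat("SPADE estimates (contextual: ", x$contextual, "), ",
      nrow(x$estimates), " tract(s)\n", sep = "")
  print(head(x$estimates, 10))
  if (nrow(x$estimates) > 10) cat("...\n")
  invisible(x)
}

#' Hierarchical moderation profile of a fitted tree
#'
#' For each terminal node, the node disparity line
#' `d_l(w) = theta1_l + theta2_l * w` over a contextual grid: the dotted
#' lines of the hierarchical-interaction display.  Vertical spread at a
#' fixed `w` reflects individual-level moderation; non-parallel lines
#' reflect moderation by the contextual variable.  The profile is flagged
#' `nearly_parallel` when the range of `theta2` across terminal nodes is
#' below `parallel_tol`.
#'
#' @param tree a fitted HPRISM [prism()] tree.
#' @param w_grid numeric grid of contextual values; defaults to 25 points
#'   over the observed range.
#' @param parallel_tol slope-range threshold for the parallelism flag
#'   (log-time units per contextual unit, default 1e-3).
#' @return An object of class `"prism_profile"`: data frame `node`, `w`,
#'   `d`; attributes `slopes` (named theta2 vector) and `nearly_parallel`.
#' @export
moderation_profile <- function(tree, w_grid = NULL, parallel_tol = 1e-3) {
  stopifnot(inherits(tree, "prism"))
  if (tree$mode != "hprism")
    stop("moderation_profile() needs an HPRISM tree (no contextual variable here)")
  ctx <- tree$config$contextual
  w_grid <- w_grid %||%
    seq(min(tree$data$W[[ctx]]), max(tree$data$W[[ctx]]), length.out = 25)
  tn <- terminal_nodes(tree)
  th <- vapply(tree$nodes[tn], function(nd) nd$model$theta, numeric(3))
  used <- vapply(tree$nodes[tn], function(nd) isTRUE(nd$model$used_w), logical(1))
  slopes <- ifelse(used, th[3, ], 0)
  names(slopes) <- as.character(tn)
  out <- do.call(rbind, lapply(seq_along(tn), function(i)
    data.frame(node = tn[i], w = w_grid,
               d = node_disparity(th[2, i], slopes[i], w_grid))))
  attr(out, "slopes") <- slopes
  attr(out, "nearly_parallel") <- diff(range(slopes)) < parallel_tol
  class(out) <- c("prism_profile", "data.frame")
  out
}

#' @export
plot.prism_profile <- function(x, ...) {
  nodes <- unique(x$node)
  plot(NA, xlim = range(x$w), ylim = range(x$d),
       xlab = "contextual value w", ylab = "disparity d(w)", ...)
  for (i in seq_along(nodes)) {
    sel <- x$node == nodes[i]
    lines(x$w[sel], x$d[sel], lty = 3, col = i)
  }
  legend("topright", legend = paste("node", nodes), col = seq_along(nodes),
         lty = 3, cex = 0.7)
  invisible(x)
}

#' Direct per-tract disparity baseline
#'
#' The naive comparison estimator: within each tract, fit Kaplan-Meier
#' curves by focus group and take the difference in log median survival
#' (focus = 1 minus focus = 0).  The estimate is undefined (`NA`) whenever a
#' tract lacks one of the groups or a group's survival curve never reaches
#' the median -- exactly the sparse-tract situations in which the
#' model-based [spade()] estimate still exists by borrowing strength.
#'
#' @param data a [prism_data()] object.
#' @return data frame `tract_id`, `d_direct`, `defined`, `n`.
#' @export
direct_tract_disparity <- function(data) {
  stopifnot(inherits(data, "prism_data"))
  tracts <- levels(data$tract)
  res <- lapply(tracts, function(m) {
    sel <- data$tract == m
    d <- NA_real_
    if (length(unique(data$x[sel])) == 2L) {
      sf <- survival::survfit(
        survival::Surv(exp(data$y[sel]), data$delta[sel]) ~ data$x[sel])
      med <- summary(sf)$table[, "median"]
      if (length(med) == 2L && !anyNA(med)) d <- log(med[2]) - log(med[1])
    }
    data.frame(tract_id = m, d_direct = d, defined = !is.na(d),
               n = sum(sel), row.names = NULL)
  })
  do.call(rbind, res)
}
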