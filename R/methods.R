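# S3 methods for fitted "prism" trees.

# Encode newdata covariates with the training metadata; unseen nominal
# levels become NA codes and are resolved at routing time.
.encode_newdata <- function(tree, newdata) {
  if (inherits(newdata, "prism_data")) {
    df <- cbind(newdata$Z,
                .x. = newdata$x,
                if (!is.null(newdata$W)) newdata$W)
  } else df <- as.data.frame(newdata)
  codes <- list()
  for (zi in tree$zinfo) {
    if (!zi$name %in% names(df))
      stop("newdata lacks covariate '", zi$name, "'")
    col <- df[[zi$name]]
    codes[[zi$name]] <-
      if (is.null(zi$levels)) as.numeric(col)
      else as.numeric(match(as.character(col), zi$levels))
  }
  list(df = df, codes = codes, n = nrow(df))
}

# Terminal-node id for each row; unseen levels fall back to the larger
# daughter with a warning.
.route <- function(tree, enc) {
  node_of <- integer(enc$n)
  warned <- FALSE
  rec <- function(id, idx) {
    nd <- tree$nodes[[id]]
    if (is.null(nd$rule)) { node_of[idx] <<- id; return(invisible()) }
    zv <- enc$codes[[nd$rule$variable]][idx]
    left <- if (nd$rule$kind == "threshold") zv < nd$rule$s
            else zv %in% nd$rule$subset_codes
    nas <- is.na(zv)
    if (any(nas)) {
      if (!warned) {
        warning("unseen covariate level(s); routed to the larger daughter")
        warned <<- TRUE
      }
      ch <- nd$children
      bigger_left <- tree$nodes[[ch[1]]]$model$n >= tree$nodes[[ch[2]]]$model$n
      left[nas] <- bigger_left
    }
    if (any(left)) rec(nd$children[1], idx[left])
    if (any(!left)) rec(nd$children[2], idx[!left])
    invisible()
  }
  rec(1L, seq_len(enc$n))
  node_of
}

#' Predict log survival time from a fitted tree
#'
#' Routes each record down the tree by its covariates and evaluates the
#' terminal node's model: `yhat = theta0 + theta1 x + theta2 x w`.
#'
#' @param object a fitted [prism()] tree.
#' @param newdata a [prism_data()] object or data frame carrying the
#'   covariates, the focus column and (HPRISM) the contextual column;
#'   defaults to the training data.
#' @param type `"response"` for predicted log survival time, `"node"` for
#'   the terminal-node id.
#' @param ... unused.
#' @return numeric (or integer node-id) vector.
#' @export
predict.prism <- function(object, newdata = NULL,
                          type = c("response", "node"), ...) {
  type <- match.arg(type)
  newdata <- newdata %||% object$data
  enc <- .encode_newdata(object, newdata)
  nid <- .route(object, enc)
  if (type == "node") return(nid)

  sp <- object$data$specs
  focus_col <- sp$name[sp$role == "focus"]
  xv <- if (inherits(newdata, "prism_data")) newdata$x
        else {
          if (!focus_col %in% names(enc$df))
            stop("newdata lacks focus column '", focus_col, "'")
          as.numeric(enc$df[[focus_col]])
        }
  wv <- 0
  if (object$mode == "hprism") {
    cv <- object$config$contextual
    wv <- if (inherits(newdata, "prism_data")) {
      if (is.null(newdata$W) || !cv %in% names(newdata$W))
        stop("newdata lacks contextual variable '", cv, "'")
      newdata$W[[cv]]
    } else {
      if (!cv %in% names(enc$df))
        stop("newdata lacks contextual variable '", cv, "'")
      as.numeric(enc$df[[cv]])
    }
  }
  th <- vapply(object$nodes, function(nd) nd$model$theta, numeric(3))
  used <- vapply(object$nodes, function(nd) isTRUE(nd$model$used_w), logical(1))
  th0 <- th[1, nid]; th1 <- th[2, nid]
  th2 <- ifelse(used[nid], th[3, nid], 0)
  as.numeric(th0 + th1 * xv + th2 * xv * wv)
}

#' Terminal-node coefficients
#'
#' @param object a fitted [prism()] tree.
#' @param ... unused.
#' @return matrix with one row per terminal node (row names are node ids)
#'   and columns `theta0`, `theta1`, `theta2`, `n`, `n_events`.
#' @export
coef.prism <- function(object, ...) {
  tn <- terminal_nodes(object)
  out <- t(vapply(object$nodes[tn], function(nd)
    c(nd$model$theta, nd$model$n, nd$model$n_events), numeric(5)))
  dimnames(out) <- list(tn, c("theta0", "theta1", "theta2", "n", "n_events"))
  out
}

#' Terminal node ids of a fitted tree
#' @param tree a fitted [prism()] tree.
#' @return integer vector of node ids.
#' @export
terminal_nodes <- function(tree) {
  stopifnot(inherits(tree, "prism"))
  which(vapply(tree$nodes, function(nd) is.null(nd$rule), logical(1)))
}

#' Residuals of a fitted tree
#'
#' Raw (`type = "raw"`) or censoring-imputed (`type = "imputed"`) residuals
#' of the terminal-node models, aligned to the training records.
#' @param object a fitted [prism()] tree.
#' @param type residual flavour.
#' @param ... unused.
#' @return numeric vector of length `n`.
#' @export
residuals.prism <- function(object, type = c("imputed", "raw"), ...) {
  type <- match.arg(type)
  ds <- object$data
  ctx <- .tree_context(ds, object$config$contextual)
  out <- numeric(ds$n)
  for (id in terminal_nodes(object)) {
    nd <- object$nodes[[id]]
    m <- nd$members
    mod <- list(theta0 = nd$model$theta[1], theta1 = nd$model$theta[2],
                theta2 = nd$model$theta[3], used_w = isTRUE(nd$model$used_w))
    ir <- impute_residuals(mod, ds$y[m], ds$delta[m], ds$x[m], ctx$w[m])
    out[m] <- if (type == "raw") ir$r else ir$r_hat
  }
  out
}

.rule_label <- function(rule, side = c("left", "right")) {
  side <- match.arg(side)
  if (rule$kind == "threshold") {
    if (is.null(rule$levels))
      sprintf("%s %s %.4g", rule$variable, if (side == "left") "<" else ">=",
              rule$s)
    else {
      lv <- rule$levels
      inl <- lv[seq_along(lv) < rule$s]
      sprintf("%s in {%s}", rule$variable,
              paste(if (side == "left") inl else setdiff(lv, inl),
                    collapse = ","))
    }
  } else {
    inl <- rule$subset_levels %||% as.character(rule$subset_codes)
    all_lv <- rule$all_levels %||% NULL
    if (side == "left")
      sprintf("%s in {%s}", rule$variable, paste(inl, collapse = ","))
    else sprintf("%s not in {%s}", rule$variable, paste(inl, collapse = ","))
  }
}

#' @export
print.prism <- function(x, digits = 4, ...) {
  cat(sprintf("%s tree (%s criterion, cp = %g)\n",
              toupper(x$mode), x$config$criterion, x$config$cp))
  if (x$mode == "hprism")
    cat("contextual variable:", x$config$contextual, "\n")
  cat(sprintf("n = %d, root imputed RSS = %.4g, %d terminal node(s)\n\n",
              x$nodes[[1]]$model$n, x$root_irss, length(terminal_nodes(x))))
  rec <- function(id, label) {
    nd <- x$nodes[[id]]
    th <- nd$model$theta
    cat(sprintf("%s%d) %s  n=%d ev=%d  ybar=%.*f  th0=%.*f th1=%.*f%s%s\n",
                strrep("  ", nd$depth), id, label, nd$model$n,
                nd$model$n_events, digits, nd$model$mean_log_surv,
                digits, th[1], digits, th[2],
                if (x$mode == "hprism")
                  sprintf(" th2=%.*f", digits, th[3]) else "",
                if (is.null(nd$rule)) " *" else ""))
    if (!is.null(nd$rule)) {
      rec(nd$children[1], .rule_label(nd$rule, "left"))
      rec(nd$children[2], .rule_label(nd$rule, "right"))
    }
  }
  rec(1L, "root")
  cat("\n* terminal node\n")
  invisible(x)
}

#' @export
summary.prism <- function(object, ...) {
  structure(list(tree = object, coef = coef(object),
                 validation = validate_prism_data(object$data)),
            class = "summary.prism")
}

#' @export
print.summary.prism <- function(x, ...) {
  print(x$tree)
  cat("\nTerminal-node models:\n")
  print(round(x$coef, 4))
  invisible(x)
}

#' Plot a fitted tree
#'
#' Draws the tree topology with split labels on the edges and the node
#' sample size and focus coefficient in each terminal node.
#' @param x a fitted [prism()] tree.
#' @param digits label precision.
#' @param ... passed to [graphics::plot()].
#' @export
plot.prism <- function(x, digits = 3, ...) {
  tn <- terminal_nodes(x)
  pos <- new.env()
  leaf_i <- 0
  depth_max <- max(vapply(x$nodes, function(nd) nd$depth, integer(1)))
  setpos <- function(id) {
    nd <- x$nodes[[id]]
    if (is.null(nd$rule)) {
      leaf_i <<- leaf_i + 1
      assign(as.character(id), c(leaf_i, -nd$depth), envir = pos)
    } else {
      setpos(nd$children[1]); setpos(nd$children[2])
      p1 <- get(as.character(nd$children[1]), envir = pos)
      p2 <- get(as.character(nd$children[2]), envir = pos)
      assign(as.character(id), c((p1[1] + p2[1]) / 2, -nd$depth), envir = pos)
    }
  }
  setpos(1L)
  plot(NA, xlim = c(0.5, max(leaf_i, 1) + 0.5),
       ylim = c(-depth_max - 0.6, 0.4), axes = FALSE,
       xlab = "", ylab = "", ...)
  for (nd in x$nodes) {
    p <- get(as.character(nd$id), envir = pos)
    if (!is.null(nd$rule)) {
      for (k in 1:2) {
        q <- get(as.character(nd$children[k]), envir = pos)
        segments(p[1], p[2], q[1], q[2], col = "grey50")
        text((p[1] + q[1]) / 2, (p[2] + q[2]) / 2,
             .rule_label(nd$rule, c("left", "right")[k]), cex = 0.6, pos = 4)
      }
    }
    lab <- if (is.null(nd$rule))
      sprintf("#%d\nn=%d\nth1=%.*f", nd$id, nd$model$n, digits,
              nd$model$theta[2])
    else sprintf("#%d", nd$id)
    text(p[1], p[2], lab, cex = 0.7,
         col = if (is.null(nd$rule)) "firebrick" else "black")
  }
  invisible(x)
}
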