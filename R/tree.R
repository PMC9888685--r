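#' Fit a PRISM or HPRISM moderation tree
#'
#' Recursively partitions the cohort on individual-level covariates and fits,
#' in every node, a Stute-weighted least-squares regression of log survival
#' time on the focus variable -- `y = theta0 + theta1 x + e` (PRISM) or
#' `y = theta0 + theta1 x + theta2 x w + e` (HPRISM, with `w` the chosen
#' area-level contextual variable).  The split search maximises the drop in
#' the sum of squared *imputed* residuals: censored residuals are replaced by
#' the mean of the uncensored residuals exceeding them, the parent term uses
#' the parent's fitted model, and each daughter term uses a model refit
#' (weights recomputed, residuals re-imputed) within that daughter.  A
#' log-rank alternative selects the split maximising the absolute difference
#' of the two daughters' focus-group log-rank statistics.
#'
#' A candidate split is admissible only when each daughter has at least
#' `min_node` records and at least `min_events_per_group` uncensored records
#' of each focus group; in HPRISM mode the uncensored records of each focus
#' group must additionally span at least two distinct tracts in each
#' daughter, so that the interaction with the tract-level variable remains
#' estimable after the split.  A split is accepted only when its residual
#' improvement is at least `cp` times the root's imputed-residual sum of
#' squares (rpart-style complexity stopping; with the log-rank criterion the
#' split is *chosen* by the log-rank score and the same Cp rule decides
#' acceptance).
#'
#' Candidate thresholds for continuous and ordinal covariates are midpoints
#' between consecutive distinct observed values within the node.  Nominal
#' covariates with at most 6 levels are scanned over all binary partitions of
#' their observed levels (in lexicographic order of the left level set);
#' with more levels, levels are ordered by the mean log time of their
#' uncensored members and scanned as ordinal.  Exact criterion ties are
#' broken toward the earlier covariate, then the smaller threshold /
#' lexicographically smaller subset.
#'
#' @param data a [prism_data()] object.
#' @param contextual name of the contextual variable (HPRISM); `NULL` fits
#'   the PRISM model.
#' @param criterion `"drss"` (imputed residual sum-of-squares improvement,
#'   the default) or `"logrank"`.
#' @param cp complexity parameter: minimum relative improvement, as a
#'   fraction of the root's imputed-residual sum of squares (default 0.01).
#' @param min_node minimum records per daughter (default 20).
#' @param min_events_per_group minimum uncensored records of each focus
#'   group per daughter (default 1).
#' @param max_depth maximum tree depth (root = 0).
#' @param daughter_residuals `"refit"` (daughters refit their own models
#'   before imputation, the default) or `"parent"` (daughter residuals use
#'   the parent's coefficients, re-imputed within each daughter).
#' @return An object of class `"prism"`: list with `nodes` (each carrying
#'   `id`, `parent`, `depth`, `children`, `rule`, `model`, `members`),
#'   `config`, `root_irss`, `mode`, and the training `data`.
#' @examples
#' ds <- simulate_prism_data(prism_truth(n = 400, M = 30), seed = 7)
#' fit <- prism(ds, contextual = "w")
#' fit
#' @export
prism <- function(data, contextual = NULL,
                  criterion = c("drss", "logrank"),
                  cp = 0.01, min_node = 20, min_events_per_group = 1,
                  max_depth = 30L,
                  daughter_residuals = c("refit", "parent")) {
  stopifnot(inherits(data, "prism_data"))
  criterion <- match.arg(criterion)
  daughter_residuals <- match.arg(daughter_residuals)
  stopifnot(cp >= 0, min_node >= 2, min_events_per_group >= 0)

  chk <- validate_prism_data(data)
  if (length(chk$fatal))
    stop("dataset fails validation: ", paste(chk$fatal, collapse = "; "))

  ctx <- .tree_context(data, contextual)
  cfg <- list(contextual = contextual, criterion = criterion, cp = cp,
              min_node = min_node, min_events_per_group = min_events_per_group,
              max_depth = max_depth, daughter_residuals = daughter_residuals)

  env <- new.env(parent = emptyenv())
  env$nodes <- list()

  fit_for <- function(members) {
    f <- cpp_node_fit(ctx$y[members], ctx$delta[members], ctx$x[members],
                      ctx$w[members], ctx$use_w)
    if (!f$ok) stop("node model unfittable")
    f
  }

  root_fit <- fit_for(seq_len(data$n))
  root_irss <- root_fit$irss
  env$nodes[[1]] <- list(id = 1L, parent = NA_integer_, depth = 0L,
                         children = NULL, rule = NULL,
                         model = root_fit, members = seq_len(data$n))

  build <- function(id) {
    node <- env$nodes[[id]]
    if (node$depth >= max_depth) return(invisible())
    if (length(node$members) < 2L * min_node) return(invisible())
    rule <- .scan_node(ctx, node$members, node$model, cfg)
    if (is.null(rule) || rule$delta_rss < cp * root_irss) return(invisible())

    left <- .rule_left(rule, ctx, node$members)
    ml <- node$members[left]
    mr <- node$members[!left]
    idL <- length(env$nodes) + 1L
    env$nodes[[idL]] <- list(id = idL, parent = id, depth = node$depth + 1L,
                             children = NULL, rule = NULL,
                             model = fit_for(ml), members = ml)
    idR <- length(env$nodes) + 1L
    env$nodes[[idR]] <- list(id = idR, parent = id, depth = node$depth + 1L,
                             children = NULL, rule = NULL,
                             model = fit_for(mr), members = mr)
    env$nodes[[id]]$rule <- rule
    env$nodes[[id]]$children <- c(idL, idR)
    build(idL)
    build(idR)
    invisible()
  }
  build(1L)

  structure(list(nodes = env$nodes, config = cfg, mode = ctx$mode,
                 root_irss = root_irss, zinfo = ctx$zinfo,
                 data = data),
            class = "prism")
}

# ---- internal machinery -----------------------------------------------------

# Numeric encoding of the dataset for the split engine.
.tree_context <- function(ds, contextual) {
  use_w <- !is.null(contextual)
  if (use_w) {
    if (is.null(ds$W) || !contextual %in% names(ds$W))
      stop("contextual variable '", contextual, "' not found in data")
    w <- as.numeric(ds$W[[contextual]])
  } else w <- numeric(ds$n)
  zinfo <- lapply(names(ds$Z), function(v) {
    col <- ds$Z[[v]]
    if (is.numeric(col)) {
      list(name = v, scale = "continuous", codes = as.numeric(col), levels = NULL)
    } else {
      list(name = v, scale = if (is.ordered(col)) "ordinal" else "nominal",
           codes = as.numeric(as.integer(col)), levels = levels(col))
    }
  })
  names(zinfo) <- names(ds$Z)
  list(y = ds$y, delta = as.numeric(ds$delta), x = as.numeric(ds$x),
       w = w, use_w = use_w, tract = as.integer(ds$tract),
       zinfo = zinfo, mode = if (use_w) "hprism" else "prism")
}

# Candidate left-level sets for a nominal covariate with codes `present`
# (ascending).  All proper binary partitions, each once (left set contains
# the smallest code), in lexicographic order of the left set.
.nominal_subsets <- function(present) {
  k <- length(present)
  rest <- present[-1]
  subs <- list()
  for (mask in 0:(2^(k - 1) - 1)) {
    s <- c(present[1], rest[bitwAnd(mask, 2^(seq_len(k - 1) - 1)) > 0])
    if (length(s) < k) subs[[length(subs) + 1L]] <- s
  }
  keys <- vapply(subs, function(s) paste(sprintf("%06d", s), collapse = ","),
                 character(1))
  subs[order(keys)]
}

# Left-side indicator of a rule among `members`.
.rule_left <- function(rule, ctx, members) {
  zv <- ctx$zinfo[[rule$variable]]$codes[members]
  if (rule$kind == "threshold") zv < rule$s else zv %in% rule$subset_codes
}

# Best split of the member set, or NULL.  `model` is the node's fitted model
# (cpp_node_fit result).
.scan_node <- function(ctx, members, model, cfg) {
  ord <- order(ctx$y[members], -ctx$delta[members])
  ms <- members[ord]
  ys <- ctx$y[ms]; ds <- ctx$delta[ms]; xs <- ctx$x[ms]
  ws <- ctx$w[ms]; ts <- ctx$tract[ms]
  parent_irss <- model$irss
  parent_theta <- if (cfg$daughter_residuals == "parent") model$theta else NULL
  req2 <- ctx$use_w
  use_lr <- cfg$criterion == "logrank"

  best <- NULL
  consider <- function(cand) {
    # strict > so earlier candidates (lower variable index, smaller s,
    # lexicographically smaller subset) win exact ties
    if (is.null(best) || cand$score > best$score) best <<- cand
  }

  for (vi in seq_along(ctx$zinfo)) {
    zi <- ctx$zinfo[[vi]]
    zv <- zi$codes[ms]

    eval_masked_rss <- function(left) {
      cpp_eval_partition(ys, ds, xs, ws, ts, left, ctx$use_w,
                         cfg$min_node, cfg$min_events_per_group, req2,
                         parent_theta, isTRUE(model$used_w))
    }
    score_of <- function(rss_sum, left) {
      if (is.na(rss_sum)) return(NULL)
      drss <- parent_irss - rss_sum
      sc <- if (use_lr) .logrank_pair_stat(ys, ds, xs, left) else drss
      if (is.na(sc)) return(NULL)
      list(score = sc, delta_rss = drss)
    }

    if (zi$scale %in% c("continuous", "ordinal") ||
        (zi$scale == "nominal" && length(unique(zv)) > 6L)) {
      if (zi$scale == "nominal") {
        # too many levels: order by mean log time of uncensored members and
        # scan the ordered levels as ordinal
        present <- sort(unique(zv))
        keyv <- vapply(present, function(cd) {
          sel <- zv == cd & ds == 1
          if (any(sel)) mean(ys[sel]) else mean(ys[zv == cd])
        }, numeric(1))
        rk <- rank(keyv, ties.method = "first")
        zr <- rk[match(zv, present)]
        cuts <- sort(rk)[-length(rk)] + 0.5
        sums <- cpp_scan_threshold(ys, ds, xs, ws, ts, zr, cuts, ctx$use_w,
                                   cfg$min_node, cfg$min_events_per_group,
                                   req2, parent_theta, isTRUE(model$used_w))
        for (ci in seq_along(cuts)) {
          sc <- score_of(sums[ci], zr < cuts[ci])
          if (is.null(sc)) next
          codes <- present[rk < cuts[ci]]
          consider(list(variable = zi$name, var_index = vi, kind = "subset",
                        subset_codes = sort(codes),
                        subset_levels = zi$levels[sort(codes)],
                        score = sc$score, delta_rss = sc$delta_rss))
        }
        next
      }
      uv <- sort(unique(zv))
      if (length(uv) < 2L) next
      cuts <- (uv[-1] + uv[-length(uv)]) / 2
      sums <- cpp_scan_threshold(ys, ds, xs, ws, ts, zv, cuts, ctx$use_w,
                                 cfg$min_node, cfg$min_events_per_group,
                                 req2, parent_theta, isTRUE(model$used_w))
      for (ci in seq_along(cuts)) {
        sc <- score_of(sums[ci], zv < cuts[ci])
        if (is.null(sc)) next
        consider(list(variable = zi$name, var_index = vi, kind = "threshold",
                      s = cuts[ci], levels = zi$levels,
                      score = sc$score, delta_rss = sc$delta_rss))
      }
    } else if (zi$scale == "nominal") {
      present <- sort(unique(zv))
      if (length(present) < 2L) next
      for (sub in .nominal_subsets(present)) {
        left <- zv %in% sub
        sc <- score_of(eval_masked_rss(left), left)
        if (is.null(sc)) next
        consider(list(variable = zi$name, var_index = vi, kind = "subset",
                      subset_codes = sub, subset_levels = zi$levels[sub],
                      score = sc$score, delta_rss = sc$delta_rss))
      }
    }
  }
  best
}

# |logrank(tau_L) - logrank(tau_R)| grouping by focus within each daughter,
# on the original time scale.  NA when either daughter is degenerate.
.logrank_pair_stat <- function(y, delta, x, left) {
  one <- function(sel) {
    if (length(unique(x[sel])) < 2L) return(NA_real_)
    if (sum(delta[sel]) < 1) return(NA_real_)
    out <- tryCatch(
      survival::survdiff(survival::Surv(exp(y[sel]), delta[sel]) ~ x[sel]),
      error = function(e) NULL)
    if (is.null(out)) return(NA_real_)
    unname(out$chisq)
  }
  a <- one(left); b <- one(!left)
  if (is.na(a) || is.na(b)) return(NA_real_)
  abs(a - b)
}

# ---- exported split-level operations ---------------------------------------

#' Evaluate one candidate split
#'
#' Computes the improvement in the sum of squared imputed residuals when the
#' given dataset (treated as one node) is split by `variable < s`
#' (continuous/ordinal) or `variable in subset` (nominal).  The parent term
#' uses the model fitted to all records; each daughter term refits its own
#' model with weights recomputed and residuals re-imputed within the
#' daughter (or re-imputes under the parent coefficients when
#' `daughter_residuals = "parent"`).
#'
#' @inheritParams prism
#' @param variable covariate name.
#' @param s numeric threshold (continuous/ordinal covariates).
#' @param subset character vector of left-daughter levels (nominal).
#' @return The criterion improvement (delta RSS), or `NA` when the split is
#'   inadmissible under the exclusion criteria.
#' @export
evaluate_split <- function(data, variable, s = NULL, subset = NULL,
                           contextual = NULL, min_node = 20,
                           min_events_per_group = 1,
                           daughter_residuals = c("refit", "parent")) {
  daughter_residuals <- match.arg(daughter_residuals)
  ctx <- .tree_context(data, contextual)
  zi <- ctx$zinfo[[variable]]
  if (is.null(zi)) stop("unknown covariate: ", variable)
  model <- cpp_node_fit(ctx$y, ctx$delta, ctx$x, ctx$w, ctx$use_w)
  if (!model$ok) stop("root model unfittable")
  ord <- order(ctx$y, -ctx$delta)
  left_all <- if (!is.null(s)) zi$codes < s
  else zi$codes %in% match(subset, zi$levels)
  pth <- if (daughter_residuals == "parent") model$theta else NULL
  rss <- cpp_eval_partition(ctx$y[ord], ctx$delta[ord], ctx$x[ord],
                            ctx$w[ord], ctx$tract[ord], left_all[ord],
                            ctx$use_w, min_node, min_events_per_group,
                            ctx$use_w, pth, isTRUE(model$used_w))
  if (is.na(rss)) return(NA_real_)
  model$irss - rss
}

#' Find the best admissible split of a dataset
#'
#' Runs the same candidate enumeration, exclusion criteria and tie-breaking
#' as the grower on the dataset treated as a single node.
#'
#' @inheritParams prism
#' @return list with `variable`, `kind` (`"threshold"`/`"subset"`), `s` or
#'   `subset_levels`, and `delta_rss`, or `NULL` when no candidate is
#'   admissible.
#' @export
best_split <- function(data, contextual = NULL,
                       criterion = c("drss", "logrank"),
                       min_node = 20, min_events_per_group = 1,
                       daughter_residuals = c("refit", "parent")) {
  criterion <- match.arg(criterion)
  daughter_residuals <- match.arg(daughter_residuals)
  ctx <- .tree_context(data, contextual)
  model <- cpp_node_fit(ctx$y, ctx$delta, ctx$x, ctx$w, ctx$use_w)
  if (!model$ok) stop("root model unfittable")
  cfg <- list(criterion = criterion, min_node = min_node,
              min_events_per_group = min_events_per_group,
              daughter_residuals = daughter_residuals)
  rule <- .scan_node(ctx, seq_len(data$n), model, cfg)
  if (is.null(rule)) return(NULL)
  rule[c("variable", "kind",
         if (rule$kind == "threshold") "s" else c("subset_codes", "subset_levels"),
         "delta_rss", "score")]
}

#' Log-rank splitting statistic for one candidate
#'
#' Within each daughter the two-sample log-rank statistic comparing the
#' focus groups is computed on the original time scale; the returned value
#' is the absolute difference of the two daughter statistics.
#'
#' @inheritParams evaluate_split
#' @return The statistic, or `NA` when a daughter lacks both focus groups
#'   with at least one event.
#' @export
logrank_split_stat <- function(data, variable, s = NULL, subset = NULL) {
  ctx <- .tree_context(data, NULL)
  zi <- ctx$zinfo[[variable]]
  if (is.null(zi)) stop("unknown covariate: ", variable)
  left <- if (!is.null(s)) zi$codes < s
  else zi$codes %in% match(subset, zi$levels)
  .logrank_pair_stat(ctx$y, ctx$delta, ctx$x, left)
}

#' Serialize a fitted tree to JSON
#'
#' @param tree a fitted [prism()] object.
#' @param file optional path; when `NULL` the JSON string is returned.
#' @param members include each node's record indices (default off).
#' @return JSON string (invisibly when written to `file`).
#' @export
prism_to_json <- function(tree, file = NULL, members = FALSE) {
  stopifnot(inherits(tree, "prism"))
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("prism_to_json() requires the 'jsonlite' package")
  nodes <- lapply(tree$nodes, function(nd) {
    out <- list(id = nd$id,
                parent = if (is.na(nd$parent)) NULL else nd$parent,
                depth = nd$depth,
                model = nd$model[c("theta", "used_w", "rss", "irss",
                                   "n", "n_events", "mean_log_surv")])
    names(out$model$theta) <- c("theta0", "theta1", "theta2")
    if (!is.null(nd$rule))
      out$rule <- list(variable = nd$rule$variable, kind = nd$rule$kind,
                       s = nd$rule$s %||% NULL,
                       subset = nd$rule$subset_levels %||% nd$rule$subset_codes)
    if (members) out$members <- nd$members
    out
  })
  js <- jsonlite::toJSON(list(mode = tree$mode, config = tree$config,
                              nodes = nodes),
                         auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(js)
}
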