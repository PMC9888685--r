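#' Harrell's concordance index for censored predictions
#'
#' Fraction of usable pairs in which the ordering of predictions agrees with
#' the ordering of observed survival.  A pair is usable when the smaller
#' observed time belongs to an event; pairs with tied observed times are
#' used only when exactly one member is an event (the event member is then
#' the shorter survivor).  Predictions here are log survival times, so
#' *higher* predicted values go with *longer* survival; ties in prediction
#' count 1/2.
#'
#' @param predicted predicted log survival times.
#' @param y observed (log) times.
#' @param delta 0/1 event indicators.
#' @return Concordance in `[0, 1]`.
#' @export
harrell_c <- function(predicted, y, delta) {
  n <- length(y)
  stopifnot(length(predicted) == n, length(delta) == n)
  ev <- delta == 1
  # ordered pairs (i, j) where i is the established shorter survivor
  shorter <- outer(y, y, "<") & ev                       # y_i < y_j, i event
  tied <- outer(y, y, "==") & outer(ev, !ev, "&")        # tie, i event only
  use <- shorter | tied
  if (!any(use)) stop("no usable pairs for concordance")
  conc <- outer(predicted, predicted, "<")
  eqp <- outer(predicted, predicted, "==")
  (sum(conc[use]) + 0.5 * sum(eqp[use])) / sum(use)
}

#' Repeated censoring-stratified holdout evaluation
#'
#' Repeats: split the cohort into training and test sets, stratified by
#' censoring status so both sets preserve the censoring fraction; fit the
#' tree on the training set; feed test records down the tree; score the
#' predictions with [harrell_c()].  Reports the per-repeat concordances,
#' their mean and the standard error `sd / sqrt(repeats)`.
#'
#' @inheritParams prism
#' @param repeats number of holdout repeats (default 100).
#' @param train_fraction fraction of each stratum assigned to training.
#' @param seed integer seed driving all splits.
#' @param keep_splits record the training indices of every repeat.
#' @param ... further arguments passed to [prism()].
#' @return An object of class `"prism_holdout"`: list with `per_repeat_c`,
#'   `mean_c`, `se_c`, `repeats`, `train_fraction`, `skipped`.
#' @export
prism_holdout <- function(data, contextual = NULL, repeats = 100,
                          train_fraction = 0.8, seed = NULL,
                          keep_splits = FALSE, ...) {
  stopifnot(inherits(data, "prism_data"),
            train_fraction > 0, train_fraction < 1, repeats >= 1)
  i_ev <- which(data$delta == 1)
  i_cn <- which(data$delta == 0)
  if (length(i_ev) == 0L || length(i_cn) == 0L)
    stop("both strata (events, censored) must be nonempty")
  splits <- if (keep_splits) vector("list", repeats) else NULL
  cs <- with_seed(seed, {
    vapply(seq_len(repeats), function(r) {
      tr <- c(sample(i_ev, round(train_fraction * length(i_ev))),
              sample(i_cn, round(train_fraction * length(i_cn))))
      if (keep_splits) splits[[r]] <<- tr
      te <- setdiff(seq_len(data$n), tr)
      fit <- tryCatch(
        prism(prism_data_subset(data, tr), contextual = contextual, ...),
        error = function(e) NULL)
      if (is.null(fit)) {
        warning("repeat ", r, ": training fit failed; repeat skipped")
        return(NA_real_)
      }
      test <- prism_data_subset(data, te)
      harrell_c(predict(fit, test), test$y, test$delta)
    }, numeric(1))
  })
  ok <- !is.na(cs)
  structure(list(per_repeat_c = cs,
                 splits = splits,
                 mean_c = mean(cs[ok]),
                 se_c = sd(cs[ok]) / sqrt(sum(ok)),
                 repeats = repeats,
                 skipped = sum(!ok),
                 train_fraction = train_fraction),
            class = "prism_holdout")
}

#' @export
print.prism_holdout <- function(x, ...) {
  cat(sprintf("Repeated holdout: %d repeat(s) (%d skipped), train fraction %.2f\n",
              x$repeats, x$skipped, x$train_fraction))
  cat(sprintf("mean Harrell's C = %.4f (SE %.4f)\n", x$mean_c, x$se_c))
  invisible(x)
}
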