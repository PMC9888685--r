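# Descriptive cohort comparisons from 2 x K contingency tables: the focus
# groups (reference group in row 1, focus group in row 2) against the levels
# of one individual variable.

.check_table <- function(counts) {
  if (!is.matrix(counts) || nrow(counts) != 2L || ncol(counts) < 2L)
    stop("counts must be a 2 x K matrix, K >= 2")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  invisible(counts)
}

#' Chi-squared test of homogeneity between focus groups
#'
#' Pearson's statistic comparing the level distribution of the two focus
#' groups, without continuity correction, on K - 1 degrees of freedom.
#'
#' @param counts 2 x K matrix of counts (rows: focus groups).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
chisq_homogeneity <- function(counts) {
  .check_table(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal total: expected counts undefined")
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Fisher's exact test (with Monte Carlo for wide tables)
#'
#' For 2 x 2 tables the exact two-sided hypergeometric p-value; for 2 x K
#' tables with K > 2 a Monte Carlo p-value over tables with the observed
#' margins.  A table with a zero row or column margin is degenerate and
#' returns p = 1.
#'
#' @param counts 2 x K matrix of counts.
#' @param mc_reps Monte Carlo replicates for K > 2 (default 1e5).
#' @param seed integer seed for the Monte Carlo draw.
#' @return list with `p_value`, `method`, and for Monte Carlo runs
#'   `mc_reps` and `seed`.
#' @export
fisher_exact <- function(counts, mc_reps = 1e5, seed = 1) {
  .check_table(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    return(list(p_value = 1, method = "degenerate margin"))
  if (ncol(counts) == 2L) {
    ft <- fisher.test(counts)
    list(p_value = ft$p.value, method = "exact")
  } else {
    p <- with_seed(seed,
      fisher.test(counts, simulate.p.value = TRUE, B = mc_reps)$p.value)
    list(p_value = p, method = "monte carlo", mc_reps = mc_reps, seed = seed)
  }
}

#' Binary logistic coefficient from a 2 x 2 table
#'
#' Closed-form (saturated-model) log odds ratio of `outcome_level` for the
#' focus group versus the reference group, with the standard error
#' `sqrt(sum of reciprocal cells)` and a Wald p-value.
#'
#' @param counts 2 x 2 matrix (rows: focus groups; columns: outcome levels).
#' @param outcome_level column name or index of the outcome category.
#' @return An `"assoc_fit"` list with `model`, `coefficients`,
#'   `standard_errors`, `p_values`.
#' @export
binary_logit <- function(counts, outcome_level = 2L) {
  .check_table(counts)
  if (ncol(counts) != 2L) stop("binary_logit needs a 2 x 2 table")
  k <- if (is.character(outcome_level)) match(outcome_level, colnames(counts))
       else as.integer(outcome_level)
  if (is.na(k) || !k %in% 1:2) stop("unknown outcome level")
  if (any(counts == 0))
    stop("zero cell: the log odds ratio estimate is infinite")
  ref <- 3L - k
  co <- log((counts[2, k] / counts[2, ref]) / (counts[1, k] / counts[1, ref]))
  se <- sqrt(sum(1 / counts))
  nm <- colnames(counts)[k] %||% paste0("level", k)
  structure(list(model = "binary_logit", reference = colnames(counts)[ref],
                 coefficients = setNames(co, nm),
                 standard_errors = setNames(se, nm),
                 p_values = setNames(2 * pnorm(-abs(co / se)), nm)),
            class = "assoc_fit")
}

#' Multinomial logistic coefficients from a 2 x K table
#'
#' Fits a baseline-category multinomial logit of the column category on the
#' focus indicator (focus group coded 1) by maximum likelihood via
#' [nnet::multinom()], and reports the focus coefficient for each
#' non-reference category: the log odds of that category versus the
#' reference for the focus group relative to the reference group.  For the
#' saturated two-group model these equal the closed-form log odds ratios
#' `log[(n_1k / n_1ref) / (n_0k / n_0ref)]` up to the optimizer's stopping
#' accuracy.  Categories with a zero cell are flagged non-estimable (the
#' true estimate diverges).
#'
#' @param counts 2 x K matrix of counts with column names.
#' @param reference reference category (column name or index).
#' @return An `"assoc_fit"` list with per-category `coefficients`,
#'   `standard_errors`, `p_values`, `non_estimable`.
#' @export
multinomial_logit <- function(counts, reference = 1L) {
  .check_table(counts)
  K <- ncol(counts)
  lv <- colnames(counts) %||% paste0("level", seq_len(K))
  colnames(counts) <- lv
  r <- if (is.character(reference)) match(reference, lv) else as.integer(reference)
  if (is.na(r) || !r %in% seq_len(K)) stop("unknown reference category")
  if (any(counts[, r] == 0))
    stop("zero cell in the reference category: model not estimable")
  lv_ord <- c(lv[r], lv[-r])
  long <- data.frame(
    cat = factor(rep(lv, 2), levels = lv_ord),
    focus = rep(c(0, 1), each = K),
    n = c(counts[1, ], counts[2, ]))
  long <- long[long$n > 0, ]
  fit <- nnet::multinom(cat ~ focus, data = long, weights = long$n,
                        trace = FALSE)
  sm <- summary(fit)
  cf <- coef(sm); ses <- sm$standard.errors
  if (is.null(dim(cf))) {  # K = 2: multinom returns plain vectors
    co <- setNames(cf[["focus"]], lv[-r])
    se <- setNames(ses[["focus"]], lv[-r])
  } else {
    co <- cf[, "focus"]
    se <- ses[, "focus"]
  }
  non_est <- lv[-r][counts[1, -r] == 0 | counts[2, -r] == 0]
  structure(list(model = "multinomial_logit", reference = lv[r],
                 coefficients = co, standard_errors = se,
                 p_values = 2 * pnorm(-abs(co / se)),
                 non_estimable = non_est),
            class = "assoc_fit")
}

#' Proportional-odds (cumulative-logit) focus coefficient
#'
#' Fits `logit P(Y <= k | x) = zeta_k - beta * x` by maximum likelihood
#' (via [MASS::polr()] with a tight convergence tolerance) to a 2 x K table
#' of ordered categories, with `x = 1` for the focus group.  For K = 2 the
#' model is saturated and the closed-form binary log odds ratio is returned.
#'
#' @param counts 2 x K matrix, columns in increasing category order.
#' @return An `"assoc_fit"` list with `coefficients` (the focus `beta`),
#'   `thresholds` (the K - 1 cutpoints, strictly increasing),
#'   `standard_errors` (named: beta then thresholds), `p_values` (for beta).
#' @export
proportional_odds <- function(counts) {
  .check_table(counts)
  K <- ncol(counts)
  lv <- colnames(counts) %||% paste0("level", seq_len(K))
  if (K == 2L) {
    # one threshold: the saturated cumulative model is the binary logit of
    # category 2 vs 1 (beta flips sign relative to P(Y <= 1))
    bl <- binary_logit(counts, outcome_level = 2L)
    zeta <- log(counts[1, 1] / counts[1, 2])
    return(structure(list(model = "proportional_odds",
                          coefficients = setNames(unname(bl$coefficients), "focus"),
                          thresholds = setNames(zeta, paste(lv[1], lv[2], sep = "|")),
                          standard_errors = c(focus = unname(bl$standard_errors)),
                          p_values = c(focus = unname(bl$p_values))),
                     class = "assoc_fit"))
  }
  long <- data.frame(
    cat = factor(rep(lv, 2), levels = lv, ordered = TRUE),
    focus = rep(c(0, 1), each = K),
    n = c(counts[1, ], counts[2, ]))
  long <- long[long$n > 0, ]
  fit <- MASS::polr(cat ~ focus, data = long, weights = long$n, Hess = TRUE,
                    control = list(reltol = 1e-12, maxit = 500))
  if (fit$convergence != 0) stop("proportional-odds fit did not converge")
  beta <- coef(fit)[["focus"]]
  zeta <- fit$zeta
  if (any(diff(zeta) <= 0)) stop("fitted thresholds not increasing")
  se <- sqrt(diag(vcov(fit)))
  structure(list(model = "proportional_odds",
                 coefficients = c(focus = beta),
                 thresholds = zeta,
                 standard_errors = se,
                 p_values = c(focus = 2 * pnorm(-abs(beta / se[["focus"]])))),
            class = "assoc_fit")
}

#' Two-group comparison of a continuous variable
#'
#' Mean difference (focus minus reference) with the standard two-sample
#' linear-model inference, the descriptive companion used for continuous
#' variables such as age.
#'
#' @param values numeric vector.
#' @param group 0/1 focus indicator.
#' @return An `"assoc_fit"` list with the mean-difference coefficient.
#' @export
group_mean_diff <- function(values, group) {
  stopifnot(length(values) == length(group), all(group %in% 0:1))
  fit <- stats::lm(values ~ group)
  sm <- summary(fit)$coefficients
  structure(list(model = "linear",
                 coefficients = c(focus = unname(sm["group", 1])),
                 standard_errors = c(focus = unname(sm["group", 2])),
                 p_values = c(focus = unname(sm["group", 4]))),
            class = "assoc_fit")
}

#' @export
print.assoc_fit <- function(x, digits = 6, ...) {
  cat(x$model, if (!is.null(x$reference))
    paste0(" (reference: ", x$reference, ")"), "\n", sep = "")
  tab <- cbind(Estimate = x$coefficients,
               SE = x$standard_errors[names(x$coefficients)])
  print(round(tab, digits))
  if (!is.null(x$thresholds)) {
    cat("thresholds:\n")
    print(round(x$thresholds, digits))
  }
  if (length(x$non_estimable))
    cat("non-estimable (zero cell):", paste(x$non_estimable, collapse = ", "), "\n")
  invisible(x)
}

#' Packaged endometrial-cancer cohort cross-tabulations
#'
#' Race-by-level contingency tables for the descriptive cohort comparisons
#' (age quartiles, grade, stage, surgery, chemotherapy, insurance, marital
#' status, histology), shipped as a plain-text fixture.  Rows are the focus
#' groups (WNH then BNH).  The surgery table's BNH row is flagged
#' inconsistent in the fixture (it duplicates the chemotherapy row); see the
#' fixture file's comment lines.
#'
#' @return named list of 2 x K integer matrices with a `flags` attribute.
#' @export
ec_cohort_tables <- function() {
  path <- system.file("extdata", "ec_cohort_tables.csv", package = "prismsurv")
  raw <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  out <- lapply(split(raw, raw$variable), function(df) {
    lv <- unique(df$level)
    m <- matrix(0L, nrow = 2, ncol = length(lv),
                dimnames = list(c("WNH", "BNH"), lv))
    for (i in seq_len(nrow(df)))
      m[df$group[i], df$level[i]] <- as.integer(df$count[i])
    m
  })
  attr(out, "flags") <- c(
    surgery = "BNH surgery row duplicates the chemo row in the source table; treat as inconsistent")
  out
}
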