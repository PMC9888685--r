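#' Define a generative truth for synthetic cohorts
#'
#' Describes a multilevel survival-moderation data-generating process with a
#' known tree structure: log event time
#' `T = theta0_l + (theta1_l + theta2_l * w) * x + e` where leaf `l` is
#' determined by individual covariates z, `w` is a tract-level contextual
#' value (constant within tract) and `e` is Gaussian noise.  Censoring is
#' random (independent of x, z, w): the censoring time is exponential on the
#' day scale with its rate calibrated so the marginal censoring probability
#' matches `censor_rate`.
#'
#' The default truth is the package's reference study condition: two leaves
#' split on the continuous covariate `z1` at 0.5, n = 2000 records over
#' M = 100 tracts with sizes drawn multinomially under a Dirichlet(1) prior
#' (so sparse tracts occur), a *standardized* contextual variable
#' `w ~ Normal(0, 1)` (area-level determinants are standardized before
#' modelling, which keeps the focus main effect and its contextual
#' interaction separately identifiable), noise sd 0.25 and a 20% censoring
#' rate.
#'
#' @param leaves list of leaves, each `list(condition =, theta0 =, theta1 =,
#'   theta2 =)`; `condition` is an R expression string in the covariates
#'   (e.g. `"z1 < 0.5"`).  Conditions must partition the covariate space.
#' @param covariates list describing covariate generation, named by
#'   covariate.  Continuous: `list(scale = "continuous", min =, max =)`
#'   (uniform).  Nominal: `list(scale = "nominal", levels =, probs =)`.
#' @param noise_sd standard deviation of the log-scale error, >= 0.
#' @param censor_rate target censoring fraction in `[0, 1)`.
#' @param M number of tracts.
#' @param w_mean,w_sd mean and sd of the tract-level contextual variable.
#' @param n total number of records.
#' @param focus_prevalence P(x = 1), a constant or a function of w.
#' @return list of class `"prism_truth"`.
#' @export
prism_truth <- function(leaves = NULL,
                        covariates = NULL,
                        noise_sd = 0.25,
                        censor_rate = 0.2,
                        M = 100,
                        w_mean = 0, w_sd = 1,
                        n = 2000,
                        focus_prevalence = 0.5) {
  if (is.null(leaves))
    leaves <- list(
      list(condition = "z1 < 0.5",  theta0 = 1.0, theta1 = -0.6, theta2 = 0.15),
      list(condition = "z1 >= 0.5", theta0 = 2.0, theta1 = 0.3,  theta2 = -0.12))
  if (is.null(covariates))
    covariates <- list(
      z1 = list(scale = "continuous", min = 0, max = 1),
      z2 = list(scale = "continuous", min = 0, max = 1),
      z3 = list(scale = "continuous", min = 0, max = 1))
  stopifnot(noise_sd >= 0, censor_rate >= 0, censor_rate < 1,
            M >= 1, n >= 2)
  structure(list(leaves = leaves, covariates = covariates,
                 noise_sd = noise_sd, censor_rate = censor_rate,
                 M = M, w_mean = w_mean, w_sd = w_sd, n = n,
                 focus_prevalence = focus_prevalence),
            class = "prism_truth")
}

#' Simulate a multilevel right-censored cohort
#'
#' Draws a cohort from a [prism_truth()] process.  Tract sizes are
#' multinomial with Dirichlet(1) probabilities; each tract receives one
#' contextual value `w ~ Normal(w_mean, w_sd)` (standardized by default); covariates and the focus
#' indicator are drawn per record; the log event time follows the leaf
#' model; censoring is exponential on the day scale with the rate solved
#' numerically so the marginal censoring probability equals `censor_rate`.
#'
#' @param truth a [prism_truth()] object (default: the reference truth).
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return A [prism_data()] object with columns `time_days`, `event`,
#'   `race`, the covariates, `tract_id` and contextual `w`.
#' @export
simulate_prism_data <- function(truth = prism_truth(), seed = 1) {
  stopifnot(inherits(truth, "prism_truth"))
  with_seed(seed, {
    n <- truth$n; M <- truth$M
    p <- rgamma(M, 1); p <- p / sum(p)            # Dirichlet(1) tract profile
    sizes <- as.vector(stats::rmultinom(1, n, p))
    tract <- rep(sprintf("t%04d", seq_len(M)), sizes)
    w_tract <- rnorm(M, truth$w_mean, truth$w_sd)
    w <- rep(w_tract, sizes)

    Z <- list()
    for (v in names(truth$covariates)) {
      cv <- truth$covariates[[v]]
      if (cv$scale == "continuous") {
        Z[[v]] <- runif(n, cv$min %||% 0, cv$max %||% 1)
      } else {
        Z[[v]] <- factor(sample(cv$levels, n, replace = TRUE,
                                prob = cv$probs %||% NULL),
                         levels = cv$levels,
                         ordered = identical(cv$scale, "ordinal"))
      }
    }
    Z <- as.data.frame(Z, stringsAsFactors = FALSE)

    fp <- truth$focus_prevalence
    pr <- if (is.function(fp)) fp(w) else rep(fp, n)
    x <- rbinom(n, 1, pr)

    leaf_of <- rep(NA_integer_, n)
    for (l in seq_along(truth$leaves)) {
      hit <- eval(parse(text = truth$leaves[[l]]$condition), envir = Z)
      clash <- hit & !is.na(leaf_of)
      if (any(clash))
        stop("leaf conditions overlap (leaves ",
             leaf_of[which(clash)[1]], " and ", l, ")")
      leaf_of[hit] <- l
    }
    if (anyNA(leaf_of))
      stop("leaf conditions do not cover the covariate space")
    counts <- tabulate(leaf_of, length(truth$leaves))
    if (any(counts == 0))
      stop("unreachable leaf (zero records matched condition ",
           which(counts == 0)[1], ")")

    th <- vapply(truth$leaves, function(l)
      c(l$theta0, l$theta1, l$theta2), numeric(3))
    Tlog <- th[1, leaf_of] + (th[2, leaf_of] + th[3, leaf_of] * w) * x +
      rnorm(n, 0, truth$noise_sd)

    if (truth$censor_rate <= 0) {
      y <- Tlog; delta <- rep(1L, n)
    } else {
      # P(censored) = E[1 - exp(-lambda * exp(T))]; monotone in lambda.
      et <- exp(Tlog)
      fr <- function(loglam) mean(1 - exp(-exp(loglam) * et)) - truth$censor_rate
      loglam <- uniroot(fr, lower = -40, upper = 40, tol = 1e-10)$root
      Clog <- log(rexp(n, rate = exp(loglam)))
      delta <- as.integer(Tlog <= Clog)
      y <- pmin(Tlog, Clog)
    }

    df <- data.frame(time_days = exp(y), event = delta, race = x,
                     tract_id = tract, w = w, stringsAsFactors = FALSE)
    df <- cbind(df, Z)
    prism_data(df, time = "time_days", event = "event", focus = "race",
               tract = "tract_id", covariates = names(Z), contextual = "w")
  })
}

#' Simulate a null cohort with no focus effect
#'
#' Same generative scaffolding as [simulate_prism_data()] but with
#' `theta1 = theta2 = 0` everywhere (no disparity, no moderation), for
#' size/type-I-style checks.
#'
#' @param n total records.
#' @param M number of tracts.
#' @param seed integer seed.
#' @param noise_sd,censor_rate noise and censoring level.
#' @return A [prism_data()] object.
#' @export
simulate_prism_null <- function(n = 2000, M = 100, seed = 1,
                                noise_sd = 0.25, censor_rate = 0.2) {
  tr <- prism_truth(
    leaves = list(list(condition = "TRUE", theta0 = 1.5,
                       theta1 = 0, theta2 = 0)),
    noise_sd = noise_sd, censor_rate = censor_rate, M = M, n = n)
  simulate_prism_data(tr, seed = seed)
}

#' Read a generative truth from a YAML configuration
#'
#' @param path YAML file with the [prism_truth()] fields (`leaves`,
#'   `covariates`, `noise_sd`, `censor_rate`, `M`, `w_mean`, `w_sd`, `n`,
#'   `focus_prevalence`).
#' @return A [prism_truth()] object.
#' @export
read_prism_truth <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("read_prism_truth() requires the 'yaml' package")
  cfg <- yaml::yaml.load_file(path)
  # YAML 1.1 reads a bare `n` key as boolean FALSE; accept either spelling
  if ("FALSE" %in% names(cfg)) {
    cfg$n <- cfg[["FALSE"]]
    cfg[["FALSE"]] <- NULL
  }
  do.call(prism_truth, cfg)
}
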