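# Small fully observed dataset with an obvious split on z1.
hand_ds <- function() {
  df <- data.frame(
    time_days = exp(c(1.0, 1.2, 0.9, 1.1, 1.3, 0.8, 2.0, 2.2, 2.4, 1.9, 2.1, 2.3)),
    event = 1,
    race = rep(0:1, 6),
    tract_id = rep(c("a", "b", "c"), 4),
    z1 = c(rep(0, 6), rep(1, 6)),
    z2 = c(0.1, 0.9, 0.4, 0.6, 0.2, 0.8, 0.3, 0.7, 0.5, 0.15, 0.85, 0.45))
  prism_data(df, covariates = c("z1", "z2"))
}

test_that("evaluate_split reproduces the plain RSS decomposition when uncensored", {
  ds <- hand_ds()
  # no censoring: Stute weights are 1/n, imputed residuals equal raw ones,
  # so delta RSS is the classical decomposition of per-node OLS sums
  rss_of <- function(sel) {
    f <- lm(ds$y[sel] ~ ds$x[sel])
    sum(resid(f)^2)
  }
  all_idx <- rep(TRUE, ds$n)
  for (s in c(0.5)) {
    want <- rss_of(all_idx) - rss_of(ds$Z$z1 < s) - rss_of(ds$Z$z1 >= s)
    got <- evaluate_split(ds, "z1", s = s, min_node = 2)
    expect_equal(got, want, tolerance = 1e-10)
  }
  # an inadmissible candidate returns NA rather than erroring
  expect_true(is.na(evaluate_split(ds, "z2", s = 0.12, min_node = 2)))
})

test_that("best_split equals exhaustive enumeration on random instances", {
  set.seed(202)
  for (rep in 1:8) {
    ds <- simulate_prism_data(
      prism_truth(n = 50, M = 6, noise_sd = 0.4, censor_rate = 0.25),
      seed = 300 + rep)
    for (ctx in list(NULL, "w")) {
      got <- best_split(ds, contextual = ctx, min_node = 10)
      want <- bf_best_split(ds, contextual = ctx, min_node = 10)
      if (is.null(want)) {
        expect_null(got)
      } else {
        expect_equal(got$variable, want$variable)
        expect_equal(got$s, want$s, tolerance = 1e-12)
        expect_equal(got$delta_rss, want$delta_rss, tolerance = 1e-8)
      }
    }
  }
})

test_that("exclusion criteria veto splits isolating one focus group's events", {
  # all x = 1 events sit at z1 < 0.5: any split on z1 starves a daughter
  df <- data.frame(
    time_days = exp(rnorm(40, 1)),
    event = rep(c(1, 0), 20),
    race = rep(0:1, each = 20),
    tract_id = rep(c("a", "b"), 20),
    z1 = c(rep(0.1, 20), rep(0.9, 20)))
  ds <- prism_data(df, covariates = "z1")
  expect_null(best_split(ds, min_node = 5))
})

test_that("exact criterion ties break to the earlier variable", {
  ds <- hand_ds()
  df <- as.data.frame(ds)
  df$z0 <- df$z1  # duplicate placed *after* z1 in the covariate list
  ds2 <- prism_data(df, covariates = c("z1", "z0"))
  b <- best_split(ds2, min_node = 2)
  expect_equal(b$variable, "z1")
})

test_that("grow stops at the root under an unachievable cp and predicts flat", {
  ds <- simulate_prism_data(prism_truth(n = 300, M = 20), seed = 17)
  fit <- prism(ds, contextual = "w", cp = 1e9)
  expect_length(terminal_nodes(fit), 1)
  th <- fit$nodes[[1]]$model$theta
  pred <- predict(fit, ds)
  expect_equal(pred, th[1] + th[2] * ds$x + th[3] * ds$x * ds$W$w,
               tolerance = 1e-12)
})

test_that("grow matches the brute-force recursive argmax on small instances", {
  set.seed(909)
  for (rep in 1:4) {
    ds <- simulate_prism_data(
      prism_truth(n = 50, M = 6, noise_sd = 0.3, censor_rate = 0.2),
      seed = 400 + rep)
    fit <- prism(ds, min_node = 10, cp = 0.01)
    walk <- function(id) {  # depth-first pre-order, matching the oracle
      nd <- fit$nodes[[id]]
      if (is.null(nd$rule)) return(list())
      c(list(list(variable = nd$rule$variable, s = nd$rule$s)),
        walk(nd$children[1]), walk(nd$children[2]))
    }
    got <- walk(1L)
    want <- bf_grow_splits(ds, NULL, cp = 0.01, min_node = 10)
    expect_equal(length(got), length(want))
    if (length(want)) {
      expect_equal(vapply(got, `[[`, character(1), "variable"),
                   vapply(want, `[[`, character(1), "variable"))
      expect_equal(vapply(got, `[[`, numeric(1), "s"),
                   vapply(want, `[[`, numeric(1), "s"), tolerance = 1e-12)
    }
  }
})

test_that("terminal nodes partition the sample and satisfy the exclusions", {
  ds <- simulate_prism_data(prism_truth(n = 800, M = 40), seed = 23)
  fit <- prism(ds, contextual = "w")
  tn <- terminal_nodes(fit)
  members <- unlist(lapply(fit$nodes[tn], `[[`, "members"))
  expect_equal(sort(members), seq_len(ds$n))
  n_splits <- sum(vapply(fit$nodes, function(nd) !is.null(nd$rule), logical(1)))
  expect_equal(length(tn), n_splits + 1)
  for (id in tn) {
    m <- fit$nodes[[id]]$members
    expect_gte(length(m), fit$config$min_node)
    for (g in 0:1) {
      ev <- m[ds$delta[m] == 1 & ds$x[m] == g]
      expect_gte(length(ev), fit$config$min_events_per_group)
      expect_gte(length(unique(ds$tract[ev])), 2)
    }
  }
})

test_that("the HPRISM node model never fits worse than PRISM on one node", {
  set.seed(66)
  for (rep in 1:10) {
    ds <- simulate_prism_data(prism_truth(n = 200, M = 15), seed = 500 + rep)
    fp <- fit_node_model(ds$y, ds$delta, ds$x)
    fh <- fit_node_model(ds$y, ds$delta, ds$x, ds$W$w)
    expect_lte(fh$rss, fp$rss + 1e-10)
  }
})

test_that("prediction evaluates the terminal model and reuses training routing", {
  ds <- simulate_prism_data(prism_truth(n = 600, M = 30), seed = 29)
  fit <- prism(ds, contextual = "w")
  nid <- predict(fit, ds, type = "node")
  node_of <- integer(ds$n)
  for (id in terminal_nodes(fit)) node_of[fit$nodes[[id]]$members] <- id
  expect_equal(nid, node_of)

  # arithmetic at a known node: theta = (1, 0.2, 0.01), x = 1, w = 50
  expect_equal(node_disparity(0.2, 0.01, 50) + 1, 1.7)
  pred <- predict(fit, ds)
  th <- coef(fit)
  one <- which(nid == terminal_nodes(fit)[1])[1]
  k <- as.character(nid[one])
  expect_equal(pred[one],
               th[k, "theta0"] + th[k, "theta1"] * ds$x[one] +
                 th[k, "theta2"] * ds$x[one] * ds$W$w[one],
               tolerance = 1e-12)
})

test_that("unseen nominal levels fall back to the larger daughter with a warning", {
  set.seed(77)
  n <- 200
  df <- data.frame(
    time_days = exp(rnorm(n, 1 + 0.8 * (rep(1:4, n / 4) > 2))),
    event = rbinom(n, 1, 0.85),
    race = rbinom(n, 1, 0.5),
    tract_id = sample(c("a", "b", "c", "d"), n, replace = TRUE),
    g = factor(sample(c("p", "q", "r", "s"), n, replace = TRUE)))
  df$time_days <- df$time_days * ifelse(df$g %in% c("p", "q"), 0.3, 3)
  ds <- prism_data(df, covariates = "g")
  fit <- prism(ds, min_node = 10)
  expect_gt(length(terminal_nodes(fit)), 1)
  new <- as.data.frame(ds)[1:3, ]
  new$g <- factor("zz")
  expect_warning(p <- predict(fit, new), "unseen")
  expect_true(all(is.finite(p)))
})

test_that("growing is deterministic and the parent-residual variant runs", {
  ds <- simulate_prism_data(prism_truth(n = 400, M = 25), seed = 31)
  f1 <- prism(ds, contextual = "w")
  f2 <- prism(ds, contextual = "w")
  expect_equal(coef(f1), coef(f2))
  f3 <- prism(ds, contextual = "w", daughter_residuals = "parent")
  expect_s3_class(f3, "prism")
})

test_that("the log-rank split statistic matches hand arithmetic and is symmetric", {
  # daughter L: times 1, 2, 3, 4 with groups 0, 1, 0, 1, all events.
  # log-rank O-E for group 1: at t=1 E=1/2; t=2 E=1/3... hand chi-square
  # computed from the standard 2x2 tables per event time.
  df <- data.frame(
    time_days = c(1, 2, 3, 4, 1, 2, 3, 4),
    event = 1,
    race = c(0, 1, 0, 1, 0, 0, 1, 1),
    tract_id = "a",
    z1 = rep(c(0, 1), each = 4))
  ds <- prism_data(df, covariates = "z1")
  got <- logrank_split_stat(ds, "z1", s = 0.5)
  hand_lr <- function(time, grp) {
    ts <- sort(unique(time))
    O <- E <- V <- 0
    for (t in ts) {
      at_risk <- time >= t
      d <- sum(time == t)
      n1 <- sum(at_risk & grp == 1); ntot <- sum(at_risk)
      O <- O + sum(time == t & grp == 1)
      E <- E + d * n1 / ntot
      if (ntot > 1)
        V <- V + d * (n1 / ntot) * (1 - n1 / ntot) * (ntot - d) / (ntot - 1)
    }
    (O - E)^2 / V
  }
  want <- abs(hand_lr(1:4, c(0, 1, 0, 1)) - hand_lr(1:4, c(0, 0, 1, 1)))
  expect_equal(got, want, tolerance = 1e-10)

  # mirroring the partition only flips left/right: statistic unchanged
  df$z1 <- 1 - df$z1
  ds2 <- prism_data(df, covariates = "z1")
  expect_equal(logrank_split_stat(ds2, "z1", s = 0.5), got, tolerance = 1e-12)

  # identical survival experience in both daughters: statistic 0
  expect_equal(abs(hand_lr(1:4, c(0, 1, 0, 1)) - hand_lr(1:4, c(0, 1, 0, 1))), 0)
})

test_that("log-rank criterion trees grow and obey the same exclusions", {
  ds <- simulate_prism_data(prism_truth(n = 400, M = 25), seed = 37)
  fit <- prism(ds, criterion = "logrank", min_node = 30)
  expect_s3_class(fit, "prism")
  for (id in terminal_nodes(fit)) {
    m <- fit$nodes[[id]]$members
    for (g in 0:1)
      expect_gte(sum(ds$delta[m] == 1 & ds$x[m] == g), 1)
  }
})

test_that("trees serialize to JSON", {
  skip_if_not_installed("jsonlite")
  ds <- simulate_prism_data(prism_truth(n = 300, M = 20), seed = 41)
  fit <- prism(ds, contextual = "w")
  js <- jsonlite::fromJSON(prism_to_json(fit), simplifyVector = FALSE)
  expect_equal(length(js$nodes), length(fit$nodes))
  expect_equal(js$mode, "hprism")
})
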