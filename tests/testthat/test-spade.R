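# Minimal hand-built two-leaf tree for closed-form checks.
toy_tree <- function(d_nodes = c(1.0, 2.0), members = list(1:4, 5:8),
                     contextual = NULL) {
  mk <- function(id, parent, rule, th, m) {
    list(id = id, parent = parent, depth = if (id == 1) 0L else 1L,
         children = if (!is.null(rule)) c(2L, 3L) else NULL, rule = rule,
         model = list(ok = TRUE, theta = th, used_w = FALSE,
                      rss = 0, irss = 0, n = length(m), n_events = length(m),
                      mean_log_surv = 0),
         members = m)
  }
  rule <- list(variable = "z1", kind = "threshold", s = 0.5)
  structure(list(
    nodes = list(
      mk(1L, NA_integer_, rule, c(0, 0, 0), 1:8),
      mk(2L, 1L, NULL, c(0, d_nodes[1], 0), members[[1]]),
      mk(3L, 1L, NULL, c(0, d_nodes[2], 0), members[[2]])),
    config = list(contextual = contextual),
    mode = if (is.null(contextual)) "prism" else "hprism",
    zinfo = list(z1 = list(name = "z1", scale = "continuous"))),
    class = "prism")
}

toy_data <- function(tracts) {
  df <- data.frame(time_days = exp(seq_len(length(tracts))), event = 1,
                   race = rep(0:1, length.out = length(tracts)),
                   tract_id = tracts,
                   z1 = seq(0, 1, length.out = length(tracts)))
  prism_data(df, covariates = "z1")
}

test_that("the tract estimate is the eta-weighted average of node disparities", {
  # tract 'm': 3 records in node 2 (d = 1.0), 1 record in node 3 (d = 2.0)
  tracts <- c("m", "m", "m", "o", "m", "o", "o", "o")
  tree <- toy_tree(members = list(c(1, 2, 3, 4), c(5, 6, 7, 8)))
  sp <- spade(tree, toy_data(tracts))
  est <- sp$estimates
  expect_equal(est$d_hat[est$tract_id == "m"], 0.75 * 1.0 + 0.25 * 2.0)
  eta_m <- sp$eta[sp$eta$tract_id == "m", ]
  expect_equal(sum(eta_m$eta), 1)
  expect_equal(est$n_contributing[est$tract_id == "m"], 4L)
})

test_that("eta weights sum to one per tract on fitted trees", {
  for (s in 1:3) {
    ds <- simulate_prism_data(prism_truth(n = 400, M = 30), seed = 80 + s)
    fit <- prism(ds, contextual = "w")
    sp <- spade(fit)
    sums <- tapply(sp$eta$eta, sp$eta$tract_id, sum)
    expect_equal(as.vector(sums), rep(1, length(sums)), tolerance = 1e-12)
    expect_setequal(sp$estimates$tract_id, levels(ds$tract))
  }
})

test_that("a root-only tree gives the closed-form disparity at each tract", {
  ds <- simulate_prism_data(prism_truth(n = 300, M = 25), seed = 85)
  fit <- prism(ds, contextual = "w", cp = 1e9)
  th <- fit$nodes[[1]]$model$theta
  sp <- spade(fit)
  w_m <- tapply(ds$W$w, ds$tract, function(u) u[1])
  expect_equal(sp$estimates$d_hat,
               as.numeric(th[2] + th[3] * w_m[sp$estimates$tract_id]),
               tolerance = 1e-12)
})

test_that("robust z-scores standardize by median and scaled MAD", {
  z <- robust_z(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1) / 1.4826, tolerance = 1e-12)
  v <- c(4, 8, 15, 16, 23, 42)
  expect_equal(median(robust_z(v)), 0, tolerance = 1e-12)
  expect_equal(robust_z(3 * v + 7), robust_z(v), tolerance = 1e-12)
  expect_error(robust_z(rep(2, 5)), "degenerate|median absolute")
  expect_error(robust_z(c(1, 1, 1, 1, 9)), "median absolute")
})

test_that("composite SPADE is the per-tract sum", {
  tracts <- c("m", "m", "m", "o", "m", "o", "o", "o")
  dat <- toy_data(tracts)
  a <- spade(toy_tree(c(0.3, 0.3)), dat)   # flat: every tract 0.3
  b <- spade(toy_tree(c(-0.1, -0.1)), dat)
  comp <- composite_spade(a, b)
  expect_equal(comp$estimates$d_hat, rep(0.2, 2), tolerance = 1e-12)
  single <- composite_spade(a)
  expect_equal(single$estimates$d_hat, a$estimates$d_hat)
  trip <- composite_spade(list(a, a, a))
  expect_equal(trip$estimates$d_hat, 3 * a$estimates$d_hat, tolerance = 1e-12)
  expect_error(composite_spade(list()), "no SPADE")

  # linearity on fitted trees with random data
  ds <- simulate_prism_data(prism_truth(n = 300, M = 20), seed = 87)
  fit <- prism(ds, contextual = "w")
  s1 <- spade(fit)
  s2 <- composite_spade(s1, s1)
  expect_equal(s2$estimates$d_hat, 2 * s1$estimates$d_hat, tolerance = 1e-12)
})

test_that("sparse tracts borrow strength where the direct estimator fails", {
  ds <- simulate_prism_data(
    prism_truth(n = 1500, M = 120, censor_rate = 0.35), seed = 90)
  fit <- prism(ds, contextual = "w")
  sp <- spade(fit)
  direct <- direct_tract_disparity(ds)
  sparse <- names(ds$n_m)[ds$n_m <= 2]
  expect_gt(length(sparse), 0)
  expect_true(all(sparse %in% sp$estimates$tract_id))
  expect_true(all(is.finite(sp$estimates$d_hat)))
  expect_true(any(!direct$defined[direct$tract_id %in% sparse]))
  expect_gt(sum(sp$estimates$tract_id %in% ds$tract),
            sum(direct$defined))  # many more tracts covered by SPADE
})

test_that("moderation profiles expose slopes and the parallelism flag", {
  ds <- simulate_prism_data(prism_truth(n = 600, M = 40), seed = 92)
  fit <- prism(ds, contextual = "w")
  prof <- moderation_profile(fit, w_grid = c(-1, 0, 1))
  tn <- terminal_nodes(fit)
  th <- coef(fit)
  for (i in seq_along(tn)) {
    sel <- prof$node == tn[i]
    expect_equal(prof$d[sel],
                 th[i, "theta1"] + th[i, "theta2"] * c(-1, 0, 1),
                 tolerance = 1e-12)
  }
  expect_false(attr(prof, "nearly_parallel"))  # truth has distinct slopes

  flat <- toy_tree(c(0.5, 0.5), contextual = "w")
  # equal (zero) slopes in both leaves: parallel at any positive tolerance
  dftoy <- data.frame(time_days = exp(1:8), event = 1,
                      race = rep(0:1, 4), tract_id = rep(c("m", "o"), 4),
                      z1 = seq(0, 1, length.out = 8), w = rep(c(0, 1), 4))
  flat$data <- prism_data(dftoy, covariates = "z1", contextual = "w")
  prof2 <- moderation_profile(flat, w_grid = 0:1, parallel_tol = 1e-9)
  expect_true(attr(prof2, "nearly_parallel"))
  expect_error(moderation_profile(prism(ds)), "HPRISM")
})
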