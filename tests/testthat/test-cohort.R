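tabs <- ec_cohort_tables()

test_that("the packaged cross-tabulations load with their structure intact", {
  expect_setequal(names(tabs),
                  c("age", "grade", "stage", "surgery", "chemo",
                    "insurance", "marital", "histology"))
  expect_equal(dim(tabs$insurance), c(2, 6))
  expect_equal(rownames(tabs$grade), c("WNH", "BNH"))
  expect_equal(sum(tabs$grade), 13506)  # full cohort size
  expect_match(attr(tabs, "flags")["surgery"], "inconsistent")
})

test_that("the homogeneity chi-square matches hand arithmetic", {
  t0 <- rbind(c(10, 20), c(20, 10))
  out <- chisq_homogeneity(t0)
  expect_equal(out$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(out$df, 1)
  expect_equal(chisq_homogeneity(t0[2:1, ])$statistic, out$statistic)

  same <- rbind(c(30, 60), c(10, 20))  # identical row proportions
  out2 <- chisq_homogeneity(same)
  expect_equal(out2$statistic, 0, tolerance = 1e-12)
  expect_equal(out2$p_value, 1, tolerance = 1e-12)

  # brute-force sum (O-E)^2/E on a random table
  set.seed(5)
  tt <- matrix(rpois(8, 30) + 1, 2, 4)
  E <- outer(rowSums(tt), colSums(tt)) / sum(tt)
  expect_equal(chisq_homogeneity(tt)$statistic, sum((tt - E)^2 / E),
               tolerance = 1e-10)
  expect_error(chisq_homogeneity(rbind(c(0, 0), c(1, 2))), "marginal")
})

test_that("Fisher p-values agree with full enumeration", {
  t1 <- rbind(c(1, 9), c(9, 1))
  # enumeration oracle: all 2x2 tables with these margins
  enum_p <- local({
    r1 <- 10; c1 <- 10; n <- 20
    probs <- vapply(0:10, function(a)
      dhyper(a, c1, n - c1, r1), numeric(1))
    sum(probs[probs <= dhyper(1, c1, n - c1, r1) * (1 + 1e-7)])
  })
  expect_equal(fisher_exact(t1)$p_value, enum_p, tolerance = 1e-10)
  expect_equal(fisher_exact(rbind(c(0, 0), c(3, 4)))$p_value, 1)

  # 2x3 Monte Carlo vs enumeration with fixed margins
  t2 <- rbind(c(3, 1, 4), c(2, 6, 2))
  enum3 <- local({
    rs <- rowSums(t2); cs <- colSums(t2)
    p_obs <- 1
    dens <- function(m) {
      # fixed-margin multivariate hypergeometric density
      exp(sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(sum(rs)) -
            sum(lfactorial(m)))
    }
    p0 <- dens(t2)
    tot <- 0
    for (a in 0:min(rs[1], cs[1])) for (b in 0:(rs[1] - a)) {
      m <- rbind(c(a, b, rs[1] - a - b), c(cs[1] - a, cs[2] - b,
                                           cs[3] - (rs[1] - a - b)))
      if (any(m < 0)) next
      if (dens(m) <= p0 * (1 + 1e-7)) tot <- tot + dens(m)
    }
    tot
  })
  mc <- fisher_exact(t2, mc_reps = 1e5, seed = 2)
  expect_equal(mc$method, "monte carlo")
  expect_lt(abs(mc$p_value - enum3), 0.01)
})

test_that("the binary logit reproduces the published chemotherapy contrast", {
  fit <- binary_logit(tabs$chemo, outcome_level = "No chemo")
  expect_equal(unname(fit$coefficients), -0.520425, tolerance = 1e-6)
  expect_equal(unname(fit$standard_errors), 0.066117, tolerance = 1e-5)

  same <- rbind(c(30, 60), c(10, 20))
  expect_equal(unname(binary_logit(same, 2)$coefficients), 0, tolerance = 1e-12)
  t2 <- rbind(c(12, 34), c(9, 41))
  expect_equal(unname(binary_logit(t2, 1)$coefficients),
               -unname(binary_logit(t2, 2)$coefficients), tolerance = 1e-12)
  expect_error(binary_logit(rbind(c(0, 5), c(2, 3)), 1), "zero cell")
})

test_that("multinomial fits reproduce the published insurance and marital contrasts", {
  ins <- multinomial_logit(tabs$insurance, reference = "Insured, NOS")
  expect_equal(unname(ins$coefficients["Medicaid"]), 1.525722, tolerance = 1e-4)
  expect_equal(unname(ins$coefficients["Not insured"]), 1.072292, tolerance = 1e-4)
  expect_equal(unname(ins$standard_errors["Medicaid"]), 0.185008, tolerance = 1e-3)

  mar <- multinomial_logit(tabs$marital, reference = "Divorced")
  expect_equal(unname(mar$coefficients["Married"]), -0.601614, tolerance = 1e-4)
  expect_equal(unname(mar$coefficients["Separated"]), 0.996007, tolerance = 1e-4)
  expect_match(mar$non_estimable, "Unmarried", all = FALSE)

  his <- multinomial_logit(tabs$histology, reference = "Carcinosarcoma")
  expect_equal(unname(his$coefficients["Endometrioid Adenocarcinoma"]),
               -1.115089, tolerance = 1e-4)

  prop <- rbind(c(10, 20, 40), c(5, 10, 20))  # proportional rows
  fitp <- multinomial_logit(prop, reference = 1)
  expect_true(all(abs(fitp$coefficients) < 1e-3))
})

test_that("multinomial ML equals the closed-form log odds ratios", {
  set.seed(13)
  for (rep in 1:10) {
    K <- sample(3:5, 1)
    tt <- matrix(rpois(2 * K, 80) + 5, nrow = 2)
    colnames(tt) <- paste0("c", seq_len(K))
    fit <- multinomial_logit(tt, reference = 1)
    expect_equal(unname(fit$coefficients), unname(mlogit_oracle(tt, 1)),
                 tolerance = 1e-3)
  }
})

test_that("the proportional-odds fits reproduce the grade and stage contrasts", {
  gr <- proportional_odds(tabs$grade)
  expect_equal(unname(gr$coefficients["focus"]), 0.713177, tolerance = 1e-4)
  expect_equal(unname(gr$thresholds["3|4"]), 3.344260, tolerance = 1e-4)
  expect_equal(unname(gr$standard_errors["focus"]), 0.050234, tolerance = 1e-3)
  expect_true(all(diff(gr$thresholds) > 0))

  st <- proportional_odds(tabs$stage)
  expect_equal(unname(st$coefficients["focus"]), 0.478276, tolerance = 1e-4)
  expect_equal(unname(st$thresholds["1|2"]), 0.941912, tolerance = 1e-4)
})

test_that("the two-level ordinal model collapses to the binary logit", {
  tt <- rbind(c(40, 25), c(12, 30))
  colnames(tt) <- c("lo", "hi")
  po <- proportional_odds(tt)
  bl <- binary_logit(tt, outcome_level = "hi")
  expect_equal(unname(po$coefficients), unname(bl$coefficients),
               tolerance = 1e-8)
})

test_that("the continuous two-group comparison matches lm", {
  set.seed(3)
  v <- rnorm(60, 50, 5); g <- rep(0:1, 30)
  v[g == 1] <- v[g == 1] - 2
  fit <- group_mean_diff(v, g)
  ref <- summary(lm(v ~ g))$coefficients
  expect_equal(unname(fit$coefficients), ref["g", 1], tolerance = 1e-12)
  expect_equal(unname(fit$p_values), ref["g", 4], tolerance = 1e-12)
})
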