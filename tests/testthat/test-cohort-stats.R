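test_that("log-rank matches the direct risk-set enumeration oracle", {
  # 6-patient worked example: all events, groups interleaved in time
  df <- tibble::tibble(os_time = c(1, 2, 3, 4, 5, 6),
                       os_event = TRUE,
                       grp = rep(c("A", "B"), each = 3))
  res <- logrank_test(df, group = "grp")
  o <- logrank_oracle(df$os_time, df$os_event, df$grp)
  expect_equal(res$statistic, o, tolerance = 1e-9)
  # identical groups: statistic 0, p = 1
  df2 <- tibble::tibble(os_time = rep(c(1, 2, 3), 2), os_event = TRUE,
                        grp = rep(c("A", "B"), each = 3))
  res2 <- logrank_test(df2, group = "grp")
  expect_equal(res2$statistic, 0, tolerance = 1e-12)
  expect_equal(res2$p, 1)
  # label swap invariance
  df3 <- df; df3$grp <- ifelse(df$grp == "A", "B", "A")
  expect_equal(logrank_test(df3, group = "grp")$statistic, res$statistic)
})

test_that("log-rank has power against a strong planted hazard ratio", {
  hits <- vapply(1:40, function(s) {
    co <- gen_bulk_cohort(bulk_cohort_truth(n = 150, survival_hr = 9,
                                            seed = 400 + s))
    logrank_test(co$clinical, group = "expression_status")$p < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("VIF screening drops collinear covariates and reports them", {
  withr::with_seed(5, {
    n <- 300
    x1 <- rnorm(n)
    x2 <- x1 + rnorm(n, sd = 0.01)   # nearly collinear
    x3 <- rnorm(n)
    t <- rexp(n, exp(0.5 * x1))
  })
  df <- tibble::tibble(os_time = t, os_event = TRUE,
                       x1 = x1, x2 = x2, x3 = x3)
  fit <- cox_ph(df, covariates = c("x1", "x2", "x3"))
  expect_true("x2" %in% fit$dropped$term || "x1" %in% fit$dropped$term)
  expect_false("x3" %in% fit$dropped$term)
  # VIF agrees with the auxiliary-regression oracle for the kept design
  mm <- cbind(x1 = x1, x2 = x2, x3 = x3)
  r2 <- summary(lm(x2 ~ x1 + x3))$r.squared
  expect_equal(unname(fit$vif["x2"]), 1 / (1 - r2), tolerance = 1e-6)
  expect_gt(fit$vif["x2"], 10)
  # a duplicated covariate: one copy is dropped, the fit proceeds
  df$x1b <- df$x1
  fit2 <- cox_ph(df, covariates = c("x1", "x1b"))
  expect_equal(nrow(fit2$dropped), 1)
  expect_true(is.infinite(fit2$dropped$vif) || fit2$dropped$vif > 1e6)
  expect_s3_class(fit2$fit, "coxph")
})

test_that("tidy() on the Cox fit brackets the hazard ratio", {
  co <- gen_bulk_cohort(bulk_cohort_truth(n = 800, seed = 77))
  clin <- co$clinical
  clin$status <- as.integer(clin$expression_status == "positive")
  fit <- cox_ph(clin, covariates = c("status", "age"))
  td <- tidy(fit)
  expect_true(all(td$conf.low < td$hr & td$hr < td$conf.high))
  g <- glance(fit)
  expect_equal(g$n, nrow(clin))
})

test_that("Fisher's exact test equals brute-force enumeration", {
  # the worked example
  tab <- matrix(c(1, 9, 11, 3), 2, byrow = TRUE)
  expect_equal(fisher_exact(tab)$p, fisher_oracle(tab), tolerance = 1e-9)
  # proportional rows and zero margins give p = 1
  expect_equal(fisher_exact(matrix(c(2, 4, 3, 6), 2))$p, 1)
  expect_equal(fisher_exact(matrix(c(0, 0, 5, 7), 2, byrow = TRUE))$p, 1)
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
  # exhaustive sweep over small tables, then random larger ones
  for (tot in c(4, 8, 12)) {
    for (a in 0:tot) for (b in 0:(tot - a)) for (cc in 0:(tot - a - b)) {
      tab <- matrix(c(a, b, cc, tot - a - b - cc), 2, byrow = TRUE)
      expect_equal(fisher_exact(tab)$p, fisher_oracle(tab),
                   tolerance = 1e-9)
    }
  }
  withr::with_seed(10, {
    for (i in 1:200) {
      tab <- matrix(rpois(4, 8), 2)
      expect_equal(fisher_exact(tab)$p, fisher_oracle(tab),
                   tolerance = 1e-9)
    }
  })
})

test_that("Mann-Whitney and Pearson wrappers match their definitions", {
  mw <- mann_whitney(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(mw$U, 12.5)   # midpoint of [0, 25]
  expect_equal(mw$p, 1)
  # exact path on small untied samples agrees with the U definition
  x <- c(1.1, 2.3, 5.2); y <- c(0.4, 3.3, 7.1, 9.0)
  mw2 <- mann_whitney(x, y)
  U_hand <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  expect_equal(mw2$U, U_hand)
  pe <- pearson(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  o <- pearson_oracle(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(pe$r, o$r)
  expect_equal(pe$p, o$p)
})

test_that("BH adjustment follows the step-up formula", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_fdr(p), rep(0.04, 4))   # step-up by hand
  expect_equal(bh_fdr(0.03), 0.03)        # single p unchanged
  withr::with_seed(2, {
    for (i in 1:25) {
      p <- runif(sample(3:40, 1))
      expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
    }
  })
})

test_that("BH is monotone: lowering a raw p never raises any FDR", {
  withr::with_seed(4, {
    for (i in 1:25) {
      p <- runif(20)
      f1 <- bh_fdr(p)
      j <- sample(20, 1)
      p2 <- p; p2[j] <- p2[j] * runif(1)
      f2 <- bh_fdr(p2)
      expect_true(all(f2 <= f1 + 1e-12))
    }
  })
})

test_that("type-I error is controlled at the nominal level", {
  withr::with_seed(6, {
    reps <- 2000
    lr <- mw <- fi <- logical(reps)
    for (i in 1:reps) {
      x <- rnorm(20); y <- rnorm(20)
      mw[i] <- mann_whitney(x, y)$p < 0.05
      t <- rexp(40); g <- rep(c("a", "b"), 20)
      df <- tibble::tibble(os_time = t, os_event = TRUE, g = g)
      lr[i] <- logrank_test(df, group = "g")$p < 0.05
      tab <- matrix(rbinom(4, 15, 0.3), 2)
      fi[i] <- fisher_exact(tab)$p < 0.05
    }
    expect_lte(mean(lr), 0.06)
    expect_lte(mean(mw), 0.06)
    expect_lte(mean(fi), 0.06)   # conservative by discreteness
  })
})

test_that("normality/unimodality wrappers behave per contract", {
  expect_error(normality_unimodality(rnorm(5)), "at least 8")
  res <- normality_unimodality(rep(2, 20))
  expect_equal(res$status, "degenerate")
  expect_true(is.na(res$shapiro_p))
  # Shapiro p is uniform under normality
  withr::with_seed(11, {
    ps <- vapply(1:80, function(i) stats::shapiro.test(rnorm(100))$p.value,
                 numeric(1))
  })
  res_norm <- normality_unimodality(rnorm(100), n_sim = 200, seed = 2)
  expect_gt(res_norm$shapiro_p, 0)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("15q and CDKN2A rules apply their strict cutoffs", {
  expect_true(call_15q_loss(rep(c(TRUE, FALSE), c(60, 40))))
  expect_false(call_15q_loss(rep(c(TRUE, FALSE), c(50, 50)))) # strict
  expect_false(call_15q_loss(rep(FALSE, 10)))
  expect_error(call_15q_loss(logical(0)), "at least one")
  expect_true(call_cdkn2a_homdel(c(-2, -2, 0)))
  expect_false(call_cdkn2a_homdel(c(-2, 0, 0)))
  expect_true(call_cdkn2a_homdel(c(-2, -2, -2)))
  expect_error(call_cdkn2a_homdel(c(-2, -2)), "three")
})

test_that("adjuvant labeling follows the label-or-early-first rule", {
  tx <- tibble::tibble(
    sample_id = c("p1", "p2", "p3", "p4", "p5"),
    regimen_label = c("ADJUVANT", NA, NA, "OTHER", NA),
    drug = "LOMUSTINE",
    start_day = c(500, 200, 400, 100, NA),
    order_index = c(2L, 1L, 1L, 2L, 1L))
  lab <- label_adjuvant(tx)
  expect_true(lab$adjuvant[lab$sample_id == "p1"])    # labeled ADJUVANT
  expect_true(lab$adjuvant[lab$sample_id == "p2"])    # first, day 200
  expect_false(lab$adjuvant[lab$sample_id == "p3"])   # day 400 > cutoff
  expect_false(lab$adjuvant[lab$sample_id == "p4"])   # not first, not labeled
  expect_true(is.na(lab$adjuvant[lab$sample_id == "p5"]))  # unlabeled
  expect_error(label_adjuvant(dplyr::mutate(tx, start_day = -5)),
               "non-negative")
})
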