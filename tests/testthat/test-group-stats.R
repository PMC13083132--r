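test_that("Welch t matches hand evaluation and the stats::t.test oracle", {
  # identical samples: t = 0, p = 1
  x <- c(1, 2, 3, 4)
  w0 <- welch_t(x, x)
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)

  # means 10 vs 12, variances 4 and 9, n = 10 each
  a <- sample_with_moments(10, 10, 2, seed = 1)
  b <- sample_with_moments(10, 12, 3, seed = 2)
  w <- welch_t(a, b)
  expect_equal(w$t, -1.7541, tolerance = 1e-4)
  expect_equal(w$nu, 15.68, tolerance = 1e-2)

  # independent oracle on arbitrary samples
  withr::with_seed(3, {
    u <- rnorm(12, 1, 2); v <- rnorm(20, 0, 0.5)
  })
  w2 <- welch_t(u, v)
  tt <- t.test(u, v)
  expect_equal(w2$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(w2$nu, unname(tt$parameter), tolerance = 1e-10)
  expect_equal(w2$p, tt$p.value, tolerance = 1e-12)

  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")
})

test_that("Welch reduces to Student's t under equal variances and ns", {
  a <- sample_with_moments(15, 0, 1.3, seed = 4)
  b <- sample_with_moments(15, 0.8, 1.3, seed = 5)
  w <- welch_t(a, b)
  st <- t.test(a, b, var.equal = TRUE)
  expect_equal(w$nu, 28, tolerance = 1e-10)
  expect_equal(w$t, unname(st$statistic), tolerance = 1e-10)
})

test_that("Cohen's d uses the classic pooled SD", {
  expect_equal(cohens_d(c(1, 2, 3), c(3, 4, 5)), -2.0)
  expect_equal(cohens_d(c(5, 6), c(5, 6)), 0)
  a <- sample_with_moments(5000, 1, 1, seed = 6)
  b <- sample_with_moments(5000, 0, 1, seed = 7)
  expect_equal(cohens_d(a, b), 1, tolerance = 1e-12)  # exact moments
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled SD")
  # sign follows mean(a) - mean(b)
  expect_gt(cohens_d(c(2, 3, 4), c(1, 2, 3)), 0)
})

test_that("BH adjustment matches the hand step-up and is permutation-invariant", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.001, 0.9)), c(0.002, 0.9))
  withr::with_seed(8, p <- runif(40))
  q <- bh_fdr(p)
  o <- sample(40)
  expect_equal(bh_fdr(p[o]), q[o])
  expect_true(all(q[order(p)] == cummax(q[order(p)])))  # monotone in p
  expect_true(all(q >= p & q <= 1))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("run_contrasts surfaces planted effects and controls the null", {
  # identical groups: nothing significant
  cfg0 <- cohort_config(group_sizes = c("SCZ" = 30, "CON" = 30),
                        conditions = "1-back",
                        effect_map = paper_effect_map()[0, ], seed = 31)
  ct0 <- run_contrasts(generate_feature_tables(cfg0),
                       contrasts = list(c("SCZ", "CON")))
  expect_true(all(ct0$q >= ct0$p))
  expect_true(all(ct0$nu >= pmin(ct0$n1, ct0$n2) - 1 - 1e-9))
  expect_true(all(ct0$nu <= ct0$n1 + ct0$n2 - 2 + 1e-9))
  expect_true(all(sign(ct0$d) == sign(ct0$mean1 - ct0$mean2)))

  # planted 1-back CER-SM deficit dominates its inter-network family
  cfg <- cohort_config(group_sizes = c("SCZ" = 200, "CON" = 200),
                       conditions = "1-back",
                       effect_map = data.frame(
                         group1 = "SCZ", group2 = "CON", condition = "1-back",
                         feature = inter_feature_name("CER", "SM"), d = -1.547,
                         stringsAsFactors = FALSE),
                       seed = 17)
  ct <- run_contrasts(generate_feature_tables(cfg),
                      contrasts = list(c("SCZ", "CON")))
  inter <- ct[feature_class(ct$feature) == "inter", ]
  target <- inter$feature == inter_feature_name("CER", "SM")
  expect_identical(inter$feature[which.max(abs(inter$d))],
                   inter_feature_name("CER", "SM"))
  expect_identical(inter$feature[which.min(inter$q)],
                   inter_feature_name("CER", "SM"))
  expect_lt(inter$q[target], 0.05)

  # missing group is reported
  expect_error(run_contrasts(generate_feature_tables(cfg0),
                             contrasts = list(c("SCZ", "CON-SIB"))),
               "CON-SIB")
})

test_that("family-wise BH keeps the null family-level FDR near nominal", {
  # 21-feature null families: fraction with any q < 0.05 stays <= 0.05
  n_sim <- 400
  any_sig <- logical(n_sim)
  withr::with_seed(99, {
    for (s in seq_len(n_sim)) {
      p <- vapply(1:21, function(j)
        welch_t(rnorm(10), rnorm(10))$p, numeric(1))
      any_sig[s] <- any(bh_fdr(p) < 0.05)
    }
  })
  rate <- mean(any_sig)
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / n_sim))
})

test_that("nodal contrasts localize planted deficits and are calibrated under the null", {
  a <- tiny_atlas()
  mk_nodal <- function(shift_cer = 0, n = 20, seed = 1) {
    withr::with_seed(seed, {
      rows <- expand.grid(subject_id = sprintf("s%02d", 1:(2 * n)),
                          roi = a$roi_labels, stringsAsFactors = FALSE)
      rows$group <- ifelse(as.integer(sub("s", "", rows$subject_id)) <= n,
                           "SCZ", "CON")
      rows$condition <- "1-back"
      rows$network <- unname(a$network_of[rows$roi])
      rows$strength <- rnorm(nrow(rows)) +
        ifelse(rows$network == "CER" & rows$group == "SCZ", shift_cer, 0)
      rows$clustering <- runif(nrow(rows))
      rows
    })
  }
  # planted cerebellar strength deficit dominates the smallest q-values
  res <- nodal_contrasts(mk_nodal(shift_cer = -2, seed = 21), "strength")
  top <- res$feature[order(res$q)][1:2]
  expect_true(all(unname(a$network_of[top]) == "CER"))

  # null: p-values approximately uniform
  ps <- unlist(lapply(1:200, function(s)
    nodal_contrasts(mk_nodal(0, n = 10, seed = 300 + s), "strength")$p))
  expect_gt(ks.test(ps, "punif")$p.value, 0.001)

  # single-ROI family: q = p
  one <- mk_nodal(0, n = 10, seed = 77)
  one <- one[one$roi == one$roi[1], ]
  res1 <- nodal_contrasts(one, "strength")
  expect_equal(res1$q, res1$p)
})

test_that("summary-statistic ANOVA matches aov and reproduces printed effect sizes", {
  # all means equal: F = 0
  z <- anova_eta(c(1, 1, 1), c(1, 2, 3), c(5, 5, 5))
  expect_equal(z$F, 0)
  expect_equal(z$eta_p_squared, 0)

  # cohort positive-symptom summaries reproduce eta_p^2 = 0.51
  s <- anova_eta(means = c(0.25, 0.05, 4.78, 0.47),
                 sds = c(0.71, 0.22, 3.78, 0.74),
                 ns = c(20, 21, 23, 33))
  expect_equal(s$df1, 3)
  expect_equal(s$df2, 93)
  expect_equal(s$eta_p_squared, 0.51, tolerance = 0.005)

  # oracle: subject-level aov on samples with those exact moments
  g1 <- sample_with_moments(8, 2, 1, seed = 11)
  g2 <- sample_with_moments(12, 3.5, 2, seed = 12)
  g3 <- sample_with_moments(10, 1, 0.5, seed = 13)
  mine <- anova_eta(c(mean(g1), mean(g2), mean(g3)),
                    c(sd(g1), sd(g2), sd(g3)), c(8, 12, 10))
  df <- data.frame(y = c(g1, g2, g3),
                   g = factor(rep(1:3, c(8, 12, 10))))
  av <- summary(aov(y ~ g, df))[[1]]
  expect_equal(mine$F, av[1, "F value"], tolerance = 1e-10)
  expect_equal(mine$eta_p_squared,
               av[1, "Sum Sq"] / sum(av[, "Sum Sq"]), tolerance = 1e-10)

  # two groups: F equals the squared pooled-variance t
  tt <- t.test(g1, g2, var.equal = TRUE)
  two <- anova_eta(c(mean(g1), mean(g2)), c(sd(g1), sd(g2)), c(8, 12))
  expect_equal(two$F, unname(tt$statistic)^2, tolerance = 1e-10)

  expect_error(anova_eta(c(1, 1), c(0, 0), c(5, 5)), "no variance")
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2)), 2 / choose(10, 5),
               tolerance = 1e-10)
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2)), 1)

  # the misclassification cross-tab from the discrimination stage
  tab <- matrix(c(3, 8, 1, 11), 2)
  expect_equal(fisher_exact_2x2(tab), enumerate_fisher_2x2(tab),
               tolerance = 1e-9)

  # random tables against the enumeration oracle
  withr::with_seed(41, {
    for (i in 1:20) {
      tb <- matrix(rpois(4, 6) + 1, 2)
      expect_equal(fisher_exact_2x2(tb), enumerate_fisher_2x2(tb),
                   tolerance = 1e-9)
    }
  })

  expect_error(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2)), "zero margin")
  expect_error(fisher_exact_2x2(matrix(c(1.5, 1, 1, 1), 2)), "integer")
})

test_that("estimated d converges to the planted value as n grows", {
  planted <- -0.8
  err <- vapply(c(50, 200, 800), function(n) {
    cfg <- cohort_config(group_sizes = c("SCZ" = n, "CON" = n),
                         conditions = "1-back",
                         effect_map = data.frame(
                           group1 = "SCZ", group2 = "CON",
                           condition = "1-back",
                           feature = inter_feature_name("CER", "SM"),
                           d = planted, stringsAsFactors = FALSE),
                         seed = 1000 + n)
    reps <- vapply(1:30, function(r) {
      cfg$seed <- 1000 + n + r
      ft <- generate_feature_tables(cfg)
      f <- inter_feature_name("CER", "SM")
      cohens_d(ft[[f]][ft$group == "SCZ"], ft[[f]][ft$group == "CON"])
    }, numeric(1))
    abs(mean(reps) - planted)
  }, numeric(1))
  expect_lt(err[3], 0.02)
  expect_lt(err[3], err[1] + 0.02)
})
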