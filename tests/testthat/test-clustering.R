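test_that("min-max normalization applies declared bounds and listwise deletion", {
  clin <- generate_clinical_table(subtype_preset(), n = 40, seed = 9)
  norm <- minmax_normalize(clin, bounds = cognitive_unit_bounds())
  expect_true(all(norm$data >= 0 & norm$data <= 1))
  expect_length(norm$dropped, 0L)
  # symptom scale endpoints map to 0 and 1, midpoint to 0.5
  expect_equal(norm$bounds_used$saps_global, c(0, 5))
  clin2 <- clin
  clin2$saps_global[1:3] <- c(0, 5, 2.5)
  n2 <- minmax_normalize(clin2, bounds = cognitive_unit_bounds())
  expect_equal(unname(n2$data[1:3, "saps_global"]), c(0, 1, 0.5))

  # 3 missing cells in 2 rows drop exactly those 2 rows
  clin3 <- clin
  clin3$lns[2] <- NA
  clin3$iq[2] <- NA
  clin3$sans_global[7] <- NA
  n3 <- minmax_normalize(clin3, bounds = cognitive_unit_bounds())
  expect_identical(n3$dropped, clin$subject_id[c(2, 7)])
  expect_identical(nrow(n3$data), 38L)

  # observed-range default for cognitive columns; constant column errors
  clin4 <- clin
  clin4$vocabulary <- 0.5
  expect_error(minmax_normalize(clin4), "vocabulary")
})

test_that("PAM equals brute-force exhaustive medoid search for small n", {
  # 1-D example: clusters {0, 1} and {10, 11}, total cost 2
  pts <- matrix(c(0, 1, 10, 11), ncol = 1)
  fit <- pam_cluster(pts, 2)
  expect_identical(fit$labels[1], fit$labels[2])
  expect_identical(fit$labels[3], fit$labels[4])
  expect_equal(pam_cost(pts, fit$labels, fit$medoids), 2)

  # k = n: every point its own medoid, zero cost
  fitn <- pam_cluster(pts, 4)
  expect_identical(fitn$labels, 1:4)
  expect_equal(pam_cost(pts, fitn$labels, fitn$medoids), 0)

  # random instances, n <= 8: PAM cost equals the exhaustive optimum
  withr::with_seed(17, {
    for (i in 1:30) {
      n <- sample(4:8, 1)
      k <- sample(2:3, 1)
      pts <- matrix(rnorm(n * 2), n, 2)
      fit <- pam_cluster(pts, k)
      oracle <- brute_force_pam(pts, k)
      expect_equal(pam_cost(pts, fit$labels, fit$medoids), oracle$cost,
                   tolerance = 1e-9)
    }
  })

  # duplicated dataset keeps the partition structure
  base <- matrix(c(0, 0.5, 9, 9.5), ncol = 1)
  dup <- rbind(base, base)
  fd <- pam_cluster(dup, 2)
  expect_identical(fd$labels[1:4], fd$labels[5:8])
  expect_identical(fd$labels[1], fd$labels[2])
  expect_false(fd$labels[1] == fd$labels[3])

  expect_error(pam_cluster(matrix(1:3), 4), "k = 4 > n = 3")
})

test_that("PAC counts ambiguous consensus entries", {
  cm <- function(v) {
    m <- diag(4)
    m[upper.tri(m)] <- v
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }
  expect_equal(pac(cm(c(0, 1, 0, 1, 0, 1))), 0)
  expect_equal(pac(cm(rep(0.5, 6))), 1)
  # entries (0.05, 0.5, 0.95, 1.0) plus two unambiguous: direct count
  m <- diag(3)
  m[1, 2] <- m[2, 1] <- 0.05
  m[1, 3] <- m[3, 1] <- 0.5
  m[2, 3] <- m[3, 2] <- 0.95
  expect_equal(pac(m), 1 / 3)
  m4 <- cm(c(0.05, 0.5, 0.95, 1.0, 0, 0))
  expect_equal(pac(m4), 1 / 6)
  # NA entries are excluded from the denominator
  m4[1, 2] <- m4[2, 1] <- NA
  expect_equal(pac(m4), 1 / 5)
})

test_that("pairwise partition similarity matches brute-force pair counting", {
  brute_jaccard <- function(l1, l2) {
    pairs <- combn(length(l1), 2)
    a <- l1[pairs[1, ]] == l1[pairs[2, ]]
    b <- l2[pairs[1, ]] == l2[pairs[2, ]]
    if (!any(a | b)) return(1)
    sum(a & b) / sum(a | b)
  }
  skip_if_not_installed("mclust")
  withr::with_seed(23, {
    for (i in 1:20) {
      l1 <- sample(1:3, 12, replace = TRUE)
      l2 <- sample(1:4, 12, replace = TRUE)
      expect_equal(jaccard_partitions(l1, l2), brute_jaccard(l1, l2))
      expect_equal(cereconn:::pair_concordance(l1, l2)$ari,
                   mclust::adjustedRandIndex(l1, l2), tolerance = 1e-12)
    }
  })
  expect_equal(jaccard_partitions(c(1, 2, 3), c(3, 1, 2)), 1)
})

test_that("consensus clustering is deterministic and certain on separated blobs", {
  withr::with_seed(5, {
    pts <- rbind(matrix(rnorm(40, 0, 0.05), 20, 2),
                 matrix(rnorm(40, 3, 0.05), 20, 2),
                 matrix(rnorm(40, 6, 0.05), 20, 2))
  })
  s1 <- consensus_cluster(pts, 3, iterations = 50, seed = 7)
  s2 <- consensus_cluster(pts, 3, iterations = 50, seed = 7)
  expect_identical(s1$labels, s2$labels)
  expect_identical(s1$consensus, s2$consensus)

  off <- s1$consensus[upper.tri(s1$consensus)]
  expect_true(all(off[!is.na(off)] %in% c(0, 1)))
  expect_equal(s1$metrics$pac, 0)
  expect_equal(s1$metrics$mean_ari, 1)
  expect_equal(s1$metrics$mean_jaccard, 1)
  expect_true(all(diag(s1$consensus) == 1))
  expect_equal(s1$consensus, t(s1$consensus))
  # truth recovered
  truth <- rep(1:3, each = 20)
  expect_equal(cereconn:::pair_concordance(s1$labels, truth)$ari, 1)

  # pure noise: PAC near its maximum for this design, far less stable
  # than planted structure (subsamples of one fixed dataset keep some
  # agreement, so the null mean ARI is depressed but not zero)
  withr::with_seed(6, noise <- matrix(runif(60 * 5), 60, 5))
  sn <- consensus_cluster(noise, 3, iterations = 50, seed = 8)
  expect_gt(sn$metrics$pac, 0.4)
  expect_lt(sn$metrics$mean_ari, 0.7)
  expect_lt(sn$metrics$mean_ari, s1$metrics$mean_ari)

  expect_error(consensus_cluster(pts[1:5, ], 5, subsample = 0.8),
               "must exceed k")
})

test_that("a pluggable embedding is applied before PAM", {
  withr::with_seed(15, pts <- cbind(rep(c(0, 5), each = 10) + rnorm(20, 0, 0.1),
                                    rnorm(20, 0, 0.1)))
  # an embedding that kills the informative axis destroys the structure
  s_id <- consensus_cluster(pts, 2, iterations = 30, seed = 3)
  s_null <- consensus_cluster(pts, 2, iterations = 30, seed = 3,
                              embedding = function(x) x[, 2, drop = FALSE])
  truth <- rep(1:2, each = 10)
  expect_equal(cereconn:::pair_concordance(s_id$labels, truth)$ari, 1)
  expect_lt(cereconn:::pair_concordance(s_null$labels, truth)$ari, 0.5)
})

test_that("silhouette and Calinski-Harabasz behave on reference fixtures", {
  withr::with_seed(25, {
    pts <- rbind(matrix(rnorm(30, 0, 0.01), 15, 2),
                 matrix(rnorm(30, 10, 0.01), 15, 2))
  })
  sol <- consensus_cluster(pts, 2, iterations = 30, seed = 2)
  expect_gt(sol$metrics$silhouette, 0.9)
  expect_gt(sol$metrics$calinski_harabasz, 1000)
  # CH against direct formula on a tiny case
  p2 <- matrix(c(0, 0, 1, 1, 10, 10, 11, 11), 4, 2, byrow = TRUE)
  lab <- c(1, 1, 2, 2)
  grand <- colMeans(p2)
  ssb <- 2 * sum((c(0.5, 0.5) - grand)^2) + 2 * sum((c(10.5, 10.5) - grand)^2)
  ssw <- 4 * 0.5  # each point 0.5^2 * 2 coords = 0.5 from its centroid
  expect_equal(calinski_harabasz(p2, lab), (ssb / 1) / (ssw / 2))
  expect_error(stability_metrics(structure(list(k = 1), class = "cluster_solution"),
                                 p2), "k = 1")
})

test_that("the permutation test uses the add-one rule and is calibrated", {
  # strong 3-blob fixture: observed CH beats every null
  withr::with_seed(33, {
    pts <- rbind(matrix(rnorm(20, 0, 0.05), 10, 2),
                 matrix(rnorm(20, 5, 0.05), 10, 2),
                 matrix(rnorm(20, 10, 0.05), 10, 2))
  })
  pt <- permutation_test(pts, 3, B = 999, seed = 4)
  expect_equal(pt$p, 1 / 1000)
  expect_true(all(pt$null < pt$observed))

  # null calibration: on column-permuted noise p is roughly uniform
  withr::with_seed(44, {
    ps <- vapply(1:40, function(i) {
      noise <- matrix(rnorm(30 * 3), 30, 3)
      permutation_test(noise, 3, B = 60, seed = 100 + i)$p
    }, numeric(1))
  })
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps), 0.75)
  # super-uniformity at the 10% level, within binomial slack
  expect_lt(mean(ps <= 0.1), 0.1 + 3 * sqrt(0.1 * 0.9 / 40))
})

test_that("select_k recovers the planted number of clusters and flags noise", {
  clin <- generate_clinical_table(subtype_preset(), n = 98, seed = 61)
  norm <- minmax_normalize(clin, bounds = cognitive_unit_bounds())
  sel <- select_k(norm$data, k_range = 2:6, iterations = 60, seed = 14)
  expect_identical(sel$k, 3L)
  expect_true(sel$stable)
  expect_identical(sel$table$k, 2:6)

  withr::with_seed(35, blobs2 <- rbind(matrix(rnorm(40, 0, 0.1), 20, 2),
                                       matrix(rnorm(40, 4, 0.1), 20, 2)))
  sel2 <- select_k(blobs2, k_range = 2:4, iterations = 40, seed = 15)
  expect_identical(sel2$k, 2L)

  # structureless data is flagged: its best PAC stays above the ceiling
  for (i in 1:3) {
    withr::with_seed(36 + i, noise <- matrix(runif(50 * 4), 50, 4))
    seln <- select_k(noise, k_range = 2:4, iterations = 40, seed = 16 + i)
    expect_false(seln$stable)
    expect_gt(min(seln$table$pac), 0.3)
  }
})

test_that("subtype profiles and composition summarize the solution", {
  # noise-free preset: profiles equal centroids exactly
  p0 <- subtype_preset(within_subtype_sd = 0)
  clin <- generate_clinical_table(p0, n = 60, seed = 19)
  norm <- minmax_normalize(clin, bounds = cognitive_unit_bounds())
  truth <- clin$true_subtype
  prof <- profile_subtypes(truth, norm)
  ctr <- default_subtype_centroids()
  for (s in 1:3)
    expect_equal(unname(prof$profiles[s, ]), unname(ctr[s, ]),
                 tolerance = 1e-12)
  # composition percentages sum to 100 and respect the preset support
  expect_equal(unname(rowSums(prof$composition)), rep(100, 3))
  expect_equal(unname(prof$composition["subtype_1", c("SCZ", "SCZ-SIB")]),
               c(0, 0))

  # default preset: verbal/visual memory means of subtype 1 in the 0.60-0.65 band
  clin2 <- generate_clinical_table(subtype_preset(), n = 200, seed = 20)
  norm2 <- minmax_normalize(clin2, bounds = cognitive_unit_bounds())
  prof2 <- profile_subtypes(clin2$true_subtype, norm2)
  expect_gt(prof2$profiles["subtype_1", "vocabulary"], 0.60)
  expect_lt(prof2$profiles["subtype_1", "vocabulary"], 0.65)
  expect_gt(prof2$profiles["subtype_1", "family_pictures"], 0.60)
  expect_lt(prof2$profiles["subtype_1", "family_pictures"], 0.65)
})
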