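# Shared fixtures and independent oracles for the test suite.

# a small atlas: 2 ROIs per canonical network (12 ROIs)
tiny_atlas <- function(per_network = 2) {
  nets <- default_networks()
  atlas_map(unlist(lapply(nets, function(nw)
    sprintf("%s_%02d", nw, seq_len(per_network)))),
    rep(nets, each = per_network))
}

# random symmetric z matrix with zero diagonal
random_z <- function(R, seed = 1) {
  withr::with_seed(seed, {
    z <- matrix(0, R, R)
    z[upper.tri(z)] <- rnorm(R * (R - 1) / 2)
    z + t(z)
  })
}

# random sparse connectome graph over an atlas
random_graph <- function(atlas, seed = 1, percentile = 85, ...) {
  R <- length(atlas$roi_labels)
  z <- random_z(R, seed)
  dimnames(z) <- list(atlas$roi_labels, atlas$roi_labels)
  threshold_sparsify(z, percentile = percentile, subject_id = paste0("s", seed),
                     group = "CON", condition = "1-back", ...)
}

# brute-force k-medoids: exhaustive search over all medoid subsets
brute_force_pam <- function(points, k) {
  d <- as.matrix(dist(points))
  n <- nrow(d)
  best_cost <- Inf
  best <- NULL
  for (med in utils::combn(n, k, simplify = FALSE)) {
    assign_cost <- apply(d[, med, drop = FALSE], 1L, min)
    cost <- sum(assign_cost)
    if (cost < best_cost - 1e-12) {
      best_cost <- cost
      best <- med
    }
  }
  labels <- apply(d[, best, drop = FALSE], 1L, which.min)
  list(medoids = best, labels = labels, cost = best_cost)
}

pam_cost <- function(points, labels, medoids) {
  d <- as.matrix(dist(points))
  sum(vapply(seq_len(nrow(d)), function(i) d[i, medoids[labels[i]]],
             numeric(1)))
}

# exhaustive two-sided Fisher p for a 2x2 table (hypergeometric enumeration)
enumerate_fisher_2x2 <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); kk <- sum(tab[, 1])
  obs <- dhyper(tab[1, 1], m, n, kk)
  xs <- max(0, kk - n):min(kk, m)
  probs <- dhyper(xs, m, n, kk)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# sample with exact first two moments (sd uses the n-1 convention)
sample_with_moments <- function(n, mean, sd, seed = 1) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    mean + sd * (x - mean(x)) / stats::sd(x)
  })
}

# equicorrelation matrix
equicorr <- function(p, rho) {
  S <- matrix(rho, p, p)
  diag(S) <- 1
  S
}

cognitive_unit_bounds <- function() {
  stats::setNames(rep(list(c(0, 1)), 9),
                  setdiff(clinical_feature_columns(),
                          grep("^(saps|sans)", clinical_feature_columns(),
                               value = TRUE)))
}
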