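random_profiles <- function(n = 500, k = 4, seed = 8) {
  withr::with_seed(seed, {
    base <- rnorm(n)
    m <- vapply(seq_len(k), function(i) base + rnorm(n, 0, 0.8), numeric(n))
    dimnames(m) <- list(sprintf("g%04d", seq_len(n)), paste0("v", seq_len(k)))
    m
  })
}

test_that("condition profiles are replicate means", {
  m <- cbind(a1 = c(1, 5), a2 = c(3, 7), b1 = c(2, 2))
  rownames(m) <- c("g1", "g2")
  sheet <- data.frame(sample_id = c("a1", "a2", "b1"),
                      species = c("human", "human", "mouse"),
                      tissue = "heart",
                      ploidy_class = c("polyploid", "polyploid", "diploid"),
                      replicate = c(1, 2, 1))
  prof <- condition_profiles(m, sheet)
  expect_identical(ncol(prof), 2L)
  expect_equal(unname(prof[, "human_heart"]), c(2, 6))
  expect_equal(unname(prof[, "mouse_heart"]), c(2, 2))   # single replicate
})

test_that("two-variable PCA matches the closed form", {
  prof <- random_profiles(n = 2000, k = 2, seed = 15)
  r <- cor(prof)[1, 2]
  model <- fit_pca(prof)
  expect_equal(abs(unname(model$loadings[, 1])),
               rep(sqrt((1 + r) / 2), 2), tolerance = 1e-10)
  expect_equal(abs(unname(model$loadings[, 2])),
               rep(sqrt((1 - r) / 2), 2), tolerance = 1e-10)
  expect_equal(unname(model$var_fraction),
               c((1 + r) / 2, (1 - r) / 2), tolerance = 1e-10)
})

test_that("full-rank PCA identities hold on random inputs", {
  for (seed in c(1, 2, 3)) {
    prof <- random_profiles(seed = seed)
    model <- fit_pca(prof)
    # rotation, no information loss
    expect_identical(ncol(model$loadings), ncol(prof))
    expect_equal(sum(model$var_fraction), 1, tolerance = 1e-9)
    # loadings are correlations: row sums of squares are 1
    expect_equal(unname(rowSums(model$loadings^2)), rep(1, ncol(prof)),
                 tolerance = 1e-9)
    # mean squared loading per component equals its variance fraction
    expect_equal(unname(variance_from_loadings(model$loadings)),
                 unname(model$var_fraction), tolerance = 1e-9)
    # scores standardized per component
    expect_lt(max(abs(colMeans(model$scores))), 1e-9)
    expect_lt(max(abs(apply(model$scores, 2, sd) - 1)), 1e-9)
    # reconstruction of the standardized profiles
    Z <- scale(prof)
    recon <- (model$scores %*% diag(model$score_scale)) %*% t(model$rotation)
    expect_lt(max(abs(recon - Z)) / max(abs(Z)), 1e-8)
    # loadings equal the correlations between variables and scores
    expect_equal(cor(prof, model$scores), model$loadings,
                 ignore_attr = TRUE, tolerance = 1e-6)
  }
})

test_that("degenerate inputs are rejected with the variable named", {
  prof <- random_profiles(n = 50, k = 3)
  prof[, 2] <- 7
  expect_error(fit_pca(prof), "v2")
  expect_error(fit_pca(prof[, 1, drop = FALSE]), ">= 2")
})

test_that("component labelling recovers the planted factor hierarchy", {
  cfg <- synth_config(n_genes = 3000, seed = 31)
  d <- generate_cross_species_dataset(cfg)
  model <- label_components(fit_pca(condition_profiles(d$expr, d$sheet)))
  expect_identical(unname(model$labels),
                   c("shared", "tissue", "species", "ploidy"))
  # variance hierarchy follows shared > tissue > species > ploidy
  expect_true(all(diff(model$var_fraction) < 0))
  # canonical orientation: polyploid variables negative on the ploidy axis
  poly_vars <- model$conditions$ploidy_class == "polyploid"
  expect_true(all(model$loadings[poly_vars, 4] < 0))
  expect_true(all(model$loadings[!poly_vars, 4] > 0))
  # induced genes (low scores) are the planted up-regulated ones
  sel <- select_by_score(model, 2)
  expect_gt(length(intersect(sel$induced, d$truth$ploidy_up)) /
              length(sel$induced), 0.9)
})

test_that("two-condition labelling gives (shared, ploidy)", {
  cfg <- synth_config(n_genes = 2000, reps_per_condition = 3,
                      noise_sd = 0.3, seed = 2)
  d <- generate_two_condition_dataset(cfg)
  model <- label_components(fit_pca(condition_profiles(d$expr, d$sheet)))
  expect_identical(unname(model$labels), c("shared", "ploidy"))
  # sign patterns: (+,+) then (+,-) after orientation with diploid positive
  expect_true(all(model$loadings[, 1] > 0))
  dip <- model$conditions$ploidy_class == "diploid"
  expect_true(model$loadings[dip, 2] > 0 && model$loadings[!dip, 2] < 0)
})

test_that("patterns matching no factor stay unassigned; confounds error", {
  # hand-built model: 4 variables, a (+,-,-,+) pattern vs ploidy (+,-,+,-)
  cond <- data.frame(condition = paste0("v", 1:4),
                     species = c("human", "human", "mouse", "mouse"),
                     tissue = c("heart", "liver", "heart", "liver"),
                     ploidy_class = c("polyploid", "diploid",
                                      "diploid", "polyploid"))
  model <- list(loadings = matrix(c(0.5, -0.5, -0.5, 0.5), 4, 1,
                                  dimnames = list(paste0("v", 1:4), "PC1")),
                rotation = matrix(0.5, 4, 1), scores = matrix(0, 2, 1),
                var_fraction = c(PC1 = 1), labels = c(PC1 = "unassigned"),
                orientation = c(PC1 = 1), conditions = cond)
  # (+,-,-,+) is the ploidy coding of this reciprocal design
  out <- label_components(model)
  expect_identical(unname(out$labels), "ploidy")
  model2 <- model
  model2$loadings[, 1] <- c(0.5, 0.5, -0.5, 0.5)   # matches nothing
  expect_identical(unname(label_components(model2)$labels), "unassigned")
  cond_conf <- cond
  cond_conf$species <- c("human", "mouse", "human", "mouse")
  cond_conf$ploidy_class <- c("polyploid", "diploid", "polyploid", "diploid")
  model3 <- model
  model3$conditions <- cond_conf
  expect_error(label_components(model3), "confounded")
})

test_that("score selection is strict, oriented and nested across thresholds", {
  scores <- matrix(c(-3.5, -2.5, -1, 0, 1, 2.5, 3.5), ncol = 1,
                   dimnames = list(paste0("g", 1:7), "PC2"))
  model <- list(scores = scores, labels = c(PC2 = "ploidy"))
  s2 <- select_by_score(model, 2)
  s3 <- select_by_score(model, 3)
  expect_setequal(s2$induced, c("g1", "g2"))
  expect_setequal(s2$suppressed, c("g6", "g7"))
  expect_true(all(s3$induced %in% s2$induced))
  expect_true(all(s3$suppressed %in% s2$suppressed))
  expect_setequal(s3$induced, "g1")
  # all scores within the band: both sets empty
  model_in <- list(scores = scores / 10, labels = c(PC2 = "ploidy"))
  s <- select_by_score(model_in, 2)
  expect_length(s$induced, 0); expect_length(s$suppressed, 0)
  expect_error(select_by_score(list(scores = scores,
                                    labels = c(PC2 = "shared")), 2),
               "ploidy")
})

test_that("kurtosis diagnostics match hand-computed moments", {
  mk <- function(v) list(scores = matrix(v, ncol = 1,
                                         dimnames = list(NULL, "PC1")))
  expect_equal(score_diagnostics(mk(c(0, 0, 0, 0, 10)), "PC1")$kurtosis,
               832 / 256)
  expect_equal(score_diagnostics(mk(rep(c(-1, 1), 10)), "PC1")$kurtosis, 1)
  withr::with_seed(99, {
    d <- score_diagnostics(mk(rnorm(1e6)), "PC1")
    expect_equal(d$kurtosis, 3, tolerance = 0.05 / 3)
  })
  expect_error(score_diagnostics(mk(c(1, 2, 3)), "PC1"), ">= 4")
  # sparse planted signal inflates kurtosis far beyond the Gaussian 3
  cfg <- synth_config(n_genes = 2000, reps_per_condition = 3, seed = 2)
  d <- generate_two_condition_dataset(cfg)
  m <- label_components(fit_pca(condition_profiles(d$expr, d$sheet)))
  expect_gt(score_diagnostics(m, "PC2")$kurtosis, 6)
  cfg0 <- synth_config(n_genes = 2000, reps_per_condition = 3,
                       frac_ploidy_up = 0, frac_ploidy_down = 0, seed = 2)
  d0 <- generate_two_condition_dataset(cfg0)
  m0 <- fit_pca(condition_profiles(d0$expr, d0$sheet))
  expect_equal(score_diagnostics(m0, "PC2")$kurtosis, 3, tolerance = 0.15)
})
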