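test_that("quantile normalization equalizes column distributions", {
  m <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
  rownames(m) <- paste0("g", 1:3)
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, 2]), c(2.5, 3.5, 4.5))

  ident <- cbind(a = c(3, 1, 2), b = c(3, 1, 2))
  rownames(ident) <- paste0("g", 1:3)
  expect_equal(quantile_normalize(ident), ident)

  set.seed(4)
  r <- matrix(rnorm(600), 100, 6,
              dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:6)))
  qr <- quantile_normalize(r)
  sorted <- apply(qr, 2, sort)
  expect_equal(sorted, sorted[, c(1, 1, 1, 1, 1, 1)],
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(quantile_normalize(r[, 1, drop = FALSE]), "2 samples")
})

test_that("empirical-Bayes prior fitting recovers known hyperparameters", {
  # identical variances: no excess dispersion, infinite prior df
  p <- fit_ebayes(rep(0.25, 50), df = 4)
  expect_identical(p$d0, Inf)
  expect_equal(p$s0_sq, 0.25)

  # variances drawn from the scaled-F prior with d0 = 4, s0^2 = 0.25
  set.seed(101)
  s2 <- 0.25 * rf(20000, df1 = 4, df2 = 4)
  fit <- fit_ebayes(s2, df = 4)
  expect_gt(fit$d0, 3); expect_lt(fit$d0, 5)
  expect_equal(fit$s0_sq, 0.25, tolerance = 0.1)

  expect_error(fit_ebayes(c(0.1, 0.2), df = 4), ">= 10 genes")
  expect_error(fit_ebayes(rep(0, 50), df = 4), "zero")
})

test_that("moderated t matches the closed form and its limits", {
  # two groups of 3 with delta = 1, s_g^2 = 0.25 exactly, d0 = 4, s0^2 = 0.25
  base <- c(-0.5, 0, 0.5)   # mean 0, ss = 0.5 per group => pooled s2 = 0.25
  m <- rbind(g1 = c(base + 1, base))   # polyploid first
  colnames(m) <- c(paste0("p", 1:3), paste0("d", 1:3))
  sheet <- tiny_sheet()
  sheet$sample_id <- c(paste0("p", 1:3), paste0("d", 1:3))
  sheet$ploidy_class <- rep(c("polyploid", "diploid"), each = 3)
  de <- moderated_t_test(m, sheet,
                         c("mouse_decidua_polyploid", "mouse_decidua_diploid"),
                         params = list(d0 = 4, s0_sq = 0.25))
  expect_equal(de$delta, 1)
  expect_equal(de$t_mod, 1 / (0.5 * sqrt(2 / 3)), tolerance = 1e-12)
  expect_equal(de$df_total, 8)

  # delta = 0 gives t = 0, p = 1
  m0 <- rbind(g1 = c(base, base)); colnames(m0) <- colnames(m)
  de0 <- moderated_t_test(m0, sheet,
                          c("mouse_decidua_polyploid", "mouse_decidua_diploid"),
                          params = list(d0 = 4, s0_sq = 0.25))
  expect_equal(de0$t_mod, 0)
  expect_equal(de0$p, 1)

  # d0 = 0: the ordinary pooled two-sample t-test
  x <- tiny_two_group_matrix(n_genes = 30)
  de_ord <- moderated_t_test(x, tiny_sheet(),
                             c("mouse_decidua_polyploid",
                               "mouse_decidua_diploid"),
                             params = list(d0 = 0))
  ref <- apply(x, 1, function(v)
    unname(t.test(v[4:6], v[1:3], var.equal = TRUE)$statistic))
  expect_equal(de_ord$t_mod, unname(ref), tolerance = 1e-10)

  # d0 -> infinity: z-like statistic at the prior variance
  de_inf <- moderated_t_test(x, tiny_sheet(),
                             c("mouse_decidua_polyploid",
                               "mouse_decidua_diploid"),
                             params = list(d0 = 1e8, s0_sq = 0.3))
  z <- (rowMeans(x[, 4:6]) - rowMeans(x[, 1:3])) /
    (sqrt(0.3) * sqrt(2 / 3))
  expect_equal(de_inf$t_mod, unname(z), tolerance = 1e-6)

  expect_error(
    moderated_t_test(x, tiny_sheet(), c("mouse_decidua_polyploid", "nope")),
    "absent")
})

test_that("moderated test agrees with an independent linear-model fit", {
  x <- tiny_two_group_matrix(n_genes = 200, seed = 42)
  de <- moderated_t_test(x, tiny_sheet(),
                         c("mouse_decidua_polyploid", "mouse_decidua_diploid"))
  design <- cbind(intercept = 1, poly = rep(c(0, 1), each = 3))
  fit <- limma::eBayes(limma::lmFit(x, design))
  expect_equal(de$t_mod, unname(fit$t[, 2]), tolerance = 1e-10)
  expect_equal(de$p, unname(fit$p.value[, 2]), tolerance = 1e-10)
})

test_that("change filter applies the inclusive reciprocal 15% rule", {
  de <- fake_de(paste0("g", 1:5),
                delta = log2(c(1.10, 1.20, 1.15, 1 / 1.15, 1 / 1.10)),
                p = rep(0.001, 5))
  cf <- change_filter(de)
  expect_identical(cf$pass, c(FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_identical(cf$direction, c(NA, "up", "up", "down", NA))
  # boundary: delta = log2(1.15) passes upward
  expect_true(change_filter(fake_de("g", log2(1.15), 0.5))$pass)
})

test_that("tier construction enforces concordance and subset structure", {
  orth <- data.frame(group_id = paste0("OG", 1:6),
                     gene_a = paste0("h", 1:6), gene_b = paste0("m", 1:6))
  heart <- fake_de(paste0("OG", 1:6),
                   delta = log2(c(1.20, 1.18, 1.30, 0.8, 1.25, 1.0)),
                   p = c(0.001, 0.005, 0.002, 0.001, 0.5, 0.9))
  liver <- fake_de(paste0("OG", 1:6),
                   delta = log2(c(1.18, 1.22, 0.7, 0.82, 1.30, 1.0)),
                   p = c(0.005, 0.001, 0.001, 0.002, 0.001, 0.9))
  decid <- fake_de(paste0("m", 1:6),
                   delta = log2(c(1.25, 0.9, 1.4, 0.75, 1.2, 1.0)),
                   p = c(0.002, 0.5, 0.001, 0.001, 0.004, 0.9))
  tiers <- build_tiered_lists(heart, liver, decid, orth)
  # OG1: up everywhere -> tiers A and B; OG2: up in heart+liver only -> B
  expect_setequal(tiers$tier_B_up, c("OG1", "OG2"))
  expect_identical(tiers$tier_A_up, "OG1")
  # OG3: up in heart, down in liver -> excluded from A and B
  expect_false("OG3" %in% c(tiers$tier_B_up, tiers$tier_B_down))
  expect_setequal(tiers$tier_B_down, "OG4")
  expect_setequal(tiers$tier_A_down, "OG4")
  expect_setequal(tiers$tier_C_up, c("m1", "m3", "m5"))
  # p-gate off: OG5 (p=0.5 in heart) still passes on fold change
  tiers_nop <- build_tiered_lists(heart, liver, decid, orth,
                                  use_p_gate = FALSE)
  expect_true("OG5" %in% tiers_nop$tier_B_up)
  # subset invariants
  expect_true(all(tiers$tier_A_up %in% tiers$tier_B_up))
  expect_true(all(tiers$tier_A_down %in% tiers$tier_B_down))
  expect_length(intersect(tiers$tier_B_up, tiers$tier_B_down), 0)
  expect_error(build_tiered_lists(heart, fake_de("X1", 0, 1)), "share no")
})
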