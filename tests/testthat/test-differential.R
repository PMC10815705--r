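make_simple_study <- function(means, genotypes = c("WT", "NDKO"),
                              n_rep = 4) {
  m <- matrix(rep(means, length(genotypes)), ncol = length(genotypes),
              dimnames = list(names(means) %||%
                                sprintf("g%02d", seq_along(means)),
                              genotypes))
  study_from_means(m, n_rep = n_rep)
}

test_that("filter_expressed keeps the top mean-TPM quantile", {
  tpm <- matrix(rep(1:8, 2), ncol = 2,
                dimnames = list(paste0("g", 1:8), c("WT_1", "WT_2")))
  design <- data.frame(sample = c("WT_1", "WT_2"), genotype = "WT",
                       replicate = 1:2)
  st <- expression_study(tpm, design)
  kept <- filter_expressed(st, 0.25)
  expect_setequal(rownames(kept$tpm), c("g7", "g8"))
  expect_identical(filter_expressed(st, 1.0)$tpm, st$tpm)
  expect_error(filter_expressed(st, 0), "quantile")
  expect_error(filter_expressed(st, 1.2), "quantile")
})

test_that("cutoff ties resolve by gene-id lexicographic order", {
  means <- c(a = 10, b = 5, m1 = 3, m2 = 3, m3 = 3, z1 = 1, z2 = 1,
             z3 = 1, z4 = 1, z5 = 1)
  tpm <- cbind(WT_1 = means, WT_2 = means)
  st <- expression_study(tpm, data.frame(sample = c("WT_1", "WT_2"),
                                         genotype = "WT", replicate = 1:2))
  # brute-force oracle: sort by (-mean, id), take floor(q * n)
  oracle <- names(means)[order(-means, names(means))][1:4]
  kept <- filter_expressed(st, 0.4)
  expect_setequal(rownames(kept$tpm), oracle)
  expect_true(all(c("m1", "m2") %in% rownames(kept$tpm)))
  expect_false("m3" %in% rownames(kept$tpm))
})

test_that("identical groups give t = 0, p = 1 and no DEG flag", {
  v <- matrix(1:4, nrow = 1)
  st <- study_from_log2(list(WT = v, NDKO = v))
  res <- contrast(st, "NDKO")
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_false(res$deg_up || res$deg_down)
})

test_that("pooled t matches the textbook value and t.test", {
  st <- study_from_log2(list(WT = matrix(c(1, 2, 3, 4), nrow = 1),
                             NDKO = matrix(c(3, 4, 5, 6), nrow = 1)))
  res <- contrast(st, "NDKO")
  # oracle: t.test(c(3,4,5,6), c(1,2,3,4), var.equal = TRUE)
  expect_equal(res$t, 2.19089023002, tolerance = 1e-9)
  expect_equal(res$p, 0.070987654321, tolerance = 1e-9)

  # randomised cross-check against stats::t.test on log2(TPM + 1)
  set.seed(42)
  for (i in 1:20) {
    wt <- matrix(runif(8, 0, 8), nrow = 2)
    mu <- matrix(runif(8, 0, 8), nrow = 2)
    st <- study_from_log2(list(WT = wt, N1KO = mu))
    res <- contrast(st, "N1KO")
    for (g in 1:2) {
      tt <- t.test(mu[g, ], wt[g, ], var.equal = TRUE)
      expect_equal(res$p[g], tt$p.value, tolerance = 1e-12)
      expect_equal(res$t[g], unname(tt$statistic), tolerance = 1e-12)
    }
  }
})

test_that("a 3-fold significant increase is flagged deg_up", {
  m <- matrix(c(10, 30), ncol = 2, dimnames = list("g1", c("WT", "NDKO")))
  st <- study_from_means(m, n_rep = 4, jitter = 0.01)
  res <- contrast(st, "NDKO")
  expect_equal(res$fc, 3, tolerance = 1e-12)
  expect_lt(res$p, 0.05)
  expect_true(res$deg_up)
  expect_false(res$deg_down)
})

test_that("p-values are valid and group swap negates log2fc, keeps p", {
  set.seed(7)
  wt <- matrix(runif(40, 0, 6), nrow = 10)
  mu <- matrix(runif(40, 0, 6), nrow = 10)
  a <- contrast(study_from_log2(list(WT = wt, NDKO = mu)), "NDKO")
  b <- contrast(study_from_log2(list(WT = mu, NDKO = wt)), "NDKO")
  expect_true(all(a$p >= 0 & a$p <= 1))
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-12)
})

test_that("contrast commutes with gene permutation", {
  set.seed(8)
  sim <- simulate_expression(sim_config(n_genes = 50, seed = 8))
  res <- contrast(sim$study, "NDKO")
  perm <- sample(nrow(sim$study$tpm))
  st_p <- expression_study(sim$study$tpm[perm, ], sim$study$design)
  res_p <- contrast(st_p, "NDKO")
  expect_equal(res_p[order(res_p$gene), ], res[order(res$gene), ],
               ignore_attr = TRUE, tolerance = 1e-14)
})

test_that("degenerate variance and 0/0 fold changes are handled explicitly", {
  tpm <- rbind(g_eq = rep(8, 8),                 # constant everywhere
               g_shift = c(rep(4, 4), rep(9, 4)), # zero var, unequal means
               g_zero = rep(0, 8))               # 0/0 fold change
  colnames(tpm) <- paste(rep(c("WT", "NDKO"), each = 4), 1:4, sep = "_")
  design <- data.frame(sample = colnames(tpm),
                       genotype = rep(c("WT", "NDKO"), each = 4),
                       replicate = rep(1:4, 2))
  res <- contrast(expression_study(tpm, design), "NDKO")
  expect_equal(res[res$gene == "g_eq", "p"], 1)
  expect_equal(res[res$gene == "g_shift", "p"], 0)
  expect_true(res[res$gene == "g_shift", "degenerate"])
  expect_true(is.nan(res[res$gene == "g_zero", "fc"]))
  expect_true(res[res$gene == "g_zero", "fc_undefined"])
  expect_false(res[res$gene == "g_zero", "deg_up"])
  expect_false(res[res$gene == "g_zero", "deg_down"])
})

test_that("power and type-I rates hold on the standard synthetic study", {
  fr <- c(null = 0.8, ndko_exclusive_up = 0.05, ndko_exclusive_down = 0.05,
          additive_up = 0.025, additive_down = 0.025,
          alpha_dominant_up = 0.025, alpha_dominant_down = 0.025)
  sim <- simulate_expression(sim_config(n_genes = 2000, class_fractions = fr,
                                        replicate_sd = 0.15, n_replicates = 4,
                                        delta = log2(3), seed = 101))
  res <- contrast(sim$study, "NDKO")
  truth <- sim$truth
  planted <- truth$delta_nd != 0
  called <- ifelse(truth$delta_nd > 0, res$deg_up, res$deg_down)
  expect_gte(mean(called[planted]), 0.95)
  null_any <- rep(FALSE, nrow(truth))
  for (g in MUTANT_GENOTYPES) {
    r <- contrast(sim$study, g)
    null_any <- null_any | r$deg_up | r$deg_down
  }
  expect_lte(mean(null_any[truth$class == "null"]), 0.07)
})

test_that("comparative Ct recovers planted expression ratios", {
  q <- data.frame(sample = c("c1", "c2", "t1"),
                  group = c("WT", "WT", "KO"),
                  ct_target = c(20, 20, 19),
                  ct_reference = c(15, 15, 15))
  out <- ddct(q, "WT")
  expect_equal(out$rel_expr, c(1, 1, 2))

  # dCt 6.3 vs control mean 5.0 -> 2^(-1.3)
  q2 <- data.frame(sample = c("c1", "c2", "t1"), group = c("W", "W", "K"),
                   ct_target = c(21, 23, 21.3), ct_reference = c(16, 18, 15))
  out2 <- ddct(q2, "W")
  expect_equal(out2$rel_expr[3], 2^(-1.3), tolerance = 1e-12)
  # geometric mean of the control group is exactly 1
  expect_equal(exp(mean(log(out2$rel_expr[out2$group == "W"]))), 1,
               tolerance = 1e-12)
})

test_that("ddct skips samples with missing Ct and needs a control group", {
  q <- data.frame(sample = c("c1", "t1", "t2"), group = c("WT", "KO", "KO"),
                  ct_target = c(20, NA, 19), ct_reference = c(15, 15, 15))
  expect_warning(out <- ddct(q, "WT"), "t1")
  expect_identical(nrow(out), 2L)
  expect_error(suppressWarnings(ddct(q[2:3, ], "WT")), "control group")
})
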