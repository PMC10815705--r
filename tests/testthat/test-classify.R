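contrasts_for <- function(genes) {
  # genes: list(gene = list(N1 = c(fc, p), N2 = ..., ND = ...))
  rows <- do.call(rbind, lapply(names(genes), function(g) {
    v <- genes[[g]]
    data.frame(gene = g, genotype = c("N1KO", "N2KO", "NDKO"),
               fc = c(v$N1[1], v$N2[1], v$ND[1]),
               p = c(v$N1[2], v$N2[2], v$ND[2]),
               stringsAsFactors = FALSE)
  }))
  mk_contrasts(rows)
}

test_that("dominance criteria label the canonical cases", {
  ct <- contrasts_for(list(
    a = list(N1 = c(2.2, 0.01), N2 = c(1.1, 0.5), ND = c(2.5, 0.01)),
    x = list(N1 = c(1.0, 0.9), N2 = c(1.0, 0.9), ND = c(1.8, 0.01)),
    d = list(N1 = c(0.5, 0.01), N2 = c(0.9, 0.5), ND = c(0.4, 0.01)),
    b = list(N1 = c(1.05, 0.7), N2 = c(2.0, 0.02), ND = c(3.0, 0.001)),
    s = list(N1 = c(2.0, 0.01), N2 = c(1.4, 0.3), ND = c(2.5, 0.01))))
  cl <- classify_isoforms(ct)
  get <- function(g) cl$class[cl$gene == g]
  expect_identical(get("a"), "alpha_dominant")      # N2 below 1.3
  expect_identical(get("x"), "ndko_exclusive")      # DEG in neither single
  expect_identical(get("d"), "alpha_dominant")      # down: 0.9 > 1/1.3
  expect_identical(cl$direction[cl$gene == "d"], "down")
  expect_identical(get("b"), "beta_dominant")
  expect_identical(get("s"), "shared")              # N2 fc 1.4 >= 1.3 bound
})

test_that("secondary criterion is fold-change only, no p requirement", {
  # N2 changes 1.2-fold with a tiny p: still alpha-dominant (below the
  # 1.3-fold bound; significance of the other single mutant is irrelevant)
  ct <- contrasts_for(list(
    g = list(N1 = c(2.0, 0.01), N2 = c(1.2, 0.001), ND = c(2.2, 0.01))))
  expect_identical(classify_isoforms(ct)$class, "alpha_dominant")
})

test_that("classes partition the NDKO DEG set per direction", {
  set.seed(21)
  sim <- simulate_expression(sim_config(n_genes = 400, seed = 21))
  ct <- contrast_all(sim$study)
  cl <- classify_isoforms(ct)
  vs <- venn_summary(ct)
  for (d in c("up", "down")) {
    expect_identical(nrow(cl[cl$direction == d, ]),
                     as.integer(vs$n_ND[vs$direction == d]))
  }
  expect_false(any(duplicated(paste(cl$gene, cl$direction))))
  expect_true(all(cl$class %in% c("ndko_exclusive", "alpha_dominant",
                                  "beta_dominant", "shared", "ambiguous")))
})

test_that("relabelling N1KO and N2KO swaps alpha and beta calls", {
  set.seed(22)
  sim <- simulate_expression(sim_config(n_genes = 300, replicate_sd = 0.1,
                                        seed = 22))
  ct <- contrast_all(sim$study)
  swapped <- ct
  swapped$genotype <- c(N1KO = "N2KO", N2KO = "N1KO",
                        NDKO = "NDKO")[ct$genotype]
  a <- classify_isoforms(ct)
  b <- classify_isoforms(swapped)
  flip <- c(alpha_dominant = "beta_dominant", beta_dominant = "alpha_dominant",
            ndko_exclusive = "ndko_exclusive", shared = "shared",
            ambiguous = "ambiguous")
  a <- a[order(a$gene, a$direction), ]
  b <- b[order(b$gene, b$direction), ]
  expect_identical(unname(flip[a$class]), b$class)
})

test_that("classification errors name a gene missing a genotype row", {
  ct <- contrasts_for(list(
    g1 = list(N1 = c(2, 0.01), N2 = c(1, 0.5), ND = c(2, 0.01))))
  expect_error(classify_isoforms(ct[ct$genotype != "N2KO", ]), "g1")
})

test_that("venn cells match a brute-force membership enumeration", {
  set.seed(33)
  genes <- sprintf("g%03d", 1:120)
  for (rep in 1:5) {
    s1 <- sample(genes, 30)
    s2 <- sample(genes, 25)
    sd_ <- sample(genes, 40)
    rows <- expand.grid(gene = genes, genotype = MUTANT_GENOTYPES,
                        stringsAsFactors = FALSE)
    rows$fc <- 1
    rows$p <- 1
    rows$deg_up <- (rows$genotype == "N1KO" & rows$gene %in% s1) |
      (rows$genotype == "N2KO" & rows$gene %in% s2) |
      (rows$genotype == "NDKO" & rows$gene %in% sd_)
    rows$deg_down <- FALSE
    vs <- venn_summary(rows)
    up <- vs[vs$direction == "up", ]
    expect_identical(up$n_N1, length(s1))
    expect_identical(up$nd_only, length(setdiff(sd_, union(s1, s2))))
    expect_identical(up$all3, length(Reduce(intersect, list(s1, s2, sd_))))
    expect_identical(up$n1_n2, length(setdiff(intersect(s1, s2), sd_)))
    # disjoint cells sum to each set's total
    expect_identical(up$n_ND,
                     up$nd_only + up$n1_nd + up$n2_nd + up$all3)
    expect_identical(up$n_N1,
                     up$n1_only + up$n1_n2 + up$n1_nd + up$all3)
    expect_equal(up$ndko_exclusive_pct,
                 round(100 * up$nd_only / up$n_ND, 2))
  }
})

test_that("exclusive fraction reproduces the printed two-decimal values", {
  expect_identical(exclusive_fraction(757, 1033), 73.28)
  expect_identical(exclusive_fraction(955, 1495), 63.88)
  expect_true(is.na(exclusive_fraction(0, 0)))
})

test_that("an empty NDKO DEG set yields a not-applicable fraction", {
  rows <- expand.grid(gene = c("a", "b"), genotype = MUTANT_GENOTYPES,
                      stringsAsFactors = FALSE)
  rows$fc <- 1
  rows$p <- 1
  rows$deg_up <- rows$genotype == "N1KO"
  rows$deg_down <- FALSE
  vs <- venn_summary(rows)
  expect_true(is.na(vs$ndko_exclusive_pct[vs$direction == "up"]))
})
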