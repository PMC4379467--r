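test_that("covariance-model p-values are affine-invariant and match lm", {
  set.seed(1)
  ages <- runif(30, 5, 80)
  sexes <- rep(c("male", "female"), 15)
  y <- 5 + 0.02 * ages + rnorm(30)
  p1 <- fit_covariance_model(y, ages, sexes)
  p2 <- fit_covariance_model(10 * y + 7, ages, sexes)
  expect_equal(p1, p2)
  # agreement with a direct lm fit
  fit <- lm(y ~ ages + I(sexes == "male"))
  ct <- coef(summary(fit))
  expect_equal(unname(p1["p_age"]), ct[2, 4])
  expect_equal(unname(p1["p_sex"]), ct[3, 4])
})

test_that("a clean linear age trend is highly significant", {
  ages <- c(10, 20, 30, 40, 50, 60)
  sexes <- c("male", "female", "male", "female", "male", "female")
  y <- c(2.1, 3.9, 6.2, 7.8, 10.1, 11.9)
  p <- fit_covariance_model(y, ages, sexes)
  expect_lt(p["p_age"], 0.001)
})

test_that("singular designs and degenerate genes are caught", {
  ages <- runif(10, 1, 80)
  expect_error(fit_covariance_model(rnorm(10), ages, rep("male", 10)),
               "one sex")
  expect_error(fit_covariance_model(rnorm(10), rep(50, 10),
                                    rep(c("male", "female"), 5)), "age")
  expect_warning(p <- fit_covariance_model(rep(3, 10), ages,
                                           rep(c("male", "female"), 5)),
                 "skipped")
  expect_true(all(is.na(p)))
  expect_error(fit_covariance_model(rnorm(3), ages[1:3],
                                    c("male", "female", "male")), "5 samples")
})

test_that("BH q-values follow the step-up arithmetic", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.5), 0.5)
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")
  # permutation equivariance
  set.seed(4)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(benjamini_hochberg(p)[perm], benjamini_hochberg(p[perm]))
})

test_that("BH matches the naive quadratic reference", {
  set.seed(11)
  for (i in 1:25) {
    p <- runif(sample(5:80, 1))
    expect_equal(benjamini_hochberg(p), naive_bh(p))
  }
})

test_that("Spearman correlation and p-values follow the rank formulas", {
  expect_equal(unname(spearman_with_age(1:6, c(3, 9, 20, 35, 50, 70))["rho"]), 1)
  expect_equal(unname(spearman_with_age(6:1, c(3, 9, 20, 35, 50, 70))["rho"]), -1)
  out <- spearman_with_age(c(10, 30, 20, 40), c(1, 2, 3, 4))
  expect_equal(unname(out["rho"]), 0.8)
  # exact permutation p at n = 4, checked against the exact reference
  ref <- cor.test(c(10, 30, 20, 40), 1:4, method = "spearman")
  expect_equal(unname(out["p_rho"]), ref$p.value, tolerance = 1e-12)
  expect_warning(spearman_with_age(rep(2, 5), 1:5), "undefined")
})

test_that("small-n Spearman p agrees with the exact cor.test reference", {
  set.seed(6)
  for (i in 1:10) {
    n <- sample(5:9, 1)
    y <- rnorm(n)
    a <- runif(n, 1, 80)
    got <- spearman_with_age(y, a)
    ref <- suppressWarnings(cor.test(y, a, method = "spearman"))
    expect_equal(unname(got["rho"]), unname(ref$estimate), tolerance = 1e-12)
    expect_equal(unname(got["p_rho"]), ref$p.value, tolerance = 1e-9)
  }
})

test_that("significance calls use strict p and inclusive q thresholds", {
  tab <- data.frame(gene = c("a", "b", "c", "d"),
                    p_age = c(0.0005, 0.0011, 0.001, 0.0005),
                    q_age = c(0.01, 0.01, 0.01, 0.05),
                    p_sex = 1, q_sex = 1,
                    rho = c(0.5, 0.5, 0.5, -0.5))
  out <- call_significant(tab)
  expect_equal(out$sig_age, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(out$direction, c(1, 0, 0, -1))
  # monotone: lowering p never removes significance
  tab2 <- tab
  tab2$p_age <- tab$p_age / 10
  out2 <- call_significant(tab2)
  expect_true(all(out2$sig_age >= out$sig_age))
})

test_that("merging is a union with |rho|-weighted direction tie-break", {
  mk <- function(genes, rhos, sig) {
    data.frame(gene = genes, beta_age = rhos, beta_sex = 0.2,
               p_age = 1e-5, p_sex = 1, q_age = 0.01, q_sex = 1,
               rho = rhos, p_rho = 1e-4, q_rho = 0.01,
               sig_age = sig, sig_sex = FALSE,
               direction = sign(rhos) * sig)
  }
  t1 <- mk(c("A", "B"), c(0.4, 0.3), TRUE)
  t2 <- mk(c("B", "C"), c(0.5, -0.2), TRUE)
  m <- merge_nonredundant(list(c1 = t1, c2 = t2))
  age <- m[m$covariate == "age", ]
  expect_setequal(age$gene, c("A", "B", "C"))
  expect_equal(age$cohorts[age$gene == "B"], "c1,c2")
  # conflicting directions: larger |rho| wins
  t3 <- mk("G", 0.4, TRUE)
  t4 <- mk("G", -0.2, TRUE)
  m2 <- merge_nonredundant(list(c1 = t3, c2 = t4))
  expect_equal(m2$direction[m2$covariate == "age"], 1)
  expect_equal(m2$cohorts[m2$covariate == "age"], "c1,c2")
  # exact tie -> 0 with warning
  t5 <- mk("G", -0.4, TRUE)
  expect_warning(m3 <- merge_nonredundant(list(c1 = t3, c2 = t5)), "tie")
  expect_equal(m3$direction[m3$covariate == "age"], 0)
  # empty cohorts give an empty set
  empty <- merge_nonredundant(list(c1 = mk("A", 0.4, FALSE)))
  expect_equal(nrow(empty), 0)
  # idempotent / order-invariant over cohorts
  m4 <- merge_nonredundant(list(c2 = t2, c1 = t1))
  expect_equal(m4[order(m4$gene), c("gene", "direction", "cohorts")],
               age[order(age$gene), c("gene", "direction", "cohorts")],
               ignore_attr = TRUE)
})

test_that("class proportion test reproduces exact Fisher tails", {
  catalog <- data.frame(symbol = sprintf("g%02d", 1:10),
                        class = rep(c("RBP", "TF"), each = 5))
  merged <- data.frame(gene = sprintf("g%02d", 1:5), covariate = "age",
                       direction = 1, cohorts = "c1")
  res <- class_proportion_test(catalog, merged, "RBP", "TF")
  expect_equal(unname(res$table[1, ]), c(5, 0))
  expect_equal(res$p, 2 / 252, tolerance = 1e-12)
  # identical proportions -> p = 1
  merged2 <- data.frame(gene = c(sprintf("g%02d", 1:2), sprintf("g%02d", 6:7)),
                        covariate = "age", direction = 1, cohorts = "c1")
  expect_equal(class_proportion_test(catalog, merged2, "RBP", "TF")$p, 1)
  expect_error(class_proportion_test(catalog, merged, "RBP", "missing"),
               "empty")
})

test_that("Fisher p equals brute-force enumeration for small margins", {
  set.seed(13)
  for (i in 1:20) {
    tab <- matrix(sample(0:6, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher.test(tab)$p.value, enum_fisher_two_sided(tab),
                 tolerance = 1e-9)
  }
})

test_that("sex difference summary uses the exact rank-sum distribution", {
  expr <- rbind(g1 = c(5, 6, 7, 1, 2, 3), g2 = c(4, 4, 4, 4, 4, 4))
  colnames(expr) <- paste0("s", 1:6)
  meta <- data.frame(sample_id = paste0("s", 1:6),
                     sex = rep(c("male", "female"), each = 3))
  out <- sex_difference_summary(expr, meta)
  expect_equal(out$p[out$gene == "g1"], 0.1)
  expect_equal(out$median_male[out$gene == "g1"], 6)
  expect_equal(out$median_female[out$gene == "g1"], 2)
  expect_equal(out$p[out$gene == "g2"], 1)
  # rank invariance under constant shifts
  out2 <- sex_difference_summary(expr + 100, meta)
  expect_equal(out2$p, out$p)
})

test_that("age bins use the half-open convention with a closed last bin", {
  meta <- data.frame(sample_id = 1:6,
                     age = c(19.9, 20, 0, 5, 25, 45))
  bins <- bin_ages(meta)
  expect_equal(bins[1], "[0,20)")
  expect_equal(bins[2], "[20,40)")
  expect_equal(length(unique(bins[4:6])), 3)
  expect_equal(bin_ages(data.frame(age = 120))[1], "[100,120]")
  expect_error(bin_ages(meta, width = 0), "positive")
})

test_that("bin means average member samples and flag empty bins", {
  expr <- rbind(const = rep(4, 4), lin = 1:4)
  colnames(expr) <- paste0("s", 1:4)
  bins <- c("[0,20)", "[0,20)", "[20,40)", "[20,40)")
  bm <- bin_means(expr, bins)
  expect_equal(unname(bm["const", ]), c(4, 4))
  expect_equal(unname(bm["lin", ]), c(1.5, 3.5))
  bm2 <- bin_means(expr, bins, levels = c("[0,20)", "[20,40)", "[40,60)"))
  expect_true(all(is.na(bm2[, "[40,60)"])))
})

test_that("correlation-distance clustering separates duplicated profiles", {
  base1 <- c(1, 2, 3, 4, 5)
  base2 <- c(5, 4, 3, 2, 1)
  m <- rbind(a1 = base1, a2 = base1, a3 = base1,
             b1 = base2, b2 = base2, b3 = base2)
  lab <- hierarchical_clusters(m, k = 2)
  expect_equal(length(unique(lab[c("a1", "a2", "a3")])), 1)
  expect_equal(length(unique(lab[c("b1", "b2", "b3")])), 1)
  expect_false(lab["a1"] == lab["b1"])
  # row scaling/shifting leaves labels unchanged
  m2 <- m * 3 + 10
  expect_equal(hierarchical_clusters(m2, k = 2), lab)
  # constant rows go to the residual cluster with a warning
  m3 <- rbind(m, flat = rep(2, 5))
  expect_warning(lab3 <- hierarchical_clusters(m3, k = 2), "residual")
  expect_equal(unname(lab3["flat"]), 0L)
})

test_that("two-block correlation structure is recovered as the best cut", {
  set.seed(21)
  t1 <- sin(seq(0, pi, length.out = 8))
  t2 <- -t1
  m <- rbind(x1 = t1 + rnorm(8, 0, 0.01), x2 = t1 + rnorm(8, 0, 0.01),
             x3 = t1 + rnorm(8, 0, 0.01), y1 = t2 + rnorm(8, 0, 0.01),
             y2 = t2 + rnorm(8, 0, 0.01), y3 = t2 + rnorm(8, 0, 0.01))
  lab <- hierarchical_clusters(m, k = 2)
  expect_equal(length(unique(lab[1:3])), 1)
  expect_equal(length(unique(lab[4:6])), 1)
  expect_false(lab[1] == lab[4])
  # exhaustive check: no 2-partition has lower within-cluster distance
  z <- t(scale(t(m)))
  d <- 1 - cor(t(z))
  within <- function(members) {
    s <- 0
    for (cl in unique(members)) {
      idx <- which(members == cl)
      if (length(idx) > 1) s <- s + sum(d[idx, idx]) / 2
    }
    s
  }
  best <- Inf
  for (code in 1:(2^5)) {   # partitions of 6 items into <= 2 blocks
    members <- c(1, as.integer(intToBits(code))[1:5] + 1L)
    best <- min(best, within(members))
  }
  expect_equal(within(as.integer(factor(lab))), best)
})

test_that("the vectorized screen matches the per-gene model", {
  cfg <- synthetic_config(n_genes = 40, n_samples = 60,
                          frac_age_assoc = 0.25, frac_sex_assoc = 0.25,
                          age_slope = 0.05, sex_shift = 1.5, seed = 17L)
  co <- gen_cohort(cfg)
  scr <- assoc_screen(co$expr, co$meta)
  for (g in sample(rownames(co$expr), 8)) {
    ref <- fit_covariance_model(co$expr[g, ], co$meta$age, co$meta$sex)
    row <- scr$table[scr$table$gene == g, ]
    expect_equal(row$p_age, unname(ref["p_age"]), tolerance = 1e-10)
    expect_equal(row$p_sex, unname(ref["p_sex"]), tolerance = 1e-10)
    rs <- spearman_with_age(co$expr[g, ], co$meta$age)
    expect_equal(row$rho, unname(rs["rho"]), tolerance = 1e-10)
  }
  expect_s3_class(scr, "assoc_screen")
  expect_output(print(scr), "age-associated")
  expect_output(print(summary(scr)), "Top age associations")
})
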