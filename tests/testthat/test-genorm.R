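test_that("pairwise variation has its closed-form values", {
  q <- rbind(j = c(1, 2, 4), k = c(2, 4, 8))
  colnames(q) <- paste0("s", 1:3)
  expect_equal(pairwise_variation(q, "j", "k"), 0)

  q2 <- rbind(j = c(1, 1), k = c(1, 2))
  colnames(q2) <- c("s1", "s2")
  expect_equal(pairwise_variation(q2, "j", "k"), sd(c(0, -1)))
  expect_equal(pairwise_variation(q2, "j", "k"), 1 / sqrt(2),
               tolerance = 1e-12)

  one <- rbind(j = 1, k = 2); colnames(one) <- "s1"
  expect_error(pairwise_variation(one, "j", "k"),
               class = "ctstab_insufficient_data")
})

test_that("pairwise variation is symmetric on random matrices", {
  q <- random_q(6, 7, seed = 21)
  for (a in rownames(q)) for (b in rownames(q)) {
    if (a != b) {
      expect_equal(pairwise_variation(q, a, b),
                   pairwise_variation(q, b, a), tolerance = 1e-14)
    }
  }
})

test_that("M equals the brute-force pairwise-SD mean", {
  q <- random_q(4, 4, seed = 2)
  for (g in rownames(q)) {
    expect_equal(m_value(q, g), brute_force_m(q, g), tolerance = 1e-12)
  }
  # genes with identical profiles attain the smallest M
  q3 <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8),
              c = c(1, 8, 2, 0.5))
  colnames(q3) <- paste0("s", 1:4)
  m <- sapply(rownames(q3), function(g) m_value(q3, g))
  expect_lt(max(m[c("a", "b")]), m["c"])
  expect_error(m_value(q3, "a", subset = "a"),
               class = "ctstab_insufficient_data")
})

test_that("stepwise exclusion removes the noisiest gene first", {
  # three genes, two identical: the outlier goes first, pair M = 0
  q3 <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8),
              c = c(1, 8, 2, 0.5))
  colnames(q3) <- paste0("s", 1:4)
  fit3 <- genorm(q3)
  expect_identical(fit3$exclusion_order, "c")
  expect_setequal(fit3$final_pair, c("a", "b"))
  expect_equal(fit3$stability$m[fit3$stability$gene %in% c("a", "b")],
               c(0, 0))

  # planted large-noise gene on top of a stable panel
  set.seed(31)
  base <- matrix(2^rnorm(5 * 20, sd = 0.1), 5, 20)
  noisy <- 2^rnorm(20, sd = 2)
  q <- rbind(base, noisy)
  rownames(q) <- paste0("g", 1:6); colnames(q) <- paste0("s", 1:20)
  fit <- genorm(q)
  expect_identical(fit$exclusion_order[1], "g6")
  expect_identical(fit$stability$rank[6], 6L)
})

test_that("reported M values follow the exclusion-round convention", {
  q <- random_q(6, 9, seed = 13)
  fit <- genorm(q)
  expect_true(all(fit$stability$m >= 0))
  # final pair shares one M value and joint rank 1
  pair_rows <- fit$stability$gene %in% fit$final_pair
  expect_identical(length(unique(fit$stability$m[pair_rows])), 1L)
  expect_identical(fit$stability$rank[pair_rows], c(1L, 1L))
  # ranks are 1,1,3..k
  expect_identical(sort(fit$stability$rank), c(1L, 1L, 3:6))
  # each excluded gene's M is its M in the round of removal
  remaining <- rownames(q)
  for (i in seq_along(fit$exclusion_order)) {
    g <- fit$exclusion_order[i]
    expect_equal(fit$stability$m[fit$stability$gene == g],
                 m_value(q, g, remaining), tolerance = 1e-12)
    remaining <- setdiff(remaining, g)
  }
  # full-set M agrees with brute force
  for (g in rownames(q)) {
    expect_equal(fit$full_set_m[[g]], brute_force_m(q, g),
                 tolerance = 1e-12)
  }
})

test_that("normalization factors are geometric means of the top genes", {
  q <- rbind(a = c(1, 9), b = c(4, 16), c = c(2, 5))
  colnames(q) <- c("s1", "s2")
  nf <- normalization_factor(q, c("a", "b", "c"), 2)
  expect_equal(unname(nf), c(2, 12))
  # order within the chosen set does not matter
  expect_equal(normalization_factor(q, c("b", "a", "c"), 2), nf)
  expect_error(normalization_factor(q, c("a", "b", "c"), 1),
               class = "ctstab_validation_error")
  expect_error(normalization_factor(q, c("a", "b", "c"), 4),
               class = "ctstab_validation_error")
})

test_that("the V criterion picks the smallest adequate n", {
  # top genes near-identical: adding a third changes nothing, V2/3 ~ 0
  set.seed(17)
  stable <- 2^rnorm(12, sd = 0.02)
  q <- rbind(a = stable * 2^rnorm(12, sd = 0.01),
             b = stable * 2^rnorm(12, sd = 0.01),
             c = stable * 2^rnorm(12, sd = 0.01),
             d = 2^rnorm(12, sd = 1.5))
  colnames(q) <- paste0("s", 1:12)
  fit <- genorm(q)
  expect_identical(fit$optimal_n, 2L)
  expect_false(fit$v_warning)
  expect_true(all(fit$v >= 0))

  # nothing below threshold: fall back to all genes with a warning flag
  set.seed(18)
  qq <- matrix(2^rnorm(4 * 10, sd = 2), 4, 10,
               dimnames = list(letters[1:4], paste0("s", 1:10)))
  fit2 <- genorm(qq)
  if (all(fit2$v > 0.15)) {
    expect_identical(fit2$optimal_n, 4L)
    expect_true(fit2$v_warning)
  }
  vc <- v_criterion(qq, rownames(qq), v_threshold = 1e9)
  expect_identical(vc$optimal_n, 2L)
})

test_that("M and V are invariant to per-gene and per-sample scaling", {
  q <- random_q(5, 8, seed = 23)
  fit <- genorm(q)
  # per-gene multiplicative scaling (additive Ct shift)
  gene_scaled <- q * 2^runif(5, -3, 3)
  fit_g <- genorm(gene_scaled)
  expect_equal(fit_g$full_set_m, fit$full_set_m, tolerance = 1e-12)
  expect_equal(fit_g$v, fit$v, tolerance = 1e-12)
  expect_identical(fit_g$ranking, fit$ranking)
  # per-sample multiplicative scaling (loading differences)
  sample_scaled <- sweep(q, 2, 2^runif(8, -2, 2), "*")
  fit_s <- genorm(sample_scaled)
  expect_equal(fit_s$full_set_m, fit$full_set_m, tolerance = 1e-12)
  expect_equal(fit_s$v, fit$v, tolerance = 1e-12)
})

test_that("exclusion ties break toward the later gene deterministically", {
  # two identical unstable genes tie for worst M every round
  set.seed(41)
  stable <- matrix(2^rnorm(3 * 10, sd = 0.05), 3, 10)
  wobble <- 2^rnorm(10, sd = 1)
  q <- rbind(stable, wobble, wobble)
  rownames(q) <- paste0("g", 1:5); colnames(q) <- paste0("s", 1:10)
  fit <- genorm(q)
  expect_identical(fit$exclusion_order[1], "g5")
  expect_identical(fit$exclusion_order[2], "g4")
})
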