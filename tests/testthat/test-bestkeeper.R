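test_that("descriptive statistics match direct formulas", {
  const <- matrix(25, 1, 5, dimnames = list("g", paste0("s", 1:5)))
  d <- bestkeeper_descriptives(const)
  expect_equal(d$sd_ct, 0)
  expect_equal(d$cv_pct, 0)
  expect_equal(d$geo_mean_ct, 25)

  two <- matrix(c(20, 30), 1, dimnames = list("g", c("a", "b")))
  d2 <- bestkeeper_descriptives(two)
  expect_equal(d2$arith_mean_ct, 25)
  expect_equal(d2$geo_mean_ct, sqrt(600), tolerance = 1e-12)

  set.seed(61)
  m <- matrix(runif(40, 18, 34), 5, 8,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  d3 <- bestkeeper_descriptives(m)
  for (i in 1:5) {
    expect_equal(d3$geo_mean_ct[i], exp(mean(log(m[i, ]))),
                 tolerance = 1e-12)
    expect_equal(d3$sd_ct[i], sd(m[i, ]), tolerance = 1e-12)
    expect_equal(d3$cv_pct[i], 100 * sd(m[i, ]) / mean(m[i, ]),
                 tolerance = 1e-12)
    expect_equal(d3$min_ct[i], min(m[i, ]))
    expect_equal(d3$max_ct[i], max(m[i, ]))
  }
  # the applet-compatible dispersion mode
  d4 <- bestkeeper_descriptives(m, sd_mode = "mad_geomean")
  for (i in 1:5) {
    expect_equal(d4$sd_ct[i],
                 mean(abs(m[i, ] - exp(mean(log(m[i, ]))))),
                 tolerance = 1e-12)
  }
})

test_that("panel reduction keeps the jointly best genes", {
  sim <- simulate_ct_panel(panel_spec("stress", n_genes = 14, seed = 62))
  m <- average_replicates(sim$ct)
  g_fit <- genorm(relative_quantities(m))
  n_fit <- normfinder(-m, groups = rep(c("leaf", "root"), each = 25))
  kept <- select_input_genes(g_fit, n_fit, limit = 10)
  expect_identical(length(kept), 10L)
  # planted unstable genes are ranked worst by both methods: always cut
  expect_false(any(c("G13", "G14") %in% kept))
  # small panels pass through unchanged
  small_g <- genorm(relative_quantities(m[1:8, ]))
  small_n <- normfinder(-m[1:8, ], groups = rep(c("leaf", "root"),
                                                each = 25))
  expect_identical(select_input_genes(small_g, small_n, limit = 10),
                   rownames(m)[1:8])
  expect_error(select_input_genes(small_g, n_fit),
               class = "ctstab_integrity_error")
})

test_that("unambiguous worst genes are exactly the ones dropped", {
  mk_rank <- function(genes, ranks) {
    list(stability = data.frame(gene = genes, rank = ranks,
                                stringsAsFactors = FALSE))
  }
  genes <- paste0("g", 1:12)
  g_fit <- mk_rank(genes, 1:12)
  n_fit <- mk_rank(genes, c(2, 1, 3:12))
  kept <- select_input_genes(g_fit, n_fit, limit = 10)
  expect_setequal(kept, genes[1:10])
})

test_that("index correlation flags SD and significance failures", {
  set.seed(63)
  n <- 12
  base <- 25 + rnorm(n, sd = 0.6)
  m <- rbind(g1 = base + rnorm(n, sd = 0.05),
             g2 = base + rnorm(n, sd = 0.05),
             g3 = base + rnorm(n, sd = 0.05),
             wild = 27 + rnorm(n, sd = 2.5),     # SD > 1: excluded
             flat = rep(26, n) + rnorm(n, sd = 0.02))  # uncorrelated
  colnames(m) <- paste0("s", 1:n)
  fit <- bestkeeper(m)
  st <- fit$stability
  expect_false(st$valid[st$gene == "wild"])
  expect_match(st$reason[st$gene == "wild"], "SD")
  expect_false("wild" %in% fit$retained)
  # excluded genes still receive an r for reporting
  expect_true(is.finite(st$r[st$gene == "wild"]))
  expect_false(st$valid[st$gene == "flat"])
  expect_match(st$reason[st$gene == "flat"], "P")
  # index is the geometric mean over retained genes only
  expect_equal(fit$index,
               exp(colMeans(log(m[fit$retained, ]))), tolerance = 1e-12)
  # valid ranks are 1..n_valid without gaps, ordered by descending r
  vr <- st[st$valid, ]
  expect_setequal(vr$rank, seq_len(nrow(vr)))
  expect_identical(order(-vr$r), order(vr$rank))
})

test_that("r matches the direct Pearson formula and its t-test", {
  set.seed(64)
  m <- matrix(25 + rnorm(36, sd = 0.4), 3, 12,
              dimnames = list(c("a", "b", "c"), paste0("s", 1:12)))
  fit <- bestkeeper(m)
  for (i in 1:3) {
    r_direct <- direct_pearson(m[i, ], fit$index)
    expect_equal(fit$stability$r[i], r_direct, tolerance = 1e-12)
    tt <- r_direct * sqrt(10) / sqrt(1 - r_direct^2)
    expect_equal(fit$stability$p_value[i], 2 * pt(-abs(tt), df = 10),
                 tolerance = 1e-10)
  }
  expect_true(all(abs(fit$stability$r) <= 1))
})

test_that("a gene proportional to the index correlates perfectly", {
  set.seed(65)
  base <- 25 + rnorm(10, sd = 0.5)
  m <- rbind(g1 = base, g2 = base + 0.2, g3 = 20 + 0.5 * (base - 25))
  colnames(m) <- paste0("s", 1:10)
  fit <- bestkeeper(m)
  # near 1, not exact: the geometric-mean index is not affine in Ct
  expect_equal(fit$stability$r, rep(1, 3), tolerance = 1e-6)

  # exactly identical profiles: every r = 1 and all ranks tie at 1
  ident <- rbind(g1 = base, g2 = base, g3 = base)
  colnames(ident) <- paste0("s", 1:10)
  fid <- bestkeeper(ident)
  expect_equal(fid$stability$r, rep(1, 3))
  expect_true(all(fid$stability$rank == 1L))
})

test_that("index is permutation-invariant and the SD filter is local", {
  set.seed(66)
  m <- matrix(25 + rnorm(48, sd = 0.4), 4, 12,
              dimnames = list(letters[1:4], paste0("s", 1:12)))
  f1 <- bestkeeper(m)
  f2 <- bestkeeper(m[c(3, 1, 4, 2), ])
  expect_equal(f2$index, f1$index, tolerance = 1e-12)
  expect_equal(sort(f2$stability$r), sort(f1$stability$r),
               tolerance = 1e-12)
  # adding an excluded gene does not change the others' SDs
  wild <- matrix(27 + rnorm(12, sd = 3), 1, 12,
                 dimnames = list("wild", colnames(m)))
  f3 <- bestkeeper(rbind(m, wild))
  expect_equal(f3$descriptives$sd_ct[1:4], f1$descriptives$sd_ct,
               tolerance = 1e-12)
  # degenerate: SD filter leaves fewer than 2 genes
  mm <- rbind(a = 25 + rnorm(12, sd = 3), b = 25 + rnorm(12, sd = 3),
              c = 25 + rnorm(12, sd = 0.1))
  colnames(mm) <- paste0("s", 1:12)
  expect_error(bestkeeper(mm), class = "ctstab_degenerate_index")
})
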