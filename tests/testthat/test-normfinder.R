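# builds grouped log-expression data under the variance model:
# y_igj = mu_i + tau_j + d_ig + noise(sigma_i)
make_grouped_y <- function(sigma, d, n_per_group, seed = 1,
                           sd_loading = 0.3) {
  set.seed(seed)
  k <- length(sigma)
  glev <- colnames(d)
  n <- n_per_group * length(glev)
  groups <- rep(glev, each = n_per_group)
  mu <- runif(k, 20, 30)
  tau <- rnorm(n, 0, sd_loading)
  y <- outer(mu, rep(1, n)) + outer(rep(1, k), tau) +
    d[, groups] + matrix(rnorm(k * n, 0, sigma), k, n)
  dimnames(y) <- list(names(sigma), paste0("s", seq_len(n)))
  list(y = y, groups = groups)
}

test_that("degenerate shared-profile data yields all-zero stability", {
  profile <- c(1, 3, 2, 5, 4, 6)
  y <- matrix(rep(profile, each = 4), 4, 6,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  fit <- normfinder(y, groups = rep(c("A", "B"), each = 3))
  expect_equal(fit$stability$s, rep(0, 4), tolerance = 1e-12)
  fit_u <- normfinder(y)
  expect_equal(fit_u$stability$s, rep(0, 4), tolerance = 1e-12)
})

test_that("input guards reject undersized problems", {
  y <- matrix(rnorm(2 * 6, 25), 2, 6,
              dimnames = list(c("a", "b"), paste0("s", 1:6)))
  expect_error(normfinder(y), class = "ctstab_insufficient_genes")
  y3 <- matrix(rnorm(3 * 3, 25), 3, 3,
               dimnames = list(letters[1:3], paste0("s", 1:3)))
  expect_error(normfinder(y3, groups = c("A", "A", "B")),
               class = "ctstab_insufficient_samples")
})

test_that("S is invariant to per-sample and per-gene additive shifts", {
  set.seed(52)
  y <- matrix(rnorm(5 * 12, 25, 1), 5, 12,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
  groups <- rep(c("leaf", "root"), each = 6)
  base <- normfinder(y, groups)
  shift_samples <- sweep(y, 2, runif(12, -4, 4), "+")
  shift_genes <- sweep(y, 1, runif(5, -4, 4), "+")
  expect_equal(normfinder(shift_samples, groups)$stability$s,
               base$stability$s, tolerance = 1e-10)
  expect_equal(normfinder(shift_genes, groups)$stability$s,
               base$stability$s, tolerance = 1e-10)
  # sign flip of the whole matrix (Ct vs -Ct orientation) also preserved
  expect_equal(normfinder(-y, groups)$stability$s,
               base$stability$s, tolerance = 1e-10)
})

test_that("ungrouped ordering matches the residual-sd oracle", {
  set.seed(53)
  sigma <- c(0.1, 0.5, 0.2, 0.9, 0.35, 0.15)
  names(sigma) <- paste0("g", 1:6)
  y <- outer(runif(6, 20, 30), rep(1, 40)) +
    outer(rep(1, 6), rnorm(40, 0, 0.3)) +
    matrix(rnorm(6 * 40, 0, sigma), 6, 40)
  dimnames(y) <- list(names(sigma), paste0("s", 1:40))
  fit <- normfinder(y)
  # direct two-way centering oracle
  r <- y - rowMeans(y) - matrix(colMeans(y), 6, 40, byrow = TRUE) +
    mean(y)
  resid_sd <- apply(r, 1, function(z) sqrt(sum(z^2) / (ncol(y) - 1)))
  expect_identical(order(fit$stability$s), order(resid_sd))
})

test_that("variance components are recovered on generated truth", {
  # the study-condition noise structure: a mostly-stable panel with two
  # planted unstable genes drifting in opposite directions across groups
  sigma <- c(g1 = 0.15, g2 = 0.15, g3 = 0.15, g4 = 0.15, g5 = 0.15,
             g6 = 0.15, g7 = 0.3, g8 = 0.3)
  d <- cbind(A = c(0, 0, 0, 0, 0, 0, 0.8, -0.8),
             B = c(0, 0, 0, 0, 0, 0, -0.8, 0.8))
  rownames(d) <- names(sigma)
  dat <- make_grouped_y(sigma, d, n_per_group = 200, seed = 54)
  fit <- normfinder(dat$y, dat$groups)
  sigma2_hat <- rowMeans(fit$sigma2)
  expect_true(all(abs(sigma2_hat - sigma^2) / sigma^2 < 0.15))
  # planted unstable genes occupy the last two stability ranks
  expect_setequal(fit$stability$gene[order(-fit$stability$s)][1:2],
                  c("g7", "g8"))
  expect_true(all(fit$stability$s >= 0))
})

test_that("sigma2 estimates are unbiased on homoscedastic panels", {
  sigma <- rep(0.4, 6); names(sigma) <- paste0("g", 1:6)
  d <- cbind(A = rep(0, 6), B = rep(0, 6)); rownames(d) <- names(sigma)
  means <- vapply(1:50, function(s) {
    dat <- make_grouped_y(sigma, d, n_per_group = 500, seed = 1000 + s)
    mean(normfinder(dat$y, dat$groups)$sigma2)
  }, numeric(1))
  expect_equal(mean(means), 0.16, tolerance = 0.02)
  expect_true(all(normfinder(make_grouped_y(sigma, d, 50)$y,
                             rep(c("A", "B"), each = 50))$sigma2 >= 0))
})

test_that("opposite-drift genes pair up and beat any single gene", {
  sigma <- c(a = 0.2, b = 0.2, up = 0.2, down = 0.2, e = 0.6)
  d <- cbind(A = c(0.05, -0.05, 1.2, -1.2, 0.4),
             B = c(-0.05, 0.05, -1.2, 1.2, -0.4))
  rownames(d) <- names(sigma)
  dat <- make_grouped_y(sigma, d, n_per_group = 60, seed = 55)
  fit <- normfinder(dat$y, dat$groups)
  bp <- best_pair(fit)
  expect_setequal(bp$pair, c("up", "down"))
  expect_lt(bp$s, min(fit$stability$s[match(c("up", "down"),
                                            fit$stability$gene)]))
  # independent recomputation of the pair statistic
  i <- match(bp$pair[1], fit$stability$gene)
  j <- match(bp$pair[2], fit$stability$gene)
  dA <- (fit$d_shrunk[i, ] + fit$d_shrunk[j, ]) / 2
  vA <- ((fit$sigma2[i, ] + fit$sigma2[j, ]) / 4) / fit$n_g
  g <- fit$gamma_hat
  expect_equal(bp$s, mean(abs(dA) + sqrt(vA * g / (g + vA))),
               tolerance = 1e-12)
})

test_that("best pair requires grouped mode", {
  set.seed(56)
  y <- matrix(rnorm(4 * 8, 25), 4, 8,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:8)))
  fit <- normfinder(y)
  expect_error(best_pair(fit), class = "ctstab_unsupported_mode")
})
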