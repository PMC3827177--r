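make_long <- function(n_subj, levs, fun) {
  g <- expand.grid(c(list(subject = sprintf("S%02d", seq_len(n_subj))), levs),
                   stringsAsFactors = FALSE)
  g$y <- fun(g)
  g
}

test_that("rm_anova returns F = 0 when every cell is identical", {
  d <- make_long(6, list(a = c("x", "y"), b = c("p", "q", "r")),
                 function(g) rep(7, nrow(g)))
  fit <- rm_anova(d, "y", "subject", c("a", "b"))
  expect_true(all(fit$F == 0))
  expect_true(all(fit$p == 1))
})

test_that("two-level factors have epsilon = 1 and p_gg = p", {
  set.seed(1)
  d <- make_long(10, list(a = c("x", "y")),
                 function(g) rnorm(nrow(g)) + (g$a == "y"))
  fit <- rm_anova(d, "y", "subject", "a")
  expect_equal(fit$epsilon, 1)
  expect_equal(fit$p_gg, fit$p)
  expect_equal(fit$df1, 1)
  expect_equal(fit$df2, 9)
})

test_that("rm_anova matches aov sums of squares on a random 3-way design", {
  set.seed(2)
  d <- make_long(8, list(a = c("a1", "a2"), b = c("b1", "b2", "b3"),
                         c = c("c1", "c2")),
                 function(g) rnorm(nrow(g)))
  fit <- rm_anova(d, "y", "subject", c("a", "b", "c"))
  d2 <- d
  for (f in c("subject", "a", "b", "c")) d2[[f]] <- factor(d2[[f]])
  ref <- summary(stats::aov(y ~ a * b * c + Error(subject / (a * b * c)),
                            data = d2))
  for (eff in c("a", "b", "c", "a:b", "a:c", "b:c", "a:b:c")) {
    stratum <- ref[[paste0("Error: subject:", eff)]][[1]]
    expect_equal(fit$F[fit$effect == eff], stratum[eff, "F value"],
                 tolerance = 1e-8, label = paste("F for", eff))
    expect_equal(fit$p[fit$effect == eff], stratum[eff, "Pr(>F)"],
                 tolerance = 1e-8, label = paste("p for", eff))
  }
})

test_that("rm_anova rejects unbalanced designs and tiny samples", {
  d <- make_long(4, list(a = c("x", "y")), function(g) rnorm(nrow(g)))
  expect_error(rm_anova(d[-1, ], "y", "subject", "a"), "not balanced")
  d1 <- d[d$subject == "S01", ]
  expect_error(rm_anova(d1, "y", "subject", "a"), "at least 2")
})

test_that("posthoc flags the shifted cell and orders LSD <= HSD", {
  set.seed(3)
  d <- make_long(12, list(a = c("a1", "a2", "a3")),
                 function(g) rnorm(nrow(g), sd = 0.3) + 2 * (g$a == "a3"))
  fit <- rm_anova(d, "y", "subject", "a")
  hsd <- posthoc(fit, "a", "tukey_hsd")
  lsd <- posthoc(fit, "a", "fisher_lsd")
  expect_true(all(lsd$p <= hsd$p + 1e-12))
  involves3 <- grepl("a3", hsd$cell_a) | grepl("a3", hsd$cell_b)
  expect_true(max(hsd$p[involves3]) < min(hsd$p[!involves3]))
  expect_true(all(hsd$p[involves3] < 0.01))
  expect_error(posthoc(fit, "a", "scheffe"))
})

test_that("posthoc on identical cell means gives p near 1", {
  set.seed(4)
  subj_eff <- rnorm(9)
  d <- make_long(9, list(a = c("a1", "a2")),
                 function(g) subj_eff[match(g$subject,
                                            unique(g$subject))] +
                   rnorm(nrow(g), sd = 1e-8))
  fit <- rm_anova(d, "y", "subject", "a")
  expect_gt(min(posthoc(fit, "a", "tukey_hsd")$p), 0.2)
})

test_that("wilcoxon_paired handles degenerate and extreme cases", {
  x <- 1:8
  expect_warning(res <- wilcoxon_paired(x, x), "all paired differences")
  expect_identical(res$W, 0)
  expect_identical(res$p, 1)
  # all differences positive and distinct: W maximal, exact p = 2 / 2^n
  y <- x - (1:8) / 10
  res2 <- wilcoxon_paired(x, y)
  expect_equal(res2$W, 8 * 9 / 2)
  expect_equal(res2$p, 2 / 2^8)
  expect_error(wilcoxon_paired(1:4, 2:5), "at least 5")
})

test_that("wilcoxon_paired agrees with full enumeration at n = 10", {
  set.seed(5)
  x <- rnorm(10)
  y <- x + rnorm(10, 0.4)
  res <- wilcoxon_paired(x, y)
  d <- x - y
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  expect_equal(res$W, W_obs)
  # enumerate all 2^10 sign assignments
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 10)))
  Ws <- signs %*% r
  mu <- 10 * 11 / 4
  p_exact <- mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-12)
  expect_equal(res$p, p_exact, tolerance = 1e-12)
})

test_that("spearman_perm recovers perfect monotone association", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  res <- spearman_perm(x, exp(x), n_perm = 999)
  expect_equal(res$rho, 1)
  # only re-draws of the identity permutation can tie |rho| = 1
  expect_lte(res$p, 0.01)
  res2 <- spearman_perm(x, -x, n_perm = 999)
  expect_equal(res2$rho, -1)
  expect_error(spearman_perm(x, rep(1, 7)), "constant")
  expect_error(spearman_perm(1:2, 2:1), "at least 3")
})

test_that("spearman_perm rho matches the rank-difference formula at n = 18", {
  set.seed(6)
  x <- rnorm(18)
  y <- rnorm(18)
  res <- spearman_perm(x, y, n_perm = 99, rng_seed = 2)
  d <- rank(x) - rank(y)
  expect_equal(res$rho, 1 - 6 * sum(d^2) / (18 * (18^2 - 1)),
               tolerance = 1e-12)
  # seeded determinism
  expect_identical(res, spearman_perm(x, y, n_perm = 99, rng_seed = 2))
})

test_that("feature_regression is exact on a noiseless linear response", {
  set.seed(7)
  X <- data.frame(a = rnorm(20), b = rnorm(20))
  yy <- 2 + 3 * X$a - X$b
  # summary.lm warns about the (intended) essentially perfect fit
  res <- suppressWarnings(feature_regression(X, yy))
  expect_equal(res$r_squared, 1, tolerance = 1e-12)
  est <- res$coefficients$estimate
  names(est) <- res$coefficients$term
  expect_equal(unname(est[c("(Intercept)", "a", "b")]), c(2, 3, -1),
               tolerance = 1e-9)
  expect_lt(res$p, 1e-12)
})

test_that("feature_regression null R^2 matches its expectation k/(n-1)", {
  set.seed(8)
  r2 <- replicate(300, {
    X <- data.frame(a = rnorm(25), b = rnorm(25), c = rnorm(25))
    feature_regression(X, rnorm(25))$r_squared
  })
  expect_equal(mean(r2), 3 / 24, tolerance = 0.025)
})

test_that("feature_regression warns on collinearity, errors on tiny n", {
  set.seed(9)
  a <- rnorm(15)
  X <- data.frame(a = a, b = a + rnorm(15, sd = 1e-4))
  expect_warning(feature_regression(X, rnorm(15)), "collinear")
  expect_error(feature_regression(data.frame(a = rnorm(5)), rnorm(5)),
               "at least 10")
  expect_error(feature_regression(data.frame(a = rnorm(12)), rnorm(10)),
               "length mismatch")
})
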