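test_that("t tests handle degenerate and identical inputs", {
  r <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$terms$statistic, 0)
  expect_equal(r$terms$p, 1)
  r2 <- unpaired_t(c(2, 2, 2), c(2, 2, 2))
  expect_equal(r2$terms$statistic, 0)
  expect_equal(r2$terms$p, 1)
})

test_that("unpaired t uses pooled variance with df = n1 + n2 - 2", {
  set.seed(1)
  x <- rnorm(11)
  y <- rnorm(11, 0.5)
  r <- unpaired_t(x, y)
  expect_equal(r$terms$df1, 20)
  # agrees with the textbook pooled formula
  sp <- sqrt(((10) * var(x) + (10) * var(y)) / 20)
  t_manual <- (mean(x) - mean(y)) / (sp * sqrt(1 / 11 + 1 / 11))
  expect_equal(r$terms$statistic, t_manual, tolerance = 1e-12)
})

test_that("RM ANOVA: equal level means give F = 0; df are epsilon-scaled", {
  Y <- matrix(rnorm(8), 8, 3)[, c(1, 1, 1)] # identical columns per subject
  r <- rm_anova_gg(wide_to_long(Y), posthoc = FALSE)
  expect_equal(r$terms$statistic, 0)
  expect_equal(r$terms$df1, r$terms$epsilon * 2)
})

test_that("RM ANOVA with k = 2 equals the squared paired t with epsilon 1", {
  set.seed(2)
  for (i in 1:10) {
    Y <- matrix(rnorm(12, rep(c(0, 0.8), each = 6)), 6, 2)
    r <- rm_anova_gg(wide_to_long(Y), posthoc = FALSE)
    t <- paired_t(Y[, 1], Y[, 2])$terms$statistic
    expect_equal(r$terms$statistic, t^2, tolerance = 1e-10)
    expect_equal(r$terms$epsilon, 1)
  }
})

test_that("RM ANOVA F matches a brute-force sums-of-squares oracle", {
  set.seed(3)
  for (i in 1:10) {
    n <- sample(3:6, 1)
    k <- sample(3:5, 1)
    Y <- matrix(rnorm(n * k, rep(rnorm(k), each = n)), n, k)
    r <- rm_anova_gg(wide_to_long(Y), posthoc = FALSE)
    expect_equal(r$terms$statistic, oracle_rm_anova(Y), tolerance = 1e-10)
  }
})

test_that("RM ANOVA agrees with the multivariate-model route (GG included)", {
  set.seed(4)
  Y <- matrix(rnorm(21, rep(c(0, 0.4, 1), each = 7)), 7, 3)
  r <- rm_anova_gg(wide_to_long(Y), posthoc = FALSE)
  fit <- lm(Y ~ 1)
  a <- suppressWarnings(
    summary(car::Anova(fit, idata = data.frame(c_ = factor(1:3)),
                       idesign = ~c_, type = 3),
            multivariate = FALSE))
  expect_equal(r$terms$statistic,
               unname(a$univariate.tests["c_", "F value"]),
               tolerance = 1e-10)
  expect_equal(r$terms$epsilon, unname(a$pval.adjustments["c_", "GG eps"]),
               tolerance = 1e-10)
  expect_equal(r$terms$p, unname(a$pval.adjustments["c_", "Pr(>F[GG])"]),
               tolerance = 1e-10)
})

test_that("incomplete within designs are rejected naming the subject", {
  d <- wide_to_long(matrix(rnorm(12), 4, 3))
  d <- d[-5, ]
  expect_error(rm_anova_gg(d), "missing cells for subject")
})

test_that("Greenhouse-Geisser epsilon stays within its bounds", {
  set.seed(5)
  for (i in 1:30) {
    k <- sample(3:6, 1)
    n <- k + sample(2:5, 1)
    Y <- matrix(rnorm(n * k), n, k)
    Y[, 1] <- Y[, 1] * runif(1, 0.3, 3)  # break sphericity
    r <- rm_anova_gg(wide_to_long(Y), posthoc = FALSE)
    expect_gte(r$terms$epsilon, 1 / (k - 1) - 1e-12)
    expect_lte(r$terms$epsilon, 1 + 1e-12)
  }
})

test_that("mixed ANOVA matches the brute-force oracle on balanced designs", {
  set.seed(6)
  for (i in 1:8) {
    n_g <- 4
    k <- sample(3:4, 1)
    Y <- rbind(matrix(rnorm(n_g * k), n_g, k),
               matrix(rnorm(n_g * k, 0.6), n_g, k))
    grp <- rep(c("A", "B"), each = n_g)
    r <- mixed_anova(wide_to_long(Y, grp), posthoc = FALSE)
    o <- oracle_mixed_anova(Y, grp)
    expect_equal(r$terms$statistic[r$terms$term == "group"],
                 unname(o["group"]), tolerance = 1e-10)
    expect_equal(r$terms$statistic[r$terms$term == "condition"],
                 unname(o["time"]), tolerance = 1e-10)
    expect_equal(r$terms$statistic[r$terms$term == "group:condition"],
                 unname(o["interaction"]), tolerance = 1e-10)
  }
})

test_that("mixed ANOVA agrees with the multivariate route when unbalanced", {
  set.seed(7)
  n1 <- 5; n2 <- 8; k <- 3
  Y <- rbind(matrix(rnorm(n1 * k), n1, k),
             matrix(rnorm(n2 * k, rep(c(0, .5, 1), each = n2)), n2, k))
  grp <- c(rep("A", n1), rep("B", n2))
  r <- mixed_anova(wide_to_long(Y, grp), posthoc = FALSE)
  fit <- lm(Y ~ g, data = data.frame(g = factor(grp)),
            contrasts = list(g = "contr.sum"))
  a <- suppressWarnings(
    summary(car::Anova(fit, idata = data.frame(c_ = factor(1:k)),
                       idesign = ~c_, type = 3),
            multivariate = FALSE))
  ut <- a$univariate.tests
  expect_equal(r$terms$statistic, unname(ut[c("g", "c_", "g:c_"), "F value"]),
               tolerance = 1e-10)
  expect_equal(r$terms$p[2:3],
               unname(a$pval.adjustments[c("c_", "g:c_"), "Pr(>F[GG])"]),
               tolerance = 1e-10)
})

test_that("duplicating identical level profiles across groups kills the interaction", {
  set.seed(8)
  base <- matrix(rnorm(15), 5, 3)
  Y <- rbind(base, base + 2)       # pure group shift, parallel cell profiles
  grp <- rep(c("A", "B"), each = 5)
  r <- mixed_anova(wide_to_long(Y, grp), posthoc = FALSE)
  expect_equal(r$terms$statistic[r$terms$term == "group:condition"], 0,
               tolerance = 1e-12)
})

test_that("two-way ANOVA reproduces a brute-force 2x2 interaction contrast", {
  set.seed(9)
  for (i in 1:5) {
    n <- 6
    d <- expand.grid(group = c("A", "B"), treatment = c("x", "y"))
    d <- d[rep(1:4, each = n), ]
    d$value <- rnorm(nrow(d), as.integer(d$group) * as.integer(d$treatment))
    r <- two_way_anova(d, posthoc = FALSE)
    # balanced 2x2: interaction F = (contrast estimate)^2 / (4 MSE / n)
    cm <- tapply(d$value, list(d$group, d$treatment), mean)
    est <- cm[1, 1] - cm[2, 1] - cm[1, 2] + cm[2, 2]
    mse <- sum(unlist(tapply(d$value, list(d$group, d$treatment),
                             function(v) (v - mean(v))^2))) / (4 * n - 4)
    f_manual <- est^2 / (4 * mse / n)
    expect_equal(r$terms$statistic[3], f_manual, tolerance = 1e-10)
  }
})

test_that("two-way ANOVA rejects empty cells", {
  d <- data.frame(value = rnorm(12),
                  group = rep(c("A", "B"), each = 6),
                  treatment = rep(c("x", "y", "x"), 4))
  d <- d[!(d$group == "B" & d$treatment == "y"), ]
  expect_error(two_way_anova(d), "empty design cell")
})

test_that("Sidak adjustment follows its closed form", {
  expect_equal(sidak_adjust(0.05, 1), 0.05)
  expect_equal(sidak_adjust(0.01, 3), 1 - 0.99^3)
  expect_equal(sidak_adjust(0.01, 3), 0.029701)
  expect_equal(sidak_adjust(0, 10), 0)
  expect_equal(sidak_adjust(1, 5), 1)
  set.seed(10)
  p <- runif(20)
  expect_true(all(sidak_adjust(p, 4) >= p))
})

test_that("Kruskal-Wallis H matches the hand-rank oracle", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  r <- kruskal_wallis(g, posthoc = FALSE)
  expect_equal(r$terms$statistic, oracle_kruskal_h(g), tolerance = 1e-12)
  expect_equal(r$terms$df1, 2)

  set.seed(11)
  g2 <- list(x = rnorm(7), y = rnorm(9, 1), z = rnorm(5))
  r2 <- kruskal_wallis(g2, posthoc = FALSE)
  expect_equal(r2$terms$statistic, oracle_kruskal_h(g2), tolerance = 1e-10)
})

test_that("tie correction lowers H relative to jittered untied data", {
  g_tied <- list(a = c(1, 1, 2), b = c(2, 3, 3), c = c(4, 4, 5))
  g_untied <- list(a = c(1, 1.01, 2), b = c(2.01, 3, 3.01),
                   c = c(4, 4.01, 5))
  # same rank structure, but untied data lack the tie penalty scaling
  h_tied_uncorrected <- oracle_kruskal_h(g_tied) *
    (1 - sum(sapply(table(unlist(g_tied)), function(t) t^3 - t)) /
       (9^3 - 9))
  expect_lt(h_tied_uncorrected, kruskal_wallis(g_tied)$terms$statistic)
  expect_equal(kruskal_wallis(g_untied, posthoc = FALSE)$terms$statistic,
               oracle_kruskal_h(g_untied), tolerance = 1e-10)
})

test_that("identical values across groups give H = 0, p = 1", {
  r <- kruskal_wallis(list(a = c(2, 2), b = c(2, 2, 2)))
  expect_equal(r$terms$statistic, 0)
  expect_equal(r$terms$p, 1)
})

test_that("Dunn post-hoc p-values are valid and symmetric in group order", {
  set.seed(12)
  g <- list(a = rnorm(8), b = rnorm(8, 2), c = rnorm(8))
  r <- kruskal_wallis(g)
  expect_true(all(r$posthoc$p_adj >= r$posthoc$p_raw - 1e-12))
  expect_true(all(r$posthoc$p_adj >= 0 & r$posthoc$p_adj <= 1))
  r_rev <- kruskal_wallis(rev(g))
  expect_equal(sort(r_rev$posthoc$p_raw), sort(r$posthoc$p_raw),
               tolerance = 1e-12)
})

test_that("assumption checks flag degenerate samples and accept normal ones", {
  expect_true(assumption_checks(rep(3, 10))$degenerate)
  set.seed(13)
  x <- rnorm(60)
  g <- rep(c("a", "b"), 30)
  ch <- assumption_checks(x, g)
  expect_false(ch$degenerate)
  expect_gt(ch$ks_p, 0.01)
  expect_gt(ch$levene_p, 0.01)
  expect_true(ch$levene_p <= 1)
})

test_that("statistical results print in the reporting style", {
  r <- rm_anova_gg(wide_to_long(matrix(rnorm(12), 4, 3)))
  out <- capture.output(print(r))
  expect_match(out[1], "RM ANOVA")
  expect_match(paste(out, collapse = "\n"), "post-hoc")
})
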