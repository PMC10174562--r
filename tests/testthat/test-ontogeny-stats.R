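# brute-force sums-of-squares oracle for the one-way model
oneway_oracle <- function(values, groups) {
  g <- factor(groups)
  grand <- mean(values)
  means <- tapply(values, g, mean)
  ns <- tapply(values, g, length)
  ss_b <- sum(ns * (means - grand)^2)
  ss_w <- sum((values - means[g])^2)
  k <- nlevels(g); n <- length(values)
  f <- (ss_b / (k - 1)) / (ss_w / (n - k))
  list(f = f, r2 = ss_b / (ss_b + ss_w),
       p = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

test_that("one-way LM agrees with the sums-of-squares oracle", {
  set.seed(12)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    ns <- sample(3:9, k, replace = TRUE)
    g <- rep(letters[1:k], ns)
    y <- rnorm(sum(ns), mean = rep(runif(k, 0, 3), ns))
    fit <- fit_group_lm(y, g)
    orc <- oneway_oracle(y, g)
    expect_equal(fit$f_statistic, orc$f, tolerance = 1e-10)
    expect_equal(fit$r_squared, orc$r2, tolerance = 1e-10)
    expect_equal(fit$p_value, orc$p, tolerance = 1e-10)
    expect_equal(unname(fit$df), c(k - 1, sum(ns) - k))
  }
})

test_that("one-way LM handles degenerate and separated groups", {
  y <- c(1.0, 1.1, 0.9, 1.0, 1.1, 0.9)
  g <- rep(c("a", "b"), each = 3)
  fit <- fit_group_lm(y, g)
  expect_lt(fit$f_statistic, 1e-10)
  expect_gt(fit$p_value, 0.99)

  y2 <- c(1, 1.01, 0.99, 2, 2.01, 1.99)
  expect_lt(fit_group_lm(y2, g)$p_value, 1e-3)

  expect_error(fit_group_lm(c(1, 2, 3), c("a", "a", "b")), "b")
  expect_error(fit_group_lm(c(1, 2), c("a", "a")), "2 groups")
})

test_that("pairwise contrasts match Tukey HSD and reduce to t for k = 2", {
  set.seed(3)
  y <- rnorm(30, rep(c(0, 2, 5), each = 10))
  g <- rep(c("a", "b", "c"), each = 10)
  pw <- pairwise_contrasts(y, g, method = "tukey")
  hsd <- stats::TukeyHSD(stats::aov(y ~ factor(g)))$`factor(g)`
  expect_equal(sort(pw$adjusted_p), sort(unname(hsd[, "p adj"])),
               tolerance = 1e-8)
  expect_equal(sort(pw$estimate), sort(unname(hsd[, "diff"])),
               tolerance = 1e-10)

  # with two groups the Tukey adjustment is the plain two-sided t test
  y2 <- rnorm(12, rep(c(0, 0.5), each = 6))
  g2 <- rep(c("a", "b"), each = 6)
  pw2 <- pairwise_contrasts(y2, g2, method = "tukey")
  tt <- stats::t.test(y2[g2 == "b"], y2[g2 == "a"], var.equal = TRUE)
  expect_equal(pw2$adjusted_p, tt$p.value, tolerance = 1e-10)

  # three well-separated groups: everything significant
  expect_true(all(pw$adjusted_p < 0.05))
  expect_error(pairwise_contrasts(y, g, method = "bonferroni"), "arg")
})

test_that("compact letters encode the pairwise pattern exactly", {
  mk <- function(p) data.frame(group_i = c("g1", "g1", "g2"),
                               group_j = c("g2", "g3", "g3"),
                               adjusted_p = p)
  # all different
  expect_setequal(unname(compact_letter_display(mk(c(.001, .001, .001)))),
                  c("a", "b", "c"))
  # none different
  expect_equal(unname(compact_letter_display(mk(c(.5, .5, .5)))),
               rep("a", 3))
  # chain: g1 != g3, g1 == g2, g2 == g3  ->  a / ab / b
  cl <- compact_letter_display(mk(c(.5, .001, .5)))
  expect_equal(unname(cl[c("g1", "g2", "g3")]), c("a", "ab", "b"))

  # exhaustive random patterns for k <= 5: groups share a letter
  # iff their comparison is non-significant
  set.seed(21)
  for (rep_i in 1:60) {
    k <- sample(2:5, 1)
    gs <- paste0("g", 1:k)
    pairs <- utils::combn(gs, 2)
    pw <- data.frame(group_i = pairs[1, ], group_j = pairs[2, ],
                     adjusted_p = sample(c(0.001, 0.5), ncol(pairs),
                                         replace = TRUE))
    cl <- compact_letter_display(pw)
    for (p in seq_len(nrow(pw))) {
      li <- strsplit(cl[[pw$group_i[p]]], "")[[1]]
      lj <- strsplit(cl[[pw$group_j[p]]], "")[[1]]
      shares <- length(intersect(li, lj)) > 0
      expect_identical(shares, pw$adjusted_p[p] >= 0.05)
    }
    expect_true(all(nzchar(cl)))
  }
})

test_that("AIC selection minimises 2k - 2lnL with ties to fewer params", {
  set.seed(8)
  x <- rnorm(40); y <- 1 + 2 * x + rnorm(40, 0, 0.5)
  m1 <- lm(y ~ x); m2 <- lm(y ~ x + I(x^2))
  sel <- aic_select(list(linear = m1, quadratic = m2))
  expect_equal(sel$best, names(which.min(sel$aic)))
  expect_equal(unname(sel$aic["linear"]), stats::AIC(m1), tolerance = 1e-10)

  expect_equal(aic_select(list(only = m1))$best, "only")

  # identical AIC: the smaller model wins the tie-break
  fake <- function(ll, df) structure(list(), class = "fakefit",
                                     ll = ll, df = df)
  registerS3method("logLik", "fakefit", function(object, ...)
    structure(attr(object, "ll"), df = attr(object, "df"),
              class = "logLik"))
  a <- fake(-10, 2); b <- fake(-9, 3)  # both AIC = 24
  expect_equal(aic_select(list(big = b, small = a))$best, "small")

  # when the simpler nested model is true it is selected at the rate the
  # chi-square theory of the AIC penalty predicts: the complex model (two
  # extra parameters) wins when its deviance improvement exceeds 4, i.e.
  # with probability P(chisq_2 > 4) = exp(-2) ~ 0.135; 200 replicates give
  # 173 +/- 5 expected wins for the simple model, tested at 3 SD below
  wins <- 0L
  set.seed(15)
  for (i in 1:200) {
    x <- rnorm(25); y <- 1 + 2 * x + rnorm(25)
    sel <- aic_select(list(simple = lm(y ~ x),
                           complex = lm(y ~ x + I(x^2) + I(x^3))))
    if (sel$best == "simple") wins <- wins + 1L
  }
  expect_gte(wins, 158L)
})

test_that("covariate-adjusted contrasts match estimated marginal means", {
  set.seed(44)
  n <- 36
  g <- rep(c("4", "6", "9"), each = n / 3)
  x <- rnorm(n, rep(c(1, 2, 3), each = n / 3), 0.5)  # confounded covariate
  y <- 2 + 0.8 * x + rep(c(0, -0.5, -1.2), each = n / 3) + rnorm(n, 0, 0.4)

  res <- fit_group_lm(y, g, covariate = x)
  expect_equal(unname(res$df), c(2, n - 4))
  fit <- lm(y ~ x + gf, data = data.frame(y = y, x = x, gf = factor(g)))
  expect_equal(res$f_statistic, anova(fit)$`F value`[2], tolerance = 1e-10)

  em <- emmeans::emmeans(fit, "gf")
  es <- as.data.frame(em)
  expect_equal(unname(res$group_means[es$gf]), es$emmean, tolerance = 1e-8)

  pw <- pairwise_contrasts(y, g, method = "tukey", covariate = x)
  ep <- as.data.frame(emmeans::contrast(em, "pairwise", adjust = "tukey"))
  # emmeans reports first minus second level; ours is second minus first
  expect_equal(pw$estimate, -ep$estimate, tolerance = 1e-8)
  expect_equal(pw$se, ep$SE, tolerance = 1e-8)
  expect_equal(pw$adjusted_p, ep$p.value, tolerance = 1e-6)

  cmp <- compare_groups(y, g, covariate = x)
  expect_identical(cmp$pairwise$adjusted_p, pw$adjusted_p)
})

test_that("compare_groups assembles ANOVA, contrasts and letters", {
  set.seed(30)
  y <- rnorm(30, rep(c(0, 0.2, 5), each = 10), 0.5)
  g <- rep(c("4", "6", "9"), each = 10)
  cmp <- compare_groups(y, g)
  expect_s3_class(cmp, "group_comparison")
  expect_lt(cmp$anova$p_value, 1e-6)
  # group 9 differs from both others; 4 and 6 share a letter
  l <- cmp$letters
  expect_true(length(intersect(strsplit(l[["4"]], "")[[1]],
                               strsplit(l[["6"]], "")[[1]])) > 0)
  expect_false(any(strsplit(l[["9"]], "")[[1]] %in%
                     strsplit(l[["4"]], "")[[1]]))
})
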