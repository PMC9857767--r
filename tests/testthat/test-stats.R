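test_that("Box-Cox transform honors lambda = 1 and lambda = 0 exactly", {
  y <- c(0.5, 1, 2, 7, 11)
  expect_equal(boxcox_transform(y, lambda = 1)$values, y - 1)
  expect_equal(boxcox_transform(y, lambda = 0)$values, log(y))
  expect_error(boxcox_transform(c(1, 0, 2), lambda = 0), "record\\(s\\): 2")
})

test_that("Box-Cox lambda recovery: lognormal data give lambda near 0", {
  set.seed(123)
  y <- exp(rnorm(500))
  bt <- boxcox_transform(y)
  expect_lt(abs(bt$lambda), 0.15)
})

test_that("Box-Cox profile likelihood agrees with the MASS oracle", {
  skip_if_not_installed("MASS")
  set.seed(77)
  y <- exp(rnorm(300, 1, 0.7))
  bt <- boxcox_transform(y)
  bc <- MASS::boxcox(y ~ 1, lambda = seq(-3, 3, 0.01), plotit = FALSE)
  lambda_mass <- bc$x[which.max(bc$y)]
  expect_lt(abs(bt$lambda - lambda_mass), 0.02)
})

test_that("ANOVA degrees of freedom are pure functions of the design", {
  set.seed(10)
  recs <- simulate_records(list(A = 20, B = 25, C = 22), n_per_cell = 6)
  fit <- fit_accuracy_lm(recs, "trueness")
  tab <- fit$anova
  expect_equal(tab$df[tab$term == "scanner"], 2)
  expect_equal(tab$df[tab$term == "distance_group"], 1)
  expect_equal(tab$df[tab$term == "scanner:distance_group"], 2)
  expect_equal(tab$df[tab$term == "Residuals"], 3 * 2 * 6 - 2 * 3)
  expect_equal(tab$chisq, tab$F_value * tab$df)
})

test_that("empty scanner-by-group cells raise an explicit aliasing error", {
  recs <- simulate_records(list(A = 20, B = 25), n_per_cell = 5)
  recs <- recs[!(recs$scanner_id == "B" & recs$group == "long"), ]
  expect_error(fit_accuracy_lm(recs, "trueness"), "aliased",
               class = "scanmetry_aliasing_error")
})

test_that("Type-III and sequential sums of squares coincide on balanced data", {
  set.seed(55)
  recs <- simulate_records(list(A = 20, B = 30, C = 25, D = 28), n_per_cell = 8)
  fit <- fit_accuracy_lm(recs, "trueness", lambda = 1)
  seq_ss <- anova(fit$model)
  for (term in c("scanner", "distance_group", "scanner:distance_group")) {
    expect_equal(fit$anova$sum_sq[fit$anova$term == term],
                 seq_ss[term, "Sum Sq"], tolerance = 1e-8)
  }
})

test_that("type-I error of the scanner term is nominal under the null", {
  # lognormal absolute errors with no scanner effect; lambda = 0 is the
  # exactly normalizing transform, so the F-test level should be 0.05
  set.seed(2024)
  n_sim <- 300L
  n_cell <- 30L
  pvals <- vapply(seq_len(n_sim), function(s) {
    recs <- simulate_records(list(A = 3, B = 3, C = 3), n_per_cell = n_cell,
                             sd = 0.4, rdist = function(n, m, s) exp(rnorm(n, m, s)))
    fit <- fit_accuracy_lm(recs, "trueness", lambda = 0)
    fit$anova$p_value[fit$anova$term == "scanner"]
  }, numeric(1L))
  rate <- mean(pvals < 0.05)
  ci_half <- qnorm(0.995) * sqrt(0.05 * 0.95 / n_sim)
  expect_lt(abs(rate - 0.05), ci_half)
})

test_that("power to detect a 3-residual-SD scanner effect exceeds 0.8", {
  # 9 scanners x 2 groups x 30 replicates, scanner effects spanning 3 residual
  # SDs on the transformed scale
  set.seed(808)
  n_sim <- 500L
  effects <- seq(-1.5, 1.5, length.out = 9)
  names(effects) <- paste0("S", 1:9)
  hits <- vapply(seq_len(n_sim), function(s) {
    recs <- simulate_records(as.list(20 + 3 * effects), n_per_cell = 30, sd = 1)
    fit <- fit_accuracy_lm(recs, "trueness", lambda = 1)
    fit$anova$p_value[fit$anova$term == "scanner"] < 0.05
  }, logical(1L))
  expect_gte(mean(hits), 0.8)
})

test_that("Tukey letters separate shifted groups and join identical ones", {
  set.seed(31)
  recs <- simulate_records(list(A = 20, B = 20, C = 20 + 10), n_per_cell = 30,
                           sd = 1)
  fit <- fit_accuracy_lm(recs, "trueness", lambda = 1)
  ph <- tukey_posthoc(fit)
  for (g in c("short", "long")) {
    lt <- ph$letters[ph$letters$group == g, ]
    l <- setNames(lt$letters, lt$scanner)
    shares <- function(a, b) length(intersect(strsplit(l[[a]], "")[[1]],
                                              strsplit(l[[b]], "")[[1]])) > 0
    expect_true(shares("A", "B"))
    expect_false(shares("A", "C"))
    expect_false(shares("B", "C"))
  }
})

test_that("with two scanners the Tukey-adjusted p equals the plain t-test p", {
  set.seed(17)
  recs <- simulate_records(list(A = 20, B = 22), n_per_cell = 15)
  fit <- fit_accuracy_lm(recs, "trueness", lambda = 1)
  ph <- tukey_posthoc(fit)
  for (k in seq_len(nrow(ph$contrasts))) {
    row <- ph$contrasts[k, ]
    p_t <- 2 * pt(-abs(row$t_ratio), row$df)
    expect_equal(row$p_adj, p_t, tolerance = 1e-10)
  }
})

test_that("compact letters are consistent with the p matrix, exhaustively", {
  # crafted chain: A~B, B~C not significant, A-C significant
  pm <- matrix(c(NA, 0.2, 0.01, 0.2, NA, 0.3, 0.01, 0.3, NA), 3L,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  cl <- compact_letters(pm, c(A = 1, B = 2, C = 3))
  expect_equal(unname(cl), c("a", "ab", "b"))

  set.seed(63)
  for (rep in 1:25) {
    k <- sample(3:8, 1)
    g <- paste0("G", seq_len(k))
    pm <- matrix(NA_real_, k, k, dimnames = list(g, g))
    pv <- runif(k * (k - 1) / 2)^2
    pm[upper.tri(pm)] <- pv
    pm[lower.tri(pm)] <- t(pm)[lower.tri(pm)]
    means <- setNames(rnorm(k), g)
    cl <- compact_letters(pm, means, alpha = 0.05)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      share <- length(intersect(strsplit(cl[[g[i]]], "")[[1]],
                                strsplit(cl[[g[j]]], "")[[1]])) > 0
      expect_identical(share, pm[i, j] >= 0.05,
                       label = sprintf("rep %d pair %s-%s (p=%.3f)",
                                       rep, g[i], g[j], pm[i, j]))
    }
  }
})
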