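# Procrustes ANOVA, CVA, permutation tests, DFA and LOO cross-validation

test_that("procrustesAnova reproduces the factorial df bookkeeping", {
  ds <- simulateLandmarkDataset(seed = 3)     # 165 specimens, 13 landmarks
  fit <- gpa(ds)
  lab <- specimenLabels(fit)
  tab <- procrustesAnova(tangentCoords(fit), lab$sex, lab$species)
  expect_equal(tab$df, c(22, 22, 22, 3542))
  expect_equal(tab$MS, tab$SS / tab$df)
  # sequential SS decomposition sums to the total SS
  tg <- tangentCoords(fit)
  total <- sum(sweep(tg, 2, colMeans(tg))^2)
  expect_equal(sum(tab$SS), total, tolerance = 1e-8)
  # main effects tested over the interaction stratum by default
  expect_equal(tab$F[1], tab$MS[1] / tab$MS[3])
  tab_res <- procrustesAnova(tg, lab$sex, lab$species,
                             error_stratum = "residual")
  expect_equal(tab_res$F[1], tab_res$MS[1] / tab_res$MS[4])
  expect_equal(tab_res$SS, tab$SS)
})

test_that("procrustesAnova sequential SS match a brute-force nested-fit oracle", {
  set.seed(60)
  n <- 24
  Y <- matrix(rnorm(n * 6), n, 6)       # pretend 3-landmark tangent data
  sex <- factor(rep(c("F", "M"), each = n / 2))
  species <- factor(rep(c("canis", "orientis", "canis"), c(7, 9, 8)))
  tab <- procrustesAnova(Y, sex, species)
  # oracle: per-coordinate lm() residual sums over nested models
  rss <- function(form) {
    sum(vapply(seq_len(ncol(Y)), function(j) {
      df <- data.frame(y = Y[, j], sex = sex, species = species)
      sum(resid(lm(form, data = df))^2)
    }, 0))
  }
  r0 <- rss(y ~ 1); r1 <- rss(y ~ sex); r2 <- rss(y ~ sex + species)
  r3 <- rss(y ~ sex * species)
  expect_equal(tab$SS, c(r0 - r1, r1 - r2, r2 - r3, r3), tolerance = 1e-10)
  expect_equal(tab$df, c(2, 2, 2, (n - 4) * 2))
  # reversing the sequential order changes main-effect SS but not their sum
  tab_rev <- procrustesAnova(Y, sex, species, order = c("species", "sex"))
  expect_equal(sum(tab_rev$SS), sum(tab$SS), tolerance = 1e-10)
})

test_that("procrustesAnova flags degenerate designs and zero variance", {
  Y <- matrix(rnorm(40), 10, 4)
  expect_error(procrustesAnova(Y, factor(rep("F", 10)),
                               factor(rep(c("a", "b"), 5))),
               "2 levels")
  sex <- factor(rep(c("F", "M"), each = 5))
  species <- factor(c(rep("a", 5), rep("b", 5)))   # empty F:b cell
  expect_error(procrustesAnova(Y, sex, species), "empty")
  Yconst <- matrix(1, 12, 6)
  sex <- factor(rep(c("F", "M"), 6)); sp <- factor(rep(c("a", "a", "b"), 4))
  expect_warning(tab <- procrustesAnova(Yconst, sex, sp), "zero")
  expect_true(all(is.nan(tab$F[1:3])))
})

test_that("cva yields g-1 canonical variates with variance summing to 100", {
  ds <- simulateLandmarkDataset(group_sizes = c(20L, 15L, 18L, 12L), seed = 8)
  fit <- gpa(ds)
  lab <- specimenLabels(fit)
  cv <- cva(tangentCoords(fit), factor(lab$group), n_perm = 0)
  expect_length(cv@eigenvalues, 3)
  expect_equal(sum(cv@percentVar), 100, tolerance = 1e-6)
  expect_true(all(diff(cv@percentVar) <= 1e-9))
  expect_true(all(cv@percentVar >= 0))
  # scores have unit pooled within-group variance on every axis
  W <- fleamorph:::.pooledWithin(cv@scores, cv@groups)
  expect_equal(diag(W), rep(1, 3), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("two-group CVA matches the discriminant direction and a brute-force Mahalanobis", {
  set.seed(70)
  n1 <- 25; n2 <- 30; d <- 5
  Y <- rbind(matrix(rnorm(n1 * d), n1, d),
             matrix(rnorm(n2 * d, mean = 0.8), n2, d))
  g <- factor(rep(c("a", "b"), c(n1, n2)))
  cv <- cva(Y, g, n_perm = 0)
  expect_length(cv@eigenvalues, 1)
  # CV1 parallel to W^-1 (mu1 - mu2)
  W <- fleamorph:::.pooledWithin(Y, g)
  dirn <- solve(W, colMeans(Y[g == "a", ]) - colMeans(Y[g == "b", ]))
  cosang <- abs(sum(cv@axes[, 1] * dirn)) /
    sqrt(sum(cv@axes[, 1]^2) * sum(dirn^2))
  expect_gt(cosang, 1 - 1e-8)
  # Mahalanobis distance by direct quadratic form
  delta <- colMeans(Y[g == "a", ]) - colMeans(Y[g == "b", ])
  expect_equal(cv@mahalanobis[1, 2],
               sqrt(drop(t(delta) %*% solve(W, delta))), tolerance = 1e-8)
  # identical group means: zero distance and eigenvalue
  Y0 <- rbind(Y[g == "a", ], sweep(Y[g == "b", ], 2, delta, "+"))
  cv0 <- cva(Y0, g, n_perm = 0)
  expect_lt(cv0@mahalanobis[1, 2], 1e-8)
  expect_lt(cv0@eigenvalues[1], 1e-14)
})

test_that("Mahalanobis distances are invariant to affine transforms", {
  set.seed(71)
  Y <- matrix(rnorm(60 * 4), 60, 4)
  Y[31:60, ] <- Y[31:60, ] + 1
  g <- factor(rep(c("a", "b"), each = 30))
  A <- matrix(rnorm(16), 4, 4) + diag(4) * 2     # invertible
  m1 <- cva(Y, g, n_perm = 0)@mahalanobis[1, 2]
  m2 <- cva(Y %*% A, g, n_perm = 0)@mahalanobis[1, 2]
  expect_equal(m1, m2, tolerance = 1e-6)
})

test_that("cva cross-checks against MASS::lda on full-rank data", {
  skip_if_not_installed("MASS")
  set.seed(72)
  Y <- rbind(matrix(rnorm(40 * 3), 40, 3),
             matrix(rnorm(35 * 3, 1), 35, 3),
             matrix(rnorm(30 * 3, c(2, 0, 1)), 30, 3))
  g <- factor(rep(c("a", "b", "c"), c(40, 35, 30)))
  cv <- cva(Y, g, n_perm = 0)
  ld <- MASS::lda(Y, g)
  pv_mass <- 100 * ld$svd^2 / sum(ld$svd^2)
  expect_equal(cv@percentVar, pv_mass, tolerance = 1e-6)
})

test_that("permutation p-values are seeded, minimal under saturation", {
  set.seed(80)
  Y <- rbind(matrix(rnorm(15 * 4), 15, 4),
             matrix(rnorm(15 * 4, mean = 6), 15, 4))   # huge separation
  g <- factor(rep(c("a", "b"), each = 15))
  p1 <- permutationGroupTest(Y, g, "mahalanobis", n_perm = 199, seed = 9)
  p2 <- permutationGroupTest(Y, g, "mahalanobis", n_perm = 199, seed = 9)
  expect_identical(p1, p2)
  expect_equal(p1[1, 2], 1 / 200)         # minimum attainable
  p3 <- permutationGroupTest(Y, g, "procrustes", n_perm = 199, seed = 9)
  expect_equal(p3[1, 2], 1 / 200)
  expect_true(is.na(p1[1, 1]))
})

test_that("dfaTwoGroup separates, recovers the generating axis and validates", {
  set.seed(90)
  d <- 6
  u <- rnorm(d); u <- u / sqrt(sum(u^2))
  Y <- rbind(t(replicate(40, 3 * u + rnorm(d, sd = 0.5))),
             t(replicate(35, -3 * u + rnorm(d, sd = 0.5))))
  g <- factor(rep(c("a", "b"), c(40, 35)))
  fit <- dfaTwoGroup(Y, g, n_perm = 99, seed = 4)
  expect_equal(sum(fit@resubstitution) - sum(diag(fit@resubstitution)), 0)
  expect_equal(rowSums(fit@resubstitution), c(a = 40, b = 35),
               ignore_attr = TRUE)
  cosang <- abs(sum(fit@axis * u)) / sqrt(sum(fit@axis^2))
  expect_gt(cosang, 0.95)
  expect_equal(fit@permutationP, 0.01)
  expect_equal(sum(fit@loo) - sum(diag(fit@loo)), 0)  # LOO also perfect
})

test_that("LOO error is at least resubstitution error on average", {
  set.seed(91)
  n_rep <- 40
  gaps <- vapply(seq_len(n_rep), function(r) {
    Y <- rbind(matrix(rnorm(12 * 5), 12, 5),
               matrix(rnorm(12 * 5, mean = 0.5), 12, 5))
    g <- factor(rep(c("a", "b"), each = 12))
    fit <- dfaTwoGroup(Y, g, n_perm = 0)
    loo_err <- sum(fit@loo) - sum(diag(fit@loo))
    res_err <- sum(fit@resubstitution) - sum(diag(fit@resubstitution))
    loo_err - res_err
  }, 0)
  expect_gte(mean(gaps), 0)
})

test_that("classificationImprovement reports printed-rate folds", {
  before <- rbind(canis = c(35, 16), orientis = c(4, 3))  # 16/51 = 31%
  after <- rbind(canis = c(44, 3), orientis = c(1, 6))    # 3/47 = 6%
  imp <- classificationImprovement(before, after)
  expect_equal(imp$rate_before[1], 31)
  expect_equal(imp$rate_after[1], 6)
  expect_equal(imp$fold[1], 5.2)
  # equal tables: fold 1 everywhere
  eq <- classificationImprovement(before, before)
  expect_true(all(eq$fold == 1))
  # perfect after-table: infinite fold flagged
  perf <- rbind(canis = c(51, 0), orientis = c(0, 7))
  expect_warning(imp2 <- classificationImprovement(before, perf), "infinite")
  expect_true(all(is.infinite(imp2$fold)))
})
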