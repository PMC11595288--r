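test_that("pearson handles exact linear dependence, masks and degeneracy", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson(x, 2 * x + 1), 1)
  expect_equal(pearson(x, -x), -1)
  expect_equal(pearson(c(1, 2, 3), c(1, 3, 2)), 0.5)  # direct covariance oracle
  expect_true(is.na(pearson(x, rep(5, 4))))            # zero variance
  expect_true(is.na(pearson(c(1, 2, NA, NA), c(2, 1, NA, NA))))  # < 3 pairs
  expect_equal(pearson(c(1, 2, 3, NA), c(2, 4, 6, 0)), 1)  # pairwise deletion
})

test_that("the sample correlation matrix is symmetric with unit diagonal", {
  set.seed(21)
  m <- matrix(rnorm(12 * 50), 50, 12,
              dimnames = list(paste0("f", 1:50), all_conditions))
  cm <- sample_correlation_matrix(lfc_fixture(m))
  expect_equal(cm$r, t(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, 12))
  expect_true(all(abs(cm$r) <= 1 + 1e-12))

  # duplicated sample columns correlate exactly 1
  m2 <- m; m2[, "Mo_T1"] <- m2[, "E_T1"]
  cm2 <- sample_correlation_matrix(lfc_fixture(m2))
  expect_equal(cm2$r["E_T1", "Mo_T1"], 1)
})

test_that("per-sample affine rescaling leaves sample correlations unchanged", {
  set.seed(22)
  m <- matrix(rnorm(12 * 30), 30, 12,
              dimnames = list(paste0("f", 1:30), all_conditions))
  a <- runif(12, 0.5, 3)
  b <- rnorm(12)
  m2 <- sweep(sweep(m, 2, a, "*"), 2, b, "+")
  expect_equal(sample_correlation_matrix(lfc_fixture(m))$r,
               sample_correlation_matrix(lfc_fixture(m2))$r,
               tolerance = 1e-12)
})

test_that("insufficient feature overlap masks a correlation cell", {
  m <- matrix(rnorm(4 * 12), 4, 12,
              dimnames = list(paste0("f", 1:4), all_conditions))
  m[1:2, "E_T1"] <- NA
  m[3:4, "E_T2"] <- NA   # E_T1/E_T2 share 0 unmasked features
  cm <- sample_correlation_matrix(lfc_fixture(m))
  expect_true(is.na(cm$r["E_T1", "E_T2"]))
})

test_that("within/between summary averages the right sample pairs", {
  # block-structured correlation matrix built directly from data
  set.seed(23)
  base <- matrix(rnorm(12 * 200), 200, 12,
                 dimnames = list(paste0("f", 1:200), all_conditions))
  cm <- sample_correlation_matrix(lfc_fixture(base))
  s <- within_between_summary(cm)
  lin <- cm$samples$lineage
  # independent recomputation of one within and one between cell
  eidx <- which(lin == "E")
  expect_equal(unname(s$within[["E"]]),
               mean(cm$r[eidx, eidx][upper.tri(diag(3))]))
  expect_equal(unname(s$between[["E:Mo"]]),
               mean(cm$r[lin == "E", lin == "Mo"]))
  expect_equal(s$within_mean, mean(s$within))
  expect_equal(s$between_mean, mean(s$between))
  expect_equal(s$ratio, s$within_mean / s$between_mean)
})

test_that("constant cross-sample correlation gives ratio one", {
  r <- matrix(0.6, 12, 12, dimnames = list(all_conditions, all_conditions))
  diag(r) <- 1
  cm <- structure(list(r = r, samples = parse_sample_keys(all_conditions)),
                  class = "hn_corr")
  s <- within_between_summary(cm)
  expect_equal(s$ratio, 1)
})

test_that("a lineage with one sample has a masked within entry", {
  cols <- c("E_T1", "Mo_T1", "Mo_T2", "Mo_T3")
  m <- matrix(rnorm(4 * 30), 30, 4, dimnames = list(paste0("f", 1:30), cols))
  s <- within_between_summary(sample_correlation_matrix(lfc_fixture(m)))
  expect_true(is.na(s$within[["E"]]))
  expect_false(is.na(s$within[["Mo"]]))
})

test_that("printed-cell aggregation reproduces overall means and ratio", {
  agg <- aggregate_lineage_correlations(c(0.2, 0.4), c(0.1, 0.2, 0.3),
                                        digits = 2)
  expect_equal(agg$within_mean, 0.3)
  expect_equal(agg$between_mean, 0.2)
  expect_equal(agg$ratio, 1.5)
})

test_that("two-factor ANOVA matches a Type-II oracle on unbalanced data", {
  skip_if_not_installed("car")
  set.seed(24)
  n <- 40
  fa <- factor(sample(c("y", "n"), n, TRUE))
  fb <- factor(sample(c("m", "c"), n, TRUE))
  y <- rnorm(n) + (fa == "y") * 0.8
  ours <- two_factor_anova(y, fa, fb)
  oracle <- car::Anova(lm(y ~ fa + fb), type = 2)
  expect_equal(ours$F, oracle$`F value`[1:2], tolerance = 1e-10)
  expect_equal(ours$p, oracle$`Pr(>F)`[1:2], tolerance = 1e-10)
  expect_equal(ours$sum_sq, oracle$`Sum Sq`[1:2], tolerance = 1e-10)
})

test_that("a factor that explains everything yields an infinite F", {
  y <- c(0, 0, 0, 1, 1, 1)
  fa <- c("a", "a", "a", "b", "b", "b")
  fb <- c("x", "y", "x", "y", "x", "y")
  out <- two_factor_anova(y, fa, fb)
  expect_true(is.infinite(out$F[1]))
  expect_equal(out$p[1], 0)
})

test_that("ANOVA rejects degenerate inputs", {
  expect_error(two_factor_anova(rep(1, 6), rep(c("a", "b"), 3),
                                rep(c("x", "y"), 3)), "constant")
  expect_error(two_factor_anova(rnorm(6), rep("a", 6), rep(c("x", "y"), 3)),
               "both levels")
})

test_that("the mean-shifted factor dominates F in a balanced design", {
  set.seed(25)
  n <- 50
  fa <- rep(c("a", "b"), each = 2 * n)
  fb <- rep(rep(c("x", "y"), each = n), 2)
  mu <- ifelse(fa == "b", 1, 0)   # cell means 0,0,1,1: factor A shifts
  y <- rnorm(4 * n, mu)
  out <- two_factor_anova(y, fa, fb)
  expect_gt(out$F[1], 10 * max(out$F[2], 1))
  # balanced-design oracle: direct sums of squares
  ss_a <- sum(tapply(y, fa, function(v) length(v) * (mean(v) - mean(y))^2))
  expect_equal(out$sum_sq[1], ss_a, tolerance = 1e-8)
})

test_that("ANOVA p-values are uniform under the null", {
  set.seed(26)
  reps <- 1000
  fa <- rep(c("a", "b"), each = 10)
  fb <- rep(rep(c("x", "y"), each = 5), 2)
  rej <- replicate(reps, {
    out <- two_factor_anova(rnorm(20), fa, fb)
    out$p < 0.05
  })
  for (i in 1:2) {
    expect_gt(mean(rej[i, ]), 0.03)
    expect_lt(mean(rej[i, ]), 0.07)
  }
})
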