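mk <- function(v, dims = c(4, 4, 2)) array(as.integer(v), dims)

test_that("dsc matches its defining examples", {
  a <- mk(c(rep(1, 8), rep(0, 24)))
  expect_equal(dsc(a, a), 1.0)
  b <- mk(c(rep(0, 8), rep(1, 8), rep(0, 16)))
  expect_equal(dsc(a, b), 0.0)
  # |a| = 4, |b| = 6, overlap 3 -> 2*3/(4+6) = 0.6
  a2 <- mk(c(1, 1, 1, 1, rep(0, 28)))
  b2 <- mk(c(1, 1, 1, 0, 1, 1, 1, rep(0, 25)))
  expect_equal(dsc(a2, b2), 0.6)
  expect_equal(dsc(b2, a2), 0.6)  # symmetry
  expect_error(dsc(a, mk(0, c(2, 2, 2))), "shapes differ")
})

test_that("dsc conventions for empty masks hold", {
  e <- mk(rep(0, 32))
  expect_equal(dsc(e, e), 1.0)
  expect_equal(dsc(e, mk(c(1, rep(0, 31)))), 0.0)
})

test_that("dsc is symmetric on random mask pairs", {
  set.seed(42)
  for (i in 1:20) {
    a <- mk(runif(32) < 0.4)
    b <- mk(runif(32) < 0.4)
    expect_equal(dsc(a, b), dsc(b, a))
  }
})

test_that("voxel_auc matches its defining examples", {
  truth <- mk(c(1, 0, 1, 0), c(4, 1, 1))
  expect_equal(voxel_auc(array(c(0.9, 0.8, 0.4, 0.3), c(4, 1, 1)), truth),
               0.75)
  expect_equal(voxel_auc(array(c(1, 0, 1, 0), c(4, 1, 1)), truth), 1.0)
  expect_equal(voxel_auc(array(0.5, c(4, 1, 1)), truth), 0.5)
  expect_error(voxel_auc(array(0.5, c(4, 1, 1)), mk(rep(1, 4), c(4, 1, 1))),
               "both classes")
})

test_that("voxel_auc equals the exhaustive pair-counting oracle", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(20:500, 1)
    scores <- round(runif(n), 2)  # rounding forces ties
    labels <- as.integer(runif(n) < 0.3)
    if (length(unique(labels)) < 2) next
    got <- voxel_auc(array(scores, c(n, 1, 1)), mk(labels, c(n, 1, 1)))
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
    expect_equal(got, mean(cmp))
    # invariance under a strictly monotone transform
    expect_equal(voxel_auc(array(exp(3 * scores), c(n, 1, 1)),
                           mk(labels, c(n, 1, 1))), got)
  }
})

test_that("icc_agreement matches a brute-force ANOVA oracle", {
  m <- matrix(c(8.1, 7.9, 6.2, 6.5, 9.0, 8.7, 5.1, 5.4, 7.7, 7.2, 6.9, 7.0),
              nrow = 6, byrow = TRUE)
  got <- icc_agreement(m)
  # oracle: variance components from the two-way ANOVA table, by hand
  n <- nrow(m); k <- ncol(m); gm <- mean(m)
  msr <- k * sum((rowMeans(m) - gm)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - gm)^2) / (k - 1)
  mse <- (sum((m - gm)^2) - (n - 1) * msr / k * k - (k - 1) * msc / n * n) /
    ((n - 1) * (k - 1))
  oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(got$estimate, oracle, tolerance = 1e-6)
  expect_true(got$ci[1] <= got$estimate && got$estimate <= got$ci[2])
})

test_that("icc_agreement reproduces a published-form worked matrix", {
  # 6 subjects x 4 raters; reference values computed independently with a
  # two-way ANOVA implementation (ICC(A,1) = 0.3547881, CI 0.033-0.809)
  m <- matrix(c(9, 2, 5, 8, 2, 1, 1, 2, 8, 4, 6, 8, 6, 1, 2, 5,
                8, 2, 3, 6, 7, 1, 2, 4), nrow = 6, byrow = TRUE)
  got <- icc_agreement(m)
  expect_equal(got$estimate, 0.3547881, tolerance = 1e-6)
  expect_equal(got$ci, c(0.0334091, 0.8088620), tolerance = 1e-5)
  expect_equal(got$p_value, 6.395413e-05, tolerance = 1e-5)
})

test_that("icc degenerate and identical-rating cases follow the contract", {
  # all runs identical per subject, subjects differ -> 1
  m <- matrix(rep(c(1, 2, 3, 4), 3), nrow = 4)
  expect_equal(icc_agreement(m)$estimate, 1.0)
  # every value equal -> estimate 1, CI [1, 1]
  r <- icc_agreement(matrix(5, 4, 3))
  expect_equal(r$estimate, 1.0)
  expect_equal(r$ci, c(1, 1))
  expect_error(icc_agreement(matrix(1, 1, 4)), ">= 2")
  expect_error(icc_agreement(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
})

test_that("icc under the null is near zero", {
  m <- withr::with_seed(99, matrix(rnorm(50 * 4), 50, 4))
  r <- icc_agreement(m)
  expect_lt(abs(r$estimate), 0.15)
  expect_true(r$ci[1] <= r$estimate && r$estimate <= r$ci[2])
})

test_that("metrics_report aggregates per-subject DSC and AUC", {
  dims <- c(6, 6, 2)
  truth <- array(0L, dims); truth[2:3, 2:3, 1] <- 1L
  p <- array(0.1, dims); p[2:3, 2:3, 1] <- 0.9
  map <- structure(list(p = p, spacing = c(1, 1, 1), subject_id = "s1"),
                   class = "probability_map")
  seg <- threshold_and_select(map)
  rep <- metrics_report(list(map), list(seg), list(label_map(truth)))
  expect_equal(rep$n_subjects, 1L)
  expect_equal(rep$per_subject$dsc, 1.0)
  expect_equal(rep$per_subject$auc, 1.0)
})
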