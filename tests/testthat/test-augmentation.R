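# Channel augmentation: correlations, candidate ranking, RMSECV curve,
# elbow selection, and the assembled ACLS fit.

test_that("channelR2 computes per-channel squared correlations", {
  A <- cbind(c(1, 2, 3), c(5, 5, 5))
  expect_equal(channelR2(A, c(1, 2, 3)), c(1, 0))
  # hand-computed case: cor(c(1,2,4), c(1,2,3))^2 = (7/sqrt(14*4/3/3))^2 ...
  a <- c(1, 2, 4); y <- c(1, 2, 3)
  expect_equal(channelR2(cbind(a), y), cor(a, y)^2)
  expect_equal(channelR2(cbind(a), y), 0.9642857, tolerance = 1e-6)
})

test_that("channelR2 matches cor()^2 on random matrices and stays in [0, 1]", {
  set.seed(5)
  A <- matrix(rnorm(200), 20)
  y <- rnorm(20)
  expect_equal(channelR2(A, y), as.numeric(cor(A, y))^2, tolerance = 1e-12)
  expect_true(all(channelR2(A, y) >= 0 & channelR2(A, y) <= 1))
})

test_that("channelR2 rejects degenerate input", {
  expect_error(channelR2(matrix(1, 2, 3), c(1, 2)), "3 samples")
  expect_error(channelR2(matrix(1:9, 3), c(2, 2, 2)), "constant")
  expect_error(channelR2(matrix(1:9, 3), c(1, 2)), "length")
})

test_that("rankCandidates sorts by ascending correlation below the threshold", {
  r2 <- c(0.5, 0.05, 0.15, 0.01, 0.3)
  wn <- c(100, 300, 500, 700, 900)
  expect_equal(rankCandidates(r2, wn, r2Threshold = 0.2, minSpacing = 100),
               c(4L, 2L, 3L))
})

test_that("rankCandidates enforces the minimum wavenumber spacing greedily", {
  r2 <- c(0.01, 0.02, 0.03, 0.04)
  wn <- c(100, 150, 260, 150 + 99)   # 2 within 100 of 1; 4 within 100 of 3
  expect_equal(rankCandidates(r2, wn, minSpacing = 100), c(1L, 3L))
  # relaxing the spacing readmits them in r2 order
  expect_equal(rankCandidates(r2, wn, minSpacing = 10), 1:4)
})

test_that("rankCandidates errors when no channel falls below the threshold", {
  expect_error(rankCandidates(c(0.5, 0.9), c(1, 2), r2Threshold = 0.2),
               "no channel")
})

test_that("augmentConcentrationMatrix appends channels with bookkeeping", {
  set.seed(9)
  pr <- randomCLSProblem(L = 12, M = 2, P = 10)
  A <- pr$A + matrix(rnorm(120, 0, 0.1), 12)
  out <- augmentConcentrationMatrix(pr$C, A, c(3L, 7L))
  expect_equal(ncol(out), 4L)
  expect_equal(colnames(out)[3:4], c("ch3", "ch7"))
  expect_equal(out[, "ch3"], A[, 3])
  expect_equal(attr(out, "componentKind"), c("analyte", "analyte", "channel", "channel"))
  expect_equal(attr(out, "sourceChannel"), c(NA_integer_, NA_integer_, 3L, 7L))
  expect_equal(unname(augmentConcentrationMatrix(pr$C, A, integer(0))),
               unname(pr$C), ignore_attr = TRUE)
})

test_that("augmentConcentrationMatrix drops collinear channels with a warning", {
  set.seed(10)
  C <- cbind(a = runif(8))
  A <- cbind(C[, 1] * 2, rnorm(8), C[, 1] * 3)   # channels 1, 3 collinear with a
  expect_warning(out <- augmentConcentrationMatrix(C, A, c(1L, 2L, 3L)),
                 "collinear channel")
  expect_equal(colnames(out), c("a", "ch2"))
})

test_that("augmentConcentrationMatrix stops at the overfit guard", {
  set.seed(12)
  C <- cbind(a = runif(4))
  A <- matrix(rnorm(4 * 6), 4)
  expect_error(augmentConcentrationMatrix(C, A, 1:4), "overfit guard")
  expect_error(augmentConcentrationMatrix(C, A, 9L), "out of range")
})

test_that("looRmsecvCurve matches an independent naive leave-one-out oracle", {
  set.seed(13)
  toy <- toyMixture(L = 14, P = 20, interferent = TRUE, noiseSd = 0.01)
  A <- intensities(toy$re); C <- concentrations(toy$re)
  r2 <- channelR2(A, C[, 1])
  cand <- rankCandidates(r2, toy$axis, r2Threshold = 0.9, minSpacing = 30)[1:3]
  curve <- looRmsecvCurve(A, C, cand, mMax = 2L, target = 1L, center = FALSE)
  # oracle: explicit pseudoinverse LOO, no shared code with the package
  oracle <- vapply(0:2, function(m) {
    Caug <- cbind(C, A[, cand[seq_len(m)], drop = FALSE])
    pred <- vapply(seq_len(nrow(A)), function(i) {
      K <- MASS::ginv(Caug[-i, , drop = FALSE]) %*% A[-i, , drop = FALSE]
      (A[i, , drop = FALSE] %*% MASS::ginv(K))[1, 1]
    }, numeric(1))
    sqrt(mean((pred - C[, 1])^2))
  }, numeric(1))
  expect_equal(unname(curve), oracle, tolerance = 1e-8)
})

test_that("looRmsecvCurve is zero at m = 0 for fully modeled noiseless data", {
  toy <- toyMixture(L = 12, P = 18)
  A <- intensities(toy$re); C <- concentrations(toy$re)
  curve <- looRmsecvCurve(A, C, integer(0), mMax = 0L)
  expect_lt(curve[["m0"]], 1e-10)
})

test_that("looRmsecvCurve validates its inputs", {
  toy <- toyMixture(L = 10, P = 15)
  A <- intensities(toy$re); C <- concentrations(toy$re)
  expect_error(looRmsecvCurve(A, C, 1L, mMax = 5L), "mMax exceeds")
  expect_error(looRmsecvCurve(A, C, 1:8, mMax = 8L), "not enough samples")
  expect_error(looRmsecvCurve(A, C, 1L, mMax = 1L, target = "nope"), "unknown target")
})

test_that("chooseAugmentationSize finds the elbow of an L-shaped curve", {
  expect_equal(chooseAugmentationSize(c(1, 0.9, 0.1, 0.09, 0.08)), 2L)
  # flat after the drop at k: elbow at the drop regardless of tail length
  expect_equal(chooseAugmentationSize(c(5, 5, 0.5, 0.5, 0.5, 0.5, 0.5)), 2L)
  expect_equal(chooseAugmentationSize(c(3, 0.2, 0.19, 0.18)), 1L)
})

test_that("chooseAugmentationSize returns 0 for curves with no elbow", {
  expect_equal(chooseAugmentationSize(c(1, 0.9, 0.8, 0.7, 0.6)), 0L)  # linear
  expect_equal(chooseAugmentationSize(c(1, 1, 1, 1)), 0L)             # flat
})

test_that("chooseAugmentationSize honors an explicit override and skips NAs", {
  expect_equal(chooseAugmentationSize(c(1, 0.9, 0.1, 0.09), override = 24), 24L)
  expect_equal(chooseAugmentationSize(c(1, NA, 0.1, 0.09, 0.08)), 2L)
  expect_error(chooseAugmentationSize(c(1, 2)), "at least 3 points")
  expect_error(chooseAugmentationSize(c(NA_real_, NA, NA)), "no finite values")
})

test_that("chooseAugmentationSize falls back to 0 when the elbow is worse than m = 0", {
  expect_warning(m <- chooseAugmentationSize(c(1, 8, 1.5, 1.4, 20)),
                 "falling back")
  expect_equal(m, 0L)
})

test_that("fitACLS equals the manual composition of its pipeline stages", {
  set.seed(17)
  toy <- toyMixture(L = 20, P = 30, interferent = TRUE, noiseSd = 0.005)
  fit <- suppressWarnings(fitACLS(toy$re, target = "A", r2Threshold = 0.9,
                                  minSpacing = 30, mMax = 4L))
  A <- intensities(toy$re); C <- concentrations(toy$re)
  r2 <- channelR2(A, C[, "A"])
  cand <- rankCandidates(r2, toy$axis, 0.9, 30)
  curve <- suppressWarnings(looRmsecvCurve(A, C, cand, 4L, target = 1L))
  m <- suppressWarnings(chooseAugmentationSize(curve))
  expect_equal(fit@r2, r2)
  expect_equal(fit@candidateOrder, cand)
  expect_equal(unname(rmsecvCurve(fit)), unname(curve))
  expect_equal(fit@chosenM, m)
  Caug <- augmentConcentrationMatrix(C, A, cand[seq_len(m)])
  cc <- meanCenter(A, Caug)
  expect_equal(pureSpectra(fit), fitCLS(cc$C, cc$A))
  expect_equal(augmentedChannels(fit), cand[seq_len(m)])
})

test_that("fitACLS honors an explicit augmentation size override", {
  set.seed(18)
  toy <- toyMixture(L = 20, P = 30, interferent = TRUE, noiseSd = 0.005)
  fit <- suppressWarnings(fitACLS(toy$re, r2Threshold = 0.9, minSpacing = 30,
                                  mMax = 4L, m = 3L))
  expect_equal(fit@chosenM, 3L)
  expect_equal(length(augmentedChannels(fit)), 3L)
})

test_that("fitACLS is deterministic for a fixed dataset", {
  toy <- toyMixture(L = 20, P = 30, interferent = TRUE, noiseSd = 0.005)
  f1 <- suppressWarnings(fitACLS(toy$re, r2Threshold = 0.9, minSpacing = 30, mMax = 4L))
  f2 <- suppressWarnings(fitACLS(toy$re, r2Threshold = 0.9, minSpacing = 30, mMax = 4L))
  expect_equal(pureSpectra(f1), pureSpectra(f2))
  expect_equal(f1@chosenM, f2@chosenM)
})

test_that("appending concentration-orthogonal columns leaves predictions unchanged", {
  # Columns orthogonal to every concentration column get numerically zero
  # pure-spectrum rows on noiseless fully modeled data, so the (minimum-norm)
  # target prediction is unchanged.
  set.seed(19)
  pr <- randomCLSProblem(L = 25, M = 3, P = 35)
  v <- rnorm(25)
  v <- as.numeric(v - pr$C %*% solve(crossprod(pr$C), crossprod(pr$C, v)))
  Caug <- cbind(pr$C, ortho = v)
  K0 <- fitCLS(pr$C, pr$A)
  K1 <- fitCLS(Caug, pr$A)
  expect_lt(max(abs(K1["ortho", ])), 1e-8 * max(abs(pr$A)))
  p0 <- predictCLS(pr$A, K0, target = 1L)$target
  p1 <- suppressWarnings(predictCLS(pr$A, K1, target = 1L)$target)
  expect_lt(max(abs(p1 - p0)), 1e-8)
})
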