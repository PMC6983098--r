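test_that("the augmented pattern matrix has the (1, x, x^2) layout", {
  Q <- build_pattern_matrix(matrix(c(2, 3), ncol = 1))
  expect_equal(unname(Q), rbind(c(1, 1), c(2, 3), c(4, 9)))
  expect_equal(unname(build_pattern_matrix(matrix(0, 1, 2))[, 1]),
               c(1, 0, 0, 0, 0))
  set.seed(2)
  X <- matrix(rnorm(40), 10, 4)
  Q <- build_pattern_matrix(X)
  expect_equal(Q[6:9, ], Q[2:5, ]^2)
  expect_error(build_pattern_matrix(matrix(nrow = 0, ncol = 2)), "empty")
})

test_that("one-hot targets have unit column sums", {
  Tm <- build_target_matrix(c(1, 3, 2, 1), 3)
  expect_equal(colSums(Tm), rep(1, 4))
  expect_equal(Tm[cbind(c(1, 3, 2, 1), 1:4)], rep(1, 4))
})

test_that("Wiener-Hopf weights match an independent least-squares solve", {
  set.seed(123)
  for (i in 1:200) {
    L <- sample(1:5, 1)
    N <- sample((2 * L + 2):50, 1)
    M <- sample(2:4, 1)
    X <- matrix(rnorm(N * L), N, L)
    y <- sample.int(M, N, replace = TRUE)
    Q <- build_pattern_matrix(X)
    Tm <- build_target_matrix(y, M)
    V <- train_lsdqc(Q, Tm)
    V_qr <- t(stats::lm.fit(t(Q), t(Tm))$coefficients)  # QR, not normal eqs
    expect_lt(max(abs(V - V_qr)) / max(abs(V_qr)), 1e-8)
  }
})

test_that("training is invariant to duplicating every pattern", {
  set.seed(5)
  Q <- build_pattern_matrix(matrix(rnorm(30), 10, 3))
  Tm <- build_target_matrix(sample(1:2, 10, TRUE), 2)
  V1 <- train_lsdqc(Q, Tm)
  V2 <- train_lsdqc(cbind(Q, Q), cbind(Tm, Tm))
  expect_equal(V1, V2, tolerance = 1e-10)
  expect_error(train_lsdqc(matrix(0, 3, 4), matrix(0, 2, 4)), "degenerate")
})

test_that("the trained solution is a local MSE minimum", {
  set.seed(6)
  Q <- build_pattern_matrix(matrix(rnorm(60), 20, 3))
  Tm <- build_target_matrix(sample(1:3, 20, TRUE), 3)
  V <- train_lsdqc(Q, Tm)
  base <- mse(V, Q, Tm)
  for (i in 1:100) {
    expect_gte(mse(V + matrix(rnorm(length(V), 0, 0.01), nrow(V)), Q, Tm),
               base)
  }
})

test_that("classification takes the argmax with lowest-index tie-break", {
  Q <- build_pattern_matrix(matrix(rnorm(8), 4, 2))
  V <- rbind(rep(0, 5), rep(1, 5), rep(0, 5))
  V2 <- V
  V2[2, ] <- 0                         # classes 1 and 3 tie with class 2
  expect_equal(classify(V, abs(Q)), rep(2, 4))
  expect_equal(classify(V2, Q), rep(1, 4))
  expect_error(classify(V, Q[1:3, ]), "shape mismatch")
})

test_that("decisions agree with scalar evaluation of the quadratic rule", {
  set.seed(7)
  X <- matrix(rnorm(50), 10, 5)
  Q <- build_pattern_matrix(X)
  Tm <- build_target_matrix(sample(1:3, 10, TRUE), 3)
  V <- train_lsdqc(Q, Tm)
  lab <- classify(V, Q)
  L <- ncol(X)
  for (n in 1:10) {
    y_m <- vapply(1:3, function(m) {
      V[m, 1] + sum(V[m, 2:(L + 1)] * X[n, ]) +
        sum(V[m, (L + 2):(2 * L + 1)] * X[n, ]^2)
    }, 0)
    expect_equal(lab[n], which.max(y_m))
  }
})

test_that("MSE matches elementwise brute force and its closed forms", {
  set.seed(8)
  for (i in 1:10) {
    V <- matrix(rnorm(15), 3, 5)
    Q <- matrix(rnorm(25), 5, 5)
    Tm <- build_target_matrix(sample(1:3, 5, TRUE), 3)
    expect_equal(mse(V, Q, Tm), sum((V %*% Q - Tm)^2) / 5)
  }
  Q <- diag(3)
  Tm <- diag(3)
  expect_equal(mse(diag(3), Q, Tm), 0)       # perfect reconstruction
  expect_equal(mse(matrix(0, 3, 3), Q, Tm), 1)  # one-hot norm per column
})

test_that("separable classes reach zero resubstitution error", {
  d <- toy_separable()
  Q <- build_pattern_matrix(d$X)
  Tm <- build_target_matrix(d$y, d$M)
  V <- train_lsdqc(Q, Tm)
  expect_equal(mean(classify(V, Q) != d$y), 0)
})

test_that("LOSO outputs equal the manual train-on-rest composition", {
  d <- toy_random(S = 4)
  mask <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  o <- loso_outputs(d, mask, "S2")
  tr <- d$subjects != "S2"
  Xm <- d$X[, mask, drop = FALSE]
  V <- train_lsdqc(build_pattern_matrix(Xm[tr, ]),
                   build_target_matrix(d$y[tr], d$M))
  Q_te <- build_pattern_matrix(Xm[!tr, ])
  expect_equal(o$Y, V %*% Q_te)
  expect_equal(o$labels, classify(V, Q_te))
  expect_error(loso_outputs(d, mask, "S9"), "unknown subject")
})

test_that("a duplicated subject's LOSO decisions equal its twin's resubstitution", {
  d <- toy_random(S = 3, n_per_class = 6, L = 3, seed = 4)
  # make S3 an exact copy of S1
  i1 <- d$subjects == "S1"
  i3 <- d$subjects == "S3"
  d$X[i3, ] <- d$X[i1, ]
  d$y[i3] <- d$y[i1]
  o <- loso_outputs(d, NULL, "S3")
  tr <- !i3
  V <- train_lsdqc(build_pattern_matrix(d$X[tr, ]),
                   build_target_matrix(d$y[tr], d$M))
  resub <- classify(V, build_pattern_matrix(d$X[i1, ]))
  expect_equal(o$labels, resub)
})

test_that("two-subject LOSO runs and per-fold errors average to the rate", {
  d <- toy_random(S = 2, n_per_class = 10, L = 2, seed = 10)
  r <- kfold_error(d)
  expect_length(r$per_fold_error, 2)
  expect_equal(r$error, mean(r$per_fold_error))
  expect_gte(r$error, 0)
  expect_lte(r$error, 1)
})

test_that("chance-level labels give about 2/3 error; separable data near 0", {
  set.seed(31)
  S <- 6
  n <- 3000
  X <- matrix(rnorm(n * 3), n, 3)
  d_noise <- labeled_dataset(X, sample(1:3, n, TRUE),
                             rep(sprintf("S%d", 1:S), length.out = n))
  expect_equal(kfold_error(d_noise)$error, 2 / 3, tolerance = 0.05 / (2 / 3))
  d_sep <- synth_feature_dataset(S = 4, n_per_class = 15, class_gap = 4,
                                 subject_sd = 0, subject_sd_informative = 0,
                                 L_total = 6, seed = 3)
  expect_lt(kfold_error(d_sep)$error, 0.05)
})

test_that("k-fold error is invariant to feature permutation within the mask", {
  d <- toy_random(S = 4, seed = 17)
  e1 <- kfold_error(d)$error
  d2 <- d
  d2$X <- d$X[, 5:1]
  expect_equal(kfold_error(d2)$error, e1)
})

test_that("models round-trip through JSON export", {
  set.seed(12)
  V <- matrix(rnorm(15), 3, 5)
  tf <- tempfile(fileext = ".json")
  export_model(V, c(1, 0, 1), c("neutral", "sadness", "disgust"), tf)
  m <- import_model(tf)
  expect_equal(m$V, V, ignore_attr = TRUE)
  expect_equal(m$mask, c(1L, 0L, 1L))
  expect_equal(m$classes, c("neutral", "sadness", "disgust"))
})
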