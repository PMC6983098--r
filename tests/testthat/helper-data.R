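# Shared fixtures, all generated in code.

# tiny well-separated 2-class, 1-D dataset (resubstitution-separable)
toy_separable <- function(n = 50, seed = 42) {
  set.seed(seed)
  X <- matrix(c(rnorm(n, -1, 0.1), rnorm(n, 1, 0.1)), ncol = 1)
  labeled_dataset(X, rep(1:2, each = n), rep(c("A", "B", "C", "D"),
                                             length.out = 2 * n))
}

# random multi-subject dataset for oracle comparisons
toy_random <- function(S = 4, n_per_class = 8, L = 5, seed = 1) {
  set.seed(seed)
  N <- S * 3 * n_per_class
  labeled_dataset(matrix(rnorm(N * L), N, L),
                  rep(rep(1:3, each = n_per_class), S),
                  rep(sprintf("S%d", 1:S), each = 3 * n_per_class))
}

# brute-force Eq.-style SDEO: train on design subjects, MSE on design set
sdeo_bruteforce <- function(d, mask, s) {
  dm <- d
  dm$X <- d$X[, as.logical(mask), drop = FALSE]
  des <- dm$subjects != s
  Q <- build_pattern_matrix(dm$X[des, , drop = FALSE])
  Tm <- build_target_matrix(dm$y[des], dm$M)
  V <- train_lsdqc(Q, Tm)
  sum((V %*% Q - Tm)^2) / ncol(Q)
}

# brute-force nested-loop KFBEO
kfbeo_bruteforce <- function(d, mask, s) {
  dm <- d
  dm$X <- d$X[, as.logical(mask), drop = FALSE]
  inner <- setdiff(unique(dm$subjects), s)
  sse <- 0
  ntot <- 0
  for (n in inner) {
    tr <- !(dm$subjects %in% c(s, n))
    V <- train_lsdqc(build_pattern_matrix(dm$X[tr, , drop = FALSE]),
                     build_target_matrix(dm$y[tr], dm$M))
    te <- dm$subjects == n
    Qn <- build_pattern_matrix(dm$X[te, , drop = FALSE])
    Tn <- build_target_matrix(dm$y[te], dm$M)
    sse <- sse + sum((V %*% Qn - Tn)^2)
    ntot <- ntot + sum(te)
  }
  sse / ntot
}

# exhaustive search over all feasible masks for a small problem
exhaustive_best_mask <- function(d, g, budget, s, fitfun) {
  L <- ncol(d$X)
  ctx <- fold_context(d)
  best <- NULL
  best_fit <- Inf
  for (code in 1:(2^L - 1)) {
    m <- as.logical(bitwAnd(code, 2^(0:(L - 1))) > 0)
    if (mask_cost(m, g) > budget) next
    f <- fitfun(NULL, m, s, ctx = ctx)
    if (f < best_fit) {
      best_fit <- f
      best <- m
    }
  }
  list(mask = best, fitness = best_fit)
}
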