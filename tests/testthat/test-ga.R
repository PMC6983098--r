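small_cfg <- function(cost_budget = 10, ...) {
  ga_config(population_size = 20, generations = 15,
            cost_budget = cost_budget, seed = 1, ...)
}

test_that("GA runs are deterministic given the seed and respect the budget", {
  d <- synth_feature_dataset(S = 4, n_per_class = 8, L_total = 10, seed = 2)
  g <- uniform_cost_graph(colnames(d$X))
  cfg <- small_cfg(cost_budget = 4)
  r1 <- ga_select(d, g, cfg)
  r2 <- ga_select(d, g, cfg)
  expect_identical(lapply(r1$folds, `[[`, "mask"),
                   lapply(r2$folds, `[[`, "mask"))
  expect_identical(lapply(r1$folds, `[[`, "trace"),
                   lapply(r2$folds, `[[`, "trace"))
  for (f in r1$folds) {
    expect_lte(mask_cost(f$mask, g), 4)
    expect_gte(sum(f$mask), 1)
  }
})

test_that("an infeasible budget is rejected up front", {
  d <- synth_feature_dataset(S = 3, n_per_class = 5, L_total = 6, seed = 3)
  g <- uniform_cost_graph(colnames(d$X), cost = 100)
  expect_error(ga_select(d, g, small_cfg(cost_budget = 50)),
               "no feasible mask")
})

test_that("selection beats random feasible masks on separable data", {
  d <- synth_feature_dataset(S = 4, n_per_class = 10, class_gap = 3,
                             subject_sd = 0.5, L_total = 10, seed = 4)
  g <- uniform_cost_graph(colnames(d$X))
  res <- ga_select(d, g, small_cfg(cost_budget = 5))
  ctx <- fold_context(d)
  s <- ctx$subjects[1]
  best <- res$folds[[1]]$fitness
  set.seed(99)
  rand_fit <- replicate(100, {
    m <- runif(10) < 0.3
    if (!any(m)) m[1] <- TRUE
    m[which(m)[-(1:min(5, sum(m)))]] <- FALSE   # cap at budget
    sdeo_fitness(NULL, m, s, ctx = ctx)
  })
  expect_lte(best, min(rand_fit))
})

test_that("the best-fitness trace never increases (elitism)", {
  d <- synth_feature_dataset(S = 3, n_per_class = 6, L_total = 8, seed = 5)
  g <- uniform_cost_graph(colnames(d$X))
  res <- ga_select(d, g, small_cfg(cost_budget = 8))
  for (f in res$folds) {
    expect_true(all(diff(f$trace) <= 1e-12))
  }
})

test_that("the held-out subject cannot influence its own fold's selection", {
  d <- synth_feature_dataset(S = 4, n_per_class = 8, L_total = 10, seed = 6)
  g <- uniform_cost_graph(colnames(d$X))
  cfg <- small_cfg(cost_budget = 4, fitness_kind = "KFBEO")
  r1 <- ga_select(d, g, cfg)
  d2 <- d
  i3 <- d$subjects == "S03"
  set.seed(77)
  d2$X[i3, ] <- matrix(rnorm(sum(i3) * ncol(d$X), 0, 10), sum(i3))
  r2 <- ga_select(d2, g, cfg)
  expect_identical(r1$folds[["S03"]]$mask, r2$folds[["S03"]]$mask)
})

test_that("selection frequencies match brute-force counting", {
  masks <- list(c(TRUE, FALSE, TRUE), c(TRUE, TRUE, FALSE),
                c(TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE))
  sf <- selection_frequency(masks, features = c("a", "b", "c"))
  expect_equal(sf$percentage[sf$feature == "a"], 100)
  expect_equal(sf$percentage[sf$feature == "b"], 25)
  expect_equal(sf$percentage[sf$feature == "c"], 50)
  expect_equal(attr(sf, "attempts"), 4)
  expect_equal(sf$feature[1], "a")           # sorted descending
  # threshold view excludes never/rarely selected features
  sf20 <- selection_frequency(masks, features = c("a", "b", "c"),
                              min_percent = 30)
  expect_setequal(sf20$feature, c("a", "c"))
})

test_that("the error-vs-budget report has complete bookkeeping", {
  d <- synth_feature_dataset(S = 3, n_per_class = 6, L_total = 8, seed = 7)
  g <- uniform_cost_graph(colnames(d$X))
  cfg <- ga_config(population_size = 10, generations = 5, cost_budget = 4,
                   seed = 3)
  rep <- error_vs_budget_curve(d, g, budgets = c(3, 6), cfg,
                               repetitions = 2, fitness_kinds = "SDEO")
  expect_equal(nrow(rep$runs), 2 * 2)        # budgets x repetitions
  expect_length(rep$masks, 4)
  expect_true(all(rep$runs$error >= 0 & rep$runs$error <= 1))
  for (key in names(rep$masks)) {
    b <- as.numeric(strsplit(key, "|", fixed = TRUE)[[1]][2])
    for (m in rep$masks[[key]]) expect_lte(mask_cost(m, g), b)
  }
})

test_that("a larger budget never worsens the best achievable design fitness", {
  # exhaustive check on an 8-feature problem: feasible sets are nested
  d <- synth_feature_dataset(S = 3, n_per_class = 6, L_total = 8, seed = 8)
  g <- uniform_cost_graph(colnames(d$X))
  s <- unique(d$subjects)[1]
  fits <- vapply(c(2, 4, 6, 8), function(b) {
    exhaustive_best_mask(d, g, b, s, sdeo_fitness)$fitness
  }, 0)
  expect_true(all(diff(fits) <= 1e-12))
})
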