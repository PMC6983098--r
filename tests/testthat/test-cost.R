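test_that("filter costs follow N*F for FIR and N*F/SF for IFIR", {
  expected <- c(LFECG = 25000, MFECG = 25000, RFECG = 11500,
                LFTEB = 10000, RFTEB = 4000, EFTEB = 4000)
  tab <- filter_table()
  for (nm in names(expected)) {
    f <- design_filter(nm, tab$fs[tab$name == nm])
    expect_identical(filter_ops(f), unname(expected[nm]))
  }
})

test_that("statistic costs come from the packaged table, with a counting oracle for the mean", {
  expect_equal(statistic_ops("Mean"), 300)
  expect_equal(statistic_ops("Kurtosis"), 2701)
  expect_equal(statistic_ops("Trimmean"), 27805)
  expect_error(statistic_ops("Mode"), "unknown statistic")
  # explicit count: 2999 additions + 1 division per 10-s emission
  expect_equal(count_statistic_ops("Mean", window_n = 3000, emission_s = 10),
               statistic_ops("Mean"))
})

test_that("the pipeline cost graph is a complete DAG over the 84 features", {
  g <- build_cost_graph()
  expect_setequal(names(g$deps), feature_names())
  expect_true(all(g$nodes$ops_per_second >= 0))
  # every feature reaches at least one filter node
  filt <- g$nodes$node[g$nodes$kind == "filter"]
  expect_true(all(vapply(g$deps, function(dep) any(dep %in% filt),
                         logical(1))))
})

test_that("mask cost counts shared blocks once", {
  g <- build_cost_graph()
  empty <- rep(FALSE, 84)
  expect_equal(mask_cost(empty, g), 0)
  # two features on the same stream share every upstream block
  one <- mask_cost("TEB_PPM_Mean", g)
  two <- mask_cost(c("TEB_PPM_Mean", "TEB_PPM_Max"), g)
  expect_equal(two, one + statistic_ops("Max"))
  # brute-force union oracle on random masks
  set.seed(9)
  for (i in 1:20) {
    m <- runif(84) < 0.2
    if (!any(m)) next
    nodes <- unique(unlist(g$deps[m]))
    expect_equal(mask_cost(m, g),
                 sum(g$nodes$ops_per_second[g$nodes$node %in% nodes]))
  }
})

test_that("mask cost is monotone and subadditive", {
  g <- build_cost_graph()
  set.seed(21)
  full <- mask_cost(rep(TRUE, 84), g)
  for (i in 1:20) {
    m <- runif(84) < 0.3
    if (!any(m)) next
    expect_lte(mask_cost(m, g), full)
    m2 <- m
    m2[sample(which(!m), 1)] <- TRUE
    expect_gte(mask_cost(m2, g), mask_cost(m, g))
    singles <- sum(vapply(which(m), function(j) {
      mj <- rep(FALSE, 84); mj[j] <- TRUE; mask_cost(mj, g)
    }, 0))
    expect_lte(mask_cost(m, g), singles)
  }
})

test_that("cost tables and reports round-trip through files", {
  g <- uniform_cost_graph(c("a", "b", "c"), cost = 2)
  tf <- tempfile(fileext = ".csv")
  write_cost_table(g, tf)
  expect_equal(read.csv(tf)$ops_per_second, c(2, 2, 2))
  rf <- tempfile(fileext = ".json")
  mask_cost_report(c(TRUE, FALSE, TRUE), g, rf)
  rep <- jsonlite::read_json(rf, simplifyVector = TRUE)
  expect_equal(rep$ops_per_second, 4)
  expect_equal(rep$selected, c("a", "c"))
  expect_error(mask_cost(c(TRUE, FALSE), g), "mask length")
})
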