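test_that("z-score fit uses the population convention and rejects degenerate columns", {
  tbl <- tibble::tibble(name = c("a", "b", "c"),
                        HNR = c(1, 2, 3),
                        `MDVP:Jitter(%)` = c(0.1, 0.1, 0.4))
  st <- zscore_fit(tbl)
  hnr <- st[st$feature == "HNR", ]
  expect_equal(hnr$mu, 2)
  expect_equal(hnr$sigma, sqrt(2 / 3), tolerance = 1e-12) # 0.81650 by direct arithmetic
  expect_identical(attr(st, "ddof"), 0)

  # sample convention on request
  st1 <- zscore_fit(tbl, ddof = 1)
  expect_equal(st1$sigma[st1$feature == "HNR"], 1)

  const <- tbl
  const$HNR <- 5
  expect_error(zscore_fit(const), regexp = "HNR")
})

test_that("applying fitted stats standardizes the fitting table to mean 0, pop sd 1", {
  tbl <- simulate_voice_features(synth_params(n = 40, seed = 6))
  st <- zscore_fit(tbl)
  std <- zscore_apply(tbl, st)
  X <- fmat(std)
  expect_true(all(abs(colMeans(X)) < 1e-9))
  pop_sd <- sqrt(colMeans(sweep(X, 2, colMeans(X))^2))
  expect_true(all(abs(pop_sd - 1) < 1e-9))

  # hand instance
  z <- (c(1, 2, 3) - 2) / sqrt(2 / 3)
  expect_equal(z, c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)

  # train-fitted stats applied to held-out data: no refitting
  held <- simulate_voice_features(synth_params(n = 40, seed = 60))
  held_std <- zscore_apply(held, st)
  expect_gt(max(abs(colMeans(fmat(held_std)))), 1e-3)

  # feature-name mismatch is an error
  expect_error(zscore_apply(dplyr::select(tbl, -"NHR"), st),
               class = "voicerisk_value_error")
})

test_that("heaviside is 1 strictly above zero and 0 at and below zero", {
  expect_identical(heaviside(c(0.5, 0, -3)), c(1L, 0L, 0L))
  expect_error(heaviside(NaN), class = "voicerisk_value_error")
})

test_that("the Heaviside and conjunction forms of the rule agree everywhere", {
  # full 9-cell boundary grid around both thresholds
  grid <- expand.grid(hnr = c(19.9, 20, 20.1), jitter = c(0.0049, 0.005, 0.0051))
  expect_identical(assign_label(grid$hnr, grid$jitter),
                   assign_label_conjunction(grid$hnr, grid$jitter))
  # the grid's own expected labels: low risk only strictly inside
  expect_identical(assign_label(grid$hnr, grid$jitter),
                   as.integer(!(grid$hnr > 20 & grid$jitter < 0.005)))

  # randomized property
  set.seed(42)
  h <- runif(10000, 5, 35)
  j <- exp(runif(10000, log(5e-4), log(0.05)))
  expect_identical(assign_label(h, j), assign_label_conjunction(h, j))

  expect_identical(assign_label(25, 0.003), 0L)
  expect_identical(assign_label(20, 0.003), 1L)
  expect_identical(assign_label(25, 0.005), 1L)
  expect_error(assign_label(NaN, 0.001), class = "voicerisk_value_error")
})

test_that("table labelling matches a row-by-row recount and ignores other columns", {
  tbl <- simulate_voice_features(synth_params(n = 1000, seed = 4))
  ds <- assign_labels(tbl)
  # independent recount oracle: scalar loop over rows
  recount <- vapply(seq_len(nrow(tbl)), function(i) {
    if (tbl$HNR[i] > 20 && tbl$`MDVP:Jitter(%)`[i] < 0.005) 0L else 1L
  }, integer(1))
  expect_identical(ds$risk_label, recount)

  # permuting a non-rule column leaves labels unchanged
  perm <- tbl
  perm$PPE <- rev(perm$PPE)
  expect_identical(assign_labels(perm)$risk_label, ds$risk_label)

  # a table entirely inside the low-risk region gets all-zero labels
  r0 <- tbl
  r0$HNR <- 30
  r0$`MDVP:Jitter(%)` <- 0.001
  expect_true(all(assign_labels(r0)$risk_label == 0L))
})

test_that("custom thresholds shift the rule boundary", {
  rule <- label_rule(hnr_min = 15, jitter_max = 0.01)
  expect_identical(assign_label(18, 0.007, rule), 0L)
  expect_identical(assign_label(18, 0.007), 1L)
})

test_that("stratified split hits exact per-class allocations", {
  ds <- tibble::tibble(name = sprintf("s%d", 1:100),
                       HNR = rnorm(100, 22), `MDVP:Jitter(%)` = 0.004,
                       risk_label = rep(c(0L, 1L), c(60, 40)))
  parts <- stratified_split(ds, 0.2, seed = 3)
  expect_equal(sum(parts$test$risk_label == 0), 12)
  expect_equal(sum(parts$test$risk_label == 1), 8)

  # n = 195 gives a 39-row test set regardless of class mix
  ds195 <- tibble::tibble(name = sprintf("s%d", 1:195),
                          risk_label = rep(c(0L, 1L), c(90, 105)))
  parts195 <- stratified_split(ds195, 0.2, seed = 1)
  expect_equal(nrow(parts195$test), 39)
  expect_equal(sum(parts195$test$risk_label == 0), 18)
  expect_equal(sum(parts195$test$risk_label == 1), 21)
})

test_that("stratified split is seeded, disjoint and exhaustive", {
  ds <- simulate_labeled_dataset(synth_params(n = 137, seed = 8, target_balance = 0.4))
  a <- stratified_split(ds, 0.25, seed = 5)
  b <- stratified_split(ds, 0.25, seed = 5)
  expect_identical(a, b)
  c <- stratified_split(ds, 0.25, seed = 6)
  expect_false(identical(a$test$name, c$test$name))
  expect_equal(nrow(c$test), nrow(a$test))

  expect_length(intersect(a$train$name, a$test$name), 0)
  expect_setequal(c(a$train$name, a$test$name), ds$name)

  # test-set class shares track the overall shares to within one sample
  overall <- table(ds$risk_label)
  test_tab <- table(a$test$risk_label)
  for (cl in names(overall)) {
    expect_lte(abs(test_tab[[cl]] - overall[[cl]] * 0.25), 1)
  }

  single <- ds[ds$risk_label == 1, ]
  expect_error(stratified_split(single, 0.2, seed = 1),
               class = "voicerisk_stratification_error")
})
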