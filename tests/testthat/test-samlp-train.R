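test_that("training is deterministic per seed and learns the synthetic task", {
  std <- small_training_set(n = 300, seed = 21)
  tc <- train_config(epochs = 8, seed = 13)
  a <- samlp_train(std, training = tc)
  b <- samlp_train(std, training = tc)
  expect_identical(a$history, b$history)
  expect_identical(predict(a, std, type = "prob"), predict(b, std, type = "prob"))

  # learning occurred: loss at the best epoch is below the first epoch's
  expect_lte(a$history$train_loss[a$best_epoch], a$history$train_loss[1])
  expect_lte(a$best_epoch, a$stopped_epoch)
  expect_lte(a$stopped_epoch, tc$epochs)

  # different seed: same shape, different fit
  c <- samlp_train(std, training = train_config(epochs = 8, seed = 14))
  expect_false(identical(a$params$W1, c$params$W1))
})

test_that("early stopping contract: patience 0 and patience >= epochs run all epochs", {
  std <- small_training_set(n = 150, seed = 22)
  off <- samlp_train(std, training = train_config(epochs = 6, patience = 0, seed = 1))
  expect_equal(nrow(off$history), 6)
  expect_equal(off$stopped_epoch, 6)

  big <- samlp_train(std, training = train_config(epochs = 6, patience = 6, seed = 1))
  expect_equal(nrow(big$history), 6)

  # with a tiny patience, training can stop early and restores best weights
  tight <- samlp_train(std, training = train_config(epochs = 30, patience = 2, seed = 1))
  expect_lte(tight$stopped_epoch, 30)
  expect_equal(tight$best_val_loss, min(tight$history$val_loss))
})

test_that("single-class training data is rejected", {
  std <- small_training_set(n = 60, seed = 23)
  one <- std[std$risk_label == 1, ]
  expect_error(samlp_train(one), class = "voicerisk_training_error")
})

test_that("prediction thresholds probabilities with ties going to high risk", {
  std <- small_training_set(n = 80, seed = 24)
  fit <- samlp_train(std, training = train_config(epochs = 2, seed = 2))

  # all-zero output head: every probability is exactly 0.5 -> label 1
  fit0 <- fit
  fit0$params$W3[] <- 0
  fit0$params$b3 <- 0
  expect_true(all(predict(fit0, std, type = "prob") == 0.5))
  expect_true(all(predict(fit0, std, type = "class") == 1L))

  # predict(class) is exactly the thresholded probability
  prob <- predict(fit, std, type = "prob")
  expect_identical(predict(fit, std, type = "class"),
                   as.integer(prob >= fit$config$classification_threshold))

  # feature-name contract
  bad <- std
  names(bad)[names(bad) == "PPE"] <- "ppe_renamed"
  expect_error(predict(fit, bad), class = "voicerisk_value_error")
})

test_that("broom-style methods summarise a fit", {
  std <- small_training_set(n = 80, seed = 25)
  fit <- samlp_train(std, training = train_config(epochs = 3, seed = 3))
  td <- tidy(fit)
  expect_named(td, c("epoch", "train_loss", "val_loss"))
  expect_equal(nrow(td), fit$stopped_epoch)
  gl <- glance(fit)
  expect_equal(gl$n_parameters, 20353)
  expect_equal(gl$model, "sa_mlp")
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("the DNN baseline drops exactly the attention parameters", {
  std <- small_training_set(n = 80, seed = 26)
  dnn <- dnn_baseline(std, training = train_config(epochs = 2, seed = 4))
  expect_false(dnn$config$use_attention)
  expect_false(any(c("WQ", "WK", "WV", "WO") %in% names(dnn$params)))
  # parameter count difference = the four hidden x hidden projections + biases
  expect_equal(20353 - glance(dnn)$n_parameters, 4 * (64 * 64 + 64))
})

test_that("a trained model recovers the labelling rule on the feature grid", {
  ds <- simulate_labeled_dataset(synth_params(n = 2000, seed = 1, target_balance = 0.5))
  st <- zscore_fit(ds)
  std <- zscore_apply(ds, st)
  fit <- samlp_train(std, training = train_config(seed = 1))

  grid <- tidyr::expand_grid(hnr = seq(10, 34, length.out = 50),
                             jitter = exp(seq(log(0.001), log(0.02), length.out = 50)))
  rule_y <- assign_label(grid$hnr, grid$jitter)
  X <- matrix(0, nrow(grid), 22, dimnames = list(NULL, st$feature))
  X[, "HNR"] <- (grid$hnr - st$mu[st$feature == "HNR"]) /
    st$sigma[st$feature == "HNR"]
  X[, "MDVP:Jitter(%)"] <- (grid$jitter - st$mu[st$feature == "MDVP:Jitter(%)"]) /
    st$sigma[st$feature == "MDVP:Jitter(%)"]
  pred <- predict(fit, X, type = "class")
  expect_gte(mean(pred == rule_y), 0.90)
})

test_that("baselines clear a meaningful accuracy bar on the synthetic task", {
  ds <- simulate_labeled_dataset(synth_params(n = 1000, seed = 2, target_balance = 0.5))
  parts <- stratified_split(ds, 0.2, seed = 2)
  st <- zscore_fit(parts$train)
  tr <- zscore_apply(parts$train, st)
  te <- zscore_apply(parts$test, st)
  dnn <- dnn_baseline(tr, training = train_config(seed = 2))
  expect_gte(mean(predict(dnn, te) == te$risk_label), 0.85)
  expect_gte(mean(knn_predict(tr, te) == te$risk_label), 0.70)
})
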