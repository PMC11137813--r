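test_that("database sampling respects every range constraint", {
  db <- sample_param_database(4000, seed = 3)
  expect_equal(nrow(db), 4000)
  expect_true(all(validate_param_record(db)))
  s <- db$epsilon1 + db$epsilon2
  q <- db$epsilon1 / db$epsilon2
  expect_true(all(s > 8 & s < 12))
  expect_true(all(q > 0.3 & q < 0.6))
  expect_true(min(db$sigma2) > 1.8 && max(db$sigma2) < 2.05)
  expect_true(min(db$sigma1) > 2.5 && max(db$sigma1) < 3.0)
  # a ratio outside the admissible band is rejected by the validator
  bad <- tibble::tibble(epsilon1 = 4.2, sigma1 = 2.7, epsilon2 = 6.0,
                        sigma2 = 1.9)  # ratio 0.7
  expect_false(validate_param_record(bad))
  # seeded sampling is reproducible
  expect_identical(db, sample_param_database(4000, seed = 3))
})

test_that("an 80/20 split of 12,000 records gives 9,600 / 2,400", {
  db <- sample_param_database(12000, seed = 1)
  db <- partition_database(db, seed = 1)
  expect_equal(sum(db$partition == "train"), 9600)
  expect_equal(sum(db$partition == "test"), 2400)
})

test_that("featurization reduces to the active site and is deterministic", {
  # distal pair essentially off: features collapse to the proximal pair
  f <- featurize_record(1e-6, 2.74, 6.55, 1.90, seed = 5, angle_ps = 6)
  expect_true(f$converged)
  expect_equal(f$epsilon_f, -6.55, tolerance = 0.8)
  expect_equal(f$sigma_f, 1.90, tolerance = 0.08)

  f1 <- featurize_record(4.0, 2.7, 7.0, 1.95, seed = 8, angle_ps = 6)
  f2 <- featurize_record(4.0, 2.7, 7.0, 1.95, seed = 8, angle_ps = 6)
  expect_identical(f1, f2)

  # features move smoothly under a small sigma2 perturbation
  fa <- featurize_record(4.0, 2.7, 7.0, 1.90, seed = 8, angle_ps = 6)
  fb <- featurize_record(4.0, 2.7, 7.0, 1.92, seed = 8, angle_ps = 6)
  expect_lt(abs(fb$sigma_f - fa$sigma_f), 0.1)
  expect_lt(abs(fb$epsilon_f - fa$epsilon_f), 1.0)
})

test_that("the network learns an easy synthetic map almost perfectly", {
  # targets that are an exact linear map of the features: the architecture
  # can represent it, so test error should approach zero
  set.seed(2)
  n <- 2000
  db <- tibble::tibble(
    mean_angle = runif(n, 90, 150),
    epsilon_f = runif(n, -9, -5),
    sigma_f = runif(n, 1.9, 2.2))
  db$epsilon1 <- 0.05 * db$mean_angle + 0.4 * db$epsilon_f + 2
  db$sigma1 <- 0.02 * db$mean_angle + 0.5 * db$sigma_f
  db$epsilon2 <- -db$epsilon_f
  db$sigma2 <- db$sigma_f - 0.003 * db$mean_angle
  db <- partition_database(db, seed = 7)
  m <- train_fnn(db, epochs = 400, seed = 7)
  # loss decreases and generalizes: test RMSE near zero on every output
  expect_lt(tail(m$loss, 1), m$loss[1] / 50)
  scale <- c(sd(db$epsilon1), sd(db$sigma1), sd(db$epsilon2), sd(db$sigma2))
  expect_true(all(m$rmse$test_rmse < 0.1 * scale))
  # no gross overfit: train and test RMSE of the same order
  expect_true(all(m$rmse$test_rmse < 3 * m$rmse$train_rmse + 0.05))

  # held-out recovery: predictions within a few test-RMSE of truth
  te <- which(db$partition == "test")[1:50]
  pred <- predict(m, db[te, ])
  rmse_e2 <- m$rmse$test_rmse[m$rmse$output == "epsilon2"]
  expect_lt(mean(abs(pred$epsilon2 - db$epsilon2[te])), 3 * rmse_e2 + 0.05)

  # inversion: negative-sign convention and deterministic inference
  inv1 <- invert_features(m, db[te[1], c("mean_angle", "epsilon_f", "sigma_f")])
  inv2 <- invert_features(m, db[te[1], c("mean_angle", "epsilon_f", "sigma_f")])
  expect_identical(inv1, inv2)
  expect_lt(inv1$epsilon2, 0)
  # a target far outside the training features is flagged as extrapolation
  far <- tibble::tibble(mean_angle = 500, epsilon_f = -2, sigma_f = 2)
  expect_true(invert_features(m, far)$extrapolated)
})

test_that("model serialization roundtrips through JSON", {
  set.seed(4)
  db <- sample_param_database(400, seed = 4)
  db$mean_angle <- 120 + db$epsilon1
  db$epsilon_f <- -db$epsilon2
  db$sigma_f <- db$sigma2
  m <- train_fnn(db, epochs = 30, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_fnn(m, path)
  m2 <- read_fnn(path)
  x <- db[1:5, c("mean_angle", "epsilon_f", "sigma_f")]
  expect_equal(predict(m2, x), predict(m, x), tolerance = 1e-10)
})
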