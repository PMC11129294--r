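make_tiny_dataset <- function(n, seed) {
  mols <- generate_toy_molecules(n, seed = seed, max_heavy_atoms = 8)
  charge_dataset(mols, lapply(mols, eem_reference_charges))
}

test_that("squared loss sums squared residuals over atoms and molecules", {
  expect_equal(squared_loss(c(0.1, -0.2), c(0.1, -0.2)), 0)
  expect_equal(squared_loss(c(0.1, -0.1), c(0, 0)), 0.02)
  p <- c(0.3, -0.1, 0.4); r <- c(0.1, 0.1, 0)
  perm <- c(2, 3, 1)
  expect_equal(squared_loss(p[perm], r[perm]), squared_loss(p, r))
  expect_equal(squared_loss(list(p[1:2], p[3]), list(r[1:2], r[3])),
               squared_loss(p, r))
  expect_error(squared_loss(1:2, 1:3), class = "qeqnet_dim_error")
})

test_that("per-molecule RMSE matches hand evaluation", {
  expect_equal(charge_rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(charge_rmse(c(0.4, -0.1), c(0.3, -0.2)), 0.1)
  expect_equal(charge_rmse(c(0.3, 0, 0), c(0, 0, 0)), 0.3 / sqrt(3))
  expect_error(charge_rmse(numeric(0), numeric(0)), class = "qeqnet_dim_error")
})

test_that("bootstrap CI is deterministic, degenerate-safe, and brackets the mean", {
  expect_equal(bootstrap_ci(rep(0.25, 10), n_boot = 50, seed = 1),
               c(lower = 0.25, upper = 0.25))
  v <- c(0.12, 0.05, 0.31, 0.2, 0.09, 0.44, 0.17, 0.02, 0.26, 0.15)
  ci1 <- bootstrap_ci(v, n_boot = 2000, seed = 9)
  ci2 <- bootstrap_ci(v, n_boot = 2000, seed = 9)
  expect_identical(ci1, ci2)
  expect_lt(ci1[["lower"]], mean(v))
  expect_gt(ci1[["upper"]], mean(v))
  expect_error(bootstrap_ci(numeric(0)), class = "qeqnet_dim_error")
})

test_that("dataset construction validates reference charges", {
  mols <- generate_toy_molecules(3, seed = 33)
  refs <- lapply(mols, eem_reference_charges)
  expect_s3_class(charge_dataset(mols, refs), "qeq_dataset")
  bad <- refs; bad[[2]] <- bad[[2]] + 0.2
  expect_error(charge_dataset(mols, bad), class = "qeqnet_dataset_error")
  short <- refs; short[[1]] <- short[[1]][-1]
  expect_error(charge_dataset(mols, short), class = "qeqnet_dim_error")
})

test_that("splits are a seeded disjoint partition near the requested fractions", {
  ds <- make_tiny_dataset(50, seed = 35)
  ds1 <- split_dataset(ds, seed = 5)
  ds2 <- split_dataset(ds, seed = 5)
  expect_identical(ds1$split, ds2$split)
  tab <- table(ds1$split)
  expect_identical(sum(tab), 50L)
  expect_equal(unname(tab[["train"]]), 40)
})

test_that("zero epochs return the initialized model with empty history", {
  ds <- split_dataset(make_tiny_dataset(10, seed = 37), seed = 1)
  model <- tiny_model(seed = 38)
  fit <- train_charge_model(ds, model, train_config(epochs = 0))
  expect_identical(nrow(fit$history), 0L)
  expect_equal(fit$model$weights, model$weights, tolerance = 0)
})

test_that("training is reproducible and improves the fit", {
  ds <- split_dataset(make_tiny_dataset(40, seed = 39), seed = 2)
  cfg <- train_config(epochs = 8, lr = 3e-3, batch_size = 16, seed = 3)
  args <- list(n_layers = 2, hidden = 12, embed_dim = 12)
  fit1 <- train_charge_model(ds, config = cfg, model_args = args)
  fit2 <- train_charge_model(ds, config = cfg, model_args = args)
  expect_identical(fit1$history, fit2$history)
  expect_lt(tail(fit1$history$train_loss, 1), fit1$history$train_loss[1])
  # best-so-far validation loss is monotone nonincreasing
  expect_true(all(diff(cummin(fit1$history$val_loss)) <= 0))
  expect_s3_class(tidy(fit1), "tbl_df")
  expect_identical(glance(fit1)$epochs_run, nrow(fit1$history))
})

test_that("a short run already recovers generator charges approximately", {
  ds <- split_dataset(make_tiny_dataset(80, seed = 43), seed = 4)
  cfg <- train_config(epochs = 40, lr = 5e-3, batch_size = 32, seed = 5)
  fit <- train_charge_model(ds, config = cfg,
                            model_args = list(n_layers = 2, hidden = 24,
                                              embed_dim = 24))
  ev <- stratified_eval(ds, fit$model, n_boot = 200)
  expect_lt(ev$mean_rmse, 0.05)
})
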