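eval_fixture <- function(n = 40, seed = 45) {
  mols <- generate_toy_molecules(n, seed = seed, max_heavy_atoms = 8)
  ds <- charge_dataset(mols, lapply(mols, eem_reference_charges))
  split_dataset(ds, seed = seed)
}

test_that("bin counts partition the evaluated split", {
  ds <- eval_fixture()
  model <- tiny_model(seed = 46)
  ev <- stratified_eval(ds, model, n_boot = 100)
  n_test <- sum(ds$split == "test")
  expect_identical(sum(ev$by_charge$n_test), n_test)
  expect_identical(sum(ev$by_size$n_test), n_test)
  expect_identical(nrow(ev$per_molecule), n_test)
  expect_lte(ev$ci[["lower"]], ev$mean_rmse)
  expect_gte(ev$ci[["upper"]], ev$mean_rmse)
})

test_that("a single stratum reproduces the dataset mean; empty bins are NA", {
  ds <- eval_fixture(20, seed = 47)
  ds$split <- rep(c("train", "test"), length.out = nrow(ds))
  model <- tiny_model(seed = 48)
  ev <- stratified_eval(ds, model, size_bin_width = 10000L, n_boot = 100)
  expect_identical(nrow(ev$by_size), 1L)
  expect_equal(ev$by_size$mean_rmse[1], ev$mean_rmse)
  # force a charge bin with no molecules
  ev2 <- stratified_eval(ds, model, charge_bins = c(-5L, sort(unique(ds$Q))),
                         n_boot = 100)
  empty <- ev2$by_charge[ev2$by_charge$bin == "-5", ]
  expect_identical(empty$n_test, 0L)
  expect_true(is.na(empty$mean_rmse))
})

test_that("degrading one stratum's labels raises exactly that stratum's RMSE", {
  mols <- generate_toy_molecules(60, seed = 49,
                                 charge_probs = c(`-1` = 0.5, `0` = 0.5))
  refs <- lapply(mols, eem_reference_charges)
  # corrupt the labels of the Q = -1 molecules only (still summing to Q)
  set.seed(50)
  refs <- lapply(seq_along(mols), function(i) {
    r <- refs[[i]]
    if (total_formal_charge(mols[[i]]) == -1L && length(r) > 1) {
      noise <- rnorm(length(r), sd = 0.2)
      r <- r + noise - mean(noise)
    }
    r
  })
  ds <- charge_dataset(mols, refs)
  ds$split <- "test"
  model <- tiny_model(seed = 51)
  ev <- stratified_eval(ds, model, n_boot = 100)
  rm1 <- ev$by_charge$mean_rmse[ev$by_charge$bin == "-1"]
  rm0 <- ev$by_charge$mean_rmse[ev$by_charge$bin == "0"]
  expect_gt(rm1, rm0)
})

test_that("evaluation metrics are invariant to dataset ordering", {
  ds <- eval_fixture(30, seed = 53)
  model <- tiny_model(seed = 54)
  ev <- stratified_eval(ds, model, n_boot = 100)
  perm <- sample(nrow(ds))
  ev_p <- stratified_eval(ds[perm, ], model, n_boot = 100)
  expect_equal(ev_p$mean_rmse, ev$mean_rmse)
  expect_equal(
    ev_p$by_charge[order(ev_p$by_charge$bin), ],
    ev$by_charge[order(ev$by_charge$bin), ]
  )
})

test_that("reports export as CSV and tidy/glance/autoplot work", {
  ds <- eval_fixture(20, seed = 55)
  model <- tiny_model(seed = 56)
  ev <- stratified_eval(ds, model, n_boot = 100)
  dir <- withr::local_tempdir()
  write_eval_report(ev, dir)
  expect_true(all(file.exists(file.path(
    dir, c("per_molecule.csv", "by_charge.csv", "by_size.csv")))))
  expect_identical(nrow(utils::read.csv(file.path(dir, "per_molecule.csv"))),
                   nrow(ev$per_molecule))
  expect_s3_class(tidy(ev), "tbl_df")
  expect_identical(nrow(glance(ev)), 1L)
  expect_s3_class(autoplot(ev), "ggplot")
})
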