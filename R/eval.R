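# Per-molecule predicted charges for a set of dataset rows (one batched pass).
predict_dataset_charges <- function(dataset, model, idx = seq_len(nrow(dataset))) {
  graphs <- lapply(dataset$molecule[idx], build_graph, scheme = model$scheme)
  batch <- batch_graphs(graphs)
  fwd <- gnn_forward(batch, model)
  sol <- qeq_solve_segments(fwd$e, fwd$s, batch$Q, batch$segment_ids)
  unbatch_node_values(batch, sol$q)
}

#' Evaluate a model with stratified per-molecule RMSE
#'
#' Computes the per-molecule charge RMSE against the dataset's reference
#' charges, its unweighted mean over test molecules with a percentile
#' bootstrap confidence interval, and mean-RMSE tables stratified by total
#' molecular charge (integer bins) and by molecule size (atom-count bins),
#' each annotated with the number of test and training molecules in the bin.
#' Bins that contain no test molecule are reported with count 0 and `NA`
#' RMSE rather than an error.
#'
#' @param dataset A split [charge_dataset()].
#' @param model A [charge_model()] (or the `model` field of a `qeq_fit`).
#' @param charge_bins Integer charges defining the charge strata; defaults to
#'   the full range present in the dataset.
#' @param size_bin_width Width of the atom-count strata (default 10 atoms).
#' @param eval_split Which split to evaluate (default `"test"`).
#' @param n_boot,boot_seed Bootstrap replicates and seed for the CI of the
#'   mean RMSE.
#' @return An object of class `qeq_eval`: list with `per_molecule` (tibble),
#'   `mean_rmse`, `ci` (lower/upper), `by_charge`, `by_size` (tibbles with
#'   `n_test`, `n_train`, `mean_rmse`), `eval_split`.
#' @export
stratified_eval <- function(dataset, model, charge_bins = NULL,
                            size_bin_width = 10L, eval_split = "test",
                            n_boot = 1000L, boot_seed = 1L) {
  stopifnot(inherits(dataset, "qeq_dataset"), inherits(model, "qeq_model"))
  if (all(is.na(dataset$split))) {
    qeq_abort("dataset has no split labels; call split_dataset() first",
              "dataset_error")
  }
  idx <- which(dataset$split == eval_split)
  if (!length(idx)) qeq_abort(paste0("split '", eval_split, "' is empty"),
                              "dataset_error")
  preds <- predict_dataset_charges(dataset, model, idx)
  per_mol <- tibble(
    name = dataset$name[idx],
    split = dataset$split[idx],
    n_atoms = dataset$n_atoms[idx],
    Q = dataset$Q[idx],
    rmse = vapply(seq_along(idx), function(k) {
      charge_rmse(preds[[k]], dataset$ref[[idx[k]]])
    }, numeric(1))
  )
  mean_rmse <- mean(per_mol$rmse)
  ci <- bootstrap_ci(per_mol$rmse, n_boot = n_boot, seed = boot_seed)

  if (is.null(charge_bins)) {
    charge_bins <- seq.int(min(dataset$Q), max(dataset$Q))
  }
  by_charge <- bind_rows(lapply(charge_bins, function(qb) {
    in_bin <- per_mol$Q == qb
    tibble(
      bin = as.character(qb),
      n_test = sum(in_bin),
      n_train = sum(dataset$Q == qb & dataset$split == "train"),
      mean_rmse = if (any(in_bin)) mean(per_mol$rmse[in_bin]) else NA_real_
    )
  }))

  size_bin_of <- function(n) (n - 1L) %/% size_bin_width
  all_bins <- sort(unique(size_bin_of(dataset$n_atoms)))
  by_size <- bind_rows(lapply(all_bins, function(sb) {
    in_bin <- size_bin_of(per_mol$n_atoms) == sb
    tibble(
      bin = paste0(sb * size_bin_width + 1L, "-", (sb + 1L) * size_bin_width),
      n_test = sum(in_bin),
      n_train = sum(size_bin_of(dataset$n_atoms) == sb & dataset$split == "train"),
      mean_rmse = if (any(in_bin)) mean(per_mol$rmse[in_bin]) else NA_real_
    )
  }))

  structure(
    list(per_molecule = per_mol, mean_rmse = mean_rmse, ci = ci,
         by_charge = by_charge, by_size = by_size, eval_split = eval_split),
    class = "qeq_eval"
  )
}

#' @export
print.qeq_eval <- function(x, ...) {
  cat("<qeq_eval> ", nrow(x$per_molecule), " ", x$eval_split,
      " molecules; mean per-molecule RMSE ",
      format(x$mean_rmse, digits = 4), " e (95% CI ",
      format(x$ci[["lower"]], digits = 4), " - ",
      format(x$ci[["upper"]], digits = 4), ")\n", sep = "")
  cat("by total charge:\n"); print(x$by_charge)
  cat("by molecule size:\n"); print(x$by_size)
  invisible(x)
}

#' @export
tidy.qeq_eval <- function(x, ...) x$per_molecule

#' @export
glance.qeq_eval <- function(x, ...) {
  tibble(
    n = nrow(x$per_molecule),
    mean_rmse = x$mean_rmse,
    ci_lower = x$ci[["lower"]],
    ci_upper = x$ci[["upper"]]
  )
}

#' @export
autoplot.qeq_eval <- function(object, ...) {
  long <- bind_rows(
    mutate(object$by_charge, stratum = "total charge"),
    mutate(object$by_size, stratum = "molecule size (atoms)")
  )
  long$bin <- factor(long$bin, levels = unique(long$bin))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin, y = .data$mean_rmse)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = paste0(.data$n_test, "\n", .data$n_train)),
                       vjust = -0.2, size = 3) +
    ggplot2::facet_wrap(~.data$stratum, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "mean per-molecule charge RMSE (e)")
}

#' Export an evaluation report as CSV tables
#'
#' Writes `per_molecule.csv`, `by_charge.csv` and `by_size.csv` into `dir`.
#'
#' @param x A [stratified_eval()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(x, dir) {
  stopifnot(inherits(x, "qeq_eval"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(x$per_molecule, file.path(dir, "per_molecule.csv"),
                   row.names = FALSE)
  utils::write.csv(x$by_charge, file.path(dir, "by_charge.csv"), row.names = FALSE)
  utils::write.csv(x$by_size, file.path(dir, "by_size.csv"), row.names = FALSE)
  invisible(dir)
}
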