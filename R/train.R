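#' Bundle molecules and reference charges into a dataset
#'
#' @param molecules List of [molecule()] objects.
#' @param charges List of numeric per-atom reference charge vectors, one per
#'   molecule, each summing to the molecule's integer total charge within
#'   0.01 (tolerance for upstream rounding).
#' @return A tibble of class `qeq_dataset`: columns `name`, `molecule`
#'   (list), `ref` (list), `n_atoms`, `Q`, `split` (`NA` until
#'   [split_dataset()] assigns labels).
#' @export
charge_dataset <- function(molecules, charges) {
  if (length(molecules) != length(charges)) {
    qeq_abort("one reference charge vector per molecule is required", "dim_error")
  }
  n_at <- vapply(molecules, n_atoms, integer(1))
  lens <- lengths(charges)
  if (any(n_at != lens)) {
    qeq_abort(
      paste0("reference charge length mismatch at record ",
             which(n_at != lens)[1]),
      "dim_error"
    )
  }
  Q <- vapply(molecules, total_formal_charge, integer(1))
  sums <- vapply(charges, sum, numeric(1))
  if (any(abs(sums - Q) > 0.01)) {
    qeq_abort(
      paste0("reference charges of record ", which(abs(sums - Q) > 0.01)[1],
             " do not sum to the molecule's total formal charge (within 0.01)"),
      "dataset_error"
    )
  }
  out <- tibble(
    name = vapply(molecules, function(m) m$name, character(1)),
    molecule = molecules,
    ref = lapply(charges, as.numeric),
    n_atoms = n_at,
    Q = Q,
    split = NA_character_
  )
  class(out) <- c("qeq_dataset", class(out))
  out
}

#' Assign train/validation/test splits
#'
#' Random assignment by molecule with a seeded shuffle; splits are disjoint
#' by construction.
#'
#' @param dataset A [charge_dataset()].
#' @param fractions Named numeric vector `c(train=, val=, test=)` summing to 1.
#' @param seed Integer seed.
#' @return The dataset with its `split` column filled.
#' @export
split_dataset <- function(dataset, fractions = c(train = 0.8, val = 0.1, test = 0.1),
                          seed = 1L) {
  stopifnot(inherits(dataset, "qeq_dataset"),
            abs(sum(fractions) - 1) < 1e-8,
            all(c("train", "val", "test") %in% names(fractions)))
  n <- nrow(dataset)
  perm <- with_local_seed(seed, sample.int(n))
  n_train <- round(fractions[["train"]] * n)
  n_val <- round(fractions[["val"]] * n)
  lab <- rep("test", n)
  lab[perm[seq_len(n_train)]] <- "train"
  if (n_val > 0) lab[perm[n_train + seq_len(min(n_val, n - n_train))]] <- "val"
  dataset$split <- lab
  dataset
}

#' Squared training loss
#'
#' Sum over atoms of squared charge residuals, summed over the molecules of
#' a batch (atoms weigh equally; large molecules therefore weigh more — the
#' printed-form "squared loss").
#'
#' @param pred,ref Numeric vectors, or lists of per-molecule numeric vectors.
#' @return Scalar loss.
#' @export
squared_loss <- function(pred, ref) {
  if (is.list(pred)) pred <- unlist(pred, use.names = FALSE)
  if (is.list(ref)) ref <- unlist(ref, use.names = FALSE)
  if (length(pred) != length(ref)) {
    qeq_abort("pred and ref must have equal length", "dim_error")
  }
  sum((pred - ref)^2)
}

#' Per-molecule charge RMSE
#'
#' Root-mean-square deviation over a molecule's atoms; dataset-level
#' summaries are unweighted means of this quantity over molecules.
#'
#' @param pred,ref Equal-length numeric vectors of per-atom charges.
#' @return Scalar RMSE (elementary charge units).
#' @export
charge_rmse <- function(pred, ref) {
  if (length(pred) == 0L) qeq_abort("empty molecule has no RMSE", "dim_error")
  if (length(pred) != length(ref)) {
    qeq_abort("pred and ref must have equal length", "dim_error")
  }
  sqrt(mean((pred - ref)^2))
}

#' Percentile bootstrap confidence interval of a mean
#'
#' Resamples the per-molecule values with replacement `n_boot` times and
#' returns the percentile interval of the resampled means. Deterministic
#' given the seed.
#'
#' @param values Non-empty numeric vector (e.g. per-molecule RMSEs).
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(lower=, upper=)`.
#' @export
bootstrap_ci <- function(values, n_boot = 1000L, seed = 1L, level = 0.95) {
  if (length(values) == 0L) qeq_abort("no values to bootstrap", "dim_error")
  stopifnot(n_boot >= 1)
  means <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      mean(values[sample.int(length(values), replace = TRUE)])
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  ci <- unname(quantile(means, c(alpha, 1 - alpha), type = 7))
  c(lower = ci[1], upper = ci[2])
}

#' Training configuration
#'
#' @param epochs Maximum number of epochs.
#' @param lr Adam learning rate.
#' @param batch_size Molecules per minibatch.
#' @param seed Seed controlling the split shuffle, minibatch partition and
#'   any weight initialization performed by [train_charge_model()].
#' @param optimizer Only `"adam"` is provided.
#' @param fractions Split fractions used when the dataset is unsplit.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement); `Inf` disables early stopping.
#' @return A list of class `qeq_train_config`.
#' @export
train_config <- function(epochs = 200L, lr = 1e-3, batch_size = 64L, seed = 1L,
                         optimizer = "adam",
                         fractions = c(train = 0.8, val = 0.1, test = 0.1),
                         patience = 30L) {
  stopifnot(epochs >= 0, lr > 0, batch_size >= 1, optimizer == "adam")
  structure(
    list(epochs = as.integer(epochs), lr = lr,
         batch_size = as.integer(batch_size), seed = as.integer(seed),
         optimizer = optimizer, fractions = fractions, patience = patience),
    class = "qeq_train_config"
  )
}

# ---- parameter flattening (Adam works on one flat vector) ----

flatten_params <- function(w) unlist(w, use.names = FALSE)

unflatten_params <- function(flat, skeleton) {
  pos <- 0L
  walk <- function(x) {
    if (is.list(x)) return(lapply(x, walk))
    k <- length(x)
    out <- flat[pos + seq_len(k)]
    pos <<- pos + k
    if (!is.null(dim(x))) dim(out) <- dim(x)
    out
  }
  walk(skeleton)
}

# loss and weight gradients on one prepared minibatch
batch_loss_grad <- function(batch, ref, model, want_grad = TRUE) {
  fwd <- gnn_forward(batch, model, cache = want_grad)
  sol <- qeq_solve_segments(fwd$e, fwd$s, batch$Q, batch$segment_ids)
  resid <- sol$q - ref
  loss <- sum(resid^2)
  if (!want_grad) return(list(loss = loss))
  gq <- 2 * resid
  d_es <- qeq_backward(fwd$e, fwd$s, sol$q, batch$segment_ids, batch$n_mol, gq)
  grads <- gnn_backward(fwd, model, d_es$de, d_es$ds)
  list(loss = loss, grads = grads)
}

#' Fit the charge model to reference charges
#'
#' Minimizes the summed squared charge loss with Adam and minibatch gradient
#' descent, backpropagating analytically through the closed-form
#' charge-equilibration solution and the message-passing network. The model
#' snapshot with the best validation loss is returned; with zero epochs the
#' initialized model is returned untouched and the history is empty. Fully
#' reproducible given the config seed.
#'
#' @param dataset A [charge_dataset()]; split labels are assigned with the
#'   config's fractions if still missing.
#' @param model A [charge_model()], or `NULL` to initialize one from
#'   `model_args` and the config seed.
#' @param config A [train_config()].
#' @param model_args List of arguments for [charge_model()] when `model` is
#'   `NULL`.
#' @param quiet Suppress per-epoch progress.
#' @return An object of class `qeq_fit`: list with `model` (best
#'   checkpoint), `history` (tibble: epoch, train_loss, val_loss, best),
#'   `best_epoch`, `config`, `dataset_splits`.
#' @export
train_charge_model <- function(dataset, model = NULL, config = train_config(),
                               model_args = list(), quiet = TRUE) {
  stopifnot(inherits(dataset, "qeq_dataset"))
  if (all(is.na(dataset$split))) {
    dataset <- split_dataset(dataset, config$fractions, config$seed)
  }
  if (is.null(model)) {
    model <- do.call(charge_model, c(model_args, list(seed = config$seed)))
  }
  tr <- which(dataset$split == "train")
  va <- which(dataset$split == "val")
  if (!length(tr)) qeq_abort("training split is empty", "dataset_error")
  scheme <- model$scheme
  graphs <- lapply(dataset$molecule, build_graph, scheme = scheme)

  make_batches <- function(idx, bs) {
    split(idx, ceiling(seq_along(idx) / bs))
  }
  prep <- function(idx) {
    list(batch = batch_graphs(graphs[idx]),
         ref = unlist(dataset$ref[idx], use.names = FALSE))
  }
  eval_loss <- function(batches, mdl) {
    sum(vapply(batches, function(b) {
      batch_loss_grad(b$batch, b$ref, mdl, want_grad = FALSE)$loss
    }, numeric(1)))
  }

  history <- tibble(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0), best = logical(0))
  best_model <- model
  best_epoch <- 0L
  if (config$epochs > 0L) {
    with_local_seed(config$seed + 1L, {
      # fixed seeded minibatch partition, reused across epochs
      train_batches <- lapply(make_batches(sample(tr), config$batch_size), prep)
      val_batches <- if (length(va)) lapply(make_batches(va, config$batch_size), prep)
      theta <- flatten_params(model$weights)
      m_t <- v_t <- numeric(length(theta))
      beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
      step <- 0L
      best_val <- Inf
      stall <- 0L
      for (epoch in seq_len(config$epochs)) {
        ep_loss <- 0
        for (b in train_batches) {
          res <- batch_loss_grad(b$batch, b$ref, model)
          if (!is.finite(res$loss)) {
            qeq_abort(paste0("training diverged (non-finite loss) at epoch ",
                             epoch), "numeric_error")
          }
          ep_loss <- ep_loss + res$loss
          g <- flatten_params(res$grads)
          step <- step + 1L
          m_t <- beta1 * m_t + (1 - beta1) * g
          v_t <- beta2 * v_t + (1 - beta2) * g^2
          mhat <- m_t / (1 - beta1^step)
          vhat <- v_t / (1 - beta2^step)
          theta <- theta - config$lr * mhat / (sqrt(vhat) + eps)
          model$weights <- unflatten_params(theta, model$weights)
        }
        vl <- if (length(va)) eval_loss(val_batches, model) else ep_loss
        is_best <- vl < best_val
        if (is_best) {
          best_val <- vl
          best_model <- model
          best_epoch <- epoch
          stall <- 0L
        } else {
          stall <- stall + 1L
        }
        history <- bind_rows(history, tibble(epoch = epoch, train_loss = ep_loss,
                                             val_loss = vl, best = is_best))
        if (!quiet) {
          message(sprintf("epoch %3d  train %.6f  val %.6f%s", epoch, ep_loss,
                          vl, if (is_best) " *" else ""))
        }
        if (stall >= config$patience) break
      }
    })
  }
  structure(
    list(model = best_model, history = history, best_epoch = best_epoch,
         config = config, dataset_splits = table(dataset$split)),
    class = "qeq_fit"
  )
}

#' @export
print.qeq_fit <- function(x, ...) {
  cat("<qeq_fit> ", nrow(x$history), " epochs run; best validation loss ",
      if (nrow(x$history)) format(min(x$history$val_loss), digits = 6) else "NA",
      " at epoch ", x$best_epoch, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.qeq_fit <- function(x, ...) x$history

#' @export
glance.qeq_fit <- function(x, ...) {
  tibble(
    epochs_run = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_loss = if (nrow(x$history)) min(x$history$val_loss) else NA_real_,
    final_train_loss = if (nrow(x$history)) tail(x$history$train_loss, 1) else NA_real_
  )
}

#' @export
autoplot.qeq_fit <- function(object, ...) {
  h <- object$history
  long <- bind_rows(
    tibble(epoch = h$epoch, loss = h$train_loss, which = "train"),
    tibble(epoch = h$epoch, loss = h$val_loss, which = "validation")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "summed squared charge loss", colour = NULL)
}
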