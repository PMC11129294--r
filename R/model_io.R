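#' Save a charge model checkpoint
#'
#' Serializes the full model — featurization scheme, architecture and
#' weights — to a single versioned JSON file (written atomically via a
#' temporary file). JSON keeps the checkpoint portable and diffable; numbers
#' are written at full precision so save/load round trips are exact.
#'
#' @param model A [charge_model()] or the `model` field of a `qeq_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_charge_model <- function(model, path) {
  if (inherits(model, "qeq_fit")) model <- model$model
  stopifnot(inherits(model, "qeq_model"))
  payload <- list(
    checkpoint_format = "qeqnet-checkpoint-1",
    version = model$version,
    scheme = unclass(model$scheme),
    n_layers = model$n_layers,
    hidden = model$hidden,
    embed_dim = model$embed_dim,
    agg = model$agg,
    seed = model$seed,
    weights = model$weights
  )
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(payload, tmp, digits = NA, auto_unbox = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Load a charge model checkpoint
#'
#' Reads a checkpoint written by [save_charge_model()]. The loader refuses a
#' checkpoint whose featurization version does not match `expect_version`
#' (by default the package's current scheme version): features and weights
#' must agree or predictions would be silently wrong.
#'
#' @param path Checkpoint file.
#' @param expect_version Required featurization version tag, or `NULL` to
#'   accept any.
#' @return A [charge_model()].
#' @export
load_charge_model <- function(path,
                              expect_version = featurization_config()$version) {
  if (!file.exists(path)) {
    qeq_abort(paste0("checkpoint not found: ", path), "io_error")
  }
  payload <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE),
    error = function(e) NULL
  )
  if (is.null(payload) ||
      !identical(payload$checkpoint_format, "qeqnet-checkpoint-1")) {
    qeq_abort(paste0("not a readable qeqnet checkpoint: ", path), "io_error")
  }
  sc <- payload$scheme
  scheme <- featurization_config(
    elements = sc$elements, max_degree = sc$max_degree,
    charge_range = range(sc$charge_levels), wl_rounds = sc$wl_rounds,
    version = sc$version
  )
  if (scheme$n_features != sc$n_features) {
    qeq_abort("checkpoint featurization is internally inconsistent", "io_error")
  }
  if (!is.null(expect_version) && !identical(scheme$version, expect_version)) {
    qeq_abort(
      paste0("checkpoint featurization version '", scheme$version,
             "' does not match expected '", expect_version, "'"),
      "io_error"
    )
  }
  fix <- function(w) {
    if (is.list(w)) return(lapply(w, fix))
    if (is.null(dim(w))) as.numeric(w) else matrix(as.numeric(w), nrow(w))
  }
  weights <- fix(payload$weights)
  # jsonlite reads the per-layer list as an unnamed list already
  model <- structure(
    list(
      version = payload$version,
      scheme = scheme,
      n_layers = as.integer(payload$n_layers),
      hidden = as.integer(payload$hidden),
      embed_dim = as.integer(payload$embed_dim),
      agg = payload$agg,
      seed = as.integer(payload$seed),
      weights = weights
    ),
    class = "qeq_model"
  )
  model
}
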