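# Self-describing JSON checkpoints: architecture config, normalizer and
# weight arrays. Text-only on purpose so checkpoints survive source-only
# distribution and diffing.

mat_to_list <- function(m) {
  if (is.matrix(m)) list(dim = dim(m), data = as.numeric(m))
  else list(dim = length(m), data = as.numeric(m))
}

list_to_mat <- function(l) {
  if (length(l$dim) == 2) matrix(l$data, l$dim[1], l$dim[2])
  else as.numeric(l$data)
}

#' Save / load a response model checkpoint (JSON)
#'
#' @param model a `response_model`.
#' @param path file path (`.json`).
#' @export
save_model <- function(model, path) {
  obj <- list(
    kind = "pdsched_response_model",
    id = model_id(model$cfg),
    cfg = unclass(model$cfg),
    trained = isTRUE(model$trained),
    norm = if (!is.null(model$norm)) unclass(model$norm),
    params = lapply(model$params, mat_to_list))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (!identical(obj$kind, "pdsched_response_model"))
    stop(sprintf("'%s' is not a response-model checkpoint", path))
  cfg <- if (obj$cfg$type == "history") {
    history_model_config(obj$cfg$n_prev_states, obj$cfg$k_prev_doses,
                         unlist(obj$cfg$hidden_sizes), obj$cfg$target_mode,
                         obj$cfg$tanh_output)
  } else {
    impulse_model_config(obj$cfg$lstm_units, unlist(obj$cfg$hidden_sizes),
                         obj$cfg$target_mode, obj$cfg$tanh_output)
  }
  model <- init_model(cfg, seed = 1)
  model$params <- lapply(obj$params, function(p) {
    p$dim <- unlist(p$dim); p$data <- unlist(p$data); list_to_mat(p)
  })
  if (!is.null(obj$norm)) {
    model$norm <- structure(lapply(obj$norm, unlist), class = "normalizer")
  }
  model$trained <- isTRUE(obj$trained)
  model
}
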