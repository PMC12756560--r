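# Checkpoint serialization: parameter environments flattened to plain lists
# with a config fingerprint, so checkpoints survive across sessions.

cfg_fingerprint <- function(cfg) {
  flat <- unlist(cfg[order(names(cfg))], use.names = TRUE)
  paste(names(flat), as.character(flat), sep = "=", collapse = ";")
}

#' Save an encoder or fusion model to an RDS checkpoint
#'
#' @param model a `moltitox_encoder` or `moltitox_fusion`.
#' @param path file path (`.rds`).
#' @export
save_model <- function(model, path) {
  obj <- list(
    class = class(model)[1],
    cfg = unclass(model$cfg),
    fingerprint = cfg_fingerprint(model$cfg),
    params = as.list(model$params, all.names = TRUE),
    state = if (!is.null(model$state)) as.list(model$state, all.names = TRUE),
    vocab = model$vocab,
    consts = model$consts,
    encoder_dims = model$encoder_dims,
    modality = model$modality
  )
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint written by [save_model()]
#'
#' @param path checkpoint path.
#' @return the reconstructed model.
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  params <- list2env(obj$params, parent = emptyenv())
  if (obj$class == "moltitox_fusion") {
    cfg <- structure(obj$cfg, class = "fusion_config")
    return(structure(list(cfg = cfg, params = params,
                          encoder_dims = obj$encoder_dims),
                     class = "moltitox_fusion"))
  }
  cfg <- structure(obj$cfg, class = "encoder_config")
  structure(list(modality = obj$modality, cfg = cfg, params = params,
                 state = list2env(obj$state %||% list(), parent = emptyenv()),
                 consts = obj$consts, vocab = obj$vocab,
                 conv_cache = new.env(parent = emptyenv())),
            class = "moltitox_encoder")
}
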