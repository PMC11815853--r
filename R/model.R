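# The nmdn_model object bundles the embedding provider, the two mixture
# density heads (protein-ligand and metal-ligand) and the interaction
# module, with the classic fit/predict surface.

#' Training and scoring configuration
#'
#' @param train_cutoff pair cutoff used for the density training loss,
#'   Angstrom (default 9)
#' @param test_cutoff pair cutoff used at scoring time (default 9)
#' @param ref_distance reference distance for score normalization
#'   (default: equal to `test_cutoff`, which sweeps of cutoff/reference
#'   combinations show performs comparably to shorter references)
#' @param lr Adam learning rate (default 1e-4)
#' @param lr_decay multiplicative learning-rate decay per epoch (default 1,
#'   i.e. constant; values just below 1 help the mean-absolute-error
#'   affinity objective converge, whose gradients do not shrink near the
#'   optimum)
#' @param batch_size complexes per minibatch (default 8)
#' @param epochs training epochs (default 10)
#' @param seed RNG seed controlling initialization, shuffling and dropout
#' @param w_nmdn,w_pkd combined-loss weights (defaults 1, 1)
#' @param mode "joint" (density + affinity) or "screen_finetune"
#'   (weak-binder hinge objective; mixture heads frozen)
#' @return a list of class `nmdn_config`
#' @export
nmdn_config <- function(train_cutoff = 9.0, test_cutoff = 9.0,
                        ref_distance = test_cutoff, lr = 1e-4,
                        lr_decay = 1.0, batch_size = 8L, epochs = 10L,
                        seed = 1L, w_nmdn = 1.0, w_pkd = 1.0,
                        mode = c("joint", "screen_finetune")) {
  mode <- match.arg(mode)
  stopifnot(train_cutoff > 0, test_cutoff > 0, ref_distance > 0.5,
            lr > 0, lr_decay > 0, lr_decay <= 1, batch_size >= 1L,
            epochs >= 0L)
  structure(list(train_cutoff = train_cutoff, test_cutoff = test_cutoff,
                 ref_distance = ref_distance, lr = lr, lr_decay = lr_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 w_nmdn = w_nmdn, w_pkd = w_pkd, mode = mode),
            class = "nmdn_config")
}

#' Construct an (untrained) NMDN model
#'
#' @param encoder embedding provider from [baseline_encoder()], or NULL
#'   when every dataset record carries precomputed embeddings
#' @param dims embedding widths `c(D_prot, D_lig, D_metal)` when `encoder`
#'   is NULL
#' @param hidden hidden width of the mixture heads (default 64 for the
#'   synthetic study scale; the full-scale width is 4096)
#' @param n_components mixture components (default 10)
#' @param n_layers MLP depth of the heads (default 5)
#' @param dropout dropout rate (default 0.1)
#' @param interaction_hidden gated hidden width (default 128)
#' @param seed initialization seed
#' @return object of class `nmdn_model`
#' @export
nmdn_model <- function(encoder = baseline_encoder(seed = seed), dims = NULL,
                       hidden = 64L, n_components = 10L, n_layers = 5L,
                       dropout = 0.1, interaction_hidden = 128L, seed = 1L) {
  if (is.null(encoder)) {
    stopifnot(!is.null(dims), length(dims) == 3L)
  } else {
    dims <- encoder$dims
  }
  pl_head <- new_mdn_head(dims[1L] + dims[2L], hidden = hidden,
                          n_layers = n_layers, n_components = n_components,
                          dropout = dropout, seed = seed)
  ml_head <- new_mdn_head(dims[3L] + dims[2L], hidden = hidden,
                          n_layers = n_layers, n_components = n_components,
                          dropout = dropout, seed = seed + 1L)
  inter <- new_interaction_params(dims[1L], dims[2L], dims[3L],
                                  hidden = interaction_hidden,
                                  seed = seed + 2L)
  structure(list(encoder = encoder, dims = as.integer(dims),
                 pl_head = pl_head, ml_head = ml_head, interaction = inter,
                 config = nmdn_config(seed = seed), history = NULL,
                 trained = FALSE),
            class = "nmdn_model")
}

#' @export
print.nmdn_model <- function(x, ...) {
  cat("Normalized mixture density network scoring model\n")
  cat(sprintf("  embeddings: %s (D_prot=%d, D_lig=%d, D_metal=%d)\n",
              if (is.null(x$encoder)) "precomputed" else x$encoder$provider_id,
              x$dims[1L], x$dims[2L], x$dims[3L]))
  cat(sprintf("  mixture heads: %d layers x %d hidden, %d components\n",
              x$pl_head$n_layers, x$pl_head$hidden, x$pl_head$n_components))
  cat(sprintf("  interaction module: hidden %d, %d RBFs, cutoff %.1f A\n",
              x$interaction$hidden, x$interaction$n_basis,
              x$interaction$cutoff))
  cat(sprintf("  trained: %s\n", if (isTRUE(x$trained)) "yes" else "no"))
  invisible(x)
}

#' @export
summary.nmdn_model <- function(object, ...) {
  print(object)
  np <- function(pl) sum(vapply(pl, length, integer(1)))
  cat(sprintf("  parameters: PL head %d, ML head %d, interaction %d\n",
              np(object$pl_head$params), np(object$ml_head$params),
              np(object$interaction$params)))
  if (!is.null(object$history)) {
    h <- object$history
    cat(sprintf("  training: %d epochs, loss %.4f -> %.4f\n",
                nrow(h), h$total[1L], h$total[nrow(h)]))
  }
  invisible(object)
}

#' Embed a complex with the model's provider
#' @param model an `nmdn_model`
#' @param complex an [nmdn_complex()]
#' @return an `nmdn_embeddings`
#' @export
model_embed <- function(model, complex) {
  if (is.null(model$encoder))
    stop("model has no encoder; supply precomputed embeddings")
  embed_with_baseline(model$encoder, complex)
}

#' Score poses or predict affinity with a fitted model
#'
#' @param object an `nmdn_model`
#' @param complex an [nmdn_complex()] (or list of them)
#' @param type "nmdn" for the pose score, "pkd" for binding affinity
#' @param extras a [ligand_extras()] (needed for `type = "pkd"`)
#' @param embeddings optional precomputed `nmdn_embeddings`
#' @param ... unused
#' @return an `nmdn_scorebreakdown` or `nmdn_affinity` (or list of them)
#' @export
predict.nmdn_model <- function(object, complex, type = c("nmdn", "pkd"),
                               extras = NULL, embeddings = NULL, ...) {
  type <- match.arg(type)
  if (is.list(complex) && !inherits(complex, "nmdn_complex")) {
    return(lapply(complex, function(cx)
      predict(object, cx, type = type, extras = extras)))
  }
  em <- if (is.null(embeddings)) model_embed(object, complex) else embeddings
  if (type == "nmdn") {
    nmdn_score(complex, em, object$pl_head, object$ml_head,
               cutoff = object$config$test_cutoff,
               ref_distance = object$config$ref_distance)
  } else {
    if (is.null(extras)) extras <- ligand_extras()
    predict_pkd(complex, em, extras, object$interaction,
                cutoff = object$interaction$cutoff)
  }
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single file holding head and interaction
#' parameters, encoder tables, batch-norm state and configuration; a
#' reloaded model reproduces evaluation-mode outputs exactly.
#' @param model an `nmdn_model`
#' @param path checkpoint file
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "nmdn_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return the restored `nmdn_model`
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "nmdn_model")) stop("not an nmdn_model checkpoint: ", path)
  model
}
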