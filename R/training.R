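# Joint training of the mixture density heads and the interaction module
# with the combined loss, via the in-package autodiff engine and Adam.

adam_new <- function() list(m = list(), v = list(), t = 0L)

adam_step <- function(opt, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (is.null(opt$m[[nm]])) {
      opt$m[[nm]] <- 0 * g
      opt$v[[nm]] <- 0 * g
    }
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(opt = opt, params = params)
}

# mixture negative log-likelihood (summed over pairs) as an autodiff node
mdn_nll_node <- function(fw, d) {
  n <- length(d)
  K <- ncol(ad_value(fw$mu))
  Dm <- matrix(d, n, K)
  logw <- ad_sub_cvec(fw$logits, ad_logsumexp_rows(fw$logits))
  t2 <- ad_div(ad_sub(ad_node(Dm), fw$mu), fw$sigma)
  logN <- ad_sub(ad_addc(ad_scale(ad_mul(t2, t2), -0.5), -0.5 * log(2 * pi)),
                 ad_log(fw$sigma))
  logp <- ad_logsumexp_rows(ad_add(logw, logN))
  ad_scale(ad_sum(logp), -1)
}

# Precompute per-record index structures so the epoch loop never re-parses
# or re-enumerates anything.
prep_record <- function(model, rec, config) {
  cx <- rec$complex
  ps_train <- enumerate_pairs(cx, cutoff = config$train_cutoff)
  ps_aff <- if (abs(model$interaction$cutoff - config$train_cutoff) < 1e-12)
    ps_train else enumerate_pairs(cx, cutoff = model$interaction$cutoff)
  aa_levels <- if (!is.null(model$encoder)) rownames(model$encoder$aa_table) else NULL
  list(
    n_res = length(cx$residues), n_lig = length(cx$lig_elements),
    n_met = length(cx$metal_elements),
    aa_idx = if (!is.null(aa_levels))
      match(vapply(cx$residues, `[[`, character(1), "aa_code"), aa_levels) else NULL,
    elem_idx = if (!is.null(model$encoder))
      match(cx$lig_elements, rownames(model$encoder$elem_table)) else NULL,
    metal_idx = if (!is.null(model$encoder) && length(cx$metal_elements))
      match(cx$metal_elements, rownames(model$encoder$metal_table)) else integer(0),
    geomfeat = ligand_geom_features(cx$lig_coords),
    emb = rec$embeddings,
    pl = ps_train$pl, ml = ps_train$ml,
    pl_aff = ps_aff$pl, ml_aff = ps_aff$ml,
    extras = if (is.null(rec$extras)) ligand_extras() else rec$extras,
    label = if (is.null(rec$label)) NA_real_ else rec$label,
    is_binder = if (is.null(rec$is_binder)) TRUE else isTRUE(rec$is_binder)
  )
}

make_leaves <- function(model) {
  lv <- list()
  for (nm in names(model$pl_head$params))
    lv[[paste0("pl.", nm)]] <- ad_leaf(model$pl_head$params[[nm]])
  for (nm in names(model$ml_head$params))
    lv[[paste0("ml.", nm)]] <- ad_leaf(model$ml_head$params[[nm]])
  for (nm in names(model$interaction$params))
    lv[[paste0("inter.", nm)]] <- ad_leaf(model$interaction$params[[nm]])
  if (!is.null(model$encoder)) {
    lv[["enc.aa_table"]] <- ad_leaf(unname(model$encoder$aa_table))
    lv[["enc.elem_table"]] <- ad_leaf(unname(model$encoder$elem_table))
    lv[["enc.metal_table"]] <- ad_leaf(unname(model$encoder$metal_table))
    lv[["enc.geom_W"]] <- ad_leaf(model$encoder$geom_W)
  }
  lv
}

pick <- function(leaves, prefix) {
  sel <- leaves[startsWith(names(leaves), paste0(prefix, "."))]
  names(sel) <- sub(paste0("^", prefix, "\\."), "", names(sel))
  sel
}

# Forward pass for a batch of prepped records; returns loss nodes and the
# batch-norm updates of the heads.
batch_forward <- function(model, preps, leaves, train, config,
                          mode = config$mode) {
  G <- length(preps)
  res_off <- cumsum(c(0L, vapply(preps, `[[`, integer(1), "n_res")))
  lig_off <- cumsum(c(0L, vapply(preps, `[[`, integer(1), "n_lig")))
  met_off <- cumsum(c(0L, vapply(preps, `[[`, integer(1), "n_met")))

  if (!is.null(model$encoder)) {
    aa_idx <- unlist(lapply(preps, `[[`, "aa_idx"))
    elem_idx <- unlist(lapply(preps, `[[`, "elem_idx"))
    geomfeat <- do.call(rbind, lapply(preps, `[[`, "geomfeat"))
    H_res <- ad_index_rows(leaves[["enc.aa_table"]], aa_idx)
    H_lig <- ad_add(ad_index_rows(leaves[["enc.elem_table"]], elem_idx),
                    ad_matmul(ad_node(geomfeat), leaves[["enc.geom_W"]]))
    metal_idx <- unlist(lapply(preps, `[[`, "metal_idx"))
    H_met <- if (length(metal_idx))
      ad_index_rows(leaves[["enc.metal_table"]], metal_idx) else NULL
  } else {
    H_res <- ad_node(do.call(rbind, lapply(preps, function(p) p$emb$residue_emb)))
    H_lig <- ad_node(do.call(rbind, lapply(preps, function(p) p$emb$ligand_emb)))
    mets <- lapply(preps, function(p) p$emb$metal_emb)
    mets <- mets[vapply(mets, nrow, integer(1)) > 0L]
    H_met <- if (length(mets)) ad_node(do.call(rbind, mets)) else NULL
  }

  gather_pairs <- function(field) {
    ii <- list(); jj <- list(); kk <- list(); dd <- list(); grp <- list()
    for (gi in seq_len(G)) {
      tab <- preps[[gi]][[field]]
      if (nrow(tab) == 0L) next
      if ("i" %in% names(tab)) {
        ii[[length(ii) + 1L]] <- tab$i + res_off[gi]
      } else {
        kk[[length(kk) + 1L]] <- tab$k + met_off[gi]
      }
      jj[[length(jj) + 1L]] <- tab$j + lig_off[gi]
      dd[[length(dd) + 1L]] <- tab$d
      grp[[length(grp) + 1L]] <- rep(gi, nrow(tab))
    }
    list(i = unlist(ii), k = unlist(kk), j = unlist(jj), d = unlist(dd),
         group = unlist(grp))
  }

  # density loss at the training cutoff
  plp <- gather_pairs("pl")
  bn_updates <- list()
  if (length(plp$d)) {
    Xpl <- ad_concat_cols(ad_index_rows(H_res, plp$i),
                          ad_index_rows(H_lig, plp$j))
    fw <- mdn_head_forward(model$pl_head, Xpl, pick(leaves, "pl"),
                           train = train && mode != "screen_finetune")
    L_pl <- mdn_nll_node(fw, plp$d)
    bn_updates$pl <- fw$bn_update
  } else L_pl <- ad_node(matrix(0, 1L, 1L))

  mlp <- gather_pairs("ml")
  if (length(mlp$d)) {
    Xml <- ad_concat_cols(ad_index_rows(H_met, mlp$k),
                          ad_index_rows(H_lig, mlp$j))
    fw <- mdn_head_forward(model$ml_head, Xml, pick(leaves, "ml"),
                           train = train && mode != "screen_finetune")
    L_ml <- mdn_nll_node(fw, mlp$d)
    bn_updates$ml <- fw$bn_update
  } else L_ml <- ad_node(matrix(0, 1L, 1L))

  # affinity loss at the interaction cutoff
  pla <- gather_pairs("pl_aff")
  mla <- gather_pairs("ml_aff")
  pd <- list(
    n_complex = G,
    n_pl = length(pla$d),
    Hp = if (length(pla$d)) ad_index_rows(H_res, pla$i) else NULL,
    Hl_pl = if (length(pla$d)) ad_index_rows(H_lig, pla$j) else NULL,
    d_pl = pla$d,
    rmsd_pl = if (length(pla$d))
      vapply(preps, function(p) p$extras$mmff_rmsd, numeric(1))[pla$group] else numeric(0),
    group_pl = pla$group,
    n_ml = length(mla$d),
    Hm = if (length(mla$d)) ad_index_rows(H_met, mla$k) else NULL,
    Hl_ml = if (length(mla$d)) ad_index_rows(H_lig, mla$j) else NULL,
    d_ml = mla$d, group_ml = mla$group,
    dG_gw = vapply(preps, function(p) p$extras$dG_gas_to_water, numeric(1)),
    dG_wo = vapply(preps, function(p) p$extras$dG_oct_to_water, numeric(1))
  )
  out <- interaction_forward(model$interaction, pd, pick(leaves, "inter"))
  labels <- vapply(preps, `[[`, numeric(1), "label")
  if (anyNA(labels)) {
    L_pkd <- ad_node(matrix(0, 1L, 1L))
  } else {
    diff <- ad_sub(out$pkd, ad_node(matrix(labels, ncol = 1L)))
    if (mode == "screen_finetune") {
      bind <- vapply(preps, `[[`, logical(1), "is_binder")
      mask_b <- matrix(as.numeric(bind), ncol = 1L)
      mask_w <- matrix(as.numeric(!bind), ncol = 1L)
      hinge <- ad_relu(ad_addc(diff, -1.0))
      L_pkd <- ad_mean(ad_add(ad_mul(ad_abs(diff), ad_node(mask_b)),
                              ad_mul(hinge, ad_node(mask_w))))
    } else {
      L_pkd <- ad_mean(ad_abs(diff))
    }
  }

  total <- ad_add(ad_scale(ad_add(L_pl, L_ml), config$w_nmdn),
                  ad_scale(L_pkd, config$w_pkd))
  list(total = total, L_pl = L_pl, L_ml = L_ml, L_pkd = L_pkd,
       pkd = out$pkd, bn_updates = bn_updates)
}

#' Combined training loss on a batch
#'
#' `w_nmdn * (L_density_PL + L_density_ML) + w_pkd * L_affinity`, where the
#' density terms are negative log-likelihoods summed over all pairs within
#' the training cutoff and the affinity term is the batch MAE (or the
#' weak-binder hinge objective in `screen_finetune` mode). Evaluated in
#' inference mode (no dropout, running batch-norm statistics).
#'
#' @param model an `nmdn_model`
#' @param batch list of records: each a list with `complex`, and optionally
#'   `label` (experimental pKd), `is_binder`, `extras`, `embeddings`
#' @param config an [nmdn_config()] (default: the model's)
#' @param mode override the config mode
#' @return a `LossReport` list: `total`, `nmdn_pl`, `nmdn_ml`, `pkd`, and
#'   the weights used
#' @export
combined_loss <- function(model, batch, config = model$config,
                          mode = config$mode) {
  preps <- lapply(batch, function(r) prep_record(model, r, config))
  leaves <- make_leaves(model)
  fw <- batch_forward(model, preps, leaves, train = FALSE, config = config,
                      mode = mode)
  list(total = as.numeric(ad_value(fw$total)),
       nmdn_pl = as.numeric(ad_value(fw$L_pl)),
       nmdn_ml = as.numeric(ad_value(fw$L_ml)),
       pkd = as.numeric(ad_value(fw$L_pkd)),
       w_nmdn = config$w_nmdn, w_pkd = config$w_pkd)
}

trainable_names <- function(model, mode) {
  nms <- names(make_leaves(model))
  drop <- character(0)
  if (!is.null(model$encoder)) {
    fl <- finetune_flags(model$encoder)
    if (!fl$residue) drop <- c(drop, "enc.aa_table")
    if (!fl$ligand) drop <- c(drop, "enc.elem_table", "enc.geom_W")
    if (!fl$metal) drop <- c(drop, "enc.metal_table")
  }
  if (mode == "screen_finetune") {
    # weak-binder fine-tuning adjusts the interaction module only
    drop <- c(drop, grep("^(pl|ml|enc)\\.", nms, value = TRUE))
  }
  setdiff(nms, drop)
}

write_back <- function(model, leaves) {
  for (nm in names(leaves)) {
    v <- leaves[[nm]]$value
    key <- sub("^[a-z]+\\.", "", nm)
    if (startsWith(nm, "pl.")) model$pl_head$params[[key]] <- v
    else if (startsWith(nm, "ml.")) model$ml_head$params[[key]] <- v
    else if (startsWith(nm, "inter.")) model$interaction$params[[key]] <- v
    else if (nm == "enc.aa_table") model$encoder$aa_table[, ] <- v
    else if (nm == "enc.elem_table") model$encoder$elem_table[, ] <- v
    else if (nm == "enc.metal_table") model$encoder$metal_table[, ] <- v
    else if (nm == "enc.geom_W") model$encoder$geom_W <- v
  }
  model
}

#' Fit an NMDN model
#'
#' Joint minibatch training of the mixture density heads and the
#' interaction module with Adam on the combined loss. Deterministic given
#' the config seed (single-threaded BLAS assumed); diverging (non-finite)
#' loss aborts with diagnostics. In `screen_finetune` mode the mixture
#' heads are frozen and only the interaction module is updated against the
#' weak-binder hinge objective.
#'
#' @param dataset list of records; each a list with `complex` and
#'   optionally `label`, `is_binder`, `extras`, `embeddings`
#' @param config an [nmdn_config()]
#' @param model optional starting `nmdn_model` (default: a fresh one with
#'   the baseline encoder)
#' @param ... passed to [nmdn_model()] when `model` is NULL
#' @return the fitted `nmdn_model`, with a per-epoch `history` data frame
#' @export
fit_nmdn <- function(dataset, config = nmdn_config(), model = NULL, ...) {
  stopifnot(length(dataset) >= 1L)
  set.seed(config$seed)
  if (is.null(model)) {
    model <- nmdn_model(encoder = baseline_encoder(seed = config$seed),
                        seed = config$seed, ...)
  }
  model$config <- config
  preps <- lapply(dataset, function(r) prep_record(model, r, config))
  tnames <- trainable_names(model, config$mode)
  opt <- adam_new()
  n <- length(preps)
  hist <- NULL

  lr_decay <- if (is.null(config$lr_decay)) 1.0 else config$lr_decay
  for (epoch in seq_len(config$epochs)) {
    lr_epoch <- config$lr * lr_decay^(epoch - 1L)
    ord <- sample.int(n)
    ep <- c(total = 0, nmdn_pl = 0, nmdn_ml = 0, pkd = 0)
    nb <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      leaves <- make_leaves(model)
      ad_tape_start()
      fw <- tryCatch(
        batch_forward(model, preps[idx], leaves, train = TRUE, config = config),
        finally = NULL)
      loss_val <- as.numeric(ad_value(fw$total))
      if (!is.finite(loss_val)) {
        ad_tape_stop()
        stop(sprintf("training diverged at epoch %d (loss = %g)", epoch,
                     loss_val))
      }
      ad_backward(fw$total)
      ad_tape_stop()
      grads <- lapply(leaves[tnames], ad_grad)
      params <- lapply(leaves[tnames], `[[`, "value")
      st <- adam_step(opt, params, grads, lr = lr_epoch)
      opt <- st$opt
      for (nm in tnames) leaves[[nm]]$value <- st$params[[nm]]
      model <- write_back(model, leaves)
      for (nm in names(fw$bn_updates$pl))
        model$pl_head$bn_state[[nm]] <- fw$bn_updates$pl[[nm]]
      for (nm in names(fw$bn_updates$ml))
        model$ml_head$bn_state[[nm]] <- fw$bn_updates$ml[[nm]]
      ep <- ep + c(loss_val, as.numeric(ad_value(fw$L_pl)),
                   as.numeric(ad_value(fw$L_ml)),
                   as.numeric(ad_value(fw$L_pkd)))
      nb <- nb + 1L
    }
    hist <- rbind(hist, data.frame(epoch = epoch, total = unname(ep[1L]) / nb,
                                   nmdn_pl = unname(ep[2L]) / nb,
                                   nmdn_ml = unname(ep[3L]) / nb,
                                   pkd = unname(ep[4L]) / nb,
                                   row.names = NULL))
  }
  model$history <- hist
  model$trained <- TRUE
  model
}

#' Train a mixture density head directly on labelled pair samples
#'
#' The pair-level counterpart of [fit_nmdn()] for density (parameter
#' recovery) studies: features are the concatenated embeddings of each
#' pair, targets the observed distances.
#'
#' @param head an [new_mdn_head()]
#' @param X feature matrix (n x d_in)
#' @param d observed distances (length n)
#' @param epochs,batch_size,lr,seed optimization settings
#' @return the trained head
#' @export
fit_mdn_head <- function(head, X, d, epochs = 20L, batch_size = 256L,
                         lr = 1e-3, seed = 1L) {
  stopifnot(nrow(X) == length(d), ncol(X) == head$d_in)
  set.seed(seed)
  opt <- adam_new()
  n <- nrow(X)
  for (epoch in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      leaves <- lapply(head$params, ad_leaf)
      ad_tape_start()
      fw <- mdn_head_forward(head, X[idx, , drop = FALSE], leaves, train = TRUE)
      loss <- ad_scale(mdn_nll_node(fw, d[idx]), 1 / length(idx))
      if (!is.finite(ad_value(loss))) {
        ad_tape_stop()
        stop("density training diverged (non-finite loss)")
      }
      ad_backward(loss)
      ad_tape_stop()
      grads <- lapply(leaves, ad_grad)
      params <- lapply(leaves, `[[`, "value")
      st <- adam_step(opt, params, grads, lr = lr)
      opt <- st$opt
      head$params <- st$params
      for (nm in names(fw$bn_update)) head$bn_state[[nm]] <- fw$bn_update[[nm]]
    }
  }
  head
}

#' Finite-difference gradient check of the combined loss
#'
#' Compares reverse-mode gradients with central finite differences on a
#' random subset of parameter coordinates. Run in deterministic training
#' mode (batch statistics, dropout disabled) so the batch-norm training
#' path is exercised.
#'
#' @param model an `nmdn_model` (its dropout is ignored for the check)
#' @param batch list of records as in [combined_loss()]
#' @param n_coords coordinates sampled per parameter tensor (default 3)
#' @param h finite-difference step (default 1e-5)
#' @param seed seed for coordinate sampling
#' @return list with `max_rel_err` and the per-coordinate comparison table.
#'   The relative error uses `max(|analytic|, |fd|, 1e-4)` as denominator:
#'   coordinates whose gradient magnitude sits below the central-difference
#'   noise floor are compared on an absolute scale.
#' @export
gradient_check <- function(model, batch, n_coords = 3L, h = 1e-5, seed = 1L) {
  model$pl_head$dropout <- 0
  model$ml_head$dropout <- 0
  config <- model$config
  preps <- lapply(batch, function(r) prep_record(model, r, config))

  loss_of <- function(m) {
    leaves <- make_leaves(m)
    fw <- batch_forward(m, preps, leaves, train = TRUE, config = config)
    as.numeric(ad_value(fw$total))
  }
  leaves <- make_leaves(model)
  ad_tape_start()
  fw <- batch_forward(model, preps, leaves, train = TRUE, config = config)
  ad_backward(fw$total)
  ad_tape_stop()

  set.seed(seed)
  rows <- NULL
  for (nm in names(leaves)) {
    g <- ad_grad(leaves[[nm]])
    npar <- length(leaves[[nm]]$value)
    for (ci in sample.int(npar, min(n_coords, npar))) {
      m2 <- model
      bump <- function(mm, delta) {
        lv <- make_leaves(mm)
        v <- lv[[nm]]$value
        v[ci] <- v[ci] + delta
        lv[[nm]]$value <- v
        write_back(mm, lv)
      }
      fplus <- loss_of(bump(model, h))
      fminus <- loss_of(bump(model, -h))
      fd <- (fplus - fminus) / (2 * h)
      an <- g[ci]
      rel <- abs(an - fd) / max(abs(an), abs(fd), 1e-4)
      rows <- rbind(rows, data.frame(param = nm, coord = ci,
                                     analytic = an, fd = fd, rel_err = rel))
    }
  }
  list(max_rel_err = max(rows$rel_err), table = rows)
}
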