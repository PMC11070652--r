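# Hand-derived reverse-mode gradients for the shell encoders and regression
# head, plus the AdamW optimizer and the training recipe (step-halved
# learning rate, early stopping on validation loss, best-checkpoint
# selection). Gradient correctness is pinned by finite-difference tests.

ln_backward <- function(dy, xhat, sd, g) {
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- sweep(dy, 2L, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) / sd
  list(dx = dx, dg = dg, db = db)
}

# backward through one encoder layer; returns input grad, parameter grads and
# the per-head attention-score grads (the bias gradients)
layer_backward <- function(dH2, fw, layer, n_heads) {
  ln2 <- ln_backward(dH2, fw$ln2$xhat, fw$ln2$sd, layer$g2)
  dR2 <- ln2$dx
  dF <- dR2
  dW2 <- crossprod(fw$F1, dF); db2 <- colSums(dF)
  dF1 <- dF %*% t(layer$W2)
  dZ1 <- dF1 * (fw$Z1 > 0)
  dW1 <- crossprod(fw$H1, dZ1); db1 <- colSums(dZ1)
  dH1 <- dR2 + dZ1 %*% t(layer$W1)
  ln1 <- ln_backward(dH1, fw$ln1$xhat, fw$ln1$sd, layer$g1)
  dR1 <- ln1$dx
  dHin <- dR1                       # residual branch
  dO <- dR1
  att <- fw$att
  dWo <- crossprod(att$O, dO); dbo <- colSums(dO)
  dOcat <- dO %*% t(layer$Wo)
  d <- ncol(dH2); dh <- d %/% n_heads; s <- sqrt(dh)
  dQ <- matrix(0, nrow(dH2), d); dK <- dQ; dV <- dQ
  dA_heads <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    Ph <- att$P[[h]]
    dOh <- dOcat[, cols, drop = FALSE]
    Vh <- att$V[, cols, drop = FALSE]
    dPh <- tcrossprod(dOh, Vh)
    dVh <- crossprod(Ph, dOh)
    dAh <- Ph * (dPh - rowSums(dPh * Ph))
    dA_heads[[h]] <- dAh
    dQ[, cols] <- dAh %*% att$K[, cols, drop = FALSE] / s
    dK[, cols] <- crossprod(dAh, att$Q[, cols, drop = FALSE]) / s
    dV[, cols] <- dVh
  }
  H_in <- fw$H_in
  dWq <- crossprod(H_in, dQ); dWk <- crossprod(H_in, dK); dWv <- crossprod(H_in, dV)
  dHin <- dHin + dQ %*% t(layer$Wq) + dK %*% t(layer$Wk) + dV %*% t(layer$Wv)
  gl <- list(Wq = dWq, Wk = dWk, Wv = dWv, Wo = dWo, bo = dbo,
             g1 = ln1$dg, be1 = ln1$db, W1 = dW1, b1 = db1,
             W2 = dW2, b2 = db2, g2 = ln2$dg, be2 = ln2$db)
  list(dH = dHin, gl = gl, dA_heads = dA_heads)
}

shell_backward <- function(sp, g, prep, cache, de) {
  m0 <- prep$m0; M <- prep$M
  d <- ncol(sp$W_in)
  gW_emb <- outer(cache$h_read, de)
  gb_emb <- de
  dH <- matrix(0, M, d)
  dh_read <- as.vector(sp$W_emb %*% de)
  if (identical(cache$readout, "mean")) {
    dH[seq_len(m0), ] <- matrix(dh_read / m0, m0, d, byrow = TRUE)
  } else {
    dH[M, ] <- dh_read
  }
  n_heads <- nrow(sp$bias_tab)
  n_layers <- length(sp$layers)
  glayers <- vector("list", n_layers)
  gtab <- matrix(0, n_heads, ncol(sp$bias_tab))
  dC <- matrix(0, M, M)
  for (l in seq.int(n_layers, 1L)) {
    lb <- layer_backward(dH, cache$caches[[l]], sp$layers[[l]], n_heads)
    glayers[[l]] <- lb$gl
    dH <- lb$dH
    for (h in seq_len(n_heads)) {
      dAh <- lb$dA_heads[[h]]
      dC <- dC + dAh
      for (sl in seq_len(ncol(gtab))) {
        idx <- prep$slot_groups[[sl]]
        if (length(idx)) gtab[h, sl] <- gtab[h, sl] + sum(dAh[idx])
      }
    }
  }
  gwE <- matrix(0, nrow(sp$wE), ncol(sp$wE))
  G <- dC * prep$ninv
  for (p in seq_along(prep$pos_idx)) {
    idx <- prep$pos_idx[[p]]
    if (!length(idx)) next
    gwE[p, ] <- as.vector(crossprod(g$edge_feat[prep$pos_eid[[p]], , drop = FALSE],
                                    G[idx]))
  }
  dH0 <- dH
  list(W_in = crossprod(g$X, dH0[seq_len(m0), , drop = FALSE]),
       b_in = colSums(dH0[seq_len(m0), , drop = FALSE]),
       h_cls = dH0[M, ],
       bias_tab = gtab, wE = gwE, layers = glayers,
       W_emb = gW_emb, b_emb = gb_emb)
}

# gradient of the squared error of one pose w.r.t. every model parameter,
# returned with the same nesting as list(shells = ..., head = ...)
pose_backward <- function(model, fw, dpred) {
  ds <- dpred * sigmoid(fw$s)
  nh <- length(model$head)
  ghead <- vector("list", nh)
  da <- matrix(ds, 1L, 1L)
  for (q in seq.int(nh, 1L)) {
    inp <- fw$hcache[[q]]
    dz <- if (q < nh) da * (fw$hcache[[q + 1L]] > 0) else da
    ghead[[q]] <- list(W = crossprod(inp, dz), b = as.vector(dz))
    da <- dz %*% t(model$head[[q]]$W)
  }
  dz_vec <- as.vector(da)
  d_embed <- model$config$d_embed
  n_shells <- model$config$layout$n_shells
  gshells <- vector("list", n_shells)
  for (k in seq_len(n_shells)) {
    de <- dz_vec[((k - 1L) * d_embed + 1L):(k * d_embed)]
    gshells[[k]] <- shell_backward(model$shells[[k]], fw$graphs[[k]],
                                   fw$prep[[k]], fw$enc[[k]], de)
  }
  list(shells = gshells, head = ghead)
}

# ---------------------------------------------------------------------------
# flatten / unflatten and AdamW
# ---------------------------------------------------------------------------

pflatten <- function(x) unlist(x, use.names = FALSE)

punflatten <- function(flat, skel) {
  pos <- 0L
  rec <- function(s) {
    if (is.list(s)) return(lapply(s, rec))
    n <- length(s)
    v <- flat[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (!is.null(dim(s))) dim(v) <- dim(s)
    v
  }
  out <- rec(skel)
  if (pos != length(flat)) stop2("parameter vector length mismatch")
  out
}

adamw_step <- function(theta, grad, state, lr, weight_decay, decay_mask,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  theta <- theta - lr * (mhat / (sqrt(vhat) + eps) +
                           weight_decay * decay_mask * theta)
  list(theta = theta, state = state)
}

# decoupled weight decay applies to weight matrices only; biases, layer-norm
# gains/offsets, the readout token and the learnable attention-bias scalars
# are exempt (the usual transformer convention)
.decayed_names <- c("Wq", "Wk", "Wv", "Wo", "W1", "W2", "W_in", "W_emb", "W")

build_decay_mask <- function(skel) {
  rec <- function(s, nm) {
    if (is.list(s))
      return(unlist(lapply(seq_along(s), function(q)
        rec(s[[q]], names(s)[q] %||% "")), use.names = FALSE))
    rep(if (nm %in% .decayed_names) 1 else 0, length(s))
  }
  rec(skel, "")
}

# ---------------------------------------------------------------------------
# Training
# ---------------------------------------------------------------------------

featurize_dataset <- function(poses, layout, schema, hop_max, quiet = TRUE) {
  lapply(poses, function(p) {
    if (inherits(p, "pose_features")) p
    else featurize_pose(p, layout, schema, hop_max)
  })
}

usable_training_pose <- function(f) {
  !f$dissociated && !is.null(f$rmsd_label) && is.finite(f$rmsd_label)
}

#' Train the scoring model
#'
#' Minimises the mean squared error between predicted and true RMSD with
#' AdamW (decoupled weight decay), halving the learning rate every `step`
#' epochs. Training stops at `max_epochs` or as soon as the validation loss
#' has not improved (by at least `improve_tol`) for `step` consecutive
#' epochs; the returned model carries the parameters of the epoch with the
#' lowest validation loss, not the last one. Dissociated or unlabelled poses
#' are dropped before training. With the same configuration (seed included)
#' and data, two runs produce bit-identical models.
#'
#' @param train,validation Lists of labelled [complex_pose()] or pre-built
#'   `pose_features`. `validation = NULL` falls back to monitoring the
#'   training loss.
#' @param config A [gs_config()].
#' @param schema Featurization schema.
#' @param quiet Suppress per-epoch messages.
#' @return A trained [gs_model()] with a `history` data.frame (columns
#'   `epoch` (0-based), `lr`, `train_loss`, `val_loss`) and `best_epoch`.
#' @export
train_model <- function(train, validation = NULL, config = gs_config(),
                        schema = feature_schema(), quiet = TRUE) {
  if (length(train) == 0L) stop2("empty training set")
  layout <- config$layout
  tr <- featurize_dataset(train, layout, schema, config$hop_max)
  va <- if (length(validation)) featurize_dataset(validation, layout, schema,
                                                  config$hop_max) else list()
  ok <- vapply(tr, usable_training_pose, TRUE)
  if (!all(ok)) message(sum(!ok), " dissociated/unlabelled pose(s) dropped from training")
  tr <- tr[ok]
  va <- va[vapply(va, usable_training_pose, TRUE)]
  if (length(tr) == 0L) stop2("no usable training poses")
  for (q in seq_along(tr)) tr[[q]]$prep <- lapply(tr[[q]]$graphs, prep_graph_tensors)
  for (q in seq_along(va)) va[[q]]$prep <- lapply(va[[q]]$graphs, prep_graph_tensors)
  y_tr <- vapply(tr, function(f) f$rmsd_label, 1.0)
  y_va <- vapply(va, function(f) f$rmsd_label, 1.0)

  set.seed(config$seed)
  model <- init_model(config, schema)
  # warm-start the output bias so the initial prediction is the mean training
  # label (softplus-inverted); a standard base-rate initialisation
  ybar <- max(mean(y_tr), 1e-3)
  nh <- length(model$head)
  model$head[[nh]]$b <- log(expm1(ybar))
  skel <- list(shells = model$shells, head = model$head)
  theta <- pflatten(skel)
  dmask <- build_decay_mask(skel)
  state <- list(m = numeric(length(theta)), v = numeric(length(theta)), t = 0L)

  n <- length(tr)
  bs <- max(1L, min(config$batch_size, n))
  best_val <- Inf; best_theta <- theta; best_epoch <- -1L; wait <- 0L
  hist <- vector("list", config$max_epochs)

  val_loss_of <- function() {
    if (!length(va)) return(NA_real_)
    preds <- vapply(va, function(f) pose_forward(model, f)$pred, 1.0)
    mse_loss(preds, y_va)
  }

  for (epoch in seq.int(0L, config$max_epochs - 1L)) {
    lr <- lr_at_epoch(epoch, config$lr, config$step)
    ord <- sample.int(n)
    sq_err <- numeric(n)
    for (b0 in seq(1L, n, by = bs)) {
      batch <- ord[b0:min(b0 + bs - 1L, n)]
      gacc <- numeric(length(theta))
      for (i in batch) {
        fw <- pose_forward(model, tr[[i]], keep_cache = TRUE)
        fw$graphs <- tr[[i]]$graphs
        err <- fw$pred - y_tr[i]
        sq_err[i] <- err^2
        grads <- pose_backward(model, fw, dpred = 2 * err / length(batch))
        gacc <- gacc + pflatten(grads)
      }
      st <- adamw_step(theta, gacc, state, lr, config$weight_decay, dmask)
      theta <- st$theta; state <- st$state
      up <- punflatten(theta, skel)
      model$shells <- up$shells; model$head <- up$head
    }
    train_loss <- mean(sq_err)
    val_loss <- val_loss_of()
    monitored <- if (is.na(val_loss)) train_loss else val_loss
    hist[[epoch + 1L]] <- data.frame(epoch = epoch, lr = lr,
                                     train_loss = train_loss,
                                     val_loss = val_loss)
    if (!quiet)
      message(sprintf("epoch %3d lr %.2e train %.4f val %.4f",
                      epoch, lr, train_loss, val_loss))
    if (monitored < best_val - config$improve_tol) {
      best_val <- monitored; best_theta <- theta
      best_epoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$step) break
    }
  }
  up <- punflatten(best_theta, skel)
  model$shells <- up$shells; model$head <- up$head
  model$history <- do.call(rbind, hist[!vapply(hist, is.null, TRUE)])
  model$best_epoch <- best_epoch
  model$best_val <- best_val
  model
}

#' Split complexes into disjoint ensemble parts
#'
#' Poses of one complex never straddle two parts. Deterministic under the
#' seed.
#'
#' @param complex_ids Character vector, one entry per pose.
#' @param n_parts Number of parts.
#' @param seed RNG seed.
#' @return Integer vector of part assignments (one per pose).
#' @export
split_complexes <- function(complex_ids, n_parts = 4L, seed = 1L) {
  cids <- unique(complex_ids)
  if (length(cids) < n_parts)
    stop2("need at least %d complexes to form %d ensemble parts",
          n_parts, n_parts)
  set.seed(seed)
  ord <- sample(cids)
  part_of_cid <- rep(seq_len(n_parts), length.out = length(cids))
  names(part_of_cid) <- ord
  unname(part_of_cid[complex_ids])
}

#' Train the four-part ensemble
#'
#' The labelled dataset is split evenly into `ensemble_parts`
#' complex-disjoint parts. Each member model trains on one part and
#' validates on another randomly selected part (used for checkpoint
#' selection). Regression metrics of each member on its validation part are
#' summarised as mean and standard deviation across the members.
#'
#' @param dataset List of labelled [complex_pose()] or `pose_features`
#'   (include the replicated native poses; see [make_learnable_dataset()]).
#' @param config A [gs_config()].
#' @param schema Featurization schema.
#' @param quiet Suppress per-epoch messages.
#' @return List of class `gs_ensemble`: `models`, `report` (data.frame with
#'   per-metric mean and sd), `metrics` (member x metric matrix) and `parts`
#'   (part assignment per pose).
#' @export
train_ensemble <- function(dataset, config = gs_config(),
                           schema = feature_schema(), quiet = TRUE) {
  feats <- featurize_dataset(dataset, config$layout, schema, config$hop_max)
  cids <- vapply(feats, function(f) f$complex_id, "")
  parts <- split_complexes(cids, config$ensemble_parts, config$seed)
  set.seed(config$seed + 7L)
  val_part <- vapply(seq_len(config$ensemble_parts), function(i)
    sample(setdiff(seq_len(config$ensemble_parts), i), 1L), 1L)
  models <- vector("list", config$ensemble_parts)
  metr <- matrix(NA_real_, config$ensemble_parts, 3L,
                 dimnames = list(NULL, c("rmse", "pearson_r", "spearman_rho")))
  for (i in seq_len(config$ensemble_parts)) {
    tr <- feats[parts == i]
    va <- feats[parts == val_part[i]]
    cfg_i <- config; cfg_i$seed <- config$seed + i
    models[[i]] <- train_model(tr, va, cfg_i, schema, quiet = quiet)
    va_ok <- va[vapply(va, usable_training_pose, TRUE)]
    preds <- vapply(va_ok, function(f)
      pose_forward(models[[i]], f)$pred, 1.0)
    truth <- vapply(va_ok, function(f) f$rmsd_label, 1.0)
    rm <- regression_metrics(preds, truth)
    metr[i, ] <- c(rm$rmse, rm$pearson_r, rm$spearman_rho)
  }
  report <- data.frame(metric = colnames(metr),
                       mean = colMeans(metr),
                       sd = apply(metr, 2L, stats::sd),
                       row.names = NULL)
  structure(list(models = models, report = report, metrics = metr,
                 parts = parts, val_part = val_part),
            class = "gs_ensemble")
}

#' @export
print.gs_ensemble <- function(x, ...) {
  cat(sprintf("ensemble of %d models; validation metrics (mean +/- sd):\n",
              length(x$models)))
  for (q in seq_len(nrow(x$report)))
    cat(sprintf("  %-12s %.4f +/- %.4f\n", x$report$metric[q],
                x$report$mean[q], x$report$sd[q]))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Checkpoints (self-describing JSON, text only)
# ---------------------------------------------------------------------------

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the full configuration (shell layout, hop_max,
#' dimensions, training recipe, seed) alongside the parameters, so a loaded
#' model refuses to score poses featurized under a different schema width.
#'
#' @param model A [gs_model()].
#' @param path JSON file path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  cf <- model$config
  obj <- list(
    config = list(layout = unclass(cf$layout),
                  hop_max = cf$hop_max, d_hidden = cf$d_hidden,
                  n_heads = cf$n_heads, n_layers = cf$n_layers,
                  d_ff = cf$d_ff, d_embed = cf$d_embed,
                  head_widths = cf$head_widths, lr = cf$lr, step = cf$step,
                  max_epochs = cf$max_epochs, batch_size = cf$batch_size,
                  weight_decay = cf$weight_decay, improve_tol = cf$improve_tol,
                  readout = cf$readout %||% "cls",
                  ensemble_parts = cf$ensemble_parts, seed = cf$seed),
    schema_widths = as.list(model$schema_widths),
    theta = pflatten(list(shells = model$shells, head = model$head)),
    history = model$history)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lc <- obj$config$layout
  cf <- gs_config(layout = shell_layout(lc$d0, lc$d, lc$n_shells),
                  hop_max = obj$config$hop_max, d_hidden = obj$config$d_hidden,
                  n_heads = obj$config$n_heads, n_layers = obj$config$n_layers,
                  d_ff = obj$config$d_ff, d_embed = obj$config$d_embed,
                  head_widths = obj$config$head_widths, lr = obj$config$lr,
                  step = obj$config$step, max_epochs = obj$config$max_epochs,
                  batch_size = obj$config$batch_size,
                  weight_decay = obj$config$weight_decay,
                  improve_tol = obj$config$improve_tol,
                  readout = obj$config$readout %||% "cls",
                  ensemble_parts = obj$config$ensemble_parts,
                  seed = obj$config$seed)
  set.seed(cf$seed)
  sw <- unlist(obj$schema_widths)
  schema <- feature_schema()
  if (schema$node_width != sw[["node"]])
    stop2("checkpoint schema width %d does not match this package's schema (%d)",
          sw[["node"]], schema$node_width)
  model <- init_model(cf, schema)
  skel <- list(shells = model$shells, head = model$head)
  up <- punflatten(as.numeric(obj$theta), skel)
  model$shells <- up$shells; model$head <- up$head
  if (!is.null(obj$history)) model$history <- as.data.frame(obj$history)
  model
}
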