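#' Model and training configuration
#'
#' Collects every tunable of the scoring model: shell layout, shortest-path
#' truncation, encoder dimensions, regression-head widths, and the training
#' recipe (AdamW at initial learning rate 0.001 halved every `step` epochs,
#' early stopping after `step` non-improving validation epochs, at most 150
#' epochs, four-part ensemble). Unknown settings are rejected because the
#' function signature is the schema.
#'
#' @param layout A [shell_layout()].
#' @param hop_max Shortest-path truncation for the attention biases.
#' @param d_hidden Encoder hidden width (divisible by `n_heads`).
#' @param n_heads Attention heads per encoder layer.
#' @param n_layers Encoder layers per shell.
#' @param d_ff Feed-forward inner width.
#' @param d_embed Per-shell embedding width (128; the concatenated pose
#'   vector has length `d_embed * n_shells`).
#' @param head_widths Hidden widths of the regression MLP.
#' @param lr Initial learning rate.
#' @param step Epoch period for halving the learning rate; also the early
#'   stopping patience.
#' @param max_epochs Hard cap on training epochs.
#' @param batch_size Minibatch size.
#' @param weight_decay AdamW decoupled weight decay.
#' @param improve_tol Minimum absolute validation-loss improvement that
#'   resets the early-stopping counter.
#' @param readout Shell-graph readout: `"cls"` (virtual readout token) or
#'   `"mean"` (mean pooling over atom nodes).
#' @param ensemble_parts Number of complex-disjoint training parts.
#' @param seed RNG seed governing initialisation and batch shuffling.
#' @return A list of class `gs_config`.
#' @export
gs_config <- function(layout = shell_layout(), hop_max = 5L, d_hidden = 128L,
                      n_heads = 4L, n_layers = 4L, d_ff = 2L * d_hidden,
                      d_embed = 128L, head_widths = c(256L, 64L),
                      lr = 0.001, step = 25L, max_epochs = 150L,
                      batch_size = 32L, weight_decay = 0.01,
                      improve_tol = 1e-4, readout = c("cls", "mean"),
                      ensemble_parts = 4L, seed = 1L) {
  readout <- match.arg(readout)
  stopifnot(inherits(layout, "shell_layout"))
  if (step < 1L) stop2("step must be >= 1")
  if (max_epochs < step) stop2("max_epochs must be >= step")
  if (d_hidden %% n_heads != 0L) stop2("d_hidden must be divisible by n_heads")
  structure(list(layout = layout, hop_max = as.integer(hop_max),
                 d_hidden = as.integer(d_hidden), n_heads = as.integer(n_heads),
                 n_layers = as.integer(n_layers), d_ff = as.integer(d_ff),
                 d_embed = as.integer(d_embed),
                 head_widths = as.integer(head_widths), lr = lr,
                 step = as.integer(step), max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 weight_decay = weight_decay, improve_tol = improve_tol,
                 readout = readout,
                 ensemble_parts = as.integer(ensemble_parts),
                 seed = as.integer(seed)),
            class = "gs_config")
}

glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

#' Initialise an untrained shell-graph scoring model
#'
#' One encoder per shell (weights not shared between shells: each shell sees
#' a different molecular environment), each with its own spatial-bias table
#' (one learnable scalar per head per hop value, shared across layers within
#' the encoder, including a dedicated slot for the unreachable sentinel -1)
#' and position-indexed edge-bias weights. A regression MLP maps the
#' concatenated shell embeddings to a single non-negative RMSD via softplus.
#'
#' @param config A [gs_config()].
#' @param schema The [feature_schema()] the model is bound to.
#' @return An object of class `gs_model`.
#' @export
init_model <- function(config = gs_config(), schema = feature_schema()) {
  d <- config$d_hidden
  n_shells <- config$layout$n_shells
  shells <- lapply(seq_len(n_shells), function(k) {
    layers <- lapply(seq_len(config$n_layers), function(l) list(
      Wq = glorot(d, d), Wk = glorot(d, d), Wv = glorot(d, d),
      Wo = glorot(d, d), bo = numeric(d),
      g1 = rep(1, d), be1 = numeric(d),
      W1 = glorot(d, config$d_ff), b1 = numeric(config$d_ff),
      W2 = glorot(config$d_ff, d), b2 = numeric(d),
      g2 = rep(1, d), be2 = numeric(d)))
    list(W_in = glorot(schema$node_width, d), b_in = numeric(d),
         h_cls = stats::rnorm(d, sd = 0.02),
         bias_tab = matrix(0, config$n_heads, config$hop_max + 2L),
         wE = matrix(0, config$hop_max, schema$edge_width),
         layers = layers,
         W_emb = glorot(d, config$d_embed), b_emb = numeric(config$d_embed))
  })
  zin <- config$d_embed * n_shells
  widths <- c(zin, config$head_widths, 1L)
  # small positive biases keep the narrow ReLU head away from the all-dead
  # regime at initialisation
  head <- lapply(seq_len(length(widths) - 1L), function(q)
    list(W = glorot(widths[q], widths[q + 1L]),
         b = rep(if (q < length(widths) - 1L) 0.01 else 0,
                 widths[q + 1L])))
  structure(list(config = config,
                 schema_widths = c(node = schema$node_width,
                                   edge = schema$edge_width),
                 shells = shells, head = head),
            class = "gs_model")
}

#' @export
print.gs_model <- function(x, ...) {
  cf <- x$config
  cat(sprintf(paste0("shell-graph scoring model: %d shells, %d layers x %d heads,",
                     " d_hidden %d, embedding %d (concat %d)\n"),
              cf$layout$n_shells, cf$n_layers, cf$n_heads, cf$d_hidden,
              cf$d_embed, cf$d_embed * cf$layout$n_shells))
  if (!is.null(x$history))
    cat(sprintf("trained %d epochs (best val loss %.4f)\n", nrow(x$history),
                min(x$history$val_loss)))
  invisible(x)
}

softplus <- function(s) pmax(s, 0) + log1p(exp(-abs(s)))
sigmoid <- function(s) 1 / (1 + exp(-s))

# concatenated shell embeddings + head forward; caches for backprop
pose_forward <- function(model, feats, keep_cache = FALSE) {
  if (feats$dissociated)
    return(list(pred = Inf, dissociated = TRUE))
  n_shells <- model$config$layout$n_shells
  if (length(feats$graphs) != n_shells)
    stop2("pose featurized with %d shells but model expects %d",
          length(feats$graphs), n_shells)
  if (is.null(feats$prep))
    feats$prep <- lapply(feats$graphs, prep_graph_tensors)
  enc <- lapply(seq_len(n_shells), function(k)
    shell_forward(model$shells[[k]], feats$graphs[[k]], feats$prep[[k]],
                  keep_cache = keep_cache,
                  readout = model$config$readout %||% "cls"))
  z <- unlist(lapply(enc, `[[`, "e"), use.names = FALSE)
  a <- matrix(z, 1L)
  hcache <- list(a)
  nh <- length(model$head)
  for (q in seq_len(nh)) {
    zq <- a %*% model$head[[q]]$W + rep(model$head[[q]]$b, each = 1L)
    a <- if (q < nh) relu(zq) else zq
    hcache[[q + 1L]] <- a
  }
  s <- drop(a)
  list(pred = softplus(s), s = s, z = z, enc = enc, hcache = hcache,
       prep = feats$prep, dissociated = FALSE)
}

#' Predict the RMSD of one pose
#'
#' Concatenates the per-shell embeddings (`d_embed * n_shells` values, 1280
#' at the defaults), pushes them through the regression head, and maps the
#' scalar through softplus so the prediction is non-negative. A dissociated
#' pose (no protein atom in any shell) short-circuits to `+Inf`: the ligand
#' has left the binding site and no finite RMSD estimate is meaningful.
#'
#' @param complex A [complex_pose()] or a pre-featurized `pose_features`.
#' @param model A [gs_model()] from [init_model()] or [train_model()].
#' @param schema Schema used when featurizing a raw complex.
#' @return Predicted RMSD in Angstrom (or `Inf`).
#' @export
forward_score <- function(complex, model, schema = feature_schema()) {
  feats <- if (inherits(complex, "pose_features")) complex
  else featurize_pose(complex, model$config$layout, schema,
                      model$config$hop_max)
  if (model$schema_widths[["node"]] != ncol(feats$graphs[[1L]]$X))
    stop2("model/featurizer schema mismatch: %d vs %d node dims",
          model$schema_widths[["node"]], ncol(feats$graphs[[1L]]$X))
  pose_forward(model, feats)$pred
}

#' Concatenated embedding vector of a pose
#'
#' @inheritParams forward_score
#' @return Numeric vector of length `d_embed * n_shells` (1280 at the
#'   defaults), or `NULL` for a dissociated pose.
#' @export
pose_embedding <- function(complex, model, schema = feature_schema()) {
  feats <- if (inherits(complex, "pose_features")) complex
  else featurize_pose(complex, model$config$layout, schema,
                      model$config$hop_max)
  fw <- pose_forward(model, feats)
  if (isTRUE(fw$dissociated)) return(NULL)
  fw$z
}

#' Score a list of poses into a ranking table
#'
#' @param poses List of [complex_pose()] or `pose_features`.
#' @param model A trained [gs_model()].
#' @param schema Featurization schema.
#' @return data.frame with columns `complex_id`, `pose_id`, `score`
#'   (predicted RMSD; `Inf` for dissociated poses) and `rmsd` (the true label
#'   where known, else `NA`).
#' @export
predict_poses <- function(poses, model, schema = feature_schema()) {
  rows <- lapply(poses, function(p) {
    feats <- if (inherits(p, "pose_features")) p
    else featurize_pose(p, model$config$layout, schema, model$config$hop_max)
    data.frame(complex_id = feats$complex_id, pose_id = feats$pose_id,
               score = pose_forward(model, feats)$pred,
               rmsd = feats$rmsd_label %||% NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mean squared error loss
#'
#' @param predictions,labels Equal-length numeric vectors (finite; poses
#'   scored `+Inf` are excluded upstream, mirroring how extreme predicted
#'   RMSDs are excluded from error summaries).
#' @return `mean((predictions - labels)^2)`.
#' @examples
#' mse_loss(c(1, 2), c(1, 4))  # 2
#' @export
mse_loss <- function(predictions, labels) {
  if (length(predictions) == 0L) stop2("empty input to mse_loss")
  if (length(predictions) != length(labels)) stop2("length mismatch in mse_loss")
  if (any(!is.finite(predictions)) || any(!is.finite(labels)))
    stop2("mse_loss requires finite values; filter infinity-scored poses first")
  mean((predictions - labels)^2)
}

#' Stepwise-halved learning-rate schedule
#'
#' `initial_lr * 0.5^floor(epoch / step)`: the learning rate is halved every
#' `step` epochs (epochs are counted from 0).
#'
#' @param epoch Epoch index (0-based).
#' @param initial_lr Initial learning rate.
#' @param step Halving period in epochs.
#' @return Learning rate at that epoch.
#' @examples
#' lr_at_epoch(0, 0.001, 25)    # 0.001
#' lr_at_epoch(25, 0.001, 25)   # 5e-04
#' lr_at_epoch(149, 0.001, 25)  # 3.125e-05
#' @export
lr_at_epoch <- function(epoch, initial_lr = 0.001, step = 25L) {
  stopifnot(all(epoch >= 0), step >= 1L)
  initial_lr * 0.5^(epoch %/% step)
}
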