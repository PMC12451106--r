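#' Training configuration
#'
#' Collects every tunable of the training loop. Defaults: batch size
#' `m = 1000`, 200 epochs with early stopping, Adam at `lr = 1e-3`,
#' fusion weight `alpha = 0.5`, focusing coefficient `beta = 2`,
#' confidence fraction `tau = 0.9`, `k = 15` KNN neighbors for both the
#' cell graph and the pseudo-label graph, 2000 highly variable genes,
#' dynamic loss balancing and Leiden pseudo-labels refreshed once per
#' epoch.
#'
#' @param K_target number of clusters to target in pseudo-labeling.
#' @param m batch size (clipped to the number of cells).
#' @param epochs maximum training epochs.
#' @param lr Adam learning rate.
#' @param alpha attribute/structure fusion weight in `[0, 1]`.
#' @param beta hard-sample focusing coefficient (>= 0).
#' @param tau high-confidence fraction in `(0, 1]`.
#' @param k KNN neighbor count for the cell graph.
#' @param p number of highly variable genes (used by [run_schsc()]).
#' @param seed integer seed driving all randomness.
#' @param omega_mode `"dynamic"` or `"fixed"` loss balancing.
#' @param omega_fixed the fixed balance weight when `omega_mode = "fixed"`.
#' @param community `"leiden"` or `"louvain"` for pseudo-labels.
#' @param pseudo_refresh `"epoch"` (labels computed once per cell per
#'   epoch) or `"iteration"` (recomputed every batch).
#' @param graph_k neighbor count for the pseudo-label embedding graph.
#' @param embed_dim,hidden_attr,hidden_struct encoder architecture,
#'   see [encoder_config()].
#' @param sampling `"partition"` (shuffle then chunk, every epoch covers
#'   every cell exactly once) or `"independent"` (fresh draw without
#'   replacement each iteration).
#' @param use_weighting apply hard-sample weighting (`FALSE` gives the
#'   uniform-weight ablation, W identically 1).
#' @param hs_weight multiplier on the contrastive term (0 disables it,
#'   leaving a pure ZINB autoencoder).
#' @param early_stop_window,early_stop_tol stop when the relative change
#'   of the total loss over the window falls below the tolerance.
#' @return An object of class `schsc_train_config`.
#' @export
train_config <- function(K_target, m = 1000, epochs = 200, lr = 1e-3,
                         alpha = 0.5, beta = 2, tau = 0.9, k = 15,
                         p = 2000, seed = 0,
                         omega_mode = c("dynamic", "fixed"),
                         omega_fixed = NULL,
                         community = c("leiden", "louvain"),
                         pseudo_refresh = c("epoch", "iteration"),
                         graph_k = 15, embed_dim = 32,
                         hidden_attr = c(512, 256), hidden_struct = 256,
                         sampling = c("partition", "independent"),
                         use_weighting = TRUE, hs_weight = 1,
                         early_stop_window = 10, early_stop_tol = 1e-4) {
  stopifnot(K_target >= 1, m >= 1, epochs >= 0, lr > 0,
            alpha >= 0, alpha <= 1, beta >= 0, tau > 0, tau <= 1,
            k >= 1, hs_weight >= 0)
  structure(list(K_target = as.integer(K_target), m = as.integer(m),
                 epochs = as.integer(epochs), lr = lr, alpha = alpha,
                 beta = beta, tau = tau, k = as.integer(k),
                 p = as.integer(p), seed = as.integer(seed),
                 omega_mode = match.arg(omega_mode),
                 omega_fixed = omega_fixed,
                 community = match.arg(community),
                 pseudo_refresh = match.arg(pseudo_refresh),
                 graph_k = as.integer(graph_k),
                 embed_dim = as.integer(embed_dim),
                 hidden_attr = as.integer(hidden_attr),
                 hidden_struct = as.integer(hidden_struct),
                 sampling = match.arg(sampling),
                 use_weighting = isTRUE(use_weighting),
                 hs_weight = hs_weight,
                 early_stop_window = as.integer(early_stop_window),
                 early_stop_tol = early_stop_tol),
            class = "schsc_train_config")
}

#' Partition cells into one epoch of batches
#'
#' Shuffles the cell indices with the current RNG state and chunks them
#' into `ceiling(N / m)` batches of size `m` (the last possibly
#' smaller), so successive batches within an epoch sample without
#' replacement and jointly cover every cell exactly once. `m > N` is
#' clipped to `N`.
#'
#' @param N number of cells.
#' @param m batch size.
#' @return list of integer index vectors.
#' @export
sample_epoch_batches <- function(N, m) {
  stopifnot(N >= 1, m >= 1)
  m <- min(m, N)
  perm <- sample.int(N)
  unname(split(perm, ceiling(seq_along(perm) / m)))
}

# Loss + parameter gradients for one batch, given precomputed views and
# a weight matrix. Pseudo-labels, H, Q and the Norm statistics inside W
# are constants (no gradient flows through them). Returns the detached
# loss components and a gradient structure parallel to `weights`.
schsc_loss_grads <- function(weights, views, S, W, x_raw, lib,
                             alpha, omega, hs_weight = 1) {
  m <- nrow(views$Z_v1)
  ls <- hard_sample_loss_grad(S, W, m)
  params <- zinb_decode(views$Z_fused, weights, lib, keep_cache = TRUE)
  nll <- zinb_nll(x_raw, params)

  # contrastive gradient into the stacked normalized embeddings
  Gs <- hs_weight * ls$grad_S
  Gsym <- Gs + t(Gs)
  Zc <- rbind(views$Z_v1, views$Z_v2)
  Ec <- rbind(views$E_v1, views$E_v2)
  GZc <- alpha * (Gsym %*% Zc)
  GEc <- (1 - alpha) * (Gsym %*% Ec)

  # ZINB gradient into the fused embedding and decoder heads
  zg <- zinb_nll_grad(x_raw, params$Pi, params$Mu, params$Theta)
  h_pi <- params$cache$h_pi; h_mu <- params$cache$h_mu
  h_th <- params$cache$h_th
  sig <- sigmoid(h_pi)
  G_hpi <- omega * zg$d_pi * sig * (1 - sig) *
    (sig > 1e-6 & sig < 1 - 1e-6)
  mu_un <- params$size_factors * exp(h_mu)
  G_hmu <- omega * zg$d_mu * mu_un * (mu_un > 1e-6 & mu_un < 1e6)
  th_un <- exp(h_th)
  G_hth <- omega * zg$d_th * th_un * (th_un > 1e-6 & th_un < 1e6)

  Zf <- views$Z_fused
  g_pi <- list(W = crossprod(Zf, G_hpi), b = colSums(G_hpi))
  g_mu <- list(W = crossprod(Zf, G_hmu), b = colSums(G_hmu))
  g_th <- list(W = crossprod(Zf, G_hth), b = colSums(G_hth))
  G_Zf <- G_hpi %*% t(weights$pi$W) + G_hmu %*% t(weights$mu$W) +
    G_hth %*% t(weights$th$W)

  GZ1n <- GZc[seq_len(m), , drop = FALSE] + 0.5 * G_Zf
  GZ2n <- GZc[(m + 1L):(2L * m), , drop = FALSE] + 0.5 * G_Zf
  GE1n <- GEc[seq_len(m), , drop = FALSE]
  GE2n <- GEc[(m + 1L):(2L * m), , drop = FALSE]

  nm <- views$cache$norms
  bz1 <- mlp_backward(weights$z1, views$cache$fz1,
                      l2_normalize_backward(views$Z_v1, nm$z1, GZ1n))
  bz2 <- mlp_backward(weights$z2, views$cache$fz2,
                      l2_normalize_backward(views$Z_v2, nm$z2, GZ2n))
  be1 <- mlp_backward(weights$e1, views$cache$fe1,
                      l2_normalize_backward(views$E_v1, nm$e1, GE1n))
  be2 <- mlp_backward(weights$e2, views$cache$fe2,
                      l2_normalize_backward(views$E_v2, nm$e2, GE2n))

  list(L_hs = ls$loss, L_zinb = nll,
       grads = list(z1 = bz1$grads, z2 = bz2$grads,
                    e1 = be1$grads, e2 = be2$grads,
                    pi = g_pi, mu = g_mu, th = g_th))
}

# Pseudo-label a batch, honoring the per-epoch label cache.
batch_pseudo <- function(Zf, idx, cfg, label_cache) {
  cached <- label_cache[idx]
  if (cfg$pseudo_refresh == "epoch" && !anyNA(cached)) {
    labels <- match(cached, sort(unique(cached)))
    centers <- rowsum(Zf, labels) / as.vector(table(labels))
    diffs <- Zf - centers[labels, , drop = FALSE]
    pl <- list(labels = labels, K = max(labels),
               dist_to_center = sqrt(rowSums(diffs^2)))
  } else {
    pl <- pseudo_labels(Zf, K_target = min(cfg$K_target, nrow(Zf) - 1L),
                        graph_k = cfg$graph_k, method = cfg$community,
                        seed = cfg$seed)
    label_cache[idx] <- pl$labels
  }
  list(pl = pl, label_cache = label_cache)
}

#' Train the hard-sample contrastive model
#'
#' Runs the full training loop on a preprocessed bundle: builds the KNN
#' cell graph and Laplacian-filters the expression matrix once, then per
#' iteration samples a batch, encodes the four views, computes the fused
#' similarity, pseudo-labels the batch (per the refresh policy), forms
#' the hard-sample weight matrix and contrastive loss, decodes ZINB
#' parameters and their likelihood on the raw counts, and takes one Adam
#' step on the combined objective. The balance weight `omega` is
#' initialized to the first batch's loss ratio and smoothed once per
#' epoch in dynamic mode.
#'
#' @param bundle a [preprocess_counts()] result.
#' @param cfg a [train_config()].
#' @return An object of class `schsc_fit`: list with `weights`,
#'   `encoder_config`, `config`, `history` (one row per epoch: `L_hs`,
#'   `L_zinb`, `omega`, `total`, `seconds`), `graph`, `X_filtered`,
#'   `library_size`, `cell_ids`, `epochs_run`.
#' @export
train_schsc <- function(bundle, cfg) {
  stopifnot(inherits(bundle, "schsc_bundle"),
            inherits(cfg, "schsc_train_config"))
  X <- bundle$values
  N <- nrow(X); p_act <- ncol(X)
  set.seed(cfg$seed)

  g <- knn_graph(X, min(cfg$k, N - 1L))
  Xf <- laplacian_filter(g, X)
  A_dense <- as.matrix(g$adjacency_sym)

  enc_cfg <- encoder_config(p_act, N, hidden_attr = cfg$hidden_attr,
                            hidden_struct = cfg$hidden_struct,
                            embed_dim = cfg$embed_dim, seed = cfg$seed)
  weights <- init_weights(enc_cfg)
  opt <- adam_init(weights)
  ostate <- omega_state(cfg$omega_mode, value = cfg$omega_fixed)

  m_eff <- min(cfg$m, N)
  hist <- vector("list", cfg$epochs)
  label_cache <- rep(NA_integer_, N)
  totals <- numeric(0)
  epochs_run <- 0L

  for (epoch in seq_len(cfg$epochs)) {
    t0 <- proc.time()[["elapsed"]]
    batches <- if (cfg$sampling == "partition") {
      sample_epoch_batches(N, m_eff)
    } else {
      replicate(ceiling(N / m_eff), sample.int(N, m_eff), simplify = FALSE)
    }
    label_cache[] <- NA_integer_
    e_hs <- 0; e_zinb <- 0; nb <- 0L

    for (it in seq_along(batches)) {
      idx <- batches[[it]]
      m <- length(idx)
      views <- encode_views(Xf[idx, , drop = FALSE],
                            A_dense[idx, , drop = FALSE],
                            weights, keep_cache = TRUE)
      S <- fused_similarity(views, cfg$alpha)
      bp <- batch_pseudo(views$Z_fused, idx, cfg, label_cache)
      label_cache <- bp$label_cache
      W <- if (cfg$use_weighting) {
        H <- high_confidence_set(bp$pl, cfg$tau)
        Q <- indicator_matrix(bp$pl$labels)
        weight_matrix(S, Q, H, cfg$beta)
      } else {
        matrix(1, 2L * m, 2L * m)
      }

      if (is.null(ostate$omega)) {
        # initialize the balance weight from the first batch's detached ratio
        L_hs0 <- hard_sample_loss(S, W, m)
        prm0 <- zinb_decode(views$Z_fused, weights,
                            bundle$library_size[idx])
        L_z0 <- zinb_nll(bundle$raw[idx, , drop = FALSE], prm0)
        ostate$omega <- L_hs0 / max(L_z0, ostate$eps)
      }

      res <- schsc_loss_grads(weights, views, S, W,
                              bundle$raw[idx, , drop = FALSE],
                              bundle$library_size[idx],
                              alpha = cfg$alpha, omega = ostate$omega,
                              hs_weight = cfg$hs_weight)
      if (!is.finite(res$L_hs) || !is.finite(res$L_zinb))
        stop(sprintf("non-finite loss at epoch %d, iteration %d (L_hs = %g, L_zinb = %g)",
                     epoch, it, res$L_hs, res$L_zinb))
      step <- adam_step(weights, res$grads, opt, lr = cfg$lr)
      weights <- step$params
      opt <- step$state
      e_hs <- e_hs + res$L_hs
      e_zinb <- e_zinb + res$L_zinb
      nb <- nb + 1L
    }

    e_hs <- e_hs / nb; e_zinb <- e_zinb / nb
    comb <- combine_losses(e_hs, e_zinb, ostate)  # per-epoch omega update
    ostate <- comb$state
    total <- e_hs + comb$breakdown$omega * e_zinb
    totals <- c(totals, total)
    hist[[epoch]] <- data.frame(epoch = epoch, L_hs = e_hs,
                                L_zinb = e_zinb,
                                omega = comb$breakdown$omega,
                                total = total,
                                seconds = proc.time()[["elapsed"]] - t0)
    epochs_run <- epoch
    w <- cfg$early_stop_window
    if (epoch > w) {
      ref <- totals[epoch - w]
      if (abs(total - ref) / max(abs(ref), 1e-12) < cfg$early_stop_tol) break
    }
  }

  structure(list(weights = weights, encoder_config = enc_cfg,
                 config = cfg,
                 history = if (epochs_run > 0)
                   do.call(rbind, hist[seq_len(epochs_run)])
                 else
                   data.frame(epoch = integer(), L_hs = numeric(),
                              L_zinb = numeric(), omega = numeric(),
                              total = numeric(), seconds = numeric()),
                 graph = g, X_filtered = Xf,
                 library_size = bundle$library_size,
                 cell_ids = bundle$cell_ids,
                 labels = bundle$labels,
                 epochs_run = epochs_run),
            class = "schsc_fit")
}

#' @export
print.schsc_fit <- function(x, ...) {
  cat(sprintf("schsc_fit: %d cells, %d features, %d epochs run\n",
              nrow(x$X_filtered), ncol(x$X_filtered), x$epochs_run))
  if (x$epochs_run > 0) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final losses: L_hs = %.4f, L_zinb = %.1f, omega = %.3g, total = %.4f\n",
                last$L_hs, last$L_zinb, last$omega, last$total))
  }
  invisible(x)
}

#' Preprocess, train and cluster in one call
#'
#' Convenience wrapper chaining [preprocess_counts()], [train_schsc()],
#' [embed_all()] and [final_clustering()].
#'
#' @param cm a [count_matrix()].
#' @param cfg a [train_config()].
#' @return list with `bundle`, `fit`, `embeddings`, `clustering`.
#' @export
run_schsc <- function(cm, cfg) {
  bundle <- preprocess_counts(cm, p = cfg$p)
  fit <- train_schsc(bundle, cfg)
  emb <- embed_all(fit)
  cl <- final_clustering(emb, k = cfg$k, K_target = cfg$K_target,
                         seed = cfg$seed)
  list(bundle = bundle, fit = fit, embeddings = emb, clustering = cl)
}
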