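# Minimal dense-network machinery shared by the VAE and the CNN: parameter
# lists of matrices/vectors trained with Adam.

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

relu <- function(x) pmax(x, 0)

glorot <- function(nin, nout) {
  matrix(rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
}

# row-broadcast addition of a bias vector
addb <- function(M, b) sweep(M, 2, b, `+`)

# ---- Variational autoencoder --------------------------------------------

#' Fit a variational autoencoder to one class's feature vectors
#'
#' A small fully connected VAE: two hidden layers in the encoder (mirrored
#' in the decoder) and a two-dimensional Gaussian latent space, trained
#' with mean-squared reconstruction loss plus the Kullback-Leibler
#' divergence of the approximate posterior from the standard-normal prior.
#' Inputs are normalized internally (per-dimension mean, pooled scale);
#' [vae_sample()] undoes the normalization and re-adjusts samples to the
#' class mean and scale.
#'
#' Implemented from scratch in base matrix operations with hand-written
#' backpropagation and Adam, sized for the few-hundred-sample,
#' few-hundred-dimension regime this package targets.
#'
#' @param vectors Matrix (samples x dims) of one class's feature vectors
#'   (>= 20 rows recommended).
#' @param latent_dim Latent dimensionality (default 2).
#' @param hidden Encoder hidden widths (decoder mirrors them).
#' @param epochs Training epochs (full-batch).
#' @param lr Adam learning rate.
#' @param seed RNG seed for initialization and reparameterization noise.
#' @param kl_weight Weight of the KL term.
#' @return An `"fi_vae"` generator for [vae_sample()].
#' @export
vae_fit <- function(vectors, latent_dim = 2, hidden = c(256, 64),
                    epochs = 200, lr = 1e-3, seed = 1, kl_weight = 1) {
  X0 <- as.matrix(vectors)
  n <- nrow(X0); d <- ncol(X0)
  mu_x <- colMeans(X0)
  centred <- sweep(X0, 2, mu_x)
  scale_x <- sd(as.numeric(centred))
  X <- if (scale_x > 0) centred / scale_x else centred
  h1 <- hidden[1]; h2 <- hidden[2]; L <- latent_dim
  with_seed(seed, {
    params <- list(
      We1 = glorot(d, h1), be1 = numeric(h1),
      We2 = glorot(h1, h2), be2 = numeric(h2),
      Wmu = glorot(h2, L), bmu = numeric(L),
      Wlv = glorot(h2, L) * 0.01, blv = numeric(L),
      Wd1 = glorot(L, h2), bd1 = numeric(h2),
      Wd2 = glorot(h2, h1), bd2 = numeric(h1),
      Wo = glorot(h1, d), bo = numeric(d)
    )
    st <- adam_init(params)
    loss <- NA_real_
    for (ep in seq_len(epochs)) {
      p <- params
      H1p <- addb(X %*% p$We1, p$be1); H1 <- relu(H1p)
      H2p <- addb(H1 %*% p$We2, p$be2); H2 <- relu(H2p)
      MU <- addb(H2 %*% p$Wmu, p$bmu)
      LV <- addb(H2 %*% p$Wlv, p$blv)
      LV <- pmin(pmax(LV, -10), 10)
      EPS <- matrix(rnorm(n * L), n, L)
      Z <- MU + exp(LV / 2) * EPS
      D1p <- addb(Z %*% p$Wd1, p$bd1); D1 <- relu(D1p)
      D2p <- addb(D1 %*% p$Wd2, p$bd2); D2 <- relu(D2p)
      XH <- addb(D2 %*% p$Wo, p$bo)
      recon <- sum((X - XH)^2) / n
      kl <- -0.5 * sum(1 + LV - MU^2 - exp(LV)) / n
      loss <- recon + kl_weight * kl
      if (!is.finite(loss)) {
        abort(paste0("VAE training diverged at epoch ", ep,
                     " (loss non-finite)"))
      }
      # backward
      dXH <- 2 * (XH - X) / n
      g <- list()
      g$Wo <- crossprod(D2, dXH); g$bo <- colSums(dXH)
      dD2 <- (dXH %*% t(p$Wo)) * (D2p > 0)
      g$Wd2 <- crossprod(D1, dD2); g$bd2 <- colSums(dD2)
      dD1 <- (dD2 %*% t(p$Wd2)) * (D1p > 0)
      g$Wd1 <- crossprod(Z, dD1); g$bd1 <- colSums(dD1)
      dZ <- dD1 %*% t(p$Wd1)
      dMU <- dZ + kl_weight * MU / n
      dLV <- dZ * EPS * exp(LV / 2) / 2 + kl_weight * 0.5 * (exp(LV) - 1) / n
      g$Wmu <- crossprod(H2, dMU); g$bmu <- colSums(dMU)
      g$Wlv <- crossprod(H2, dLV); g$blv <- colSums(dLV)
      dH2 <- (dMU %*% t(p$Wmu) + dLV %*% t(p$Wlv)) * (H2p > 0)
      g$We2 <- crossprod(H1, dH2); g$be2 <- colSums(dH2)
      dH1 <- (dH2 %*% t(p$We2)) * (H1p > 0)
      g$We1 <- crossprod(X, dH1); g$be1 <- colSums(dH1)
      upd <- adam_step(params, g, st, lr = lr)
      params <- upd$params; st <- upd$state
    }
    structure(list(params = params, latent_dim = L, mu_x = mu_x,
                   scale_x = scale_x, d = d, final_loss = loss,
                   class_mean = colMeans(X0),
                   class_scale = sd(as.numeric(sweep(X0, 2, colMeans(X0))))),
              class = "fi_vae")
  })
}

vae_decode <- function(model, Z) {
  p <- model$params
  D1 <- relu(addb(Z %*% p$Wd1, p$bd1))
  D2 <- relu(addb(D1 %*% p$Wd2, p$bd2))
  addb(D2 %*% p$Wo, p$bo)
}

#' Draw synthetic feature vectors from a fitted VAE
#'
#' Samples latent points from the standard-normal prior, decodes them, and
#' mean-adjusts and re-scales the batch to the training class's mean and
#' pooled scale (so sample moments match the class by construction).
#'
#' @param model An `"fi_vae"` from [vae_fit()].
#' @param n Number of samples.
#' @param seed RNG seed.
#' @return Matrix (`n` x dims) of synthetic vectors.
#' @export
vae_sample <- function(model, n, seed = 1) {
  stopifnot(inherits(model, "fi_vae"))
  with_seed(seed, {
    Z <- matrix(rnorm(n * model$latent_dim), n, model$latent_dim)
    XH <- vae_decode(model, Z)
    XH <- if (model$scale_x > 0) XH * model$scale_x else XH
    XH <- sweep(XH, 2, -model$mu_x)  # undo normalization
    # re-adjust batch moments to the class
    gen_mean <- colMeans(XH)
    centred <- sweep(XH, 2, gen_mean)
    gen_scale <- sd(as.numeric(centred))
    ratio <- if (gen_scale > 1e-12) model$class_scale / gen_scale else 0
    sweep(centred * ratio, 2, -model$class_mean)
  })
}

# ---- Convolutional network ----------------------------------------------

# Flatten the (33n x f1) stacked layer-1 activations to an n x (33*f1)
# matrix with a fixed (row-within-sample, filter) layout.
stack_to_flat <- function(Z, n, nr) {
  f1 <- ncol(Z)
  matrix(aperm(array(Z, c(nr, n, f1)), c(2, 1, 3)), n, nr * f1)
}

flat_to_stack <- function(F, n, nr) {
  f1 <- ncol(F) / nr
  matrix(aperm(array(F, c(n, nr, f1)), c(2, 1, 3)), n * nr, f1)
}

cnn_init <- function(nr, arch) {
  list(W1 = glorot(nr, arch$f1), b1 = numeric(arch$f1),
       W2 = glorot(nr * arch$f1, arch$f2), b2 = numeric(arch$f2),
       W3 = glorot(arch$f2, arch$dense), b3 = numeric(arch$dense),
       W4 = glorot(arch$dense, 2), b4 = numeric(2))
}

cnn_forward <- function(params, Xstack, n, nr, dropout = 0, train = FALSE) {
  Z1p <- addb(Xstack %*% params$W1, params$b1)  # row convolution (1 x N)
  Z1 <- relu(Z1p)
  F1 <- stack_to_flat(Z1, n, nr)
  H2p <- addb(F1 %*% params$W2, params$b2)      # column convolution (N x 1)
  H2 <- relu(H2p)
  H3p <- addb(H2 %*% params$W3, params$b3)
  H3 <- relu(H3p)
  mask <- NULL
  if (train && dropout > 0) {
    mask <- matrix(stats::rbinom(length(H3), 1, 1 - dropout) / (1 - dropout),
                   nrow(H3), ncol(H3))
    H3 <- H3 * mask
  }
  S <- addb(H3 %*% params$W4, params$b4)
  S <- S - apply(S, 1, max)
  P <- exp(S) / rowSums(exp(S))
  list(Z1p = Z1p, Z1 = Z1, F1 = F1, H2p = H2p, H2 = H2, H3p = H3p, H3 = H3,
       mask = mask, P = P)
}

#' Train and evaluate a compact convolutional classifier on feature matrices
#'
#' A connectome-style CNN for N x N interaction matrices: a 1 x N "row"
#' convolution stage (each filter spans a full matrix row; 64 filters),
#' an N x 1 "column" stage collapsing the row axis (128 filters), then
#' dense(96) and a 2-way softmax, with dropout on the dense layer. Trained
#' by full-batch Adam on the softmax cross-entropy with early stopping on a
#' held-out validation slice of the training fold. Evaluation uses
#' subject-level Monte Carlo cross-validation; when `augment = TRUE` a VAE
#' is fitted per class on the training fold only and its synthetic samples
#' (matricized to the feature kind's symmetry) are added to the training
#' data -- the test fold is never touched, and the function errors if asked
#' to augment from vectors outside the training fold.
#'
#' @param mats Named list of N x N feature matrices (names = subject ids),
#'   one per subject.
#' @param labels Named vector subject id -> class.
#' @param augment Add VAE-synthesized training samples (doubling each
#'   class's effective training count)?
#' @param kind Matrix symmetry for matricizing augmented vectors:
#'   `"skew"` or `"symmetric"`.
#' @param diag Diagonal value used when matricizing.
#' @param arch Architecture: `f1`, `f2`, `dense`, `dropout`.
#' @param epochs Maximum training epochs per repetition.
#' @param patience Early-stopping patience on validation loss.
#' @param lr Adam learning rate.
#' @param n_reps,train_frac,seed Split parameters ([mc_splits()]).
#' @param vae_epochs Epochs for the per-class augmentation VAEs.
#' @param positive_class Positive label for sensitivity.
#' @return An `"fi_classification"` object.
#' @export
cnn_fit_eval <- function(mats, labels, augment = FALSE,
                         kind = c("symmetric", "skew"), diag = 0,
                         arch = list(f1 = 64, f2 = 128, dense = 96,
                                     dropout = 0.5),
                         epochs = 60, patience = 10, lr = 1e-3,
                         n_reps = 10, train_frac = 0.7, seed = 1,
                         vae_epochs = 100, positive_class = "patient") {
  kind <- match.arg(kind)
  stopifnot(is.list(mats), !is.null(names(mats)))
  nr <- nrow(mats[[1]])
  labels <- labels[names(mats)]
  classes <- sort(unique(labels))
  if (length(classes) != 2) abort("CNN evaluation needs exactly 2 classes")
  splits <- mc_splits(labels, n_reps, train_frac, seed, stratified = TRUE)
  seeds <- with_seed(seed, fan_seeds(seed, n_reps))
  per_rep <- purrr::map_dfr(seq_len(n_reps), function(r) {
    sp <- splits[[r]]
    preds <- with_seed(seeds[r], {
      tr_ids <- sp$train; te_ids <- sp$test
      tr_mats <- mats[tr_ids]; tr_lab <- labels[tr_ids]
      if (augment) {
        for (cl in classes) {
          ids_cl <- tr_ids[tr_lab == cl]
          if (!all(ids_cl %in% sp$train)) {
            abort("augmentation source leaked outside the training fold")
          }
          vecs <- do.call(rbind, lapply(mats[ids_cl], vectorize_upper))
          vae <- vae_fit(vecs, epochs = vae_epochs,
                         seed = sample.int(2^30, 1))
          syn <- vae_sample(vae, nrow(vecs), seed = sample.int(2^30, 1))
          syn_mats <- lapply(seq_len(nrow(syn)), function(i) {
            matricize_upper(syn[i, ], kind = kind, diag = diag)
          })
          names(syn_mats) <- paste0("aug_", cl, "_", seq_along(syn_mats))
          tr_mats <- c(tr_mats, syn_mats)
          tr_lab <- c(tr_lab, setNames(rep(cl, length(syn_mats)),
                                       names(syn_mats)))
        }
      }
      cnn_train_predict(tr_mats, tr_lab, mats[te_ids], classes, nr, arch,
                        epochs, patience, lr)
    })
    dplyr::mutate(evaluate_predictions(preds, labels[sp$test],
                                       positive_class), rep = r)
  })
  summ <- dplyr::summarise(per_rep, dplyr::across(
    c("sensitivity", "specificity", "accuracy", "balanced_accuracy"),
    list(mean = ~mean(.x, na.rm = TRUE), sd = ~sd(.x, na.rm = TRUE))))
  structure(list(per_rep = per_rep, summary = summ,
                 classifier = if (augment) "cnn_augmented" else "cnn",
                 n_reps = n_reps, positive_class = positive_class),
            class = "fi_classification")
}

cnn_train_predict <- function(tr_mats, tr_lab, te_mats, classes, nr, arch,
                              epochs, patience, lr) {
  n_all <- length(tr_mats)
  # held-out validation slice for early stopping (stratified tail)
  val_n <- max(2, round(0.15 * n_all))
  val_idx <- unlist(lapply(classes, function(cl) {
    idx <- which(tr_lab == cl)
    tail(idx, max(1, round(val_n * length(idx) / n_all)))
  }))
  fit_idx <- setdiff(seq_len(n_all), val_idx)
  to_stack <- function(ms) do.call(rbind, ms)
  Xfit <- to_stack(tr_mats[fit_idx]); yfit <- tr_lab[fit_idx]
  Xval <- to_stack(tr_mats[val_idx]); yval <- tr_lab[val_idx]
  Y <- function(y) cbind(y == classes[1], y == classes[2]) * 1
  params <- cnn_init(nr, arch)
  st <- adam_init(params)
  nf <- length(fit_idx); nv <- length(val_idx)
  best <- list(loss = Inf, params = params); wait <- 0
  for (ep in seq_len(epochs)) {
    fw <- cnn_forward(params, Xfit, nf, nr, arch$dropout, train = TRUE)
    Yf <- Y(yfit)
    dS <- (fw$P - Yf) / nf
    g <- list()
    g$W4 <- crossprod(fw$H3, dS); g$b4 <- colSums(dS)
    dH3 <- dS %*% t(params$W4)
    if (!is.null(fw$mask)) dH3 <- dH3 * fw$mask
    dH3 <- dH3 * (fw$H3p > 0)
    g$W3 <- crossprod(fw$H2, dH3); g$b3 <- colSums(dH3)
    dH2 <- (dH3 %*% t(params$W3)) * (fw$H2p > 0)
    g$W2 <- crossprod(fw$F1, dH2); g$b2 <- colSums(dH2)
    dF1 <- dH2 %*% t(params$W2)
    dZ1 <- flat_to_stack(dF1, nf, nr) * (fw$Z1p > 0)
    g$W1 <- crossprod(Xfit, dZ1); g$b1 <- colSums(dZ1)
    upd <- adam_step(params, g, st, lr = lr)
    params <- upd$params; st <- upd$state
    vw <- cnn_forward(params, Xval, nv, nr, 0, train = FALSE)
    vloss <- -mean(log(pmax(rowSums(vw$P * Y(yval)), 1e-12)))
    if (!is.finite(vloss)) abort("CNN training diverged (loss non-finite)")
    if (vloss < best$loss - 1e-6) {
      best <- list(loss = vloss, params = params); wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= patience) break
    }
  }
  Xte <- to_stack(te_mats); nte <- length(te_mats)
  pw <- cnn_forward(best$params, Xte, nte, nr, 0, train = FALSE)
  classes[max.col(pw$P)]
}
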