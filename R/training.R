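#' Training configuration
#'
#' Defaults follow the method's standard training recipe: 100 epochs, batch size
#' 128, Adam with learning rate 0.001, adversarial trade-off
#' `lambda_adv = 0.1`, and an optional center loss with its own SGD at
#' learning rate 0.05 (off by default, so the default objective is exactly
#' the cross-entropy-minus-lambda-times-discriminator objective).
#'
#' @param epochs training epochs (>= 1).
#' @param batch_size mini-batch size.
#' @param lr Adam learning rate for all networks.
#' @param lambda_adv nonnegative adversarial weight; 0 disables adversarial
#'   training (the non-adversarial ablation).
#' @param center_loss list with `enabled`, `weight`, `lr` (SGD learning rate
#'   for the class centers).
#' @param disc_steps discriminator updates per mini-batch: the first is the
#'   shared gradient-reversal backward pass, the rest refine the
#'   discriminators on the same (frozen) features so the reversed gradient
#'   tracks a near-optimal discriminator.
#' @param validation_fraction fraction of training segments held out (
#'   stratified by class and episode) to estimate branch error rates.
#' @param fusion `"decision"` (default), `"data"` or `"feature"`.
#' @param weights `"dynamic"` (error-rate weights, default), `"fixed"`
#'   (0.5/0.5) or `"learned"` (softmax-parameterized, trained jointly).
#' @param seed integer seed controlling initialization, batching and dropout.
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 128L, lr = 0.001,
                         lambda_adv = 0.1,
                         center_loss = list(enabled = FALSE, weight = 0.01,
                                            lr = 0.05),
                         disc_steps = 5L,
                         validation_fraction = 0.2,
                         fusion = c("decision", "data", "feature"),
                         weights = c("dynamic", "fixed", "learned"),
                         seed = 1L) {
  cfg <- list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              lr = lr, lambda_adv = lambda_adv,
              center_loss = utils::modifyList(
                list(enabled = FALSE, weight = 0.01, lr = 0.05), center_loss),
              disc_steps = as.integer(disc_steps),
              validation_fraction = validation_fraction,
              fusion = match.arg(fusion), weights = match.arg(weights),
              seed = as.integer(seed))
  bad <- function(field, msg) {
    stop(sprintf("TrainConfig.%s %s", field, msg), call. = FALSE)
  }
  if (is.na(cfg$epochs) || cfg$epochs < 1L) bad("epochs", "must be >= 1")
  if (is.na(cfg$batch_size) || cfg$batch_size < 1L) bad("batch_size", "must be >= 1")
  if (!is.numeric(cfg$lr) || cfg$lr <= 0) bad("lr", "must be > 0")
  if (!is.numeric(cfg$lambda_adv) || cfg$lambda_adv < 0) {
    bad("lambda_adv", "must be >= 0")
  }
  if (cfg$validation_fraction <= 0 || cfg$validation_fraction >= 1) {
    bad("validation_fraction", "must lie in (0, 1)")
  }
  if (is.na(cfg$disc_steps) || cfg$disc_steps < 1L) {
    bad("disc_steps", "must be >= 1")
  }
  class(cfg) <- "train_config"
  cfg
}

slice3 <- function(a, idx) a[idx, , , drop = FALSE]

# drop layer groups (lists of layer environments) that are identical (by
# reference) to one of `drop`
setdiff_groups <- function(groups, drop) {
  keep <- vapply(groups, function(g) {
    !any(vapply(drop, function(d) identical(d, g), logical(1)))
  }, logical(1))
  groups[keep]
}

# Stratified validation indices: ~frac of each (class x episode) cell.
split_validation <- function(y, d, frac) {
  val <- integer(0)
  for (cell in split(seq_along(y), interaction(y, d, drop = TRUE))) {
    k <- max(1L, round(frac * length(cell)))
    val <- c(val, sample(cell, k))
  }
  sort(val)
}

branch_error <- function(prob, y) mean((max.col(prob, "first") - 1L) != y)

# forward a layer stack in eval mode over batches (bounded memory)
eval_forward <- function(layers, x, batch = 512L) {
  n <- dim(x)[1L]
  out <- NULL
  for (s in seq(1L, n, by = batch)) {
    e <- min(n, s + batch - 1L)
    r <- net_forward(layers, x[s:e, , , drop = FALSE], train = FALSE)
    if (is.null(out)) out <- matrix(0, n, ncol(r))
    out[s:e, ] <- r
  }
  out
}

#' Train one leave-one-episode-out fold
#'
#' Jointly optimizes the modality branches, their classifier heads and the
#' per-episode discriminators (attached through gradient reversal) on every
#' episode except `test_episode`. Fusion weights are recomputed from the
#' validation error rates of the two branches after each epoch; the weights
#' finally used are those of the epoch with the lowest validation fused
#' error. Episode labels seen by the discriminators are the training
#' episodes of the fold, relabeled `0..K-1`; the held-out episode has no
#' discriminator class.
#'
#' @param dataset an `szfuse_dataset` from [preprocess_patient()].
#' @param test_episode episode id held out from training.
#' @param cfg a [train_config()].
#' @param bcfg a [branch_config()]; `n_episode_classes` is overridden per
#'   fold.
#' @return Object of class `szfuse_fit`.
#' @export
train_fold <- function(dataset, test_episode, cfg = train_config(),
                       bcfg = branch_config()) {
  d <- dataset$d; y <- dataset$y
  train_eps <- sort(setdiff(unique(d), test_episode))
  if (length(train_eps) < 2L) {
    stop("train_fold: need at least 2 training episodes")
  }
  tr_idx <- which(d %in% train_eps)
  if (length(unique(y[tr_idx])) < 2L) {
    stop("train_fold: degenerate labels (training fold contains one class)")
  }
  K <- length(train_eps)
  dmap <- match(d, train_eps) - 1L          # NA for the held-out episode

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)

  val_idx <- tr_idx[split_validation(y[tr_idx], d[tr_idx],
                                     cfg$validation_fraction)]
  fit_idx <- setdiff(tr_idx, val_idx)

  C <- dim(dataset$eeg)[2L]; Ts <- dim(dataset$eeg)[3L]
  Sc <- dim(dataset$scal)[2L]; St <- dim(dataset$scal)[3L]
  bcfg$n_episode_classes <- K
  mode <- cfg$fusion

  if (mode == "data") {
    xdat <- array(0, c(dim(dataset$eeg)[1L], C + 1L, Ts))
    xdat[, seq_len(C), ] <- dataset$eeg
    xdat[, C + 1L, ] <- dataset$ecg
    br1 <- build_eeg_branch(bcfg, C + 1L, Ts)
    br2 <- NULL
    disc1 <- build_discriminator(bcfg); disc2 <- NULL
    fhead <- NULL
    groups <- list(br1$extractor, br1$head, disc1)
  } else {
    br1 <- build_eeg_branch(bcfg, C, Ts)
    br2 <- build_ecg_branch(bcfg, Sc, St)
    disc1 <- build_discriminator(bcfg)
    disc2 <- build_discriminator(bcfg)
    fhead <- if (mode == "feature") {
      fb <- bcfg; fb$feature_dim <- 2L * bcfg$feature_dim
      build_head(2L * bcfg$feature_dim, bcfg$fc_sizes[1L], bcfg$n_classes,
                 bcfg$dropout)
    } else NULL
    groups <- c(list(br1$extractor, br1$head, br2$extractor, br2$head,
                     disc1, disc2),
                if (!is.null(fhead)) list(fhead))
  }
  grl1 <- layer_grl(1); grl2 <- layer_grl(1)
  disc_groups <- if (mode == "data") list(disc1) else list(disc1, disc2)
  main_groups <- setdiff_groups(groups, disc_groups)
  opt <- optim_adam(main_groups, lr = cfg$lr)
  opt_d <- optim_adam(disc_groups, lr = cfg$lr)

  cl <- cfg$center_loss
  centers1 <- matrix(0, bcfg$n_classes, bcfg$feature_dim)
  centers2 <- matrix(0, bcfg$n_classes, bcfg$feature_dim)

  W_cur <- fixed_weights()
  wpar <- c(0, 0)                           # learned-weights logits
  best <- list(err = Inf, W = W_cur, epoch = 0L)
  hist <- vector("list", cfg$epochs)

  apply_center <- function(f, yb, centers, g) {
    if (!isTRUE(cl$enabled)) return(list(g = g, centers = centers))
    cy <- centers[yb + 1L, , drop = FALSE]
    g <- g + cl$weight * (f - cy) / nrow(f)
    for (k in seq_len(nrow(centers))) {
      sel <- yb == (k - 1L)
      if (any(sel)) {
        delta <- colSums(centers[rep(k, sum(sel)), , drop = FALSE] -
                           f[sel, , drop = FALSE]) / (1 + sum(sel))
        centers[k, ] <- centers[k, ] - cl$lr * delta
      }
    }
    list(g = g, centers = centers)
  }

  for (ep in seq_len(cfg$epochs)) {
    # adversarial strength ramps from 0 to lambda_adv over training so the
    # class signal is acquired before invariance pressure kicks in (the
    # usual schedule for gradient-reversal training)
    p <- ep / cfg$epochs
    lam <- cfg$lambda_adv * (2 / (1 + exp(-10 * p)) - 1)
    ord <- sample(fit_idx)
    nb <- 0L; sum_lc <- 0; sum_ld1 <- 0; sum_ld2 <- 0
    for (s in seq(1L, length(ord), by = cfg$batch_size)) {
      bidx <- ord[s:min(length(ord), s + cfg$batch_size - 1L)]
      yb <- y[bidx]; db <- dmap[bidx]
      if (mode == "data") {
        xb <- slice3(xdat, bidx)
        f1 <- net_forward(br1$extractor, xb, train = TRUE)
        p1 <- net_forward(br1$head, f1, train = TRUE)
        L_c <- ce_from_probs(p1, yb)
        gf <- net_backward(br1$head, ce_grad_probs(p1, yb))
        pd1 <- net_forward(disc1, grl1$forward(f1), train = TRUE)
        L_d1 <- ce_from_probs(pd1, db); L_d2 <- 0
        if (lam > 0) {
          gf <- gf + grl1$backward(net_backward(disc1, lam * ce_grad_probs(pd1, db)))
        }
        r <- apply_center(f1, yb, centers1, gf)
        centers1 <- r$centers
        net_backward(br1$extractor, r$g)
      } else {
        x1 <- slice3(dataset$eeg, bidx)
        x2 <- slice3(dataset$scal, bidx)
        f1 <- net_forward(br1$extractor, x1, train = TRUE)
        f2 <- net_forward(br2$extractor, x2, train = TRUE)
        if (mode == "feature") {
          fc <- cbind(f1, f2)
          pf <- net_forward(fhead, fc, train = TRUE)
          L_c <- ce_from_probs(pf, yb)
          gc <- net_backward(fhead, ce_grad_probs(pf, yb))
          g1 <- gc[, seq_len(bcfg$feature_dim), drop = FALSE]
          g2 <- gc[, bcfg$feature_dim + seq_len(bcfg$feature_dim), drop = FALSE]
        } else {
          p1 <- net_forward(br1$head, f1, train = TRUE)
          p2 <- net_forward(br2$head, f2, train = TRUE)
          fused <- W_cur$W1 * p1 + W_cur$W2 * p2
          L_c <- ce_from_probs(fused, yb)
          gfused <- ce_grad_probs(fused, yb)
          if (cfg$weights == "learned") {
            Wl <- exp(wpar) / sum(exp(wpar))
            dW <- c(sum(gfused * p1), sum(gfused * p2))
            da <- Wl * (dW - sum(dW * Wl))
            wpar <- wpar - cfg$lr * 10 * da
          }
          g1 <- net_backward(br1$head, W_cur$W1 * gfused)
          g2 <- net_backward(br2$head, W_cur$W2 * gfused)
        }
        pd1 <- net_forward(disc1, grl1$forward(f1), train = TRUE)
        pd2 <- net_forward(disc2, grl2$forward(f2), train = TRUE)
        L_d1 <- ce_from_probs(pd1, db)
        L_d2 <- ce_from_probs(pd2, db)
        if (lam > 0) {
          g1 <- g1 + grl1$backward(net_backward(disc1, lam * ce_grad_probs(pd1, db)))
          g2 <- g2 + grl2$backward(net_backward(disc2, lam * ce_grad_probs(pd2, db)))
        }
        r1 <- apply_center(f1, yb, centers1, g1); centers1 <- r1$centers
        r2 <- apply_center(f2, yb, centers2, g2); centers2 <- r2$centers
        net_backward(br1$extractor, r1$g)
        net_backward(br2$extractor, r2$g)
      }
      opt$step()
      if (lam > 0) {
        opt_d$step()
        # extra discriminator refinements on the same frozen features
        for (rfn in seq_len(cfg$disc_steps - 1L)) {
          pd1 <- net_forward(disc1, f1, train = TRUE)
          net_backward(disc1, ce_grad_probs(pd1, db))
          if (!is.null(disc2)) {
            pd2 <- net_forward(disc2, f2, train = TRUE)
            net_backward(disc2, ce_grad_probs(pd2, db))
          }
          opt_d$step()
        }
      }
      nb <- nb + 1L
      sum_lc <- sum_lc + L_c; sum_ld1 <- sum_ld1 + L_d1; sum_ld2 <- sum_ld2 + L_d2
    }

    # end of epoch: validation error rates -> fusion weights
    yv <- y[val_idx]
    if (mode == "data") {
      pv <- eval_forward(c(br1$extractor, br1$head), slice3(xdat, val_idx))
      err1 <- branch_error(pv, yv); err2 <- NA_real_
      val_err <- err1
      W_cur <- fixed_weights()
    } else {
      pv1 <- eval_forward(c(br1$extractor, br1$head), slice3(dataset$eeg, val_idx))
      pv2 <- eval_forward(c(br2$extractor, br2$head), slice3(dataset$scal, val_idx))
      err1 <- branch_error(pv1, yv); err2 <- branch_error(pv2, yv)
      if (mode == "feature") {
        fv1 <- eval_forward(br1$extractor, slice3(dataset$eeg, val_idx))
        fv2 <- eval_forward(br2$extractor, slice3(dataset$scal, val_idx))
        pvf <- net_forward(fhead, cbind(fv1, fv2), train = FALSE)
        val_err <- branch_error(pvf, yv)
        W_cur <- fixed_weights()
      } else {
        W_cur <- switch(cfg$weights,
          dynamic = dynamic_weights(err1, err2),
          fixed = fixed_weights(),
          learned = {
            Wl <- exp(wpar) / sum(exp(wpar))
            structure(list(err1 = err1, err2 = err2, w1 = exp(wpar[1L]),
                           w2 = exp(wpar[2L]), W1 = Wl[1L], W2 = Wl[2L]),
                      class = "fusion_weights")
          })
        val_err <- branch_error(W_cur$W1 * pv1 + W_cur$W2 * pv2, yv)
      }
    }
    if (val_err < best$err) {
      # keep the best-validation-epoch state (parameters, batch-norm
      # statistics and fusion weights); the returned model is this snapshot
      snap <- lapply(groups, net_get_state)
      best <- list(err = val_err, W = W_cur, epoch = ep, state = snap)
    }
    hist[[ep]] <- data.frame(epoch = ep, L_c = sum_lc / nb,
                             L_d_eeg = sum_ld1 / nb, L_d_ecg = sum_ld2 / nb,
                             err1 = err1, err2 = err2,
                             W1 = W_cur$W1, W2 = W_cur$W2, val_err = val_err)
  }

  if (!is.null(best$state)) {
    for (i in seq_along(groups)) net_set_state(groups[[i]], best$state[[i]])
  }

  structure(list(mode = mode, branch_eeg = br1, branch_ecg = br2,
                 fusion_head = fhead,
                 discriminators = list(eeg = disc1, ecg = disc2),
                 weights = best$W, best_epoch = best$epoch,
                 history = do.call(rbind, hist),
                 train_episodes = train_eps, test_episode = test_episode,
                 episode_map = train_eps, cfg = cfg, bcfg = bcfg,
                 centers = list(centers1, centers2),
                 n_channels = C, n_samples = Ts),
            class = "szfuse_fit")
}

#' @export
print.szfuse_fit <- function(x, ...) {
  cat(sprintf("<szfuse_fit> %s fusion, test episode %d, trained on episodes {%s}\n",
              x$mode, x$test_episode,
              paste(x$train_episodes, collapse = ", ")))
  cat(sprintf("  epochs %d (best validation epoch %d), lambda_adv = %g\n",
              x$cfg$epochs, x$best_epoch, x$cfg$lambda_adv))
  if (x$mode == "decision") print(x$weights)
  invisible(x)
}

#' Predict on segments with a fitted fold model
#'
#' @param object an `szfuse_fit`.
#' @param dataset the `szfuse_dataset` the model was built for (same shapes).
#' @param indices segment indices to score; default all.
#' @param ... unused.
#' @return List with fused `prob` (n x 2), 0-based `class`, and (decision
#'   mode) the per-branch probabilities `prob_eeg`, `prob_ecg`.
#' @export
predict.szfuse_fit <- function(object, dataset, indices = NULL, ...) {
  if (is.null(indices)) indices <- seq_along(dataset$y)
  if (object$mode == "data") {
    C <- object$n_channels
    x <- array(0, c(length(indices), C + 1L, object$n_samples))
    x[, seq_len(C), ] <- slice3(dataset$eeg, indices)
    x[, C + 1L, ] <- dataset$ecg[indices, , drop = FALSE]
    p <- eval_forward(c(object$branch_eeg$extractor, object$branch_eeg$head), x)
    return(list(prob = p, class = max.col(p, "first") - 1L,
                prob_eeg = p, prob_ecg = NULL))
  }
  x1 <- slice3(dataset$eeg, indices)
  x2 <- slice3(dataset$scal, indices)
  if (object$mode == "feature") {
    f1 <- eval_forward(object$branch_eeg$extractor, x1)
    f2 <- eval_forward(object$branch_ecg$extractor, x2)
    p <- net_forward(object$fusion_head, cbind(f1, f2), train = FALSE)
    return(list(prob = p, class = max.col(p, "first") - 1L,
                prob_eeg = NULL, prob_ecg = NULL))
  }
  p1 <- eval_forward(c(object$branch_eeg$extractor, object$branch_eeg$head), x1)
  p2 <- eval_forward(c(object$branch_ecg$extractor, object$branch_ecg$head), x2)
  fz <- fuse_decisions(p1, p2, object$weights)
  list(prob = fz$prob, class = fz$class, prob_eeg = p1, prob_ecg = p2)
}

#' Extract frozen branch features
#'
#' Runs a fitted branch's feature extractor in eval mode; used e.g. to probe
#' how episode-discriminable the learned features are.
#'
#' @param fit an `szfuse_fit`.
#' @param dataset the matching `szfuse_dataset`.
#' @param indices segment indices (default all).
#' @param modality `"eeg"` or `"ecg"`.
#' @return n x feature_dim matrix.
#' @export
extract_features <- function(fit, dataset, indices = NULL,
                             modality = c("eeg", "ecg")) {
  modality <- match.arg(modality)
  if (is.null(indices)) indices <- seq_along(dataset$y)
  if (modality == "eeg") {
    x <- if (fit$mode == "data") {
      C <- fit$n_channels
      xx <- array(0, c(length(indices), C + 1L, fit$n_samples))
      xx[, seq_len(C), ] <- slice3(dataset$eeg, indices)
      xx[, C + 1L, ] <- dataset$ecg[indices, , drop = FALSE]
      xx
    } else slice3(dataset$eeg, indices)
    eval_forward(fit$branch_eeg$extractor, x)
  } else {
    if (is.null(fit$branch_ecg)) stop("extract_features: fit has no ECG branch")
    eval_forward(fit$branch_ecg$extractor, slice3(dataset$scal, indices))
  }
}

#' Leave-one-episode-out cross-validation
#'
#' One fold per episode: the fold's episode is held out, all others train
#' the model ([train_fold()]), and the held-out segments are scored. A
#' patient must have at least three episodes — with fewer, each fold would
#' train on a single episode and overfit its idiosyncrasies, so the run is
#' refused.
#'
#' @param dataset an `szfuse_dataset`.
#' @param cfg a [train_config()]; per-fold seeds are derived
#'   deterministically from `cfg$seed`.
#' @param bcfg a [branch_config()].
#' @param patient_id identifier carried into the reports.
#' @param sp_definition specificity convention, see
#'   [classification_metrics()].
#' @param keep_fits whether to retain the per-fold fitted models.
#' @return Object of class `szfuse_loocv`: per-fold reports, pooled and
#'   averaged metrics, stored per-segment predictions, and (optionally) the
#'   fits.
#' @export
loocv <- function(dataset, cfg = train_config(), bcfg = branch_config(),
                  patient_id = "patient", sp_definition = "standard",
                  keep_fits = TRUE) {
  episodes <- sort(unique(dataset$d))
  if (length(episodes) < 3L) {
    stop("loocv: at least three episodes per patient are required; fewer preictal/interictal periods cause an overfitting problem in training")
  }
  reports <- list(); fits <- list(); preds <- list(); weights <- list()
  for (k in seq_along(episodes)) {
    epi <- episodes[k]
    fcfg <- cfg
    fcfg$seed <- as.integer((abs(cfg$seed) * 131L + 7919L * k) %% 2147483629L)
    fit <- train_fold(dataset, epi, fcfg, bcfg)
    te_idx <- which(dataset$d == epi)
    pr <- predict(fit, dataset, te_idx)
    reports[[k]] <- fold_report(dataset$y[te_idx], pr$class,
                                patient_id = patient_id,
                                held_out_episode = epi,
                                sp_definition = sp_definition)
    preds[[k]] <- list(episode = epi, index = te_idx, y = dataset$y[te_idx],
                       class = pr$class, prob = pr$prob,
                       prob_eeg = pr$prob_eeg, prob_ecg = pr$prob_ecg)
    weights[[k]] <- fit$weights
    if (keep_fits) fits[[k]] <- fit
  }
  structure(list(reports = reports,
                 aggregate = aggregate_folds(reports, sp_definition),
                 predictions = preds, fold_weights = weights,
                 fits = if (keep_fits) fits else NULL,
                 episodes = episodes, patient_id = patient_id,
                 cfg = cfg, bcfg = bcfg),
            class = "szfuse_loocv")
}

#' @export
print.szfuse_loocv <- function(x, ...) {
  ag <- x$aggregate
  cat(sprintf("<szfuse_loocv> %s: %d episodes, %s fusion, %s weights, lambda_adv = %g\n",
              x$patient_id, length(x$episodes), x$cfg$fusion, x$cfg$weights,
              x$cfg$lambda_adv))
  print(round(ag$per_fold, 4))
  cat(sprintf("mean  ACC %.4f (+/- %.4f)  SN %.4f  SP %.4f  FAR %.4f\n",
              ag$mean$acc, ag$sd$acc, ag$mean$sn, ag$mean$sp, ag$mean$far))
  cat(sprintf("pooled ACC %.4f  SN %.4f  SP %.4f  FAR %.4f\n",
              ag$pooled$acc, ag$pooled$sn, ag$pooled$sp, ag$pooled$far))
  invisible(x)
}

#' @export
summary.szfuse_loocv <- function(object, ...) {
  print(object)
  cat("\nPer-fold fusion weights:\n")
  for (k in seq_along(object$fold_weights)) {
    w <- object$fold_weights[[k]]
    cat(sprintf("  episode %d: W1 = %.4f, W2 = %.4f (err1 = %s, err2 = %s)\n",
                object$episodes[k], w$W1, w$W2,
                format(w$err1, digits = 3), format(w$err2, digits = 3)))
  }
  invisible(object)
}

#' @export
plot.szfuse_loocv <- function(x, ...) {
  pf <- x$aggregate$per_fold
  graphics::barplot(pf$acc, names.arg = pf$held_out_episode,
                    ylim = c(0, 1), xlab = "held-out episode",
                    ylab = "accuracy",
                    main = sprintf("%s: leave-one-episode-out accuracy",
                                   x$patient_id), ...)
  graphics::abline(h = 0.5, lty = 2)
  invisible(x)
}

#' Re-fuse stored leave-one-out predictions with different weights
#'
#' Uses the per-branch probabilities stored in an `szfuse_loocv` run to
#' evaluate an alternative weighting (e.g. fixed 0.5/0.5) without
#' retraining.
#'
#' @param run an `szfuse_loocv` from decision-level fusion.
#' @param weights a `fusion_weights` object, or `NULL` to reuse each fold's
#'   fitted weights.
#' @return Aggregate as from [aggregate_folds()].
#' @export
refuse_predictions <- function(run, weights = NULL) {
  if (run$cfg$fusion != "decision") {
    stop("refuse_predictions: stored branch probabilities require decision fusion")
  }
  reports <- lapply(seq_along(run$predictions), function(k) {
    p <- run$predictions[[k]]
    w <- if (is.null(weights)) run$fold_weights[[k]] else weights
    fz <- fuse_decisions(p$prob_eeg, p$prob_ecg, w)
    fold_report(p$y, fz$class, patient_id = run$patient_id,
                held_out_episode = p$episode)
  })
  aggregate_folds(reports)
}
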