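#' Training configuration
#'
#' Defaults follow the published configuration: Adam with learning rate 1e-4,
#' batch size 8, diameter-loss weight gamma = 1/8, KL weight beta = 1 and 200
#' epochs, with paired rotation/translation augmentation.
#'
#' @param gamma weight of the L1 diameter term in the reconstruction loss.
#' @param beta weight of the hierarchical KL term in the ELBO.
#' @param learning_rate,batch_size,epochs Adam optimisation settings.
#' @param reconstruction_mode `"iou_l1"` (soft IoU plus gamma-weighted L1 on
#'   the soft longest diameter), `"iou_only"`, or `"bce"` (per-pixel binary
#'   cross-entropy) — the latter two are the loss-ablation variants.
#' @param augment apply paired augmentation to images and masks.
#' @param aug_rotate_deg,aug_translate_px augmentation ranges (degrees,
#'   pixels).
#' @param seed integer seed controlling shuffling, augmentation and latent
#'   sampling during training.
#' @return A `training_config` object.
#' @export
training_config <- function(gamma = 1 / 8, beta = 1, learning_rate = 1e-4,
                            batch_size = 8L, epochs = 200L,
                            reconstruction_mode = c("iou_l1", "iou_only",
                                                    "bce"),
                            augment = TRUE, aug_rotate_deg = 15,
                            aug_translate_px = 3L, seed = 1L) {
  reconstruction_mode <- match.arg(reconstruction_mode)
  if (gamma < 0 || beta < 0) stopf("gamma and beta must be >= 0")
  if (learning_rate <= 0 || batch_size < 1 || epochs < 0) {
    stopf("learning_rate must be > 0, batch_size >= 1, epochs >= 0")
  }
  structure(list(gamma = gamma, beta = beta, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 reconstruction_mode = reconstruction_mode,
                 augment = isTRUE(augment), aug_rotate_deg = aug_rotate_deg,
                 aug_translate_px = as.integer(aug_translate_px),
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Soft intersection-over-union loss
#'
#' `1 - (sum(p*y) + eps) / (sum(p) + sum(y) - sum(p*y) + eps)` with
#' `eps = 1e-6`; 0 for a perfect binary prediction, close to 1 for disjoint
#' masks, and differentiable in the soft prediction.
#'
#' @param pred soft mask in \[0,1\].
#' @param target binary mask of the same shape.
#' @param eps stabiliser.
#' @return Scalar loss in \[0,1\].
#' @export
soft_iou_loss <- function(pred, target, eps = 1e-6) {
  if (!all(dim(pred) == dim(target))) stopf("pred/target shape mismatch")
  i <- sum(pred * target)
  1 - (i + eps) / (sum(pred) + sum(target) - i + eps)
}

#' Differentiable longest diameter of a soft mask
#'
#' Soft Feret estimate: over `n_dir` caliper directions, the extent is the
#' difference between the mask-weighted softmax and softmin expectations of
#' the pixel-centre projections (log-sum-exp weights at temperature `temp`
#' per pixel); the widest extent plus one pixel, scaled by the spacing. On
#' binary masks this agrees with the hard extractor to within about half a
#' pixel at temperature 8; an empty mask gives 0.
#'
#' @param pred soft mask in \[0,1\].
#' @param spacing_mm pixel spacing (mm/pixel).
#' @param temp softmax temperature (1/pixel).
#' @param n_dir number of caliper directions over \[0, pi).
#' @return Diameter in mm.
#' @export
soft_longest_diameter <- function(pred, spacing_mm = 1, temp = 4,
                                  n_dir = 16L) {
  g <- ad_graph()
  nd <- op_soft_feret(g, op_const(g, as_batch(pred)), spacing_mm, temp, n_dir)
  as.numeric(nd$value[1])
}

#' Reconstruction loss between a predicted and a reference segmentation
#'
#' Mode `"iou_l1"` is the tailored loss: soft IoU plus `gamma` times the L1
#' distance between the soft longest diameter of the prediction and the
#' reference diameter (mm). `"iou_only"` drops the diameter term; `"bce"` is
#' plain per-pixel binary cross-entropy.
#'
#' @param pred soft 32x32 mask.
#' @param target_mask binary reference mask.
#' @param target_d1_mm reference follow-up diameter (mm).
#' @param spacing_mm pixel spacing (mm/pixel).
#' @param config a [training_config()] (supplies gamma and the mode).
#' @return Scalar loss.
#' @export
reconstruction_loss <- function(pred, target_mask, target_d1_mm, spacing_mm,
                                config = training_config()) {
  switch(config$reconstruction_mode,
    iou_l1 = soft_iou_loss(pred, target_mask) + config$gamma *
      abs(soft_longest_diameter(pred, spacing_mm) - target_d1_mm),
    iou_only = soft_iou_loss(pred, target_mask),
    bce = {
      p <- clamp(pred, 1e-7, 1 - 1e-7)
      -mean(target_mask * log(p) + (1 - target_mask) * log(1 - p))
    },
    stopf("unknown reconstruction mode '%s'", config$reconstruction_mode))
}

#' Hierarchical KL divergence between posterior and prior latents
#'
#' Sum over the 4 levels and all grid cells of the closed-form KL between the
#' diagonal Gaussians `q` (posterior) and `p` (prior). During training the
#' nested expectation over coarser latents is approximated by the single
#' posterior sample drawn per step, which conditions both subnets' finer
#' levels.
#'
#' @param posterior,prior `latent_hierarchy` objects with matching structure.
#' @return Scalar KL >= 0.
#' @export
kl_hierarchy <- function(posterior, prior) {
  if (length(posterior$levels) != length(prior$levels)) {
    stopf("latent hierarchies have different depths")
  }
  tot <- 0
  for (i in seq_along(posterior$levels)) {
    q <- posterior$levels[[i]]; p <- prior$levels[[i]]
    if (!all(dim(q$mean) == dim(p$mean))) stopf("level %d grid mismatch", i)
    if (any(q$std <= 0) || any(p$std <= 0)) stopf("latent std must be > 0")
    tot <- tot + sum(log(p$std / q$std) +
                       (q$std^2 + (q$mean - p$mean)^2) / (2 * p$std^2) - 0.5)
  }
  tot
}

#' Evidence-lower-bound loss for one record
#'
#' Runs a training-style forward pass (posterior latents injected into the
#' prior decoder) and returns `reconstruction_loss + beta * kl_hierarchy`.
#'
#' @param record a [growth_record()] with both time points.
#' @param model an [hpnet_model()].
#' @param config a [training_config()].
#' @param seed integer seed or `NULL`.
#' @return Scalar loss with attributes `lrec` and `kl`.
#' @export
elbo_loss <- function(record, model, config = training_config(),
                      seed = NULL) {
  ft <- forward_train(model, record, seed = seed)
  lrec <- reconstruction_loss(ft$reconstruction, record$mask_t1,
                              record$d1_mm, record$spacing_mm, config)
  kl <- kl_hierarchy(ft$posterior, ft$prior)
  structure(lrec + config$beta * kl, lrec = lrec, kl = kl)
}

# Paired nearest-neighbour rotation + integer translation (masks stay binary).
transform_patch <- function(m, angle_deg, dx, dy) {
  n <- nrow(m)
  ctr <- (n + 1) / 2
  th <- angle_deg * pi / 180
  i <- rep(seq_len(n), times = n) - ctr
  j <- rep(seq_len(n), each = n) - ctr
  si <- round(cos(th) * i - sin(th) * j + ctr - dx)
  sj <- round(sin(th) * i + cos(th) * j + ctr - dy)
  ok <- si >= 1 & si <= n & sj >= 1 & sj <= n
  out <- numeric(n * n)
  out[ok] <- m[cbind(si[ok], sj[ok])]
  matrix(out, n, n)
}

adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- gr * 0
      state$v[[nm]] <- gr * 0
    }
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * gr
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * gr^2
    params[[nm]] <- params[[nm]] - lr * (state$m[[nm]] / corr1) /
      (sqrt(state$v[[nm]] / corr2) + eps)
  }
  params
}

#' Train the hierarchical probabilistic network on a cohort
#'
#' Minimises the ELBO (reconstruction plus beta-weighted hierarchical KL)
#' with Adam. Every record must carry both time points. Augmentation applies
#' the same rotation/translation to the images and the target mask of a
#' record. Training aborts with a diagnostic if the loss becomes
#' non-finite. The run is deterministic given the seeds (up to floating-point
#' non-associativity in BLAS reductions).
#'
#' @param cohort a [growth_cohort()].
#' @param net_config a [network_config()].
#' @param train_config a [training_config()].
#' @param verbose print per-epoch losses.
#' @return List with `model` (trained [hpnet_model()]) and `history`
#'   (data.frame epoch / lrec / kl / total). `epochs = 0` returns the
#'   initialised model with an empty history.
#' @export
train_hpnet <- function(cohort, net_config = network_config(),
                        train_config = training_config(), verbose = FALSE) {
  recs <- cohort$records
  if (!length(recs)) stopf("cannot train on an empty cohort")
  if (any(vapply(recs, function(r) is.null(r$image_t1), logical(1)))) {
    stopf("all training records need both time points")
  }
  model <- hpnet_model(net_config)
  cfg <- train_config
  hist <- data.frame(epoch = integer(), lrec = numeric(), kl = numeric(),
                     total = numeric())
  if (cfg$epochs == 0L) return(list(model = model, history = hist))
  state <- new.env(parent = emptyenv())
  state$t <- 0L; state$m <- list(); state$v <- list()
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample(length(recs))
      ep <- c(lrec = 0, kl = 0, total = 0)
      nb <- 0L
      for (start in seq(1, length(ord), by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
        B <- length(idx)
        I0 <- I1 <- array(0, c(32, 32, 1, B))
        Y <- array(0, c(32, 32, B))
        d1 <- sp <- tn <- dn <- numeric(B)
        for (b in seq_len(B)) {
          r <- recs[[idx[b]]]
          img0 <- r$image_t0; img1 <- r$image_t1; msk <- r$mask_t1
          if (cfg$augment) {
            ang <- stats::runif(1, -cfg$aug_rotate_deg, cfg$aug_rotate_deg)
            sh <- sample(-cfg$aug_translate_px:cfg$aug_translate_px, 2,
                         replace = TRUE)
            img0 <- transform_patch(img0, ang, sh[1], sh[2])
            img1 <- transform_patch(img1, ang, sh[1], sh[2])
            msk <- round(transform_patch(msk, ang, sh[1], sh[2]))
          }
          I0[, , 1, b] <- img0; I1[, , 1, b] <- img1; Y[, , b] <- msk
          d1[b] <- r$d1_mm; sp[b] <- r$spacing_mm
          cc <- encode_conditioning(r$elapsed_days, r$d0_mm)
          tn[b] <- cc$t_norm; dn[b] <- cc$d_norm
        }
        res <- hpnet_forward_core(model, I0, I1, tn, dn, mode = "train")
        g <- res$g
        pred <- res$out$prior
        lrec_node <- switch(cfg$reconstruction_mode,
          iou_l1 = {
            li <- op_loss_iou(g, pred, Y)
            l1 <- op_l1_vec(g, op_soft_feret(g, pred, sp), d1)
            op_wsum(g, list(li, l1), c(1, cfg$gamma))
          },
          iou_only = op_loss_iou(g, pred, Y),
          bce = op_loss_bce(g, pred, Y))
        kls <- lapply(seq_len(4), function(i) {
          op_kl_gauss(g, res$streams$post$hier[[i]]$mu,
                      res$streams$post$hier[[i]]$sd,
                      res$streams$prior$hier[[i]]$mu,
                      res$streams$prior$hier[[i]]$sd, scale = 1 / B)
        })
        kl_node <- op_wsum(g, kls, rep(1, 4))
        total <- op_wsum(g, list(lrec_node, kl_node), c(1, cfg$beta))
        if (!is.finite(total$value)) {
          stopf("non-finite loss at epoch %d (lrec=%.4g, kl=%.4g); aborting",
                epoch, lrec_node$value, kl_node$value)
        }
        ad_backward(g, total)
        grads <- lapply(g$leaves, function(nd) nd$grad %||% (nd$value * 0))
        model$params <- adam_step(model$params, grads, state,
                                  cfg$learning_rate)
        ep <- ep + c(lrec_node$value, kl_node$value, total$value)
        nb <- nb + 1L
      }
      ep <- ep / nb
      hist <- rbind(hist, data.frame(epoch = epoch, lrec = ep[["lrec"]],
                                     kl = ep[["kl"]], total = ep[["total"]]))
      if (verbose) {
        message(sprintf("epoch %3d  lrec %.4f  kl %.4f  total %.4f",
                        epoch, ep[["lrec"]], ep[["kl"]], ep[["total"]]))
      }
    }
  })
  list(model = model, history = hist)
}
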