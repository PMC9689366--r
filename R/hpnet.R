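#' Network configuration
#'
#' Architecture switches for the hierarchical probabilistic segmentation
#' network. The backbone is a 4-level residual U-Net (encoder filters
#' `base_filters * c(1, 2, 4, 8)` at resolutions 32/16/8/4) with four latent
#' blocks interleaved in the decoder at spatial grids 1, 2, 4 and 8 (one
#' channel each, so flattened latent dimensions 1, 4, 16 and 64). Attention
#' gates on the skip connections and the baseline-diameter input channel can
#' be disabled independently to reproduce the ablation variants.
#'
#' @param base_filters filters at the finest resolution (doubled per level).
#' @param use_attention gate the skip connections with learned attention
#'   coefficients; when `FALSE` skips pass through unchanged.
#' @param use_d0_input condition on the normalised baseline diameter in
#'   addition to the time-to-predict.
#' @param seed integer seed for weight initialisation.
#' @return A `network_config` object (depth is fixed at 4 by the latent-block
#'   geometry).
#' @export
network_config <- function(base_filters = 32L, use_attention = TRUE,
                           use_d0_input = TRUE, seed = 1L) {
  if (base_filters < 1) stopf("base_filters must be >= 1")
  structure(list(base_filters = as.integer(base_filters), depth = 4L,
                 use_attention = isTRUE(use_attention),
                 use_d0_input = isTRUE(use_d0_input), seed = as.integer(seed)),
            class = "network_config")
}

latent_grids <- c(1L, 2L, 4L, 8L)

# ---- parameter initialisation ----------------------------------------------

he_conv <- function(k, cin, cout) {
  list(W = matrix(stats::rnorm(k * k * cin * cout, 0,
                               sqrt(2 / (k * k * cin))), k * k * cin, cout),
       b = numeric(cout))
}

add_conv <- function(params, name, k, cin, cout) {
  p <- he_conv(k, cin, cout)
  params[[paste0(name, ".W")]] <- p$W
  params[[paste0(name, ".b")]] <- p$b
  params
}

add_resblock <- function(params, name, cin, cout, force_sc = FALSE) {
  params <- add_conv(params, paste0(name, ".c1"), 3, cin, cout)
  params <- add_conv(params, paste0(name, ".c2"), 3, cout, cout)
  if (cin != cout || force_sc) {
    params <- add_conv(params, paste0(name, ".sc"), 1, cin, cout)
  }
  params
}

add_attention <- function(params, name, cx, cg) {
  ca <- max(cx %/% 2L, 4L)
  params <- add_conv(params, paste0(name, ".wx"), 1, cx, ca)
  params <- add_conv(params, paste0(name, ".wg"), 1, cg, ca)
  add_conv(params, paste0(name, ".psi"), 1, ca, 1)
}

init_subnet <- function(params, p, cin, f, config) {
  ncond <- 1L + as.integer(config$use_d0_input)
  # the stem always projects its shortcut so prior and posterior keep
  # identical structure apart from the input channel count
  params <- add_resblock(params, paste0(p, ".enc1"), cin, f, force_sc = TRUE)
  params <- add_conv(params, paste0(p, ".down1"), 3, f, 2 * f)
  params <- add_resblock(params, paste0(p, ".enc2"), 2 * f, 2 * f)
  params <- add_conv(params, paste0(p, ".down2"), 3, 2 * f, 4 * f)
  params <- add_resblock(params, paste0(p, ".enc3"), 4 * f, 4 * f)
  params <- add_conv(params, paste0(p, ".down3"), 3, 4 * f, 8 * f)
  params <- add_resblock(params, paste0(p, ".enc4"), 8 * f, 8 * f)
  params <- add_conv(params, paste0(p, ".cond"), 1, 8 * f + ncond, 8 * f)
  # decoder ladder with interleaved latent blocks
  params <- add_conv(params, paste0(p, ".lat1.mu"), 1, 8 * f, 1)
  params <- add_conv(params, paste0(p, ".lat1.sr"), 1, 8 * f, 1)
  params <- add_conv(params, paste0(p, ".proj1"), 1, 8 * f + 1, 8 * f)
  params <- add_conv(params, paste0(p, ".mix2"), 3, 16 * f, 8 * f)
  params <- add_conv(params, paste0(p, ".lat2.mu"), 1, 8 * f, 1)
  params <- add_conv(params, paste0(p, ".lat2.sr"), 1, 8 * f, 1)
  params <- add_conv(params, paste0(p, ".proj2"), 1, 8 * f + 1, 8 * f)
  params <- add_resblock(params, paste0(p, ".dec4"), 16 * f, 4 * f)
  params <- add_conv(params, paste0(p, ".lat4.mu"), 1, 4 * f, 1)
  params <- add_conv(params, paste0(p, ".lat4.sr"), 1, 4 * f, 1)
  params <- add_conv(params, paste0(p, ".proj4"), 1, 4 * f + 1, 4 * f)
  params <- add_resblock(params, paste0(p, ".dec8"), 8 * f, 2 * f)
  params <- add_conv(params, paste0(p, ".lat8.mu"), 1, 2 * f, 1)
  params <- add_conv(params, paste0(p, ".lat8.sr"), 1, 2 * f, 1)
  params <- add_conv(params, paste0(p, ".proj8"), 1, 2 * f + 1, 2 * f)
  params <- add_resblock(params, paste0(p, ".dec16"), 4 * f, f)
  params <- add_resblock(params, paste0(p, ".dec32"), 2 * f, f)
  params <- add_conv(params, paste0(p, ".head"), 1, f, 1)
  if (config$use_attention) {
    params <- add_attention(params, paste0(p, ".att4"), 8 * f, 8 * f)
    params <- add_attention(params, paste0(p, ".att8"), 4 * f, 4 * f)
    params <- add_attention(params, paste0(p, ".att16"), 2 * f, 2 * f)
    params <- add_attention(params, paste0(p, ".att32"), f, f)
  }
  params
}

#' Initialise a hierarchical probabilistic network model
#'
#' Creates the prior subnet (baseline image input) and the posterior subnet
#' (baseline plus follow-up image input); the two share the same decoder
#' architecture and differ only in the first convolution's input channels.
#' Weights use fan-in (He) initialisation under the configuration seed.
#'
#' @param config a [network_config()].
#' @return Object of class `hpnet_model` with elements `params` (named list of
#'   weight arrays) and `config`.
#' @export
hpnet_model <- function(config = network_config()) {
  stopifnot(inherits(config, "network_config"))
  with_seed(config$seed, {
    f <- config$base_filters
    params <- list()
    params <- init_subnet(params, "prior", 1L, f, config)
    params <- init_subnet(params, "post", 2L, f, config)
    # damp the latent heads so prior and posterior start close together
    # (moderate initial KL) with std ~ softplus(-1) = 0.31
    for (nm in grep("\\.lat[0-9]+\\.(mu|sr)\\.W$", names(params),
                    value = TRUE)) {
      params[[nm]] <- params[[nm]] * 0.1
    }
    for (nm in grep("\\.lat[0-9]+\\.sr\\.b$", names(params), value = TRUE)) {
      params[[nm]] <- params[[nm]] - 1
    }
    structure(list(params = params, config = config), class = "hpnet_model")
  })
}

#' @export
print.hpnet_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf(paste0("<hpnet_model> base_filters=%d attention=%s d0_input=%s ",
                     "(%s parameters)\n"),
              x$config$base_filters, x$config$use_attention,
              x$config$use_d0_input, format(np, big.mark = ",")))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single serialized file holding the weights and an echo of
#' the network configuration.
#'
#' @param model an `hpnet_model`.
#' @param path checkpoint file path.
#' @return `save_checkpoint` returns the path invisibly; `load_checkpoint`
#'   returns the restored `hpnet_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "hpnet_model"))
  saveRDS(list(params = model$params, config = unclass(model$config)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  cfg <- do.call(network_config, x$config[c("base_filters", "use_attention",
                                            "use_d0_input", "seed")])
  structure(list(params = x$params, config = cfg), class = "hpnet_model")
}

# ---- graph building blocks -------------------------------------------------

conv_l <- function(g, params, name, x, stride = 1L, pad = 1L) {
  op_conv(g, x, op_param(g, params, paste0(name, ".W")),
          op_param(g, params, paste0(name, ".b")), stride = stride, pad = pad)
}

conv1_l <- function(g, params, name, x) conv_l(g, params, name, x, 1L, 0L)

resblock_l <- function(g, params, name, x) {
  h <- op_relu(g, conv_l(g, params, name = paste0(name, ".c1"), x))
  h <- conv_l(g, params, paste0(name, ".c2"), h)
  s <- if (!is.null(params[[paste0(name, ".sc.W")]])) {
    conv1_l(g, params, paste0(name, ".sc"), x)
  } else x
  op_relu(g, op_add(g, h, s))
}

attn_l <- function(g, params, name, skip, gating, enabled) {
  if (!enabled) return(skip)
  q <- op_relu(g, op_add(g, conv1_l(g, params, paste0(name, ".wx"), skip),
                         conv1_l(g, params, paste0(name, ".wg"), gating)))
  alpha <- op_sigmoid(g, conv1_l(g, params, paste0(name, ".psi"), q))
  op_gate_mul(g, skip, alpha)
}

encoder_l <- function(g, params, p, x, cond) {
  e1 <- resblock_l(g, params, paste0(p, ".enc1"), x)
  e2 <- resblock_l(g, params, paste0(p, ".enc2"),
                   conv_l(g, params, paste0(p, ".down1"), e1, stride = 2L))
  e3 <- resblock_l(g, params, paste0(p, ".enc3"),
                   conv_l(g, params, paste0(p, ".down2"), e2, stride = 2L))
  e4 <- resblock_l(g, params, paste0(p, ".enc4"),
                   conv_l(g, params, paste0(p, ".down3"), e3, stride = 2L))
  b0 <- op_relu(g, conv1_l(g, params, paste0(p, ".cond"),
                           op_concat(g, c(list(e4), cond))))
  list(e1 = e1, e2 = e2, e3 = e3, e4 = e4, b0 = b0)
}

latent_l <- function(g, params, p, name, feats) {
  list(mu = conv1_l(g, params, paste0(p, ".", name, ".mu"), feats),
       sd = op_softplus(g, conv1_l(g, params, paste0(p, ".", name, ".sr"),
                                   feats)))
}

as_batch <- function(x, N = 1L) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1, 1))
  if (length(dim(x)) == 3) x <- array(x, c(dim(x)[1:2], 1, dim(x)[3]))
  if (dim(x)[4] == 1 && N > 1) x <- x[, , , rep(1L, N), drop = FALSE]
  x
}

cond_nodes <- function(g, t_norm, d_norm, use_d0, grid = 4L, N = 1L) {
  t_norm <- rep(t_norm, length.out = N)
  d_norm <- rep(d_norm, length.out = N)
  tile <- function(v) {
    a <- array(0, c(grid, grid, 1, N))
    for (n in seq_len(N)) a[, , 1, n] <- v[n]
    op_const(g, a)
  }
  if (use_d0) list(tile(t_norm), tile(d_norm)) else list(tile(t_norm))
}

draw_eps <- function(N) {
  lapply(latent_grids, function(gr) array(stats::rnorm(gr * gr * N),
                                          c(gr, gr, 1, N)))
}

# Core forward pass. `mode` selects which subnet(s) run and where the latent
# samples come from:
#   prior_sample    -- prior net, z ~ prior (stochastic generation)
#   prior_mean      -- prior net, z = prior mean (deterministic)
#   posterior_params-- posterior net, z = posterior mean (deterministic)
#   train           -- both nets in lockstep, z ~ posterior (reparameterised),
#                      injected into both decoders
# Returns the graph, per-stream output node and per-stream latent levels.
hpnet_forward_core <- function(model, I0, I1 = NULL, t_norm, d_norm,
                               mode = "prior_sample", eps = NULL,
                               z_override = NULL) {
  cfg <- model$config
  params <- model$params
  g <- ad_graph()
  I0 <- as_batch(I0)
  N <- dim(I0)[4]
  cond <- cond_nodes(g, t_norm, d_norm, cfg$use_d0_input, N = N)
  use_post <- mode %in% c("posterior_params", "train")
  use_prior <- mode != "posterior_params"
  streams <- list()
  if (use_prior) {
    streams$prior <- new.env(parent = emptyenv())
    streams$prior$p <- "prior"
    streams$prior$enc <- encoder_l(g, params, "prior", op_const(g, I0), cond)
  }
  if (use_post) {
    if (is.null(I1)) stopf("posterior pass requires the follow-up image")
    I1 <- as_batch(I1, N)
    xin <- op_const(g, abind2(I0, I1))
    streams$post <- new.env(parent = emptyenv())
    streams$post$p <- "post"
    streams$post$enc <- encoder_l(g, params, "post", xin, cond)
  }
  zsrc <- switch(mode, prior_sample = "prior", prior_mean = "prior",
                 posterior_params = "post", train = "post")
  sample_z <- mode %in% c("prior_sample", "train")
  if (sample_z && is.null(eps)) eps <- draw_eps(N)
  for (s in streams) {
    s$hier <- vector("list", 4)
    s$u <- NULL
  }

  inject <- function(i, lname, feats_of) {
    # compute latent params per stream, pick z, project and record
    lat <- list()
    for (nm in names(streams)) {
      lat[[nm]] <- latent_l(g, params, streams[[nm]]$p, lname, feats_of[[nm]])
    }
    z <- if (!is.null(z_override)) {
      op_const(g, as_batch(z_override[[i]], N))
    } else if (sample_z) {
      op_add(g, lat[[zsrc]]$mu, op_cmul(g, lat[[zsrc]]$sd, eps[[i]]))
    } else {
      lat[[zsrc]]$mu
    }
    for (nm in names(streams)) {
      streams[[nm]]$hier[[i]] <- list(mu = lat[[nm]]$mu, sd = lat[[nm]]$sd,
                                      z = z)
    }
    z
  }

  # level 1 (1x1 grid)
  feats <- lapply(streams, function(s) op_avgpool_to(g, s$enc$b0, 1L))
  z <- inject(1L, "lat1", feats)
  for (nm in names(streams)) {
    s <- streams[[nm]]
    u <- op_relu(g, conv1_l(g, params, paste0(s$p, ".proj1"),
                            op_concat(g, list(feats[[nm]], z))))
    s$u <- op_upsample2(g, u)
  }
  # level 2 (2x2 grid)
  feats <- lapply(streams, function(s) {
    skip <- op_avgpool_to(g, s$enc$b0, 2L)
    op_relu(g, conv_l(g, params, paste0(s$p, ".mix2"),
                      op_concat(g, list(s$u, skip))))
  })
  z <- inject(2L, "lat2", feats)
  for (nm in names(streams)) {
    s <- streams[[nm]]
    u <- op_relu(g, conv1_l(g, params, paste0(s$p, ".proj2"),
                            op_concat(g, list(feats[[nm]], z))))
    s$u <- op_upsample2(g, u)
  }
  # level 3 (4x4 grid, encoder skip with attention)
  feats <- lapply(streams, function(s) {
    skip <- attn_l(g, params, paste0(s$p, ".att4"), s$enc$e4, s$u,
                   cfg$use_attention)
    resblock_l(g, params, paste0(s$p, ".dec4"), op_concat(g, list(s$u, skip)))
  })
  z <- inject(3L, "lat4", feats)
  for (nm in names(streams)) {
    s <- streams[[nm]]
    u <- op_relu(g, conv1_l(g, params, paste0(s$p, ".proj4"),
                            op_concat(g, list(feats[[nm]], z))))
    s$u <- op_upsample2(g, u)
  }
  # level 4 (8x8 grid)
  feats <- lapply(streams, function(s) {
    skip <- attn_l(g, params, paste0(s$p, ".att8"), s$enc$e3, s$u,
                   cfg$use_attention)
    resblock_l(g, params, paste0(s$p, ".dec8"), op_concat(g, list(s$u, skip)))
  })
  z <- inject(4L, "lat8", feats)
  out <- list()
  for (nm in names(streams)) {
    s <- streams[[nm]]
    u <- op_relu(g, conv1_l(g, params, paste0(s$p, ".proj8"),
                            op_concat(g, list(feats[[nm]], z))))
    u <- op_upsample2(g, u)
    skip <- attn_l(g, params, paste0(s$p, ".att16"), s$enc$e2, u,
                   cfg$use_attention)
    u <- op_upsample2(g, resblock_l(g, params, paste0(s$p, ".dec16"),
                                    op_concat(g, list(u, skip))))
    skip <- attn_l(g, params, paste0(s$p, ".att32"), s$enc$e1, u,
                   cfg$use_attention)
    m <- resblock_l(g, params, paste0(s$p, ".dec32"),
                    op_concat(g, list(u, skip)))
    out[[nm]] <- op_sigmoid(g, conv1_l(g, params, paste0(s$p, ".head"), m))
  }
  list(g = g, out = out, streams = streams, N = N)
}

abind2 <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d[1], d[2], d[3] + dim(b)[3], d[4]))
  out[, , seq_len(d[3]), ] <- a
  out[, , d[3] + seq_len(dim(b)[3]), ] <- b
  out
}

# Extract a plain-array latent hierarchy for record n from graph nodes.
hier_values <- function(levels, n = 1L) {
  structure(list(levels = lapply(seq_along(levels), function(i) {
    lv <- levels[[i]]
    gr <- latent_grids[i]
    list(grid = gr,
         mean = matrix(lv$mu$value[, , 1, n], gr, gr),
         std = matrix(lv$sd$value[, , 1, n], gr, gr),
         z = matrix(lv$z$value[, , 1, n], gr, gr))
  })), class = "latent_hierarchy")
}

#' @export
print.latent_hierarchy <- function(x, ...) {
  dims <- vapply(x$levels, function(l) l$grid^2, numeric(1))
  cat(sprintf("<latent_hierarchy> %d levels, flattened dims %s\n",
              length(x$levels), paste(dims, collapse = "/")))
  invisible(x)
}

#' Generate one future-segmentation sample from the prior subnet
#'
#' Runs the baseline image, encoded time-to-predict and baseline diameter
#' through the prior subnet, sampling each latent block; every call with a new
#' seed yields a new plausible future segmentation.
#'
#' @param model an [hpnet_model()].
#' @param image_t0 32x32 baseline patch in \[0,1\].
#' @param t_norm,d_norm conditioning scalars from [encode_conditioning()].
#' @param seed integer seed (or `NULL` to consume the current RNG stream).
#' @param z_mode `"sample"` (default) draws latents from the prior;
#'   `"mean"` uses the prior means (deterministic).
#' @param z_override optional list of 4 latent matrices (grids 1/2/4/8)
#'   bypassing the latent distributions.
#' @return List with `sample` (32x32 soft mask in \[0,1\]) and `hierarchy`
#'   (a `latent_hierarchy` of prior parameters and the sampled z).
#' @export
forward_prior <- function(model, image_t0, t_norm, d_norm, seed = NULL,
                          z_mode = c("sample", "mean"), z_override = NULL) {
  z_mode <- match.arg(z_mode)
  assert_patch(image_t0, "image_t0")
  res <- with_seed(seed, hpnet_forward_core(
    model, image_t0, t_norm = t_norm, d_norm = d_norm,
    mode = if (z_mode == "sample") "prior_sample" else "prior_mean",
    z_override = z_override))
  list(sample = matrix(res$out$prior$value[, , 1, 1], 32, 32),
       hierarchy = hier_values(res$streams$prior$hier))
}

#' Posterior latent parameters for a nodule pair
#'
#' Runs both time-point images through the posterior subnet and returns the
#' diagonal-Gaussian latent parameters at the 4 hierarchy levels. Finer levels
#' are conditioned on the posterior means, so the result is deterministic.
#'
#' @inheritParams forward_prior
#' @param image_t1 32x32 follow-up patch in \[0,1\].
#' @return A `latent_hierarchy` (the `z` slots hold the posterior means).
#' @export
forward_posterior <- function(model, image_t0, image_t1, t_norm, d_norm) {
  if (is.null(image_t1)) stopf("forward_posterior requires image_t1")
  assert_patch(image_t0, "image_t0"); assert_patch(image_t1, "image_t1")
  res <- hpnet_forward_core(model, image_t0, image_t1, t_norm, d_norm,
                            mode = "posterior_params")
  hier_values(res$streams$post$hier)
}

#' Training-style forward pass for one record
#'
#' Runs prior and posterior subnets in lockstep: at every latent level a
#' single z is drawn from the posterior distribution (reparameterised) and
#' injected into both decoders, so the reconstruction is the prior decoder's
#' output under posterior latents and both parameter sets are available for
#' the KL term.
#'
#' @param model an [hpnet_model()].
#' @param record a [growth_record()] with both time points.
#' @param seed integer seed or `NULL`.
#' @return List with `reconstruction` (32x32 soft mask), `prior` and
#'   `posterior` latent hierarchies.
#' @export
forward_train <- function(model, record, seed = NULL) {
  if (is.null(record$image_t1)) stopf("forward_train requires image_t1")
  cond <- encode_conditioning(record$elapsed_days, record$d0_mm)
  res <- with_seed(seed, hpnet_forward_core(
    model, record$image_t0, record$image_t1, cond$t_norm, cond$d_norm,
    mode = "train"))
  list(reconstruction = matrix(res$out$prior$value[, , 1, 1], 32, 32),
       prior = hier_values(res$streams$prior$hier),
       posterior = hier_values(res$streams$post$hier))
}

#' Reparameterised sampling from one latent level
#'
#' `z = mean + std * eps` with standard-normal `eps`; `std` 0 is allowed
#' (degenerate, `z = mean`), negative values are an error.
#'
#' @param level list with `mean` and `std` (equal-shaped numerics, std >= 0).
#' @param seed integer seed or `NULL`.
#' @return Sampled `z` with the shape of `mean`.
#' @export
sample_latent <- function(level, seed = NULL) {
  if (any(level$std < 0)) stopf("latent std must be >= 0")
  with_seed(seed, level$mean + level$std * stats::rnorm(length(level$mean)))
}

#' Attention-gate a skip connection
#'
#' Computes additive attention coefficients `alpha = sigmoid(psi(relu(Wx x +
#' Wg g)))` in \[0,1\] from the skip and gating features and returns the
#' element-wise gated skip. With `use_attention = FALSE` the skip passes
#' through unchanged.
#'
#' @param skip (H, W, C) array (or H x W matrix) of skip features.
#' @param gating equal-spatial-shape gating features.
#' @param weights list with conv entries `wx.W, wx.b, wg.W, wg.b, psi.W,
#'   psi.b` as produced by the model initialiser.
#' @param use_attention logical switch.
#' @return Gated features with the shape of `skip`.
#' @export
attention_gate <- function(skip, gating, weights = NULL, use_attention = TRUE) {
  if (!use_attention) return(skip)
  if (is.null(weights)) stopf("weights required when use_attention is TRUE")
  tow <- function(x) {
    if (is.matrix(x)) x <- array(x, c(dim(x), 1))
    array(x, c(dim(x)[1:2], dim(x)[3], 1))
  }
  xs <- tow(skip); gs <- tow(gating)
  if (!all(dim(xs)[1:2] == dim(gs)[1:2])) {
    stopf("skip and gating spatial shapes differ")
  }
  g <- ad_graph()
  pl <- stats::setNames(weights, paste0("att.", names(weights)))
  out <- attn_l(g, pl, "att", op_const(g, xs), op_const(g, gs), TRUE)
  res <- out$value[, , , 1, drop = TRUE]
  if (is.matrix(skip)) matrix(res, nrow(skip), ncol(skip)) else res
}
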