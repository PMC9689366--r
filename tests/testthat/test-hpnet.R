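small_model <- function(f = 2, seed = 1, ...) {
  hpnet_model(network_config(base_filters = f, seed = seed, ...))
}

test_that("prior forward pass is deterministic, bounded and stochastic", {
  m <- small_model()
  p <- render_nodule(8, 0, 0.75, seed = 3)
  a <- forward_prior(m, p$image, 0.5, 0.3, seed = 7)
  b <- forward_prior(m, p$image, 0.5, 0.3, seed = 7)
  expect_identical(a$sample, b$sample)
  expect_true(all(a$sample >= 0 & a$sample <= 1))
  # different seeds explore the latent space: nonzero per-pixel variance
  samples <- sapply(1:20, function(s) {
    forward_prior(m, p$image, 0.5, 0.3, seed = s)$sample
  })
  expect_gt(max(apply(samples, 1, var)), 0)
})

test_that("latent hierarchy has flattened dims 1/4/16/64 with positive std", {
  for (f in c(2, 3)) {
    m <- small_model(f)
    p <- render_nodule(8, 0, 0.75, seed = 3)
    h <- forward_prior(m, p$image, 0.2, 0.4, seed = 1)$hierarchy
    expect_equal(vapply(h$levels, function(l) length(l$z), numeric(1)),
                 c(1, 4, 16, 64))
    expect_true(all(vapply(h$levels, function(l) all(l$std > 0), logical(1))))
  }
})

test_that("forcing the latents removes all seed dependence", {
  m <- small_model()
  p <- render_nodule(8, 0, 0.75, seed = 3)
  zs <- lapply(c(1, 2, 4, 8), function(g) matrix(0.1, g, g))
  a <- forward_prior(m, p$image, 0.5, 0.3, seed = 1, z_override = zs)
  b <- forward_prior(m, p$image, 0.5, 0.3, seed = 999, z_override = zs)
  expect_identical(a$sample, b$sample)
  d <- forward_prior(m, p$image, 0.5, 0.3, z_mode = "mean")
  e <- forward_prior(m, p$image, 0.5, 0.3, z_mode = "mean")
  expect_identical(d$sample, e$sample)
})

test_that("posterior params are finite, positive-std and need both images", {
  m <- small_model()
  p <- render_nodule(8, 0, 0.75, seed = 3)
  expect_error(forward_posterior(m, p$image, NULL, 0.5, 0.3), "image_t1")
  set.seed(5)
  for (i in 1:50) {
    i0 <- matrix(runif(1024), 32, 32)
    i1 <- matrix(runif(1024), 32, 32)
    h <- forward_posterior(m, i0, i1, runif(1), runif(1))
    for (l in h$levels) {
      expect_true(all(is.finite(l$mean)) && all(is.finite(l$std)))
      expect_true(all(l$std > 0))
    }
  }
})

test_that("posterior equals prior when weights are shared and I1 is ignored", {
  m <- small_model(f = 2, seed = 8)
  # copy every prior parameter into the posterior twin
  for (nm in grep("^prior\\.", names(m$params), value = TRUE)) {
    tgt <- sub("^prior\\.", "post.", nm)
    if (nm == "prior.enc1.c1.W" || nm == "prior.enc1.sc.W") {
      # posterior first conv has an extra input channel (I1): rows are
      # ordered offset-fastest within channel, so channel 1 rows come first
      k2 <- nrow(m$params[[nm]])
      m$params[[tgt]][] <- 0
      m$params[[tgt]][seq_len(k2), ] <- m$params[[nm]]
    } else {
      m$params[[tgt]] <- m$params[[nm]]
    }
  }
  p <- render_nodule(8, 0, 0.75, seed = 3)
  i1 <- matrix(runif(1024), 32, 32)
  hq <- forward_posterior(m, p$image, i1, 0.5, 0.3)
  hp <- forward_prior(m, p$image, 0.5, 0.3, z_mode = "mean")$hierarchy
  for (i in 1:4) {
    expect_equal(hq$levels[[i]]$mean, hp$levels[[i]]$mean, tolerance = 1e-12)
    expect_equal(hq$levels[[i]]$std, hp$levels[[i]]$std, tolerance = 1e-12)
  }
})

test_that("train-style forward returns both hierarchies and a valid mask", {
  m <- small_model()
  co <- tiny_cohort(2, 1, seed = 4)
  ft <- forward_train(m, co$records[[1]], seed = 2)
  expect_true(all(ft$reconstruction >= 0 & ft$reconstruction <= 1))
  expect_equal(dim(ft$reconstruction), c(32, 32))
  expect_s3_class(ft$prior, "latent_hierarchy")
  expect_s3_class(ft$posterior, "latent_hierarchy")
  # injected z is the shared posterior sample at every level
  for (i in 1:4) {
    expect_identical(ft$prior$levels[[i]]$z, ft$posterior$levels[[i]]$z)
  }
})

test_that("reconstruction gradients flow through the posterior means", {
  m <- small_model(f = 2, seed = 3)
  co <- tiny_cohort(2, 1, seed = 4)
  r <- co$records[[1]]
  cfg <- training_config(beta = 0, reconstruction_mode = "iou_only")
  loss_at <- function(shift) {
    m2 <- m
    m2$params[["post.lat1.mu.b"]] <- m2$params[["post.lat1.mu.b"]] + shift
    as.numeric(elbo_loss(r, m2, cfg, seed = 11))
  }
  h <- 1e-4
  fd <- (loss_at(h) - loss_at(-h)) / (2 * h)
  expect_true(is.finite(fd))
  expect_gt(abs(fd), 1e-8)
})

test_that("attention gating is an identity when disabled and bounded when on", {
  skip <- array(runif(8 * 8 * 4, -1, 1), c(8, 8, 4))
  gating <- array(runif(8 * 8 * 4), c(8, 8, 4))
  expect_identical(attention_gate(skip, gating, use_attention = FALSE), skip)
  set.seed(6)
  w <- list()
  w <- nodugrowth:::add_conv(w, "wx", 1, 4, 4)
  w <- nodugrowth:::add_conv(w, "wg", 1, 4, 4)
  w <- nodugrowth:::add_conv(w, "psi", 1, 4, 1)
  out <- attention_gate(skip, gating, w)
  expect_true(all(abs(out) <= abs(skip) + 1e-12))
  # zero conv weights: alpha collapses to a constant sigmoid of the biases
  w0 <- w
  w0$wx.W[] <- 0; w0$wg.W[] <- 0; w0$psi.W[] <- 0
  w0$psi.b <- 0.7
  out0 <- attention_gate(skip, gating, w0)
  expect_equal(out0, skip * (1 / (1 + exp(-0.7))), tolerance = 1e-12)
})

test_that("latent sampling is reparameterised and seed-exact", {
  lvl <- list(mean = matrix(1:4 / 2, 2, 2), std = matrix(0, 2, 2))
  expect_equal(sample_latent(lvl, seed = 1), lvl$mean)
  lvl$std <- matrix(0.5, 2, 2)
  expect_identical(sample_latent(lvl, seed = 9), sample_latent(lvl, seed = 9))
  expect_error(sample_latent(list(mean = 0, std = -1)), "std")
  set.seed(2)
  z <- replicate(1e5, 0 + 1 * rnorm(1))  # reference moments
  zs <- sample_latent(list(mean = rep(0, 1e5), std = rep(1, 1e5)), seed = 3)
  expect_lt(abs(mean(zs)), 3 / sqrt(1e5))
  expect_lt(abs(stats::sd(zs) - 1), 3 / sqrt(2 * 1e5))
})

test_that("checkpoints round-trip the weights and configuration", {
  m <- small_model(f = 2, seed = 10, use_attention = FALSE)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_equal(m2$params, m$params)
  expect_equal(m2$config$use_attention, FALSE)
  p <- render_nodule(8, 0, 0.75, seed = 3)
  expect_identical(forward_prior(m, p$image, 0.5, 0.3, seed = 4)$sample,
                   forward_prior(m2, p$image, 0.5, 0.3, seed = 4)$sample)
})

test_that("ablation toggles change only the intended parameters", {
  full <- small_model(f = 2, seed = 1)
  noatt <- small_model(f = 2, seed = 1, use_attention = FALSE)
  expect_true(any(grepl("att", names(full$params))))
  expect_false(any(grepl("att", names(noatt$params))))
  nod0 <- small_model(f = 2, seed = 1, use_d0_input = FALSE)
  # conditioning conv loses one input channel
  expect_equal(nrow(full$params[["prior.cond.W"]]) -
                 nrow(nod0$params[["prior.cond.W"]]), 1L)
  # posterior exceeds prior only by the extra I1 input channel
  count <- function(m, p) {
    sum(vapply(m$params[grep(paste0("^", p, "\\."), names(m$params))],
               length, numeric(1)))
  }
  extra <- count(full, "post") - count(full, "prior")
  expect_equal(extra, 9 * 1 * 2 + 1 * 2)  # 3x3 conv + 1x1 shortcut rows
})
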