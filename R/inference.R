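#' Longest diameter of a binary mask
#'
#' Takes the largest 4-connected foreground component and returns the maximum
#' pairwise Euclidean distance between its pixel centres plus one pixel
#' extent, scaled by the spacing (so a single pixel measures one spacing and
#' a rendered disk returns its nominal diameter). An empty mask measures 0.
#'
#' @param mask binary matrix.
#' @param spacing_mm pixel spacing (mm/pixel).
#' @return Diameter in mm.
#' @export
extract_longest_diameter <- function(mask, spacing_mm = 1) {
  if (sum(mask) == 0) return(0)
  lab <- EBImage::bwlabel(mask)
  tab <- tabulate(lab[lab > 0])
  keep <- which.max(tab)
  idx <- which(lab == keep, arr.ind = TRUE)
  if (nrow(idx) == 1) return(spacing_mm)
  pts <- idx
  if (nrow(pts) > 50) {
    hull <- grDevices::chull(pts[, 1], pts[, 2])
    pts <- pts[hull, , drop = FALSE]
  }
  (max(stats::dist(pts)) + 1) * spacing_mm
}

#' Logistic growth probability
#'
#' Maps a growth size (mm) to the probability that growth exceeds the 2 mm
#' clinical threshold: `F(delta) = 1 / (1 + exp(-(delta - 2)))`, a strictly
#' increasing bijection onto (0,1) with midpoint 0.5 at 2 mm.
#'
#' @param delta_mm growth size(s) in mm.
#' @return Probability vector in (0,1).
#' @export
growth_probability <- function(delta_mm) {
  1 / (1 + exp(-(delta_mm - 2)))
}

#' Monte-Carlo growth prediction from a baseline patch
#'
#' Draws `K` stochastic future segmentations from the prior subnet, extracts
#' each sample's longest diameter after thresholding, and summarises the
#' growth sizes `delta_k = D1'_k - D0` into the growth estimate: mean and
#' (population) standard deviation of the sizes, of the per-sample logistic
#' growth probabilities, and per-pixel mean/std images of the soft samples.
#'
#' @param model an [hpnet_model()], or a sampler `function(K, seed)` returning
#'   a 32 x 32 x K array of soft masks (used for stubs and alternative
#'   generators).
#' @param image_t0 32x32 baseline patch (ignored when `model` is a sampler
#'   function).
#' @param t_norm,d_norm conditioning scalars from [encode_conditioning()].
#' @param d0_mm baseline diameter (mm) used to convert diameters to growths.
#' @param spacing_mm pixel spacing (mm/pixel).
#' @param K number of Monte-Carlo samples.
#' @param threshold binarisation threshold applied before diameter
#'   extraction.
#' @param seed integer seed; the whole estimate is deterministic given it.
#' @param batch_size samples generated per network pass.
#' @return Object of class `growth_estimate` with fields `deltas`,
#'   `delta_mean`, `delta_std`, `prob_mean`, `prob_std`, `mean_image`,
#'   `std_image`, `K`, `d0_mm`, and logical `all_empty` flagging the
#'   degenerate case where every sampled mask was empty (each delta then
#'   equals `-d0_mm`).
#' @export
monte_carlo_predict <- function(model, image_t0 = NULL, t_norm = 0,
                                d_norm = 0, d0_mm, spacing_mm = 0.75,
                                K = 1000L, threshold = 0.5, seed = 1L,
                                batch_size = 32L) {
  K <- as.integer(K)
  if (K < 1) stopf("K must be >= 1")
  soft <- if (is.function(model)) {
    s <- model(K, seed)
    if (!all(dim(s)[1:2] == c(32, 32)) || dim(s)[3] != K) {
      stopf("sampler function must return a 32x32xK array")
    }
    s
  } else if (inherits(model, "hpnet_model")) {
    if (is.null(image_t0)) stopf("image_t0 required for a network model")
    assert_patch(image_t0, "image_t0")
    out <- array(0, c(32, 32, K))
    with_seed(seed, {
      done <- 0L
      while (done < K) {
        B <- min(batch_size, K - done)
        res <- hpnet_forward_core(model, as_batch(image_t0, B),
                                  t_norm = rep(t_norm, B),
                                  d_norm = rep(d_norm, B),
                                  mode = "prior_sample")
        out[, , done + seq_len(B)] <- res$out$prior$value[, , 1, ]
        done <- done + B
      }
    })
    out
  } else {
    stopf("model must be an hpnet_model or a sampler function")
  }
  d1 <- vapply(seq_len(K), function(k) {
    extract_longest_diameter(matrix(as.numeric(soft[, , k] > threshold),
                                    32, 32), spacing_mm)
  }, numeric(1))
  deltas <- d1 - d0_mm
  probs <- growth_probability(deltas)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  mean_image <- apply(soft, c(1, 2), mean)
  std_image <- sqrt(pmax(apply(soft^2, c(1, 2), mean) - mean_image^2, 0))
  structure(list(
    deltas = deltas, delta_mean = mean(deltas), delta_std = pop_sd(deltas),
    prob_mean = mean(probs), prob_std = pop_sd(probs),
    mean_image = mean_image, std_image = std_image,
    K = K, d0_mm = d0_mm, all_empty = all(d1 == 0)
  ), class = "growth_estimate")
}

#' @export
print.growth_estimate <- function(x, ...) {
  cat(sprintf(paste0("<growth_estimate> K=%d  growth %.2f +/- %.2f mm  ",
                     "P(growth) %.2f +/- %.2f\n"),
              x$K, x$delta_mean, x$delta_std, x$prob_mean, x$prob_std))
  invisible(x)
}

#' Binary growth decision from a growth estimate
#'
#' Growth is called when the mean logistic growth probability exceeds 0.5
#' (strictly), i.e. when the Monte-Carlo evidence puts the growth size above
#' the 2 mm guideline threshold.
#'
#' @param estimate a `growth_estimate`.
#' @return 0 or 1.
#' @export
classify_growth <- function(estimate) {
  as.integer(estimate$prob_mean > 0.5)
}
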