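#' Parameters of the synthetic longitudinal nodule cohort
#'
#' Defaults emulate the statistics of the clinical cohort the method was
#' designed around: baseline diameters of at least 5 mm, growth of roughly
#' 2.5--2.8 +/- 3.6--4.0 mm across annotators, inter-observer diameter noise
#' with standard deviation 0.97 mm, and scan intervals between 32 and 2464
#' days. Growth depends on the encoded time-to-predict (longer intervals grow
#' more on average) and leaves a visually learnable trace: the baseline nodule
#' texture intensity is monotone in the subsequent true growth, with strength
#' `signal_strength` (0 removes the signal; this is a test-harness device, not
#' a biological claim).
#'
#' @param n_nodules number of unique nodules.
#' @param n_annotators number of annotating radiologists (1--3).
#' @param d0_range_mm range of true baseline diameters (mm).
#' @param growth_mean_mm base mean growth (mm); the realised mean for a nodule
#'   is `growth_mean_mm * (0.5 + t_norm)` with `t_norm` the encoded time bin.
#' @param growth_std_mm standard deviation of growth (mm).
#' @param annotator_noise_std_mm per-measurement annotator noise (mm).
#' @param time_range_days range of elapsed days, sampled log-uniformly.
#' @param irregularity boundary perturbation amplitude in \[0,1\].
#' @param spacing_mm baseline pixel spacing (mm/pixel); enlarged per nodule
#'   when needed so the lesion fits the 32x32 patch.
#' @param dropout per-(nodule, annotator) probability that the annotation is
#'   missing, mirroring unequal per-radiologist counts.
#' @param signal_strength multiplier of the texture-growth correlation.
#' @param seed integer seed making the whole cohort deterministic.
#' @return A `simulation_params` list.
#' @export
simulation_params <- function(n_nodules = 122L, n_annotators = 3L,
                              d0_range_mm = c(5, 25), growth_mean_mm = 2.6,
                              growth_std_mm = 3.8,
                              annotator_noise_std_mm = 0.97,
                              time_range_days = c(32, 2464),
                              irregularity = 0.2, spacing_mm = 0.75,
                              dropout = 0.15, signal_strength = 1,
                              seed = 1L) {
  if (diff(d0_range_mm) < 0 || diff(time_range_days) < 0) {
    stopf("parameter ranges must be ordered")
  }
  if (annotator_noise_std_mm < 0 || growth_std_mm < 0) {
    stopf("noise standard deviations must be >= 0")
  }
  if (!n_annotators %in% 1:3) stopf("n_annotators must be 1, 2 or 3")
  if (spacing_mm <= 0) stopf("spacing_mm must be > 0")
  structure(list(
    n_nodules = as.integer(n_nodules), n_annotators = as.integer(n_annotators),
    d0_range_mm = d0_range_mm, growth_mean_mm = growth_mean_mm,
    growth_std_mm = growth_std_mm,
    annotator_noise_std_mm = annotator_noise_std_mm,
    time_range_days = time_range_days, irregularity = irregularity,
    spacing_mm = spacing_mm, dropout = dropout,
    signal_strength = signal_strength, seed = as.integer(seed)
  ), class = "simulation_params")
}

#' Render a synthetic nodule patch and mask
#'
#' The nodule is a star-convex shape: the angular radius profile is a smooth
#' random harmonic perturbation of a disk, rescaled so that the maximum
#' caliper width matches the requested diameter under the pixel-extent
#' convention of [extract_longest_diameter()]. The intensity patch is the mask
#' at level `intensity`, Gaussian-blurred, with additive background noise.
#'
#' @param diameter_mm target longest diameter (mm); must fit the patch
#'   (`diameter_mm <= 0.9 * 32 * spacing_mm`).
#' @param irregularity boundary perturbation amplitude in \[0,1\]; 0 gives a
#'   seed-invariant disk.
#' @param spacing_mm pixel spacing (mm/pixel).
#' @param seed integer seed (or `NULL` to consume the current RNG stream).
#' @param intensity interior intensity level in (0,1).
#' @return List with `image` and `mask`, both 32x32 matrices.
#' @export
render_nodule <- function(diameter_mm, irregularity = 0, spacing_mm = 0.75,
                          seed = NULL, intensity = 0.55) {
  if (diameter_mm > 0.9 * 32 * spacing_mm) {
    stopf("diameter %.1f mm exceeds the patch extent at spacing %.2f mm/px",
          diameter_mm, spacing_mm)
  }
  with_seed(seed, {
    r0 <- max((diameter_mm / spacing_mm - 1) / 2, 0.6)
    theta_fn <- if (irregularity > 0) {
      kk <- 2:5
      amp <- stats::runif(length(kk), 0, 1)
      phi <- stats::runif(length(kk), 0, 2 * pi)
      raw_un <- function(th) {
        rowSums(sapply(seq_along(kk),
                       function(i) amp[i] * cos(kk[i] * th + phi[i])))
      }
      fine <- seq(0, 2 * pi, length.out = 721)[-721]
      norm <- max(1e-9, max(abs(raw_un(fine))))
      raw <- function(th) raw_un(th) / norm
      # rescale so the widest caliper width equals 2*r0
      rr <- r0 * (1 + irregularity * raw(fine))
      width <- rr[1:360] + rr[c(361:720)]
      sc <- 2 * r0 / max(width)
      function(th) pmax(0.8, sc * r0 * (1 + irregularity * raw(th)))
    } else {
      function(th) rep(r0, length(th))
    }
    ctr <- (32 - 1) / 2
    dx <- rep(seq_len(32) - 1 - ctr, times = 32)
    dy <- rep(seq_len(32) - 1 - ctr, each = 32)
    th <- atan2(dy, dx)
    rad <- sqrt(dx^2 + dy^2)
    mask <- matrix(as.numeric(rad <= theta_fn(th %% (2 * pi))), 32, 32)
    img <- gaussian_blur(mask * intensity, sigma = 1) +
      stats::rnorm(32 * 32, 0, 0.02)
    list(image = matrix(clamp(img, 0, 1), 32, 32), mask = mask)
  })
}

# Small separable Gaussian blur (reflection padding), as a linear operator.
gaussian_blur <- function(m, sigma = 1) {
  r <- max(1L, ceiling(2 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  n <- nrow(m)
  reflect <- function(j) ifelse(j < 1, 2 - j, ifelse(j > n, 2 * n - j, j))
  C <- matrix(0, n, n)
  for (o in -r:r) {
    src <- reflect(seq_len(n) + o)
    C[cbind(seq_len(n), src)] <- C[cbind(seq_len(n), src)] + k[o + r + 1]
  }
  C %*% m %*% t(C)
}

#' Simulate the true future diameter of a nodule
#'
#' Growth is drawn from `Normal(growth_mean_mm * (0.5 + t_norm),
#' growth_std_mm)` so that longer prediction horizons grow more on average;
#' the future diameter is floored at 0.
#'
#' @param d0_mm true baseline diameter (mm).
#' @param t_norm encoded time bin in \[0,1\] (see [encode_conditioning()]).
#' @param params a [simulation_params()] object.
#' @param seed integer seed or `NULL`.
#' @return The true follow-up diameter `d1_true` in mm.
#' @export
simulate_growth <- function(d0_mm, t_norm, params, seed = NULL) {
  with_seed(seed, {
    g <- stats::rnorm(1, params$growth_mean_mm * (0.5 + t_norm),
                      params$growth_std_mm)
    max(0, d0_mm + g)
  })
}

#' Simulate per-annotator diameter measurements
#'
#' Each annotator reports the true diameter plus independent Gaussian noise,
#' floored at 0.5 mm. With noise standard deviation s, pairwise differences
#' between annotators have standard deviation s*sqrt(2) and mean absolute
#' difference 2s/sqrt(pi).
#'
#' @param d_true_mm true diameter (mm).
#' @param params a [simulation_params()] object.
#' @param seed integer seed or `NULL`.
#' @return Numeric vector of length `params$n_annotators`.
#' @export
simulate_annotators <- function(d_true_mm, params, seed = NULL) {
  with_seed(seed, {
    pmax(0.5, d_true_mm +
           stats::rnorm(params$n_annotators, 0, params$annotator_noise_std_mm))
  })
}

#' Generate a synthetic multi-annotator growth cohort
#'
#' For each nodule: draw the true baseline diameter and a log-uniform scan
#' interval, simulate true growth and per-annotator measurements at both time
#' points, drop annotations at rate `dropout` (keeping at least one), render
#' the baseline and follow-up patches from the true diameters (shared by all
#' annotators of the nodule, as in a real scan pair), and emit one
#' [growth_record()] per retained annotator. The per-record pixel spacing is
#' enlarged beyond `spacing_mm` when needed so the lesion fits the patch.
#'
#' @param params a [simulation_params()] object.
#' @return A [growth_cohort()] with a `sim_summary` attribute holding the
#'   realised growth and inter-observer statistics for calibration checks.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  with_seed(params$seed, {
    recs <- list()
    truth <- data.frame()
    ann_ids <- paste0("RX", 0:2)[seq_len(params$n_annotators)]
    for (i in seq_len(params$n_nodules)) {
      d0_true <- stats::runif(1, params$d0_range_mm[1], params$d0_range_mm[2])
      lt <- log(params$time_range_days)
      elapsed <- as.integer(round(exp(stats::runif(1, lt[1], lt[2]))))
      elapsed <- min(max(elapsed, params$time_range_days[1]),
                     params$time_range_days[2])
      t_norm <- encode_conditioning(elapsed, d0_true)$t_norm
      d1_true <- simulate_growth(d0_true, t_norm, params)
      g_true <- d1_true - d0_true
      d0_ann <- pmax(5, simulate_annotators(d0_true, params))
      d1_ann <- simulate_annotators(d1_true, params)
      keep <- stats::runif(params$n_annotators) >= params$dropout
      if (!any(keep)) keep[1] <- TRUE
      spacing <- max(params$spacing_mm,
                     1.05 * max(d0_true, d1_true) / (0.9 * 32))
      int0 <- clamp(0.45 + 0.04 * params$signal_strength * g_true, 0.15, 0.95)
      p0 <- render_nodule(d0_true, params$irregularity, spacing,
                          intensity = int0)
      p1 <- render_nodule(max(d1_true, spacing), params$irregularity, spacing,
                          intensity = 0.55)
      nid <- sprintf("N%04d", i)
      for (a in which(keep)) {
        recs[[length(recs) + 1L]] <- growth_record(
          nodule_id = nid, annotator_id = ann_ids[a],
          image_t0 = p0$image, image_t1 = p1$image,
          mask_t0 = p0$mask, mask_t1 = p1$mask,
          d0_mm = d0_ann[a], d1_mm = d1_ann[a],
          elapsed_days = elapsed, spacing_mm = spacing
        )
      }
      truth <- rbind(truth, data.frame(nodule_id = nid, d0_true = d0_true,
                                       d1_true = d1_true, g_true = g_true,
                                       elapsed_days = elapsed))
    }
    cohort <- growth_cohort(recs)
    g_ann <- vapply(recs, function(r) r$d1_mm - r$d0_mm, numeric(1))
    attr(cohort, "sim_summary") <- list(
      truth = truth,
      growth_mean_mm = mean(g_ann), growth_sd_mm = stats::sd(g_ann),
      n_records = length(recs)
    )
    cohort
  })
}
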