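# Independent oracles and fixture builders used across the suite.

# Binary disk of a given (even) diameter centred between pixels, following
# the pixel-extent convention: pixels within (d/spacing - 1)/2 of the centre,
# so extract_longest_diameter returns the nominal diameter.
disk_mask <- function(diameter_mm, spacing_mm = 1, size = 32L,
                      center = c(16.5, 16.5)) {
  r <- (diameter_mm / spacing_mm - 1) / 2
  i <- rep(seq_len(size), times = size) - center[1]
  j <- rep(seq_len(size), each = size) - center[2]
  matrix(as.numeric(i^2 + j^2 <= r^2 + 1e-9), size, size)
}

# Pixel-centred rasterised circle of a given radius in pixels.
circle_px <- function(radius_px, size = 32L, center = c(16, 16)) {
  i <- rep(seq_len(size), times = size) - center[1]
  j <- rep(seq_len(size), each = size) - center[2]
  matrix(as.numeric(i^2 + j^2 <= radius_px^2 + 1e-9), size, size)
}

# Random connected-ish blob: union of a few random disks plus salt.
random_blob <- function(seed, size = 32L, p_salt = 0.01) {
  set.seed(seed)
  m <- matrix(0, size, size)
  for (k in seq_len(sample(1:3, 1))) {
    ctr <- sample(8:24, 2)
    d <- runif(1, 2, 14)
    m <- pmax(m, disk_mask(d, 1, size, ctr))
  }
  salt <- matrix(rbinom(size^2, 1, p_salt), size, size)
  pmax(m, salt)
}

# Brute-force longest diameter: flood-fill (4-connectivity, no image
# library), keep the largest component, max all-pairs distance + 1 pixel.
oracle_feret <- function(mask, spacing_mm = 1) {
  n <- nrow(mask)
  lab <- matrix(0L, n, n)
  cur <- 0L
  for (si in seq_len(n)) for (sj in seq_len(n)) {
    if (mask[si, sj] == 1 && lab[si, sj] == 0L) {
      cur <- cur + 1L
      queue <- list(c(si, sj))
      lab[si, sj] <- cur
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
          q <- p + d
          if (all(q >= 1) && all(q <= n) && mask[q[1], q[2]] == 1 &&
              lab[q[1], q[2]] == 0L) {
            lab[q[1], q[2]] <- cur
            queue[[length(queue) + 1L]] <- q
          }
        }
      }
    }
  }
  if (cur == 0L) return(0)
  sizes <- tabulate(lab[lab > 0L])
  pts <- which(lab == which.max(sizes), arr.ind = TRUE)
  if (nrow(pts) == 1) return(spacing_mm)
  best <- 0
  for (a in seq_len(nrow(pts) - 1)) for (b in (a + 1):nrow(pts)) {
    best <- max(best, sqrt(sum((pts[a, ] - pts[b, ])^2)))
  }
  (best + 1) * spacing_mm
}

# Double-loop generalized energy distance recomputation.
oracle_ged <- function(preds, gts) {
  d <- function(a, b) {
    u <- sum(pmax(a, b))
    if (u == 0) 0 else 1 - sum(a * b) / u
  }
  n <- length(preds); m <- length(gts)
  cross <- sum(vapply(preds, function(a) {
    sum(vapply(gts, function(b) d(a, b), numeric(1)))
  }, numeric(1)))
  wp <- sum(vapply(preds, function(a) {
    sum(vapply(preds, function(b) d(a, b), numeric(1)))
  }, numeric(1)))
  wg <- sum(vapply(gts, function(a) {
    sum(vapply(gts, function(b) d(a, b), numeric(1)))
  }, numeric(1)))
  2 * cross / (n * m) - wp / n^2 - wg / m^2
}

# Minimal in-memory cohort for I/O and training tests.
tiny_cohort <- function(n_nodules = 3, n_annotators = 2, seed = 99) {
  generate_cohort(simulation_params(
    n_nodules = n_nodules, n_annotators = n_annotators, dropout = 0,
    seed = seed))
}

# Single-row mask of exactly known longest diameter under the pixel-extent
# convention: n = d/spacing pixels span n - 1, plus 1 pixel extent.
bar_mask <- function(diameter_mm, spacing_mm = 1, size = 32L) {
  n <- round(diameter_mm / spacing_mm)
  m <- matrix(0, size, size)
  start <- (size - n) %/% 2 + 1
  m[16, start:(start + n - 1)] <- 1
  m
}

# Stub sampler: cycles masks with exactly the given extracted diameters.
disk_sampler <- function(diameters_mm, spacing_mm = 1) {
  function(K, seed) {
    out <- array(0, c(32, 32, K))
    for (k in seq_len(K)) {
      d <- diameters_mm[(k - 1) %% length(diameters_mm) + 1]
      out[, , k] <- bar_mask(d, spacing_mm)
    }
    out
  }
}
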