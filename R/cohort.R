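#' Construct a single nodule growth record
#'
#' A growth record is one annotator's view of one nodule pair: the baseline and
#' follow-up 32x32 intensity patches (normalised to \[0,1\]), the binary nodule
#' masks at both time points, the annotator's longest-diameter measurements
#' D0/D1 in mm, the elapsed time between scans and the pixel spacing.
#'
#' @param nodule_id,annotator_id character identifiers; the pair is unique
#'   within a cohort.
#' @param image_t0,image_t1 32x32 numeric matrices in \[0,1\]; `image_t1` may be
#'   `NULL` at pure inference time.
#' @param mask_t0,mask_t1 32x32 binary matrices; `mask_t1` is the ground-truth
#'   future segmentation.
#' @param d0_mm,d1_mm longest diameters (mm) at baseline and follow-up.
#' @param elapsed_days integer >= 1, time between the two scans.
#' @param spacing_mm pixel size in mm/pixel (> 0).
#' @param growth_label optional 0/1; recomputed from the diameters (growth
#'   means an increase of more than 2 mm) and checked if supplied.
#' @return An object of class `growth_record`.
#' @export
growth_record <- function(nodule_id, annotator_id, image_t0, mask_t0, mask_t1,
                          d0_mm, d1_mm, elapsed_days, spacing_mm,
                          image_t1 = NULL, growth_label = NULL) {
  assert_patch(image_t0, "image_t0")
  assert_patch(mask_t0, "mask_t0")
  assert_patch(mask_t1, "mask_t1")
  if (!is.null(image_t1)) assert_patch(image_t1, "image_t1")
  if (!is_binary_mask(mask_t0) || !is_binary_mask(mask_t1)) {
    stopf("masks must be binary {0,1} matrices (nodule %s)", nodule_id)
  }
  if (!is.numeric(d0_mm) || d0_mm <= 0) {
    stopf("d0_mm must be > 0 (nodule %s, got %s)", nodule_id, d0_mm)
  }
  if (d1_mm < 0) stopf("d1_mm must be >= 0 (nodule %s)", nodule_id)
  if (elapsed_days < 1) stopf("elapsed_days must be >= 1 (nodule %s)", nodule_id)
  if (spacing_mm <= 0) stopf("spacing_mm must be > 0 (nodule %s)", nodule_id)
  lab <- derive_growth_label(d0_mm, d1_mm)
  if (!is.null(growth_label) && !is.na(growth_label) && growth_label != lab) {
    stopf("growth_label %s inconsistent with diameters (nodule %s: D0=%.2f, D1=%.2f)",
          growth_label, nodule_id, d0_mm, d1_mm)
  }
  structure(list(
    nodule_id = as.character(nodule_id),
    annotator_id = as.character(annotator_id),
    image_t0 = image_t0, image_t1 = image_t1,
    mask_t0 = mask_t0, mask_t1 = mask_t1,
    d0_mm = as.numeric(d0_mm), d1_mm = as.numeric(d1_mm),
    elapsed_days = as.integer(elapsed_days),
    spacing_mm = as.numeric(spacing_mm),
    growth_label = lab
  ), class = "growth_record")
}

#' Assemble growth records into a cohort
#'
#' @param records list of [growth_record()] objects.
#' @return Object of class `growth_cohort` with elements `records` and
#'   `annotators` (sorted unique annotator ids).
#' @export
growth_cohort <- function(records) {
  keys <- vapply(records, function(r) paste(r$nodule_id, r$annotator_id, sep = "\r"),
                 character(1))
  if (anyDuplicated(keys)) {
    stopf("duplicate (nodule, annotator) pair: %s",
          gsub("\r", "/", keys[duplicated(keys)][1]))
  }
  nod <- vapply(records, `[[`, character(1), "nodule_id")
  per <- table(nod)
  if (length(per) && any(per > 3)) {
    stopf("nodule %s has %d annotator records (max 3)",
          names(per)[per > 3][1], max(per))
  }
  ann <- sort(unique(vapply(records, `[[`, character(1), "annotator_id")))
  structure(list(records = records, annotators = ann), class = "growth_cohort")
}

#' @export
print.growth_cohort <- function(x, ...) {
  nod <- unique(vapply(x$records, `[[`, character(1), "nodule_id"))
  cat(sprintf("<growth_cohort> %d records, %d unique nodules, %d annotators\n",
              length(x$records), length(nod), length(x$annotators)))
  invisible(x)
}

#' @export
length.growth_cohort <- function(x) length(x$records)

#' Derive the binary growth label from two diameters
#'
#' Growth is defined by the radiological guideline criterion: an increase of
#' the longest diameter of strictly more than 2 mm between the two scans.
#'
#' @param d0_mm,d1_mm diameters in mm (vectorised).
#' @return Integer 0/1 vector.
#' @export
derive_growth_label <- function(d0_mm, d1_mm) {
  if (any(d0_mm < 0) || any(d1_mm < 0)) stopf("diameters must be >= 0")
  as.integer(d1_mm - d0_mm > 2.0)
}

#' Encode the conditioning scalars for the network
#'
#' The time to predict is encoded ordinally over the radiological follow-up
#' categories (up to 6, 12, 24, or more than 24 months), mapped to
#' \{0, 1/3, 2/3, 1\} with day boundaries 183/365/730; the baseline diameter is
#' normalised by the conventional 30 mm nodule/mass boundary and clamped to 1.
#'
#' @param elapsed_days integer days >= 1 (vectorised).
#' @param d0_mm baseline diameter in mm > 0 (vectorised).
#' @return List with numeric vectors `t_norm` and `d_norm`, both in \[0,1\].
#' @export
encode_conditioning <- function(elapsed_days, d0_mm) {
  if (any(elapsed_days < 1)) stopf("elapsed_days must be >= 1")
  if (any(d0_mm <= 0)) stopf("d0_mm must be > 0")
  bin <- findInterval(elapsed_days, c(184, 366, 731))
  list(t_norm = bin / 3, d_norm = pmin(d0_mm, 30) / 30)
}

manifest_columns <- c("nodule_id", "annotator_id", "path_img_t0", "path_img_t1",
                      "path_mask_t0", "path_mask_t1", "d0_mm", "d1_mm",
                      "elapsed_days", "spacing_mm", "growth_label")

read_patch_nifti <- function(path, binary = FALSE, row = NA) {
  if (!file.exists(path)) stopf("row %s: patch file not found: %s", row, path)
  x <- as.array(RNifti::readNifti(path))
  if (length(dim(x)) > 2) x <- array(x, dim(x)[1:2])
  if (!is.matrix(x) || nrow(x) != 32 || ncol(x) != 32) {
    stopf("row %s: patch %s has shape %s, expected 32x32", row, path,
          paste(dim(x), collapse = "x"))
  }
  if (binary) {
    x <- matrix(as.numeric(x > 0.5), 32, 32)
  } else {
    x <- x / 65535
  }
  x
}

write_patch_nifti <- function(x, path, binary = FALSE) {
  v <- if (binary) {
    array(as.integer(round(x)), dim(x))
  } else {
    array(as.integer(round(clamp(x, 0, 1) * 65535)), dim(x))
  }
  RNifti::writeNifti(RNifti::asNifti(v), path,
                     datatype = if (binary) "uint8" else "uint16")
  invisible(path)
}

#' Load a cohort from a manifest CSV
#'
#' The manifest has one row per (nodule, annotator) pair with columns
#' `nodule_id, annotator_id, path_img_t0, path_img_t1, path_mask_t0,
#' path_mask_t1, d0_mm, d1_mm, elapsed_days, spacing_mm, growth_label`.
#' Patch paths are resolved relative to the manifest's directory; patches are
#' NIfTI files, 32x32, intensities stored as 16-bit and rescaled to \[0,1\] on
#' load. The growth label is recomputed from the diameters and checked against
#' the stored value.
#'
#' @param path path to the manifest CSV.
#' @return A [growth_cohort()].
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(manifest_columns, names(df))
  if (length(missing)) stopf("manifest missing column(s): %s",
                             paste(missing, collapse = ", "))
  base <- dirname(path)
  recs <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    rp <- function(p) if (is.na(p) || p == "") NULL else file.path(base, p)
    img1 <- rp(row$path_img_t1)
    recs[[i]] <- growth_record(
      nodule_id = row$nodule_id, annotator_id = row$annotator_id,
      image_t0 = read_patch_nifti(rp(row$path_img_t0), row = i),
      image_t1 = if (is.null(img1)) NULL else read_patch_nifti(img1, row = i),
      mask_t0 = read_patch_nifti(rp(row$path_mask_t0), binary = TRUE, row = i),
      mask_t1 = read_patch_nifti(rp(row$path_mask_t1), binary = TRUE, row = i),
      d0_mm = row$d0_mm, d1_mm = row$d1_mm,
      elapsed_days = row$elapsed_days, spacing_mm = row$spacing_mm,
      growth_label = row$growth_label
    )
  }
  growth_cohort(recs)
}

#' Write a cohort to a directory as patches plus a manifest CSV
#'
#' Writes one NIfTI file per patch/mask (16-bit intensities, 8-bit masks) and a
#' manifest referencing them with paths relative to the directory, so that
#' [load_manifest()] inverts the operation.
#'
#' @param cohort a [growth_cohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(cohort$records)
  df <- data.frame(matrix(nrow = n, ncol = length(manifest_columns)))
  names(df) <- manifest_columns
  for (i in seq_len(n)) {
    r <- cohort$records[[i]]
    stem <- sprintf("%s_%s", r$nodule_id, r$annotator_id)
    f <- c(img_t0 = sprintf("%s_img_t0.nii.gz", stem),
           img_t1 = sprintf("%s_img_t1.nii.gz", stem),
           mask_t0 = sprintf("%s_mask_t0.nii.gz", stem),
           mask_t1 = sprintf("%s_mask_t1.nii.gz", stem))
    write_patch_nifti(r$image_t0, file.path(dir, f["img_t0"]))
    if (!is.null(r$image_t1)) {
      write_patch_nifti(r$image_t1, file.path(dir, f["img_t1"]))
    } else {
      f["img_t1"] <- ""
    }
    write_patch_nifti(r$mask_t0, file.path(dir, f["mask_t0"]), binary = TRUE)
    write_patch_nifti(r$mask_t1, file.path(dir, f["mask_t1"]), binary = TRUE)
    df[i, ] <- list(r$nodule_id, r$annotator_id, f[["img_t0"]], f[["img_t1"]],
                    f[["mask_t0"]], f[["mask_t1"]], r$d0_mm, r$d1_mm,
                    r$elapsed_days, r$spacing_mm, r$growth_label)
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(df, manifest, row.names = FALSE)
  invisible(manifest)
}

#' Split a cohort by nodule into training and test parts
#'
#' All records of a nodule go to the same side, so no nodule appears in both
#' outputs (leakage-free longitudinal splitting).
#'
#' @param cohort a [growth_cohort()].
#' @param train_fraction fraction of unique nodules in the training part
#'   (0 < f < 1).
#' @param seed integer seed; the split is deterministic given the seed.
#' @return List with cohorts `train` and `test`.
#' @export
split_by_nodule <- function(cohort, train_fraction = 0.7, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stopf("train_fraction must be in (0, 1)")
  }
  nod <- unique(vapply(cohort$records, `[[`, character(1), "nodule_id"))
  if (length(nod) < 2) stopf("need at least 2 unique nodules to split")
  ntr <- max(1L, min(length(nod) - 1L, round(train_fraction * length(nod))))
  tr <- with_seed(seed, sample(nod, ntr))
  in_tr <- vapply(cohort$records, function(r) r$nodule_id %in% tr, logical(1))
  list(train = growth_cohort(cohort$records[in_tr]),
       test = growth_cohort(cohort$records[!in_tr]))
}
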