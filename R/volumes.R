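#' Multi-channel MR volume
#'
#' Container for a skull-stripped, co-registered 4-channel brain MR study.
#' Channels are held in the fixed order FLAIR, T1, T2, T1ce as a single
#' numeric array of dimension `(X, Y, Z, 4)`.
#'
#' @param data numeric 4-D array `(X, Y, Z, 4)`, or a named list of four
#'   identically shaped 3-D arrays with names among FLAIR, T1, T2, T1ce.
#' @param spacing voxel size in mm along each axis (default 1 mm isotropic).
#' @param reference optional NIfTI header (from [RNifti::niftiHeader()]) used
#'   to carry geometry through to [write_volume()] untouched.
#' @return An object of class `mc_volume`.
#' @export
mc_volume <- function(data, spacing = c(1, 1, 1), reference = NULL) {
  if (is.list(data) && !is.array(data)) {
    missing <- setdiff(MR_CHANNELS, names(data))
    if (length(missing) > 0L)
      stop("missing channel(s): ", paste(missing, collapse = ", "))
    shapes <- lapply(data[MR_CHANNELS], dim)
    if (!all(vapply(shapes, identical, logical(1), shapes[[1]])))
      stop("channel shape mismatch: all four channels must be identically shaped")
    arr <- array(0, c(shapes[[1]], 4L))
    for (i in seq_along(MR_CHANNELS)) arr[, , , i] <- data[[MR_CHANNELS[i]]]
    data <- arr
  }
  if (length(dim(data)) != 4L || dim(data)[4] != 4L)
    stop("data must be an (X, Y, Z, 4) array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three strictly positive values (mm)")
  dimnames(data) <- c(vector("list", 3L), list(MR_CHANNELS))
  structure(list(data = data, spacing = spacing, reference = reference),
            class = "mc_volume")
}

#' @export
print.mc_volume <- function(x, ...) {
  d <- dim(x$data)
  cat("Multi-channel MR volume\n")
  cat(sprintf("  shape   : %d x %d x %d voxels\n", d[1], d[2], d[3]))
  cat(sprintf("  spacing : %s mm\n", paste(format(x$spacing), collapse = " x ")))
  cat(sprintf("  channels: %s\n", paste(MR_CHANNELS, collapse = ", ")))
  invisible(x)
}

#' @export
dim.mc_volume <- function(x) dim(x$data)[1:3]

#' Per-voxel tissue label volume
#'
#' Integer labels in the file convention 0 (background/healthy),
#' 1 (necrosis/non-enhancing), 2 (edema), 4 (enhancing tumor).
#'
#' @param labels 3-D integer array with values in `{0, 1, 2, 4}`.
#' @param spacing voxel size in mm per axis.
#' @param reference optional NIfTI header carried through on write.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing = c(1, 1, 1), reference = NULL) {
  if (length(dim(labels)) != 3L) stop("labels must be a 3-D array")
  storage.mode(labels) <- "integer"
  check_label_values(labels)
  structure(list(labels = labels, spacing = as.numeric(spacing),
                 reference = reference),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  tab <- table(factor(as.vector(x$labels), levels = FILE_LABELS))
  cat("Tissue label volume\n")
  cat(sprintf("  shape: %d x %d x %d voxels\n", d[1], d[2], d[3]))
  cat(sprintf("  voxels: background %s | necrosis %s | edema %s | enhancing %s\n",
              tab[["0"]], tab[["1"]], tab[["2"]], tab[["4"]]))
  invisible(x)
}

#' @export
dim.label_volume <- function(x) dim(x$labels)

# Resolve the file for one channel inside a study directory. T1 must not
# swallow T1ce/T1Gd, so contrast-enhanced aliases are matched first.
find_channel_file <- function(files, channel) {
  base <- tolower(basename(files))
  pat <- switch(channel,
    FLAIR = "flair",
    T1ce  = "t1ce|t1gd|t1c\\b|t1_ce",
    T2    = "(^|[^1])t2",
    T1    = "t1")
  hit <- grepl(pat, base)
  if (channel == "T1") hit <- hit & !grepl("t1ce|t1gd|t1c\\b|t1_ce", base)
  files[hit]
}

#' Read a volume from NIfTI
#'
#' A directory containing the four per-channel NIfTI files (identified by
#' FLAIR/T1/T2/T1ce in their file names) is read as an [mc_volume()]; a single
#' NIfTI file is read as a [label_volume()]. Geometry metadata is preserved
#' and passed through on write.
#'
#' @param path a NIfTI file (label volume) or a directory of four channel files.
#' @return An `mc_volume` or `label_volume`.
#' @export
read_volume <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
    chans <- list()
    ref <- NULL
    spacing <- c(1, 1, 1)
    for (ch in MR_CHANNELS) {
      f <- find_channel_file(files, ch)
      if (length(f) == 0L) stop("missing channel: ", ch, " (no matching file in ", path, ")")
      img <- RNifti::readNifti(f[1])
      if (is.null(ref)) {
        ref <- RNifti::niftiHeader(img)
        spacing <- RNifti::pixdim(img)[1:3]
      }
      chans[[ch]] <- array(as.numeric(img), dim(img))
    }
    shapes <- lapply(chans, dim)
    if (!all(vapply(shapes, identical, logical(1), shapes[[1]])))
      stop("channel shape mismatch across NIfTI files in ", path)
    mc_volume(chans, spacing = spacing, reference = ref)
  } else if (file.exists(path)) {
    img <- RNifti::readNifti(path)
    label_volume(array(as.integer(round(img)), dim(img)),
                 spacing = RNifti::pixdim(img)[1:3],
                 reference = RNifti::niftiHeader(img))
  } else {
    stop("path does not exist: ", path)
  }
}

#' Write a volume to NIfTI
#'
#' An [mc_volume()] is written as four per-channel files
#' (`<prefix>_FLAIR.nii.gz`, ...); a [label_volume()] as a single file.
#'
#' @param x volume to write.
#' @param path output directory (`mc_volume`) or file path (`label_volume`).
#' @param prefix file-name prefix for per-channel files.
#' @return Invisibly, the paths written.
#' @export
write_volume <- function(x, path, prefix = "volume") {
  nifti_of <- function(arr, tmpl) {
    if (!is.null(tmpl)) RNifti::asNifti(arr, reference = tmpl)
    else RNifti::asNifti(arr, pixdim = x$spacing)
  }
  if (inherits(x, "mc_volume")) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    out <- character(0)
    for (i in seq_along(MR_CHANNELS)) {
      f <- file.path(path, sprintf("%s_%s.nii.gz", prefix, MR_CHANNELS[i]))
      RNifti::writeNifti(nifti_of(x$data[, , , i], x$reference), f)
      out <- c(out, f)
    }
    invisible(out)
  } else if (inherits(x, "label_volume")) {
    dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
    RNifti::writeNifti(nifti_of(x$labels, x$reference), path, datatype = "int16")
    invisible(path)
  } else stop("x must be an mc_volume or label_volume")
}

#' Derive the binary brain mask of a skull-stripped volume
#'
#' Skull-stripped data has exact-zero background, so a voxel belongs to the
#' brain iff any channel is nonzero there. Compute the mask before intensity
#' normalization (which rescales in-brain voxels only).
#'
#' @param volume an [mc_volume()].
#' @return A logical 3-D array (`TRUE` = brain).
#' @export
derive_brain_mask <- function(volume) {
  stopifnot(inherits(volume, "mc_volume"))
  m <- volume$data[, , , 1] != 0
  for (i in 2:4) m <- m | (volume$data[, , , i] != 0)
  if (!any(m)) stop("all-zero volume: no brain present")
  m
}

#' Z-score intensity normalization within the brain mask
#'
#' Each channel is shifted and scaled so its in-mask intensities have zero
#' mean and unit variance (population standard deviation). Background voxels
#' outside the mask stay exactly 0, preserving the skull-stripped contract.
#'
#' @param volume an [mc_volume()].
#' @param mask logical brain mask from [derive_brain_mask()].
#' @return A normalized `mc_volume`.
#' @export
zscore_normalize <- function(volume, mask) {
  stopifnot(inherits(volume, "mc_volume"))
  if (!identical(dim(mask), dim(volume$data)[1:3]))
    stop("mask shape does not match volume")
  if (sum(mask) < 2L) stop("mask must contain at least 2 voxels")
  out <- volume$data
  for (i in seq_along(MR_CHANNELS)) {
    ch <- out[, , , i]
    v <- ch[mask]
    mu <- mean(v)
    sdev <- sqrt(mean((v - mu)^2))
    if (sdev < 1e-12)
      stop("zero in-mask intensity spread in channel ", MR_CHANNELS[i])
    ch[mask] <- (v - mu) / sdev
    ch[!mask] <- 0
    out[, , , i] <- ch
  }
  mc_volume(out, spacing = volume$spacing, reference = volume$reference)
}

#' Optional N4 bias-field correction hook
#'
#' Bias-field correction is delegated to an external N4 executable when one is
#' configured; nothing is re-implemented here. With `n4_path = NULL` (the
#' default) the volume is returned unchanged.
#'
#' @param volume an [mc_volume()].
#' @param n4_path path to an N4 bias-field-correction executable, or `NULL`.
#' @return The corrected (or untouched) `mc_volume`.
#' @export
bias_field_hook <- function(volume, n4_path = NULL) {
  stopifnot(inherits(volume, "mc_volume"))
  if (is.null(n4_path)) return(volume)
  if (!nzchar(Sys.which(n4_path)) && !file.exists(n4_path))
    stop("N4 executable not found: ", n4_path)
  tmp <- tempfile("n4")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  write_volume(volume, tmp, prefix = "in")
  chans <- list()
  for (ch in MR_CHANNELS) {
    src <- file.path(tmp, sprintf("in_%s.nii.gz", ch))
    dst <- file.path(tmp, sprintf("out_%s.nii.gz", ch))
    status <- system2(n4_path, c("-i", src, "-o", dst))
    if (status != 0L) stop("N4 correction failed for channel ", ch)
    img <- RNifti::readNifti(dst)
    chans[[ch]] <- array(as.numeric(img), dim(img))
  }
  mc_volume(chans, spacing = volume$spacing, reference = volume$reference)
}
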