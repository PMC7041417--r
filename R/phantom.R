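default_intensity_table <- function() {
  # rows: tissue; cols: FLAIR, T1, T2, T1ce. Qualitative MR contrasts:
  # edema bright on FLAIR/T2, enhancing rim bright on T1ce, necrotic core
  # dark on T1ce. Background is exactly 0 (skull-stripped contract).
  m <- rbind(background = c(0.00, 0.00, 0.00, 0.00),
             healthy    = c(0.35, 0.50, 0.40, 0.50),
             edema      = c(0.80, 0.40, 0.80, 0.45),
             enhancing  = c(0.55, 0.60, 0.55, 0.90),
             necrosis   = c(0.45, 0.30, 0.65, 0.15))
  colnames(m) <- MR_CHANNELS
  m
}

#' Synthetic glioma phantom configuration
#'
#' The phantom emulates the data regime of skull-stripped multi-channel
#' glioma MRI: a zero-background brain ellipsoid holding a nested, smoothly
#' deformed tumor (necrotic core inside an enhancing rim inside edema), with
#' tissue-specific channel intensities plus Gaussian noise and severe class
#' imbalance (tumor on the order of 1 percent of voxels at full size).
#' Defaults scale with `shape`; at 240 x 240 x 155 the non-tumor fraction
#' lands near 99 percent.
#'
#' @param shape grid shape (default 96^3 for desk-scale runs).
#' @param brain_semi_axes brain ellipsoid semi-axes in voxels.
#' @param tumor_center center of the primary tumor focus.
#' @param radii increasing radii (necrosis, enhancing, edema) in voxels.
#' @param intensities 5 x 4 tissue-by-channel mean intensity table
#'   (rows background, healthy, edema, enhancing, necrosis).
#' @param noise_sd additive Gaussian noise SD inside the brain.
#' @param deform relative amplitude of the smooth radial deformation
#'   applied to the tumor surfaces (0 = perfect spheres).
#' @param n_foci number of tumor foci (a second focus is placed mirrored
#'   through the brain center at 0.45 x the radii).
#' @param seed RNG seed; phantoms are bit-reproducible given the config.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(96L, 96L, 96L),
                           brain_semi_axes = 0.42 * shape,
                           tumor_center = NULL,
                           radii = c(0.06, 0.10, 0.16) * min(shape),
                           intensities = default_intensity_table(),
                           noise_sd = 0.05, deform = 0.15, n_foci = 1L,
                           seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape > 0L), length(radii) == 3L,
            n_foci >= 1L, noise_sd >= 0, deform >= 0, deform < 0.3)
  if (!(radii[1] < radii[2] && radii[2] < radii[3]))
    stop("radii must be strictly increasing (necrosis < enhancing < edema)")
  bc <- (shape + 1) / 2
  if (is.null(tumor_center))
    tumor_center <- bc + c(0.30, 0.15, -0.20) * brain_semi_axes
  it <- intensities
  if (any(it["background", ] != 0))
    stop("background intensities must be exactly 0 (skull-stripped data)")
  if (!(it["edema", "FLAIR"] > it["healthy", "FLAIR"] &&
        it["edema", "T2"] > it["healthy", "T2"]))
    stop("intensity table must make edema brighter than healthy on FLAIR and T2")
  if (!(it["enhancing", "T1ce"] > it["healthy", "T1ce"]))
    stop("intensity table must make enhancing tissue brighter than healthy on T1ce")
  if (!(it["necrosis", "T1ce"] < it["enhancing", "T1ce"]))
    stop("intensity table must make necrosis darker than enhancing on T1ce")
  cfg <- structure(list(shape = shape, brain_semi_axes = brain_semi_axes,
                        brain_center = bc, tumor_center = tumor_center,
                        radii = radii, intensities = it, noise_sd = noise_sd,
                        deform = deform, n_foci = as.integer(n_foci),
                        seed = as.integer(seed)),
                   class = "phantom_config")
  for (f in phantom_foci(cfg)) {
    e <- sqrt(sum(((f$center - bc) / brain_semi_axes)^2))
    if (e + f$radii[3] * (1 + 2 * cfg$deform) / min(brain_semi_axes) > 1)
      stop("tumor focus does not fit inside the brain ellipsoid")
  }
  cfg
}

# Focus list: the primary focus plus, for n_foci = 2, a smaller mirrored one.
phantom_foci <- function(config) {
  foci <- list(list(center = config$tumor_center, radii = config$radii))
  if (config$n_foci >= 2L) {
    for (i in 2:config$n_foci) {
      mirror <- config$brain_center -
        (config$tumor_center - config$brain_center) * (0.8 + 0.1 * (i - 2L))
      foci[[i]] <- list(center = mirror, radii = config$radii * 0.45)
    }
  }
  foci
}

# Squared-distance field sum_ax ((coord - center)/scale)^2 as a 3-D array.
dist2_field <- function(shape, center, scale = c(1, 1, 1)) {
  d1 <- ((seq_len(shape[1]) - center[1]) / scale[1])^2
  d2 <- ((seq_len(shape[2]) - center[2]) / scale[2])^2
  d3 <- ((seq_len(shape[3]) - center[3]) / scale[3])^2
  outer(outer(d1, d2, `+`), d3, `+`)
}

# Smooth radial modulation field: 1 + deform * (low-order polynomial of the
# unit direction from the focus center), clamped. Avoids perfectly spherical
# tumors that a network could fit with a sphere prior.
deform_field <- function(shape, center, deform, coef_seed) {
  if (deform == 0) return(array(1, shape))
  co <- with_seed(coef_seed, rnorm(8, 0, 0.5))
  d1 <- seq_len(shape[1]) - center[1]
  d2 <- seq_len(shape[2]) - center[2]
  d3 <- seq_len(shape[3]) - center[3]
  r <- sqrt(dist2_field(shape, center))
  r[r == 0] <- 1
  ux <- array(d1, shape) / r
  uy <- array(rep(d2, each = shape[1]), shape) / r
  uz <- array(rep(d3, each = shape[1] * shape[2]), shape) / r
  h <- co[1] * ux + co[2] * uy + co[3] * uz + co[4] * ux * uy +
    co[5] * ux * uz + co[6] * uy * uz + co[7] * (ux^2 - uy^2) +
    co[8] * (uy^2 - uz^2)
  s <- 1 + deform * h
  pmin(pmax(s, 1 - 2 * deform), 1 + 2 * deform)
}

#' Generate a synthetic glioma phantom
#'
#' Builds the brain ellipsoid and nested deformed tumor spheroids described
#' by the config, then fills the four MR channels from the tissue intensity
#' table plus seeded Gaussian noise (inside the brain only; background stays
#' exactly 0). Channels and labels are geometrically aligned by construction
#' and the result is bit-reproducible given the config.
#'
#' @param config a [phantom_config()].
#' @return List of `volume` (an [mc_volume()]) and `labels`
#'   (a [label_volume()]).
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  shape <- config$shape
  seeds <- derive_seeds(config$seed, 2L + config$n_foci)
  brain <- dist2_field(shape, config$brain_center,
                       config$brain_semi_axes) <= 1
  labels <- array(0L, shape)
  for (i in seq_along(phantom_foci(config))) {
    f <- phantom_foci(config)[[i]]
    r <- sqrt(dist2_field(shape, f$center))
    s <- deform_field(shape, f$center, config$deform, seeds[2L + i])
    wt_f <- r <= f$radii[3] * s
    if (any(wt_f & !brain)) stop("tumor focus extends outside the brain")
    labels[wt_f] <- 2L                        # edema
    labels[r <= f$radii[2] * s] <- 4L         # enhancing rim
    labels[r <= f$radii[1] * s] <- 1L         # necrotic core
  }
  it <- config$intensities
  tissue_of_label <- c("0" = "healthy", "1" = "necrosis", "2" = "edema",
                       "4" = "enhancing")
  chans <- vector("list", 4L)
  noise_seeds <- derive_seeds(seeds[1], 4L)
  for (ci in seq_along(MR_CHANNELS)) {
    ch <- array(0, shape)
    for (lab in c(0L, 1L, 2L, 4L)) {
      sel <- brain & labels == lab
      ch[sel] <- it[tissue_of_label[as.character(lab)], MR_CHANNELS[ci]]
    }
    if (config$noise_sd > 0) {
      nz <- with_seed(noise_seeds[ci], rnorm(sum(brain), 0, config$noise_sd))
      ch[brain] <- ch[brain] + nz
    }
    chans[[ci]] <- ch
  }
  names(chans) <- MR_CHANNELS
  list(volume = mc_volume(chans), labels = label_volume(labels))
}

#' Per-class voxel fractions
#'
#' Quantifies the class imbalance of a label volume: the fraction of voxels
#' in each of the four classes (file convention 0/1/2/4). Full-size phantoms
#' generated with default radii land in the regime where non-tumor voxels
#' are on the order of 99 percent of the grid.
#'
#' @param labels a [label_volume()] or integer label array.
#' @return Named numeric vector of fractions (names "0", "1", "2", "4").
#' @export
imbalance_profile <- function(labels) {
  arr <- if (inherits(labels, "label_volume")) labels$labels else labels
  tab <- table(factor(as.vector(arr), levels = FILE_LABELS))
  fr <- as.numeric(tab) / length(arr)
  names(fr) <- as.character(FILE_LABELS)
  fr
}
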