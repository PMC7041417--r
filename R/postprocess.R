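#' Retain the largest 3D connected tumor component
#'
#' Connected components are computed on the binary whole-tumor mask
#' (any nonzero label) — not per class, so a necrotic core disconnected from
#' its enhancing rim is not deleted. All tumor voxels outside the single
#' largest component are relabeled background; class labels inside the kept
#' component are untouched. Size ties break to the component discovered
#' first in raster scan order. Note this removes genuine secondary foci of
#' multifocal tumors; `min_size_fraction` switches to keeping every
#' component at least that fraction of the largest.
#'
#' @param labels a [label_volume()] or integer label array.
#' @param connectivity voxel adjacency: 6, 18 or 26 (default 26).
#' @param min_size_fraction if > 0, keep all components whose size is at
#'   least this fraction of the largest instead of only the largest.
#' @return List of `labels` (same type as input) and `report` with
#'   `component_count`, `component_sizes`, `retained_component_id`.
#' @export
keep_largest_component <- function(labels, connectivity = 26L,
                                   min_size_fraction = 0) {
  is_lv <- inherits(labels, "label_volume")
  arr <- if (is_lv) labels$labels else labels
  wt <- arr != 0L
  if (!any(wt)) {
    report <- list(component_count = 0L, component_sizes = numeric(0),
                   retained_component_id = NA_integer_)
    return(list(labels = labels, report = report))
  }
  cc <- .label_components_3d(wt, as.integer(connectivity))
  sizes <- cc$sizes
  keep_id <- which.max(sizes)
  keep <- if (min_size_fraction > 0)
    cc$labels %in% which(sizes >= min_size_fraction * max(sizes))
  else cc$labels == keep_id
  out <- arr
  out[!keep] <- 0L
  report <- list(component_count = length(sizes), component_sizes = sizes,
                 retained_component_id = as.integer(keep_id))
  if (is_lv) {
    labels$labels <- out
    list(labels = labels, report = report)
  } else list(labels = out, report = report)
}

#' Intersect a segmentation with the brain mask
#'
#' Logical-AND overlay: any tumor label predicted outside the brain mask
#' (e.g. in the zero-padding margin) is set to background; in-mask voxels
#' pass through unchanged.
#'
#' @param labels a [label_volume()] or integer label array.
#' @param mask logical brain mask of the same shape.
#' @return Labels of the same type as the input.
#' @export
apply_brain_mask <- function(labels, mask) {
  is_lv <- inherits(labels, "label_volume")
  arr <- if (is_lv) labels$labels else labels
  if (!identical(dim(arr), dim(mask)))
    stop("labels and mask shapes differ")
  arr[!mask] <- 0L
  if (is_lv) { labels$labels <- arr; labels } else arr
}

#' Full false-positive removal step
#'
#' Applies [keep_largest_component()] then [apply_brain_mask()], the default
#' post-processing after tiled prediction.
#'
#' @inheritParams keep_largest_component
#' @inheritParams apply_brain_mask
#' @return A cleaned labels object (same type as input).
#' @export
postprocess_segmentation <- function(labels, mask, connectivity = 26L,
                                     min_size_fraction = 0) {
  out <- keep_largest_component(labels, connectivity, min_size_fraction)$labels
  apply_brain_mask(out, mask)
}
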