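#' Derive the nested evaluation regions
#'
#' The three regions scored in brain-tumor segmentation are nested:
#' enhancing tumor ET = label 4; tumor core TC = labels 1 and 4 (enhancing
#' plus necrotic/non-enhancing); whole tumor WT = labels 1, 2 and 4 (core
#' plus edema).
#'
#' @param labels a [label_volume()] or integer label array.
#' @return A list of logical arrays `ET`, `TC`, `WT` with `ET ⊆ TC ⊆ WT`.
#' @export
derive_regions <- function(labels) {
  arr <- if (inherits(labels, "label_volume")) labels$labels else labels
  list(ET = arr == 4L,
       TC = arr == 1L | arr == 4L,
       WT = arr != 0L)
}

check_same_shape <- function(p, t) {
  if (!identical(dim(p), dim(t))) stop("mask shapes differ")
}

#' Overlap and surface-distance metrics
#'
#' `dice_score(P, T) = 2|P ∩ T| / (|P| + |T|)`;
#' `sensitivity(P, T) = |P ∩ T| / |T|` (true positive rate);
#' `specificity(P, T) = |P0 ∩ T0| / |T0|` (true negative rate over the
#' complements). Each returns `NA` (the undefined sentinel) when its
#' denominator is empty; see [summarize_cohort()] for the scoring policy.
#'
#' @param p,t logical prediction and ground-truth masks of one region.
#' @return A fraction in `[0, 1]`, or `NA` when undefined.
#' @export
dice_score <- function(p, t) {
  check_same_shape(p, t)
  den <- sum(p) + sum(t)
  if (den == 0) return(NA_real_)
  2 * sum(p & t) / den
}

#' @rdname dice_score
#' @export
sensitivity <- function(p, t) {
  check_same_shape(p, t)
  if (!any(t)) return(NA_real_)
  sum(p & t) / sum(t)
}

#' @rdname dice_score
#' @export
specificity <- function(p, t) {
  check_same_shape(p, t)
  n0 <- sum(!t)
  if (n0 == 0) return(NA_real_)
  sum(!p & !t) / n0
}

# Voxels of a mask with at least one face-adjacent (6-connected) voxel
# outside the mask; out-of-grid neighbours count as outside.
surface_voxels <- function(mask) {
  d <- dim(mask)
  interior <- array(TRUE, d)
  for (ax in 1:3) {
    n <- d[ax]
    for (dir in c(-1L, 1L)) {
      nb <- array(FALSE, d)
      src <- if (dir == 1L) 1:(n - 1) else 2:n
      dst <- if (dir == 1L) 2:n else 1:(n - 1)
      idx_src <- idx_dst <- list(TRUE, TRUE, TRUE)
      idx_src[[ax]] <- src; idx_dst[[ax]] <- dst
      nb <- do.call(`[<-`, c(list(nb), idx_dst,
                             list(do.call(`[`, c(list(mask), idx_src)))))
      interior <- interior & nb
    }
  }
  which(mask & !interior, arr.ind = TRUE)
}

#' 95th-percentile Hausdorff surface distance
#'
#' Surface voxels of each mask are voxels with a 6-adjacent neighbor outside
#' the mask. Directed nearest-surface distances are computed both ways and
#' HD95 is the maximum of the two 95th percentiles (linear interpolation
#' between order statistics), in mm — robust to small outlying protrusions,
#' unlike the plain Hausdorff distance. `method = "pooled"` instead takes the
#' 95th percentile of the two directed distance sets pooled together.
#'
#' @param p,t logical prediction and truth masks.
#' @param spacing voxel size in mm per axis (anisotropic spacing honored).
#' @param method `"max_directed"` (default) or `"pooled"`.
#' @return Distance in mm, or `NA` if either mask is empty.
#' @export
hausdorff95 <- function(p, t, spacing = c(1, 1, 1),
                        method = c("max_directed", "pooled")) {
  check_same_shape(p, t)
  method <- match.arg(method)
  if (!any(p) || !any(t)) return(NA_real_)
  sp <- surface_voxels(p)
  st <- surface_voxels(t)
  A <- sweep(sp, 2L, spacing, `*`)
  B <- sweep(st, 2L, spacing, `*`)
  d_pt <- .nn_directed_dists(A, B)
  d_tp <- .nn_directed_dists(B, A)
  if (method == "max_directed")
    max(quantile(d_pt, 0.95, type = 7, names = FALSE),
        quantile(d_tp, 0.95, type = 7, names = FALSE))
  else quantile(c(d_pt, d_tp), 0.95, type = 7, names = FALSE)
}

#' Per-case evaluation report
#'
#' Computes Dice, sensitivity, specificity and HD95 for the three nested
#' regions ET, TC and WT of one predicted/truth label pair. Undefined values
#' (empty denominators or empty masks) are `NA`.
#'
#' @param pred,truth [label_volume()]s or integer label arrays of one case.
#' @param spacing voxel spacing in mm.
#' @param case optional case identifier carried into the report.
#' @return A data frame with one row per region.
#' @export
evaluate_segmentation <- function(pred, truth, spacing = c(1, 1, 1),
                                  case = NA_character_) {
  rp <- derive_regions(pred)
  rt <- derive_regions(truth)
  rows <- lapply(c("ET", "TC", "WT"), function(rg) {
    data.frame(case = case, region = rg,
               dice = dice_score(rp[[rg]], rt[[rg]]),
               sensitivity = sensitivity(rp[[rg]], rt[[rg]]),
               specificity = specificity(rp[[rg]], rt[[rg]]),
               hd95 = hausdorff95(rp[[rg]], rt[[rg]], spacing),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cohort aggregation of per-case metrics
#'
#' Aggregates per-case reports into mean, sample SD (n-1), median, and the
#' 25th/75th percentiles (linear interpolation) per region and metric.
#' Under the default `undefined = "zero"` policy an undefined Dice or
#' sensitivity (region present on only one side, or absent on both) scores
#' 0, matching challenge-style scoring of missed or hallucinated regions;
#' `"exclude"` drops undefined values instead. Undefined HD95 and
#' specificity values are always excluded (no finite penalty is defined for
#' them).
#'
#' @param reports a list of data frames from [evaluate_segmentation()], or
#'   one row-bound data frame.
#' @param undefined policy for undefined Dice/sensitivity: `"zero"` or
#'   `"exclude"`.
#' @return A data frame with columns region, metric, mean, sd, median, q25,
#'   q75, n.
#' @export
summarize_cohort <- function(reports, undefined = c("zero", "exclude")) {
  undefined <- match.arg(undefined)
  if (is.data.frame(reports)) df <- reports
  else {
    if (length(reports) == 0L) stop("no reports to summarize")
    df <- do.call(rbind, reports)
  }
  metrics <- c("dice", "sensitivity", "specificity", "hd95")
  out <- list()
  for (rg in unique(df$region)) {
    for (m in metrics) {
      v <- df[[m]][df$region == rg]
      if (m %in% c("dice", "sensitivity") && undefined == "zero")
        v[is.na(v)] <- 0
      v <- v[!is.na(v)]
      out[[length(out) + 1L]] <- data.frame(
        region = rg, metric = m,
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1L) sd(v) else if (length(v)) 0 else NA_real_,
        median = if (length(v)) median(v) else NA_real_,
        q25 = if (length(v)) quantile(v, 0.25, type = 7, names = FALSE)
              else NA_real_,
        q75 = if (length(v)) quantile(v, 0.75, type = 7, names = FALSE)
              else NA_real_,
        n = length(v), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
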