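# Independent brute-force oracles used by unit and acceptance tests. These
# deliberately avoid the package's own computational paths.

oracle_dice <- function(p, t) {
  inter <- 0; np <- 0; nt <- 0
  for (i in seq_along(p)) {
    if (p[i] && t[i]) inter <- inter + 1
    if (p[i]) np <- np + 1
    if (t[i]) nt <- nt + 1
  }
  if (np + nt == 0) return(NA_real_)
  2 * inter / (np + nt)
}

oracle_sensitivity <- function(p, t) {
  if (sum(t) == 0) return(NA_real_)
  sum(p[t]) / sum(t)
}

oracle_specificity <- function(p, t) {
  if (sum(!t) == 0) return(NA_real_)
  sum(!p[!t]) / sum(!t)
}

# All-pairs Euclidean HD95 oracle on surface voxels (surface extracted by a
# per-voxel 6-neighbour scan, distances by outer products).
oracle_surface <- function(mask) {
  d <- dim(mask)
  out <- NULL
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (!mask[x, y, z]) next
    nb <- rbind(c(x - 1, y, z), c(x + 1, y, z), c(x, y - 1, z),
                c(x, y + 1, z), c(x, y, z - 1), c(x, y, z + 1))
    outside <- apply(nb, 1, function(v)
      any(v < 1) || v[1] > d[1] || v[2] > d[2] || v[3] > d[3] ||
        !mask[v[1], v[2], v[3]])
    if (any(outside)) out <- rbind(out, c(x, y, z))
  }
  out
}

oracle_hd95 <- function(p, t, spacing = c(1, 1, 1)) {
  if (!any(p) || !any(t)) return(NA_real_)
  A <- sweep(oracle_surface(p), 2, spacing, `*`)
  B <- sweep(oracle_surface(t), 2, spacing, `*`)
  D2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  D2[D2 < 0] <- 0  # guard tiny negative values from cancellation
  D <- sqrt(D2)
  max(quantile(apply(D, 1, min), 0.95, type = 7, names = FALSE),
      quantile(apply(D, 2, min), 0.95, type = 7, names = FALSE))
}

# Per-voxel 6-neighbour scan for whole-tumor boundary voxels.
oracle_wt_boundary <- function(labels) {
  wt <- labels != 0
  d <- dim(wt)
  out <- NULL
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    nb <- rbind(c(x - 1, y, z), c(x + 1, y, z), c(x, y - 1, z),
                c(x, y + 1, z), c(x, y, z - 1), c(x, y, z + 1))
    vals <- apply(nb, 1, function(v) {
      if (any(v < 1) || v[1] > d[1] || v[2] > d[2] || v[3] > d[3]) FALSE
      else wt[v[1], v[2], v[3]]
    })
    if (any(vals != wt[x, y, z])) out <- rbind(out, c(x, y, z))
  }
  out
}

# BFS flood fill returning component labels under a given connectivity.
oracle_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  man <- rowSums(abs(offs))
  offs <- offs[man > 0 & man <= switch(as.character(connectivity),
                                       "6" = 1, "18" = 2, "26" = 3), ,
               drop = FALSE]
  lab <- array(0L, d)
  nxt <- 0L
  for (sz in 1:d[3]) for (sy in 1:d[2]) for (sx in 1:d[1]) {
    if (!mask[sx, sy, sz] || lab[sx, sy, sz] != 0L) next
    nxt <- nxt + 1L
    queue <- matrix(c(sx, sy, sz), ncol = 3)
    lab[sx, sy, sz] <- nxt
    while (nrow(queue) > 0) {
      v <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (i in seq_len(nrow(offs))) {
        w <- v + offs[i, ]
        if (any(w < 1) || w[1] > d[1] || w[2] > d[2] || w[3] > d[3]) next
        if (mask[w[1], w[2], w[3]] && lab[w[1], w[2], w[3]] == 0L) {
          lab[w[1], w[2], w[3]] <- nxt
          queue <- rbind(queue, w)
        }
      }
    }
  }
  lab
}

# Soft Dice loss by explicit per-class voxel summation.
oracle_dice_loss <- function(probs, truth_onehot, eps = 1e-5) {
  nc <- dim(probs)[4]
  total <- 0
  for (cc in seq_len(nc)) {
    pc <- probs[, , , cc]; tc <- truth_onehot[, , , cc]
    num <- 0; dp <- 0; dt <- 0
    for (i in seq_along(pc)) {
      num <- num + pc[i] * tc[i]; dp <- dp + pc[i]; dt <- dt + tc[i]
    }
    total <- total + (2 * num + eps) / (dp + dt + eps)
  }
  1 - total / nc
}
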