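# Shared fixtures, built in code. Phantoms are memoized per session because
# several files reuse them.

.fixture_env <- new.env(parent = emptyenv())

small_phantom <- function(seed = 1L, shape = c(48L, 48L, 48L), n_foci = 1L) {
  key <- sprintf("ph_%d_%d_%d", seed, shape[1], n_foci)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_phantom(
      phantom_config(shape = shape, n_foci = n_foci, seed = seed))
  .fixture_env[[key]]
}

# A 4-channel volume built from explicit arrays.
toy_volume <- function(shape = c(8L, 8L, 8L), fill = 1) {
  arr <- array(0, c(shape, 4L))
  core <- 3:6
  for (i in 1:4) arr[core, core, core, i] <- fill * i
  mc_volume(arr)
}

random_mask <- function(shape, p = 0.3) {
  array(runif(prod(shape)) < p, shape)
}

random_labels <- function(shape, p_tumor = 0.2) {
  vals <- sample(c(0L, 1L, 2L, 4L), prod(shape), replace = TRUE,
                 prob = c(1 - p_tumor, p_tumor / 3, p_tumor / 3, p_tumor / 3))
  array(vals, shape)
}
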