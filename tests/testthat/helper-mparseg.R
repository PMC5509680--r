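# Shared fixtures, all generated in code.

# Small phantom used across tests: 32 x 32 x 8 voxels at 2 x 2 x 5 mm.
tiny_phantom_config <- function(seed = 1L, tumour_radius = 8, ...) {
  phantom_config(grid_shape = c(32, 32, 8), spacing = c(2, 2, 5),
                 tumour_radius = tumour_radius, seed = seed, ...)
}

# Two-cluster linearly separable toy patch set: background tiles are pure
# noise, tumour tiles carry a strong channel-2 offset (as on high-b DWI).
toy_patch_set <- function(n_per_class = 150, M = 5, sep = 2.5, seed = 1L) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    patches <- array(rnorm(M * M * 3 * n, 0, 1), c(M, M, 3, n))
    labels <- rep(c(0L, 1L), each = n_per_class)
    for (i in which(labels == 1L)) {
      patches[, , 2, i] <- patches[, , 2, i] + sep
      patches[, , 1, i] <- patches[, , 1, i] + sep / 2
    }
    structure(
      list(patches = patches, labels = labels,
           coords = matrix(1L, n, 3), strata = ifelse(labels == 1, "T", "B3"),
           subject_id = "toy", M = as.integer(M),
           n_per_class = as.integer(n_per_class)),
      class = "patch_set"
    )
  })
}

# Label-only patch set (1 x 1 patches) for split accounting at scale.
dummy_patch_set <- function(labels, M = 1L) {
  n <- length(labels)
  structure(
    list(patches = array(0, c(M, M, 3, n)), labels = as.integer(labels),
         coords = matrix(1L, n, 3),
         strata = ifelse(labels == 1, "T", "B3"),
         subject_id = "dummy", M = as.integer(M), n_per_class = n %/% 2L),
    class = "patch_set"
  )
}

# Independent flood-fill component labelling (BFS, pure R) used as the
# oracle for the compiled connected-component kernel.
flood_fill_components <- function(mask, connectivity = 26) {
  dims <- dim(mask)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  lab <- array(0L, dims)
  nxt <- 0L
  for (s in which(mask != 0)) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      v0 <- v - 1L
      x <- v0 %% dims[1] + 1L
      y <- (v0 %/% dims[1]) %% dims[2] + 1L
      z <- v0 %/% (dims[1] * dims[2]) + 1L
      nb <- cbind(x + offs[, 1], y + offs[, 2], z + offs[, 3])
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 &
        nb[, 2] <= dims[2] & nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + dims[1] * (nb[, 2] - 1L + dims[2] * (nb[, 3] - 1L))
      new <- lin[mask[lin] != 0 & lab[lin] == 0L]
      lab[new] <- nxt
      queue <- c(queue, new)
    }
  }
  lab
}
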