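# Region-stratified patch sampling. The background is split into three
# strata so the classifier spends its sample budget where classification is
# hard: the tumour's immediate surroundings (B1, a 1 cm morphological
# dilation shell), other DWI-hyperintense tissue (B2, the structures that
# share the tumour's high-b signal), and everything else (B3).

#' Integer voxel offsets inside a physical sphere
#'
#' Enumerates every integer offset `o` with
#' `sum((o * spacing)^2) <= radius_mm^2`: the anisotropy-aware spherical
#' structuring element. With spacing (2, 2, 5) mm and a 10 mm radius the
#' half-widths are (5, 5, 2) voxels.
#'
#' @param radius_mm sphere radius in mm.
#' @param spacing voxel spacing in mm.
#' @return Integer matrix (n x 3) of offsets, including the origin.
#' @export
sphere_offsets <- function(radius_mm, spacing) {
  hw <- floor(radius_mm / spacing)
  g <- expand.grid(dx = -hw[1]:hw[1], dy = -hw[2]:hw[2], dz = -hw[3]:hw[3])
  d2 <- (g$dx * spacing[1])^2 + (g$dy * spacing[2])^2 + (g$dz * spacing[3])^2
  as.matrix(g[d2 <= radius_mm^2, , drop = FALSE])
}

#' Decompose a labelled volume into sampling strata
#'
#' Partitions every voxel into exactly one of four strata: `T` (the tumour,
#' i.e. the label-map support), `B1` (the non-tumour shell obtained by
#' morphological dilation of the tumour with a spherical structuring
#' element of `radius_mm` physical radius), `B2` (voxels outside T and B1
#' whose standardized high-b DWI intensity exceeds `threshold`; after
#' standardization the mu + 2*sigma criterion is the fixed value 2.00) and
#' `B3` (the remainder).
#'
#' @param dwi_high_b standardized high-b DWI array.
#' @param mask a [label_map] (or binary 3D array); must be non-empty.
#' @param spacing voxel spacing in mm.
#' @param radius_mm dilation radius in mm (default 10, i.e. 1 cm).
#' @param threshold DWI hyperintensity threshold (default 2.0).
#' @return Object of class `region_decomposition` with `stratum` (integer
#'   array, codes 1=T, 2=B1, 3=B2, 4=B3), `counts` (named) and the
#'   parameters used.
#' @export
decompose_regions <- function(dwi_high_b, mask, spacing, radius_mm = 10,
                              threshold = 2.0) {
  if (inherits(mask, "label_map")) mask <- mask$mask
  if (!identical(dim(dwi_high_b), dim(mask))) {
    stopf("volume and mask shapes differ")
  }
  dims <- dim(mask)
  tum <- mask == 1L
  if (!any(tum)) stopf("empty tumour mask: nothing to learn from")
  if (all(tum)) stopf("mask covers the whole volume: no background")
  offs <- sphere_offsets(radius_mm, spacing)
  tc <- which(tum, arr.ind = TRUE)
  n_off <- nrow(offs)
  # dilate: tumour coords + every structuring-element offset, clipped
  px <- rep(tc[, 1], each = n_off) + rep(offs[, 1], times = nrow(tc))
  py <- rep(tc[, 2], each = n_off) + rep(offs[, 2], times = nrow(tc))
  pz <- rep(tc[, 3], each = n_off) + rep(offs[, 3], times = nrow(tc))
  ok <- px >= 1L & px <= dims[1] & py >= 1L & py <= dims[2] &
    pz >= 1L & pz <= dims[3]
  lin <- unique(px[ok] + dims[1] * ((py[ok] - 1L) + dims[2] * (pz[ok] - 1L)))
  dil <- array(FALSE, dims)
  dil[lin] <- TRUE
  b1 <- dil & !tum
  b2 <- (dwi_high_b > threshold) & !tum & !b1
  stratum <- array(4L, dims)
  stratum[b2] <- 3L
  stratum[b1] <- 2L
  stratum[tum] <- 1L
  counts <- c(T = sum(tum), B1 = sum(b1), B2 = sum(b2),
              B3 = sum(stratum == 4L))
  structure(
    list(stratum = stratum, counts = counts, radius_mm = radius_mm,
         threshold = threshold, spacing = spacing),
    class = "region_decomposition"
  )
}

#' @export
print.region_decomposition <- function(x, ...) {
  cat("<region_decomposition>",
      paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = " "),
      "\n")
  invisible(x)
}

# Background quota per stratum: N/4 from B1, N/2 from B2, N/4 from B3.
# Quotas of empty strata are reallocated proportionally to the non-empty
# ones; rounding keeps the total at exactly N.
background_quotas <- function(n, counts) {
  base <- c(B1 = n / 4, B2 = n / 2, B3 = n / 4)
  avail <- counts[c("B1", "B2", "B3")] > 0
  if (!any(avail)) stopf("all background strata are empty")
  w <- base * avail
  q <- w / sum(w) * n
  qf <- floor(q)
  rem <- n - sum(qf)
  if (rem > 0) {
    ord <- order(q - qf, decreasing = TRUE)
    qf[ord[seq_len(rem)]] <- qf[ord[seq_len(rem)]] + 1
  }
  qf
}

#' Sample class-balanced, region-weighted patches
#'
#' Draws exactly `n_per_class` tumour patch centres from stratum T and
#' `n_per_class` background centres split N/4 : N/2 : N/4 across B1, B2 and
#' B3, then extracts the in-plane M x M multiparametric patch around each
#' centre. The ground-truth label of a patch is the label of its central
#' voxel. Sampling is without replacement when a stratum holds at least its
#' quota, with replacement otherwise; an empty background stratum donates
#' its quota to the others.
#'
#' @param volume a (standardized) [mp_volume].
#' @param regions a [region_decomposition] for the same volume.
#' @param n_per_class per-class sample budget N (divisible by 4;
#'   default 5000).
#' @param M patch edge length in voxels (odd; default 21).
#' @param seed integer seed for the draws.
#' @return Object of class `patch_set`: `patches` (M x M x 3 x n array;
#'   channels t2w, dwi_high_b, dwi_b0), `labels` (integer 0/1), `coords`
#'   (n x 3 voxel indices), `strata` (codes "T","B1","B2","B3"),
#'   `subject_id`, `M`, `n_per_class`.
#' @export
sample_patches <- function(volume, regions, n_per_class = 5000, M = 21,
                           seed = 1L) {
  stopifnot(inherits(volume, "mp_volume"),
            inherits(regions, "region_decomposition"))
  if (n_per_class %% 4 != 0) stopf("n_per_class must be divisible by 4")
  if (M %% 2 == 0) stopf("patch edge M must be odd")
  n <- n_per_class
  quotas <- background_quotas(n, regions$counts)
  draw <- function(lin_idx, k) {
    # sample() would misread a length-1 vector as 1:n
    lin_idx[sample.int(length(lin_idx), k, replace = length(lin_idx) < k)]
  }
  with_seed(seed, {
    strat <- regions$stratum
    tum_idx <- which(strat == 1L)
    picks <- list(
      T = draw(tum_idx, n),
      B1 = if (quotas[["B1"]] > 0) draw(which(strat == 2L), quotas[["B1"]]) else integer(0),
      B2 = if (quotas[["B2"]] > 0) draw(which(strat == 3L), quotas[["B2"]]) else integer(0),
      B3 = if (quotas[["B3"]] > 0) draw(which(strat == 4L), quotas[["B3"]]) else integer(0)
    )
    lin <- unlist(picks, use.names = FALSE)
    strata <- rep(names(picks), times = lengths(picks))
    dims <- dim(strat)
    coords <- cbind(
      ((lin - 1L) %% dims[1]) + 1L,
      ((lin - 1L) %/% dims[1]) %% dims[2] + 1L,
      (lin - 1L) %/% (dims[1] * dims[2]) + 1L
    )
    patches <- cpp_extract_patches(as_channel_array(volume),
                                   coords, as.integer(M))
    structure(
      list(patches = patches,
           labels = as.integer(strata == "T"),
           coords = coords, strata = strata,
           subject_id = volume$subject_id, M = as.integer(M),
           n_per_class = as.integer(n)),
      class = "patch_set"
    )
  })
}

#' Extract one multiparametric patch
#'
#' The axial in-plane M x M neighbourhood centred on `voxel`, one channel
#' per sequence (t2w, dwi_high_b, dwi_b0). Positions outside the volume are
#' zero-filled (zero is the background mean after standardization).
#'
#' @param volume an [mp_volume].
#' @param voxel integer length-3 voxel index (1-based).
#' @param M patch edge length (odd).
#' @return M x M x 3 numeric array.
#' @export
extract_patch <- function(volume, voxel, M = 21) {
  stopifnot(inherits(volume, "mp_volume"))
  if (M %% 2 == 0) stopf("patch edge M must be odd")
  dims <- dim(volume$sequences$t2w)
  voxel <- as.integer(voxel)
  if (any(voxel < 1L) || any(voxel > dims)) stopf("voxel outside the volume")
  p <- cpp_extract_patches(as_channel_array(volume),
                           matrix(voxel, nrow = 1), as.integer(M))
  array(p, dim = c(M, M, 3))
}

# Stack the sequences into a (nx, ny, nz, 3) array in the fixed channel
# order t2w, dwi_high_b, dwi_b0.
as_channel_array <- function(volume) {
  d <- dim(volume$sequences$t2w)
  out <- array(0, dim = c(d, 3))
  out[, , , 1] <- volume$sequences$t2w
  out[, , , 2] <- volume$sequences$dwi_high_b
  out[, , , 3] <- volume$sequences$dwi_b0
  out
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches (%d x %d x 3), %d tumour / %d background\n",
              length(x$labels), x$M, x$M, sum(x$labels == 1L),
              sum(x$labels == 0L)))
  invisible(x)
}

#' Combine patch sets from several subjects
#'
#' @param ... `patch_set` objects (or a single list of them).
#' @return A single `patch_set`; `subject_id` becomes a per-patch vector.
#' @export
combine_patch_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1]], "patch_set")) {
    sets <- sets[[1]]
  }
  M <- sets[[1]]$M
  stopifnot(all(vapply(sets, function(s) s$M, integer(1)) == M))
  n <- vapply(sets, function(s) length(s$labels), integer(1))
  total <- sum(n)
  patches <- array(0, dim = c(M, M, 3, total))
  at <- 0L
  for (s in sets) {
    k <- length(s$labels)
    patches[, , , at + seq_len(k)] <- s$patches
    at <- at + k
  }
  structure(
    list(patches = patches,
         labels = unlist(lapply(sets, `[[`, "labels")),
         coords = do.call(rbind, lapply(sets, `[[`, "coords")),
         strata = unlist(lapply(sets, `[[`, "strata")),
         subject_id = unlist(lapply(sets, function(s) {
           rep(s$subject_id, length.out = length(s$labels))
         })),
         M = M, n_per_class = sets[[1]]$n_per_class),
    class = "patch_set"
  )
}

# Subset a patch set by index (used by the discovery split).
subset_patch_set <- function(ps, idx) {
  structure(
    list(patches = ps$patches[, , , idx, drop = FALSE],
         labels = ps$labels[idx],
         coords = ps$coords[idx, , drop = FALSE],
         strata = ps$strata[idx],
         subject_id = if (length(ps$subject_id) > 1) ps$subject_id[idx] else ps$subject_id,
         M = ps$M, n_per_class = ps$n_per_class),
    class = "patch_set"
  )
}
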