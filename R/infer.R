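#' Voxelwise probability map
#'
#' Applies the trained patch classifier at every voxel of a standardized
#' multiparametric volume: the probability assigned to a voxel is the
#' tumour-class softmax output for the in-plane patch centred on it
#' (borders zero-padded, as during sampling). Batching is a pure
#' implementation detail: results are identical for any batch size.
#'
#' @param model a trained `mparseg_model`.
#' @param volume an [mp_volume] (standardized).
#' @param batch voxels classified per forward pass.
#' @return Object of class `probability_map`: `p` (3D array in `[0, 1]`,
#'   same shape as the volume) and `spacing`.
#' @export
predict_volume <- function(model, volume, batch = 4096L) {
  stopifnot(inherits(model, "mparseg_model"), inherits(volume, "mp_volume"))
  dims <- dim(volume$sequences$t2w)
  M <- model$patch_edge
  chan <- as_channel_array(volume)
  nvox <- prod(dims)
  p <- numeric(nvox)
  coords_all <- as.matrix(expand.grid(x = seq_len(dims[1]),
                                      y = seq_len(dims[2]),
                                      z = seq_len(dims[3])))
  storage.mode(coords_all) <- "integer"
  for (start in seq(1, nvox, by = batch)) {
    idx <- start:min(start + batch - 1L, nvox)
    patches <- cpp_extract_patches(chan, coords_all[idx, , drop = FALSE],
                                   as.integer(M))
    fw <- nn_forward(model$spec, model$params, patches, dropout = FALSE)
    p[idx] <- fw$probs[2, ]
  }
  structure(list(p = array(p, dims), spacing = volume$spacing,
                 subject_id = volume$subject_id),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  d <- dim(x$p)
  cat(sprintf("<probability_map> %d x %d x %d, p in [%.3f, %.3f]\n",
              d[1], d[2], d[3], min(x$p), max(x$p)))
  invisible(x)
}

#' Threshold a probability map and keep the largest component
#'
#' Voxels with `p(v) >= t` are classified as tumour; the final segmentation
#' is the largest 3D connected component of that suprathreshold set (empty
#' if no voxel passes). Size ties are broken deterministically in favour of
#' the component containing the smallest (column-major) voxel index.
#'
#' @param p a [probability_map] (or bare 3D array of probabilities).
#' @param t probability threshold in `[0, 1]` (default 0.5).
#' @param connectivity 26 (default) or 6 neighbourhood.
#' @return Object of class `seg_mask`: `mask` (binary 3D array, a single
#'   connected component or empty), `component_count` (suprathreshold
#'   components before selection) and `selected_size` (voxels kept).
#' @export
threshold_and_select <- function(p, t = 0.5, connectivity = 26) {
  if (inherits(p, "probability_map")) p <- p$p
  if (!is.numeric(t) || length(t) != 1L || t < 0 || t > 1) {
    stopf("threshold t must be a single probability in [0, 1]")
  }
  if (!connectivity %in% c(6, 26)) stopf("connectivity must be 6 or 26")
  bin <- array(as.integer(p >= t), dim(p))
  lab <- cpp_label_components(bin, as.integer(connectivity))
  ncomp <- max(lab)
  if (ncomp == 0L) {
    return(structure(list(mask = bin * 0L, component_count = 0L,
                          selected_size = 0L),
                     class = "seg_mask"))
  }
  sizes <- tabulate(lab[lab > 0L], nbins = ncomp)
  # components are labelled in order of their smallest linear voxel index,
  # so which.max resolves size ties lexicographically
  keep <- which.max(sizes)
  structure(
    list(mask = array(as.integer(lab == keep), dim(p)),
         component_count = as.integer(ncomp),
         selected_size = as.integer(sizes[keep])),
    class = "seg_mask"
  )
}

#' @export
print.seg_mask <- function(x, ...) {
  cat(sprintf("<seg_mask> %d voxels kept (of %d suprathreshold components)\n",
              x$selected_size, x$component_count))
  invisible(x)
}
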