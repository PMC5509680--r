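# Simplified deformable registration: multi-resolution cubic B-spline
# free-form deformation driven by Parzen-window mutual information with a
# control-lattice bending-energy penalty. This is a pluggable, deliberately
# compact stand-in for a full registration toolbox: same ingredients
# (metric, transform, penalty, multi-resolution), none of the toolbox
# internals.

#' Registration configuration
#'
#' @param grid_spacing B-spline control-point spacing in mm (default 4 mm,
#'   a dense lattice able to capture small local bowel movements).
#' @param penalty_weight weight of the bending-energy penalty relative to
#'   the similarity metric (default 20, i.e. a strong 1:20 weighting that
#'   keeps the recovered field near-rigid unless the data insist).
#' @param metric similarity metric; only the Parzen-window mutual
#'   information variant is implemented.
#' @param n_resolutions number of multi-resolution levels (coarse to fine).
#' @param max_iterations gradient-ascent iterations per level.
#' @param n_bins histogram bins for the joint intensity distribution.
#' @param step_init initial ascent step in mm.
#' @param seed integer (kept for interface symmetry; the optimizer is
#'   deterministic).
#' @return Object of class `registration_config`.
#' @export
registration_config <- function(grid_spacing = 4, penalty_weight = 20,
                                metric = "parzen_mi", n_resolutions = 2,
                                max_iterations = 40, n_bins = 32,
                                step_init = 2.0, seed = 1L) {
  if (grid_spacing <= 0) stopf("grid_spacing must be > 0")
  if (penalty_weight < 0) stopf("penalty_weight must be >= 0")
  structure(
    list(grid_spacing = grid_spacing, penalty_weight = penalty_weight,
         metric = metric, n_resolutions = as.integer(n_resolutions),
         max_iterations = as.integer(max_iterations),
         n_bins = as.integer(n_bins), step_init = step_init,
         seed = as.integer(seed)),
    class = "registration_config"
  )
}

# --- small numerics ---------------------------------------------------------

# Separable Gaussian smoothing of a 3D array (sigma per axis, voxel units).
smooth3d <- function(arr, sigma) {
  d <- dim(arr)
  for (ax in 1:3) {
    if (sigma[ax] <= 0) next
    r <- max(1L, ceiling(3 * sigma[ax]))
    k <- exp(-(seq(-r, r))^2 / (2 * sigma[ax]^2))
    n <- d[ax]
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- pmin(pmax(i + seq(-r, r), 1L), n)
      for (q in seq_along(j)) K[i, j[q]] <- K[i, j[q]] + k[q]
    }
    K <- K / rowSums(K)
    perm <- switch(ax, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
    a <- aperm(arr, perm)
    da <- dim(a)
    a <- array(K %*% matrix(a, da[1]), da)
    arr <- aperm(a, order(perm))
  }
  arr
}

# Cubic B-spline window and its derivative (support |t| < 2).
bspline3 <- function(t) {
  a <- abs(t)
  ifelse(a < 1, (4 - 6 * a^2 + 3 * a^3) / 6,
         ifelse(a < 2, (2 - a)^3 / 6, 0))
}
bspline3_d <- function(t) {
  a <- abs(t)
  s <- sign(t)
  ifelse(a < 1, s * (-12 * a + 9 * a^2) / 6,
         ifelse(a < 2, s * (-3 * (2 - a)^2) / 6, 0))
}

# Sparse voxel->control-point interpolation matrix for a cubic B-spline
# lattice with spacing g (mm). Voxel i sits at (i-1)*sp mm. The lattice is
# shared across resolution levels (defined in mm on the full volume).
bspline_matrix <- function(dims, sp, extent, g) {
  kmax <- floor(extent / g) + 2L   # ctrl indices run -1 .. kmax
  nk <- kmax + 2L                  # count per axis (index k stored at k+2)
  pos <- lapply(1:3, function(a) (seq_len(dims[a]) - 1) * sp[a] / g)
  i0 <- lapply(pos, floor)
  u <- lapply(1:3, function(a) pos[[a]] - i0[[a]])
  w <- lapply(1:3, function(a) {
    cbind(bspline3(u[[a]] + 1), bspline3(u[[a]]),
          bspline3(u[[a]] - 1), bspline3(u[[a]] - 2))
  })
  nvox <- prod(dims)
  g3 <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                    z = seq_len(dims[3]))
  vox <- seq_len(nvox)
  ii <- jj <- xx <- vector("list", 64L)
  q <- 0L
  for (dz in 0:3) for (dy in 0:3) for (dx in 0:3) {
    q <- q + 1L
    kx <- i0[[1]][g3$x] + dx - 1L + 2L   # 1-based lattice index
    ky <- i0[[2]][g3$y] + dy - 1L + 2L
    kz <- i0[[3]][g3$z] + dz - 1L + 2L
    ii[[q]] <- vox
    jj[[q]] <- kx + nk[1] * (ky - 1L + nk[2] * (kz - 1L))
    xx[[q]] <- w[[1]][g3$x, dx + 1] * w[[2]][g3$y, dy + 1] *
      w[[3]][g3$z, dz + 1]
  }
  B <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(nvox, prod(nk)))
  list(B = B, nk = nk)
}

# Bending energy (mean squared second difference of the control lattice,
# per mm^2) and its gradient wrt the lattice displacements.
bending_energy <- function(theta, nk, g) {
  be <- 0
  grad <- array(0, dim = c(nk, 3))
  th <- array(theta, dim = c(nk, 3))
  nterm <- 0
  for (cc in 1:3) for (ax in 1:3) {
    n <- nk[ax]
    if (n < 3) next
    perm <- switch(ax, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 2, 1))
    a <- aperm(th[, , , cc, drop = TRUE], perm)
    da <- dim(a)
    m <- matrix(a, da[1])
    d2 <- (m[1:(n - 2), , drop = FALSE] - 2 * m[2:(n - 1), , drop = FALSE] +
             m[3:n, , drop = FALSE]) / g^2
    be <- be + sum(d2^2)
    nterm <- nterm + length(d2)
    gm <- matrix(0, n, ncol(m))
    gm[1:(n - 2), ] <- gm[1:(n - 2), ] + 2 * d2 / g^2
    gm[2:(n - 1), ] <- gm[2:(n - 1), ] - 4 * d2 / g^2
    gm[3:n, ] <- gm[3:n, ] + 2 * d2 / g^2
    ga <- aperm(array(gm, da), order(perm))
    grad[, , , cc] <- grad[, , , cc] + ga
  }
  if (nterm == 0) nterm <- 1
  list(be = be / nterm, grad = grad / nterm)
}

# Parzen-window mutual information between a (hard-binned) fixed image and
# the moving image warped by voxel-space points `pts`, plus its gradient
# wrt the warped moving intensities. Bin edges are frozen per level.
mi_and_grad <- function(fix_bin, moving, grads, pts, sp, nb, mrange) {
  nvox <- length(fix_bin)
  mw <- cpp_trilinear(moving, pts)
  sm <- (mw - mrange[1]) / (mrange[2] - mrange[1]) * (nb - 1)
  sm <- pmin(pmax(sm, 0), nb - 1)
  j0 <- floor(sm)
  hist_ij <- NULL
  for (dj in -1:2) {
    j <- j0 + dj
    ok <- j >= 0 & j <= nb - 1
    wgt <- bspline3(j - sm)
    h <- Matrix::sparseMatrix(i = fix_bin[ok] + 1L, j = j[ok] + 1L,
                              x = wgt[ok], dims = c(nb, nb))
    hist_ij <- if (is.null(hist_ij)) h else hist_ij + h
  }
  p <- as.matrix(hist_ij) / nvox
  pf <- rowSums(p)
  pm <- colSums(p)
  pos <- p > 0
  mi <- sum(p[pos] * log(p[pos] / (pf[row(p)[pos]] * pm[col(p)[pos]])))
  lg <- matrix(0, nb, nb)
  okm <- pm > 0
  lg[, okm] <- log(pmax(sweep(p[, okm, drop = FALSE], 2, pm[okm], "/"),
                        1e-12))
  dmi_dsm <- numeric(nvox)
  for (dj in -1:2) {
    j <- j0 + dj
    ok <- j >= 0 & j <= nb - 1
    # d/dsm of bspline3(j - sm) = -bspline3_d(j - sm)
    dmi_dsm[ok] <- dmi_dsm[ok] -
      bspline3_d(j[ok] - sm[ok]) * lg[cbind(fix_bin[ok] + 1L, j[ok] + 1L)]
  }
  dmi_dsm <- dmi_dsm / nvox
  dmi_dm <- dmi_dsm * (nb - 1) / (mrange[2] - mrange[1])
  gsamp <- vapply(1:3, function(a) cpp_trilinear(grads[[a]], pts),
                  numeric(nvox))
  gu <- gsamp * dmi_dm / rep(sp, each = nvox)  # wrt displacement in mm
  list(mi = mi, grad_u = gu, warped = mw)
}

#' Deformable registration of a moving volume to a reference
#'
#' Estimates a smooth displacement field (cubic B-spline free-form
#' deformation on a `grid_spacing`-mm lattice) maximizing Parzen-window
#' mutual information between the warped moving volume and the fixed
#' reference, penalized by control-lattice bending energy. Optimization is
#' multi-resolution backtracking gradient ascent; the returned solution is
#' never worse (in the penalized metric) than the identity initialization,
#' so similarity is never degraded.
#'
#' @param moving,fixed numeric 3D arrays of identical shape (standardized).
#' @param config a [registration_config()].
#' @param spacing voxel spacing in mm.
#' @return List with `warped` (moving resampled into the fixed frame),
#'   `displacement` (nx x ny x nz x 3 array, mm, pointing from fixed-space
#'   voxel to its source location in the moving volume), `mi_before`,
#'   `mi_after` and `bending_energy`.
#' @export
register_to_reference <- function(moving, fixed, config = registration_config(),
                                  spacing = c(1, 1, 1)) {
  if (!identical(dim(moving), dim(fixed))) {
    stopf("moving and fixed volumes must have the same shape")
  }
  dims <- dim(fixed)
  spacing <- as.numeric(spacing)
  extent <- (dims - 1) * spacing
  g <- config$grid_spacing
  bm_full <- bspline_matrix(dims, spacing, extent, g)
  nk <- bm_full$nk
  theta <- array(0, dim = c(nk, 3))
  factors <- rev(2^(seq_len(config$n_resolutions) - 1))
  for (f in factors) {
    fa <- pmax(1L, pmin(f, dims %/% 8L))
    if (all(fa == 1L)) {
      fixl <- fixed
      movl <- moving
      spl <- spacing
    } else {
      sg <- ifelse(fa > 1, fa / 2, 0)
      fixl <- smooth3d(fixed, sg)[seq(1, dims[1], fa[1]),
                                  seq(1, dims[2], fa[2]),
                                  seq(1, dims[3], fa[3]), drop = FALSE]
      movl <- smooth3d(moving, sg)[seq(1, dims[1], fa[1]),
                                   seq(1, dims[2], fa[2]),
                                   seq(1, dims[3], fa[3]), drop = FALSE]
      spl <- spacing * fa
    }
    dl <- dim(fixl)
    bm <- if (all(fa == 1L)) bm_full else bspline_matrix(dl, spl, extent, g)
    nb <- config$n_bins
    frange <- range(fixl)
    if (diff(frange) <= 0) frange <- frange + c(-0.5, 0.5)
    fix_bin <- pmin(pmax(floor((as.vector(fixl) - frange[1]) /
                                 diff(frange) * nb), 0), nb - 1L)
    mrange <- range(movl)
    if (diff(mrange) <= 0) mrange <- mrange + c(-0.5, 0.5)
    grads <- list(grad_axis(movl, 1), grad_axis(movl, 2), grad_axis(movl, 3))
    gcoords <- as.matrix(expand.grid(x = seq_len(dl[1]), y = seq_len(dl[2]),
                                     z = seq_len(dl[3])))
    eval_obj <- function(th) {
      u <- as.matrix(bm$B %*% matrix(th, ncol = 3))
      pts <- gcoords + sweep(u, 2, spl, "/")
      r <- mi_and_grad(fix_bin, movl, grads, pts, spl, nb, mrange)
      bp <- bending_energy(th, nk, g)
      list(obj = r$mi - config$penalty_weight * bp$be, mi = r$mi,
           be = bp$be,
           grad = array(as.matrix(Matrix::crossprod(bm$B, r$grad_u)),
                        dim = c(nk, 3)) - config$penalty_weight * bp$grad)
    }
    # never start a level worse than identity
    cur <- eval_obj(theta)
    if (any(theta != 0)) {
      id0 <- eval_obj(array(0, dim = c(nk, 3)))
      if (id0$obj > cur$obj) {
        theta <- array(0, dim = c(nk, 3))
        cur <- id0
      }
    }
    step <- config$step_init
    for (it in seq_len(config$max_iterations)) {
      gmax <- max(abs(cur$grad))
      if (gmax < 1e-12) break
      cand <- theta + step * cur$grad / gmax
      new <- eval_obj(cand)
      if (new$obj > cur$obj + 1e-9) {
        theta <- cand
        cur <- new
        step <- min(step * 1.2, 4)
      } else {
        step <- step / 2
        if (step < 1e-3) break
      }
    }
  }
  u_full <- as.matrix(bm_full$B %*% matrix(theta, ncol = 3))
  gfull <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                                 z = seq_len(dims[3])))
  pts <- gfull + sweep(u_full, 2, spacing, "/")
  warped <- array(cpp_trilinear(moving, pts), dims)
  nb <- config$n_bins
  mi0 <- plain_mi(fixed, moving, nb)
  mi1 <- plain_mi(fixed, warped, nb)
  be <- bending_energy(theta, nk, g)$be
  list(warped = warped,
       displacement = array(u_full, dim = c(dims, 3)),
       mi_before = mi0, mi_after = mi1, bending_energy = be)
}

# Central-difference gradient along one axis (intensity per voxel).
grad_axis <- function(arr, ax) {
  d <- dim(arr)
  n <- d[ax]
  idx_p <- pmin(seq_len(n) + 1L, n)
  idx_m <- pmax(seq_len(n) - 1L, 1L)
  sel <- function(i) {
    switch(ax, `1` = arr[i, , , drop = FALSE], `2` = arr[, i, , drop = FALSE],
           `3` = arr[, , i, drop = FALSE])
  }
  (sel(idx_p) - sel(idx_m)) / 2
}

# Histogram mutual information (hard binning both images); reporting only.
plain_mi <- function(a, b, nb = 32) {
  bin <- function(x) {
    r <- range(x)
    if (diff(r) <= 0) r <- r + c(-0.5, 0.5)
    pmin(pmax(floor((as.vector(x) - r[1]) / diff(r) * nb), 0), nb - 1L)
  }
  ia <- bin(a)
  ib <- bin(b)
  p <- as.matrix(Matrix::sparseMatrix(i = ia + 1L, j = ib + 1L,
                                      x = rep(1, length(ia)),
                                      dims = c(nb, nb))) / length(ia)
  pf <- rowSums(p)
  pm <- colSums(p)
  pos <- p > 0
  sum(p[pos] * log(p[pos] / (pf[row(p)[pos]] * pm[col(p)[pos]])))
}
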