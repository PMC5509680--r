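test_that("the spherical structuring element is anisotropy-aware", {
  offs <- sphere_offsets(10, c(2, 2, 5))
  # half-widths (5, 5, 2) voxels for a 10 mm sphere at 2 x 2 x 5 mm
  expect_equal(apply(abs(offs), 2, max), c(dx = 5, dy = 5, dz = 2))
  # matches exhaustive enumeration over a generous bounding box
  g <- expand.grid(dx = -8:8, dy = -8:8, dz = -8:8)
  d2 <- (2 * g$dx)^2 + (2 * g$dy)^2 + (5 * g$dz)^2
  expect_equal(nrow(offs), sum(d2 <= 100))
})

test_that("B1 of a single central voxel equals the brute-force physical sphere", {
  dims <- c(21, 21, 9)
  sp <- c(2, 2, 5)
  mask <- array(0L, dims)
  centre <- c(11, 11, 5)
  mask[centre[1], centre[2], centre[3]] <- 1L
  vol <- array(0, dims)
  dec <- decompose_regions(vol, label_map(mask), sp)
  # oracle: every voxel within 10 mm physical distance of the centre,
  # excluding the tumour voxel itself
  g <- expand.grid(x = 1:dims[1], y = 1:dims[2], z = 1:dims[3])
  d2 <- ((g$x - centre[1]) * sp[1])^2 + ((g$y - centre[2]) * sp[2])^2 +
    ((g$z - centre[3]) * sp[3])^2
  oracle_b1 <- sum(d2 <= 100) - 1L
  expect_equal(unname(dec$counts["B1"]), oracle_b1)
  expect_equal(unname(dec$counts["B1"]), 204L)
})

test_that("strata partition the volume and match brute-force reclassification", {
  for (seed in 1:4) {
    cfg <- phantom_config(grid_shape = c(16, 16, 8), spacing = c(2, 2, 5),
                          tumour_radius = 6, seed = seed)
    ph <- generate_phantom(cfg)
    hb <- standardize(ph$volume$sequences$dwi_high_b)
    attributes(hb) <- list(dim = dim(hb))
    dec <- decompose_regions(hb, ph$labels, cfg$spacing)
    # partition: every voxel exactly one code
    expect_equal(sum(dec$counts), prod(dim(hb)))
    expect_true(all(dec$stratum %in% 1:4))
    # T equals the label support
    expect_identical(dec$stratum == 1L, ph$labels$mask == 1L)
    # brute-force reclassification of each voxel
    tum <- which(ph$labels$mask == 1L, arr.ind = TRUE)
    g <- as.matrix(expand.grid(x = 1:16, y = 1:16, z = 1:8))
    mind2 <- apply(g, 1, function(v) {
      min(colSums((t(tum) - v)^2 * cfg$spacing^2))
    })
    in_t <- as.vector(ph$labels$mask == 1L)
    in_b1 <- !in_t & mind2 <= 100
    in_b2 <- !in_t & !in_b1 & as.vector(hb) > 2.0
    expected <- ifelse(in_t, 1L, ifelse(in_b1, 2L, ifelse(in_b2, 3L, 4L)))
    expect_identical(as.vector(dec$stratum), expected)
  }
})

test_that("B2 is empty when nothing is hyperintense outside T and B1", {
  dims <- c(16, 16, 8)
  mask <- array(0L, dims)
  mask[8, 8, 4] <- 1L
  vol <- array(-1, dims)  # nowhere above threshold
  dec <- decompose_regions(vol, label_map(mask), c(2, 2, 5))
  expect_equal(unname(dec$counts["B2"]), 0L)
  expect_equal(unname(dec$counts["B3"]),
               prod(dims) - 1L - unname(dec$counts["B1"]))
})

test_that("degenerate masks are rejected", {
  vol <- array(0, c(16, 16, 8))
  expect_error(decompose_regions(vol, label_map(array(0L, c(16, 16, 8))),
                                 c(2, 2, 5)), "empty tumour mask")
  expect_error(decompose_regions(vol, label_map(array(1L, c(16, 16, 8))),
                                 c(2, 2, 5)), "no background")
  expect_error(decompose_regions(vol, label_map(array(0L, c(8, 8, 8))),
                                 c(2, 2, 5)), "shapes differ")
})

sampling_fixture <- function(seed = 1) {
  ph <- generate_phantom(tiny_phantom_config(seed = seed))
  v <- standardize_volume(ph$volume)
  dec <- decompose_regions(v$sequences$dwi_high_b, ph$labels, v$spacing)
  list(v = v, dec = dec, ph = ph)
}

test_that("quotas follow the N, N/4, N/2, N/4 rule", {
  fx <- sampling_fixture()
  ps <- sample_patches(fx$v, fx$dec, n_per_class = 8, M = 5, seed = 2)
  expect_equal(sum(ps$labels == 1L), 8)
  expect_equal(sum(ps$labels == 0L), 8)
  expect_equal(as.integer(table(ps$strata)[c("B1", "B2", "B3")]),
               c(2L, 4L, 2L))
  expect_error(sample_patches(fx$v, fx$dec, n_per_class = 6, M = 5),
               "divisible by 4")
  expect_error(sample_patches(fx$v, fx$dec, n_per_class = 8, M = 4), "odd")
})

test_that("an empty stratum donates its quota proportionally", {
  dims <- c(16, 16, 8)
  mask <- array(0L, dims)
  mask[8, 8, 4] <- 1L
  vol <- mp_volume(array(rnorm(prod(dims)), dims),
                   array(rnorm(prod(dims)), dims),
                   array(-1, dims), c(2, 2, 5))  # high-b all below 2.0
  dec <- decompose_regions(vol$sequences$dwi_high_b, label_map(mask),
                           c(2, 2, 5))
  expect_equal(unname(dec$counts["B2"]), 0L)
  ps <- sample_patches(vol, dec, n_per_class = 8, M = 3, seed = 1)
  tab <- table(ps$strata)
  expect_equal(unname(tab["B1"]), 4L)  # B2's N/2 split evenly to B1/B3
  expect_equal(unname(tab["B3"]), 4L)
  expect_false("B2" %in% ps$strata)
})

test_that("sampled coordinates are reproducible and match their strata", {
  fx <- sampling_fixture(seed = 7)
  a <- sample_patches(fx$v, fx$dec, n_per_class = 40, M = 5, seed = 9)
  b <- sample_patches(fx$v, fx$dec, n_per_class = 40, M = 5, seed = 9)
  expect_identical(a$coords, b$coords)
  expect_identical(a$patches, b$patches)
  code <- c(T = 1L, B1 = 2L, B2 = 3L, B3 = 4L)
  expect_equal(unname(code[a$strata]),
               fx$dec$stratum[a$coords])
  # label equals the label of the central voxel
  expect_equal(a$labels, unname(fx$ph$labels$mask[a$coords]))
})

test_that("patches are centred, channel-ordered and zero-padded at borders", {
  fx <- sampling_fixture(seed = 3)
  v <- fx$v
  vox <- c(16L, 16L, 4L)
  p <- extract_patch(v, vox, M = 5)
  expect_equal(dim(p), c(5, 5, 3))
  expect_equal(p[3, 3, 1], v$sequences$t2w[16, 16, 4])
  expect_equal(p[3, 3, 2], v$sequences$dwi_high_b[16, 16, 4])
  expect_equal(p[3, 3, 3], v$sequences$dwi_b0[16, 16, 4])
  # degenerate M = 1 patch is just the voxel's three sequence values
  p1 <- extract_patch(v, vox, M = 1)
  expect_equal(as.vector(p1),
               c(v$sequences$t2w[16, 16, 4],
                 v$sequences$dwi_high_b[16, 16, 4],
                 v$sequences$dwi_b0[16, 16, 4]))
  # corner patch keeps its shape, margin zero-filled
  pc <- extract_patch(v, c(1L, 1L, 1L), M = 21)
  expect_equal(dim(pc), c(21, 21, 3))
  expect_true(all(pc[1:10, , ] == 0))
  expect_equal(pc[11, 11, 1], v$sequences$t2w[1, 1, 1])
  expect_error(extract_patch(v, c(0L, 1L, 1L), M = 5), "outside")
  expect_error(extract_patch(v, vox, M = 4), "odd")
})

test_that("patch sets combine and subset consistently", {
  fx <- sampling_fixture()
  a <- sample_patches(fx$v, fx$dec, 8, M = 5, seed = 1)
  b <- sample_patches(fx$v, fx$dec, 8, M = 5, seed = 2)
  ab <- combine_patch_sets(list(a, b))
  expect_equal(length(ab$labels), 32)
  expect_equal(ab$patches[, , , 1:16], a$patches)
  sub <- mparseg:::subset_patch_set(ab, 17:32)
  expect_equal(sub$patches, b$patches)
  expect_equal(sub$labels, b$labels)
})
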