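test_that("phantom config validates its invariants", {
  expect_error(phantom_config(grid_shape = c(4, 32, 8)), "grid_shape")
  expect_error(phantom_config(spacing = c(2, 0, 5)), "spacing")
  expect_error(phantom_config(tumour_radius = -1), "tumour_radius")
})

test_that("phantom generation is a pure function of (config, seed)", {
  cfg <- tiny_phantom_config(seed = 11)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$volume$sequences, b$volume$sequences)
  expect_identical(a$labels$mask, b$labels$mask)
  cfg2 <- tiny_phantom_config(seed = 12)
  c <- generate_phantom(cfg2)
  expect_false(identical(a$volume$sequences$t2w, c$volume$sequences$t2w))
})

test_that("tumour voxel count matches the analytic sphere volume", {
  cfg <- phantom_config(grid_shape = c(64, 64, 16), spacing = c(2, 2, 5),
                        tumour_radius = 10, seed = 1)
  ph <- generate_phantom(cfg)
  expected <- (4 / 3 * pi * 10^3) / prod(c(2, 2, 5))  # ~209 voxels
  n <- sum(ph$labels$mask)
  expect_gt(n, expected * 0.85)
  expect_lt(n, expected * 1.15)
  # oracle: voxels whose centre lies inside the analytic sphere
  gs <- cfg$grid_shape
  sp <- cfg$spacing
  g <- expand.grid(x = seq_len(gs[1]), y = seq_len(gs[2]), z = seq_len(gs[3]))
  d2 <- ((g$x - 1) * sp[1] - cfg$tumour_centre[1])^2 +
    ((g$y - 1) * sp[2] - cfg$tumour_centre[2])^2 +
    ((g$z - 1) * sp[3] - cfg$tumour_centre[3])^2
  expect_equal(n, sum(d2 <= 100))
})

test_that("zero tumour radius gives an all-zero label map", {
  ph <- generate_phantom(tiny_phantom_config(tumour_radius = 0))
  expect_true(all(ph$labels$mask == 0L))
})

test_that("tumour and distractors are hyperintense on standardized high-b DWI", {
  cfg <- tiny_phantom_config(
    seed = 4,
    distractors = list(list(centre = c(12, 12, 17.5), radius = 5,
                            offsets = c(t2w = 3, dwi_b0 = 2, dwi_high_b = 4)))
  )
  ph <- generate_phantom(cfg)
  v <- standardize_volume(ph$volume)
  hb <- v$sequences$dwi_high_b
  tum <- ph$labels$mask == 1L
  bg <- !tum & !ph$distractors[[1]]
  # tumour mean at least 2 background SDs above the background mean
  expect_gt(mean(hb[tum]), mean(hb[bg]) + 2 * sd(hb[bg]))
  expect_gt(mean(hb[tum]), 2.0)
  expect_gt(mean(hb[ph$distractors[[1]]]), 2.0)
  # t2w intermediate: above background, below its own high-b contrast
  expect_gt(mean(v$sequences$t2w[tum]), mean(v$sequences$t2w[bg]))
  expect_lt(mean(v$sequences$t2w[tum]), mean(hb[tum]))
})

test_that("invalid geometry is rejected", {
  expect_error(
    generate_phantom(tiny_phantom_config(tumour_centre = c(2, 31, 17.5))),
    "outside the grid"
  )
  expect_error(
    generate_phantom(tiny_phantom_config(
      distractors = list(list(centre = c(31, 31, 17.5), radius = 6,
                              offsets = c(t2w = 1, dwi_b0 = 1,
                                          dwi_high_b = 1))))),
    "overlaps the tumour"
  )
})

test_that("artefact and misalignment modes produce valid volumes", {
  for (mode in c("fat_suppression_band", "ghosting")) {
    ph <- generate_phantom(tiny_phantom_config(artefact_mode = mode))
    expect_true(all(is.finite(ph$volume$sequences$dwi_high_b)))
  }
  ph0 <- generate_phantom(tiny_phantom_config(seed = 5))
  ph1 <- generate_phantom(tiny_phantom_config(seed = 5, misalignment = 4))
  expect_false(identical(ph0$volume$sequences$t2w, ph1$volume$sequences$t2w))
  expect_identical(ph0$volume$sequences$dwi_high_b,
                   ph1$volume$sequences$dwi_high_b)
})

test_that("cohorts are reproducible with distinct jittered subjects", {
  base <- tiny_phantom_config()
  co <- generate_cohort(30, base, seed = 21)
  co2 <- generate_cohort(30, base, seed = 21)
  ids <- vapply(co, function(s) s$volume$subject_id, character(1))
  expect_length(unique(ids), 30)
  centres <- t(vapply(co, function(s) s$config$tumour_centre, numeric(3)))
  expect_equal(nrow(unique(centres)), 30)
  expect_identical(co[[17]]$volume$sequences, co2[[17]]$volume$sequences)
  expect_identical(generate_cohort(1, base, seed = 3)[[1]]$labels$mask,
                   generate_cohort(1, base, seed = 3)[[1]]$labels$mask)
})

test_that("a distractor configured larger than the tumour stays larger", {
  base <- phantom_config(
    grid_shape = c(64, 64, 16), spacing = c(2, 2, 5), tumour_radius = 8,
    distractors = list(list(centre = c(95, 36, 37.5), radius = 13,
                            offsets = c(t2w = 1.5, dwi_b0 = 0.5,
                                        dwi_high_b = 4)))
  )
  co <- generate_cohort(5, base, seed = 8)
  for (s in co) {
    expect_gt(sum(s$distractors[[1]]), sum(s$labels$mask))
  }
})
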