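test_that("top-hat of a constant raster is zero and offsets are removed exactly", {
  x <- matrix(500, 48, 48)
  expect_true(all(tophat_filter(x, 5) == 0))

  sc <- simulate_micrograph(n_nuclei = 0, n_foci = 3, n_puncta = 0,
                            image_shape = c(96, 96), noise_sd = 200,
                            cytosol_amplitude = 0, seed = 2)
  y <- sc$micrograph$channels$gal8
  expect_identical(tophat_filter(y, 5), tophat_filter(y + 1234, 5))
})

test_that("top-hat matches the brute-force min/max opening oracle", {
  # a Gaussian spot (sigma << radius) on a constant offset, 64x64
  x <- matrix(500, 64, 64)
  for (r in 1:64) for (cc in 1:64) {
    x[r, cc] <- x[r, cc] + 3000 * exp(-((r - 32)^2 + (cc - 20)^2) / (2 * 1.5^2))
  }
  got <- tophat_filter(x, 5)
  want <- brute_tophat(x, 5)
  expect_equal(got, want, tolerance = 1e-8)
  expect_gte(min(got), 0)
  expect_gt(got[32, 20], 2900)   # spot preserved
  expect_lt(max(got[, 50:64]), 1e-6)  # offset removed away from the spot

  # and on a rough random raster
  set.seed(71)
  z <- matrix(runif(32 * 32, 0, 1000), 32, 32)
  expect_equal(tophat_filter(z, 4), brute_tophat(z, 4), tolerance = 1e-8)
})

test_that("top-hat rejects radii that do not fit the image", {
  expect_error(tophat_filter(matrix(0, 20, 20), 10),
               class = "colloidquant_bad_input")
})

test_that("segmentation without watershed equals flood-fill components", {
  cfg <- channel_config(threshold_method = "fixed", threshold_value = 0.5,
                        min_area = 1, watershed = FALSE)
  withr::with_seed(123, {
    for (i in 1:50) {
      mask <- matrix(runif(64 * 64) < runif(1, 0.05, 0.5), 64, 64)
      labels <- segment_objects(mask * 1, cfg)
      expect_identical(count_objects(labels), flood_fill_count(mask))
    }
  })
})

test_that("watershed splits two overlapping disks that merge without it", {
  # centres 1.4 radii apart -> one connected component, two true objects
  scene <- disk_scene(c(64, 64), rbind(c(30, 25), c(30, 39)), radius = 10) * 5000
  on <- channel_config(threshold_method = "fixed", threshold_value = 100,
                       min_area = 1, watershed = TRUE)
  off <- channel_config(threshold_method = "fixed", threshold_value = 100,
                        min_area = 1, watershed = FALSE)
  expect_identical(count_objects(segment_objects(scene, on)), 2L)
  expect_identical(count_objects(segment_objects(scene, off)), 1L)
})

test_that("blank rasters and sub-minimum features yield no labels", {
  cfg <- channel_config(threshold_method = "fixed", threshold_value = 10,
                        min_area = 20, watershed = TRUE)
  expect_identical(count_objects(segment_objects(matrix(0, 32, 32), cfg)), 0L)
  # otsu on a constant raster: empty mask, no error
  expect_identical(
    count_objects(segment_objects(matrix(7, 32, 32),
                                  channel_config(threshold_method = "otsu"))),
    0L)
  small <- disk_scene(c(32, 32), cbind(16, 16), radius = 2) * 100  # area ~13 < 20
  expect_identical(count_objects(segment_objects(small, cfg)), 0L)
})

test_that("count_objects counts distinct nonzero labels", {
  expect_identical(count_objects(matrix(0L, 5, 5)), 0L)
  lab <- matrix(0L, 5, 5)
  lab[1, 1:5] <- 1:5
  lab[3, 1:5] <- 6:10
  expect_identical(count_objects(lab), 10L)
})

test_that("increasing min_area never increases any count", {
  sc <- simulate_micrograph(n_nuclei = 20, n_foci = 15, n_puncta = 60,
                            image_shape = c(384, 384), seed = 17)
  th <- tophat_filter(sc$micrograph$channels$did, 5)
  counts <- vapply(c(1, 3, 6, 12, 25), function(a) {
    count_objects(segment_objects(th, channel_config(min_area = a)))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("full-pipeline counts recover the scene truth", {
  sc <- simulate_micrograph(n_nuclei = 100, n_foci = 40, n_puncta = 250,
                            n_vesicles = 0, seed = 21)
  q <- quantify_image(sc$micrograph)
  tc <- truth_counts(sc$truth)
  expect_lte(abs(q$nuclei - tc$nuclei) / tc$nuclei, 0.05)
  expect_lte(abs(q$foci - tc$foci) / tc$foci, 0.05)
  expect_lte(abs(q$puncta - tc$puncta) / tc$puncta, 0.05)
  expect_identical(q$vesicles, 0L)
  expect_equal(q$foci_per_cell, q$foci / q$nuclei)
  expect_equal(q$puncta_per_cell, q$puncta / q$nuclei)
})

test_that("blocker-well scenes report zero puncta per cell", {
  sc <- simulate_micrograph(n_nuclei = 50, n_foci = 10, n_puncta = 0,
                            image_shape = c(512, 512), seed = 8,
                            treatment = list(compound = "F", concentration_uM = 5,
                                             blocker = TRUE))
  q <- quantify_image(sc$micrograph)
  expect_identical(q$puncta, 0L)
  expect_identical(q$puncta_per_cell, 0)
  expect_true(q$blocker)
})

test_that("an all-blank micrograph reports zero counts and undefined ratios", {
  sc <- simulate_micrograph(n_nuclei = 0, n_foci = 0, n_puncta = 0,
                            image_shape = c(128, 128), noise_sd = 0, seed = 1)
  q <- quantify_image(sc$micrograph)
  expect_identical(unlist(q[c("nuclei", "foci", "puncta", "vesicles")]),
                   c(nuclei = 0L, foci = 0L, puncta = 0L, vesicles = 0L))
  expect_true(all(is.na(q[c("foci_per_cell", "puncta_per_cell",
                            "vesicles_per_cell")])))
})

test_that("replicate aggregation is the arithmetic mean of member ratios", {
  counts <- tibble::tibble(
    well_id = c("a", "b", "c"), replicate_id = "r1",
    foci_per_cell = c(0.2, 0.4, 0.6),
    puncta_per_cell = c(1, 2, 3),
    vesicles_per_cell = c(0, 0, 0)
  )
  agg <- aggregate_replicates(counts, "replicate_id")
  expect_equal(agg$foci_per_cell, 0.4)
  expect_equal(agg$puncta_per_cell, 2)
  expect_identical(agg$n_images, 3L)

  # three identical records aggregate to themselves
  same <- counts
  same$foci_per_cell <- 0.3
  same$puncta_per_cell <- 2.5
  agg2 <- aggregate_replicates(same, "replicate_id")
  expect_equal(agg2$foci_per_cell, 0.3)
  expect_error(aggregate_replicates(counts[0, ]), class = "colloidquant_bad_input")
})

test_that("replicate aggregate of three generated images tracks the truth ratio", {
  qs <- purrr::map_dfr(1:3, function(i) {
    sc <- simulate_micrograph(n_nuclei = 60, n_foci = 30, n_puncta = 120,
                              image_shape = c(640, 640), seed = 100 + i,
                              well_id = sprintf("w%d", i))
    dplyr::mutate(quantify_image(sc$micrograph), replicate_id = "rep1")
  })
  agg <- aggregate_replicates(qs, "replicate_id")
  expect_equal(agg$foci_per_cell, 0.5, tolerance = 0.05)
  expect_equal(agg$puncta_per_cell, 2, tolerance = 0.05)
})

test_that("mutual centroid overlap counting finds coincident foci and puncta", {
  img <- matrix(0, 96, 96)
  gal8 <- add_spot <- function(m, r, c) {
    for (i in 1:96) for (j in 1:96) {
      m[i, j] <- m[i, j] + 8000 * exp(-((i - r)^2 + (j - c)^2) / (2 * 1.5^2))
    }
    m
  }
  g <- add_spot(add_spot(img, 30, 30), 70, 70)
  d <- add_spot(add_spot(img, 30, 30), 20, 80)  # one shared site
  m <- micrograph(list(gal8 = g, did = d))
  spot_cfg <- channel_config(threshold_method = "fixed", threshold_value = 2000,
                             min_area = 3)
  cfg <- quant_config(gal8 = spot_cfg, did = spot_cfg)
  expect_identical(count_overlaps(m, cfg), 1L)
})
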