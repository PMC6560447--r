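test_that("center crops have the calibrated pixel size and stay centered", {
  img <- crumb_image(matrix(runif(600 * 600, 0, 255), 600, 600), ppcm = 138)
  cr <- crop_center(img, side_cm = 3.9)
  expect_equal(dim(cr$pixels), c(538, 538)) # round(3.9 * 138)
  # identity crop
  small <- crumb_image(matrix(runif(100 * 100), 100, 100), ppcm = 100)
  expect_equal(crop_center(small, 1)$pixels, small$pixels)
  # crop centroid within one pixel of the image centroid
  for (n in c(101, 102)) {
    im <- crumb_image(matrix(0, n, n), ppcm = 10)
    px <- round(5.7 * 10)
    expect_error(cc <- crop_center(im, 5.7), NA)
    off <- floor((n - px) / 2)
    expect_lte(abs((off + (px + 1) / 2) - (n + 1) / 2), 1)
  }
  expect_error(crop_center(small, 10), "smaller")
})

test_that("two-tone images segment exactly with the dark phase as cells", {
  set.seed(1)
  px <- matrix(200, 60, 60)
  px[20:30, 15:40] <- 40
  img <- crumb_image(px, ppcm = 138)
  seg <- kmeans_segment(img, seed = 3)
  expect_identical(seg$mask, px == 40)
  expect_equal(seg$n_cells, 1L)
  # same seed gives the identical mask
  seg2 <- kmeans_segment(img, seed = 3)
  expect_identical(seg$mask, seg2$mask)
  # inverted polarity
  seg3 <- kmeans_segment(img, seed = 3, dark_cells = FALSE)
  expect_identical(seg3$mask, px == 200)
})

test_that("uniform images are flagged degenerate", {
  img <- crumb_image(matrix(128, 20, 20))
  expect_warning(seg <- kmeans_segment(img), "degenerate")
  expect_true(seg$degenerate)
  expect_equal(sum(seg$mask), 0)
})

test_that("labeling is 8-connected and respects the minimum size", {
  px <- matrix(200, 20, 20)
  px[2, 2] <- px[3, 3] <- px[4, 4] <- px[5, 5] <- 30   # diagonal chain
  px[10:13, 10:13] <- 30
  img <- crumb_image(px)
  seg <- kmeans_segment(img, seed = 1, min_size = 4)
  expect_equal(seg$n_cells, 2L) # chain of 4 counts as one 8-connected cell
  seg2 <- kmeans_segment(img, seed = 1, min_size = 5)
  expect_equal(seg2$n_cells, 1L) # the chain falls below min_size
})

test_that("disc geometry is recovered within discretization tolerance", {
  syn <- synth_crumb_image(n_cells = 50, radius_px = 5, radius_sd_px = 0,
                           field_cm = 3.9, ppcm = 138, noise_sd = 0, seed = 42)
  seg <- kmeans_segment(syn$image, seed = 1)
  gf <- grain_features(seg, syn$image)
  field_mm2 <- (538 * (10 / 138))^2
  expect_equal(gf$cde, 50 / field_mm2, tolerance = 1e-9)
  expect_equal(gf$mca, pi * (5 * 10 / 138)^2, tolerance = 0.05)
  expect_equal(gf$vfr, 50 * gf$mca / field_mm2, tolerance = 1e-9)
})

test_that("VFR = CDE x MCA on arbitrary segmented images", {
  for (s in 1:5) {
    syn <- synth_crumb_image(n_cells = 10 + 5 * s, radius_px = 4,
                             radius_sd_px = 1, field_cm = 1.5, ppcm = 100,
                             noise_sd = 8, seed = s)
    seg <- kmeans_segment(syn$image, seed = s)
    gf <- grain_features(seg, syn$image)
    expect_equal(gf$vfr, gf$cde * gf$mca, tolerance = 1e-9)
  }
})

test_that("a single cell covering the field gives VFR 1", {
  side <- 30
  seg <- structure(list(mask = matrix(TRUE, side, side),
                        labels = matrix(1L, side, side),
                        centroids = c(60, 200), n_cells = 1L,
                        min_size = 0L, degenerate = FALSE),
                   class = "crumb_segmentation")
  img <- crumb_image(matrix(60, side, side), ppcm = 10)
  gf <- grain_features(seg, img)
  expect_equal(gf$vfr, 1)
  expect_equal(gf$cde, 1 / gf$field_mm2)
  expect_equal(gf$mca, gf$field_mm2)
})

test_that("an empty mask reports zero features with a flag", {
  side <- 20
  seg <- structure(list(mask = matrix(FALSE, side, side),
                        labels = matrix(0L, side, side),
                        centroids = c(60, 200), n_cells = 0L,
                        min_size = 4L, degenerate = FALSE),
                   class = "crumb_segmentation")
  gf <- grain_features(seg, crumb_image(matrix(200, side, side), ppcm = 10))
  expect_true(gf$no_cells)
  expect_equal(c(gf$mca, gf$cde, gf$vfr), c(0, 0, 0))
})

test_that("features are invariant to order-preserving intensity rescaling", {
  syn <- synth_crumb_image(n_cells = 20, radius_px = 4, field_cm = 1.5,
                           ppcm = 100, noise_sd = 5, seed = 9)
  g1 <- grain_features(kmeans_segment(syn$image, seed = 2), syn$image)
  resc <- crumb_image(0.6 * syn$image$pixels + 40, syn$image$ppcm)
  g2 <- grain_features(kmeans_segment(resc, seed = 2), resc)
  expect_equal(g1$vfr, g2$vfr, tolerance = 1e-9)
  expect_equal(g1$cde, g2$cde, tolerance = 1e-9)
})

test_that("merging cells at fixed area lowers CDE and raises MCA", {
  side <- 60
  base <- matrix(200, side, side)
  sep <- base
  # eight separate 4x4 squares
  pos <- cbind(c(5, 5, 20, 20, 35, 35, 50, 50), c(5, 25, 5, 25, 5, 25, 5, 25))
  for (r in seq_len(nrow(pos))) {
    sep[pos[r, 1]:(pos[r, 1] + 3), pos[r, 2]:(pos[r, 2] + 3)] <- 40
  }
  merged <- base
  # same total area in four 4x8 blocks
  pos2 <- cbind(c(5, 20, 35, 50), c(45, 45, 45, 45))
  for (r in seq_len(nrow(pos2))) {
    merged[pos2[r, 1]:(pos2[r, 1] + 3), pos2[r, 2]:(pos2[r, 2] + 7)] <- 40
  }
  im1 <- crumb_image(sep, ppcm = 50)
  im2 <- crumb_image(merged, ppcm = 50)
  f1 <- grain_features(kmeans_segment(im1, seed = 1), im1)
  f2 <- grain_features(kmeans_segment(im2, seed = 1), im2)
  expect_equal(f1$vfr, f2$vfr, tolerance = 1e-12)
  expect_lt(f2$cde, f1$cde)
  expect_gt(f2$mca, f1$mca)
})

test_that("segmentation recovers the ground-truth mask under noise", {
  syn <- synth_crumb_image(n_cells = 30, radius_px = 5, radius_sd_px = 1,
                           field_cm = 2, ppcm = 138, noise_sd = 10, seed = 17)
  seg <- kmeans_segment(syn$image, seed = 4)
  jacc <- sum(seg$mask & syn$mask) / sum(seg$mask | syn$mask)
  expect_gte(jacc, 0.95)
})

test_that("synthetic image bookkeeping is exact and pipeline error is small", {
  blank <- synth_crumb_image(n_cells = 0, field_cm = 1, ppcm = 100, seed = 1)
  expect_equal(blank$truth$vfr, 0)
  expect_equal(sum(blank$mask), 0)
  syn <- synth_crumb_image(n_cells = 12, radius_px = 5, field_cm = 1.5,
                           ppcm = 100, noise_sd = 0, seed = 3)
  expect_equal(syn$truth$vfr, sum(syn$mask) / length(syn$mask),
               tolerance = 1e-12)
  errs <- vapply(1:20, function(s) {
    sy <- synth_crumb_image(n_cells = 25, radius_px = 5, radius_sd_px = 1,
                            field_cm = 2, ppcm = 100, noise_sd = 10,
                            seed = 100 + s)
    sg <- kmeans_segment(sy$image, seed = s)
    abs(grain_features(sg, sy$image)$vfr - sy$truth$vfr)
  }, numeric(1))
  expect_lte(median(errs), 0.02)
})

test_that("images written to disk read back identically", {
  syn <- synth_crumb_image(n_cells = 5, radius_px = 4, field_cm = 1,
                           ppcm = 100, noise_sd = 0, seed = 2)
  for (ext in c(".png", ".tif")) {
    f <- tempfile(fileext = ext)
    write_crumb_image(syn$image, f)
    back <- crumb_image(f, ppcm = 100)
    expect_equal(dim(back$pixels), dim(syn$image$pixels))
    expect_lt(max(abs(back$pixels - syn$image$pixels)), 1.01)
    unlink(f)
  }
})
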