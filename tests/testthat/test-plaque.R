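test_that("Otsu segmentation recovers a noiseless synthetic mask exactly", {
  mask <- disk_mask()
  truth <- generate_plaque_image(mask, 6, seed = 2)
  seg <- segment_plaques(truth$image, mask)
  expect_equal(seg, truth$truth_mask, ignore_attr = TRUE)
  expect_equal(attr(seg, "method"), "otsu")
  expect_true(attr(seg, "threshold") > 0 && attr(seg, "threshold") < 0.8)
})

test_that("a blank region segments to an empty mask, not spurious plaques", {
  mask <- disk_mask()
  blank <- matrix(0.2, 200, 200)
  seg <- segment_plaques(blank, mask)
  expect_equal(sum(seg), 0)
  expect_equal(plaque_burden(seg, mask), 0)
})

test_that("segmentation stays accurate under realistic pixel noise", {
  mask <- disk_mask()
  truth <- generate_plaque_image(mask, 8, noise_sd = 0.08, seed = 4)
  seg <- segment_plaques(truth$image, mask)
  inter <- sum(seg & truth$truth_mask)
  dice <- 2 * inter / (sum(seg) + sum(truth$truth_mask))
  expect_gt(dice, 0.95)
  expect_lt(abs(plaque_burden(seg, mask) -
                  plaque_burden(truth$truth_mask, mask)), 1)
})

test_that("the burden formula is plaque pixels over region pixels times 100", {
  region <- matrix(FALSE, 10, 10)
  region[1:5, 1:8] <- TRUE                      # 40 region pixels
  plaque <- matrix(FALSE, 10, 10)
  plaque[1:2, 1:5] <- TRUE                      # 10 plaque pixels
  expect_equal(plaque_burden(plaque, region), 25)
  expect_equal(plaque_burden(region, region), 100)
  outside <- plaque
  outside[10, 10] <- TRUE
  expect_error(plaque_burden(outside, region), "outside")
  expect_error(plaque_burden(plaque, matrix(FALSE, 10, 10)), "zero area")
})

test_that("Otsu thresholding is invariant to affine intensity rescaling", {
  mask <- disk_mask()
  truth <- generate_plaque_image(mask, 5, noise_sd = 0.05, seed = 9)
  seg1 <- segment_plaques(truth$image, mask)
  seg2 <- segment_plaques(0.25 + 0.5 * truth$image, mask)
  expect_equal(seg1, seg2, ignore_attr = TRUE)
})

test_that("estimated burden increases with the true burden", {
  mask <- disk_mask()
  est <- vapply(c(1, 4, 8, 12), function(f) {
    truth <- generate_plaque_image(mask, f, noise_sd = 0.05, seed = 30 + f)
    plaque_burden(segment_plaques(truth$image, mask), mask)
  }, 0)
  expect_true(all(diff(est) > 0))
})

test_that("fixed thresholds and blob-size filtering behave as documented", {
  img <- matrix(0, 20, 20)
  img[2:4, 2:4] <- 0.9          # 9-pixel blob
  img[10, 10] <- 0.9            # single-pixel speck
  region <- matrix(TRUE, 20, 20)
  seg <- segment_plaques(img, region, method = "fixed", threshold = 0.5)
  expect_equal(sum(seg), 10)
  expect_equal(attr(seg, "threshold"), 0.5)
  seg2 <- segment_plaques(img, region, method = "fixed", threshold = 0.5,
                          min_blob = 4)
  expect_equal(sum(seg2), 9)           # speck removed
  expect_false(seg2[10, 10])
  expect_error(segment_plaques(img, region, method = "fixed"), "threshold")
  expect_error(segment_plaques(img, region[1:10, 1:10]), "shape")
})

test_that("histology images round-trip through PNG and TIFF", {
  mask <- disk_mask(64, 24)
  truth <- generate_plaque_image(mask, 7, seed = 11)
  dir <- withr::local_tempdir()
  for (ext in c("png", "tiff")) {
    path <- file.path(dir, paste0("img.", ext))
    write_histology_image(truth$image, path)
    back <- read_histology_image(path)
    expect_equal(dim(back), dim(truth$image))
    # 8-bit PNG quantizes; 1/255 covers both formats
    expect_lt(max(abs(back - truth$image)), 1 / 255 + 1e-9)
    # segmentation of the re-read image still recovers the truth mask
    expect_equal(segment_plaques(back, mask), truth$truth_mask,
                 ignore_attr = TRUE)
  }
  mpath <- file.path(dir, "mask.png")
  write_histology_image(truth$truth_mask, mpath)
  expect_equal(read_histology_image(mpath) > 0.5, truth$truth_mask)
  expect_error(read_histology_image(file.path(dir, "img.bmp")), "format")
  expect_error(write_histology_image(truth$image * 2,
                                     file.path(dir, "x.png")), "0, 1")
})

test_that("the burden table runs the full quantification per image", {
  mask <- disk_mask(100, 40)
  imgs <- list(
    a = list(image = generate_plaque_image(mask, 4, seed = 1)$image,
             region_mask = mask, animal = "m1", region = "AI"),
    b = list(image = generate_plaque_image(mask, 9, seed = 2)$image,
             region_mask = mask, animal = "m2", region = "AI"))
  tab <- plaque_burden_table(imgs)
  expect_equal(tab$animal, c("m1", "m2"))
  expect_equal(tab$burden, c(4, 9), tolerance = 0.02)
  expect_gt(tab$burden[2], tab$burden[1])
})
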