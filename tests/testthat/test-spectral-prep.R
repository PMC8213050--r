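test_that("mean_fill sets outside pixels to the exact domain mean", {
  px <- matrix(0.9, 4, 4)
  px[2, 1] <- 0.2; px[3, 1] <- 0.4
  dom <- manual_domain(px, top = 1, bottom = 3)    # mask rows 1..2 (0-based)
  mf <- mean_fill(dom)
  inside <- dom$mask
  expect_equal(mf$fill_value, mean(px[inside]))
  expect_true(all(mf$image[!inside] == mf$fill_value))
  expect_identical(mf$image[inside], px[inside])
  # mean of the filled image equals the mean of the masked pixels exactly
  expect_equal(mean(mf$image), mean(px[inside]))
  # constant image is a fixed point
  dom2 <- manual_domain(matrix(0.5, 6, 6), top = 2, bottom = 4)
  expect_identical(mean_fill(dom2)$image, matrix(0.5, 6, 6))
  # empty mask errors
  dom3 <- manual_domain(matrix(0.5, 6, 6), top = 5, bottom = 5)
  expect_error(mean_fill(dom3), "empty")
})

test_that("flattening aligns the rounded ISOS row exactly", {
  H <- 64; W <- 300
  isos <- 40 + 10 * sin(2 * pi * (0:(W - 1)) / 150)
  img <- matrix(0.1, H, W)
  img[cbind(round(isos) + 1, 1:W)] <- 1    # marker at the ISOS row
  fl <- flatten_to_isos(img, isos, reference_row = 32, fill_value = 0.1)
  marker_rows <- apply(fl$image, 2, which.max) - 1
  expect_true(all(marker_rows == 32))      # zero variance after flattening
  # identity when already flat at the reference
  img2 <- matrix(runif(H * W), H, W)
  fl2 <- flatten_to_isos(img2, rep(32, W), 32, 0)
  expect_identical(fl2$image, img2)
})

test_that("flattening refuses shifts that push the domain out of frame", {
  px <- matrix(0.5, 64, 100)
  dom <- manual_domain(px, top = 10, bottom = 60)
  mf <- mean_fill(dom)
  expect_error(
    flatten_to_isos(mf$image, rep(30, 100), reference_row = 60,
                    fill_value = mf$fill_value, mask = mf$mask),
    "outside the frame")
})

test_that("flattened curved scenes match their flat twins axially", {
  curved <- render_bscan(scene_spec(curvature_amp_px = 10,
                                    curvature_period_px = 160,
                                    pit_depth_px = 0, speckle_cv = 0))
  flat <- render_bscan(scene_spec(curvature_amp_px = 0, pit_depth_px = 0,
                                  speckle_cv = 0))
  pc <- prepare_domain(extract_domain(curved$image, curved$truth, "FULL"),
                       curved$truth)
  pf <- prepare_domain(extract_domain(flat$image, flat$truth, "FULL"),
                       flat$truth)
  prof_c <- rowMeans(pc$pixels)
  prof_f <- rowMeans(pf$pixels)
  expect_lt(max(abs(prof_c - prof_f)), 0.02)   # within ~1 px of blur
})

test_that("edge ramping blends linearly from the fill level", {
  px <- matrix(0.8, 64, 100)
  dom <- manual_domain(px, top = 10, bottom = 50)
  img <- px; fill <- 0.3
  # ramp_width 1: only the outermost domain columns replaced by fill
  r1 <- ramp_edges(img, dom$mask, fill, 1)
  expect_true(all(r1[, 1] == fill) && all(r1[, 100] == fill))
  expect_identical(r1[, 2:99], img[, 2:99])
  # ramp_width 16 on a 0.8 domain with fill 0.3
  r16 <- ramp_edges(img, dom$mask, fill, 16)
  expect_equal(r16[30, 1], 0.3)                  # edge: w = 0
  expect_equal(r16[30, 9], 0.55)                 # midpoint: w = 0.5
  expect_equal(r16[30, 17], 0.8)                 # first unramped column
  # a domain equal to its mean is a fixed point
  rfix <- ramp_edges(matrix(fill, 64, 100), dom$mask, fill, 16)
  expect_identical(rfix, matrix(fill, 64, 100))
  expect_error(ramp_edges(img, dom$mask, fill, 40), "third")
})

test_that("embedding centers the source in the frame", {
  src <- matrix(runif(60 * 768), 60, 768)
  em <- embed_frame(src, fill_value = 0.25, frame_px = 800)
  expect_equal(dim(em), c(800, 800))
  expect_identical(em[370 + 1:60, 16 + 1:768], src)    # cols 16..783
  outside <- em; outside[370 + 1:60, 16 + 1:768] <- 0.25
  expect_true(all(outside == 0.25))
  # full-size source is embedded unchanged
  big <- matrix(runif(800 * 800), 800, 800)
  expect_identical(embed_frame(big, 0, 800), big)
  expect_error(embed_frame(matrix(0, 801, 10), 0, 800), "frame")
})

test_that("the composite prep preserves domain pixels outside the ramp", {
  r <- render_bscan(flat_scene(speckle = 0.1, seed = 8, width = 256))
  dom <- extract_domain(r$image, r$truth, "FULL")
  prep <- prepare_domain(dom, r$truth, ramp_width_px = 16)
  # integer shifts + embedding: the multiset of domain pixels in unramped
  # columns survives intact
  dcols <- 17:240                          # domain columns minus the ramps
  orig <- sort(as.vector(r$image$pixels[, dcols][dom$mask[, dcols]]))
  kept <- prep$pixels[, 272 + dcols]       # embed offset for width 256
  expect_true(all(sort(kept[abs(kept - prep$fill_value) > 1e-12]) %in% orig))
  # DC of the prepared frame lies within the domain intensity range
  expect_gte(mean(prep$pixels), min(r$image$pixels[dom$mask]))
  expect_lte(mean(prep$pixels), max(r$image$pixels[dom$mask]))
})
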