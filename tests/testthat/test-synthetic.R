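test_that("noise-free flat scene paints the layer stack exactly", {
  sp <- flat_scene()
  out <- render_bscan(sp)
  px <- out$image$pixels
  # column profile equals the reflectance of the band each row falls in
  refl <- sp$layer_reflectance
  depths <- c(40, 60, 90, 140, 165)
  expected <- refl[findInterval(0:219, depths) + 1]
  for (cc in c(1, 100, 256))
    expect_identical(px[, cc], expected)
  # ground-truth consistency: per-band means equal reflectance exactly
  bands <- findInterval(0:219, depths) + 1
  for (b in 1:6)
    expect_identical(unique(as.vector(px[bands == b, ])), refl[b])
  # truth boundaries are the painted rows
  expect_equal(out$truth$rows$ILM, rep(40, 256))
  expect_equal(out$truth$rows$RPE_CH, rep(165, 256))
})

test_that("rendering is deterministic given the seed", {
  sp <- study_scene(seed = 11)
  a <- render_bscan(sp)
  b <- render_bscan(sp)
  expect_identical(a$image$pixels, b$image$pixels)
  sp2 <- study_scene(seed = 12)
  expect_false(identical(render_bscan(sp2)$image$pixels, a$image$pixels))
})

test_that("speckle is multiplicative with the requested coefficient of variation", {
  for (cv in c(0.05, 0.15)) {
    sp <- flat_scene(speckle = cv, seed = 3)
    px <- render_bscan(sp)$image$pixels
    layer <- px[95:135, ]   # inside the 0.24 band, > 1e4 pixels
    expect_gt(length(layer), 1e4)
    sample_cv <- sd(layer) / mean(layer)
    expect_lt(abs(sample_cv - cv) / cv, 0.10)
    expect_lt(abs(mean(layer) - 0.24), 0.01)  # noise mean 1
  }
})

test_that("a focus raises the in-disc mean by its intensity delta", {
  # 18 um focus (~3 px) in the dark outer-nuclear band, speckle_cv = 0.05
  sp <- scene_spec(curvature_amp_px = 0, pit_depth_px = 0, speckle_cv = 0.05,
                   foci = list(focus_spec(300, 242, 18, 0.3)), seed = 7)
  px <- render_bscan(sp)$image$pixels
  rad <- 18 / (2 * sp$um_per_px)
  rg <- matrix(0:495, 496, 768)
  cg <- matrix(0:767, 496, 768, byrow = TRUE)
  d2 <- (rg - 242)^2 + (cg - 300)^2
  disc <- d2 <= rad^2
  layer <- rg >= 232 & rg <= 252 & cg >= 280 & cg <= 320
  surround <- layer & d2 > (rad + 2)^2
  expect_lt(abs((mean(px[disc]) - mean(px[surround])) - 0.3), 0.02)
  # dark cyst-like blob
  spd <- scene_spec(curvature_amp_px = 0, pit_depth_px = 0, speckle_cv = 0,
                    foci = list(focus_spec(300, 242, 18, -0.2)), seed = 7)
  pxd <- render_bscan(spd)$image$pixels
  expect_lt(mean(pxd[disc]) - mean(pxd[surround]), -0.19)
})

test_that("invalid scene specs are rejected", {
  expect_error(scene_spec(boundary_depths = c(40, 60, 55, 140, 165)),
               "increasing")
  expect_error(scene_spec(layer_reflectance = c(0.1, 1.2, 0.3, 0.4, 0.5, 0.6)),
               "\\[0, 1\\]")
  expect_error(scene_spec(speckle_cv = -0.1), "speckle_cv")
  # pit deep enough to push inner boundaries through the ISOS
  expect_error(scene_spec(pit_depth_px = 40), "cross")
  expect_error(
    scene_spec(foci = list(focus_spec(9999, 100, 18, 0.3))), "outside")
  expect_error(focus_spec(10, 10, -5, 0.3), "diameter_um")
})

test_that("null-perturbation cohorts are identical within pairs", {
  cs <- cohort_spec(2, control_scene = study_scene(), seed = 21)
  coh <- render_cohort(cs)
  for (p in 1:2)
    expect_identical(coh$cases[[p]]$image$pixels,
                     coh$controls[[p]]$image$pixels)
  expect_equal(nrow(coh$foci), 0)
  # independent speckle breaks the identity but keeps the structure
  csi <- cohort_spec(2, control_scene = study_scene(),
                     speckle_sharing = "independent", seed = 21)
  cohi <- render_cohort(csi)
  expect_false(identical(cohi$cases[[1]]$image$pixels,
                         cohi$controls[[1]]$image$pixels))
})

test_that("cohort manifest and foci bookkeeping are exact", {
  cs <- cohort_spec(5, case_perturbation = list(n_foci = 30), seed = 31)
  coh <- render_cohort(cs)
  expect_equal(length(coh$cases), 5)
  expect_equal(length(coh$controls), 5)
  expect_equal(nrow(coh$manifest), 10)
  expect_equal(sort(unique(coh$manifest$group)), c("case", "control"))
  expect_equal(nrow(coh$foci), 150)                   # 30 per case image
  expect_true(all(grepl("^case_", coh$foci$subject_id)))
  # reproducible given seed
  coh2 <- render_cohort(cs)
  expect_identical(coh$cases[[3]]$image$pixels, coh2$cases[[3]]$image$pixels)
  expect_identical(coh$foci, coh2$foci)
})

test_that("cohort round-trips through PNG and CSV on disk", {
  dir <- withr::local_tempdir()
  cs <- cohort_spec(2, control_scene = flat_scene(speckle = 0.05),
                    case_perturbation = list(n_foci = 3), seed = 41)
  coh <- render_cohort(cs)
  write_cohort(coh, dir)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 4)
  b <- read_bscan(man$image[1], um_per_px = 200 / 33)
  orig <- coh$cases[[man$pair_id[1]]]$image$pixels
  expect_lt(max(abs(b$pixels - orig)), 1 / 255)       # 8-bit quantization
  bounds <- read.csv(file.path(dir, "boundaries.csv"))
  expect_equal(sort(unique(bounds$boundary)),
               sort(c("ILM", "NFL_GCL", "IPL_INL", "ISOS", "RPE_CH")))
})
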