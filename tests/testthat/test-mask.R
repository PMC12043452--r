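test_that("mask construction thresholds labels and computes volume", {
  m <- voxel_mask(array(1L, c(10, 10, 10)), spacing = c(1, 1, 1))
  expect_equal(mask_volume(m), 1.000)

  lab <- array(0L, c(5, 4, 3))
  lab[1:2, , ] <- 255L
  m2 <- voxel_mask(lab)
  expect_setequal(unique(as.vector(m2$occupancy)), c(0L, 1L))
  expect_identical(sum(m2$occupancy), sum(lab > 0))   # voxel count preserved

  expect_equal(mask_volume(voxel_mask(array(0L, c(4, 4, 4)))), 0)
  expect_error(voxel_mask(array(1, c(2, 2)), c(1, 1, 1)), "3D")
  expect_error(voxel_mask(array(1, c(2, 2, 2)), c(1, 0, 1)), "positive")
})

test_that("mask_volume is invariant under axis permutation", {
  set.seed(11)
  occ <- array(rbinom(3 * 4 * 5, 1, 0.4), c(3, 4, 5))
  sp <- c(0.5, 1.25, 2)
  v1 <- mask_volume(voxel_mask(occ, sp))
  v2 <- mask_volume(voxel_mask(aperm(occ, c(3, 1, 2)), sp[c(3, 1, 2)]))
  expect_equal(v1, v2)
})

test_that("MetaIO and NRRD round trips preserve everything bit-exactly", {
  set.seed(42)
  occ <- array(rbinom(6 * 7 * 5, 1, 0.5), c(6, 7, 5))
  # anisotropic thick-slice spacing as found on clinical scanners
  m <- voxel_mask(occ, spacing = c(0.9375, 0.9375, 5.5),
                  origin = c(-12.5, 3, 0.25))
  for (ext in c("mhd", "nrrd")) {
    path <- file.path(withr::local_tempdir(), paste0("mask.", ext))
    write_mask(m, path)
    back <- read_mask(path)
    expect_identical(back$occupancy, m$occupancy)
    expect_identical(back$spacing, m$spacing)
    expect_identical(back$origin, m$origin)
  }
})

test_that("empty masks round trip with volume zero", {
  m <- voxel_mask(array(0L, c(4, 5, 6)))
  path <- file.path(withr::local_tempdir(), "empty.mhd")
  write_mask(m, path)
  expect_equal(mask_volume(read_mask(path)), 0)
})

test_that("NRRD ascii encoding and non-binary payloads are readable", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "labels.nrrd")
  vals <- c(0, 255, 0, 7, 0, 0, 255, 1, 0, 0, 3, 0)  # 2 x 3 x 2 label map
  writeLines(c("NRRD0004", "type: short", "dimension: 3", "sizes: 2 3 2",
               "spacings: 1.5 1.5 2", "encoding: ascii", "",
               paste(vals, collapse = " ")), path)
  m <- read_mask(path)
  expect_equal(dim(m$occupancy), c(2, 3, 2))
  expect_identical(sum(m$occupancy), sum(vals > 0))
  expect_equal(m$spacing, c(1.5, 1.5, 2))
})

test_that("malformed volumes raise format and dimension errors", {
  dir <- withr::local_tempdir()
  p2d <- file.path(dir, "twod.nrrd")
  writeLines(c("NRRD0004", "type: unsigned char", "dimension: 2",
               "sizes: 4 4", "encoding: ascii", "",
               paste(rep(1, 16), collapse = " ")), p2d)
  expect_error(read_mask(p2d), "3D")
  bad <- file.path(dir, "bad.mhd")
  writeLines(c("NDims = 3", "no equals sign here!"), bad)
  expect_error(read_mask(bad), "malformed|lacks")
  expect_error(read_mask(file.path(dir, "nope.mhd")), "not found")
})

test_that("resampling at identity spacing is the identity on occupancy", {
  set.seed(7)
  m <- voxel_mask(array(rbinom(1000, 1, 0.3), c(10, 10, 10)))
  r <- resample_nearest(m, 1)
  expect_identical(r$occupancy, m$occupancy)
})

test_that("resampling preserves volume of solid and curved shapes", {
  # solid 20 mm cube sampled at 2 mm, resampled to 1 mm: 8 cm^3
  cube <- voxel_mask(array(1L, c(10, 10, 10)), spacing = c(2, 2, 2))
  fine <- resample_nearest(cube, 1)
  expect_lt(abs(mask_volume(fine) - 8) / 8, 0.05)

  ell <- synthesize_ellipsoid_mask(30, spacing = 2, seed = 3,
                                   irregularity = 0.15)
  v0 <- mask_volume(ell)
  v1 <- mask_volume(resample_nearest(ell, 1))
  expect_lt(abs(v1 - v0) / v0, 0.05)

  # anisotropic thick slices to near-isotropic
  thick <- resample_nearest(ell, c(0.9375, 0.9375, 5.5))
  viso <- mask_volume(resample_nearest(thick, 1))
  expect_lt(abs(viso - mask_volume(thick)) / mask_volume(thick), 0.05)
  expect_error(resample_nearest(ell, 0), "target_spacing")
})

test_that("ellipsoid formula gives unit and sphere volumes and matches voxels", {
  expect_equal(ellipsoid_volume(1, 1, 1), pi / 6, tolerance = 1e-12)
  expect_equal(ellipsoid_volume(2, 2, 2), 4 / 3 * pi, tolerance = 1e-12)
  expect_error(ellipsoid_volume(0, 1, 1), "positive")
  # voxel-count oracle: axis-aligned ellipsoid with axes 3 x 2 x 1.5 cm
  ax_cm <- c(3, 2, 1.5)
  sp <- 0.5
  half_mm <- ax_cm * 10 / 2
  n <- ceiling(2 * half_mm / sp) + 3
  cx <- lapply(n, function(k) (seq_len(k) - (k + 1) / 2) * sp)
  inside <- outer(outer((cx[[1]] / half_mm[1])^2, (cx[[2]] / half_mm[2])^2,
                        `+`), (cx[[3]] / half_mm[3])^2, `+`) <= 1
  vm <- mask_volume(voxel_mask(array(as.integer(inside), n), rep(sp, 3)))
  expect_lt(abs(vm - ellipsoid_volume(3, 2, 1.5)) / vm, 0.05)
})

test_that("volume reduction matches the clinical determinations", {
  # segmentation volumes of the three reference patients
  expect_equal(round(volume_reduction(126.25, 10.58), 1), 91.6)
  expect_equal(round(volume_reduction(526.99, 70.72), 1), 86.6)
  expect_equal(round(volume_reduction(235.64, 108.22), 1), 54.1)
  expect_equal(volume_reduction(42, 42), 0)
  expect_lt(volume_reduction(10, 15), 0)
  expect_error(volume_reduction(0, 1), "v_pre")
})

test_that("synthetic masks hit their target volume and are seeded", {
  m <- synthesize_ellipsoid_mask(1, spacing = 1, seed = 5, irregularity = 0)
  expect_lt(abs(mask_volume(m) - 1), 0.01)
  m2 <- synthesize_ellipsoid_mask(1, spacing = 1, seed = 5, irregularity = 0)
  expect_identical(m$occupancy, m2$occupancy)
  m3 <- synthesize_ellipsoid_mask(1, spacing = 1, seed = 6, irregularity = 0)
  expect_false(identical(m$occupancy, m3$occupancy))
  # the three pre-chemo segmentation volumes, coarser grids to stay small
  for (target in c(126.25, 526.99, 235.64)) {
    mk <- synthesize_ellipsoid_mask(target, spacing = 3, seed = 1)
    expect_lt(abs(mask_volume(mk) - target) / target, 0.01)
  }
  expect_error(synthesize_ellipsoid_mask(0.0001, spacing = 2, seed = 1),
               "smaller than one voxel")
})
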