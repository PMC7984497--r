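test_that("vol3d validates its invariants", {
  expect_error(vol3d(matrix(0, 2, 2)), "3D")
  expect_error(vol3d(array(0, c(2, 2, 2)), spacing = c(1, -1, 1)),
               "positive")
  expect_error(vol3d(array(c(NA, rep(0, 7)), c(2, 2, 2))), "finite")
  v <- vol3d(array(1:8, c(2, 2, 2)), spacing = c(1, 2, 3),
             origin = c(-1, 0, 1))
  expect_s3_class(v, "vol3d")
  expect_identical(dim(v), c(2L, 2L, 2L))
})

test_that("NIfTI write/read round-trips data, spacing and origin", {
  dir <- withr::local_tempdir()
  set.seed(42)
  v <- vol3d(array(rnorm(64), c(4, 4, 4)), spacing = c(3, 2, 1),
             origin = c(-10, 5, 2.5))
  p <- file.path(dir, "v.nii.gz")
  write_volume(v, p)
  w <- read_volume(p)
  expect_equal(w$data, v$data, tolerance = 0)
  expect_equal(w$spacing, v$spacing)
  expect_equal(w$origin, v$origin)
})

test_that("MetaImage write/read round-trips for .mha and .mhd", {
  dir <- withr::local_tempdir()
  set.seed(43)
  v <- vol3d(array(rnorm(60), c(3, 4, 5)), spacing = c(1, 2, 3),
             origin = c(0.5, -1.5, 8))
  for (ext in c("mha", "mhd")) {
    p <- file.path(dir, paste0("v.", ext))
    write_volume(v, p)
    w <- read_volume(p)
    expect_identical(w$data, v$data)
    expect_equal(w$spacing, v$spacing)
    expect_equal(w$origin, v$origin)
  }
})

test_that("masks re-read as exact 0/1 volumes", {
  dir <- withr::local_tempdir()
  m <- vol3d(array(c(TRUE, FALSE), c(4, 4, 4)))
  for (fname in c("m.nii.gz", "m.mha")) {
    p <- file.path(dir, fname)
    write_volume(m, p)
    w <- read_volume(p)
    expect_setequal(unique(as.numeric(w$data)), c(0, 1))
    expect_identical(w$data > 0.5, m$data)
  }
})

test_that("I/O rejects bad inputs", {
  dir <- withr::local_tempdir()
  v <- vol3d(array(0, c(2, 2, 2)))
  expect_error(write_volume(v, file.path(dir, "nope", "x.nii.gz")),
               "directory")
  expect_error(read_volume(file.path(dir, "missing.nii.gz")), "not found")
  writeLines("not a volume", file.path(dir, "x.txt"))
  expect_error(read_volume(file.path(dir, "x.txt")), "format")
  # 2D MetaImage header -> dimensionality error
  p2 <- file.path(dir, "flat.mha")
  con <- file(p2, "wb")
  writeLines(c("ObjectType = Image", "NDims = 2", "DimSize = 2 2",
               "ElementType = MET_DOUBLE", "ElementDataFile = LOCAL"), con)
  writeBin(rep(0, 4), con, size = 8L)
  close(con)
  expect_error(read_volume(p2), "3D")
})

test_that("grid compatibility detects shape, spacing and origin mismatch", {
  a <- vol3d(array(0, c(4, 4, 4)), spacing = c(1, 1, 1))
  expect_true(check_grid_compatible(a, a))
  b <- vol3d(array(0, c(4, 4, 4)), origin = c(0.5, 0, 0))
  expect_false(check_grid_compatible(a, b, tol_mm = 0.1))
  expect_true(check_grid_compatible(a, b, tol_mm = 1))
  expect_false(check_grid_compatible(a, vol3d(array(0, c(4, 4, 5)))))
  # downstream operations refuse incompatible grids
  cs <- random_case(1)
  sct <- generate_sct(cs$dixon, cs$masks, cs$model)
  shifted <- vol3d(sct$data, sct$spacing, sct$origin + 1)
  expect_error(tissue_mae(shifted, sct, cs$masks), "grid")
})

test_that("dixon_volume enforces shared grid and non-negative signals", {
  w <- vol3d(array(1, c(3, 3, 3)))
  f <- vol3d(array(2, c(3, 3, 3)))
  dx <- dixon_volume(w, f)
  expect_equal(dx$in_phase$data, array(3, c(3, 3, 3)))
  expect_error(dixon_volume(w, vol3d(array(-1, c(3, 3, 3)))),
               "non-negative")
  expect_error(dixon_volume(w, vol3d(array(1, c(3, 3, 4)))), "grid")
})

test_that("mask_set partitions body into bone and soft", {
  for (seed in 1:5) {
    set.seed(seed)
    body <- array(runif(27) < 0.7, c(3, 3, 3))
    bone <- body & array(runif(27) < 0.4, c(3, 3, 3))
    ms <- mask_set(vol3d(body), vol3d(bone))
    expect_identical(ms$soft$data, body & !bone)
    expect_equal(sum(ms$soft$data) + sum(ms$bone$data), sum(ms$body$data))
    expect_false(any(ms$bone$data & !ms$body$data))
  }
  bad_bone <- vol3d(array(TRUE, c(3, 3, 3)))
  some_body <- vol3d(array(c(TRUE, FALSE), c(3, 3, 3)))
  expect_error(mask_set(some_body, bad_bone), "subset")
})

test_that("derive_soft_tissue handles edge cases", {
  body <- vol3d(array(c(TRUE, TRUE, FALSE, TRUE), c(1, 2, 2)))
  none <- vol3d(array(FALSE, c(1, 2, 2)))
  expect_identical(derive_soft_tissue(body, none)$data, body$data)
  expect_false(any(derive_soft_tissue(body, body)$data))
  expect_error(derive_soft_tissue(none, body), "subset")
})
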