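test_that("tissue MAE matches hand computation and the scalar loop", {
  cs <- random_case(3)
  ct <- generate_sct(cs$dixon, cs$masks, cs$model)
  expect_equal(unlist(tissue_mae(ct, ct, cs$masks)[1:3]),
               c(mae_bone = 0, mae_soft = 0, mae_body = 0))
  shifted <- with_data(ct, ct$data + 10)
  expect_equal(unlist(tissue_mae(ct, shifted, cs$masks)[1:3]),
               c(mae_bone = 10, mae_soft = 10, mae_body = 10))
  # two-voxel body with errors 4 and 6 -> MAE 5
  body <- vol3d(array(c(TRUE, TRUE, rep(FALSE, 6)), c(2, 2, 2)))
  ms <- mask_set(body)
  a <- vol3d(array(0, c(2, 2, 2)))
  b <- vol3d(array(c(4, -6, rep(0, 6)), c(2, 2, 2)))
  expect_equal(tissue_mae(a, b, ms)$mae_body, 5)
  # empty compartment reported as absent
  expect_true(is.na(tissue_mae(a, b, ms)$mae_bone))
  # agreement with the brute-force loop
  mae <- tissue_mae(ct, shifted, cs$masks)
  expect_equal(mae$mae_soft, oracle_mae(ct, shifted, cs$masks$soft))
})

test_that("3D bone alignment recovers known translations", {
  ph <- small_phantom()
  ct <- ph$ct
  expect_equal(rigid_align_3d(ct, ct, ph$masks$bone, search_mm = 5),
               c(0, 0, 0))
  half_vox <- 0.5 * max(ct$spacing)
  for (shift in list(c(2.5, -5, 7.5), c(3.0, -2.5, 5.0))) {
    cb <- simulate_cbct(ct, shift, noise_sigma_hu = 0, seed = 1)
    rec <- rigid_align_3d(ct, cb, ph$masks$bone, search_mm = 12.5)
    expect_lt(max(abs(rec - shift)), half_vox)
    cbn <- simulate_cbct(ct, shift, noise_sigma_hu = 20, seed = 2)
    recn <- rigid_align_3d(ct, cbn, ph$masks$bone, search_mm = 12.5)
    expect_lt(max(abs(recn - shift)), half_vox)
  }
  expect_error(rigid_align_3d(ct, ct, ph$masks$bone, search_mm = 1e4),
               "search window")
})

test_that("CBCT offset difference is algebraically consistent", {
  ph <- small_phantom()
  dx <- simulate_dixon(ph, noise_sigma = 0, seed = 1)
  sct <- generate_sct(dx, ph$masks, ph$model)
  cb <- simulate_cbct(ph$ct, c(2.5, -2.5, 5), noise_sigma_hu = 0, seed = 3)
  # identical references -> exactly zero difference
  expect_equal(cbct_offset_difference(ph$ct, ph$ct, cb, ph$masks$bone,
                                      search_mm = 10), c(0, 0, 0))
  # cbct == ct -> difference is minus the sct-to-ct alignment
  d <- cbct_offset_difference(ph$ct, sct, ph$ct, ph$masks$bone,
                              search_mm = 10)
  expect_equal(d, -rigid_align_3d(sct, ph$ct, ph$masks$bone,
                                  search_mm = 10))
  # phantom sCT as reference: near-zero penalty across simulated CBCTs
  diffs <- sapply(1:3, function(s) {
    shift <- c(3, -3, 3) * (s - 2)
    cb <- simulate_cbct(ph$ct, shift, noise_sigma_hu = 10, seed = s)
    cbct_offset_difference(ph$ct, sct, cb, ph$masks$bone, search_mm = 12.5)
  })
  expect_lt(max(abs(diffs)), 1.0)
})

test_that("dose proxy matches closed forms", {
  u <- vol3d(array(0, c(5, 5, 5)), spacing = c(1, 1, 1))
  beam <- list(list(axis = "AP", direction = 1))
  d <- dose_proxy(u, beam, mu_water = 0.02, d0 = 2, deposit = "fluence")
  expect_equal(d$data[3, , 3], 2 * exp(-0.02 * (1:5)), tolerance = 1e-12)
  # kerma mode agrees on water (mu == mu_water)
  dk <- dose_proxy(u, beam, mu_water = 0.02, d0 = 2, deposit = "kerma")
  expect_equal(dk$data, d$data, tolerance = 1e-12)
  # all-air volume: transmitted fluence d0 everywhere, zero deposition
  air <- vol3d(array(-1000, c(5, 5, 5)))
  expect_true(all(dose_proxy(air, beam, deposit = "fluence")$data == 2))
  expect_true(all(dose_proxy(air, beam, deposit = "kerma")$data == 0))
  # opposed beams on a uniform phantom: symmetric about the midplane
  both <- list(list(axis = "AP", direction = 1),
               list(axis = "AP", direction = -1))
  ds <- dose_proxy(u, both)
  expect_equal(ds$data, ds$data[, 5:1, ], tolerance = 1e-12)
  expect_error(dose_proxy(u, list()), "at least one")
  expect_error(dose_proxy(u, list(list(axis = "XX"))), "axis")
  fm <- matrix(FALSE, 5, 5)
  expect_error(dose_proxy(u, list(list(axis = "AP", field_mask = fm))),
               "empty field")
})

test_that("field masks restrict the irradiated rays", {
  u <- vol3d(array(0, c(4, 4, 4)))
  fm <- matrix(FALSE, 4, 4); fm[2, 3] <- TRUE  # (z, x) plane for AP beam
  d <- dose_proxy(u, list(list(axis = "AP", direction = 1,
                               field_mask = fm)))
  expect_true(all(d$data[2, , 3] > 0))
  expect_true(all(d$data[-2, , ] == 0) && all(d$data[2, , -3] == 0))
})

test_that("DVH metrics agree with the sorting oracle", {
  # 100-voxel structure, doses 1..100, 1 mm voxels: volume 0.1 cc
  dose <- vol3d(array(c(1:100, rep(0, 25)), c(5, 5, 5)))
  st <- vol3d(array(c(rep(TRUE, 100), rep(FALSE, 25)), c(5, 5, 5)))
  expect_warning(m <- dvh_metrics(dose, st), "1 cm")
  expect_equal(m$d_max, 100)
  expect_equal(m$d_mean, 50.5)
  expect_true(m$d1cc_capped)
  expect_equal(m$d_1cc, m$d_max)
  expect_equal(m$d_95, oracle_dx(1:100, 0.95))
  expect_equal(m$d_53, oracle_dx(1:100, 0.53))
  # uniform dose: every metric equals it
  ud <- vol3d(array(2, c(10, 10, 10)), spacing = c(5, 5, 5))
  us <- vol3d(array(TRUE, c(10, 10, 10)), spacing = c(5, 5, 5))
  um <- dvh_metrics(ud, us)
  expect_equal(unlist(um[c("d_max", "d_mean", "d_95", "d_53", "d_1cc")]),
               c(d_max = 2, d_mean = 2, d_95 = 2, d_53 = 2, d_1cc = 2))
  expect_false(um$d1cc_capped)
  # random grids: oracle agreement and Dx monotonicity
  for (seed in 1:20) {
    set.seed(seed)
    dv <- vol3d(array(runif(6^3, 0, 80), c(6, 6, 6)), spacing = c(4, 4, 4))
    sv <- vol3d(array(runif(6^3) < 0.6, c(6, 6, 6)), spacing = c(4, 4, 4))
    if (!any(sv$data)) next
    m <- dvh_metrics(dv, sv)
    o <- oracle_dvh(dv, sv)
    expect_equal(unlist(m[names(o)]), unlist(o), tolerance = 1e-9)
    expect_lte(m$d_95, m$d_53)
    expect_lte(m$d_53, m$d_max)
  }
})

test_that("percent dose differences are exact ratios", {
  ud <- vol3d(array(2, c(10, 10, 10)), spacing = c(5, 5, 5))
  us <- vol3d(array(TRUE, c(10, 10, 10)), spacing = c(5, 5, 5))
  m <- dvh_metrics(ud, us)
  expect_equal(unname(percent_dose_diff(m, m)), rep(0, 5))
  m2 <- dvh_metrics(with_data(ud, ud$data * 1.01), us)
  expect_equal(unname(percent_dose_diff(m, m2)), rep(1, 5),
               tolerance = 1e-9)
  # report form
  r1 <- dose_metrics_report(ud, list(all = us))
  r2 <- dose_metrics_report(with_data(ud, ud$data * 1.01), list(all = us))
  pd <- percent_dose_diff(r1, r2)
  expect_named(pd, "all")
  expect_equal(unname(pd$all), rep(1, 5), tolerance = 1e-9)
})

test_that("reports assemble, print and round-trip through JSON", {
  empty <- make_report()
  expect_equal(empty$schema_version, "1.0")
  cs <- random_case(5)
  ct <- generate_sct(cs$dixon, cs$masks, cs$model)
  mae <- tissue_mae(ct, with_data(ct, ct$data + 5), cs$masks)
  rep <- make_report(mae = mae, drr_pcc = c(AP = 0.99, RL = 0.98),
                     offsets = c(0.1, -0.2, 0.3))
  expect_named(rep$mae, c("bone", "soft", "body"))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "report.json")
  report_to_json(rep, p)
  back <- report_from_json(p)
  expect_equal(back$mae$bone, rep$mae$bone)
  expect_equal(back$alignment_offset_mm$si, 0.3)
  expect_output(print(rep), "MAE")
})
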