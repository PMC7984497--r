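make_point_dixon <- function(w_vals, f_vals) {
  n <- length(w_vals)
  sh <- c(n, 1, 1)
  dixon_volume(vol3d(array(w_vals, sh)), vol3d(array(f_vals, sh)))
}

all_true_mask <- function(n) vol3d(array(TRUE, c(n, 1, 1)))

test_that("cluster estimation is a fixed point on two-point data", {
  w <- rep(c(95, 5), each = 500)
  f <- rep(c(5, 95), each = 500)
  est <- estimate_cluster_centers(make_point_dixon(w, f),
                                  all_true_mask(1000))
  expect_equal(est$water_center, c(95, 5))
  expect_equal(est$fat_center, c(5, 95))
  expect_true(est$converged)
})

test_that("cluster estimation recovers Gaussian mixture centers", {
  set.seed(2024)
  mu_w <- c(90, 10); mu_f <- c(12, 88)
  sep <- sqrt(sum((mu_w - mu_f)^2))
  n <- 5000
  w <- pmax(0, c(rnorm(n, mu_w[1], 0.05 * sep), rnorm(n, mu_f[1], 0.05 * sep)))
  f <- pmax(0, c(rnorm(n, mu_w[2], 0.05 * sep), rnorm(n, mu_f[2], 0.05 * sep)))
  est <- estimate_cluster_centers(make_point_dixon(w, f),
                                  all_true_mask(2 * n))
  expect_lt(sqrt(sum((est$water_center - mu_w)^2)), 0.02 * sep)
  expect_lt(sqrt(sum((est$fat_center - mu_f)^2)), 0.02 * sep)
  # independent full-assignment clustering oracle on the same sample
  km <- stats::kmeans(cbind(w, f), centers = 2, nstart = 10)
  kc <- km$centers[order(-km$centers[, 1] /
                         rowSums(km$centers)), , drop = FALSE]
  expect_lt(max(abs(est$water_center - kc[1, ])), 0.01 * sep)
  expect_lt(max(abs(est$fat_center - kc[2, ])), 0.01 * sep)
})

test_that("degenerate intensity distributions are rejected", {
  w <- rep(50, 100); f <- rep(50, 100)
  expect_error(estimate_cluster_centers(make_point_dixon(w, f),
                                        all_true_mask(100)),
               "degenerate")
  empty <- vol3d(array(FALSE, c(100, 1, 1)))
  expect_error(estimate_cluster_centers(make_point_dixon(w, f), empty),
               "empty")
})

test_that("line coordinates satisfy the defining geometry", {
  m <- hu_model(water_center = c(100, 0), fat_center = c(0, 100))
  lc <- line_coordinates(100, 0, m)
  expect_equal(c(lc$t, lc$d), c(0, 0))
  lc <- line_coordinates(0, 100, m)
  expect_equal(c(lc$t, lc$d), c(1, 0))
  # midpoint displaced perpendicular by 10 units
  v <- c(0, 100) - c(100, 0)
  nhat <- c(v[2], -v[1]) / sqrt(sum(v^2))
  p <- c(50, 50) + 10 * nhat
  lc <- line_coordinates(p[1], p[2], m)
  expect_equal(lc$t, 0.5)
  expect_equal(lc$d, 10)
})

test_that("soft-tissue and bone HU maps hit their endpoints", {
  m <- hu_model(water_center = c(100, 0), fat_center = c(0, 100))
  expect_equal(soft_tissue_hu(100, 0, m), 40)
  expect_equal(soft_tissue_hu(0, 100, m), -100)
  expect_equal(soft_tissue_hu(50, 50, m), -30)
  # beyond the segment ends: clamped, no extrapolation
  expect_equal(soft_tissue_hu(200, -100, m), 40)
  # bone: on-line floor, mid-distance, cap
  expect_equal(bone_hu(50, 50, m), 100)
  d_half <- 0.5 * m$d_max
  v <- c(-100, 100); nhat <- c(v[2], -v[1]) / sqrt(sum(v^2))
  p_half <- c(50, 50) - d_half * nhat
  expect_equal(bone_hu(p_half[1], p_half[2], m), 800)
  expect_equal(bone_hu(0, 0, m), 800)  # origin is at d = d_max/2 here
  p_far <- c(50, 50) + 2 * m$d_max * nhat
  expect_equal(bone_hu(p_far[1], p_far[2], m), 1500)
})

test_that("HU maps are continuous (small input steps, small HU steps)", {
  m <- hu_model(water_center = c(100, 0), fat_center = c(0, 100))
  g <- expand.grid(w = seq(0, 150, by = 1.5), f = seq(0, 150, by = 1.5))
  soft <- soft_tissue_hu(g$w, g$f, m)
  bone <- bone_hu(g$w, g$f, m)
  nw <- length(seq(0, 150, by = 1.5))
  soft_m <- matrix(soft, nw); bone_m <- matrix(bone, nw)
  # Lipschitz bound: |dHU| <= slope * |dsignal| with slack
  slope_soft <- abs(m$hu_fat - m$hu_muscle) / sqrt(sum((m$fat_center - m$water_center)^2))
  slope_bone <- (m$hu_cortical - m$hu_spongy) / m$d_max
  expect_lte(max(abs(diff(soft_m))), slope_soft * 1.5 + 1e-9)
  expect_lte(max(abs(diff(bone_m))), slope_bone * 1.5 + 1e-9)
})

test_that("generate_sct assigns compartments correctly", {
  cs <- random_case(99)
  sct <- generate_sct(cs$dixon, cs$masks, cs$model)
  expect_gte(min(sct$data), cs$model$hu_air)
  expect_lte(max(sct$data), cs$model$hu_cortical)
  expect_true(all(sct$data[!cs$masks$body$data] == cs$model$hu_air))
  # matches the per-voxel scalar-loop reference exactly
  expect_equal(sct$data, oracle_sct(cs$dixon, cs$masks, cs$model),
               tolerance = 0)
  # outside-body-only input gives a constant air volume
  empty <- mask_set(vol3d(array(FALSE, dim(sct$data))))
  expect_true(all(generate_sct(cs$dixon, empty, cs$model)$data ==
                  cs$model$hu_air))
})

test_that("enclosed air is mapped as soft tissue with the known HU error", {
  ph <- default_phantom()
  dx <- noiseless_dixon()
  sct <- generate_sct(dx, ph$masks, ph$model)
  air <- ph$masks$structures$internal_air$data
  expect_gt(sum(air), 0)
  # zero-signal voxels project to the line midpoint -> -30 HU at defaults
  expect_true(all(abs(sct$data[air] - (-30)) < 1e-9))
  err <- abs(sct$data[air] - ph$ct$data[air])
  expect_true(all(err > 900 & err < 1100))
})

test_that("bulk-density mode emits exactly the table's classes", {
  ph <- default_phantom()
  dx <- noiseless_dixon()
  tab <- bulk_density_table()
  sct <- generate_sct_bulk(dx, ph$masks, ph$model, tab)
  expect_identical(sort(unique(as.numeric(sct$data))),
                   as.numeric(sort(tab$hu)))
  # all-soft body with t below threshold everywhere -> binary output
  sh <- c(6, 6, 6)
  w <- vol3d(array(95, sh)); f <- vol3d(array(5, sh))
  body <- array(FALSE, sh); body[2:5, 2:5, 2:5] <- TRUE
  masks <- mask_set(vol3d(body))
  out <- generate_sct_bulk(dixon_volume(w, f), masks, ph$model, tab)
  expect_setequal(unique(as.numeric(out$data)),
                  c(tab$hu[["air"]], tab$hu[["soft"]]))
})

test_that("continuous mode beats bulk mode on noisy phantoms", {
  ph <- default_phantom()
  for (sig in c(0.01, 0.03)) {
    for (s in 1:2) {
      dx <- simulate_dixon(ph, noise_sigma = sig, seed = 200 + s)
      mc <- tissue_mae(ph$ct, generate_sct(dx, ph$masks, ph$model),
                       ph$masks)
      mb <- tissue_mae(ph$ct, generate_sct_bulk(dx, ph$masks, ph$model),
                       ph$masks)
      expect_lte(mc$mae_bone, mb$mae_bone)
      expect_lte(mc$mae_soft, mb$mae_soft)
      expect_lte(mc$mae_body, mb$mae_body)
    }
  }
})

test_that("fitted model recovers the phantom's cluster structure", {
  ph <- default_phantom()
  dx <- noiseless_dixon()
  fit <- fit_hu_model(dx, ph$masks$soft, d_max = ph$model$d_max)
  # centers sit near the generating ones; the mixed-tissue ramp and the
  # bladder pull them slightly off the pure endpoints
  expect_lt(sqrt(sum((fit$water_center - ph$model$water_center)^2)), 10)
  expect_lt(sqrt(sum((fit$fat_center - ph$model$fat_center)^2)), 10)
  wfrac <- fit$water_center[1] / sum(fit$water_center)
  ffrac <- fit$fat_center[1] / sum(fit$fat_center)
  expect_gt(wfrac, 0.9)
  expect_lt(ffrac, 0.1)
  # with the calibrated bone-distance scale the fitted model still maps
  # soft tissue accurately
  mae_fit <- tissue_mae(ph$ct, generate_sct(dx, ph$masks, fit), ph$masks)
  expect_lt(mae_fit$mae_soft, 5)
  expect_s3_class(fit, "hu_model")
  expect_true(fit$fit$converged)
  co <- coef(fit)
  expect_named(co, c("water_w", "water_f", "fat_w", "fat_f", "hu_muscle",
                     "hu_fat", "hu_spongy", "hu_cortical", "d_max",
                     "hu_air"))
  sm <- summary(fit)
  expect_s3_class(sm, "summary.hu_model")
  # predict() dispatches to both modes
  sc <- predict(fit, dx, ph$masks)
  sb <- predict(fit, dx, ph$masks, mode = "bulk")
  expect_lte(length(unique(as.numeric(sb$data))), 5)
  expect_equal(dim(sc), dim(ph$ct$data))
})

test_that("model constructor enforces its invariants", {
  expect_error(hu_model(c(1, 1), c(1, 1)), "differ")
  expect_error(hu_model(c(1, 0), c(0, 1), hu_fat = 50), "endpoints")
  expect_error(hu_model(c(1, 0), c(0, 1), d_max = -1), "positive")
  expect_error(bulk_density_table(hu = c(-1000, 40, -100, 200, 1200)),
               "increasing")
})
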