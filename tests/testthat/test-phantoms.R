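test_that("shell truth carries the closed-form equivolume lamina radius", {
  ph <- shell_clean()
  r_star <- ((0.4^3 + 0.64^3) / 2)^(1 / 3)
  expect_equal(ph$truth$r_star, r_star, tolerance = 1e-12)
  expect_equal(ph$truth$r_star, 0.546336, tolerance = 1e-4)
  expect_equal(ph$truth$thickness, 0.24)
  # thickness is independent of the lamina fraction
  ph2 <- make_shell(lamina_fraction = 0.3, noise_sd = 0)
  expect_equal(ph2$truth$thickness, 0.24)
  # mid-distance variant
  ph3 <- make_shell(lamina_at = "mid", noise_sd = 0)
  expect_equal(ph3$truth$r_star, 0.52)
})

test_that("noiseless phantoms take exactly the five configured levels", {
  ph <- shell_clean()
  expect_setequal(unique(as.vector(ph$volume$values)), c(10, 70, 50, 75, 30))
  sl <- make_folded_slab(touching = TRUE, noise_sd = 0)
  expect_true(all(sl$volume$values %in% c(10, 70, 50, 75, 30)))
})

test_that("voxelized layer volumes approach the analytic truth", {
  ph <- shell_clean()
  h3 <- prod(ph$volume$spacing)
  vol_gm <- sum(ph$masks$gm) * h3
  # relative error bounded by the surface-voxel budget, and shrinking with h
  expect_lt(abs(vol_gm - ph$truth$vol_gm) / ph$truth$vol_gm, 0.10)
  ph_fine <- make_shell(noise_sd = 0, spacing = 0.02)
  vol_fine <- sum(ph_fine$masks$gm) * prod(ph_fine$volume$spacing)
  expect_lt(abs(vol_fine - ph_fine$truth$vol_gm) / ph_fine$truth$vol_gm,
            abs(vol_gm - ph$truth$vol_gm) / ph$truth$vol_gm)
})

test_that("phantom masks satisfy the cortex invariants", {
  for (ph in list(shell_clean(), slab_touch())) {
    expect_false(any(ph$masks$wm & ph$masks$gm))
    expect_true(all(ph$masks$purkinje[ph$masks$purkinje] &
                      ph$masks$gm[ph$masks$purkinje]))
    expect_false(any(ph$masks$granular & ph$masks$molecular))
    expect_true(all((ph$masks$granular | ph$masks$molecular |
                       ph$masks$purkinje) == ph$masks$gm))
  }
})

test_that("identical seeds reproduce identical phantoms", {
  a <- make_shell(noise_sd = 2, seed = 5)
  b <- make_shell(noise_sd = 2, seed = 5)
  expect_identical(a$volume$values, b$volume$values)
  c <- make_shell(noise_sd = 2, seed = 6)
  expect_false(identical(a$volume$values, c$volume$values))
})

test_that("folded slab records the analytic contact surface", {
  sl <- slab_touch()
  expect_gt(sum(sl$truth$fissure), 0)
  expect_true(all(sl$masks$gm[sl$truth$fissure]))
  op <- slab_open()
  expect_equal(sum(op$truth$fissure), 0)
  # geometry validation errors
  expect_error(make_folded_slab(amplitude = 0.15, touching = TRUE, noise_sd = 0),
               "touching")
  expect_error(make_folded_slab(amplitude = 0.7, touching = FALSE, noise_sd = 0),
               "touching")
})

test_that("flat-limit slab has constant layer thickness", {
  sl <- make_folded_slab(amplitude = 0, touching = FALSE, noise_sd = 0)
  expect_equal(sl$truth$thickness_granular, 0.1)
  expect_equal(sl$truth$thickness_molecular, 0.1)
  # constant-thickness band: distance map below the band equals the offset
  d <- sl$truth$dist_map
  gm2 <- sl$masks$gm[, 1, ]
  expect_true(all(d[gm2] <= 0.2 + 1e-9))
})

test_that("simulated cohort honours sizes, effects and the null case", {
  sim <- simulate_cohort(seed = 1)
  expect_equal(nrow(sim$subjects), 28L)
  expect_equal(sum(sim$subjects$group == "control"), 14L)
  expect_error(simulate_cohort(n_control = 2), "at least 3")
  expect_error(simulate_cohort(noise_sd = 0), "positive")

  # volume = thickness x area by construction
  m <- sim$metrics
  g <- tidyr::pivot_wider(m[m$layer == "granular", ],
                          names_from = "metric", values_from = "value")
  expect_equal(g$volume, g$thickness * g$area, tolerance = 1e-12)
  expect_equal(g$tsr, g$thickness / sqrt(g$area), tolerance = 1e-12)

  # null cohort: group labels exchangeable (two-sample t on raw values is
  # null-distributed; check no systematic shift at generous tolerance)
  null <- simulate_cohort(n_control = 100, n_case = 100, tiv_case_shift = 0,
                          granular_thickness_effect = 0,
                          molecular_area_effect = 0, seed = 2)
  d <- dplyr::left_join(null$metrics, null$subjects, by = "subject")
  d <- d[d$layer == "granular" & d$metric == "thickness", ]
  z <- by(d, d$structure, function(x)
    t.test(x$value[x$group == "case"], x$value[x$group == "control"])$statistic)
  expect_lt(mean(abs(unlist(z))), 2)
})

test_that("case group shows the built-in TIV shift and layer effects", {
  sim <- simulate_cohort(n_control = 200, n_case = 200, seed = 3)
  sub <- sim$subjects
  expect_gt(mean(sub$tiv[sub$group == "case"]),
            mean(sub$tiv[sub$group == "control"]))
  # with the TIV shift silenced, the injected negative effects show up raw
  sim0 <- simulate_cohort(n_control = 200, n_case = 200, tiv_case_shift = 0,
                          seed = 4)
  d <- dplyr::left_join(sim0$metrics, sim0$subjects, by = "subject")
  gt <- d[d$layer == "granular" & d$metric == "thickness", ]
  expect_lt(mean(gt$value[gt$group == "case"]) -
              mean(gt$value[gt$group == "control"]), 0)
  ma <- d[d$layer == "molecular" & d$metric == "area", ]
  expect_lt(mean(ma$value[ma$group == "case"]) -
              mean(ma$value[ma$group == "control"]), 0)
})
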