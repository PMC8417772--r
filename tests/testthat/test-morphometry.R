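test_that("the codebook and merge rules give 14 analyzed and 32 layer structures", {
  cb <- cerebellum_codebook()
  expect_equal(nrow(cb), 16L)
  expect_true(all(c("1Cb", "10Cb", "Sim", "Crus 1", "Cop", "Fl") %in%
                    cb$abbreviation))
  an <- analyzed_structures()
  expect_length(an, 14L)
  expect_true("1/2Cb" %in% an)
  expect_false(any(c("1Cb", "2Cb", "Cop") %in% an))
  # two laminae over the raw 16-structure parcellation
  expect_equal(nrow(cb) * 2L, 32L)
})

test_that("TSR is the defining arithmetic and is scale invariant", {
  expect_equal(tsr(0.3, 9), 0.1)
  k <- 1.7
  expect_equal(tsr(k * 0.3, k^2 * 9), tsr(0.3, 9), tolerance = 1e-12)
  expect_error(tsr(0.3, 0), "positive")
  expect_error(tsr(0.3, -1), "positive")
})

test_that("area follows from volume and thickness", {
  # volume 2.4 mm^3 at mean thickness 0.6 mm -> area 4.0 mm^2
  expect_equal(2.4 / 0.6, 4.0)
  ph <- shell_clean()
  lay <- list(granular = ph$masks$granular, molecular = ph$masks$molecular,
              purkinje = ph$masks$purkinje)
  thk <- layer_thicknesses(ph$masks$gm, ph$masks$wm, ph$masks$pial,
                           ph$masks$purkinje, lay, ph$volume$spacing)
  m <- regional_metrics(lay, thk$vertices, ph$labels)
  wide <- tidyr::pivot_wider(m, names_from = "metric", values_from = "value")
  expect_equal(wide$area, wide$volume / wide$thickness, tolerance = 1e-12)
  expect_equal(wide$tsr, wide$thickness / sqrt(wide$area), tolerance = 1e-12)
})

test_that("symmetric shell halves get identical metrics within 2%", {
  ph <- shell_clean()
  lay <- list(granular = ph$masks$granular, molecular = ph$masks$molecular,
              purkinje = ph$masks$purkinje)
  thk <- layer_thicknesses(ph$masks$gm, ph$masks$wm, ph$masks$pial,
                           ph$masks$purkinje, lay, ph$volume$spacing)
  m <- regional_metrics(lay, thk$vertices, ph$labels)
  wide <- tidyr::pivot_wider(m, names_from = "structure", values_from = "value")
  rel <- abs(wide$HemiA - wide$HemiB) / pmax(abs(wide$HemiA), 1e-12)
  expect_lt(max(rel), 0.02)
})

test_that("TSR on the shell equals the direct recomputation", {
  ph <- shell_clean()
  lay <- list(granular = ph$masks$granular, molecular = ph$masks$molecular,
              purkinje = ph$masks$purkinje)
  thk <- layer_thicknesses(ph$masks$gm, ph$masks$wm, ph$masks$pial,
                           ph$masks$purkinje, lay, ph$volume$spacing)
  m <- regional_metrics(lay, thk$vertices, ph$labels)
  full <- m[m$layer == "full" & m$structure == "HemiA", ]
  vol <- full$value[full$metric == "volume"]
  tbar <- full$value[full$metric == "thickness"]
  byhand <- tbar / sqrt(vol / tbar)
  expect_equal(full$value[full$metric == "tsr"], byhand, tolerance = 1e-12)
})

test_that("layer volumes add up to the full GM volume per structure", {
  ph <- shell_clean()
  lay <- list(granular = ph$masks$granular, molecular = ph$masks$molecular,
              purkinje = ph$masks$purkinje)
  thk <- layer_thicknesses(ph$masks$gm, ph$masks$wm, ph$masks$pial,
                           ph$masks$purkinje, lay, ph$volume$spacing)
  m <- regional_metrics(lay, thk$vertices, ph$labels)
  h3 <- prod(ph$volume$spacing)
  for (s in c("HemiA", "HemiB")) {
    v_full <- m$value[m$structure == s & m$layer == "full" & m$metric == "volume"]
    v_g <- m$value[m$structure == s & m$layer == "granular" & m$metric == "volume"]
    v_m <- m$value[m$structure == s & m$layer == "molecular" & m$metric == "volume"]
    v_p <- sum(ph$masks$purkinje & ph$labels$labels ==
                 ph$labels$codebook$id[ph$labels$codebook$abbreviation == s]) * h3
    expect_equal(v_full, v_g + v_m + v_p, tolerance = 1e-12)
  }
})

test_that("metrics are invariant to a relabelling permutation", {
  ph <- shell_clean()
  lay <- list(granular = ph$masks$granular, molecular = ph$masks$molecular,
              purkinje = ph$masks$purkinje)
  thk <- layer_thicknesses(ph$masks$gm, ph$masks$wm, ph$masks$pial,
                           ph$masks$purkinje, lay, ph$volume$spacing)
  m1 <- regional_metrics(lay, thk$vertices, ph$labels)
  # swap ids 1 <-> 2 in both the map and the codebook
  swapped <- ph$labels
  swapped$labels <- array(c(0L, 2L, 1L)[swapped$labels + 1L],
                          dim = dim(swapped$labels))
  swapped$codebook$id <- c(2L, 1L)
  m2 <- regional_metrics(lay, thk$vertices, swapped)
  m1s <- m1[order(m1$structure, m1$layer, m1$metric), ]
  m2s <- m2[order(m2$structure, m2$layer, m2$metric), ]
  expect_equal(m1s$value, m2s$value, tolerance = 1e-12)
})

test_that("structures without vertices are reported with missing thickness", {
  ph <- shell_clean()
  lay <- list(granular = ph$masks$granular, molecular = ph$masks$molecular,
              purkinje = ph$masks$purkinje)
  thk <- layer_thicknesses(ph$masks$gm, ph$masks$wm, ph$masks$pial,
                           ph$masks$purkinje, lay, ph$volume$spacing)
  # claim all vertices for structure 1 by relabelling the lamina voxels
  lb <- ph$labels
  lb$labels[ph$masks$purkinje] <- 1L
  expect_warning(m <- regional_metrics(lay, thk$vertices, lb),
                 "without Purkinje vertices")
  hb <- m[m$structure == "HemiB", ]
  expect_true(all(is.na(hb$value[hb$metric == "thickness"])))
  expect_true(all(is.finite(hb$value[hb$metric == "volume"])))
})
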