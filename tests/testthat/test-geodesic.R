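test_that("speed map: constant image, resistant overwrite, contraction", {
  n <- 12L
  gm <- array(TRUE, dim = c(n, n, n))
  vol <- voxel_grid(array(3, dim = dim(gm)), 0.04)
  s <- build_speed(vol, gm)
  expect_equal(unname(s$speed[gm]), rep(3, sum(gm)), tolerance = 1e-10)

  res <- array(FALSE, dim = dim(gm)); res[5:6, 5:6, 5:6] <- TRUE
  s2 <- build_speed(vol, gm, resistant_mask = res)
  expect_true(all(s2$speed[res] == 1e-6))

  set.seed(2)
  noisy <- voxel_grid(array(runif(n^3, 10, 90), dim = dim(gm)), 0.04)
  s3 <- build_speed(noisy, gm)
  expect_lt(diff(range(s3$speed[gm])), diff(range(noisy$values[gm])))
  neg <- voxel_grid(array(-1, dim = dim(gm)), 0.04)
  expect_error(build_speed(neg, gm), "non-negative")
  expect_error(build_speed(vol, gm & FALSE), "empty")
})

test_that("unit-speed planar-seed distances are exact within one voxel", {
  n <- 30L
  ones <- array(1, dim = c(n, n, n))
  seeds <- array(FALSE, dim = dim(ones)); seeds[, , 15] <- TRUE
  dm <- solve_eikonal(ones, seeds = seeds, domain = array(TRUE, dim = dim(ones)),
                      spacing = 0.5)
  kz <- slice.index(ones, 3)
  truth <- abs(kz - 15) * 0.5
  expect_lt(max(abs(dm$d - truth)), 0.5)  # one voxel
})

test_that("halving the speed doubles the distance", {
  set.seed(3)
  n <- 15L
  spd <- cereblam:::.gauss_smooth(array(runif(n^3, 0.5, 2), dim = c(n, n, n)), 1)
  dom <- array(TRUE, dim = c(n, n, n))
  seeds <- array(FALSE, dim = dim(dom)); seeds[1, , ] <- TRUE
  d1 <- solve_eikonal(spd, seeds = seeds, domain = dom, spacing = 1)
  d2 <- solve_eikonal(spd / 2, seeds = seeds, domain = dom, spacing = 1)
  expect_equal(d2$d, 2 * d1$d, tolerance = 1e-10)
})

test_that("fast marching agrees with a Dijkstra graph oracle within 5%", {
  skip_if_not_installed("igraph")
  n <- 20L
  set.seed(11)
  raw <- array(runif(n^3, 0.5, 2), dim = c(n, n, n))
  spd <- cereblam:::.gauss_smooth(raw, 1.5)
  dom <- array(TRUE, dim = c(n, n, n))
  seeds <- array(FALSE, dim = dim(dom)); seeds[, , 1] <- TRUE
  dm <- solve_eikonal(spd, seeds = seeds, domain = dom, spacing = 1)

  # oracle: shortest paths on the 26-neighbour graph, edge cost =
  # Euclidean length / mean endpoint speed
  idx <- function(i, j, k) (i - 1) + n * ((j - 1) + n * (k - 1)) + 1
  offs <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  offs <- offs[!(offs$di == 0 & offs$dj == 0 & offs$dk == 0), ]
  offs <- offs[with(offs, di > 0 | (di == 0 & dj > 0) |
                      (di == 0 & dj == 0 & dk > 0)), ]
  el <- list(); wl <- list(); cnt <- 0
  for (o in seq_len(nrow(offs))) {
    di <- offs$di[o]; dj <- offs$dj[o]; dk <- offs$dk[o]
    gi <- expand.grid(i = 1:n, j = 1:n, k = 1:n)
    ok <- gi$i + di >= 1 & gi$i + di <= n & gi$j + dj >= 1 & gi$j + dj <= n &
      gi$k + dk >= 1 & gi$k + dk <= n
    gi <- gi[ok, ]
    a <- idx(gi$i, gi$j, gi$k); b <- idx(gi$i + di, gi$j + dj, gi$k + dk)
    len <- sqrt(di^2 + dj^2 + dk^2)
    w <- len / ((spd[cbind(gi$i, gi$j, gi$k)] +
                   spd[cbind(gi$i + di, gi$j + dj, gi$k + dk)]) / 2)
    cnt <- cnt + 1; el[[cnt]] <- rbind(a, b); wl[[cnt]] <- w
  }
  g <- igraph::graph_from_edgelist(t(matrix(unlist(el), nrow = 2)),
                                   directed = FALSE)
  igraph::E(g)$weight <- unlist(wl)
  dd <- igraph::distances(g, v = which(as.vector(seeds)))
  oracle <- apply(dd, 2, min)
  D <- as.vector(dm$d)
  sel <- oracle > 0
  expect_lt(mean(abs(D - oracle)[sel] / oracle[sel]), 0.05)
})

test_that("the Eikonal residual F|grad D| = 1 holds at interior voxels", {
  ph <- shell_clean()
  gm <- ph$masks$gm
  spd <- build_speed(ph$volume, gm)
  dm <- solve_eikonal(spd, seeds = ph$masks$inner)
  d <- dm$d
  g <- cereblam:::.gradient3(ifelse(is.finite(d), d, NA_real_), dm$spacing)
  gn <- sqrt(g$x^2 + g$y^2 + g$z^2)
  interior <- gm & !dilate26_once(!gm & !ph$masks$wm) & is.finite(gn)
  resid <- (spd$speed * gn)[interior & is.finite(spd$speed * gn)]
  # first-order upwind + central-difference check: median near 1
  expect_lt(abs(median(resid, na.rm = TRUE) - 1), 0.2)
})

test_that("touching folds yield a fissure on the true contact surface", {
  ph <- slab_touch()
  gm <- ph$masks$gm
  spd <- build_speed(ph$volume, gm)
  dm <- solve_eikonal(spd, seeds = ph$masks$inner)
  fis <- extract_fissures(dm, gm, speed = spd)
  expect_gt(sum(fis), 0)
  dists <- mask_dist_vox(fis, ph$truth$fissure)
  expect_gte(mean(dists <= 1.0001), 0.95)
  # the contact surface itself is covered
  cov <- mask_dist_vox(ph$truth$fissure, fis)
  expect_gte(mean(cov <= 1.0001), 0.95)
})

test_that("open folds and shells yield (near-)empty fissure sets", {
  op <- slab_open()
  spd <- build_speed(op$volume, op$masks$gm)
  f_open <- extract_fissures(solve_eikonal(spd, seeds = op$masks$inner),
                             op$masks$gm, speed = spd)
  expect_lte(sum(f_open) / sum(op$masks$gm), 0.001)

  sh <- shell_noisy()
  spd2 <- build_speed(sh$volume, sh$masks$gm)
  f_shell <- extract_fissures(solve_eikonal(spd2, seeds = sh$masks$inner),
                              sh$masks$gm, speed = spd2)
  expect_lte(sum(f_shell) / sum(sh$masks$gm), 0.001)
})

test_that("no fissure voxels appear inside resistant layers", {
  ph <- make_folded_slab(touching = TRUE, noise_sd = 2, seed = 5,
                         resistant_valley = 1)
  gm <- ph$masks$gm
  res <- ph$masks$resistant
  spd <- build_speed(ph$volume, gm, resistant_mask = res)
  fis <- extract_fissures(solve_eikonal(spd, seeds = ph$masks$inner), gm,
                          speed = spd, resistant_mask = res)
  expect_equal(sum(fis & res), 0)
  expect_gt(sum(fis), 0)  # the unbarred valley still carries its fissure
})

test_that("Purkinje contrast removal averages the lamina into its surround", {
  ph <- shell_noisy()
  gm <- ph$masks$gm
  lam <- ph$masks$purkinje
  # uniform image: identity
  flat <- voxel_grid(array(5, dim = dim(gm)), ph$volume$spacing)
  out0 <- remove_purkinje_contrast(flat, lam, gm)
  expect_equal(out0$values, flat$values, tolerance = 1e-10)

  out <- remove_purkinje_contrast(ph$volume, lam, gm)
  # averaging bound: substituted values within the surrounding layer range
  nb <- gm & !lam
  expect_true(all(out$values[lam] >= min(ph$volume$values[nb]) - 1e-9))
  expect_true(all(out$values[lam] <= max(ph$volume$values[nb]) + 1e-9))
  # contrast (mean |lamina - local surround|) reduced by >= 90%
  contrast <- function(v) {
    sm <- cereblam:::.gauss_smooth_masked(v, nb, 1.5)
    mean(abs(v[lam] - sm[lam]), na.rm = TRUE)
  }
  expect_lt(contrast(out$values), 0.1 * contrast(ph$volume$values))
  # voxels outside M_P0 are untouched
  expect_identical(out$values[!lam], ph$volume$values[!lam])
  expect_error(remove_purkinje_contrast(ph$volume, gm, gm), "covers all")
})

test_that("the improved fissure is no farther from truth than the initial one", {
  ph <- slab_touch()
  gm <- ph$masks$gm
  spd0 <- build_speed(ph$volume, gm)
  f0 <- extract_fissures(solve_eikonal(spd0, seeds = ph$masks$inner), gm,
                         speed = spd0)
  pl <- purkinje_planeness(ph$volume, gm)
  m0 <- initial_purkinje(pl$response, gm)
  sub <- remove_purkinje_contrast(ph$volume, m0, gm)
  spd1 <- build_speed(sub, gm)
  f1 <- extract_fissures(solve_eikonal(spd1, seeds = ph$masks$inner), gm,
                         speed = spd1)
  expect_gt(sum(f1), 0)
  med0 <- median(mask_dist_vox(f0, ph$truth$fissure))
  med1 <- median(mask_dist_vox(f1, ph$truth$fissure))
  expect_lte(med1, med0)
})
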