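# Shared phantom fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

shell_clean <- function() fixture("shell_clean", function()
  make_shell(noise_sd = 0))

shell_noisy <- function() fixture("shell_noisy", function()
  make_shell(noise_sd = 2, seed = 7))

shell_field <- function() fixture("shell_field", function() {
  ph <- shell_clean()
  solve_laplace(ph$masks$gm, ph$masks$wm, ph$masks$pial, ph$volume$spacing)
})

shell_equiv <- function() fixture("shell_equiv", function()
  equivolume_ratio(shell_field()))

slab_touch <- function() fixture("slab_touch", function()
  make_folded_slab(touching = TRUE, noise_sd = 2, seed = 3))

slab_open <- function() fixture("slab_open", function()
  make_folded_slab(amplitude = 0.15, touching = FALSE, noise_sd = 2, seed = 4))

# flat-slab domain: GM between z-planes, used for 1-D harmonic checks;
# boundaries are the voxel layers just outside the slab
flat_slab <- function(nz_gm = 6L, nxy = 16L, spacing = 0.04) {
  nz <- nz_gm + 6L
  dm <- c(nxy, nxy, nz)
  kz <- slice.index(array(0, dm), 3)
  z0 <- 4L
  gm <- kz >= z0 & kz < z0 + nz_gm
  inner <- kz == z0 - 1L
  outer <- kz == z0 + nz_gm
  list(gm = gm, inner = inner, outer = outer, spacing = rep(spacing, 3),
       width = nz_gm * spacing,
       depth = (kz - z0 + 0.5) * spacing)  # depth of voxel centre below inner face
}

# Euclidean distance (in voxels) from each voxel of `from` to the nearest
# voxel of `to`
mask_dist_vox <- function(from, to) {
  dd <- dim(from)
  coords <- function(w) cbind((w - 1) %% dd[1],
                              ((w - 1) %/% dd[1]) %% dd[2],
                              (w - 1) %/% (dd[1] * dd[2]))
  cf <- coords(which(from))
  ct <- coords(which(to))
  apply(cf, 1, function(p) min(sqrt(colSums((t(ct) - p)^2))))
}

dilate26_once <- function(m) {
  for (ax in 1:3)
    m <- m | cereblam:::.shift1(m + 0, ax, 1, 0) > 0 |
      cereblam:::.shift1(m + 0, ax, -1, 0) > 0
  m
}
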