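#' Analytic phantoms for cerebellar laminar morphometry
#'
#' The phantom module emulates the features the pipeline needs from
#' contrast-enhanced ex vivo data: a bright cortical ribbon on a darker
#' background, a thin bright mid-cortical lamina (the Purkinje analogue),
#' touching folia with vanished CSF gaps, and two-group cohorts with
#' TIV-correlated metrics. Every phantom carries closed-form ground truth so
#' each stage can be validated without any image download.
#'
#' @name phantoms
NULL

.default_intensities <- c(background = 10, wm = 70, granular = 50,
                          lamina = 75, molecular = 30)

.check_intensities <- function(intensities) {
  need <- names(.default_intensities)
  if (is.null(names(intensities)) || !all(need %in% names(intensities)))
    stop("`intensities` must be named with: ", paste(need, collapse = ", "))
  intensities[need]
}

#' Spherical cortical shell phantom
#'
#' A WM ball of radius `r_in` surrounded by a cortical shell up to `r_out`,
#' with a one-voxel bright lamina placed at the equivolume locus
#' `r*^3 = r_in^3 + f (r_out^3 - r_in^3)` (or at the mid-distance locus).
#' The shell geometry has closed-form laminar depth, thickness, and layer
#' volumes, which the truth record carries.
#'
#' @param r_in,r_out inner/outer shell radii in mm, `0 < r_in < r_out`.
#' @param lamina_fraction equivolume depth of the lamina in (0, 1).
#' @param intensities named numeric: background, wm, granular, lamina,
#'   molecular intensity levels.
#' @param noise_sd additive Gaussian noise sd on intensity.
#' @param spacing isotropic voxel size in mm (default 0.04, the acquisition
#'   grid emulated throughout).
#' @param margin background margin in voxels around the shell.
#' @param lamina_at `"equivolume"` (default) or `"mid"` (mid-distance locus).
#' @param seed RNG seed for the noise draw.
#' @return list with `volume` (a [voxel_grid()]), `masks` (wm, gm, pial,
#'   inner, purkinje, granular, molecular — logical arrays), `labels` (a
#'   two-region label map splitting the shell by hemisphere), and `truth`.
#' @export
make_shell <- function(r_in = 0.4, r_out = 0.64, lamina_fraction = 0.5,
                       intensities = .default_intensities, noise_sd = 2,
                       spacing = 0.04, margin = 4L,
                       lamina_at = c("equivolume", "mid"), seed = NULL) {
  if (!(r_in > 0 && r_out > r_in)) stop("need 0 < r_in < r_out")
  if (!(lamina_fraction > 0 && lamina_fraction < 1))
    stop("`lamina_fraction` must be in (0, 1)")
  lamina_at <- match.arg(lamina_at)
  intensities <- .check_intensities(intensities)
  h <- spacing
  half <- ceiling(r_out / h) + margin
  n <- 2L * as.integer(half) + 1L
  ctr <- half * h  # world coordinate of the central voxel centre
  ax <- (seq_len(n) - 1L) * h - ctr
  r <- sqrt(outer(outer(ax^2, ax^2, "+"), ax^2, "+"))

  r_star <- if (lamina_at == "equivolume") {
    (r_in^3 + lamina_fraction * (r_out^3 - r_in^3))^(1 / 3)
  } else {
    r_in + lamina_fraction * (r_out - r_in)
  }

  wm <- r < r_in
  gm <- r >= r_in & r < r_out
  lamina <- gm & abs(r - r_star) <= h / 2
  granular <- gm & r < r_star & !lamina
  molecular <- gm & r >= r_star & !lamina

  vals <- array(intensities[["background"]], dim = c(n, n, n))
  vals[wm] <- intensities[["wm"]]
  vals[granular] <- intensities[["granular"]]
  vals[molecular] <- intensities[["molecular"]]
  vals[lamina] <- intensities[["lamina"]]
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    vals <- vals + array(rnorm(length(vals), 0, noise_sd), dim = dim(vals))
  }

  # two mirror-image hemisphere labels; the central plane of the odd grid is
  # split along y so both regions carry identical voxel counts by symmetry
  labels <- array(0L, dim = dim(gm))
  xidx <- slice.index(gm, 1L)
  yidx <- slice.index(gm, 2L)
  cmid <- (n + 1L) %/% 2L
  labels[gm & (xidx < cmid | (xidx == cmid & yidx < cmid))] <- 1L
  labels[gm & (xidx > cmid | (xidx == cmid & yidx > cmid))] <- 2L
  labels[gm & xidx == cmid & yidx == cmid] <- 1L  # the axis line itself
  codebook <- tibble::tibble(id = 1:2, abbreviation = c("HemiA", "HemiB"),
                             region = "phantom")

  truth <- list(
    kind = "shell", r_in = r_in, r_out = r_out, r_star = r_star,
    lamina_fraction = lamina_fraction, lamina_at = lamina_at,
    thickness = r_out - r_in,
    thickness_granular = r_star - r_in,
    thickness_molecular = r_out - r_star,
    vol_gm = 4 * pi / 3 * (r_out^3 - r_in^3),
    vol_granular = 4 * pi / 3 * (r_star^3 - r_in^3),
    vol_molecular = 4 * pi / 3 * (r_out^3 - r_star^3),
    spacing = h, centre = ctr, radius_map = r
  )

  list(volume = voxel_grid(vals, spacing = h),
       masks = list(wm = wm, gm = gm,
                    inner = .adjacent_to(wm, gm),
                    pial = .outer_boundary(gm | wm),
                    purkinje = lamina, granular = granular,
                    molecular = molecular),
       labels = structure(list(labels = labels, spacing = rep(h, 3), codebook = codebook),
                          class = "label_map"),
       truth = truth)
}

#' Folded cortical slab phantom
#'
#' A cortical band of constant thickness draped over a sinusoidally folded
#' WM surface `z = z0 + A (1 + cos(2 pi x / wavelength)) / 2`, extruded along
#' y. With a deep, narrow valley (large amplitude) the two pial walls of
#' adjacent folia meet and the CSF gap vanishes; the analytic contact
#' mid-surface (the valley mid-plane where the closest WM-surface point is
#' distinct on the left and right walls and the band covers the plane) is
#' recorded as the true fissure. With `touching = FALSE` geometry the gap
#' stays open and the true fissure set is empty.
#'
#' The bright lamina is drawn at a constant offset `lamina_fraction *
#' cortical_thickness` from the WM surface (the paper-style equivolume locus
#' has no closed form in folded geometry; the shell phantom carries that
#' truth instead).
#'
#' @param wavelength fold wavelength in mm.
#' @param amplitude fold amplitude in mm; large amplitudes close the valley.
#' @param cortical_thickness band thickness in mm.
#' @param lamina_fraction depth fraction of the lamina within the band.
#' @param touching logical; when TRUE the default geometry must produce
#'   touching walls (validated against the analytic contact criterion).
#' @param n_folds number of full periods along x.
#' @param resistant_valley optional integer: insert a resistant-layer mask at
#'   this valley's contact plane (1-based valley count).
#' @param intensities,noise_sd,spacing,seed as in [make_shell()].
#' @return list with `volume`, `masks` (wm, gm, inner, pial, purkinje,
#'   granular, molecular, resistant), `labels` (2-region split), `truth`
#'   (incl. `fissure` mask of true contact voxels).
#' @export
make_folded_slab <- function(wavelength = 0.8, amplitude = 0.7,
                             cortical_thickness = 0.2, lamina_fraction = 0.5,
                             touching = TRUE, n_folds = 2L,
                             resistant_valley = NULL,
                             intensities = .default_intensities, noise_sd = 2,
                             spacing = 0.04, seed = NULL) {
  if (any(c(wavelength, amplitude, cortical_thickness) <= 0) && amplitude != 0)
    stop("wavelength and cortical_thickness must be positive, amplitude non-negative")
  if (amplitude < 0) stop("amplitude must be non-negative")
  intensities <- .check_intensities(intensities)
  h <- spacing
  t_cort <- cortical_thickness
  A <- amplitude
  lam <- wavelength

  # curvature at the valley bottom of z = z0 + A(1+cos(2 pi x / lam))/2:
  # f''(x_v) = 2 A pi^2 / lam^2 ; the medial ridge starts one radius of
  # curvature above the bottom and the band covers it while the wall distance
  # stays below t_cort
  cpar <- if (A > 0) A * pi^2 / lam^2 else 0

  nx <- as.integer(round(n_folds * lam / h))
  ny <- 12L
  z0 <- 0.16                         # WM base depth below the lowest valley
  zmax <- z0 + A + t_cort + 0.14
  nz <- as.integer(ceiling(zmax / h))
  xs <- (seq_len(nx) - 1L) * h
  zs <- (seq_len(nz) - 1L) * h

  f_of_x <- function(x) z0 + A * (1 + cos(2 * pi * x / lam)) / 2

  # 2-D (x, z) distance to the WM surface curve, via dense sampling
  xc <- seq(min(xs) - 2 * h, max(xs) + 2 * h, by = h / 10)
  zc <- f_of_x(xc)
  dist2curve <- function(px, pz, sel = TRUE) {
    xcs <- xc[sel]; zcs <- zc[sel]
    out <- matrix(NA_real_, length(px), length(pz))
    for (ii in seq_along(px)) {
      dx2 <- (xcs - px[ii])^2
      for (jj in seq_along(pz)) out[ii, jj] <- sqrt(min(dx2 + (zcs - pz[jj])^2))
    }
    out
  }
  dmat <- dist2curve(xs, zs)                       # nx x nz
  fvals <- f_of_x(xs)
  below <- outer(fvals, zs, function(f, z) z < f)  # below the WM surface

  wm2 <- below
  gm2 <- !below & dmat <= t_cort
  d_star <- lamina_fraction * t_cort
  lam2 <- gm2 & abs(dmat - d_star) <= h / 2
  gran2 <- gm2 & dmat < d_star & !lam2
  mol2 <- gm2 & dmat >= d_star & !lam2

  # analytic contact surface: valley mid-planes where the closest curve point
  # is distinct on each wall (height above bottom > radius of curvature) and
  # the point still lies inside the band
  valleys <- (seq_len(n_folds) - 0.5) * lam
  fis2 <- matrix(FALSE, nx, nz)
  contact <- logical(length(valleys))
  for (vi in seq_along(valleys)) {
    xv <- valleys[vi]
    col <- which.min(abs(xs - xv))
    if (A > 0) {
      rcurv <- 1 / (2 * cpar)
      zlo <- z0 + rcurv
      sel_l <- xc < xv & xc > xv - lam / 2
      sel_r <- xc > xv & xc < xv + lam / 2
      dl <- dist2curve(xs[col], zs, sel_l)[1, ]
      dr <- dist2curve(xs[col], zs, sel_r)[1, ]
      hit <- zs > zlo & dl <= t_cort & dr <= t_cort & gm2[col, ]
      fis2[col, hit] <- TRUE
      contact[vi] <- any(hit)
    }
  }
  if (touching && !any(contact))
    stop("geometry does not produce touching walls; increase amplitude or thickness")
  if (!touching && any(contact))
    stop("geometry produces touching walls; decrease amplitude or thickness")

  expand_y <- function(m2) {
    out <- array(FALSE, dim = c(nx, ny, nz))
    for (jj in seq_len(ny)) out[, jj, ] <- m2
    out
  }
  wm <- expand_y(wm2); gm <- expand_y(gm2)
  lamina <- expand_y(lam2); granular <- expand_y(gran2); molecular <- expand_y(mol2)
  fissure_true <- expand_y(fis2)

  resistant <- array(FALSE, dim = dim(gm))
  if (!is.null(resistant_valley)) {
    if (resistant_valley > length(valleys)) stop("no such valley")
    xv <- valleys[resistant_valley]
    col <- which.min(abs(xs - xv))
    res2 <- matrix(FALSE, nx, nz)
    res2[col, ] <- fis2[col, ]
    resistant <- expand_y(res2)
    fissure_true[resistant] <- FALSE  # barred region carries no true fissure
  }

  vals <- array(intensities[["background"]], dim = dim(gm))
  vals[wm] <- intensities[["wm"]]
  vals[granular] <- intensities[["granular"]]
  vals[molecular] <- intensities[["molecular"]]
  vals[lamina] <- intensities[["lamina"]]
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    vals <- vals + array(rnorm(length(vals), 0, noise_sd), dim = dim(vals))
  }

  labels <- array(0L, dim = dim(gm))
  xidx <- slice.index(gm, 1L)
  brk <- as.integer(round(lam / h))
  labels[gm & xidx <= brk] <- 1L
  labels[gm & xidx > brk] <- 2L
  codebook <- tibble::tibble(id = 1:2, abbreviation = c("FoldA", "FoldB"),
                             region = "phantom")

  truth <- list(
    kind = "folded_slab", wavelength = lam, amplitude = A,
    cortical_thickness = t_cort, lamina_fraction = lamina_fraction,
    touching = touching, valleys = valleys,
    fissure = fissure_true, spacing = h,
    thickness_granular = d_star, thickness_molecular = t_cort - d_star,
    dist_map = dmat
  )

  list(volume = voxel_grid(vals, spacing = h),
       masks = list(wm = wm, gm = gm,
                    inner = .adjacent_to(wm, gm),
                    pial = .outer_boundary(gm | wm),
                    purkinje = lamina, granular = granular,
                    molecular = molecular, resistant = resistant),
       labels = structure(list(labels = labels, spacing = rep(h, 3), codebook = codebook),
                          class = "label_map"),
       truth = truth)
}

#' Simulate a two-group morphometry cohort
#'
#' Draws per-subject, per-structure layer thickness and surface area as
#' `metric = b0 + b_tiv * (TIV - mean TIV) + effect * group + noise`, with
#' volume = thickness x area and TSR = thickness / sqrt(area). The case group
#' receives a positive TIV shift (larger heads), a negative granular-layer
#' thickness effect and a negative molecular-layer surface-area effect —
#' the qualitative pattern the pipeline is meant to detect. Effects and the
#' TIV slope are expressed in control-SD units of the respective metric.
#'
#' @param n_control,n_case group sizes (>= 3 each; defaults 14 and 14).
#' @param tiv_mean,tiv_sd control TIV distribution, mm^3.
#' @param tiv_case_shift additive TIV shift for cases, mm^3.
#' @param beta_tiv TIV slope in control-SD of metric per control-SD of TIV.
#' @param granular_thickness_effect,molecular_area_effect group effects in
#'   control-SD units (negative = smaller in cases).
#' @param noise_sd residual coefficient of variation of each metric.
#' @param structures character vector of structure names.
#' @param seed RNG seed.
#' @return list with `subjects` (tibble: subject, group, tiv), `metrics`
#'   (long morphometry tibble) and `truth` (all generating coefficients).
#' @export
simulate_cohort <- function(n_control = 14L, n_case = 14L,
                            tiv_mean = 450, tiv_sd = 15, tiv_case_shift = 30,
                            beta_tiv = 1,
                            granular_thickness_effect = -1.5,
                            molecular_area_effect = -1.5,
                            noise_sd = 0.05,
                            structures = analyzed_structures(),
                            seed = NULL) {
  if (n_control < 3L || n_case < 3L) stop("need at least 3 subjects per group")
  if (noise_sd <= 0 || tiv_sd <= 0) stop("sds must be positive")
  if (!is.null(seed)) set.seed(seed)

  ns <- length(structures)
  n <- n_control + n_case
  subjects <- tibble::tibble(
    subject = sprintf("S%02d", seq_len(n)),
    group = rep(c("control", "case"), c(n_control, n_case)),
    tiv = rnorm(n, tiv_mean, tiv_sd) + ifelse(rep(c(FALSE, TRUE), c(n_control, n_case)),
                                              tiv_case_shift, 0))
  if (any(subjects$tiv <= 0)) stop("simulated non-positive TIV; check parameters")

  # deterministic per-structure baselines (vary smoothly across structures)
  sidx <- seq_len(ns)
  base <- list(
    thickness_granular = 0.18 + 0.06 * sin(sidx / 2),
    thickness_molecular = 0.11 + 0.03 * cos(sidx / 3),
    area_granular = 7 + 3 * sin(sidx / 1.7 + 1),
    area_molecular = 8 + 3 * cos(sidx / 2.3)
  )
  lamina_thickness <- 0.015

  draw <- function(b0, effect_case) {
    sig <- noise_sd * b0                       # control residual sd
    slope <- beta_tiv * sig / tiv_sd           # per-mm^3 slope
    vapply(seq_len(n), function(i) {
      b0 + slope * (subjects$tiv[i] - tiv_mean) +
        (if (subjects$group[i] == "case") effect_case * sig else 0) +
        rnorm(ns, 0, sig)
    }, numeric(ns))                            # ns x n
  }

  tg <- draw(base$thickness_granular, granular_thickness_effect)
  tm <- draw(base$thickness_molecular, 0)
  ag <- draw(base$area_granular, 0)
  am <- draw(base$area_molecular, molecular_area_effect)
  tg <- pmax(tg, 1e-3); tm <- pmax(tm, 1e-3)
  ag <- pmax(ag, 1e-2); am <- pmax(am, 1e-2)

  tf <- tg + tm + lamina_thickness
  af <- (ag + am) / 2
  vg <- tg * ag; vm <- tm * am
  vf <- vg + vm + lamina_thickness * af

  long <- function(mat, layer, metric) {
    tibble::tibble(
      subject = rep(subjects$subject, each = ns),
      structure = rep(structures, n),
      layer = layer, metric = metric,
      value = as.vector(mat))
  }
  metrics <- dplyr::bind_rows(
    long(vg, "granular", "volume"), long(vm, "molecular", "volume"),
    long(vf, "full", "volume"),
    long(tg, "granular", "thickness"), long(tm, "molecular", "thickness"),
    long(tf, "full", "thickness"),
    long(ag, "granular", "area"), long(am, "molecular", "area"),
    long(af, "full", "area"),
    long(tg / sqrt(ag), "granular", "tsr"), long(tm / sqrt(am), "molecular", "tsr"),
    long(tf / sqrt(af), "full", "tsr"))

  truth <- list(
    n_control = n_control, n_case = n_case,
    tiv_mean = tiv_mean, tiv_sd = tiv_sd, tiv_case_shift = tiv_case_shift,
    beta_tiv = beta_tiv,
    granular_thickness_effect = granular_thickness_effect,
    molecular_area_effect = molecular_area_effect,
    noise_sd = noise_sd, baselines = base,
    lamina_thickness = lamina_thickness, structures = structures)

  list(subjects = subjects, metrics = metrics, truth = truth)
}
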