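#' Speed map for geodesic distance computation
#'
#' The Eikonal speed function is the Gaussian-smoothed (masked, normalized)
#' image intensity within the cortex, clipped below at a small positive
#' floor. Resistant-layer voxels — artificial barriers between anatomically
#' distinct but touching lobules — are overwritten with a near-zero speed so
#' the marching front cannot cross them.
#'
#' @param volume a [voxel_grid()] of (normalized) intensities, non-negative
#'   within the GM mask.
#' @param gm_mask logical cortex mask, non-empty.
#' @param sigma_speed Gaussian kernel size (default 1.5); unit set by
#'   `sigma_unit` (the printed value carries no unit; voxels is the default
#'   reading).
#' @param resistant_mask optional logical mask of resistant-layer voxels.
#' @param sigma_unit `"voxel"` or `"mm"`.
#' @param floor_frac speed floor as a fraction of the median GM intensity.
#' @param resistant_epsilon speed assigned inside resistant layers.
#' @return object of class `speed_map`: `speed` array (NA outside the
#'   domain), `domain`, `spacing`, parameters.
#' @export
build_speed <- function(volume, gm_mask, sigma_speed = 1.5,
                        resistant_mask = NULL, sigma_unit = c("voxel", "mm"),
                        floor_frac = 1e-3, resistant_epsilon = 1e-6) {
  stopifnot(inherits(volume, "voxel_grid"))
  sigma_unit <- match.arg(sigma_unit)
  if (!any(gm_mask)) stop("empty GM mask")
  v <- volume$values
  if (any(v[gm_mask] < 0, na.rm = TRUE))
    stop("normalized intensities must be non-negative within GM")
  sig_vox <- if (sigma_unit == "mm") sigma_speed / volume$spacing else
    rep(sigma_speed, 3L)
  sm <- .gauss_smooth_masked(v, gm_mask, sig_vox)
  flo <- floor_frac * median(v[gm_mask], na.rm = TRUE)
  speed <- pmax(sm, max(flo, 1e-12))
  speed[!gm_mask] <- NA_real_
  if (!is.null(resistant_mask)) speed[resistant_mask & gm_mask] <- resistant_epsilon
  structure(list(speed = speed, domain = gm_mask, spacing = volume$spacing,
                 sigma_speed = sigma_speed, sigma_unit = sigma_unit,
                 resistant_epsilon = resistant_epsilon),
            class = "speed_map")
}

#' Solve the Eikonal equation by fast marching
#'
#' First-order upwind fast marching for `F(x) |grad D(x)| = 1` with `D = 0`
#' on the seed voxels. Voxels of the domain the front never reaches keep the
#' sentinel value `Inf`.
#'
#' @param speed a `speed_map` (or a numeric array of positive speeds).
#' @param seeds logical seed mask, non-empty subset of the domain.
#' @param domain logical solution domain (defaults to the speed map domain).
#'   Seed voxels are added to the domain automatically.
#' @param spacing required when `speed` is a bare array.
#' @return object of class `distance_map`: `d` array (NA outside the domain,
#'   `Inf` where unreached), `seeds`, `domain`, `spacing`.
#' @export
solve_eikonal <- function(speed, seeds, domain = NULL, spacing = NULL) {
  if (inherits(speed, "speed_map")) {
    sp <- speed$spacing
    if (is.null(domain)) domain <- speed$domain
    f <- speed$speed
  } else {
    if (is.null(spacing)) stop("`spacing` required for a bare speed array")
    sp <- if (length(spacing) == 1L) rep(spacing, 3L) else spacing
    if (is.null(domain)) domain <- array(TRUE, dim = dim(speed))
    f <- speed
  }
  if (!any(seeds)) stop("empty seed mask")
  dom <- domain | seeds
  if (!any(dom & !seeds)) stop("domain has zero measure outside the seeds")
  fa <- f
  fa[is.na(fa)] <- median(fa[dom], na.rm = TRUE)  # seeds outside the speed domain
  d <- cpp_fast_marching(as.double(fa), as.logical(seeds), as.logical(dom),
                         .as_dim(dom), as.double(sp))
  structure(list(d = array(d, dim = dim(dom)), seeds = seeds, domain = dom,
                 spacing = sp), class = "distance_map")
}

#' Extract fissures as geodesic ridge sheets
#'
#' Fissure candidates are the directional local maxima of the geodesic
#' distance `D` along the line on which the marching fronts from the two
#' walls of a closed sulcus collide. At a collision shock the gradient of
#' `D` cancels across the sheet and runs along it, so the comparison line is
#' the principal direction of the Hessian of the (lightly smoothed) distance
#' map with the most negative eigenvalue — the across-ridge direction; `D`
#' must be maximal against the trilinear samples one voxel ahead and behind
#' along it. A ridge-prominence gate separates genuine contact creases from
#' the shallow shocks a layered speed map produces along bright laminae: the
#' drop of `D` one voxel off the ridge is expressed in units of the local
#' one-voxel distance increment `h / F` (head-on front collisions score near
#' 0.5, glancing creases near 0.2) and candidates below `min_prominence`
#' are discarded. Candidates are then thinned by recursive geodesic
#' erosion: simple points removed in increasing-D order while preserving
#' local topology, leaving a one-voxel sheet; isolated specks (which
#' topology-preserving erosion cannot remove) are dropped by a minimum
#' component size. Resistant-layer voxels never carry fissure.
#'
#' @param dist a `distance_map` from [solve_eikonal()] seeded at the WM/GM
#'   boundary.
#' @param gm_mask logical cortex mask.
#' @param resistant_mask optional logical resistant-layer mask.
#' @param speed the `speed_map` used for the distance solve; supplies the
#'   local `h / F` scale for the prominence gate. `NULL` falls back to a
#'   global gradient-based estimate.
#' @param min_distance candidates must lie at least this geodesic distance
#'   from the seeds (same units as `D`); default 0.
#' @param ridge_sigma smoothing (voxels) applied to `D` before the Hessian.
#' @param min_prominence ridge-prominence threshold (default 0.25).
#' @param min_component smallest surviving 26-connected component (voxels).
#' @return logical fissure mask (possibly empty).
#' @export
extract_fissures <- function(dist, gm_mask, speed = NULL,
                             resistant_mask = NULL,
                             min_distance = 0, ridge_sigma = 0.7,
                             min_prominence = 0.25, min_component = 6L) {
  stopifnot(inherits(dist, "distance_map"))
  d <- dist$d
  sp <- dist$spacing
  valid <- gm_mask & is.finite(d)
  if (!is.null(resistant_mask)) valid <- valid & !resistant_mask
  if (!any(valid)) return(array(FALSE, dim = dim(d)))
  ds <- .gauss_smooth_masked(ifelse(is.finite(d), d, 0), valid, ridge_sigma)
  ds[!valid] <- NA_real_
  g <- .gradient3(ds, sp)
  hxx <- .gradient3(g$x, sp); hyy <- .gradient3(g$y, sp); hzz <- .gradient3(g$z, sp)
  ev <- cpp_sym3_minvec(as.double(hxx$x), as.double(hxx$y), as.double(hxx$z),
                        as.double(hyy$y), as.double(hyy$z), as.double(hzz$z))
  dd <- dim(d)
  u <- list(x = array(ev[, 1], dd), y = array(ev[, 2], dd), z = array(ev[, 3], dd))
  lmin <- array(ev[, 4], dd)

  # ridge prominence: drop of D one voxel off the ridge over the local
  # one-voxel distance increment h / F
  h <- min(sp)
  wv <- which(valid & is.finite(u$x) & is.finite(ds))
  cand <- array(FALSE, dim = dd)
  if (length(wv)) {
    pts <- .which_vox(valid & is.finite(u$x) & is.finite(ds))
    ux <- u$x[wv] * h / sp[1]; uy <- u$y[wv] * h / sp[2]; uz <- u$z[wv] * h / sp[3]
    fwd <- .trilinear(ds, valid, cbind(pts[, 1] + ux, pts[, 2] + uy, pts[, 3] + uz))
    bwd <- .trilinear(ds, valid, cbind(pts[, 1] - ux, pts[, 2] - uy, pts[, 3] - uz))
    drop <- ds[wv] - pmax(fwd, bwd)
    incr <- if (inherits(speed, "speed_map")) {
      h / pmax(speed$speed[wv], 1e-12)
    } else {
      gn <- sqrt(g$x^2 + g$y^2 + g$z^2)
      rep(h * median(gn[valid], na.rm = TRUE), length(wv))
    }
    keep <- !is.na(drop) & drop / incr >= min_prominence
    cand[wv[keep]] <- TRUE
  }
  cand <- cand & lmin < 0 & d > min_distance
  if (!is.null(resistant_mask)) cand <- cand & !resistant_mask
  if (!any(cand)) return(array(FALSE, dim = dim(d)))
  ord <- d
  ord[!is.finite(ord)] <- 0
  thin <- array(cpp_thin_sheet(as.logical(cand), as.double(ord), .as_dim(cand)),
                dim = dim(cand))
  if (min_component > 1L && any(thin)) {
    lab <- label_components(thin, 26L)
    sz <- tabulate(lab[lab > 0L])
    small <- lab > 0L & array(sz[pmax(lab, 1L)], dim = dd) < min_component
    thin[small] <- FALSE
  }
  if (!is.null(resistant_mask)) thin <- thin & !resistant_mask
  thin & gm_mask
}

#' Remove Purkinje-layer contrast from an intensity volume
#'
#' Replaces the intensity of initial-Purkinje voxels with a multi-level
#' Gaussian average of the surrounding cortical intensities, so that a
#' second fissure-extraction pass relies on the fissure's own contrast
#' rather than the bright lamina. At each level, `M_P0` voxels take the
#' normalized Gaussian-weighted average of non-`M_P0` (and already filled)
#' neighbours; all other voxels are unchanged.
#'
#' @param volume a [voxel_grid()] of normalized intensities.
#' @param m_p0 logical initial Purkinje mask, subset of `gm_mask`.
#' @param gm_mask logical cortex mask.
#' @param levels number of diffusion levels (default 10).
#' @param sigma per-level Gaussian sigma in voxels (default 1).
#' @return a [voxel_grid()] with substituted intensities.
#' @export
remove_purkinje_contrast <- function(volume, m_p0, gm_mask, levels = 10L,
                                     sigma = 1) {
  stopifnot(inherits(volume, "voxel_grid"))
  if (any(m_p0 & !gm_mask)) stop("`m_p0` must be a subset of `gm_mask`")
  if (all(gm_mask == (gm_mask & m_p0))) stop("M_P0 covers all of GM; nothing to average from")
  v <- volume$values
  known <- gm_mask & !m_p0
  vals <- v
  vals[!known] <- 0
  w <- array(as.double(known), dim = dim(v))
  filled <- known
  for (lev in seq_len(levels)) {
    num <- .gauss_smooth(vals * w, sigma)
    den <- .gauss_smooth(w, sigma)
    upd <- m_p0 & den > 1e-8
    vals[upd] <- num[upd] / den[upd]
    filled <- filled | upd
    w <- array(as.double(filled), dim = dim(v))
    # keep the surrounding-cortex values fixed at every level
    vals[known] <- v[known]
  }
  out <- v
  out[m_p0 & filled] <- vals[m_p0 & filled]
  voxel_grid(out, spacing = volume$spacing, affine = volume$affine)
}
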