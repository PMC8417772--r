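#' Planeness filter parameters
#'
#' Defaults are the printed operating point of the filter: a fixed scale
#' `s = 0.04` mm, derivative pre-smoothing `sigma_h = 0.5` voxels, and
#' sensitivity thresholds `alpha = beta = 0.5`, `gamma = 8`.
#'
#' @param s filter scale in mm, applied as Gaussian smoothing before the
#'   derivative smoothing.
#' @param sigma_h Hessian pre-smoothing in voxels.
#' @param alpha,beta,gamma sensitivity thresholds for the plate-likeness,
#'   blobness, and structure-vs-noise terms.
#' @param response_threshold threshold for the initial Purkinje mask; `NULL`
#'   selects Otsu's threshold on the positive responses within GM.
#' @export
planeness_params <- function(s = 0.04, sigma_h = 0.5, alpha = 0.5, beta = 0.5,
                             gamma = 8, response_threshold = NULL) {
  stopifnot(s > 0, sigma_h > 0, alpha > 0, beta > 0, gamma > 0)
  structure(list(s = s, sigma_h = sigma_h, alpha = alpha, beta = beta,
                 gamma = gamma, response_threshold = response_threshold),
            class = "planeness_params")
}

#' Hessian eigenvalues of a smoothed volume
#'
#' Second derivatives of the Gaussian-smoothed image by central differences
#' in world units, followed by a symmetric 3x3 eigen-decomposition per voxel.
#' Eigenvalues are ordered by absolute value, |l1| <= |l2| <= |l3|.
#'
#' @param volume a [voxel_grid()].
#' @param sigma_h pre-smoothing in voxels (> 0).
#' @param pre_smooth_mm optional additional smoothing scale in mm applied
#'   first (the filter scale `s`); `NULL` skips it.
#' @return object of class `hessian_eigen` with eigenvalue arrays `l1`,
#'   `l2`, `l3` and the smoothing scales.
#' @export
hessian_eigenvalues <- function(volume, sigma_h = 0.5, pre_smooth_mm = NULL) {
  stopifnot(inherits(volume, "voxel_grid"), sigma_h > 0)
  sp <- volume$spacing
  if (max(sp) / min(sp) > 1 + 1e-6)
    message("hessian_eigenvalues: anisotropic spacing; derivatives scaled per axis")
  a <- volume$values
  if (!is.null(pre_smooth_mm) && pre_smooth_mm > 0)
    a <- .gauss_smooth(a, pre_smooth_mm / sp)
  a <- .gauss_smooth(a, sigma_h)
  g <- .gradient3(a, sp)
  gxx <- .gradient3(g$x, sp)
  gyy <- .gradient3(g$y, sp)
  gzz <- .gradient3(g$z, sp)
  eig <- cpp_sym3_eigs(as.double(gxx$x), as.double(gxx$y), as.double(gxx$z),
                       as.double(gyy$y), as.double(gyy$z), as.double(gzz$z))
  d <- dim(a)
  structure(list(l1 = array(eig[, 1], d), l2 = array(eig[, 2], d),
                 l3 = array(eig[, 3], d), sigma_h = sigma_h,
                 pre_smooth_mm = pre_smooth_mm, spacing = sp),
            class = "hessian_eigen")
}

#' Planar-structure (planeness) filter response
#'
#' A plate-enhancement filter adapted from the Frangi vesselness family: with
#' eigenvalues ordered |l1| <= |l2| <= |l3|,
#' \deqn{P = \exp(-R_A^2/2\alpha^2)\,\exp(-R_B^2/2\beta^2)\,(1 - \exp(-S^2/2\gamma^2))}
#' where `R_A = |l2|/|l3|` measures deviation from a plate (cross-sectional
#' asymmetry), `R_B = |l1|/sqrt(|l2 l3|)` measures deviation from a blob, and
#' `S = sqrt(l1^2+l2^2+l3^2)` separates structure from background noise.
#' The response is 0 wherever `l2 > 0` or `l3 > 0` (bright-plate polarity)
#' and lies in `[0, 1]`.
#'
#' @param eig a `hessian_eigen` object (or list with `l1`, `l2`, `l3`).
#' @param params a [planeness_params()] object.
#' @return numeric array of responses in `[0, 1]`.
#' @export
planeness_response <- function(eig, params = planeness_params()) {
  l1 <- eig$l1; l2 <- eig$l2; l3 <- eig$l3
  al <- params$alpha; be <- params$beta; ga <- params$gamma
  a1 <- abs(l1); a2 <- abs(l2); a3 <- abs(l3)
  P <- array(0, dim = dim(l1))
  ok <- !(l2 > 0 | l3 > 0) & a3 > 0 & is.finite(l1) & is.finite(l2) & is.finite(l3)
  ra <- a2[ok] / a3[ok]
  rb <- ifelse(a1[ok] == 0, 0, a1[ok] / sqrt(a2[ok] * a3[ok]))
  rb[!is.finite(rb)] <- 0  # l2 = 0 with l1 > 0 cannot occur under the ordering
  s <- sqrt(a1[ok]^2 + a2[ok]^2 + a3[ok]^2)
  P[ok] <- exp(-ra^2 / (2 * al^2)) * exp(-rb^2 / (2 * be^2)) *
    (1 - exp(-s^2 / (2 * ga^2)))
  P
}

#' Initial Purkinje-layer mask from strong planeness responses
#'
#' @param response planeness response array (computed within GM).
#' @param gm_mask logical GM mask.
#' @param threshold response threshold; `NULL` uses Otsu's threshold on the
#'   positive within-GM responses (deterministic, parameter-free).
#' @param review_mask optional mask of false-positive responses to subtract.
#' @return logical mask `M_P0`.
#' @export
initial_purkinje <- function(response, gm_mask, threshold = NULL,
                             review_mask = NULL) {
  pos <- response[gm_mask & response > 0]
  if (!length(pos)) stop("no positive planeness response within GM")
  if (is.null(threshold)) threshold <- .otsu(pos)
  if (threshold > max(pos))
    stop("response_threshold exceeds the maximum response (", signif(max(pos), 4),
         "); lower the threshold")
  m <- gm_mask & response >= threshold
  if (!is.null(review_mask)) m <- m & !review_mask
  if (!any(m)) stop("empty initial Purkinje mask; adjust the response threshold")
  attr(m, "threshold") <- threshold
  m
}

#' One-call planeness pass over a volume
#'
#' Convenience wrapper: scale smoothing, Hessian eigenvalues, filter
#' response restricted to GM.
#'
#' @inheritParams hessian_eigenvalues
#' @param gm_mask logical GM mask.
#' @param params a [planeness_params()].
#' @return list with `response` (array, 0 outside GM) and `eig`.
#' @export
purkinje_planeness <- function(volume, gm_mask, params = planeness_params()) {
  eig <- hessian_eigenvalues(volume, sigma_h = params$sigma_h,
                             pre_smooth_mm = params$s)
  resp <- planeness_response(eig, params)
  resp[!gm_mask] <- 0
  list(response = resp, eig = eig)
}
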