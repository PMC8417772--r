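#' Histogram landmarks at the standard percentiles
#'
#' Eleven intensity landmarks at the 1, 10, 20, ..., 90, 99 percentiles of
#' the within-mask intensity distribution.
#'
#' @param volume a [voxel_grid()] or numeric array.
#' @param mask logical array; landmarks are computed inside it.
#' @return numeric vector of 11 non-decreasing landmark intensities.
#' @export
intensity_landmarks <- function(volume, mask) {
  v <- if (inherits(volume, "voxel_grid")) volume$values else volume
  x <- v[mask]
  x <- x[is.finite(x)]
  if (!length(x)) stop("mask is empty")
  quantile(x, probs = c(1, seq(10, 90, 10), 99) / 100, names = FALSE, type = 7)
}

#' Piecewise-linear intensity standardization
#'
#' Maps the within-mask intensity distribution onto a reference by matching
#' 11 histogram landmarks (1st, 10th, ..., 90th, 99th percentiles) with
#' piecewise-linear interpolation, extended linearly beyond the outermost
#' landmarks. The mapping is monotone non-decreasing; voxels outside the
#' mask are passed through unchanged.
#'
#' @param volume a [voxel_grid()].
#' @param mask logical array, non-empty.
#' @param reference_landmarks 11 non-decreasing reference intensities.
#' @return a [voxel_grid()] with standardized intensities.
#' @export
normalize_intensity <- function(volume, mask, reference_landmarks) {
  stopifnot(inherits(volume, "voxel_grid"))
  if (length(reference_landmarks) != 11L)
    stop("`reference_landmarks` must have length 11")
  if (is.unsorted(reference_landmarks))
    stop("`reference_landmarks` must be non-decreasing")
  src <- intensity_landmarks(volume, mask)
  if (diff(range(src)) <= 0)
    stop("degenerate histogram inside mask: all voxel intensities are equal")
  # collapse coincident source landmarks so the map stays a function
  keep <- c(TRUE, diff(src) > 0)
  src_u <- src[keep]
  ref_u <- reference_landmarks[keep]
  map <- function(x) {
    y <- approx(src_u, ref_u, xout = x, rule = 2)$y
    ns <- length(src_u)
    lo <- x < src_u[1]
    hi <- x > src_u[ns]
    s_lo <- (ref_u[2] - ref_u[1]) / (src_u[2] - src_u[1])
    s_hi <- (ref_u[ns] - ref_u[ns - 1]) / (src_u[ns] - src_u[ns - 1])
    y[lo] <- ref_u[1] + s_lo * (x[lo] - src_u[1])
    y[hi] <- ref_u[ns] + s_hi * (x[hi] - src_u[ns])
    y
  }
  out <- volume$values
  out[mask] <- map(volume$values[mask])
  voxel_grid(out, spacing = volume$spacing, affine = volume$affine)
}

#' Gaussian mixture tissue model fitted by EM
#'
#' Fits a K-component univariate Gaussian mixture to within-mask intensities
#' by expectation-maximization, the model used for WM/GM tissue
#' classification (K = 4: one WM class and three GM classes reflecting the
#' laminar intensity contrast). Optional per-voxel spatial priors weight the
#' E-step responsibilities. The log-likelihood is asserted non-decreasing at
#' every iteration; collapsed components trigger seeded restarts with
#' perturbed means.
#'
#' @param volume a [voxel_grid()] or numeric array.
#' @param mask logical array with at least `10 * K` voxels.
#' @param K number of classes (default 4).
#' @param priors optional matrix (`sum(mask)` x K) of per-voxel class priors.
#' @param tol relative log-likelihood tolerance (default 1e-6).
#' @param max_iter maximum EM iterations (default 500).
#' @param seed seed for initialization restarts.
#' @param init_means optional starting means (length K).
#' @param max_restarts restarts allowed after component collapse.
#' @return object of class `gmm_model`: weights, means, variances (ordered by
#'   mean), `responsibilities`, hard `classification` (argmax posterior, as
#'   an integer array with 0 outside the mask), `loglik` trace.
#' @export
fit_gmm <- function(volume, mask, K = 4L, priors = NULL, tol = 1e-6,
                    max_iter = 500L, seed = NULL, init_means = NULL,
                    max_restarts = 5L) {
  v <- if (inherits(volume, "voxel_grid")) volume$values else volume
  x <- v[mask]
  keep <- is.finite(x)
  x <- x[keep]
  nv <- length(x)
  if (nv < 10L * K) stop("mask must contain at least 10*K usable voxels")
  if (!is.null(priors)) {
    priors <- as.matrix(priors)
    if (nrow(priors) != sum(mask) || ncol(priors) != K)
      stop("`priors` must be a (sum(mask) x K) matrix")
    priors <- priors[keep, , drop = FALSE]
    priors <- priors / pmax(rowSums(priors), 1e-300)
  }
  if (!is.null(seed)) set.seed(seed)
  rng_x <- diff(range(x))
  if (rng_x <= 0) stop("degenerate intensities inside mask")

  init <- function(perturb = 0) {
    mu <- if (!is.null(init_means)) as.numeric(init_means) else
      quantile(x, probs = (2 * seq_len(K) - 1) / (2 * K), names = FALSE)
    if (perturb > 0) mu <- mu + rnorm(K, 0, perturb * rng_x)
    list(w = rep(1 / K, K), mu = sort(mu), s2 = rep((rng_x / (2 * K))^2, K))
  }

  run_em <- function(par) {
    ll_trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      # E-step (log domain)
      lg <- vapply(seq_len(K), function(k) {
        dnorm(x, par$mu[k], sqrt(par$s2[k]), log = TRUE) + log(par$w[k]) +
          if (!is.null(priors)) log(pmax(priors[, k], 1e-300)) else 0
      }, numeric(nv))
      m <- apply(lg, 1L, max)
      p <- exp(lg - m)
      rs <- rowSums(p)
      ll <- sum(m + log(rs))
      p <- p / rs
      ll_trace <- c(ll_trace, ll)
      # M-step
      nk <- colSums(p)
      if (any(nk < 1e-8)) return(list(collapsed = TRUE))
      par$w <- nk / nv
      par$mu <- colSums(p * x) / nk
      par$s2 <- colSums(p * (outer(x, par$mu, "-")^2)) / nk
      if (any(par$s2 < (1e-6 * rng_x)^2)) return(list(collapsed = TRUE))
      if (it > 1L) {
        rel <- abs(ll_trace[it] - ll_trace[it - 1L]) /
          (abs(ll_trace[it - 1L]) + 1e-300)
        if (rel < tol) break
      }
    }
    list(collapsed = FALSE, par = par, resp = p, loglik = ll_trace)
  }

  fit <- NULL
  for (att in 0:max_restarts) {
    fit <- run_em(init(perturb = if (att > 0) 0.05 * att else 0))
    if (!fit$collapsed) break
  }
  if (fit$collapsed)
    stop("GMM component collapsed after ", max_restarts, " restarts")

  ord <- order(fit$par$mu)
  resp <- fit$resp[, ord, drop = FALSE]
  cls <- max.col(resp, ties.method = "first")
  classification <- array(0L, dim = dim(mask))
  idx <- which(mask)[keep]
  classification[idx] <- cls

  structure(list(
    K = K,
    weights = fit$par$w[ord],
    means = fit$par$mu[ord],
    variances = fit$par$s2[ord],
    responsibilities = resp,
    classification = classification,
    loglik = fit$loglik,
    n = nv,
    converged = length(fit$loglik) < max_iter
  ), class = "gmm_model")
}

#' @export
print.gmm_model <- function(x, ...) {
  cat(sprintf("<gmm_model> K = %d, n = %d, logLik = %.2f (%d iterations)\n",
              x$K, x$n, tail(x$loglik, 1), length(x$loglik)))
  print(tidy(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gmm_model <- function(x, ...) {
  tibble::tibble(component = seq_len(x$K), weight = x$weights,
                 mean = x$means, variance = x$variances)
}

#' @exportS3Method generics::glance
glance.gmm_model <- function(x, ...) {
  tibble::tibble(K = x$K, n = x$n, logLik = tail(x$loglik, 1),
                 iterations = length(x$loglik), converged = x$converged)
}

#' Clean the WM segmentation
#'
#' Removes voxels flagged by the planeness filter (Purkinje-layer voxels are
#' often misclassified as WM because of their similar intensity) and keeps
#' the largest 26-connected component. The GM segmentation is the cerebellar
#' mask minus the cleaned WM.
#'
#' @param wm_candidate logical array, non-empty.
#' @param cerebellar_mask logical array containing the full cerebellum.
#' The planeness response also fires along the WM/GM interface (the WM body
#' itself presents a locally bright sheet before the cortex is known), so
#' plane-positive voxels still connected to the surviving WM core are
#' reclaimed by a short geodesic dilation within the candidate: a detached
#' lamina sheet stays out, the WM boundary shell comes back.
#'
#' @param planeness_positive optional logical array of planeness-positive
#'   voxels to subtract (a manual review mask may be supplied instead).
#' @param connectivity component connectivity (default 26).
#' @param reclaim_iters dilation steps used to reclaim core-connected
#'   plane-positive voxels (default 2; 0 disables).
#' @return list with `wm` and `gm` masks.
#' @export
clean_wm <- function(wm_candidate, cerebellar_mask,
                     planeness_positive = NULL, connectivity = 26L,
                     reclaim_iters = 2L) {
  if (!any(wm_candidate)) stop("`wm_candidate` is empty")
  cand <- wm_candidate
  if (!is.null(planeness_positive)) cand <- cand & !planeness_positive
  if (!any(cand)) stop("WM candidate empty after removing planeness-positive voxels")
  lc <- .largest_component(cand, connectivity)
  if (lc$tie)
    message("clean_wm: equal-size components; kept the lexicographically first seed voxel's component")
  wm <- lc$mask
  if (!is.null(planeness_positive) && reclaim_iters > 0L) {
    for (it in seq_len(reclaim_iters)) {
      grown <- if (connectivity == 26L) {
        m <- wm
        for (ax in 1:3)
          m <- m | .shift1(m + 0, ax, 1, 0) > 0 | .shift1(m + 0, ax, -1, 0) > 0
        m
      } else .dilate6(wm)
      wm <- wm | (grown & wm_candidate)
    }
  }
  list(wm = wm, gm = cerebellar_mask & !wm)
}
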