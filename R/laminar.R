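#' Solve the Laplace equation over the cortical domain
#'
#' Jacobi iteration of the discrete Laplacian with Dirichlet conditions:
#' potential `psi = 1` on the inner (WM/GM) boundary and `psi = 0` on the
#' outer (pial) boundary. Boundary voxels lie outside the domain; their
#' condition is taken to hold at a configurable distance along the
#' connecting axis — 0.5 (the shared voxel face) for tissue boundaries,
#' 1.0 (the voxel centre) for in-cortex sheets such as extracted fissures or
#' the Purkinje lamina. The normalized gradient field F (pointing toward the
#' inner boundary, where the potential rises to 1) and its divergence are
#' computed by central differences.
#'
#' Domain voxels not connected to both boundaries are excluded and reported.
#'
#' @param gm_domain logical solution domain.
#' @param inner_boundary,outer_boundary logical boundary masks (non-empty,
#'   outside the domain; overlaps with the domain are stripped).
#' @param spacing voxel spacing (mm).
#' @param tol Jacobi stopping tolerance on the maximum update (default 1e-6).
#' @param max_iter iteration cap.
#' @param inner_dist,outer_dist boundary distance factors (x spacing); a
#'   scalar, or an array read at the boundary voxels.
#' @return object of class `laplace_field`: `psi` (array; exact values on
#'   boundary voxels), `fvec` (unit gradient field, list x/y/z), `div`,
#'   `domain`, `inner`, `outer`, `spacing`, `iterations`, `update_history`,
#'   `excluded` (voxel indices dropped for lacking a boundary connection).
#' @export
solve_laplace <- function(gm_domain, inner_boundary, outer_boundary, spacing,
                          tol = 1e-6, max_iter = 20000L,
                          inner_dist = 0.5, outer_dist = 0.5) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  inner <- inner_boundary & !gm_domain
  outer <- outer_boundary & !gm_domain
  if (!any(inner)) stop("empty inner boundary")
  if (!any(outer)) stop("empty outer boundary")
  if (any(inner & outer)) stop("inner and outer boundaries overlap")

  # connectivity audit: every domain component must touch both boundaries
  lab <- label_components(gm_domain, 26L)
  ncomp <- max(lab)
  excluded <- integer(0)
  domain <- gm_domain
  if (ncomp > 1L || TRUE) {
    touch_in <- unique(lab[.dilate6(inner) & gm_domain])
    touch_out <- unique(lab[.dilate6(outer) & gm_domain])
    ok_comp <- intersect(touch_in, touch_out)
    bad <- setdiff(seq_len(ncomp), ok_comp)
    if (length(bad)) {
      excluded <- which(lab %in% bad)
      domain[excluded] <- FALSE
      warning(length(excluded),
              " domain voxel(s) not connected to both boundaries were excluded")
    }
  }
  if (!any(domain)) stop("no domain voxels connected to both boundaries")

  bc <- array(NA_real_, dim = dim(domain))
  bc[inner] <- 1
  bc[outer] <- 0
  bdist <- array(0.5, dim = dim(domain))
  bdist[inner] <- if (length(inner_dist) > 1L) inner_dist[inner] else inner_dist
  bdist[outer] <- if (length(outer_dist) > 1L) outer_dist[outer] else outer_dist

  sol <- cpp_jacobi_laplace(as.logical(domain), as.double(bc), as.double(bdist),
                            .as_dim(domain), as.double(spacing),
                            tol, as.integer(max_iter))
  psi <- array(sol$psi, dim = dim(domain))
  g <- .gradient3(psi, spacing)
  f <- .normalize_field(g)
  dv <- .divergence3(f, spacing)

  structure(list(psi = psi, fvec = f[c("x", "y", "z")], div = dv,
                 domain = domain, inner = inner, outer = outer,
                 spacing = spacing, iterations = sol$iterations,
                 max_update = sol$max_update,
                 update_history = sol$update_history,
                 excluded = excluded),
            class = "laplace_field")
}

#' @export
print.laplace_field <- function(x, ...) {
  cat(sprintf("<laplace_field> %d domain voxels, %d Jacobi iterations (max update %.2e)\n",
              sum(x$domain), x$iterations, x$max_update))
  invisible(x)
}

#' Equivolume laminar depth ratio
#'
#' From every cortical voxel, the streamline of the normalized Laplace
#' gradient field is traced both ways with fixed step `dl`. A unit surface
#' element is evolved multiplicatively along the trace,
#' `ds[n+1] = ds[n] (1 + dl * div F)`, and the upwind volume toward the pial
#' surface (`V_pial`) and downwind volume toward WM (`V_WM`) are accumulated
#' as `sum(ds * dl)`. The equivolume ratio is
#' `R_vol = V_pial / (V_pial + V_WM)`: 0 at the pial surface, 1 at WM, and
#' equal to the volumetric (not Euclidean) depth fraction, which shifts
#' iso-depth surfaces toward the lower-curvature side of a fold.
#'
#' @param field a `laplace_field`.
#' @param dl streamline step in mm; default a quarter of the smallest
#'   spacing (must not exceed half the smallest spacing).
#' @param max_steps trace step cap; default 10x the domain diagonal / dl.
#' @return object of class `equivolume_map`: `r_vol`, `v_pial`, `v_wm`
#'   arrays, `flagged` (voxels whose trace hit the cap; imputed from the
#'   nearest valid neighbours), `dl`.
#' @export
equivolume_ratio <- function(field, dl = NULL, max_steps = NULL) {
  stopifnot(inherits(field, "laplace_field"))
  sp <- field$spacing
  if (is.null(dl)) dl <- 0.25 * min(sp)
  if (dl > 0.5 * min(sp)) stop("`dl` must not exceed half the minimal spacing")
  if (is.null(max_steps)) {
    diag_mm <- sqrt(sum((dim(field$psi) * sp)^2))
    max_steps <- as.integer(ceiling(10 * diag_mm / dl))
  }
  fx <- field$fvec$x; fy <- field$fvec$y; fz <- field$fvec$z
  dv <- field$div
  fx[is.na(fx)] <- 0; fy[is.na(fy)] <- 0; fz[is.na(fz)] <- 0
  dv[is.na(dv)] <- 0
  tr <- cpp_trace_ratio(as.double(fx), as.double(fy), as.double(fz),
                        as.double(dv), as.logical(field$domain),
                        .as_dim(field$domain), as.double(sp), dl,
                        as.integer(max_steps))
  d <- dim(field$psi)
  v_wm <- array(tr$v_wm, d); v_pial <- array(tr$v_pial, d)
  ok <- array(tr$ok, d)
  r <- v_pial / (v_pial + v_wm)
  flagged <- field$domain & !ok
  if (any(flagged)) {
    message("equivolume_ratio: ", sum(flagged),
            " trace(s) hit the step cap; imputing from neighbours")
    r[flagged] <- NA_real_
    # iterative nearest-neighbour fill within the domain
    for (it in 1:100) {
      nas <- field$domain & is.na(r)
      if (!any(nas)) break
      acc <- array(0, d); cnt <- array(0, d)
      for (ax in 1:3) for (s in c(-1, 1)) {
        sh <- .shift1(r, ax, s)
        okn <- !is.na(sh)
        acc[okn] <- acc[okn] + sh[okn]
        cnt <- cnt + okn
      }
      fill <- nas & cnt > 0
      r[fill] <- acc[fill] / cnt[fill]
    }
  }
  structure(list(r_vol = r, v_pial = v_pial, v_wm = v_wm,
                 flagged = flagged, dl = dl, spacing = sp,
                 domain = field$domain),
            class = "equivolume_map")
}
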