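#' Extrapolate the full Purkinje layer from its initial estimate
#'
#' High-curvature stretches of the lamina escape the planeness filter; they
#' are recovered from the laminar model. The equivolume depth observed at
#' the initial Purkinje voxels (`R_P = R_vol` on `M_P0`) is propagated over
#' the cortex by multi-level masked Gaussian smoothing (only voxels already
#' carrying a value contribute), giving the extrapolated Purkinje depth
#' `R_P^S`. The mismatch map `lambda = |R_vol - R_P^S|` vanishes where a
#' voxel sits at the extrapolated Purkinje depth; directional local minima
#' of `lambda` along the streamline direction with `lambda` below a
#' closeness tolerance are added: `M_PF = M_P0 | marked`.
#'
#' @param m_p0 logical initial Purkinje mask (non-empty).
#' @param equiv an `equivolume_map`.
#' @param field the `laplace_field` the map was traced on.
#' @param levels Gaussian propagation levels (default 10).
#' @param sigma per-level sigma in voxels (default 1).
#' @param closeness_tol mismatch tolerance in ratio units (default 0.05).
#' @return logical mask `M_PF` with attributes `lambda_map` and `r_ps`.
#' @export
extrapolate_purkinje <- function(m_p0, equiv, field, levels = 10L, sigma = 1,
                                 closeness_tol = 0.05) {
  if (!any(m_p0)) stop("`m_p0` is empty")
  stopifnot(inherits(equiv, "equivolume_map"), inherits(field, "laplace_field"))
  gm <- equiv$domain
  r_vol <- equiv$r_vol

  vals <- array(0, dim = dim(gm))
  vals[m_p0] <- r_vol[m_p0]
  w <- array(as.double(m_p0), dim = dim(gm))
  filled <- m_p0
  for (lev in seq_len(levels)) {
    num <- .gauss_smooth(vals * w, sigma)
    den <- .gauss_smooth(w, sigma)
    upd <- gm & !m_p0 & den > 1e-8
    vals[upd] <- num[upd] / den[upd]
    filled <- filled | upd
    w <- array(as.double(filled), dim = dim(gm))
    vals[m_p0] <- r_vol[m_p0]   # observed depths stay fixed
  }
  if (sum(filled & gm) < 0.5 * sum(gm))
    stop("Purkinje depth extrapolation covered < 50% of GM; increase `levels`")
  r_ps <- vals
  r_ps[!filled] <- NA_real_

  lambda <- abs(r_vol - r_ps)
  marked <- .directional_extrema(lambda, field$fvec,
                                 gm & filled & is.finite(lambda),
                                 field$spacing, mode = "min")
  marked <- marked & lambda < closeness_tol
  if (any(marked)) {
    # geodesic erosion of the marked set: keeps a one-voxel sheet at the
    # smallest mismatch, removing the straddling duplicates the +-1-voxel
    # trilinear comparison admits
    ord <- -lambda
    ord[!is.finite(ord)] <- 0
    marked <- array(cpp_thin_sheet(as.logical(marked), as.double(ord),
                                   .as_dim(marked)), dim = dim(marked))
  }
  m_pf <- (m_p0 | marked) & gm
  attr(m_pf, "lambda_map") <- lambda
  attr(m_pf, "r_ps") <- r_ps
  m_pf
}

#' Segment the granular and molecular layers
#'
#' With the Purkinje sheet `M_PF` separating the cortex, the internal
#' granular layer is the WM side and the molecular layer the pial side of
#' the remaining cortical domain. Segmentation is by geodesic side-labelling:
#' connected components of `GM \ M_PF` are assigned to the boundary they
#' touch; components reachable from both boundaries (holes in the sheet) are
#' leaks — their voxels are split by unit-speed geodesic distance to the two
#' boundaries and reported.
#'
#' @param gm_domain logical cortical domain (fissure/resistant voxels, which
#'   act as pial boundary, already removed).
#' @param wm_mask logical WM mask.
#' @param pial_mask logical pial boundary mask (cerebellar mask boundary
#'   united with extracted fissures).
#' @param m_pf logical final Purkinje mask.
#' @param spacing voxel spacing.
#' @return list with `granular`, `molecular` masks, `purkinje` (= `m_pf`),
#'   and `leaks`, a tibble of leaked voxel indices (empty when the sheet
#'   separates cleanly). The three masks partition `gm_domain` exactly.
#' @export
segment_layers <- function(gm_domain, wm_mask, pial_mask, m_pf, spacing) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (!any(m_pf)) stop("`m_pf` is empty")
  rest <- gm_domain & !m_pf
  lab <- label_components(rest, 6L)
  ncomp <- max(lab)
  touch_wm <- unique(lab[.dilate6(wm_mask) & rest])
  touch_pial <- unique(lab[.dilate6(pial_mask) & rest])
  touch_wm <- setdiff(touch_wm, 0L)
  touch_pial <- setdiff(touch_pial, 0L)

  gran <- array(FALSE, dim = dim(rest))
  mol <- array(FALSE, dim = dim(rest))
  leak_comp <- intersect(touch_wm, touch_pial)
  only_wm <- setdiff(touch_wm, leak_comp)
  only_pial <- setdiff(touch_pial, leak_comp)
  neither <- setdiff(seq_len(ncomp), union(touch_wm, touch_pial))
  gran[lab %in% only_wm] <- TRUE
  mol[lab %in% only_pial] <- TRUE

  leaks <- tibble::tibble(voxel = integer(0), component = integer(0))
  amb <- lab %in% c(leak_comp, neither) & rest
  if (any(amb)) {
    ones <- array(1, dim = dim(rest))
    d_wm <- solve_eikonal(ones, seeds = .adjacent_to(wm_mask, rest) | wm_mask,
                          domain = rest | wm_mask, spacing = spacing)$d
    d_pial <- solve_eikonal(ones, seeds = .adjacent_to(pial_mask, rest) | pial_mask,
                            domain = rest | pial_mask, spacing = spacing)$d
    to_gran <- amb & (ifelse(is.finite(d_wm), d_wm, Inf) <=
                        ifelse(is.finite(d_pial), d_pial, Inf))
    gran[to_gran] <- TRUE
    mol[amb & !to_gran] <- TRUE
    if (length(leak_comp)) {
      w <- which(lab %in% leak_comp & rest)
      leaks <- tibble::tibble(voxel = w, component = lab[w])
      warning("Purkinje sheet does not fully separate the cortex: ",
              length(w), " voxel(s) in ", length(leak_comp),
              " leaking component(s); split by geodesic distance")
    }
  }
  list(granular = gran, molecular = mol, purkinje = m_pf & gm_domain,
       leaks = leaks)
}
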