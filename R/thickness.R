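#' Eulerian PDE cortical thickness
#'
#' Thickness as the length of the streamlines of the Laplace field
#' connecting the two boundaries, computed without explicit tracing by
#' first-order upwind iteration of the transport equations
#' `grad(L0) . F = 1` (`L0 = 0` on the inner boundary) and
#' `-grad(L1) . F = 1` (`L1 = 0` on the outer boundary); `T = L0 + L1` in
#' mm. Boundary conditions follow the same face/centre distance convention
#' as [solve_laplace()].
#'
#' @param domain logical solution domain.
#' @param inner,outer logical boundary masks (outside the domain).
#' @param field a `laplace_field` solved on this domain with these
#'   boundaries (its unit gradient points toward the inner boundary).
#' @param tol stopping tolerance in mm (default 1e-4).
#' @param max_iter sweep cap.
#' @param inner_dist,outer_dist boundary distance factors (x spacing).
#' @return object of class `thickness_map`: arrays `l0`, `l1`, `t` (mm; NA
#'   outside the domain or where the field feeds no information).
#' @export
eulerian_thickness <- function(domain, inner, outer, field, tol = 1e-4,
                               max_iter = 2000L, inner_dist = 0.5,
                               outer_dist = 0.5) {
  stopifnot(inherits(field, "laplace_field"))
  sp <- field$spacing
  d <- dim(domain)
  fx <- field$fvec$x; fy <- field$fvec$y; fz <- field$fvec$z
  fx[is.na(fx)] <- 0; fy[is.na(fy)] <- 0; fz[is.na(fz)] <- 0
  inner <- inner & !domain
  outer <- outer & !domain
  bdist_in <- if (length(inner_dist) > 1L) inner_dist else array(inner_dist, dim = d)
  bdist_out <- if (length(outer_dist) > 1L) outer_dist else array(outer_dist, dim = d)

  # L0 grows away from the inner boundary, i.e. along -F
  s0 <- cpp_upwind_arclength(as.double(-fx), as.double(-fy), as.double(-fz),
                             as.logical(domain), as.logical(inner),
                             as.double(bdist_in), .as_dim(domain),
                             as.double(sp), tol, as.integer(max_iter))
  # L1 grows away from the outer boundary, along +F
  s1 <- cpp_upwind_arclength(as.double(fx), as.double(fy), as.double(fz),
                             as.logical(domain), as.logical(outer),
                             as.double(bdist_out), .as_dim(domain),
                             as.double(sp), tol, as.integer(max_iter))
  if (s0$max_update >= tol || s1$max_update >= tol)
    stop(sprintf(paste0("Eulerian thickness did not converge within %d sweeps ",
                        "(residuals %.3g / %.3g mm)"),
                 max_iter, s0$max_update, s1$max_update))
  l0 <- array(s0$L, d); l1 <- array(s1$L, d)
  structure(list(l0 = l0, l1 = l1, t = l0 + l1, domain = domain,
                 spacing = sp, unreached = s0$unreached + s1$unreached),
            class = "thickness_map")
}

#' Layer thicknesses sampled at the Purkinje vertices
#'
#' Computes three thickness maps — full cortex (`T_GM`, WM to pial over all
#' of GM), granular (`T_Gran`, WM to the Purkinje sheet over `M_G`) and
#' molecular (`T_Mol`, Purkinje sheet to pial over `M_M`) — and samples each
#' at the Purkinje voxels ("vertices"). The Purkinje voxels belong to
#' neither layer, so `T_Gran + T_Mol` falls short of `T_GM` by about the
#' one-voxel lamina thickness. Layer maps are sampled at each vertex by
#' trilinear interpolation at the vertex centre (falling back to the mean of
#' valid 26-neighbours at sheet-adjacent gaps).
#'
#' @param gm,wm,pial logical masks (cortical domain, WM, pial boundary).
#' @param m_pf logical final Purkinje mask (non-empty).
#' @param layers list with `granular` and `molecular` masks, e.g. from
#'   [segment_layers()].
#' @param spacing voxel spacing (mm).
#' @param fissure optional fissure mask: pial-boundary voxels that are
#'   in-cortex sheets get a centre (1.0) rather than face (0.5) boundary
#'   offset.
#' @param laplace_tol,thickness_tol solver tolerances.
#' @return list with `vertices` (tibble: voxel index, i/j/k, t_full, t_gran,
#'   t_mol) and the three `thickness_map`s plus the per-layer Laplace
#'   fields.
#' @export
layer_thicknesses <- function(gm, wm, pial, m_pf, layers, spacing,
                              fissure = NULL, laplace_tol = 1e-6,
                              thickness_tol = 1e-4) {
  if (!any(m_pf)) stop("`m_pf` is empty")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  gran <- layers$granular
  mol <- layers$molecular

  # full cortex: the lamina stays in the domain and its arclength counts;
  # fissure voxels are in-cortex sheets, so their condition sits at the centre
  outer_d <- array(0.5, dim = dim(gm))
  if (!is.null(fissure)) outer_d[fissure] <- 1.0
  fld_full <- solve_laplace(gm, wm, pial, spacing, tol = laplace_tol,
                            outer_dist = outer_d)
  tm_full <- eulerian_thickness(gm, wm, pial, fld_full, tol = thickness_tol,
                                outer_dist = outer_d)

  zero_map <- function(dom) {
    z <- array(NA_real_, dim = dim(dom))
    z[dom] <- 0
    structure(list(l0 = z, l1 = z, t = z, domain = dom, spacing = spacing,
                   unreached = 0L), class = "thickness_map")
  }

  # granular: WM (face) to the Purkinje sheet (centre)
  if (any(gran)) {
    fld_gran <- solve_laplace(gran, wm, m_pf, spacing, tol = laplace_tol,
                              outer_dist = 1.0)
    tm_gran <- eulerian_thickness(gran, wm, m_pf, fld_gran, tol = thickness_tol,
                                  outer_dist = 1.0)
  } else {
    message("layer_thicknesses: empty granular layer; thickness 0")
    fld_gran <- NULL
    tm_gran <- zero_map(gran)
  }

  # molecular: Purkinje sheet (centre) to pial (face)
  if (any(mol)) {
    fld_mol <- solve_laplace(mol, m_pf, pial, spacing, tol = laplace_tol,
                             inner_dist = 1.0, outer_dist = outer_d)
    tm_mol <- eulerian_thickness(mol, m_pf, pial, fld_mol, tol = thickness_tol,
                                 inner_dist = 1.0, outer_dist = outer_d)
  } else {
    message("layer_thicknesses: empty molecular layer; thickness 0")
    fld_mol <- NULL
    tm_mol <- zero_map(mol)
  }

  verts <- .which_vox(m_pf)
  sample_layer <- function(tm, dom) {
    if (!any(dom)) return(rep(0, nrow(verts)))  # vanished layer
    v <- .trilinear(tm$t, dom & !is.na(tm$t), verts)
    miss <- which(is.na(v))
    if (length(miss)) {
      # mean over valid 26-neighbours
      tvals <- tm$t
      for (q in miss) {
        i <- verts[q, 1] + 1L; j <- verts[q, 2] + 1L; k <- verts[q, 3] + 1L
        d <- dim(tvals)
        ii <- max(1L, i - 1L):min(d[1], i + 1L)
        jj <- max(1L, j - 1L):min(d[2], j + 1L)
        kk <- max(1L, k - 1L):min(d[3], k + 1L)
        nb <- tvals[ii, jj, kk][dom[ii, jj, kk]]
        nb <- nb[is.finite(nb)]
        if (length(nb)) v[q] <- mean(nb)
      }
    }
    v
  }
  w <- which(m_pf)
  vertices <- tibble::tibble(
    vertex = w,
    i = verts[, 1], j = verts[, 2], k = verts[, 3],
    t_full = sample_layer(tm_full, gm),
    t_gran = sample_layer(tm_gran, gran),
    t_mol = sample_layer(tm_mol, mol))
  list(vertices = vertices, full = tm_full, granular = tm_gran,
       molecular = tm_mol,
       fields = list(full = fld_full, granular = fld_gran, molecular = fld_mol))
}
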