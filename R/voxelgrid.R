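#' 3-D scalar voxel grid
#'
#' The basic volumetric container: a 3-D numeric array with voxel spacing in
#' mm and a voxel-to-world affine. Voxel indices are 0-based and
#' voxel-centred; all PDEs are solved in world (mm) units using the spacing.
#'
#' @param values numeric 3-D array (at least 3 voxels per axis).
#' @param spacing numeric length-3, mm per axis, all positive and finite. A
#'   single value is recycled (isotropic grid).
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   scaling by `spacing`.
#' @return an object of class `voxel_grid` with elements `values`, `spacing`,
#'   `affine`.
#' @export
voxel_grid <- function(values, spacing, affine = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array")
  if (any(dim(values) < 3L))
    stop("voxel grid must have at least 3 voxels per axis")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive finite values (mm)")
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  structure(list(values = values, spacing = spacing, affine = affine),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s voxels, spacing %s mm\n",
              paste(dim(x$values), collapse = " x "),
              paste(signif(x$spacing, 4), collapse = " x ")))
  v <- x$values[is.finite(x$values)]
  if (length(v))
    cat(sprintf("  finite values: range [%.4g, %.4g]\n", min(v), max(v)))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$values)

#' Read a NIfTI-1 volume
#'
#' @param path path to a readable NIfTI-1 file.
#' @return a [voxel_grid()]; data are cast to double and spacing/affine are
#'   taken from the header.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("expected a 3-D image, got ", length(d), " dimensions: ", path)
  sp <- RNifti::pixdim(img)[seq_len(3L)]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("non-positive voxel spacing in header: ", path)
  aff <- tryCatch(unclass(RNifti::xform(img)), error = function(e) NULL)
  voxel_grid(array(as.double(img), dim = d), spacing = sp, affine = aff)
}

#' Write a volume, mask, or label map as NIfTI-1
#'
#' Masks are stored as unsigned 8-bit, label maps as unsigned 16-bit, scalar
#' volumes as 32-bit float.
#'
#' @param x a [voxel_grid()], a logical 3-D array (mask) or an integer 3-D
#'   array (labels).
#' @param path output file path (`.nii` or `.nii.gz`).
#' @param spacing spacing, required when `x` is a bare array.
#' @param datatype override the on-disk datatype (RNifti datatype string).
#' @export
write_volume <- function(x, path, spacing = NULL, datatype = NULL) {
  if (inherits(x, "voxel_grid")) {
    arr <- x$values
    spacing <- x$spacing
    if (is.null(datatype)) datatype <- "float"
  } else {
    if (is.null(spacing)) stop("`spacing` is required when writing a bare array")
    arr <- x
    if (is.null(datatype))
      datatype <- if (is.logical(arr)) "uint8" else if (is.integer(arr)) "uint16" else "float"
    if (is.logical(arr)) arr <- array(as.integer(arr), dim = dim(arr))
    if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read an integer lobule label map
#'
#' @param path NIfTI path.
#' @param codebook a codebook tibble (see [cerebellum_codebook()]); every
#'   nonzero id in the image must appear in it.
#' @return list with `labels` (integer array), `spacing`, `codebook`.
#' @export
read_labels <- function(path, codebook = cerebellum_codebook()) {
  g <- read_volume(path)
  lab <- array(as.integer(round(g$values)), dim = dim(g$values))
  ids <- sort(unique(lab[lab != 0L]))
  missing <- setdiff(ids, codebook$id)
  if (length(missing))
    stop("label ids not present in codebook: ", paste(missing, collapse = ", "))
  structure(list(labels = lab, spacing = g$spacing, codebook = codebook),
            class = "label_map")
}

# ---- internal array helpers ------------------------------------------------

.as_dim <- function(mask) as.integer(dim(mask))

# shift an array by one voxel along `axis` (+1 or -1), padding with `fill`
.shift1 <- function(a, axis, step, fill = NA_real_) {
  d <- dim(a)
  out <- array(fill, dim = d)
  idx_src <- idx_dst <- lapply(d, seq_len)
  if (step > 0) {
    idx_dst[[axis]] <- 2:d[axis]
    idx_src[[axis]] <- 1:(d[axis] - 1L)
  } else {
    idx_dst[[axis]] <- 1:(d[axis] - 1L)
    idx_src[[axis]] <- 2:d[axis]
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# central differences in world units; one-sided where only one neighbour is
# finite, NA where neither is
.gradient3 <- function(a, spacing) {
  out <- vector("list", 3L)
  for (ax in 1:3) {
    h <- spacing[ax]
    vp <- .shift1(a, ax, -1)  # value at i+1 brought to i
    vm <- .shift1(a, ax, +1)  # value at i-1 brought to i
    g <- (vp - vm) / (2 * h)
    one_p <- is.na(vm) & !is.na(vp) & !is.na(a)
    one_m <- is.na(vp) & !is.na(vm) & !is.na(a)
    g[one_p] <- (vp[one_p] - a[one_p]) / h
    g[one_m] <- (a[one_m] - vm[one_m]) / h
    out[[ax]] <- g
  }
  names(out) <- c("x", "y", "z")
  out
}

.normalize_field <- function(g) {
  nrm <- sqrt(g$x^2 + g$y^2 + g$z^2)
  nrm[nrm < 1e-12] <- NA_real_
  list(x = g$x / nrm, y = g$y / nrm, z = g$z / nrm, norm = nrm)
}

.divergence3 <- function(f, spacing) {
  d <- .gradient3(f$x, spacing)[["x"]]
  d <- d + .gradient3(f$y, spacing)[["y"]]
  d + .gradient3(f$z, spacing)[["z"]]
}

# 6-neighbourhood dilation of a logical mask
.dilate6 <- function(mask) {
  out <- mask
  for (ax in 1:3) for (s in c(-1, 1)) {
    sh <- .shift1(mask + 0, ax, s, fill = 0)
    out <- out | (sh > 0)
  }
  out
}

# voxels outside `mask` that are 6-adjacent to it
.outer_boundary <- function(mask) .dilate6(mask) & !mask

# voxels of `a` that are 6-adjacent to `b`
.adjacent_to <- function(a, b) a & .dilate6(b)

#' Connected components of a binary mask
#'
#' @param mask logical 3-D array.
#' @param connectivity 6 or 26.
#' @return integer array of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(connectivity %in% c(6L, 26L))
  array(cpp_label_components(as.logical(mask), .as_dim(mask), as.integer(connectivity)),
        dim = dim(mask))
}

# largest component with a deterministic lexicographic tie-break;
# returns list(mask, tie)
.largest_component <- function(mask, connectivity = 26L) {
  lab <- label_components(mask, connectivity)
  if (!any(lab > 0L)) stop("empty mask: no connected components")
  sizes <- tabulate(lab[lab > 0L])
  best <- max(sizes)
  cand <- which(sizes == best)
  tie <- length(cand) > 1L
  if (tie) {
    # tie-break: component containing the lowest linear-index (lexicographic
    # in 0-based i,j,k order) voxel among the tied components
    firsts <- vapply(cand, function(cc) min(which(lab == cc)), integer(1))
    cand <- cand[which.min(firsts)]
  }
  list(mask = lab == cand[1L], tie = tie)
}

# Gaussian smoothing, sigma given in voxels per axis (scalar recycled);
# renormalized against the smoothed indicator so the grid edge behaves like
# replicated data (a constant image stays exactly constant)
.gauss_smooth <- function(a, sigma_vox) {
  if (length(sigma_vox) == 1L) sigma_vox <- rep(sigma_vox, 3L)
  num <- cpp_gauss3(as.double(a), .as_dim(a), as.double(sigma_vox))
  den <- cpp_gauss3(rep(1.0, length(a)), .as_dim(a), as.double(sigma_vox))
  array(num / den, dim = dim(a))
}

# raw zero-padded smoothing, for masked normalized convolution where the
# indicator itself carries the normalization
.gauss_smooth_raw <- function(a, sigma_vox) {
  if (length(sigma_vox) == 1L) sigma_vox <- rep(sigma_vox, 3L)
  array(cpp_gauss3(as.double(a), .as_dim(a), as.double(sigma_vox)), dim = dim(a))
}

# masked normalized smoothing: values outside `mask` do not contribute
.gauss_smooth_masked <- function(a, mask, sigma_vox) {
  w <- array(as.double(mask), dim = dim(a))
  v <- a * w
  num <- .gauss_smooth_raw(v, sigma_vox)
  den <- .gauss_smooth_raw(w, sigma_vox)
  out <- num / pmax(den, 1e-12)
  out[den < 1e-8] <- NA_real_
  out
}

# masked trilinear sampling at continuous 0-based voxel coordinates
.trilinear <- function(a, valid, pts, min_weight = 0.5) {
  a[is.na(a)] <- 0  # excluded through `valid`
  cpp_trilinear(as.double(a), as.logical(valid), .as_dim(valid),
                as.double(pts[, 1]), as.double(pts[, 2]), as.double(pts[, 3]),
                min_weight)
}

# Otsu's threshold on a numeric vector (deterministic, parameter-free)
.otsu <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  if (!length(x)) stop("no finite values for threshold selection")
  r <- range(x)
  if (diff(r) <= 0) return(r[1])
  br <- seq(r[1], r[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[length(mu0)]
  between <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

# voxel-centre coordinates (0-based i,j,k) of TRUE voxels
.which_vox <- function(mask) {
  w <- which(mask)
  d <- dim(mask)
  i <- (w - 1L) %% d[1]
  j <- ((w - 1L) %/% d[1]) %% d[2]
  k <- (w - 1L) %/% (d[1] * d[2])
  cbind(i = i, j = j, k = k)
}

# directional extrema along a unit vector field: compare each voxel's value
# with trilinear samples one voxel-length ahead and behind along the field;
# ties kept. Both samples must be valid.
.directional_extrema <- function(vals, field, valid, spacing,
                                 mode = c("max", "min"), eps = NULL) {
  mode <- match.arg(mode)
  d <- dim(vals)
  w <- which(valid & is.finite(vals) &
               is.finite(field$x) & is.finite(field$y) & is.finite(field$z))
  if (!length(w)) return(array(FALSE, dim = d))
  pts <- .which_vox(valid & is.finite(vals) &
                      is.finite(field$x) & is.finite(field$y) & is.finite(field$z))
  step <- min(spacing)                     # one voxel length in world units
  ux <- field$x[w] * step / spacing[1]
  uy <- field$y[w] * step / spacing[2]
  uz <- field$z[w] * step / spacing[3]
  fwd <- .trilinear(vals, valid, cbind(pts[, 1] + ux, pts[, 2] + uy, pts[, 3] + uz))
  bwd <- .trilinear(vals, valid, cbind(pts[, 1] - ux, pts[, 2] - uy, pts[, 3] - uz))
  v <- vals[w]
  if (is.null(eps)) eps <- 1e-9 * max(abs(v), 1e-12)
  keep <- if (mode == "max") {
    !is.na(fwd) & !is.na(bwd) & v >= fwd - eps & v >= bwd - eps
  } else {
    !is.na(fwd) & !is.na(bwd) & v <= fwd + eps & v <= bwd + eps
  }
  out <- array(FALSE, dim = d)
  out[w[keep]] <- TRUE
  out
}
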