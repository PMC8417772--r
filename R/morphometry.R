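#' The 16-structure cerebellar lobule codebook
#'
#' Integer ids and abbreviations for the 16 parcellated cerebellar cortical
#' lobules: vermis lobules 1Cb-10Cb and the hemispheric Sim, Crus 1, Crus 2,
#' PM, Cop, PFl and Fl.
#'
#' @return tibble with columns `id`, `abbreviation`, `region`.
#' @export
cerebellum_codebook <- function() {
  tibble::tibble(
    id = 1:16,
    abbreviation = c("1Cb", "2Cb", "3Cb", "4/5Cb", "6Cb", "7Cb", "8Cb",
                     "9Cb", "10Cb", "Sim", "Crus 1", "Crus 2", "PM", "Cop",
                     "PFl", "Fl"),
    region = c(rep("vermis", 9), rep("hemisphere", 7)))
}

#' Default structure merge/exclusion rules
#'
#' Lobules 1 and 2 are merged into a single structure (anatomical affinity);
#' Cop is excluded because it sits at the cerebellar edge where artificial
#' boundaries distort the measured morphology.
#'
#' @return list with `merge` (named list: new name -> members) and
#'   `exclude` (character).
#' @export
default_merge_rules <- function() {
  list(merge = list("1/2Cb" = c("1Cb", "2Cb")), exclude = "Cop")
}

# map raw abbreviations to analysis names; NA for excluded structures
.apply_rules <- function(abbrev, rules) {
  out <- abbrev
  for (nm in names(rules$merge)) out[out %in% rules$merge[[nm]]] <- nm
  out[out %in% rules$exclude] <- NA_character_
  out
}

#' Names of the analyzed structures after merging and exclusion
#'
#' @param codebook a codebook tibble.
#' @param rules merge/exclusion rules.
#' @return character vector (14 structures under the defaults).
#' @export
analyzed_structures <- function(codebook = cerebellum_codebook(),
                                rules = default_merge_rules()) {
  out <- .apply_rules(codebook$abbreviation, rules)
  unique(out[!is.na(out)])
}

#' Thickness-to-surface-area ratio
#'
#' `TSR = T / sqrt(A)`: dividing a 1-D measurement by the square root of a
#' 2-D one yields a dimensionless shape descriptor, invariant under
#' isotropic scaling. Raw (non-TIV-normalized) measurements are used.
#'
#' @param thickness thickness in mm.
#' @param area surface area in mm^2 (> 0).
#' @return the ratio.
#' @export
tsr <- function(thickness, area) {
  if (any(area <= 0, na.rm = TRUE)) stop("`area` must be positive")
  thickness / sqrt(area)
}

#' Per-structure, per-layer regional morphometry
#'
#' Aggregates voxel layer masks and per-vertex thickness samples into the
#' long morphometry table: per (structure, layer) the volume is the voxel
#' count times the voxel volume, the thickness is the mean of the per-vertex
#' values whose Purkinje voxel carries the structure's label, the surface
#' area is volume / thickness, and TSR = thickness / sqrt(area). A vertex
#' belongs to the structure labelled at its Purkinje voxel.
#'
#' @param layers list with `granular`, `molecular`, `purkinje` masks.
#' @param vertices per-vertex tibble from [layer_thicknesses()].
#' @param labels a `label_map` (or integer array aligned to the masks).
#' @param spacing voxel spacing in mm (taken from `labels` if available).
#' @param rules merge/exclusion rules; `NULL` keeps all raw structures.
#' @param codebook codebook tibble (taken from `labels` if available).
#' @return morphometry tibble: structure, layer (full/granular/molecular),
#'   metric (volume/thickness/area/tsr), value. Structures without Purkinje
#'   vertices get NA thickness/area/tsr with a warning.
#' @export
regional_metrics <- function(layers, vertices, labels, spacing = NULL,
                             rules = default_merge_rules(),
                             codebook = NULL) {
  if (inherits(labels, "label_map")) {
    if (is.null(spacing)) spacing <- labels$spacing
    if (is.null(codebook)) codebook <- labels$codebook
    lab <- labels$labels
  } else {
    lab <- labels
    if (is.null(codebook)) stop("`codebook` required for a bare label array")
    if (is.null(spacing)) stop("`spacing` required for a bare label array")
  }
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  vox_vol <- prod(spacing)
  if (is.null(rules)) rules <- list(merge = list(), exclude = character(0))

  id2name <- setNames(.apply_rules(codebook$abbreviation, rules), codebook$id)
  structures <- unique(id2name[!is.na(id2name)])

  vert_struct <- id2name[as.character(lab[vertices$vertex])]

  layer_defs <- list(
    full = list(mask = layers$granular | layers$molecular | layers$purkinje,
                t = vertices$t_full),
    granular = list(mask = layers$granular, t = vertices$t_gran),
    molecular = list(mask = layers$molecular, t = vertices$t_mol))

  rows <- list()
  for (ly in names(layer_defs)) {
    msk <- layer_defs[[ly]]$mask
    tv <- layer_defs[[ly]]$t
    lab_in <- lab[msk]
    nm_in <- id2name[as.character(lab_in)]
    vol <- vapply(structures, function(s)
      sum(nm_in == s, na.rm = TRUE) * vox_vol, numeric(1))
    thk <- vapply(structures, function(s) {
      v <- tv[!is.na(vert_struct) & vert_struct == s]
      v <- v[is.finite(v)]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    if (any(is.na(thk)))
      warning("structure(s) without Purkinje vertices in layer ", ly, ": ",
              paste(structures[is.na(thk)], collapse = ", "))
    area <- vol / thk
    rows[[ly]] <- tibble::tibble(
      structure = rep(structures, 4),
      layer = ly,
      metric = rep(c("volume", "thickness", "area", "tsr"), each = length(structures)),
      value = c(vol, thk, area, ifelse(is.na(area) | area <= 0, NA_real_,
                                       thk / sqrt(area))))
  }
  dplyr::bind_rows(rows)
}
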