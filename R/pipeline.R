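#' Pipeline configuration
#'
#' One flat, JSON-compatible configuration document with a validated
#' parameter block per stage. Defaults are the printed operating point of
#' the framework: speed-map smoothing `sigma_speed = 1.5`, planeness scale
#' `s = 0.04` mm with `alpha = beta = 0.5`, `gamma = 8`, 10 Gaussian levels
#' for contrast removal and depth extrapolation, and FDR `q = 0.1`.
#'
#' @param subjects list of subject records; each a list with `subject`,
#'   `group`, `tiv`, and either in-memory objects (`volume`, `masks`,
#'   `labels`, optional `resistant`) or NIfTI paths (`volume_path`,
#'   `mask_path`, `labels_path`, `resistant_path`).
#' @param out_dir output directory for persisted intermediates and tables.
#' @param seed integer seed used for every stochastic stage.
#' @param reference_landmarks optional 11 reference intensity landmarks for
#'   piecewise-linear standardization; `NULL` uses intensities as-is.
#' @param sigma_speed,planeness,levels,gmm,laplace,equivolume,purkinje,thickness,stats
#'   stage parameter blocks / values; see Details in the package vignette.
#' @param log_level `"info"` or `"quiet"`.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(subjects, out_dir = NULL, seed = 1L,
                            sigma_speed = 1.5,
                            reference_landmarks = NULL,
                            planeness = list(),
                            levels = 10L,
                            gmm = list(),
                            laplace = list(),
                            equivolume = list(),
                            purkinje = list(),
                            thickness = list(),
                            stats = list(),
                            log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  defaults <- list(
    planeness = list(s = 0.04, sigma_h = 0.5, alpha = 0.5, beta = 0.5,
                     gamma = 8, response_threshold = NULL),
    gmm = list(K = 4L, tol = 1e-6, max_iter = 500L),
    laplace = list(tol = 1e-6, max_iter = 20000L),
    equivolume = list(dl_frac = 0.25),
    purkinje = list(closeness_tol = 0.05, sigma = 1, levels = 10L),
    thickness = list(tol = 1e-4),
    stats = list(q = 0.1, n_perm = 1000L, alpha = 0.05))
  merge_block <- function(name, user) {
    d <- defaults[[name]]
    unknown <- setdiff(names(user), names(d))
    if (length(unknown))
      stop("unknown ", name, " parameter(s): ", paste(unknown, collapse = ", "))
    utils::modifyList(d, user, keep.null = TRUE)
  }
  cfg <- list(
    subjects = subjects, out_dir = out_dir, seed = as.integer(seed),
    sigma_speed = sigma_speed, levels = as.integer(levels),
    reference_landmarks = reference_landmarks,
    planeness = merge_block("planeness", planeness),
    gmm = merge_block("gmm", gmm),
    laplace = merge_block("laplace", laplace),
    equivolume = merge_block("equivolume", equivolume),
    purkinje = merge_block("purkinje", purkinje),
    thickness = merge_block("thickness", thickness),
    stats = merge_block("stats", stats),
    log_level = log_level)
  stopifnot(cfg$sigma_speed > 0, cfg$levels >= 1L,
            cfg$planeness$s > 0, cfg$stats$q > 0, cfg$stats$q < 1)
  if (!length(subjects)) stop("no subjects in config")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as JSON
#'
#' Only path-based subject records survive a round trip (in-memory phantom
#' objects are session objects).
#'
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  do.call(pipeline_config, cfg[setdiff(names(cfg), character(0))])
}

#' Write a morphometry or stats table as CSV
#'
#' Numeric fields are serialized at full precision (round-tripping doubles
#' exactly); an empty table writes the header only.
#'
#' @param rows tibble following the morphometry (subject, structure, layer,
#'   metric, value) or group-stats schema.
#' @param path output CSV path.
#' @export
write_table <- function(rows, path) {
  ok_morpho <- all(c("structure", "layer", "metric", "value") %in% names(rows))
  ok_stats <- all(c("structure", "layer", "metric", "t", "p") %in% names(rows)) ||
    all(c("vertex", "t", "p_corrected") %in% names(rows))
  if (!ok_morpho && !ok_stats)
    stop("rows do not follow the morphometry or stats table schema")
  readr::write_csv(rows, path)
  invisible(path)
}

# ---- per-subject stage chain ----------------------------------------------

.load_subject <- function(rec) {
  get1 <- function(obj, pth, reader) {
    if (!is.null(rec[[obj]])) return(rec[[obj]])
    if (!is.null(rec[[pth]])) return(reader(rec[[pth]]))
    NULL
  }
  vol <- get1("volume", "volume_path", read_volume)
  if (is.null(vol)) stop("subject ", rec$subject, ": no volume")
  msk <- rec$masks
  if (is.null(msk) && !is.null(rec$mask_path)) {
    m <- read_volume(rec$mask_path)
    msk <- list(cerebellum = m$values > 0.5)
  }
  labs <- get1("labels", "labels_path", read_labels)
  resistant <- get1("resistant", "resistant_path",
                    function(p) read_volume(p)$values > 0.5)
  list(volume = vol, masks = msk, labels = labs, resistant = resistant)
}

#' Run the laminar segmentation and morphometry chain for one subject
#'
#' Executes the stage order of the framework: tissue segmentation, initial
#' fissure extraction, laminar model, planeness filtering, initial Purkinje
#' mask, Purkinje-contrast-removed improved fissure, updated laminar model
#' and Purkinje extrapolation, layer segmentation, thickness, and regional
#' morphometry.
#'
#' @param volume a [voxel_grid()].
#' @param cerebellum_mask logical cerebellar mask.
#' @param labels a `label_map`.
#' @param config a `pipeline_config` (parameters only; subjects ignored).
#' @param resistant optional resistant-layer mask; `NULL` proceeds without
#'   resistant layers (with a log note).
#' @param wm_mask optional precomputed WM mask (skips the GMM stage, used
#'   when the phantom truth supplies tissue).
#' @param verbose print stage log lines.
#' @return list with masks, fields, vertex table and `metrics` tibble.
#' @export
process_subject <- function(volume, cerebellum_mask, labels, config,
                            resistant = NULL, wm_mask = NULL, verbose = TRUE) {
  t_all <- proc.time()[["elapsed"]]
  sp <- volume$spacing
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    .log_msg("INFO", sprintf("stage %-18s %6.2fs", name,
                             proc.time()[["elapsed"]] - t0), verbose = verbose)
    out
  }
  if (is.null(resistant))
    .log_msg("WARN", "no resistant-layer mask supplied; proceeding without",
             verbose = verbose)

  # tissue -------------------------------------------------------------
  norm <- if (!is.null(config$reference_landmarks)) {
    stage("normalize", normalize_intensity(volume, cerebellum_mask,
                                           config$reference_landmarks))
  } else volume  # no reference supplied: intensities used as-is
  plane <- stage("planeness", purkinje_planeness(norm, cerebellum_mask,
                                                 do.call(planeness_params,
                                                         config$planeness[
                                                           !vapply(config$planeness, is.null, TRUE)])))
  if (is.null(wm_mask)) {
    gmmfit <- stage("tissue_gmm", fit_gmm(norm, cerebellum_mask,
                                          K = config$gmm$K, tol = config$gmm$tol,
                                          max_iter = config$gmm$max_iter,
                                          seed = config$seed))
    wm_cand <- gmmfit$classification == gmmfit$K
    plane_pos <- plane$response > 0 &
      plane$response >= .otsu(plane$response[cerebellum_mask & plane$response > 0])
    tiss <- stage("clean_wm", clean_wm(wm_cand, cerebellum_mask, plane_pos))
  } else {
    tiss <- list(wm = wm_mask, gm = cerebellum_mask & !wm_mask)
  }
  wm <- tiss$wm; gm <- tiss$gm
  inner <- .adjacent_to(wm, gm)
  plane$response[!gm] <- 0

  # initial fissure ------------------------------------------------------
  spd0 <- stage("speed", build_speed(norm, gm, sigma_speed = config$sigma_speed,
                                     resistant_mask = resistant))
  d0 <- stage("eikonal", solve_eikonal(spd0, seeds = inner))
  fis0 <- stage("fissure_initial", extract_fissures(d0, gm, speed = spd0,
                                                   resistant_mask = resistant))

  # initial Purkinje -----------------------------------------------------
  m_p0 <- stage("purkinje_initial",
                initial_purkinje(plane$response, gm,
                                 threshold = config$planeness$response_threshold))

  # improved fissure with Purkinje contrast removed ----------------------
  sub <- stage("contrast_removal",
               remove_purkinje_contrast(norm, m_p0, gm, levels = config$levels))
  spd1 <- stage("speed_improved", build_speed(sub, gm, sigma_speed = config$sigma_speed,
                                              resistant_mask = resistant))
  d1 <- stage("eikonal_improved", solve_eikonal(spd1, seeds = inner))
  fis1 <- stage("fissure_improved", extract_fissures(d1, gm, speed = spd1,
                                                   resistant_mask = resistant))

  # laminar model on the improved pial surface ---------------------------
  barrier <- fis1 | (if (is.null(resistant)) array(FALSE, dim = dim(gm)) else resistant)
  pial <- .outer_boundary(gm | wm) | barrier
  dom <- gm & !barrier
  fld <- stage("laplace", {
    od <- array(0.5, dim = dim(gm)); od[barrier] <- 1.0
    solve_laplace(dom, wm, pial, sp, tol = config$laplace$tol,
                  max_iter = config$laplace$max_iter, outer_dist = od)
  })
  equiv <- stage("equivolume",
                 equivolume_ratio(fld, dl = config$equivolume$dl_frac * min(sp)))

  # Purkinje extrapolation and layers ------------------------------------
  m_pf <- stage("purkinje_final",
                extrapolate_purkinje(m_p0 & dom, equiv, fld,
                                     levels = config$purkinje$levels,
                                     sigma = config$purkinje$sigma,
                                     closeness_tol = config$purkinje$closeness_tol))
  lay <- stage("layers", segment_layers(dom, wm, pial, m_pf, sp))

  # thickness and morphometry -------------------------------------------
  thk <- stage("thickness", layer_thicknesses(dom, wm, pial, m_pf, lay, sp,
                                              fissure = barrier,
                                              laplace_tol = config$laplace$tol,
                                              thickness_tol = config$thickness$tol))
  metrics <- stage("morphometry", regional_metrics(lay, thk$vertices, labels))
  .log_msg("INFO", sprintf("subject chain done in %.1fs",
                           proc.time()[["elapsed"]] - t_all), verbose = verbose)
  list(masks = list(wm = wm, gm = gm, fissure_initial = fis0,
                    fissure = fis1, purkinje_initial = m_p0,
                    purkinje = m_pf, granular = lay$granular,
                    molecular = lay$molecular),
       field = fld, equivolume = equiv, thickness = thk,
       vertices = thk$vertices, metrics = metrics, leaks = lay$leaks)
}

#' Run the full pipeline over a cohort
#'
#' Chains every stage for each subject, assembles the cohort morphometry
#' table, and runs the W-score group statistics (structure level, plus
#' vertex-wise when all subjects share a common vertex indexing, as
#' phantoms do). All intermediate volumes and tables are persisted under
#' `config$out_dir` when it is set; rerunning with an identical config and
#' seed reproduces identical tables.
#'
#' @param config a `pipeline_config`.
#' @return list with `morphometry` (cohort tibble), `wscores`
#'   (`wscore_model`), `stats` (`group_stats`), `vertex_stats` (or NULL),
#'   and `subjects`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  verbose <- config$log_level == "info"
  set.seed(config$seed)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  subj_tbl <- tibble::tibble(
    subject = vapply(config$subjects, `[[`, character(1), "subject"),
    group = vapply(config$subjects, `[[`, character(1), "group"),
    tiv = vapply(config$subjects, function(s) as.numeric(s$tiv), numeric(1)))
  if (any(subj_tbl$tiv <= 0)) stop("TIV must be positive")

  results <- vector("list", length(config$subjects))
  for (si in seq_along(config$subjects)) {
    rec <- config$subjects[[si]]
    .log_msg("INFO", "subject ", rec$subject, verbose = verbose)
    dat <- .load_subject(rec)
    cereb <- if (!is.null(dat$masks$cerebellum)) dat$masks$cerebellum else
      dat$masks$wm | dat$masks$gm
    res <- process_subject(dat$volume, cereb, dat$labels, config,
                           resistant = dat$resistant,
                           wm_mask = dat$masks$wm, verbose = verbose)
    res$metrics <- dplyr::mutate(res$metrics, subject = rec$subject,
                                 .before = 1L)
    if (!is.null(out_dir)) {
      sd <- file.path(out_dir, rec$subject)
      dir.create(sd, showWarnings = FALSE, recursive = TRUE)
      sp <- dat$volume$spacing
      for (nm in names(res$masks))
        write_volume(res$masks[[nm]], file.path(sd, paste0(nm, ".nii.gz")),
                     spacing = sp)
      write_volume(voxel_grid(ifelse(is.na(res$field$psi), 0, res$field$psi), sp),
                   file.path(sd, "laplace_psi.nii.gz"))
      write_volume(voxel_grid(ifelse(is.na(res$equivolume$r_vol), 0,
                                     res$equivolume$r_vol), sp),
                   file.path(sd, "r_vol.nii.gz"))
      write_table(res$metrics, file.path(sd, "morphometry.csv"))
      readr::write_csv(res$vertices, file.path(sd, "vertices.csv"))
    }
    results[[si]] <- res
  }

  morpho <- dplyr::bind_rows(lapply(results, `[[`, "metrics"))
  ws <- w_score(morpho, subj_tbl)
  st <- structure_tests(ws, q = config$stats$q)

  # vertex-wise: identical geometry -> identity correspondence
  vs <- NULL
  vert_sets <- lapply(results, function(r) r$vertices$vertex)
  if (length(unique(vapply(vert_sets, length, integer(1)))) == 1L &&
      all(vapply(vert_sets[-1], identical, logical(1), vert_sets[[1]]))) {
    V <- vapply(results, function(r) r$vertices$t_gran, numeric(length(vert_sets[[1]])))
    keep <- apply(is.finite(V), 1L, all)
    if (any(keep))
      vs <- vertexwise_tests(V[keep, , drop = FALSE], subj_tbl,
                             n_perm = config$stats$n_perm, seed = config$seed,
                             alpha = config$stats$alpha)
  } else {
    .log_msg("INFO", "subjects lack a common vertex indexing; vertex-wise stats skipped",
             verbose = verbose)
  }

  if (!is.null(out_dir)) {
    write_table(morpho, file.path(out_dir, "morphometry.csv"))
    write_table(tidy(st), file.path(out_dir, "structure_stats.csv"))
    readr::write_csv(tidy(ws), file.path(out_dir, "wscores.csv"))
    if (!is.null(vs)) write_table(tidy(vs), file.path(out_dir, "vertex_stats.csv"))
    write_config(config[setdiff(names(config), "subjects")] |>
                   (\(x) { class(x) <- "pipeline_config"; x })(),
                 file.path(out_dir, "config.json"))
  }
  list(morphometry = morpho, wscores = ws, stats = st, vertex_stats = vs,
       subjects = subj_tbl, per_subject = results)
}
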