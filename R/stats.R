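#' W-score (TIV-adjusted) normalization of morphometrics
#'
#' For each (structure, layer, metric) an ordinary least-squares model
#' `M = b0 + b1 TIV + e` is fitted on the control subjects only; residuals
#' against the control fit are computed for every subject and standardized
#' by the control residual mean and sd (sample sd, n - 1):
#' `W = (e - mu_ctrl) / sd_ctrl`. A W-score of 0 is control-typical and its
#' units are control standard deviations. Zero TIV variance among controls
#' triggers an intercept-only fallback with a warning.
#'
#' @param metrics long morphometry tibble (subject, structure, layer,
#'   metric, value).
#' @param subjects tibble with subject, group (`control` / `case`), tiv.
#' @return object of class `wscore_model` with `model` (per-cell fit
#'   coefficients) and `scores` (per-subject W-scores).
#' @export
w_score <- function(metrics, subjects) {
  stopifnot(all(c("subject", "structure", "layer", "metric", "value") %in%
                  names(metrics)),
            all(c("subject", "group", "tiv") %in% names(subjects)))
  if (!all(metrics$subject %in% subjects$subject))
    stop("metrics contain subjects missing from the subject table")
  if (any(!is.finite(subjects$tiv)) || any(subjects$tiv <= 0))
    stop("TIV must be positive for all subjects")
  nctrl <- sum(subjects$group == "control")
  if (nctrl < 3L) stop("need at least 3 control subjects")

  df <- dplyr::left_join(metrics, subjects, by = "subject")

  fit_cell <- function(d) {
    ctrl <- d[d$group == "control" & is.finite(d$value), , drop = FALSE]
    tv <- var(ctrl$tiv)
    if (!is.finite(tv) || tv < 1e-12) {
      warning("zero TIV variance among controls; intercept-only fallback")
      b1 <- 0
      b0 <- mean(ctrl$value)
    } else {
      b1 <- stats::cov(ctrl$tiv, ctrl$value) / tv
      b0 <- mean(ctrl$value) - b1 * mean(ctrl$tiv)
    }
    res_all <- d$value - (b0 + b1 * d$tiv)
    res_ctrl <- res_all[d$group == "control" & is.finite(d$value)]
    mu <- mean(res_ctrl)
    sig <- sd(res_ctrl)
    if (!is.finite(sig) || sig < 1e-300) sig <- NA_real_
    d$resid <- res_all
    d$w <- (res_all - mu) / sig
    list(model = tibble::tibble(beta0 = b0, beta1 = b1, mu = mu, sigma = sig),
         scores = d)
  }

  nested <- df |>
    dplyr::group_by(.data$structure, .data$layer, .data$metric) |>
    dplyr::group_split()
  keys <- df |>
    dplyr::group_by(.data$structure, .data$layer, .data$metric) |>
    dplyr::group_keys()
  fits <- lapply(nested, fit_cell)
  model <- dplyr::bind_cols(keys, dplyr::bind_rows(lapply(fits, `[[`, "model")))
  scores <- dplyr::bind_rows(lapply(fits, `[[`, "scores"))

  structure(list(model = model, scores = scores, n_control = nctrl),
            class = "wscore_model")
}

#' @export
print.wscore_model <- function(x, ...) {
  cat(sprintf("<wscore_model> %d cells, %d subjects (%d controls)\n",
              nrow(x$model), length(unique(x$scores$subject)), x$n_control))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.wscore_model <- function(x, ...) {
  x$scores[, c("subject", "group", "structure", "layer", "metric", "tiv",
               "value", "resid", "w")]
}

#' @exportS3Method generics::glance
glance.wscore_model <- function(x, ...) {
  tibble::tibble(cells = nrow(x$model),
                 subjects = length(unique(x$scores$subject)),
                 controls = x$n_control)
}

#' W-score heatmap (structures x subjects)
#'
#' The panoramic "Zscape-style" panel: one tile per structure and subject
#' coloured by W-score, faceted by layer and metric.
#'
#' @param object a `wscore_model`.
#' @param metrics,layers optional filters.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.wscore_model <- function(object, metrics = NULL, layers = NULL, ...) {
  d <- tidy(object)
  if (!is.null(metrics)) d <- d[d$metric %in% metrics, ]
  if (!is.null(layers)) d <- d[d$layer %in% layers, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$subject, y = .data$structure,
                                  fill = .data$w)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(layer ~ metric) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-4, 4),
                                  oob = scales::squish) +
    ggplot2::labs(x = "subject", y = "structure", fill = "W") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

# two-sample pooled-variance t statistic; returns list(t, df, p)
.student_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
  if (!is.finite(sp2) || sp2 <= 0) {
    tt <- if (isTRUE(all.equal(mean(x), mean(y)))) 0 else Inf * sign(mean(x) - mean(y))
    return(list(t = tt, df = nx + ny - 2,
                p = if (is.finite(tt) && tt == 0) 1 else 0))
  }
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df))
}

#' Structure-level group tests on W-scores with FDR control
#'
#' Two-sided unpaired (pooled-variance) t-tests per structure on the
#' W-scores, with Benjamini-Hochberg step-up FDR control at level `q`
#' applied within each (layer, metric) family — mirroring the per-panel
#' reporting of the W-score heatmaps.
#'
#' @param w a `wscore_model`.
#' @param q FDR level (default 0.1).
#' @return object of class `group_stats`: tibble with structure, layer,
#'   metric, mean W per group, t, p, p_adj, significant.
#' @export
structure_tests <- function(w, q = 0.1) {
  stopifnot(inherits(w, "wscore_model"))
  sc <- w$scores
  if (length(unique(sc$subject[sc$group == "case"])) < 2L ||
      length(unique(sc$subject[sc$group == "control"])) < 2L)
    stop("need at least 2 subjects per group")
  res <- sc |>
    dplyr::filter(is.finite(.data$w)) |>
    dplyr::group_by(.data$structure, .data$layer, .data$metric) |>
    dplyr::summarise(
      w_control = mean(.data$w[.data$group == "control"]),
      w_case = mean(.data$w[.data$group == "case"]),
      t = .student_t(.data$w[.data$group == "case"],
                     .data$w[.data$group == "control"])$t,
      p = .student_t(.data$w[.data$group == "case"],
                     .data$w[.data$group == "control"])$p,
      .groups = "drop")
  if (any(!is.finite(res$p))) {
    warning("degenerate (zero-variance) cells; p set to the degenerate limit")
    res$p[!is.finite(res$p)] <- 1
  }
  res <- res |>
    dplyr::group_by(.data$layer, .data$metric) |>
    dplyr::mutate(p_adj = stats::p.adjust(.data$p, method = "BH"),
                  significant = .data$p_adj <= q) |>
    dplyr::ungroup()
  structure(list(table = res, q = q), class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat(sprintf("<group_stats> %d tests, FDR q = %g, %d significant\n",
              nrow(x$table), x$q, sum(x$table$significant)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.group_stats <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.group_stats <- function(x, ...) {
  tibble::tibble(tests = nrow(x$table), q = x$q,
                 significant = sum(x$table$significant))
}

#' @exportS3Method ggplot2::autoplot
autoplot.group_stats <- function(object, ...) {
  d <- object$table
  ggplot2::ggplot(d, ggplot2::aes(x = .data$structure,
                                  y = .data$w_case - .data$w_control,
                                  fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_grid(layer ~ metric) +
    ggplot2::labs(y = "case - control mean W (control SD)", x = NULL,
                  fill = sprintf("FDR q = %g", object$q)) +
    ggplot2::theme_minimal()
}

# vectorized two-sample pooled t across the rows of a matrix
.row_t <- function(X, g_case) {
  n1 <- sum(g_case); n2 <- sum(!g_case)
  m1 <- rowMeans(X[, g_case, drop = FALSE])
  m2 <- rowMeans(X[, !g_case, drop = FALSE])
  v1 <- rowSums((X[, g_case, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((X[, !g_case, drop = FALSE] - m2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  (m1 - m2) / sqrt(pmax(sp2, 1e-300) * (1 / n1 + 1 / n2))
}

#' Vertex-wise group comparison with max-T permutation correction
#'
#' Per-vertex unpaired t-tests on (optionally W-scored) thickness defined on
#' a common vertex indexing, with family-wise error control by max-T
#' permutation of the group labels: the corrected p-value of a vertex is the
#' proportion of permutations whose maximal |t| over vertices reaches its
#' observed |t|. When fewer distinct label reassignments exist than
#' `n_perm`, the full enumeration is used instead (and noted).
#'
#' @param values numeric matrix, vertices x subjects.
#' @param subjects tibble with subject, group, tiv; column order must match
#'   the matrix columns.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed for the permutation draw.
#' @param wscore logical; W-score each vertex against the control TIV
#'   regression first (default TRUE). `FALSE` tests the raw values.
#' @param alpha significance level on corrected p-values (default 0.05).
#' @return object of class `vertex_stats`: tibble with vertex, t,
#'   p_corrected, significant; attribute `n_perm_used`.
#' @export
vertexwise_tests <- function(values, subjects, n_perm = 1000L, seed = NULL,
                             wscore = TRUE, alpha = 0.05) {
  X <- as.matrix(values)
  stopifnot(ncol(X) == nrow(subjects))
  g_case <- subjects$group == "case"
  n <- ncol(X)
  if (sum(g_case) < 2L || sum(!g_case) < 2L) stop("need >= 2 subjects per group")

  if (wscore) {
    tiv <- subjects$tiv
    ctl <- !g_case
    tc <- tiv[ctl]
    tv <- var(tc)
    Xc <- X[, ctl, drop = FALSE]
    if (is.finite(tv) && tv > 1e-12) {
      b1 <- (Xc %*% (tc - mean(tc))) / ((length(tc) - 1) * tv)
    } else b1 <- matrix(0, nrow(X), 1)
    b0 <- rowMeans(Xc) - b1[, 1] * mean(tc)
    R <- X - (b0 + b1[, 1] %o% tiv)
    Rc <- R[, ctl, drop = FALSE]
    mu <- rowMeans(Rc)
    sig <- sqrt(rowSums((Rc - mu)^2) / (ncol(Rc) - 1))
    X <- (R - mu) / pmax(sig, 1e-300)
  }

  t_obs <- .row_t(X, g_case)

  n1 <- sum(g_case)
  n_distinct <- choose(n, n1)
  exhaustive <- n_distinct <= n_perm
  if (!is.null(seed)) set.seed(seed)
  perms <- if (exhaustive) {
    message("vertexwise_tests: exhaustive enumeration of ", n_distinct,
            " label assignments")
    utils::combn(n, n1, simplify = FALSE)
  } else {
    lapply(seq_len(n_perm), function(i) sample.int(n, n1))
  }
  max_t <- vapply(perms, function(ix) {
    g <- logical(n); g[ix] <- TRUE
    max(abs(.row_t(X, g)))
  }, numeric(1))
  B <- length(max_t)
  p_corr <- vapply(abs(t_obs), function(tt) (1 + sum(max_t >= tt)) / (B + 1),
                   numeric(1))
  out <- tibble::tibble(vertex = seq_len(nrow(X)), t = t_obs,
                        p_corrected = p_corr,
                        significant = p_corr <= alpha)
  structure(list(table = out, n_perm_used = B, exhaustive = exhaustive,
                 alpha = alpha), class = "vertex_stats")
}

#' @export
print.vertex_stats <- function(x, ...) {
  cat(sprintf("<vertex_stats> %d vertices, %d permutations%s, %d significant at alpha = %g\n",
              nrow(x$table), x$n_perm_used,
              if (x$exhaustive) " (exhaustive)" else "",
              sum(x$table$significant), x$alpha))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.vertex_stats <- function(x, ...) x$table
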