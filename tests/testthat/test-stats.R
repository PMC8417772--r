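test_that("control-group W-scores have mean 0 and sd 1 exactly", {
  sim <- simulate_cohort(seed = 11)
  ws <- w_score(sim$metrics, sim$subjects)
  sc <- tidy(ws)
  ctl <- sc[sc$group == "control", ]
  agg <- dplyr::summarise(dplyr::group_by(ctl, structure, layer, metric),
                          m = mean(w), s = sd(w), .groups = "drop")
  expect_lt(max(abs(agg$m)), 1e-10)
  expect_lt(max(abs(agg$s - 1)), 1e-10)
})

test_that("a case on the control regression line scores W = 0", {
  subjects <- tibble::tibble(subject = c("C1", "C2", "C3", "C4", "K1"),
                             group = c(rep("control", 4), "case"),
                             tiv = c(400, 420, 440, 460, 430))
  # controls exactly on a line; the case too
  metrics <- tibble::tibble(subject = subjects$subject, structure = "S",
                            layer = "granular", metric = "thickness",
                            value = 0.1 + 0.001 * subjects$tiv)
  metrics$value[1:4] <- metrics$value[1:4] + c(0.01, -0.01, 0.01, -0.01)
  ws <- w_score(metrics, subjects)
  sc <- tidy(ws)
  expect_equal(sc$w[sc$subject == "K1"], 0, tolerance = 1e-8)
})

test_that("the closed-form OLS matches stats::lm", {
  sim <- simulate_cohort(n_control = 10, n_case = 5, seed = 12)
  ws <- w_score(sim$metrics, sim$subjects)
  cell <- ws$model[ws$model$structure == ws$model$structure[1] &
                     ws$model$layer == "granular" &
                     ws$model$metric == "thickness", ]
  d <- dplyr::left_join(sim$metrics, sim$subjects, by = "subject")
  d <- d[d$structure == cell$structure & d$layer == "granular" &
           d$metric == "thickness" & d$group == "control", ]
  fit <- lm(value ~ tiv, data = d)
  expect_equal(cell$beta0, unname(coef(fit)[1]), tolerance = 1e-10)
  expect_equal(cell$beta1, unname(coef(fit)[2]), tolerance = 1e-10)
})

test_that("W-scores are invariant to affine rescaling of the raw metric", {
  sim <- simulate_cohort(seed = 13)
  ws1 <- w_score(sim$metrics, sim$subjects)
  m2 <- sim$metrics
  m2$value <- 1000 * m2$value + 3
  ws2 <- w_score(m2, sim$subjects)
  expect_equal(tidy(ws1)$w, tidy(ws2)$w, tolerance = 1e-8)
})

test_that("the TIV confound is removed: raw shift, no W shift", {
  sim <- simulate_cohort(n_control = 200, n_case = 200,
                         granular_thickness_effect = 0,
                         molecular_area_effect = 0, seed = 14)
  d <- dplyr::left_join(sim$metrics, sim$subjects, by = "subject")
  gt <- d[d$layer == "granular" & d$metric == "thickness", ]
  # raw case means exceed controls (bigger heads)
  expect_gt(mean(gt$value[gt$group == "case"]),
            mean(gt$value[gt$group == "control"]))
  ws <- w_score(sim$metrics, sim$subjects)
  sc <- tidy(ws)
  sgt <- sc[sc$layer == "granular" & sc$metric == "thickness", ]
  expect_lt(abs(mean(sgt$w[sgt$group == "case"])), 0.2)
})

test_that("an injected -1.5 SD granular effect is recovered at n = 200", {
  sim <- simulate_cohort(n_control = 200, n_case = 200, seed = 15)
  ws <- w_score(sim$metrics, sim$subjects)
  sc <- tidy(ws)
  gt <- sc[sc$layer == "granular" & sc$metric == "thickness", ]
  expect_equal(mean(gt$w[gt$group == "case"]), -1.5, tolerance = 0.2 / 1.5)
  expect_lt(abs(mean(gt$w[gt$group == "case"]) + 1.5), 0.2)
})

test_that("intercept-only fallback fires on zero TIV variance", {
  subjects <- tibble::tibble(subject = sprintf("S%d", 1:6),
                             group = rep(c("control", "case"), each = 3),
                             tiv = rep(450, 6))
  metrics <- tibble::tibble(subject = subjects$subject, structure = "S",
                            layer = "full", metric = "volume",
                            value = c(1, 1.1, 0.9, 1.4, 1.5, 1.3))
  expect_warning(ws <- w_score(metrics, subjects), "zero TIV variance")
  expect_equal(mean(tidy(ws)$w[1:3]), 0, tolerance = 1e-10)
})

test_that("BH step-up flags match the brute-force oracle", {
  # the worked example
  p <- c(0.001, 0.02, 0.03, 0.5)
  expect_identical(p.adjust(p, "BH") <= 0.1, c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(bh_oracle(p, 0.1), c(TRUE, TRUE, TRUE, FALSE))
  # property: 1000 random p-vectors
  set.seed(99)
  for (i in 1:1000) {
    m <- sample(3:20, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- runif(1, 0.01, 0.3)
    expect_identical(p.adjust(p, "BH") <= q, bh_oracle(p, q))
  }
})

test_that("structure tests flag an overwhelming shift and respect families", {
  sim <- simulate_cohort(granular_thickness_effect = -10,
                         molecular_area_effect = 0, tiv_case_shift = 0,
                         seed = 16)
  ws <- w_score(sim$metrics, sim$subjects)
  st <- structure_tests(ws, q = 0.1)
  tb <- tidy(st)
  gt <- tb[tb$layer == "granular" & tb$metric == "thickness", ]
  expect_true(all(gt$significant))
  # families are per layer x metric panel
  expect_equal(nrow(dplyr::distinct(tb[, c("layer", "metric")])), 12L)
})

test_that("null cohorts reject at most at the nominal FDR level", {
  set.seed(17)
  reps <- 1000L
  any_rej <- logical(reps)
  for (r in seq_len(reps)) {
    sim <- simulate_cohort(n_control = 50, n_case = 50, tiv_case_shift = 0,
                           granular_thickness_effect = 0,
                           molecular_area_effect = 0)
    m <- sim$metrics[sim$metrics$layer == "granular" &
                       sim$metrics$metric == "thickness", ]
    ws <- w_score(m, sim$subjects)
    st <- structure_tests(ws, q = 0.1)
    any_rej[r] <- any(tidy(st)$significant)
  }
  rate <- mean(any_rej)
  mc_sd <- sqrt(0.1 * 0.9 / reps)
  expect_lte(rate, 0.1 + 3 * mc_sd)
})

test_that("vertex-wise t maps negate exactly under label swap", {
  set.seed(18)
  X <- matrix(rnorm(50 * 12), 50, 12)
  subjects <- tibble::tibble(subject = sprintf("S%d", 1:12),
                             group = rep(c("control", "case"), each = 6),
                             tiv = rnorm(12, 450, 15))
  v1 <- vertexwise_tests(X, subjects, n_perm = 99, seed = 1, wscore = FALSE)
  swapped <- subjects
  swapped$group <- rev(subjects$group)
  v2 <- vertexwise_tests(X, swapped, n_perm = 99, seed = 1, wscore = FALSE)
  expect_equal(tidy(v1)$t, -tidy(v2)$t, tolerance = 1e-12)
})

test_that("max-T permutation controls the family-wise error under the null", {
  set.seed(19)
  reps <- 500L
  nv <- 40L; n <- 12L
  subjects <- tibble::tibble(subject = sprintf("S%d", 1:n),
                             group = rep(c("control", "case"), each = n / 2),
                             tiv = rnorm(n, 450, 15))
  fwer <- vapply(seq_len(reps), function(r) {
    X <- matrix(rnorm(nv * n), nv, n)
    v <- vertexwise_tests(X, subjects, n_perm = 199, wscore = FALSE)
    any(tidy(v)$significant)
  }, logical(1))
  rate <- mean(fwer)
  mc_sd <- sqrt(0.05 * 0.95 / reps)
  expect_lte(rate, 0.05 + 3 * mc_sd)
})

test_that("a localized thinning is found where it was injected", {
  set.seed(20)
  nv <- 100L; n <- 28L
  subjects <- tibble::tibble(subject = sprintf("S%d", 1:n),
                             group = rep(c("control", "case"), each = 14),
                             tiv = rnorm(n, 450, 15))
  X <- matrix(rnorm(nv * n), nv, n)
  affected <- 1:50
  X[affected, subjects$group == "case"] <-
    X[affected, subjects$group == "case"] - 2.5
  v <- vertexwise_tests(X, subjects, n_perm = 499, seed = 2, wscore = FALSE)
  sig <- tidy(v)$significant
  expect_gt(sum(sig), 0)
  expect_gte(sum(sig[affected]) / sum(sig), 0.8)
})

test_that("exhaustive enumeration replaces sampling for tiny groups", {
  set.seed(21)
  X <- matrix(rnorm(10 * 6), 10, 6)
  subjects <- tibble::tibble(subject = sprintf("S%d", 1:6),
                             group = rep(c("control", "case"), each = 3),
                             tiv = rnorm(6, 450, 15))
  expect_message(v <- vertexwise_tests(X, subjects, n_perm = 1000,
                                       wscore = FALSE),
                 "exhaustive")
  expect_equal(v$n_perm_used, choose(6, 3))
})
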