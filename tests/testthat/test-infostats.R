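test_that("descriptors follow the histogram rule", {
  expect_equal(choose_descriptor(sample(c("a", "b"), 100, replace = TRUE))$n_cells, 2L)
  expect_equal(choose_descriptor(rep(3.7, 50))$n_cells, 1L)
  set.seed(1)
  expect_equal(choose_descriptor(rnorm(128))$n_cells, 8L)  # ceil(1 + log2 128)
  expect_equal(choose_descriptor(rnorm(100))$n_cells, 8L)  # ceil(1 + log2 100)
  expect_error(choose_descriptor(numeric(0)), class = "handovr_invalid_argument")
})

test_that("mutual information is calibrated on known cases", {
  set.seed(2)
  x <- sample(0:1, 1e4, replace = TRUE)
  expect_lt(abs(mutual_information(x, x) - 1), 0.05)       # I(x,x) ~ H(fair coin)
  y <- sample(0:1, 1e4, replace = TRUE)
  expect_lt(abs(mutual_information(x, y)), 0.02)           # independent

  # uncorrected estimate on a small printed 2x2 table, against the hand
  # evaluation of the plug-in formula
  x2 <- c(rep("a", 30), rep("a", 10), rep("b", 10), rep("b", 50))
  y2 <- c(rep("u", 30), rep("v", 10), rep("u", 10), rep("v", 50))
  p <- matrix(c(30, 10, 10, 50), 2, 2) / 100
  px <- rowSums(p); py <- colSums(p)
  by_hand <- sum(p * log2(p / outer(px, py)))
  expect_equal(mutual_information(x2, y2, correct = FALSE), by_hand,
               tolerance = 1e-12)
  # and the corrected estimate subtracts exactly (Rx-1)(Ry-1)/(2N ln 2)
  expect_equal(mutual_information(x2, y2),
               by_hand - 1 / (200 * log(2)), tolerance = 1e-12)

  expect_error(mutual_information(1:3, 1:4), class = "handovr_invalid_argument")
})

test_that("MI is symmetric, and the plug-in self-information equals the entropy", {
  set.seed(3)
  for (i in 1:10) {
    x <- rnorm(60)
    y <- rnorm(60) + 0.5 * x
    expect_identical(mutual_information(x, y), mutual_information(y, x))
    expect_gte(mutual_information(x, y, correct = FALSE), 0)
  }
  z <- sample(letters[1:4], 200, replace = TRUE)
  expect_equal(mutual_information(z, z, correct = FALSE), plugin_entropy(z),
               tolerance = 1e-12)
})

test_that("the MI matrix shows independent conditions, diagonal dominance, and functional dependence", {
  ds <- hierarchy_dataset(seed = 23)
  D <- distance_matrix(ds$trajectories)
  embeddings <- lapply(setNames(c(1, 2), c("1", "2")), function(d) {
    nmds_embed(D, dim = d, seed = d)
  })
  M <- mi_matrix(ds, embeddings, correct = FALSE)
  expect_identical(unclass(M), t(unclass(M)))
  cond <- names(condition_levels())
  # the randomized factorial makes the five condition factors independent
  off <- unclass(M)[cond, cond]
  expect_lt(max(off[upper.tri(off)]), 0.05)
  # uncorrected diagonal dominates its row
  for (i in seq_len(nrow(M))) {
    expect_gte(M[i, i], max(M[i, -i]) - 1e-12)
  }
  # a trait copied from identity carries exactly H(identity)
  id <- handovr:::factor_label_table(ds)$identity
  expect_equal(mutual_information(id, as.integer(factor(id)), correct = FALSE),
               plugin_entropy(id), tolerance = 1e-12)
})

test_that("with a 1-D response all four MANOVA statistics reduce to one-way ANOVA", {
  set.seed(4)
  g <- factor(rep(letters[1:3], each = 8))
  y <- rnorm(24) + as.integer(g)
  fit <- manova_codes(matrix(y, ncol = 1), tibble::tibble(g = g), "g")
  ref <- stats::anova(stats::lm(y ~ g))
  tab <- dplyr::filter(fit$table, term == "g")
  for (i in seq_len(nrow(tab))) {
    expect_equal(tab$approx_f[i], ref$`F value`[1], tolerance = 1e-8)
    expect_equal(tab$p_value[i], ref$`Pr(>F)`[1], tolerance = 1e-8)
  }
})

test_that("MANOVA statistics agree with the standard multivariate tests", {
  set.seed(5)
  n <- 40
  g <- factor(rep(letters[1:4], each = 10))
  Y <- matrix(rnorm(n * 3), n, 3) + model.matrix(~ 0 + g) %*% matrix(rnorm(12), 4, 3)
  fit <- manova_codes(Y, tibble::tibble(g = g), "g")
  mfit <- stats::manova(Y ~ g)
  for (stat in c("Pillai", "Wilks", "Hotelling-Lawley", "Roy")) {
    ref <- summary(mfit, test = stat)$stats
    ours <- dplyr::filter(fit$table, term == "g",
                          statistic == sub("-Lawley", "", stat))
    expect_equal(ours$value, ref["g", 2], tolerance = 1e-8)
    expect_equal(ours$approx_f, ref["g", "approx F"], tolerance = 1e-8)
    expect_equal(ours$p_value, ref["g", "Pr(>F)"], tolerance = 1e-8)
  }
})

test_that("MANOVA statistics satisfy their shared-eigenvalue identities", {
  set.seed(6)
  # rank-one hypothesis: two groups give a single nonzero eigenvalue lambda
  g <- factor(rep(c("a", "b"), each = 12))
  Y <- matrix(rnorm(24 * 4), 24, 4)
  Y[g == "b", 1] <- Y[g == "b", 1] + 2
  fit <- manova_codes(Y, tibble::tibble(g = g), "g")
  lam <- max(fit$eigenvalues$g)
  vals <- setNames(dplyr::filter(fit$table, term == "g")$value,
                   dplyr::filter(fit$table, term == "g")$statistic)
  expect_equal(unname(vals["Pillai"]), lam / (1 + lam), tolerance = 1e-10)
  expect_equal(unname(vals["Wilks"]), 1 / (1 + lam), tolerance = 1e-10)
  expect_equal(unname(vals["Hotelling"]), lam, tolerance = 1e-10)
  expect_equal(unname(vals["Roy"]), lam, tolerance = 1e-10)
  expect_gt(vals["Pillai"], 0)
  expect_lte(vals["Wilks"], 1)
})

test_that("MANOVA p-values are uniform under a shuffled grouping", {
  set.seed(7)
  ps <- replicate(150, {
    g <- factor(sample(rep(c("a", "b", "c"), 12)))
    Y <- matrix(rnorm(36 * 2), 36, 2)
    fit <- manova_codes(Y, tibble::tibble(g = g), "g")
    dplyr::filter(fit$table, term == "g", statistic == "Wilks")$p_value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.05)
})

test_that("rank-deficient designs and singular error matrices are named", {
  g <- factor(rep(c("a", "b"), each = 6))
  data <- tibble::tibble(g = g, g2 = g)
  Y <- matrix(rnorm(24), 12, 2)
  expect_error(manova_codes(Y, data, c("g", "g2")),
               class = "handovr_rank_deficiency")
  # constant response column: singular E
  Y2 <- cbind(rnorm(12), 1)
  colnames(Y2) <- c("ok", "const")
  expect_error(manova_codes(Y2, data, "g"),
               class = "handovr_rank_deficiency")
})

test_that("model reduction keeps informative factors and sheds noise", {
  set.seed(8)
  n <- 60
  signal <- rnorm(n)
  noise <- rnorm(n)
  Y <- cbind(signal + rnorm(n, 0, 0.3), -signal + rnorm(n, 0, 0.3))
  data <- tibble::tibble(signal = signal, noise = noise)
  red <- model_reduction(Y, data, c("signal", "noise"))
  expect_equal(red$retained, "signal")
  expect_true("noise" %in% red$dropped$factor)

  # alpha = 1 retains every candidate
  red_all <- model_reduction(Y, data, c("signal", "noise"), alpha = 1)
  expect_setequal(red_all$retained, c("signal", "noise"))

  # all-noise candidates reduce to the empty set (stringent alpha keeps the
  # chance of a spurious retention negligible)
  Y0 <- matrix(rnorm(n * 2), n, 2)
  red0 <- model_reduction(Y0, data, c("signal", "noise"), alpha = 0.001)
  expect_length(red0$retained, 0)
  expect_null(red0$fit)

  # aliased candidates are set aside deterministically
  data2 <- tibble::tibble(a = signal, b = signal, c = noise)
  red2 <- model_reduction(Y, data2, c("a", "b", "c"))
  expect_true("b" %in% red2$dropped$factor[red2$dropped$reason == "aliased"])
})
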