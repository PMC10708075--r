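test_that("unit-variance scaling centers and scales retained columns", {
  set.seed(1)
  X <- cbind(matrix(rnorm(40), 8, 5), const = rep(2, 8))
  colnames(X)[1:5] <- paste0("v", 1:5)
  sm <- opls_scale(X, rep(c("a", "b"), each = 4))
  expect_equal(sm$dropped, "const")
  expect_equal(unname(colMeans(sm$X)), rep(0, 5), tolerance = 1e-9)
  expect_equal(unname(apply(sm$X, 2, stats::var)), rep(1, 5),
               tolerance = 1e-9)
})

test_that("a perfectly informative variable takes the top weight and VIP sqrt(p)", {
  y <- c(-1, -1, 1, 1)
  X <- cbind(inf = y, n1 = c(1, -1, 1, -1), n2 = c(1, -1, -1, 1))
  suppressWarnings(m <- fit_oplsda(X, y, n_ortho = 0, scaling = "none"))
  expect_equal(which.max(abs(m$w)), c(inf = 1))
  v <- compute_vip(m)
  expect_equal(v$vip[v$compound == "inf"], sqrt(3), tolerance = 1e-9)
  expect_equal(v$vip[v$compound != "inf"], c(0, 0), tolerance = 1e-9)
  # all-identical weights give VIP 1 everywhere
  X2 <- cbind(a = y, b = y, c = y, d = y)
  v2 <- compute_vip(suppressWarnings(fit_oplsda(X2, y, n_ortho = 0,
                                                scaling = "none")))
  expect_equal(v2$vip, rep(1, 4), tolerance = 1e-9)
})

test_that("y orthogonal to X gives r2y near 0", {
  y <- c(-1, -1, 1, 1)
  X <- cbind(a = c(1, -1, 1, -1), b = c(1, -1, -1, 1))
  expect_error(suppressWarnings(fit_oplsda(X, y, n_ortho = 0,
                                           scaling = "none")),
               "orthogonal")
})

test_that("VIP agrees with a direct-summation oracle and is normalized", {
  set.seed(7)
  for (i in 1:5) {
    X <- matrix(rnorm(30), 6, 5)
    y <- rep(c("a", "b"), each = 3)
    suppressWarnings(m <- fit_oplsda(X, y, n_ortho = 1))
    v <- compute_vip(m)
    expect_equal(v$vip[match(m$variables, v$compound)], vip_oracle(m),
                 tolerance = 1e-10)
    vp <- compute_vip(m, type = "predictive")
    expect_equal(vp$vip[match(m$variables, vp$compound)],
                 vip_oracle(m, "predictive"), tolerance = 1e-10)
  }
})

test_that("mean squared VIP is exactly 1 over 100 random matrices", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(6:12, 1); p <- sample(3:20, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rep(c("a", "b"), length.out = n)
    suppressWarnings(m <- fit_oplsda(X, y, n_ortho = sample(0:2, 1)))
    v <- compute_vip(m)
    expect_equal(sum(v$vip^2), nrow(v), tolerance = 1e-9)
  }
})

test_that("predictive and orthogonal scores are mutually orthogonal; fit is deterministic", {
  d <- separable_data(n_per = 4, p = 8, seed = 3)
  m <- fit_oplsda(d$X, d$y, n_ortho = 2)
  for (k in seq_len(m$n_ortho))
    expect_lt(abs(sum(m$t * m$T_o[, k])) /
                (sqrt(sum(m$t^2)) * sqrt(sum(m$T_o[, k]^2))), 1e-8)
  expect_true(m$r2y >= 0 && m$r2y <= 1)
  m2 <- fit_oplsda(d$X, d$y, n_ortho = 2)
  expect_identical(m, m2)
})

test_that("Q2 is high on separable data, finite under leave-one-out, and below R2Y", {
  d <- separable_data(n_per = 4, p = 6, delta = 6, sd = 0.05, seed = 5)
  q2 <- cross_validate(d$X, d$y)
  expect_gt(q2, 0.9)
  m <- fit_oplsda(d$X, d$y)
  expect_lte(q2, m$r2y + 1e-9)
  q2_loo <- cross_validate(d$X, d$y, n_folds = 8)
  expect_true(is.finite(q2_loo))
  expect_gt(q2_loo, 0.9)
})

test_that("permuted labels destroy Q2 on signal data", {
  d <- separable_data(n_per = 4, p = 6, delta = 6, sd = 0.1, seed = 11)
  pr <- permutation_test(d$X, d$y, n_permutations = 50, seed = 2)
  expect_equal(nrow(pr$permuted), 50)
  expect_gt(pr$observed["q2"], max(pr$permuted$q2, na.rm = TRUE))
  expect_lt(pr$p_value, 1 / 25)
  # a single permutation returns exactly one permuted pair
  pr1 <- permutation_test(d$X, d$y, n_permutations = 1, seed = 2)
  expect_equal(nrow(pr1$permuted), 1)
})

test_that("the permutation diagnostic shows no signal on null data", {
  cfg <- synthetic_preset("null", seed = 1)
  Xn <- relative_content(generate_peak_table(cfg))
  pr <- permutation_test(Xn, rep(c("A", "B"), each = 4),
                         n_permutations = 100, seed = 3)
  # observed model is unremarkable among permutations and the regression
  # extrapolates to a clearly non-positive Q2 at zero label correlation
  expect_gt(pr$p_value, 0.05)
  expect_lt(pr$q2_intercept, 0.2)
  expect_lt(abs(pr$q2_intercept - mean(pr$permuted$q2, na.rm = TRUE)), 0.6)
})

test_that("planted discriminant compounds attain higher mean VIP than bulk", {
  planted <- sprintf("compound-%02d", 1:4)
  tot <- stats::setNames(numeric(12), sprintf("compound-%02d", 1:12))
  for (s in 1:20) {
    cfg <- synthetic_preset("strong-signal", seed = s)
    pt <- generate_peak_table(cfg)
    v <- compute_vip(fit_oplsda(relative_content(pt), pt$samples$group))
    tot[v$compound] <- tot[v$compound] + v$vip
  }
  expect_gt(min(tot[planted]), max(tot[setdiff(names(tot), planted)]))
})

test_that("PCA explains variance in decreasing order and reconstructs X", {
  # rank-1 matrix: PC1 carries everything
  X <- outer(1:5, c(1, 2, 3)); colnames(X) <- c("a", "b", "c")
  p <- fit_pca(X, n_components = 2, scale. = FALSE)
  expect_equal(p$explained[1], 1, tolerance = 1e-9)

  d <- separable_data(n_per = 3, p = 5, seed = 13)
  pc <- stats::prcomp(d$X, center = TRUE, scale. = TRUE)
  rec <- pc$x %*% t(pc$rotation)
  expect_equal(rec, scale(d$X), ignore_attr = TRUE, tolerance = 1e-8)

  # duplicated samples give identical scores within groups
  Xd <- d$X[rep(1:2, each = 3), ]
  pd <- fit_pca(Xd, n_components = 2)
  expect_equal(pd$scores[1, ], pd$scores[2, ], tolerance = 1e-8)
  expect_warning(fit_pca(d$X, n_components = 50), "truncating")
})

test_that("PCA separates the regenerated two-species study on PC1+PC2", {
  cfg <- synthetic_preset("paper", seed = 1)
  pt <- generate_peak_table(cfg)
  p <- fit_pca(relative_content(pt), n_components = 2)
  expect_gte(sum(p$explained[1:2]), 0.6)
})
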