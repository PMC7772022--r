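test_that("z-score normalisation standardises and flags constants", {
  set.seed(1)
  x <- cbind(a = rnorm(20, 5, 3), b = runif(20), c = rep(2, 20))
  z <- normalise_attributes(x)
  expect_equal(unname(colMeans(z)), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z[, 1:2], 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_true(all(z[, "c"] == 0))
  expect_equal(unname(attr(z, "constant")), c(FALSE, FALSE, TRUE))
  ## idempotence on already-normalised data
  z2 <- normalise_attributes(z[, 1:2])
  expect_equal(unclass(z2)[, ], unclass(z[, 1:2])[, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("PCA variances match the covariance eigenvalue oracle", {
  set.seed(7)
  x <- matrix(rnorm(20), 5, 4)
  z <- normalise_attributes(x)
  p <- run_pca(z)
  expect_equal(sum(p$variance_pct), 100, tolerance = 1e-9)
  ev <- eigen(stats::cov(z))$values
  expect_equal(p$sdev^2, ev[seq_along(p$sdev)], tolerance = 1e-10)
  ## rank-1 data put all variance on the first component
  v <- rnorm(6)
  x1 <- outer(rnorm(10), v)
  p1 <- run_pca(x1)
  expect_equal(p1$variance_pct[1], 100, tolerance = 1e-9)
})

test_that("contribution floor separates dominant from negligible loadings", {
  L <- cbind(PC1 = c(1, 1e-9, 1e-12), PC2 = c(1e-10, 1e-11, 1e-13))
  rownames(L) <- c("a", "b", "c")
  pca <- structure(list(loadings = L, variance_pct = c(99, 1),
                        sdev = c(3, 0.1)), class = "pca_result")
  expect_equal(pca_contributors(pca, components = 1), "a")
  ## zero floor admits everything
  expect_setequal(pca_contributors(pca, components = 2, weight_floor = 0),
                  c("a", "b", "c"))
})

test_that("correlation mask joins Pearson and Spearman", {
  x <- seq(-2, 2, length.out = 9)
  tab <- cbind(x = x, lin = 2 * x + 1, cub = x^3)
  cm <- correlation_mask(tab, 0.9)
  expect_equal(cm$pearson["x", "lin"], 1)
  expect_equal(cm$spearman["x", "cub"], 1)
  expect_lt(cm$pearson["x", "cub"], 1)
  expect_true(cm$mask["x", "cub"])     # rank index carries it over 0.9
  expect_false(any(diag(cm$mask)))
  expect_true(isSymmetric(cm$mask * 1))
  ## brute-force Spearman on a small instance: rank-transform + Pearson
  set.seed(3)
  y1 <- rnorm(7); y2 <- rnorm(7)
  cm2 <- correlation_mask(cbind(y1, y2), 0.9)
  expect_equal(cm2$spearman[1, 2], stats::cor(rank(y1), rank(y2)),
               tolerance = 1e-12)
})

test_that("link augmentation is monotone in min_links and order-free", {
  set.seed(11)
  nm <- letters[1:8]
  m <- matrix(runif(64) < 0.35, 8, 8, dimnames = list(nm, nm))
  m <- m | t(m); diag(m) <- FALSE
  already <- c("a", "b")
  prev <- augment_by_links(m, already, 1)
  for (k in 2:5) {
    cur <- augment_by_links(m, already, k)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  ## permuting attribute order leaves the selected set unchanged
  perm <- sample(nm)
  m2 <- m[perm, perm]
  expect_setequal(augment_by_links(m2, already, 2),
                  augment_by_links(m, already, 2))
  expect_equal(augment_by_links(m & FALSE, already, 4), character(0))
  expect_equal(augment_by_links(m, already, 100), character(0))
})

test_that("the reference-study selection replays end to end", {
  m <- study_link_mask()
  aug <- augment_by_links(m, study_pca_set(), 4, sequential = TRUE)
  expect_setequal(aug, c("HP", "S3_N", "FRI_N", "FRI_T"))
  res <- prune_interdependent(union(study_pca_set(), aug),
                              pca_selected = study_pca_set(),
                              augmented = aug)
  expect_setequal(res$final,
                  c("BMI", "FPK", "FP", "HP", "TB", "S3_N", "FRI_N", "FRI_T"))
  expect_setequal(res$removed_by_interdependence, c("FAT", "STH", "CT"))
  expect_setequal(res$extension_features, c("NW", "NSA", "FA", "SAL"))
})

test_that("pruning honours rule preconditions and rejects cycles", {
  ## candidates without removable attributes pass through unchanged
  res <- prune_interdependent(c("BMI", "HP"))
  expect_setequal(res$final, c("BMI", "HP"))
  ## proxy missing: the removable attribute is retained
  res2 <- prune_interdependent(c("CT", "BMI"))
  expect_true("CT" %in% res2$final)
  expect_error(prune_interdependent("A", rules = c(A = "B", B = "A")),
               "cycle")
})

test_that("exact generating relations force the documented removals", {
  set.seed(5)
  n <- 60
  bmi <- rnorm(n, 27, 5)
  sth <- 2.3451 * bmi - 33.4440
  fat <- 71 * sth
  tb <- runif(n, 70, 95)
  tab <- cbind(BMI = bmi, STH = sth, FAT = fat, TB = tb, CT = 100 - tb,
               X = rnorm(n))
  cm <- correlation_mask(tab, 0.9)
  expect_true(cm$mask["FAT", "STH"] && cm$mask["FAT", "BMI"] &&
                cm$mask["STH", "BMI"] && cm$mask["CT", "TB"])
  res <- prune_interdependent(colnames(tab))
  expect_setequal(res$removed_by_interdependence, c("FAT", "STH", "CT"))
})
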