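test_that("log(x + 1) transform has its closed-form values and keeps order", {
  m <- matrix(c(0, exp(1) - 1, 3, 7), 2, 2)
  out <- log1_transform(m)
  expect_equal(out[1, 1], 0)
  expect_equal(out[2, 1], 1)
  expect_error(log1_transform(matrix(-1)), ">= 0")
  set.seed(5)
  col <- runif(20, 0, 1000)
  expect_identical(order(log1_transform(matrix(col))), order(col))
})

test_that("euclidean distances match a brute-force double loop", {
  m <- rbind(c(0, 0), c(3, 4))
  expect_equal(euclidean_distances(m)[1, 2], 5)
  expect_equal(diag(euclidean_distances(m)), c(0, 0))
  set.seed(17)
  for (i in 1:5) {
    x <- matrix(rnorm(50), 10, 5)
    expect_equal(unname(euclidean_distances(x)), brute_distances(x))
  }
  xm <- matrix(rnorm(20), 5, 4)
  xm[2, 3] <- NA
  expect_warning(d <- euclidean_distances(xm), "missing")
  expect_equal(dim(d), c(4, 4))
})

test_that("pco recovers the two-point closed form", {
  for (dd in c(1, 2.5, 10)) {
    d <- matrix(c(0, dd, dd, 0), 2, 2)
    p <- pco(d)
    expect_equal(length(p$var_explained), 1L)
    expect_equal(max(p$eig), dd^2 / 2)
    expect_equal(sort(p$points[, 1]), c(-dd / 2, dd / 2))
    expect_equal(p$var_explained, 1)
  }
})

test_that("pco reconstructs Euclidean configurations and matches a naive eigensolver", {
  set.seed(23)
  for (i in 1:8) {
    n <- sample(8:20, 1)
    k <- sample(2:4, 1)
    x <- matrix(rnorm(n * k, sd = 3), n, k)
    d <- euclidean_distances(x)
    p <- pco(d)
    # inter-point distances reproduced to 1e-6 relative error
    expect_lt(max(abs(as.matrix(stats::dist(p$points)) - d)) / max(d), 1e-6)
    # naive oracle: explicit-loop double centering, then eigen()
    a <- -0.5 * d^2
    b <- matrix(0, n, n)
    for (r in 1:n) {
      for (c2 in 1:n) {
        b[r, c2] <- a[r, c2] - mean(a[r, ]) - mean(a[, c2]) + mean(a)
      }
    }
    ev <- sort(eigen(b, symmetric = TRUE)$values, decreasing = TRUE)
    expect_equal(p$eig, ev, tolerance = 1e-9)
    # variance explained over positive eigenvalues sums to one
    expect_equal(sum(p$var_explained), 1, tolerance = 1e-9)
    # deterministic sign convention: largest-|coordinate| positive
    for (ax in seq_len(ncol(p$points))) {
      expect_gt(p$points[which.max(abs(p$points[, ax])), ax], 0)
    }
  }
})

test_that("pco agrees with classical metric scaling and flags bad input", {
  set.seed(4)
  x <- matrix(rnorm(36), 12, 3)
  d <- euclidean_distances(x)
  p <- pco(d)
  cm <- suppressWarnings(stats::cmdscale(d, k = 11, eig = TRUE))
  expect_equal(p$eig, cm$eig, tolerance = 1e-9)
  expect_equal(abs(p$points[, 1:2]), abs(cm$points[, 1:2]),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(pco(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  # a metric but non-Euclidean distance matrix warns about negative eigenvalues
  dn <- matrix(1, 4, 4) - diag(4)
  dn[1, 2] <- dn[2, 1] <- 1.9
  expect_warning(pco(dn), "negative eigenvalue")
})

test_that("weighted-average scores are weighted centroids of coordinates", {
  set.seed(9)
  x <- matrix(rnorm(24), 8, 3)
  p <- pco(euclidean_distances(x))
  coords <- p$points
  # delta weights pick out one observation
  w <- matrix(0, 8, 2, dimnames = list(NULL, c("a", "b")))
  w[3, 1] <- 5
  w[, 2] <- 1
  sc <- weighted_average_scores(w, coords)
  expect_equal(sc["a", ], coords[3, ])
  # uniform weights land on the centroid, the origin for centred axes
  expect_equal(unname(sc["b", ]), rep(0, ncol(coords)), tolerance = 1e-10)
  # brute-force weighted mean oracle
  wr <- matrix(runif(16), 8, 2, dimnames = list(NULL, c("u", "v")))
  sc <- weighted_average_scores(wr, coords)
  for (j in 1:2) {
    for (ax in seq_len(ncol(coords))) {
      expect_equal(sc[j, ax],
                   sum(wr[, j] * coords[, ax]) / sum(wr[, j]))
    }
  }
  wz <- cbind(wr, z = 0)
  expect_warning(sc <- weighted_average_scores(wz, coords), "all-zero")
  expect_true(all(is.na(sc["z", ])))
  expect_error(weighted_average_scores(-wr, coords), ">= 0")
})

test_that("observed pseudo-F matches the brute-force group-loop oracle", {
  set.seed(77)
  for (i in 1:10) {
    n <- sample(8:14, 1)
    a <- sample(2:3, 1)
    g <- factor(sample(letters[1:a], n, replace = TRUE))
    while (nlevels(droplevels(g)) < a) {
      g <- factor(sample(letters[1:a], n, replace = TRUE))
    }
    x <- matrix(rnorm(n * 3), n, 3)
    d <- euclidean_distances(x)
    pm <- permanova(d, g, n_perm = 9, seed = i)
    expect_equal(pm$pseudo_f, brute_pseudo_f(d, g))
    expect_equal(pm$r2, pm$ss[["among"]] / pm$ss[["total"]])
  }
})

test_that("permanova is invariant to relabeling and translation", {
  set.seed(13)
  n <- 10
  x <- matrix(rnorm(n * 2), n, 2)
  g <- factor(rep(c("a", "b"), each = 5))
  d <- euclidean_distances(x)
  f0 <- permanova(d, g, n_perm = 9, seed = 1)$pseudo_f
  # permute rows of d together with the labels
  perm <- sample(n)
  expect_equal(permanova(d[perm, perm], g[perm], n_perm = 9, seed = 1)$pseudo_f,
               f0)
  # translating every observation leaves distances, hence F, unchanged
  shifted <- sweep(x, 2, c(100, -42), "+")
  expect_equal(permanova(euclidean_distances(shifted), g,
                         n_perm = 9, seed = 1)$pseudo_f, f0)
})

test_that("permanova agrees with an independent distance-based MANOVA", {
  skip_if_not_installed("vegan")
  set.seed(41)
  x <- matrix(rnorm(45), 15, 3)
  g <- factor(rep(c("a", "b", "c"), each = 5))
  d <- euclidean_distances(x)
  pm <- permanova(d, g, n_perm = 99, seed = 2)
  ad <- vegan::adonis2(stats::as.dist(d) ~ g, permutations = 99)
  expect_equal(pm$pseudo_f, ad$F[1], tolerance = 1e-10)
  expect_equal(pm$r2, ad$R2[1], tolerance = 1e-10)
})

test_that("degenerate permanova inputs are flagged, not hidden", {
  # identical points within groups, separated groups: F diverges
  pts <- rbind(matrix(0, 3, 2), matrix(10, 3, 2))
  d <- euclidean_distances(pts)
  g <- factor(rep(c("A", "B"), each = 3))
  pm <- permanova(d, g, n_perm = 999, seed = 3)
  expect_true(is.infinite(pm$pseudo_f))
  expect_equal(pm$r2, 1)
  expect_gte(pm$p_value, 1 / 1000)
  # all observations identical: degenerate, F undefined
  d0 <- matrix(0, 6, 6)
  pm0 <- permanova(d0, g, n_perm = 99, seed = 3)
  expect_true(pm0$degenerate)
  expect_true(is.nan(pm0$pseudo_f))
  expect_error(permanova(d, factor(rep("A", 6))), "two groups")
})

test_that("the seasonal variable matrix assembles the expected columns", {
  s <- generate_survey(seed = 2)
  vm <- build_variable_matrix(s)
  expect_true(all(c("Temp", "LOI", "pH", "G1000", "G0063", "AG_B", "BG_B",
                    "D_B", "AG_C", "BG_P", "S_C", "S_N", "S_P") %in%
                    colnames(vm$matrix)))
  expect_equal(nrow(vm$matrix), nrow(vm$meta))
  # sediment stock variables use the thin surface layer by default (1 cm)
  i <- 1
  key <- vm$meta[i, ]
  sed <- s$sediment[s$sediment$species == key$species &
                      s$sediment$site == key$site &
                      s$sediment$date == key$date &
                      s$sediment$replicate == key$replicate, ]
  ct <- s$contents[s$contents$species == key$species &
                     s$contents$site == key$site &
                     s$contents$date == key$date &
                     s$contents$replicate == key$replicate &
                     s$contents$matrix == "sediment" &
                     s$contents$element == "C", ]
  expect_equal(vm$matrix[i, "S_C"],
               sediment_stock(ct$percent, sed$bulk_density_g_cm3, 1),
               ignore_attr = TRUE)
})
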