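#' Natural-log(x + 1) transform of a variable matrix
#'
#' Standard variance-stabilising transform for ecological variables mixing
#' large biomasses with percentages: `log(x + 1)` maps 0 to 0 and compresses
#' the upper tail while keeping every column's ordering. Negative values are
#' an error.
#'
#' @param m Numeric matrix or data frame, all values >= 0.
#' @return Matrix of the same shape.
#' @export
log1_transform <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m)) stop("matrix must be numeric", call. = FALSE)
  if (any(m < 0, na.rm = TRUE)) {
    stop("log(x + 1) transform requires all values >= 0", call. = FALSE)
  }
  log1p(m)
}

#' Euclidean distance matrix between observations
#'
#' d(i, j) = sqrt(sum_k (x_ik - x_jk)^2), returned as a full symmetric
#' matrix with zero diagonal. Rows containing missing values are dropped
#' with a warning before computing distances.
#'
#' @param m Numeric matrix or data frame; rows are observations.
#' @return Square symmetric matrix of distances, with row names preserved.
#' @export
euclidean_distances <- function(m) {
  m <- as.matrix(m)
  bad <- which(apply(m, 1, anyNA))
  if (length(bad)) {
    warning("dropping ", length(bad), " row(s) with missing values",
            call. = FALSE)
    m <- m[-bad, , drop = FALSE]
  }
  d <- as.matrix(stats::dist(m, method = "euclidean"))
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

.check_distance_matrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8 * max(1, max(abs(d)))) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero",
                              call. = FALSE)
  if (any(d < 0)) stop("distances must be >= 0", call. = FALSE)
  d
}

#' Principal coordinates analysis (metric multidimensional scaling)
#'
#' Classical metric scaling of a distance matrix: the squared distances are
#' Gower-transformed (`A = -d^2 / 2`), double-centred
#' (`B = (I - 11'/n) A (I - 11'/n)`) and eigendecomposed. Coordinates are
#' eigenvectors scaled by the square root of their eigenvalues; axes are
#' ordered by descending eigenvalue and kept while
#' `lambda > eig_tol * lambda_max` (suppressing numerically-zero axes).
#' Variance explained is computed over the positive eigenvalues only, the
#' classical convention for Euclidean input, where negative eigenvalues
#' cannot occur; if materially negative eigenvalues do occur (non-Euclidean
#' input) they are reported with a warning.
#'
#' The sign of each axis is fixed deterministically: the coordinate with the
#' largest absolute value on the axis is made positive, so results are
#' reproducible across linear-algebra backends.
#'
#' @param d Distance matrix (full symmetric form or `dist`).
#' @param eig_tol Relative eigenvalue tolerance for keeping an axis
#'   (default 1e-8).
#' @return Object of class `pco`: list with `points` (n x k coordinates),
#'   `eig` (all eigenvalues, descending), `var_explained` (fraction per kept
#'   axis) and `negative_eig` (any eigenvalues below `-eig_tol * lambda_max`).
#' @export
pco <- function(d, eig_tol = 1e-8) {
  d <- .check_distance_matrix(d)
  n <- nrow(d)
  a <- -0.5 * d^2
  ctr <- diag(n) - matrix(1 / n, n, n)
  b <- ctr %*% a %*% ctr
  b <- (b + t(b)) / 2  # enforce exact symmetry before eigen()
  e <- eigen(b, symmetric = TRUE)
  lambda <- e$values
  lambda_max <- max(lambda, 0)
  neg <- lambda[lambda < -eig_tol * max(lambda_max, .Machine$double.eps)]
  if (length(neg)) {
    warning("distance matrix is not Euclidean-embeddable: ",
            length(neg), " negative eigenvalue(s), largest magnitude ",
            format(max(abs(neg)), digits = 4), call. = FALSE)
  }
  keep <- which(lambda > eig_tol * max(lambda_max, .Machine$double.eps))
  pts <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(lambda[keep]), length(keep))
  # deterministic sign: largest-|coordinate| on each axis is positive
  for (k in seq_len(ncol(pts))) {
    j <- which.max(abs(pts[, k]))
    if (pts[j, k] < 0) pts[, k] <- -pts[, k]
  }
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("PCO", seq_len(ncol(pts)))
  pos_sum <- sum(lambda[lambda > 0])
  structure(
    list(points = pts, eig = lambda,
         var_explained = if (pos_sum > 0) lambda[keep] / pos_sum else
           numeric(0),
         negative_eig = neg),
    class = "pco")
}

#' @export
print.pco <- function(x, ...) {
  cat("<pco> ", nrow(x$points), " observations, ", ncol(x$points),
      " axes\n", sep = "")
  k <- min(4L, ncol(x$points))
  if (k > 0) {
    cat("  variance explained:",
        paste0(sprintf("%.1f%%", 100 * x$var_explained[seq_len(k)]),
               collapse = ", "),
        if (ncol(x$points) > k) "..." else "", "\n")
  }
  invisible(x)
}

#' Ordination scatter of the first two principal coordinate axes
#'
#' @param x A `pco` object.
#' @param groups Optional factor used to colour points.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pco <- function(x, groups = NULL, ...) {
  if (ncol(x$points) < 2L) stop("need at least two axes to plot", call. = FALSE)
  col <- if (is.null(groups)) 1L else as.integer(factor(groups))
  graphics::plot(x$points[, 1], x$points[, 2], col = col, pch = 19,
                 xlab = sprintf("PCO1 (%.1f%%)", 100 * x$var_explained[1]),
                 ylab = sprintf("PCO2 (%.1f%%)", 100 * x$var_explained[2]),
                 ...)
  if (!is.null(groups)) {
    graphics::legend("topright", legend = levels(factor(groups)),
                     col = seq_along(levels(factor(groups))), pch = 19)
  }
  invisible(x)
}

#' Weighted-average variable scores on ordination axes
#'
#' Projects each (non-negative) variable onto the ordination: the score of
#' variable j on axis k is the weighted mean of the observation coordinates,
#' weighted by the variable's values, `sum_i x_ij u_ik / sum_i x_ij`. A
#' variable concentrated on one observation lands at that observation's
#' coordinates; a uniform variable lands at the centroid. All-zero columns
#' have undefined scores (`NA` with a warning).
#'
#' @param m Non-negative matrix of variables (rows match the ordination's
#'   observations).
#' @param coords Coordinate matrix, e.g. `pco(d)$points`.
#' @return Matrix variable x axis of scores.
#' @export
weighted_average_scores <- function(m, coords) {
  m <- as.matrix(m)
  coords <- as.matrix(coords)
  if (nrow(m) != nrow(coords)) {
    stop("variable matrix and coordinates must have matching rows",
         call. = FALSE)
  }
  if (any(m < 0)) stop("weights must be >= 0", call. = FALSE)
  tot <- colSums(m)
  scores <- t(m) %*% coords / tot  # recycles tot down rows of (var x axis)
  zero <- which(tot == 0)
  if (length(zero)) {
    warning("all-zero variable column(s): ",
            paste(colnames(m)[zero], collapse = ", "),
            "; scores undefined", call. = FALSE)
    scores[zero, ] <- NA_real_
  }
  rownames(scores) <- colnames(m)
  colnames(scores) <- colnames(coords)
  scores
}

# sums of squares decomposition of a distance matrix under a grouping:
# SS_total = sum_{i<j} d_ij^2 / N ; SS_within = sum_g sum_{i<j in g} d2/n_g
.permanova_ss <- function(d2, groups) {
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1L) {
      sub <- d2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  c(total = ss_total, within = ss_within)
}

#' One-way permutational multivariate analysis of variance
#'
#' Partitions the total sum of squared interpoint distances into among- and
#' within-group components and tests the among-group component with a
#' pseudo-F statistic under random permutations of the group labels:
#' \deqn{F = \frac{SS_A / (a - 1)}{SS_W / (N - a)}}
#' with `SS_T = sum_{i<j} d_ij^2 / N`, `SS_W = sum_g sum_{i<j in g}
#' d_ij^2 / n_g` and `SS_A = SS_T - SS_W`. The p-value uses the add-one
#' convention `p = (1 + #{F* >= F}) / (1 + n_perm)`, so the smallest
#' attainable p is `1 / (n_perm + 1)`. Permutations are full uniform label
#' shuffles drawn with the given seed; the identity permutation is not
#' specially excluded.
#'
#' Degenerate cases are flagged rather than hidden: identical points within
#' groups but separated groups give `F = Inf`; a fully constant dataset
#' gives `F = NaN` with `degenerate = TRUE`.
#'
#' @param d Distance matrix (full symmetric form or `dist`).
#' @param groups Factor (or coercible) of group labels, one per observation;
#'   at least two groups.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @return Object of class `permanova`: list with `pseudo_f`, `r2`,
#'   `p_value`, `ss` (among/within/total), `df`, `n_perm`, `seed`,
#'   `degenerate`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1) {
  d <- .check_distance_matrix(d)
  groups <- factor(groups)
  n <- nrow(d)
  if (length(groups) != n) stop("one group label per observation",
                                call. = FALSE)
  a <- nlevels(groups)
  if (a < 2L) stop("need at least two groups", call. = FALSE)
  if (n < a + 1L) stop("need more observations than groups", call. = FALSE)
  d2 <- d^2

  ss <- .permanova_ss(d2, groups)
  ss_within <- ss[["within"]]
  if (ss_within < 0) {  # cannot occur except by numerical error
    warning("negative within-group sum of squares clamped to 0",
            call. = FALSE)
    ss_within <- 0
  }
  ss_among <- ss[["total"]] - ss_within
  df_among <- a - 1L
  df_within <- n - a
  f_obs <- (ss_among / df_among) / (ss_within / df_within)
  r2 <- if (ss[["total"]] > 0) ss_among / ss[["total"]] else NaN
  degenerate <- ss[["total"]] == 0

  # vectorised permutation null: for each group, an n x n_perm membership
  # indicator Z gives the within-group SS as colSums(Z * (D2 Z)) / (2 n_g)
  set.seed(seed)
  perm_labels <- replicate(n_perm, sample.int(n))
  f_perm <- rep(NaN, n_perm)
  if (!degenerate) {
    ss_w_perm <- numeric(n_perm)
    for (g in levels(groups)) {
      members <- groups == g
      n_g <- sum(members)
      if (n_g < 2L) next
      z <- matrix(0, n, n_perm)
      z[cbind(as.vector(perm_labels[members, ]),
              rep(seq_len(n_perm), each = n_g))] <- 1
      ss_w_perm <- ss_w_perm + colSums(z * (d2 %*% z)) / (2 * n_g)
    }
    ss_a_perm <- ss[["total"]] - ss_w_perm
    f_perm <- (ss_a_perm / df_among) / (ss_w_perm / df_within)
  }
  # Inf >= Inf is TRUE, so a diverging observed F is only matched by
  # permutations that also fully separate the groups
  p <- (1 + sum(f_perm >= f_obs, na.rm = TRUE)) / (1 + n_perm)

  structure(
    list(pseudo_f = f_obs, r2 = r2, p_value = p,
         ss = c(among = unname(ss_among), within = unname(ss_within),
                total = unname(ss[["total"]])),
         df = c(among = df_among, within = df_within),
         n_perm = n_perm, seed = seed, degenerate = degenerate),
    class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat("<permanova> one-way, ", x$n_perm, " permutations (seed ", x$seed,
      ")\n", sep = "")
  cat(sprintf("  pseudo-F = %s on (%d, %d) df,  R2 = %.3f,  p = %.4g\n",
              format(x$pseudo_f, digits = 4), x$df[["among"]],
              x$df[["within"]], x$r2, x$p_value))
  if (x$degenerate) cat("  NOTE: all observations identical; test degenerate\n")
  invisible(x)
}

#' Assemble the seasonal-dynamics variable matrix from a survey
#'
#' Builds the observation x variable table used by the multivariate seasonal
#' analysis: one row per (species, site, date, replicate), with sediment
#' temperature (`Temp`), organic matter (`LOI`), `pH`, the six particle-size
#' fractions (`G1000`...`G0063`), above/belowground/litter biomass (`AG_B`,
#' `BG_B`, `D_B`), plant element contents (`AG_C`, `BG_C`, `AG_N`, `BG_N`,
#' `AG_P`, `BG_P`) and sediment element stocks over a thin surface layer
#' (`S_C`, `S_N`, `S_P`; depth set by `s_depth_cm`, default 1 cm). Rows with
#' missing cells are dropped with a warning.
#'
#' @param survey A `marsh_survey`.
#' @param s_depth_cm Depth basis for the sediment stock variables
#'   (default 1 cm).
#' @return List with `matrix` (numeric matrix) and `meta` (tibble of
#'   `species`, `site`, `date`, `replicate` per retained row).
#' @export
build_variable_matrix <- function(survey, s_depth_cm = 1) {
  stopifnot(inherits(survey, "marsh_survey"))
  b <- survey$biomass
  ct <- survey$contents
  s <- survey$sediment

  key_cols <- c("species", "site", "date", "replicate")
  wide_b <- b %>%
    dplyr::mutate(var = c(aboveground = "AG_B", belowground = "BG_B",
                          litter = "D_B")[.data$compartment]) %>%
    dplyr::select(dplyr::all_of(key_cols), "var", value = "dry_mass_g_m2") %>%
    tidyr::pivot_wider(names_from = "var", values_from = "value")
  wide_ct <- ct %>%
    dplyr::filter(.data$matrix != "sediment") %>%
    dplyr::mutate(var = paste0(
      c(aboveground = "AG", belowground = "BG")[.data$matrix], "_",
      .data$element)) %>%
    dplyr::select(dplyr::all_of(key_cols), "var", value = "percent") %>%
    tidyr::pivot_wider(names_from = "var", values_from = "value")
  sed_stock <- ct %>%
    dplyr::filter(.data$matrix == "sediment") %>%
    dplyr::inner_join(
      s %>% dplyr::select(dplyr::all_of(key_cols), "bulk_density_g_cm3"),
      by = key_cols) %>%
    dplyr::mutate(
      var = paste0("S_", .data$element),
      value = sediment_stock(.data$percent, .data$bulk_density_g_cm3,
                             s_depth_cm)) %>%
    dplyr::select(dplyr::all_of(key_cols), "var", "value") %>%
    tidyr::pivot_wider(names_from = "var", values_from = "value")
  wide_s <- s %>%
    dplyr::select(dplyr::all_of(key_cols), Temp = "temperature_c",
                  LOI = "loi_percent", pH = "ph", G1000 = "g1000",
                  G500 = "g500", G250 = "g250", G125 = "g125", G063 = "g063",
                  G0063 = "g0063")

  wide <- wide_s %>%
    dplyr::inner_join(wide_b, by = key_cols) %>%
    dplyr::left_join(wide_ct, by = key_cols) %>%
    dplyr::left_join(sed_stock, by = key_cols)

  vars <- c("Temp", "LOI", "pH", "G1000", "G500", "G250", "G125", "G063",
            "G0063", "AG_B", "BG_B", "D_B", "AG_C", "BG_C", "AG_N", "BG_N",
            "AG_P", "BG_P", "S_C", "S_N", "S_P")
  vars <- intersect(vars, names(wide))
  m <- as.matrix(wide[vars])
  keep <- !apply(m, 1, anyNA)
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " observation(s) with missing variables",
            call. = FALSE)
  }
  list(matrix = m[keep, , drop = FALSE],
       meta = wide[keep, key_cols])
}
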