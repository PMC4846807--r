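# Assemblage structure among stands: pairwise dissimilarity, group-average
# (UPGMA) clustering, and correspondence analysis of the stand x species
# abundance matrix.

#' Pairwise dissimilarity between stands
#'
#' Bray-Curtis dissimilarity on raw abundances by default (values in
#' `[0, 1]`, 0 for identical stands, 1 for disjoint species sets); a
#' chi-square distance option is provided for methodological consistency
#' with correspondence analysis.
#'
#' @param mat Stand x species abundance matrix (see
#'   [stand_species_matrix()]).
#' @param metric `"bray"` (default) or `"chisq"`.
#' @return A `dist` object with stand codes as labels.
#' @export
stand_distance <- function(mat, metric = c("bray", "chisq")) {
  metric <- arg_match(metric)
  if (nrow(mat) < 2) abort("Need at least 2 stands")
  if (any(rowSums(mat) == 0)) abort("All-zero stand row(s) present")
  vegan::vegdist(mat, method = metric)
}

#' Group-average (UPGMA) clustering of stands
#'
#' Agglomerative clustering in which the distance between two clusters is
#' the mean of all cross-pair distances.  Merge heights are nondecreasing;
#' equal-height ties are resolved by the agglomeration order of the
#' underlying implementation (lowest merge index first), which is
#' deterministic for a given input ordering.
#'
#' @param d A `dist` object (e.g. from [stand_distance()]).
#' @param k Number of groups for the cut (default 2).
#' @return A list of class `"stand_clust"`: `hclust` (the dendrogram),
#'   `groups` (named integer vector of group labels at `k`), and `k`.
#' @export
cluster_stands <- function(d, k = 2) {
  hc <- hclust(d, method = "average")
  groups <- cutree(hc, k = k)
  structure(list(hclust = hc, groups = groups, k = k),
            class = "stand_clust")
}

#' @export
print.stand_clust <- function(x, ...) {
  cat("UPGMA clustering of", length(x$groups), "stands, cut at k =", x$k, "\n")
  print(split(names(x$groups), x$groups))
  invisible(x)
}

#' @export
tidy.stand_clust <- function(x, ...) {
  tibble(label = names(x$groups), group = unname(x$groups))
}

#' Export a dendrogram as a Newick string
#'
#' @param x A `stand_clust` object or an `hclust`.
#' @param digits Significant digits for branch lengths.
#' @return A Newick-format character scalar (branch lengths from merge
#'   heights, leaves at height 0).
#' @export
as_newick <- function(x, digits = 6) {
  hc <- if (inherits(x, "stand_clust")) x$hclust else x
  build <- function(i, parent_h) {
    if (i < 0) {
      lab <- hc$labels[-i]
      paste0(lab, ":", signif(parent_h, digits))
    } else {
      h <- hc$height[i]
      left <- build(hc$merge[i, 1], h)
      right <- build(hc$merge[i, 2], h)
      paste0("(", left, ",", right, "):", signif(parent_h - h, digits))
    }
  }
  n_merge <- nrow(hc$merge)
  h_root <- hc$height[n_merge]
  left <- build(hc$merge[n_merge, 1], h_root)
  right <- build(hc$merge[n_merge, 2], h_root)
  paste0("(", left, ",", right, ");")
}

#' Correspondence analysis of a stand x species abundance table
#'
#' Reciprocal-averaging ordination via singular value decomposition of the
#' chi-square-standardised matrix: with `P = X / sum(X)`, row masses `r`,
#' column masses `c`, decompose `D_r^{-1/2} (P - r c') D_c^{-1/2}`.  The sum
#' of the squared singular values (the principal inertias / eigenvalues)
#' equals the total inertia, which equals the Pearson chi-square statistic
#' of the table divided by its grand total.  Row and column scores are
#' returned in symmetric scaling (both standard coordinates scaled by the
#' square root of the singular values).
#'
#' @param mat Nonnegative stand x species matrix without all-zero rows or
#'   columns (all-zero columns are dropped with a warning).
#' @param n_axes Number of axes to keep (default all nontrivial ones).
#' @return A list of class `"stand_ca"`: `row_scores`, `col_scores`
#'   (matrices, axes in columns), `eigenvalues`, `total_inertia`,
#'   `prop_inertia`.
#' @export
correspondence_analysis <- function(mat, n_axes = NULL) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) abort("Matrix must be nonnegative")
  zero_col <- colSums(mat) == 0
  if (any(zero_col)) {
    warn(paste("Dropping", sum(zero_col), "all-zero species column(s)"))
    mat <- mat[, !zero_col, drop = FALSE]
  }
  if (any(rowSums(mat) == 0)) abort("All-zero row(s) present")
  N <- sum(mat)
  P <- mat / N
  r <- rowSums(P)
  cc <- colSums(P)
  Z <- diag(1 / sqrt(r)) %*% (P - r %o% cc) %*% diag(1 / sqrt(cc))
  sv <- svd(Z)
  keep <- which(sv$d > 1e-10)
  if (!is.null(n_axes)) keep <- head(keep, n_axes)
  d <- sv$d[keep]
  # standard coordinates, then symmetric scaling by sqrt(singular value)
  row_std <- diag(1 / sqrt(r)) %*% sv$u[, keep, drop = FALSE]
  col_std <- diag(1 / sqrt(cc)) %*% sv$v[, keep, drop = FALSE]
  row_scores <- row_std %*% diag(sqrt(d), nrow = length(d))
  col_scores <- col_std %*% diag(sqrt(d), nrow = length(d))
  dimnames(row_scores) <- list(rownames(mat), paste0("CA", seq_along(d)))
  dimnames(col_scores) <- list(colnames(mat), paste0("CA", seq_along(d)))
  ev <- d^2
  structure(
    list(
      row_scores = row_scores, col_scores = col_scores,
      eigenvalues = ev, total_inertia = sum(sv$d^2),
      prop_inertia = ev / sum(sv$d^2)
    ),
    class = "stand_ca"
  )
}

#' @export
print.stand_ca <- function(x, ...) {
  cat("Correspondence analysis:", nrow(x$row_scores), "stands x",
      nrow(x$col_scores), "species\n")
  cat("Total inertia:", signif(x$total_inertia, 5), "\n")
  cat("Axis inertia (%):",
      paste(signif(100 * x$prop_inertia, 3), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.stand_ca <- function(x, ...) {
  bind_rows(
    as_tibble(x$row_scores, rownames = "label") %>%
      mutate(score_type = "stand"),
    as_tibble(x$col_scores, rownames = "label") %>%
      mutate(score_type = "species")
  ) %>%
    select(score_type, label, dplyr::everything())
}

#' @export
glance.stand_ca <- function(x, ...) {
  tibble(
    n_axes = length(x$eigenvalues),
    total_inertia = x$total_inertia,
    axis1_prop = x$prop_inertia[1],
    axis2_prop = if (length(x$prop_inertia) > 1) x$prop_inertia[2] else NA_real_
  )
}

#' @export
autoplot.stand_ca <- function(object, axes = c(1, 2), ...) {
  sc <- tidy(object)
  ax <- paste0("CA", axes)
  ggplot2::ggplot(sc, ggplot2::aes(.data[[ax[1]]], .data[[ax[2]]],
                                   colour = score_type)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_text(
      data = function(d) dplyr::filter(d, score_type == "stand"),
      ggplot2::aes(label = label), vjust = -0.8, size = 3, show.legend = FALSE
    ) +
    ggplot2::labs(
      x = sprintf("CA%d (%.1f%%)", axes[1], 100 * object$prop_inertia[axes[1]]),
      y = sprintf("CA%d (%.1f%%)", axes[2], 100 * object$prop_inertia[axes[2]]),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}
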