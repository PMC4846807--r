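toy_mat <- function() {
  m <- rbind(
    A = c(10, 5, 0, 1),
    B = c(8, 6, 1, 0),
    C = c(0, 0, 12, 9)
  )
  colnames(m) <- paste0("sp", 1:4)
  m
}

test_that("Bray-Curtis distances behave at the extremes and match hand sums", {
  ident <- rbind(A = c(3, 2, 1), B = c(3, 2, 1))
  expect_equal(as.numeric(stand_distance(ident)), 0)
  disjoint <- rbind(A = c(5, 5, 0, 0), B = c(0, 0, 7, 3))
  expect_equal(as.numeric(stand_distance(disjoint)), 1)
  d <- as.matrix(stand_distance(toy_mat()))
  m <- toy_mat()
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(d[i, j], oracle_bray(m[i, ], m[j, ]), tolerance = 1e-12)
  }
  expect_error(stand_distance(m[1, , drop = FALSE]))
  expect_error(stand_distance(rbind(m, Z = c(0, 0, 0, 0))))
})

test_that("group-average clustering matches brute-force agglomeration", {
  # 3-leaf textbook case: merge (A,B) at 1, then C at 4
  d3 <- as.dist(matrix(c(0, 1, 4, 1, 0, 4, 4, 4, 0), 3,
                       dimnames = list(LETTERS[1:3], LETTERS[1:3])))
  cl <- cluster_stands(d3)
  expect_equal(cl$hclust$height, c(1, 4))
  expect_equal(unname(cl$groups[c("A", "B")]), c(1, 1))
  expect_false(cl$groups[["C"]] == cl$groups[["A"]])

  # random matrices up to 6 leaves against the brute-force oracle
  set.seed(41)
  for (i in 1:6) {
    n <- sample(4:6, 1)
    dm <- matrix(0, n, n, dimnames = list(LETTERS[1:n], LETTERS[1:n]))
    dm[lower.tri(dm)] <- runif(n * (n - 1) / 2, 0.1, 2)
    dm <- dm + t(dm)
    d <- as.dist(dm)
    oracle <- oracle_upgma(d)
    fit <- cluster_stands(d)
    expect_equal(fit$hclust$height, oracle$heights, tolerance = 1e-10)
    # two-group partition agrees (up to label swap)
    oracle_sets <- lapply(oracle$partition_k2,
                          function(idx) sort(LETTERS[1:n][idx]))
    fit_sets <- lapply(split(names(fit$groups), fit$groups), sort)
    expect_setequal(unname(oracle_sets), unname(fit_sets))
    expect_true(all(diff(fit$hclust$height) >= -1e-12))
  }
})

test_that("an ultrametric input is reproduced exactly", {
  hts <- c(A_B = 1, AB_C = 2, ABC_D = 3)
  dm <- matrix(c(0, 1, 2, 3,
                 1, 0, 2, 3,
                 2, 2, 0, 3,
                 3, 3, 3, 0), 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  cl <- cluster_stands(as.dist(dm))
  expect_equal(as.matrix(cophenetic(cl$hclust))[LETTERS[1:4], LETTERS[1:4]],
               dm)
})

test_that("newick export encodes the dendrogram topology", {
  d3 <- as.dist(matrix(c(0, 1, 4, 1, 0, 4, 4, 4, 0), 3,
                       dimnames = list(c("BA", "PT", "QA"),
                                       c("BA", "PT", "QA"))))
  nwk <- as_newick(cluster_stands(d3))
  expect_match(nwk, "^\\(.*\\);$")
  expect_match(nwk, "BA")
  tree <- if (requireNamespace("ape", quietly = TRUE)) {
    ape::read.tree(text = nwk)
  } else NULL
  if (!is.null(tree)) {
    expect_setequal(tree$tip.label, c("BA", "PT", "QA"))
  }
})

test_that("correspondence analysis recovers chi-square inertia", {
  m <- toy_mat()
  ca <- correspondence_analysis(m)
  # independent oracle: Pearson chi-square statistic / grand total
  chi <- suppressWarnings(chisq.test(m))$statistic
  expect_equal(ca$total_inertia, unname(chi) / sum(m), tolerance = 1e-10)
  expect_equal(sum(ca$eigenvalues), ca$total_inertia, tolerance = 1e-10)
  expect_true(all(diff(ca$eigenvalues) <= 1e-12))
  expect_true(all(ca$eigenvalues > 0 & ca$eigenvalues <= 1 + 1e-12))
  # row scores have zero weighted mean on every axis
  r <- rowSums(m) / sum(m)
  expect_equal(as.numeric(t(ca$row_scores) %*% r), rep(0, ncol(ca$row_scores)),
               tolerance = 1e-10)
  # cross-check eigenvalues against vegan's CA
  cca_ev <- as.numeric(vegan::cca(m)$CA$eig)
  expect_equal(as.numeric(ca$eigenvalues), cca_ev, tolerance = 1e-8)
})

test_that("reciprocal averaging links row and column scores", {
  m <- toy_mat()
  ca <- correspondence_analysis(m)
  P <- m / sum(m)
  r <- rowSums(P); cc <- colSums(P)
  sv <- sqrt(ca$eigenvalues)
  # symmetric scaling: row = D_r^-1 P col / sqrt(lambda)
  recon <- diag(1 / r) %*% P %*% ca$col_scores %*% diag(1 / sv,
                                                        length(sv))
  expect_equal(unname(recon), unname(ca$row_scores), tolerance = 1e-8)
})

test_that("a block-diagonal table is split by the first axis", {
  m <- rbind(A = c(10, 8, 0, 0), B = c(9, 11, 0, 0),
             C = c(0, 0, 7, 12), D = c(0, 0, 10, 9))
  colnames(m) <- paste0("sp", 1:4)
  ca <- correspondence_analysis(m)
  ax1 <- ca$row_scores[, 1]
  expect_true(sign(ax1[["A"]]) == sign(ax1[["B"]]))
  expect_true(sign(ax1[["C"]]) == sign(ax1[["D"]]))
  expect_true(sign(ax1[["A"]]) != sign(ax1[["C"]]))
  expect_s3_class(autoplot(ca), "ggplot")
})

test_that("clustering and ordination agree on synthetic two-belt surveys", {
  sv <- small_survey(seed = 44)
  mat <- stand_species_matrix(sv$stems)
  cl <- cluster_stands(stand_distance(mat))
  belts <- belt_of(rownames(mat))
  expect_equal(length(unique(cl$groups[belts == "birch"])), 1)
  expect_equal(length(unique(cl$groups[belts == "pine-oak"])), 1)
  ca <- correspondence_analysis(mat)
  ax1 <- ca$row_scores[, 1]
  expect_true(all(sign(ax1[belts == "birch"]) ==
                    sign(ax1[belts == "birch"][1])))
  expect_true(sign(ax1[belts == "birch"][1]) !=
                sign(ax1[belts == "pine-oak"][1]))
})
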