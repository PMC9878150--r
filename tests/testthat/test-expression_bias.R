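test_that("normalization excludes low-total samples and flags silence", {
  tpm <- matrix(c(10, 10, 10,   # balanced sample
                  8, 1, 1,      # biased sample
                  0.1, 0.1, 0.1 # below 0.5-TPM floor: excluded
                  ), nrow = 3)
  x <- normalize_triad_expression(tpm)
  expect_equal(ncol(x$proportions), 2)
  expect_equal(x$proportions[, 2], c(0.8, 0.1, 0.1))
  expect_equal(sum(x$mean_proportions), 1)
  expect_equal(x$n_samples_expressed, 2)
  silent <- normalize_triad_expression(matrix(0, 3, 4))
  expect_false(silent$expressed)
  expect_true(all(is.na(silent$mean_proportions)))
  # tissue breadth counts tissues with any qualifying sample
  y <- normalize_triad_expression(tpm, tissue = c("root", "root", "leaf"))
  expect_equal(y$n_tissues_expressed, 1)
})

test_that("the seven triad centroids are fixed points of assignment", {
  cents <- triad_centroids()
  expect_equal(dim(cents), c(7L, 3L))
  got <- assign_contribution_category(cents)
  expect_equal(got$category, rownames(cents))
  expect_equal(got$distance_to_centroid, rep(0, 7))
})

test_that("nearest-centroid assignment and the tie priority rule", {
  expect_equal(assign_contribution_category(c(0.333, 0.333, 0.334))$category,
               "balanced")
  expect_equal(assign_contribution_category(c(0.98, 0.01, 0.01))$category,
               "A_dominant")
  expect_equal(assign_contribution_category(c(0.02, 0.49, 0.49))$category,
               "A_suppressed")
  # exact midpoint of balanced and A_dominant: priority says balanced
  mid <- (c(1, 0, 0) + rep(1 / 3, 3)) / 2
  expect_equal(assign_contribution_category(mid)$category, "balanced")
  expect_error(assign_contribution_category(c(0.6, 0.6, 0.6)),
               "sum to 1")
})

test_that("assignment is scale invariant and label equivariant", {
  set.seed(1)
  for (i in 1:50) {
    p <- as.vector(wheatTEbias:::rdirichlet_rows(matrix(c(1, 1, 1), 1)))
    base <- assign_contribution_category(p)$category
    # scale invariance enters through normalization of TPM
    tpm <- matrix(p * 10, 3, 1)
    sc <- normalize_triad_expression(tpm * 37)$mean_proportions
    expect_equal(assign_contribution_category(sc)$category, base)
    # permuting slots of both proportions and centroids leaves the
    # assigned label unchanged (equivariance)
    perm <- c(2, 3, 1)
    got <- assign_contribution_category(p[perm], triad_centroids()[, perm])
    expect_equal(got$category, base)
  }
})

test_that("dyad and tetrad categories use the generalized centroids", {
  d <- contribution_centroids(c("A", "B"))
  expect_equal(rownames(d), c("balanced", "A_suppressed", "B_suppressed"))
  expect_equal(assign_contribution_category(c(0.5, 0.5), d)$category,
               "balanced")
  expect_equal(assign_contribution_category(c(0.05, 0.95), d)$category,
               "A_suppressed")
  q <- contribution_centroids(c("A", "B", "C", "D"))
  expect_equal(assign_contribution_category(c(0.02, 0.02, 0.48, 0.48),
                                            q)$category, "AB_suppressed")
  expect_equal(assign_contribution_category(c(0.97, 0.01, 0.01, 0.01),
                                            q)$category, "A_dominant")
  expect_equal(assign_contribution_category(c(0.01, 0.33, 0.33, 0.33),
                                            q)$category, "A_suppressed")
})

test_that("eligibility needs synteny and six of fifteen tissues", {
  df <- data.frame(group_id = c("a", "b", "c"),
                   syntenic = c(TRUE, TRUE, FALSE),
                   n_tissues_expressed = c(7, 5, 15))
  out <- select_analysis_triads(df)
  expect_equal(out$eligible, c(TRUE, FALSE, FALSE))
  expect_error(select_analysis_triads(df[, -2]), "syntenic")
})

test_that("batch summary agrees with the per-group normalizer", {
  set.seed(8)
  members <- data.frame(
    group_id = rep(c("t1", "t2"), each = 3),
    gene_id = paste0("g", 1:6),
    subgenome = rep(c("A", "B", "D"), 2),
    cardinality = 3)
  expr <- matrix(rlnorm(6 * 10, 1, 1), 6, 10,
                 dimnames = list(paste0("g", 1:6), NULL))
  expr[4:6, 1:8] <- 0  # t2 expressed in 2 samples only
  tissue <- rep(c("ta", "tb"), each = 5)
  got <- group_expression_summary(members, expr, tissue = tissue)
  for (i in 1:2) {
    ref <- normalize_triad_expression(expr[members$group_id ==
                                             got$group_id[i], ],
                                      tissue = tissue)
    expect_equal(unlist(got[i, c("prop_A", "prop_B", "prop_D")]),
                 ref$mean_proportions, ignore_attr = TRUE)
    expect_equal(got$n_tissues_expressed[i], ref$n_tissues_expressed)
  }
  expect_equal(category_family(got$category) %in%
                 c("balanced", "suppressed", "dominant"), c(TRUE, TRUE))
})
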