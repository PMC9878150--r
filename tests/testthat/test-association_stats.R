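# Counts reproduced throughout: 2,386 TE-containing expressed dyads of
# which 1,312 polymorphic (one gene with TE) and 1,074 monomorphic (both).

test_that("single-gene TE probability is the per-gene fraction", {
  dyads <- rep(c(1L, 2L), c(1312, 1074))
  expect_equal(single_gene_te_probability(dyads, 2), 3460 / 4772)
  expect_equal(single_gene_te_probability(rep(2, 10), 2), 1)
  # k = 3 hand count: groups with 1,2,3 TE genes
  expect_equal(single_gene_te_probability(c(1, 2, 3, 3), 3), 9 / 12)
  expect_error(single_gene_te_probability(integer(), 2), "no TE")
  expect_error(single_gene_te_probability(c(0, 1), 2), "1..k")
})

test_that("conditional morphism probabilities match closed forms", {
  pr <- conditional_morphism_probabilities(3460 / 4772, 2)
  expect_equal(unname(pr["poly"]) * 100, 43.13, tolerance = 1e-4)
  expect_equal(sum(pr), 1)
  expect_equal(unname(conditional_morphism_probabilities(1, 3)["poly"]), 0)
  expect_equal(unname(conditional_morphism_probabilities(0.5, 2)["poly"]),
               2 / 3)
  expect_error(conditional_morphism_probabilities(0, 2), "conditioning")
})

test_that("conditional probabilities agree with 2^k enumeration", {
  for (k in 2:4) for (p in seq(0.05, 0.95, by = 0.09)) {
    expect_equal(conditional_morphism_probabilities(p, k),
                 oracle_conditional_morphism(p, k), tolerance = 1e-12)
  }
})

test_that("expected counts scale the conditional probabilities", {
  dyads <- rep(c(1L, 2L), c(1312, 1074))
  fit <- fit_morphism_null(dyads, 2)
  e <- expected_morphism_counts(fit)
  expect_equal(sum(e), 2386)
  expect_equal(unname(round(e["poly"])), 1029)
  expect_equal(fit$chi2, 136.78, tolerance = 5e-5)
  # degenerate all-monomorphic fit
  fit1 <- fit_morphism_null(rep(3L, 20), 3)
  expect_equal(unname(expected_morphism_counts(fit1)["poly"]), 0)
})

test_that("goodness of fit is plain Pearson with df = cells - 1", {
  expect_equal(goodness_of_fit(c(10, 0), c(5, 5))$chi2, 10)
  g <- goodness_of_fit(c(7, 3), c(7, 3))
  expect_equal(g$chi2, 0)
  expect_equal(g$p_value, 1)
  expect_error(goodness_of_fit(c(1, 2), c(0, 3)), "positive")
})

test_that("independence test: Yates iff 2x2, none for wider tables", {
  # any 2x2 equals the hand formula N(|ad - bc| - N/2)^2 / margins
  set.seed(4)
  for (i in 1:50) {
    tab <- matrix(sample(5:400, 4), 2)
    it <- independence_test(tab)
    a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
    n <- sum(tab)
    hand <- n * max(0, abs(a * d - b * cc) - n / 2)^2 /
      (prod(rowSums(tab)) * prod(colSums(tab)) / n^2) / n^2
    expect_equal(it$chi2, hand, tolerance = 1e-10)
  }
  # proportional rows: statistic 0 pre-correction, p ~ 1
  it0 <- independence_test(rbind(c(10, 20), c(30, 60)), correct = FALSE)
  expect_equal(it0$chi2, 0)
  expect_equal(it0$p_value, 1)
  # 2x3 without correction, df = 2
  t23 <- rbind(c(30, 50, 20), c(10, 40, 60))
  it23 <- independence_test(t23)
  expect_equal(it23$df, 2)
  expect_equal(it23$chi2,
               suppressWarnings(chisq.test(t23, correct = FALSE)$statistic),
               ignore_attr = TRUE)
  expect_error(independence_test(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("BH adjustment matches the hand step-up and is monotone", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(9)
  for (i in 1:20) {
    p <- runif(sample(2:40, 1))
    q <- bh_adjust(p)
    expect_true(all(q >= p - 1e-12))
    expect_equal(q[order(p)], sort(q))  # q monotone in raw p
    expect_equal(q, p.adjust(p, "BH"))  # reference implementation
  }
})

test_that("screens build the published-style 2x2 cells and filter them", {
  # universe of 7,439 TE-containing triads with the printed balanced split
  set.seed(2)
  n_bal <- 6384; n_non <- 1055
  cats <- data.frame(
    group_id = sprintf("T%04d", 1:7439),
    category = c(rep("balanced", n_bal),
                 rep(c("A_suppressed", "B_dominant"), length.out = n_non)))
  mk_presence <- function(te_group, yes_in, yes_out) {
    data.frame(group_id = c(cats$group_id[seq_len(yes_in)],
                            cats$group_id[n_bal + seq_len(yes_out)]),
               te_group = te_group)
  }
  presence <- rbind(
    mk_presence("SIX", 12, 8),      # printed SIX row
    mk_presence("RLC", 1132, 227),  # printed RLC row
    mk_presence("DTA", 7, 2),       # fails the >= 5 filter
    mk_presence("DHH", 1, 1))
  res <- screen_te_groups(cats, presence, "balanced")
  six <- res[res$te_group == "SIX", ]
  expect_true(six$included)
  expect_equal(unlist(six[c("yes_in", "no_in", "yes_out", "no_out")]),
               c(yes_in = 12, no_in = 6372, yes_out = 8, no_out = 1047))
  expect_false(any(res$included[res$te_group %in% c("DTA", "DHH")]))
  expect_true(all(is.na(res$q[res$te_group %in% c("DTA", "DHH")])))
  # RLC enrichment among balanced is below expectation: negative direction
  rlc <- res[res$te_group == "RLC", ]
  expect_equal(rlc$direction, "negative")
  expect_true(all(res$q >= res$p_raw - 1e-12, na.rm = TRUE))
  # ordering invariance
  res2 <- screen_te_groups(cats[sample(nrow(cats)), ],
                           presence[sample(nrow(presence)), ], "balanced")
  expect_equal(res, res2)
  expect_error(screen_te_groups(cats[0, ], presence, "balanced"), "empty")
})

test_that("suppressed/dominant comparisons pool the per-subgenome labels", {
  cats <- data.frame(
    group_id = sprintf("T%02d", 1:40),
    category = rep(c("balanced", "A_suppressed", "B_suppressed",
                     "D_dominant"), each = 10))
  presence <- data.frame(group_id = cats$group_id[c(1:8, 11:18, 21:24)],
                         te_group = "DTM")
  sup <- screen_te_groups(cats, presence, "suppressed")
  expect_equal(unlist(sup[1, c("yes_in", "no_in", "yes_out", "no_out")]),
               c(yes_in = 12, no_in = 8, yes_out = 8, no_out = 12))
  dom <- screen_te_groups(cats, presence, "dominant")
  expect_equal(dom$yes_in, 0)
  expect_false(dom$included)
})
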