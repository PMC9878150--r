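# The generator is exercised at reduced sizes here; the full stated-world
# defaults (6,320/18,390/752 groups, 123 samples) are only scaled down for
# test runtime, never re-tuned. The planted-recovery acceptance runs at the
# stated ~14,000-triad scale in test-acceptance.R.

small_cfg <- function(seed = 1, ...) {
  simulation_config(seed = seed, n_dyads = 150, n_triads = 400,
                    n_tetrads = 30, n_samples = 20, n_tissues = 8,
                    chrom_length = 5e6, ...)
}

test_that("a fixed seed makes the generator byte-identical", {
  d1 <- generate_dataset(small_cfg(3))
  d2 <- generate_dataset(small_cfg(3))
  expect_identical(d1$genes, d2$genes)
  expect_identical(d1$tes, d2$tes)
  expect_identical(d1$expression, d2$expression)
  expect_identical(d1$gene_to_go, d2$gene_to_go)
  d3 <- generate_dataset(small_cfg(4))
  expect_false(identical(d1$tes, d3$tes))
})

test_that("p = 0 everywhere yields zero TE-containing groups", {
  ds <- generate_dataset(small_cfg(5, p_te = c(proximal = 0, distal = 0),
                                   frac_nuisance_te = 0))
  expect_equal(nrow(ds$tes), 0)
  rep <- suppressMessages(recover_parameters(ds))
  expect_true(all(rep$groups$morphism == "no_te"))
  expect_length(rep$null_models, 0)
})

test_that("marginal TE presence converges to the configured rates", {
  cfg <- simulation_config(seed = 6, n_dyads = 0, n_triads = 4000,
                           n_tetrads = 0, n_samples = 4, n_tissues = 2,
                           chrom_length = 5e7, frac_nuisance_te = 0)
  ds <- generate_dataset(cfg)
  rr <- repeat_regions(ds$tes, quiet = TRUE)
  ov <- find_te_insertions(ds$genes, rr)
  content <- summarize_gene_te_content(ds$genes$gene_id, ov, rr)
  genes_r <- assign_chromosomal_region(ds$genes, ds$partition)
  for (mac in c("proximal", "distal")) {
    sel <- genes_r$macro == mac
    rate <- mean(content$has_te_gene_body[sel])
    p <- unname(cfg$p_te[mac])
    # 99.9% binomial band around the configured probability
    half <- 3.29 * sqrt(p * (1 - p) / sum(sel))
    expect_lt(abs(rate - p), half + 0.005)
  }
})

test_that("polymorphic fraction follows the closed form at p = 0.4", {
  # presence primitive at n = 10,000 triads, uniform p = 0.4
  set.seed(10)
  pres <- wheatTEbias:::sample_te_presence(10000, 3, 0.4)
  cnt <- rowSums(pres)
  frac <- mean(cnt[cnt >= 1] < 3)
  want <- (1 - 0.4^3 - 0.6^3) / (1 - 0.6^3)  # 0.9184
  expect_lt(abs(frac - want), 0.008 + 0.004)  # 99% binomial CI half-width
})

test_that("written datasets round-trip through the pipeline readers", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(small_cfg(12), dir)
  gm <- read_gene_models(file.path(dir, "genes.gff3"))
  expect_setequal(gm$genes$gene_id, ds$genes$gene_id)
  expect_equal(nrow(gm$models), nrow(ds$models))
  tes <- read_te_annotations(file.path(dir, "tes.gff3"))
  expect_setequal(tes$te_id, ds$tes$te_id)
  expect_equal(sum(tes$status == "repeat_region"),
               sum(ds$tes$status == "repeat_region"))
  part <- read_region_partition(file.path(dir, "partition.tsv"))
  expect_equal(part, ds$partition, ignore_attr = TRUE)
  expr <- read_expression_matrix(file.path(dir, "expression.tsv"))
  expect_equal(dim(expr), dim(ds$expression))
  expect_equal(unname(expr[1, 1]), unname(ds$expression[1, 1]),
               tolerance = 1e-6)
})

test_that("the morphism GOF is calibrated with the unconditional p", {
  cal <- calibrate_morphism_gof(200, 1500, 0.4, 3, seed = 17)
  # nominal 5%; estimating p makes the test slightly conservative, so
  # accept [0, alpha + 3 * MC standard error]
  expect_lte(cal$reject_rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
  expect_gte(cal$reject_rate, 0)
  # the published conditional estimator over-rejects by construction
  cal_c <- calibrate_morphism_gof(50, 1500, 0.4, 3, seed = 18,
                                  p_method = "conditional")
  expect_gt(cal_c$reject_rate, 0.5)
})

test_that("recover_parameters finds the true generative p under the null", {
  ds <- generate_dataset(small_cfg(21, frac_nuisance_te = 0.2))
  rep <- recover_parameters(ds)
  fit <- rep$null_models[["3"]]$unconditional
  # genes are a proximal/distal mixture: p lies between the two rates
  expect_gt(fit$p, 0.25)
  expect_lt(fit$p, 0.45)
  expect_gt(fit$p_value, 0.001)
  # nuisance (nested/fragment) records never reach the overlap caller
  expect_true(all(rep$gene_content$superfamilies !=
                    "" | !rep$gene_content$has_te_gene_body))
})
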