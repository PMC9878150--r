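test_that("parse_te_code decomposes ClariTeRep names and is total", {
  x <- parse_te_code(c("RLC_famc1.6", "DTT_famn14", "XXX_famc13",
                       "DHH_fam1", "SIX_famc1"))
  expect_equal(x$code, c("RLC", "DTT", "XXX", "DHH", "SIX"))
  expect_equal(x$te_class, c("I", "II", "unknown", "II", "I"))
  expect_equal(x$te_order, c("LTR", "TIR", "unknown", "Helitron", "SINE"))
  expect_equal(x$superfamily,
               c("Copia", "Mariner", "unknown", "Helitron", "unknown"))
  expect_equal(x$family, c("famc1", "famn14", "famc13", "fam1", "famc1"))
  expect_equal(x$subfamily, c("6", NA, NA, NA, NA))
  # unknown code degrades, keeps code verbatim, warns
  expect_warning(y <- parse_te_code("QQQ_fam2"), "unrecognized")
  expect_equal(y$code, "QQQ")
  expect_equal(y$te_class, "unknown")
})

test_that("every Wicker code maps to its printed class and order", {
  w <- wicker_codes()
  got <- suppressWarnings(parse_te_code(paste0(w$code, "_famc1")))
  expect_equal(got$te_class, w$te_class)
  expect_equal(got$te_order, w$te_order)
  expect_equal(got$superfamily, w$superfamily)
  # idempotent on the code prefix
  again <- parse_te_code(got$name)
  expect_identical(got, again)
})

test_that("read_gene_models parses GFF3 with exons and flags bad input", {
  gff <- c("##gff-version 3",
           "chr1A\tsrc\tgene\t100\t200\t.\t+\t.\tID=gA;confidence=HC",
           "chr1A\tsrc\texon\t100\t140\t.\t+\t.\tID=gA.e1;Parent=gA",
           "chr1A\tsrc\texon\t160\t200\t.\t+\t.\tID=gA.e2;Parent=gA")
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gff, f)
  gm <- read_gene_models(f)
  expect_equal(nrow(gm$genes), 1)
  expect_equal(gm$genes$subgenome, "A")
  expect_equal(sum(gm$models$feature == "exon"), 2)

  # malformed coordinates: GFF3 readers reject them upstream; the TSV
  # dialect goes through our own record-level validation naming the gene
  bad_tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom\tstart\tstop", "gX\tchr1A\t300\t200"),
             bad_tsv)
  expect_error(read_gene_models(bad_tsv), "start > stop.*gX")
})

test_that("GFF3 fixture across subgenomes infers A/B/D and drops LC", {
  set.seed(42)
  chroms <- rep(paste0("chr", 1:2, rep(c("A", "B", "D"), each = 2)), 2)
  conf <- rep(c("HC", "LC"), 6)
  gff <- c("##gff-version 3",
           sprintf("%s\tsrc\tgene\t%d\t%d\t.\t+\t.\tID=g%02d;confidence=%s",
                   chroms, 1:12 * 10, 1:12 * 10 + 5, 1:12, conf))
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gff, f)
  all12 <- read_gene_models(f, include_lc = TRUE)
  expect_equal(nrow(all12$genes), 12)
  expect_equal(as.integer(table(all12$genes$subgenome)), c(4L, 4L, 4L))
  expect_equal(all12$genes$subgenome, infer_subgenome(all12$genes$chrom))
  hc <- suppressMessages(read_gene_models(f))
  expect_equal(nrow(hc$genes), 6)
  expect_true(all(hc$genes$confidence == "HC"))
})

test_that("TE reading keeps everything but exposes the repeat_region view", {
  tes <- data.frame(te_id = c("t1", "t2", "t3"), chrom = "chr1A",
                    start = c(1, 10, 20), stop = c(5, 15, 25),
                    status = c("repeat_region", "nested", "fragment"),
                    name = c("DTT_famn14", "RLC_famc1", "RLG_famc2"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_te_tsv(tes, f)
  x <- read_te_annotations(f)
  expect_equal(nrow(x), 3)
  expect_equal(x$code[1], "DTT")
  rr <- suppressMessages(repeat_regions(x))
  expect_equal(rr$te_id, "t1")
  # partition property: kept + removed = input
  expect_equal(nrow(rr) + sum(x$status != "repeat_region"), nrow(x))
  # empty file round trip
  write_te_tsv(tes[0, ], f)
  expect_equal(nrow(read_te_annotations(f)), 0)
})

test_that("gene/TE TSV round trip reproduces identical records", {
  inst <- random_instance(99)
  g <- inst$genes
  g$strand <- "+"; g$subgenome <- infer_subgenome(g$chrom)
  g$confidence <- "HC"
  f <- withr::local_tempfile(fileext = ".tsv")
  write_gene_tsv(g, f)
  back <- read_gene_models(f)$genes
  expect_equal(back[order(back$gene_id), names(g)], g[order(g$gene_id), ],
               ignore_attr = TRUE)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_te_tsv(inst$tes, f2)
  back2 <- read_te_annotations(f2)
  expect_equal(back2[, names(inst$tes)], inst$tes, ignore_attr = TRUE)
})

test_that("region assignment uses the gene midpoint with left-closed bins", {
  part <- toy_partition("chr1A")
  genes <- data.frame(
    gene_id = c("gC", "gR1", "gEdge", "gStraddle"),
    chrom = "chr1A",
    start = c(500, 10, 299, 280),  # midpoints: 510, 55, 300, 305
    stop = c(520, 100, 301, 330),
    stringsAsFactors = FALSE)
  out <- assign_chromosomal_region(genes, part)
  expect_equal(out$region, c("C", "R1", "R1", "R2a"))
  expect_equal(out$macro, c("proximal", "distal", "distal", "proximal"))
  expect_error(
    assign_chromosomal_region(
      data.frame(gene_id = "x", chrom = "chr9Z", start = 1, stop = 2), part),
    "chr9Z")
})

test_that("partition validation rejects gapped tilings", {
  part <- toy_partition("chr1A")
  part$start[3] <- 460  # gap between R2a and C
  expect_error(wheatTEbias:::validate_region_partition(part), "tile")
  expect_error(region_macro("R9"), "unknown region")
  expect_equal(region_macro(c("R1", "R2a", "C", "R2b", "R3")),
               c("distal", "proximal", "proximal", "proximal", "distal"))
})
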