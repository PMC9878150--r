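# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: per-base interval marking, exhaustive pattern
# enumeration and combinatorial tail sums.

# Per-base brute force: every covered base of each interval is materialized
# and intersected. Quadratic and slow on purpose.
oracle_overlaps <- function(genes, tes) {
  out <- list()
  for (i in seq_len(nrow(genes))) {
    gb <- seq(genes$start[i], genes$stop[i])
    for (j in seq_len(nrow(tes))) {
      if (genes$chrom[i] != tes$chrom[j]) next
      ov <- length(intersect(gb, seq(tes$start[j], tes$stop[j])))
      if (ov >= 1)
        out[[length(out) + 1]] <- data.frame(
          gene_id = genes$gene_id[i], te_id = tes$te_id[j],
          overlap_bp = ov, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(gene_id = character(), te_id = character(),
                      overlap_bp = integer()))
  o <- do.call(rbind, out)
  o[order(o$gene_id, o$te_id), ]
}

# Enumerate all 2^k presence patterns, weight by p^j (1-p)^(k-j), and
# condition on at least one present.
oracle_conditional_morphism <- function(p, k) {
  patterns <- expand.grid(rep(list(0:1), k))
  w <- apply(patterns, 1, function(x) prod(ifelse(x == 1, p, 1 - p)))
  n_present <- rowSums(patterns)
  any_te <- n_present >= 1
  denom <- sum(w[any_te])
  c(mono = sum(w[n_present == k]) / denom,
    poly = sum(w[any_te & n_present < k]) / denom)
}

# Hypergeometric upper tail P(X >= x) by explicit binomial coefficients.
oracle_hyper_tail <- function(x, K, N, n) {
  xs <- x:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Random genome instance for overlap property tests.
random_instance <- function(seed, n_genes = 25, n_tes = 50,
                            chrom_len = 2000, chroms = c("chr1A", "chr2B")) {
  set.seed(seed)
  gs <- sample(chrom_len - 60, n_genes, replace = TRUE)
  ts <- sample(chrom_len - 30, n_tes, replace = TRUE)
  list(
    genes = data.frame(
      gene_id = sprintf("g%03d", seq_len(n_genes)),
      chrom = sample(chroms, n_genes, TRUE),
      start = gs, stop = gs + sample(10:60, n_genes, TRUE),
      stringsAsFactors = FALSE),
    tes = data.frame(
      te_id = sprintf("t%03d", seq_len(n_tes)),
      chrom = sample(chroms, n_tes, TRUE),
      start = ts, stop = ts + sample(5:30, n_tes, TRUE),
      status = "repeat_region",
      name = paste0(sample(c("RLC", "DTT", "XXX"), n_tes, TRUE), "_famc1"),
      stringsAsFactors = FALSE))
}

# A small deterministic partition (one chromosome family, length 1000).
toy_partition <- function(chroms = c("chr1A", "chr1B", "chr1D")) {
  do.call(rbind, lapply(chroms, function(ch)
    data.frame(chrom = ch, region = c("R1", "R2a", "C", "R2b", "R3"),
               start = c(1, 301, 451, 601, 751),
               stop = c(300, 450, 600, 750, 1000),
               stringsAsFactors = FALSE)))
}
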