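#' Probability that a single gene carries a TE insertion
#'
#' Estimated from TE-containing groups only, as the fraction of genes with
#' at least one gene-body insertion among all genes belonging to
#' TE-containing groups: `p = sum(x) / (k * n_groups)`. Note that this
#' conditional estimator is biased upward relative to the unconditional
#' per-gene insertion rate, because groups with zero insertions are
#' excluded from the denominator (see [fit_morphism_null()]).
#'
#' @param te_genes_per_group Integer vector: for each TE-containing group,
#'   the number of member genes with at least one insertion (all values in
#'   `1..k`).
#' @param k Group cardinality (2 dyads, 3 triads, 4 tetrads).
#' @return The estimate `p` in (0, 1].
#' @export
single_gene_te_probability <- function(te_genes_per_group, k) {
  n <- length(te_genes_per_group)
  if (n == 0) stop("no TE-containing groups")
  if (any(te_genes_per_group < 1 | te_genes_per_group > k))
    stop("te_genes_per_group must lie in 1..k")
  sum(te_genes_per_group) / (k * n)
}

#' Conditional monomorphic / polymorphic probabilities
#'
#' Under independent per-gene presence with probability `p`, a group of
#' `k` genes is monomorphic (all members inserted) with probability `p^k`
#' and carries at least one insertion with probability `1 - (1-p)^k`.
#' Conditioning on the latter gives
#' `P(mono | TE) = p^k / (1 - (1-p)^k)` and
#' `P(poly | TE) = (1 - p^k - (1-p)^k) / (1 - (1-p)^k)`; the two sum to 1.
#'
#' @param p Per-gene insertion probability, in (0, 1].
#' @param k Group cardinality.
#' @return Named numeric vector `c(mono = , poly = )`.
#' @export
conditional_morphism_probabilities <- function(p, k) {
  stopifnot(length(p) == 1, length(k) == 1, k >= 2)
  if (p <= 0 || p > 1)
    stop("p must lie in (0, 1]: the conditioning event needs positive probability")
  denom <- 1 - (1 - p)^k
  mono <- p^k / denom
  c(mono = mono, poly = 1 - mono)
}

#' Fit the conditional-binomial morphism null model
#'
#' Fits the presence/absence null (independent insertions, common per-gene
#' probability) to a set of TE-containing homoeologous groups, predicting
#' how many of them should be monomorphic versus polymorphic, and tests the
#' observed split with a Pearson goodness-of-fit statistic.
#'
#' Two estimators of `p` are available. `"conditional"` (the default) uses
#' only genes in TE-containing groups, which reproduces the published
#' analysis; it is, however, inconsistent under the generative null itself
#' (conditioning inflates the estimate), so its goodness-of-fit test
#' over-rejects on data that truly satisfy independence.
#' `"unconditional"` divides by all genes in all `n_total` expressed groups
#' (TE-containing or not) and is approximately calibrated; it requires
#' `n_total`.
#'
#' @param te_genes_per_group Integer vector over TE-containing groups (see
#'   [single_gene_te_probability()]).
#' @param k Group cardinality.
#' @param p Optional: supply `p` directly instead of estimating it.
#' @param p_method `"conditional"` or `"unconditional"`.
#' @param n_total Total number of groups including those without TEs
#'   (required for `p_method = "unconditional"`).
#' @return An object of class `morphism_null`: a list with `p`, `k`,
#'   `n_groups`, `probs` (conditional mono/poly), `expected`, `observed`,
#'   `chi2`, `df`, `p_value`.
#' @export
fit_morphism_null <- function(te_genes_per_group, k, p = NULL,
                              p_method = c("conditional", "unconditional"),
                              n_total = NULL) {
  p_method <- match.arg(p_method)
  n <- length(te_genes_per_group)
  if (is.null(p)) {
    if (p_method == "conditional") {
      p <- single_gene_te_probability(te_genes_per_group, k)
    } else {
      if (is.null(n_total)) stop("unconditional estimator needs n_total")
      p <- sum(te_genes_per_group) / (k * n_total)
    }
  }
  probs <- conditional_morphism_probabilities(p, k)
  observed <- c(mono = sum(te_genes_per_group == k),
                poly = sum(te_genes_per_group < k))
  expected <- probs * n
  # p = 1 is a degenerate fit (expected poly = 0): no test possible
  gof <- if (all(expected > 0)) goodness_of_fit(observed, expected) else
    list(chi2 = NA_real_, df = NA_integer_, p_value = NA_real_)
  structure(list(p = p, k = k, n_groups = n, p_method = p_method,
                 probs = probs, expected = expected, observed = observed,
                 chi2 = gof$chi2, df = gof$df, p_value = gof$p_value),
            class = "morphism_null")
}

#' @export
print.morphism_null <- function(x, ...) {
  cat(sprintf("Conditional-binomial morphism null (k = %d, %s p)\n",
              x$k, x$p_method))
  cat(sprintf("  p(gene has TE) = %.5f over %d TE-containing groups\n",
              x$p, x$n_groups))
  cat(sprintf("  predicted polymorphic: %.2f%% (~%.1f groups)\n",
              100 * x$probs["poly"], x$expected["poly"]))
  cat(sprintf("  observed:  mono %d, poly %d\n",
              x$observed["mono"], x$observed["poly"]))
  cat(sprintf("  GOF chi^2 = %.2f, df = %d, p = %.3g\n",
              x$chi2, x$df, x$p_value))
  invisible(x)
}

#' Expected monomorphic / polymorphic counts under the null
#'
#' @param model A `morphism_null` object from [fit_morphism_null()].
#' @return Named numeric vector `c(mono = , poly = )` summing to the
#'   number of TE-containing groups.
#' @export
expected_morphism_counts <- function(model) {
  stopifnot(inherits(model, "morphism_null"))
  model$expected
}

#' Pearson chi-square goodness of fit
#'
#' `chi2 = sum((O - E)^2 / E)` with `df = cells - 1` and no continuity
#' correction.
#'
#' @param observed,expected Equal-length non-negative numeric vectors;
#'   every expected count must be positive.
#' @return A list `chi2`, `df`, `p_value`.
#' @export
goodness_of_fit <- function(observed, expected) {
  stopifnot(length(observed) == length(expected), length(observed) >= 2)
  if (any(expected <= 0)) stop("expected counts must be positive")
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Chi-square test of independence
#'
#' Pearson chi-square on an `r x c` contingency table with
#' `df = (r-1)(c-1)`. The Yates continuity correction is applied exactly
#' when the table is 2 x 2 (the convention of the contingency routine the
#' published values were computed with); each absolute deviation is
#' reduced by 0.5, clamped at zero.
#'
#' @param tab Integer matrix of counts with positive row and column sums.
#' @param correct `NULL` (auto: Yates iff 2 x 2), `TRUE` or `FALSE`.
#' @return A list `chi2`, `df`, `p_value`, `expected`, `table`.
#' @export
independence_test <- function(tab, correct = NULL) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative")
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || any(cs == 0))
    stop("zero row or column margin")
  if (is.null(correct)) correct <- all(dim(tab) == c(2, 2))
  expected <- outer(rs, cs) / n
  dev <- abs(tab - expected)
  if (correct) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
       expected = expected, table = tab)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up FDR control: `q_(i) = min_{j >= i} p_(j) * m / j`,
#' clamped at 1, mapped back to the input order.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]` (`NA` allowed and
#'   preserved).
#' @return Adjusted q-values in the input order; monotone in `p`.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  x <- p[ok]
  if (any(x < 0 | x > 1)) stop("p-values must lie in [0, 1]")
  m <- length(x)
  q <- rep(NA_real_, length(p))
  if (m > 0) {
    o <- order(x)
    xs <- x[o] * m / seq_len(m)
    xs <- rev(cummin(rev(xs)))
    xs <- pmin(xs, 1)
    qx <- numeric(m)
    qx[o] <- xs
    q[ok] <- qx
  }
  q
}

#' Screen TE groups against an expression-category comparison
#'
#' For every TE group (superfamily code or subfamily name) present in
#' `presence`, builds the 2 x 2 table of TE presence (at least one
#' insertion in at least one member gene of the triad) against category
#' membership, among the supplied triads:
#'
#' * `"balanced"`: balanced vs. non-balanced (dominant or suppressed);
#' * `"suppressed"`: any homoeolog-suppressed category vs. the rest
#'   (balanced or dominant);
#' * `"dominant"`: any homoeolog-dominant category vs. the rest.
#'
#' A TE group enters the tested family only when all four cells hold at
#' least `min_cell` observations; excluded groups are still reported with
#' `included = FALSE` and `NA` statistics. Raw p-values come from the
#' 2 x 2 chi-square with Yates correction and are Benjamini-Hochberg
#' adjusted within the tested family of this call. `direction` is
#' `"positive"` when the present-and-in-category cell exceeds its
#' expectation.
#'
#' @param categories Data.frame with `group_id` and `category` for every
#'   triad in the screen universe (typically the TE-containing eligible
#'   triads).
#' @param presence Long data.frame `group_id`, `te_group`: one row per
#'   (triad, TE group) presence.
#' @param comparison `"balanced"`, `"suppressed"` or `"dominant"`.
#' @param min_cell Minimum count required in every cell. Default 5.
#' @return A data.frame with one row per TE group: `te_group`,
#'   `comparison`, the four cells (`yes_in`, `no_in`, `yes_out`,
#'   `no_out`), `included`, `chi2`, `p_raw`, `q`, `direction`.
#' @export
screen_te_groups <- function(categories, presence,
                             comparison = c("balanced", "suppressed",
                                            "dominant"),
                             min_cell = 5) {
  comparison <- match.arg(comparison)
  if (nrow(categories) == 0) stop("empty screen universe")
  fam <- category_family(categories$category)
  in_cat <- fam == comparison
  te_groups <- sort(unique(presence$te_group))
  presence <- presence[presence$group_id %in% categories$group_id, ,
                       drop = FALSE]
  n_in <- sum(in_cat); n_out <- sum(!in_cat)
  rows <- lapply(te_groups, function(tg) {
    with_tg <- unique(presence$group_id[presence$te_group == tg])
    yes <- categories$group_id %in% with_tg
    yes_in <- sum(yes & in_cat); yes_out <- sum(yes & !in_cat)
    data.frame(te_group = tg, comparison = comparison,
               yes_in = yes_in, no_in = n_in - yes_in,
               yes_out = yes_out, no_out = n_out - yes_out,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  cells <- as.matrix(out[, c("yes_in", "no_in", "yes_out", "no_out")])
  out$included <- apply(cells >= min_cell, 1, all)
  out$chi2 <- NA_real_; out$p_raw <- NA_real_
  out$direction <- NA_character_
  for (i in which(out$included)) {
    tab <- matrix(c(out$yes_in[i], out$yes_out[i],
                    out$no_in[i], out$no_out[i]), nrow = 2, byrow = TRUE,
                  dimnames = list(c("yes", "no"), c("in", "out")))
    it <- independence_test(tab)
    out$chi2[i] <- it$chi2
    out$p_raw[i] <- it$p_value
    out$direction[i] <- if (tab["yes", "in"] >= it$expected["yes", "in"])
      "positive" else "negative"
  }
  out$q <- bh_adjust(out$p_raw)
  rownames(out) <- NULL
  out
}
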