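#' Ideal relative-contribution centroids
#'
#' For a group of `k` homoeolog slots the categories and their ideal
#' normalized expression vectors are: `balanced` (uniform, `1/k` per slot);
#' one dominant copy (`1` at the dominant slot, `0` elsewhere); one
#' suppressed copy (`0` at the suppressed slot, uniform over the rest); and,
#' for tetrads, two suppressed copies (`0` at both, `1/2` at the rest).
#' Dyads carry only balanced and suppressed categories (a dominant slot in
#' a pair is the mirror image of a suppressed one), triads the canonical
#' seven categories, tetrads all four families. Row order encodes the
#' tie-break priority: balanced first, then dominant, then suppressed (one
#' copy before two), slots in the given order.
#'
#' @param slots Character vector of slot labels in priority order, e.g.
#'   `c("A","B","D")`. Length 2, 3 or 4.
#' @return A numeric matrix (categories x slots); rownames are category
#'   labels such as `"A_dominant"` or `"B_suppressed"`.
#' @export
contribution_centroids <- function(slots = c("A", "B", "D")) {
  k <- length(slots)
  stopifnot(k %in% 2:4)
  rows <- list(balanced = rep(1 / k, k))
  if (k >= 3) {
    for (i in seq_len(k)) {
      v <- rep(0, k); v[i] <- 1
      rows[[paste0(slots[i], "_dominant")]] <- v
    }
  }
  for (i in seq_len(k)) {
    v <- rep(1 / (k - 1), k); v[i] <- 0
    rows[[paste0(slots[i], "_suppressed")]] <- v
  }
  if (k == 4) {
    pairs <- utils::combn(k, 2)
    for (j in seq_len(ncol(pairs))) {
      idx <- pairs[, j]
      v <- rep(0.5, k); v[idx] <- 0
      rows[[paste0(paste(slots[idx], collapse = ""), "_suppressed")]] <- v
    }
  }
  m <- do.call(rbind, rows)
  colnames(m) <- slots
  m
}

#' The canonical seven triad centroids
#'
#' Balanced `(1/3, 1/3, 1/3)`; A/B/D dominant `(1,0,0)` etc.; A/B/D
#' suppressed `(0, 1/2, 1/2)` etc. Shipped as an editable default: the
#' coordinates follow the ternary-diagram classification convention for
#' wheat homoeolog triads.
#'
#' @return A 7 x 3 numeric matrix with rownames `balanced`, `A_dominant`,
#'   `B_dominant`, `D_dominant`, `A_suppressed`, `B_suppressed`,
#'   `D_suppressed` and colnames `A`, `B`, `D`.
#' @export
triad_centroids <- function() contribution_centroids(c("A", "B", "D"))

#' Normalize homoeolog expression to per-sample proportions
#'
#' Each sample's TPM triplet (or k-tuple) is normalized to proportions
#' summing to one. Samples whose summed TPM is at or below `floor`
#' (default 0.5 TPM) carry no reliable signal and are excluded from the
#' mean; the category assignment uses the mean of the per-sample
#' proportions across qualifying samples (mean-of-normalized, not
#' normalized-mean), which is scale invariant.
#'
#' @param tpm Numeric matrix, one row per homoeolog slot, one column per
#'   sample.
#' @param floor Summed-TPM floor below which a sample is excluded.
#' @param tissue Optional character vector (one per sample) mapping samples
#'   to tissues; `n_tissues_expressed` counts tissues with at least one
#'   qualifying sample. Defaults to one tissue per sample.
#' @return A list: `proportions` (slots x qualifying samples),
#'   `mean_proportions` (length-k, sums to 1, or all `NA` when not
#'   expressed), `n_samples_expressed`, `n_tissues_expressed`, `expressed`.
#' @export
normalize_triad_expression <- function(tpm, floor = 0.5, tissue = NULL) {
  stopifnot(is.matrix(tpm), nrow(tpm) >= 2)
  if (is.null(tissue)) tissue <- as.character(seq_len(ncol(tpm)))
  stopifnot(length(tissue) == ncol(tpm))
  total <- colSums(tpm)
  qual <- total > floor
  props <- sweep(tpm[, qual, drop = FALSE], 2, total[qual], "/")
  expressed <- any(qual)
  mp <- if (expressed) rowMeans(props) else rep(NA_real_, nrow(tpm))
  list(proportions = props,
       mean_proportions = mp,
       n_samples_expressed = sum(qual),
       n_tissues_expressed = length(unique(tissue[qual])),
       expressed = expressed)
}

#' Assign groups to relative-contribution categories
#'
#' Each row of mean proportions is assigned to the category whose centroid
#' is nearest in Euclidean distance. Exact ties are broken by the centroid
#' priority order (balanced before dominant before suppressed, slots in
#' order), i.e. the first row of `centroids` that attains the minimum.
#'
#' @param props Numeric matrix (groups x slots) of mean proportions, each
#'   row summing to 1 within `tol`; a single group may be given as a
#'   vector.
#' @param centroids Centroid matrix as from [contribution_centroids()];
#'   defaults to the seven triad centroids.
#' @param tol Tolerance on the row-sum check. Default `1e-6`.
#' @return A data.frame `category`, `distance_to_centroid` (one row per
#'   input row).
#' @export
assign_contribution_category <- function(props, centroids = triad_centroids(),
                                         tol = 1e-6) {
  if (is.null(dim(props))) props <- matrix(props, nrow = 1)
  stopifnot(ncol(props) == ncol(centroids))
  bad <- abs(rowSums(props) - 1) > tol
  if (any(bad & !is.na(bad)))
    stop(sum(bad, na.rm = TRUE), " row(s) of proportions do not sum to 1")
  # squared distances: ||x||^2 - 2 x.c + ||c||^2, groups x categories
  d2 <- outer(rowSums(props^2), rep(1, nrow(centroids))) -
    2 * props %*% t(centroids) +
    outer(rep(1, nrow(props)), rowSums(centroids^2))
  d2 <- pmax(d2, 0)
  pick <- apply(d2, 1, function(r) {
    if (anyNA(r)) NA_integer_ else which(r <= min(r) + 1e-12)[1]
  })
  data.frame(
    category = rownames(centroids)[pick],
    distance_to_centroid = sqrt(d2[cbind(seq_len(nrow(props)), pick)]),
    stringsAsFactors = FALSE
  )
}

#' Batch expression summary for homoeolog groups
#'
#' Vectorized driver around the per-group normalization: computes mean
#' proportions, expression breadth and the nearest-centroid category for
#' every group of a given cardinality in one pass.
#'
#' @param members Membership table from [build_groups()] restricted to one
#'   cardinality.
#' @param expr TPM matrix (genes x samples).
#' @param floor Summed-TPM floor per sample. Default `0.5`.
#' @param tissue Optional sample-to-tissue map (see
#'   [normalize_triad_expression()]).
#' @return A data.frame with `group_id`, one `prop_<slot>` column per slot,
#'   `n_tissues_expressed`, `expressed`, `category`,
#'   `distance_to_centroid`. Slot order within a group follows sorted
#'   subgenome labels (duplicated subgenomes get suffixes `1`, `2`).
#' @export
group_expression_summary <- function(members, expr, floor = 0.5,
                                     tissue = NULL) {
  card <- unique(members$cardinality)
  if (length(card) != 1)
    stop("members must contain a single cardinality; got ",
         paste(card, collapse = ", "))
  k <- card
  ord <- order(members$group_id, members$subgenome, members$gene_id)
  m <- members[ord, ]
  gid <- unique(m$group_id)
  if (any(table(m$group_id) != k)) stop("unequal group sizes")
  gene_mat <- matrix(m$gene_id, ncol = k, byrow = TRUE)
  sub_mat <- matrix(m$subgenome, ncol = k, byrow = TRUE)
  slots <- sub_mat[1, ]
  if (anyDuplicated(slots)) slots <- make.unique(slots, sep = "")
  idx <- matrix(match(gene_mat, rownames(expr)), ncol = k)
  if (anyNA(idx)) stop("expression matrix does not cover all member genes")
  if (is.null(tissue)) tissue <- as.character(seq_len(ncol(expr)))

  tpm <- lapply(seq_len(k), function(j) expr[idx[, j], , drop = FALSE])
  total <- Reduce(`+`, tpm)
  qual <- total > floor                      # groups x samples
  nq <- rowSums(qual)
  props <- vapply(seq_len(k), function(j) {
    p <- tpm[[j]] / total
    p[!qual] <- NA
    rowSums(p, na.rm = TRUE) / pmax(nq, 1)
  }, numeric(nrow(qual)))
  props <- matrix(props, ncol = k)
  props[nq == 0, ] <- NA
  colnames(props) <- slots
  n_tis <- apply(qual, 1, function(q) length(unique(tissue[q])))
  cat_df <- assign_contribution_category(
    props, contribution_centroids(slots))
  out <- data.frame(group_id = gid, props,
                    n_tissues_expressed = n_tis,
                    expressed = nq > 0,
                    category = cat_df$category,
                    distance_to_centroid = cat_df$distance_to_centroid,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out)[2:(1 + k)] <- paste0("prop_", slots)
  rownames(out) <- NULL
  out
}

#' Select triads eligible for the association screens
#'
#' Eligibility follows the analysis-set definition used for the
#' Chinese Spring 123-sample / 15-tissue dataset: a triad enters the
#' screens when it is syntenic and expressed in at least `min_tissues`
#' (default 6) of the tissues.
#'
#' @param summary_df Output of [group_expression_summary()] with a logical
#'   `syntenic` column attached.
#' @param min_tissues Minimum tissues with qualifying expression. Default 6.
#' @return `summary_df` with a logical `eligible` column.
#' @export
select_analysis_triads <- function(summary_df, min_tissues = 6) {
  if (is.null(summary_df$syntenic))
    stop("summary_df needs a logical 'syntenic' column")
  summary_df$eligible <- summary_df$syntenic &
    summary_df$n_tissues_expressed >= min_tissues
  summary_df
}

#' Pool per-slot categories into balanced / suppressed / dominant
#'
#' @param category Character vector of category labels
#'   (e.g. `"B_suppressed"`).
#' @return `"balanced"`, `"suppressed"` or `"dominant"` per element.
#' @export
category_family <- function(category) {
  ifelse(category == "balanced", "balanced",
         ifelse(grepl("_suppressed$", category), "suppressed",
                ifelse(grepl("_dominant$", category), "dominant",
                       NA_character_)))
}
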