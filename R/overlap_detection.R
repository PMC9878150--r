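#' Call TE insertions within genes by interval intersection
#'
#' A TE "insertion within" a feature is operationalized as an intersection
#' of at least one base between the TE interval and the feature interval
#' (both 1-based inclusive); a TE straddling a gene edge therefore counts,
#' and a TE overlapping two genes is reported once per gene. For context
#' `"gene_body"` the feature is the full `[start, stop]` span including
#' introns; for `"exon"`, `"utr5"` and `"utr3"` the feature is the union of
#' the corresponding `models` intervals, normalized (sorted and merged) per
#' gene so that `overlap_bp` is well defined. Strand is ignored.
#'
#' @param genes Gene table (`gene_id`, `chrom`, `start`, `stop`).
#' @param tes TE table (`te_id`, `chrom`, `start`, `stop`, `status`); only
#'   `repeat_region` records are used (filtered here defensively).
#' @param context One of `"gene_body"`, `"exon"`, `"utr5"`, `"utr3"`.
#' @param models Gene-structure intervals (`gene_id`, `feature`, `start`,
#'   `stop`); required for non-gene-body contexts.
#' @return A data.frame `gene_id`, `te_id`, `context`, `overlap_bp`,
#'   ordered by (`gene_id`, `te_id`) so the output is independent of input
#'   ordering.
#' @export
find_te_insertions <- function(genes, tes,
                               context = c("gene_body", "exon", "utr5", "utr3"),
                               models = NULL) {
  context <- match.arg(context)
  if ("status" %in% names(tes))
    tes <- tes[tes$status == "repeat_region", , drop = FALSE]
  if (context == "gene_body") {
    feats <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                        start = genes$start, stop = genes$stop,
                        stringsAsFactors = FALSE)
  } else {
    if (is.null(models))
      stop("context '", context, "' requires gene-structure models")
    m <- models[models$feature == context, , drop = FALSE]
    chrom <- genes$chrom[match(m$gene_id, genes$gene_id)]
    if (anyNA(chrom))
      stop("model intervals reference unknown gene ids")
    feats <- data.frame(gene_id = m$gene_id, chrom = chrom,
                        start = m$start, stop = m$stop,
                        stringsAsFactors = FALSE)
  }
  empty <- data.frame(gene_id = character(), te_id = character(),
                      context = character(), overlap_bp = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(feats) == 0 || nrow(tes) == 0) return(empty)

  gr_f <- GenomicRanges::GRanges(feats$chrom,
                                 IRanges::IRanges(feats$start, feats$stop))
  # normalize: merge intervals belonging to the same gene
  gr_f <- unlist(GenomicRanges::reduce(
    S4Vectors::split(gr_f, feats$gene_id)))
  feat_gene <- names(gr_f)
  gr_t <- GenomicRanges::GRanges(tes$chrom,
                                 IRanges::IRanges(tes$start, tes$stop))
  hits <- GenomicRanges::findOverlaps(gr_f, gr_t, ignore.strand = TRUE)
  if (length(hits) == 0) return(empty)
  ov <- GenomicRanges::pintersect(gr_f[S4Vectors::queryHits(hits)],
                                  gr_t[S4Vectors::subjectHits(hits)])
  out <- data.frame(
    gene_id = feat_gene[S4Vectors::queryHits(hits)],
    te_id = tes$te_id[S4Vectors::subjectHits(hits)],
    overlap_bp = GenomicRanges::width(ov),
    stringsAsFactors = FALSE
  )
  # a TE can hit several merged intervals of one gene (e.g. two exons)
  out <- stats::aggregate(overlap_bp ~ gene_id + te_id, data = out, FUN = sum)
  out$context <- context
  out <- out[order(out$gene_id, out$te_id),
             c("gene_id", "te_id", "context", "overlap_bp")]
  rownames(out) <- NULL
  out
}

#' Summarize per-gene TE content across contexts
#'
#' @param gene_ids Character vector of all analyzed gene ids (genes without
#'   overlaps appear with all flags `FALSE`).
#' @param overlaps One or more outputs of [find_te_insertions()] bound
#'   together (contexts may repeat across calls).
#' @param tes The TE table the overlaps were called against, carrying the
#'   parsed classification columns (`code`, `name`).
#' @return A data.frame with one row per gene: logical flags
#'   `has_te_gene_body`, `has_te_exon`, `has_te_utr5`, `has_te_utr3`, and
#'   semicolon-joined `superfamilies` and `subfamilies` of the TEs found in
#'   the gene body (empty string when none).
#' @export
summarize_gene_te_content <- function(gene_ids, overlaps, tes) {
  out <- data.frame(gene_id = gene_ids, stringsAsFactors = FALSE)
  for (ctx in c("gene_body", "exon", "utr5", "utr3")) {
    hit <- unique(overlaps$gene_id[overlaps$context == ctx])
    out[[paste0("has_te_", ctx)]] <- out$gene_id %in% hit
  }
  body <- overlaps[overlaps$context == "gene_body", , drop = FALSE]
  if (is.null(tes$code) && !is.null(tes$name))
    tes$code <- suppressWarnings(parse_te_code(tes$name))$code
  sf <- tes$code[match(body$te_id, tes$te_id)]
  sub <- tes$name[match(body$te_id, tes$te_id)]
  if (is.null(sf)) sf <- rep(NA_character_, nrow(body))
  if (is.null(sub)) sub <- rep(NA_character_, nrow(body))
  join <- function(ids, vals) {
    v <- vapply(split(vals, ids),
                function(x) paste(sort(unique(x)), collapse = ";"), "")
    unname(v[match(gene_ids, names(v))])
  }
  out$superfamilies <- join(body$gene_id, sf)
  out$subfamilies <- join(body$gene_id, sub)
  out$superfamilies[is.na(out$superfamilies)] <- ""
  out$subfamilies[is.na(out$subfamilies)] <- ""
  rownames(out) <- NULL
  out
}
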