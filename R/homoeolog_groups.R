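#' Build homoeologous groups from a membership table
#'
#' Groups are dyads (two members, one subgenome lost: AB/AD/BD), triads
#' (one member per subgenome: ABD) or tetrads (one subgenome duplicated:
#' AABD/ABBD/ABDD). Composition is derived from the member subgenome slots;
#' groups referencing genes absent from `genes` are dropped with a message,
#' and a gene listed twice within one group is an error.
#'
#' @param group_table Long-format membership table (`group_id`, `gene_id`,
#'   `subgenome`).
#' @param genes Gene table used to resolve members.
#' @return The membership table restricted to resolvable groups, with
#'   per-group `cardinality` (2, 3 or 4) and `composition` (e.g. `"ABD"`,
#'   `"AABD"`) columns attached to every member row.
#' @export
build_groups <- function(group_table, genes) {
  dup <- duplicated(group_table[, c("group_id", "gene_id")])
  if (any(dup))
    stop("gene listed twice within a group: ",
         paste(utils::head(unique(group_table$group_id[dup]), 5),
               collapse = ", "))
  known <- group_table$gene_id %in% genes$gene_id
  if (any(!known)) {
    drop_groups <- unique(group_table$group_id[!known])
    message("dropping ", length(drop_groups),
            " group(s) referencing missing genes")
    group_table <- group_table[!group_table$group_id %in% drop_groups, ,
                               drop = FALSE]
  }
  if (nrow(group_table) == 0)
    return(cbind(group_table, cardinality = integer(),
                 composition = character()))
  comp <- vapply(split(group_table$subgenome, group_table$group_id),
                 function(s) paste(sort(s), collapse = ""), "")
  card <- nchar(comp)
  bad <- !card %in% 2:4
  if (any(bad))
    stop("group cardinality outside 2..4: ",
         paste(utils::head(names(comp)[bad], 5), collapse = ", "))
  idx <- match(group_table$group_id, names(comp))
  group_table$cardinality <- unname(card[idx])
  group_table$composition <- unname(comp[idx])
  rownames(group_table) <- NULL
  group_table
}

#' Classify groups as monomorphic / polymorphic for TE presence
#'
#' A group is monomorphic when every member gene contains at least one TE
#' insertion in its gene body, polymorphic when at least one but not all
#' members do, and `no_te` when none does. TE type, multiplicity and
#' insertion position are deliberately ignored.
#'
#' @param members Membership table from [build_groups()].
#' @param te_content Per-gene table with `gene_id` and `has_te_gene_body`
#'   (from [summarize_gene_te_content()]), covering all member genes.
#' @return Per-group data.frame: `group_id`, `cardinality`, `composition`,
#'   `n_te_genes`, `morphism` (`monomorphic`/`polymorphic`/`no_te`).
#' @export
classify_polymorphism <- function(members, te_content) {
  idx <- match(members$gene_id, te_content$gene_id)
  if (anyNA(idx))
    stop("te_content does not cover all member genes")
  has <- te_content$has_te_gene_body[idx]
  agg <- stats::aggregate(has, by = list(group_id = members$group_id), FUN = sum)
  names(agg)[2] <- "n_te_genes"
  first <- !duplicated(members$group_id)
  info <- members[first, c("group_id", "cardinality", "composition")]
  out <- merge(info, agg, by = "group_id", sort = TRUE)
  out$morphism <- ifelse(out$n_te_genes == 0, "no_te",
                         ifelse(out$n_te_genes == out$cardinality,
                                "monomorphic", "polymorphic"))
  rownames(out) <- NULL
  out
}

#' Stratify groups by chromosomal macro region
#'
#' A group is `proximal` when every member gene lies in R2a/C/R2b,
#' `distal` when every member lies in R1/R3, and `mixed` otherwise; mixed
#' groups are excluded from region-stratified analyses.
#'
#' @param members Membership table from [build_groups()].
#' @param genes Gene table with a `macro` column
#'   (see [assign_chromosomal_region()]).
#' @return Per-group data.frame `group_id`, `region_status`.
#' @export
assign_group_region <- function(members, genes) {
  macro <- genes$macro[match(members$gene_id, genes$gene_id)]
  if (anyNA(macro)) stop("every member gene needs a macro region label")
  st <- vapply(split(macro, members$group_id), function(m) {
    u <- unique(m)
    if (length(u) == 1) u else "mixed"
  }, "")
  data.frame(group_id = names(st), region_status = unname(st),
             stringsAsFactors = FALSE)
}

#' Flag expressed genes and expressed groups
#'
#' A gene counts as expressed when its mean TPM across samples exceeds
#' `floor` (default 0.5 TPM); a group is expressed when at least one member
#' gene is. Groups without any expressed gene are removed from the
#' morphism analyses.
#'
#' @param members Membership table from [build_groups()].
#' @param expr TPM matrix (genes x samples) with gene ids as rownames.
#' @param floor Per-gene mean-TPM threshold. Default `0.5`.
#' @return Per-group data.frame `group_id`, `expressed`.
#' @export
group_expression_status <- function(members, expr, floor = 0.5) {
  idx <- match(members$gene_id, rownames(expr))
  mean_tpm <- rep(0, nrow(members))
  mean_tpm[!is.na(idx)] <- rowMeans(expr[idx[!is.na(idx)], , drop = FALSE])
  gene_expr <- mean_tpm > floor
  st <- vapply(split(gene_expr, members$group_id), any, TRUE)
  data.frame(group_id = names(st), expressed = unname(st),
             stringsAsFactors = FALSE)
}

#' Assemble the per-group analysis table
#'
#' Joins morphism, region stratum and expression status into the group
#' table used by the null-model and contingency analyses.
#'
#' @param members Membership table from [build_groups()].
#' @param te_content Per-gene TE content table.
#' @param genes Gene table with `macro` labels (optional; region status is
#'   `NA` when absent).
#' @param expr TPM matrix (optional; `expressed` is `TRUE` when absent).
#' @param floor Expression floor passed to [group_expression_status()].
#' @return Per-group data.frame with `group_id`, `cardinality`,
#'   `composition`, `n_te_genes`, `morphism`, `region_status`, `expressed`.
#' @export
homoeolog_group_table <- function(members, te_content, genes = NULL,
                                  expr = NULL, floor = 0.5) {
  out <- classify_polymorphism(members, te_content)
  if (!is.null(genes) && "macro" %in% names(genes)) {
    out <- merge(out, assign_group_region(members, genes), by = "group_id")
  } else {
    out$region_status <- NA_character_
  }
  if (!is.null(expr)) {
    out <- merge(out, group_expression_status(members, expr, floor),
                 by = "group_id")
  } else {
    out$expressed <- TRUE
  }
  out[order(out$group_id), ]
}
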