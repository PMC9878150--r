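#' Map homoeolog groups to GO terms
#'
#' A group (triad) carries the union of its member genes' GO annotations;
#' unannotated groups carry empty sets. When a parent table is supplied,
#' annotations are propagated up the GO hierarchy (a term implies all of
#' its ancestors) by transitive closure.
#'
#' @param members Membership table (`group_id`, `gene_id`).
#' @param gene_to_go Data.frame `gene_id`, `go_id`.
#' @param parents Optional data.frame `go_id`, `parent_id` of direct
#'   is-a links.
#' @return A data.frame `group_id`, `go_id` with one row per distinct
#'   (group, term) pair.
#' @export
map_triads_to_go <- function(members, gene_to_go, parents = NULL) {
  if (!is.null(parents)) {
    closure <- go_ancestor_closure(parents)
    extra <- merge(gene_to_go, closure, by = "go_id")
    extra <- data.frame(gene_id = extra$gene_id, go_id = extra$ancestor_id,
                        stringsAsFactors = FALSE)
    gene_to_go <- unique(rbind(gene_to_go[, c("gene_id", "go_id")], extra))
  }
  hit <- merge(members[, c("group_id", "gene_id")],
               gene_to_go[, c("gene_id", "go_id")], by = "gene_id")
  out <- unique(hit[, c("group_id", "go_id")])
  out <- out[order(out$group_id, out$go_id), ]
  rownames(out) <- NULL
  out
}

#' Transitive closure of direct GO parent links
#'
#' @param parents Data.frame `go_id`, `parent_id`.
#' @return Data.frame `go_id`, `ancestor_id` containing every (term,
#'   proper ancestor) pair.
#' @export
go_ancestor_closure <- function(parents) {
  edges <- unique(data.frame(go_id = parents$go_id,
                             ancestor_id = parents$parent_id,
                             stringsAsFactors = FALSE))
  closure <- edges
  repeat {
    step <- merge(closure, edges, by.x = "ancestor_id", by.y = "go_id")
    step <- unique(data.frame(go_id = step$go_id,
                              ancestor_id = step$ancestor_id.y,
                              stringsAsFactors = FALSE))
    new <- step[!paste(step$go_id, step$ancestor_id) %in%
                  paste(closure$go_id, closure$ancestor_id), , drop = FALSE]
    if (nrow(new) == 0) break
    closure <- rbind(closure, new)
  }
  rownames(closure) <- NULL
  closure
}

#' Singular Enrichment Analysis (one-sided Fisher's exact test)
#'
#' Tests each GO term annotated in the background for over-representation
#' in the query: with `N` background groups, `K` of them annotated with
#' the term, and a query of `n` groups of which `x` carry the term, the
#' p-value is the hypergeometric upper tail `P(X >= x)`. Adjustment is
#' Benjamini-Hochberg within each GO domain when a domain table is given
#' (BP, MF and CC term families are reported separately), otherwise across
#' all terms. Queries mapping to fewer than `min_query_terms` distinct
#' terms are refused (short query lists do not support enrichment
#' analysis).
#'
#' @param query Character vector of query group ids; must be a subset of
#'   `background`.
#' @param background Character vector of background group ids (the full
#'   analyzed set, e.g. all eligible triads).
#' @param term_map Data.frame `group_id`, `go_id` from
#'   [map_triads_to_go()].
#' @param domains Optional data.frame `go_id`, `domain` (BP/MF/CC).
#' @param fdr_cutoff Significance threshold on the adjusted value.
#'   Default 0.05.
#' @param min_query_terms Minimum distinct terms mapped in the query.
#'   Default 2.
#' @return A data.frame with one row per background term: `go_id`,
#'   `domain`, `query_hits`, `query_size`, `background_hits`,
#'   `background_size`, `p_raw`, `fdr`, `significant`, ordered by `fdr`.
#' @export
sea <- function(query, background, term_map, domains = NULL,
                fdr_cutoff = 0.05, min_query_terms = 2) {
  if (!all(query %in% background))
    stop("query must be a subset of the background")
  query <- unique(query); background <- unique(background)
  tm <- term_map[term_map$group_id %in% background, , drop = FALSE]
  qtm <- tm[tm$group_id %in% query, , drop = FALSE]
  if (length(unique(qtm$go_id)) < min_query_terms)
    stop("query maps to fewer than ", min_query_terms,
         " GO terms; too short for enrichment analysis")
  N <- length(background)
  n <- length(query)
  bg_hits <- table(tm$go_id)
  q_hits <- table(factor(qtm$go_id, levels = names(bg_hits)))
  out <- data.frame(go_id = names(bg_hits),
                    query_hits = as.integer(q_hits),
                    query_size = n,
                    background_hits = as.integer(bg_hits),
                    background_size = N,
                    stringsAsFactors = FALSE)
  out$domain <- if (is.null(domains)) "all" else
    domains$domain[match(out$go_id, domains$go_id)]
  out$p_raw <- stats::phyper(out$query_hits - 1, out$background_hits,
                             N - out$background_hits, n,
                             lower.tail = FALSE)
  out$fdr <- NA_real_
  for (d in unique(out$domain)) {
    sel <- which(out$domain %in% d)
    out$fdr[sel] <- bh_adjust(out$p_raw[sel])
  }
  out$significant <- out$fdr <= fdr_cutoff
  out <- out[order(out$fdr, out$p_raw, out$go_id),
             c("go_id", "domain", "query_hits", "query_size",
               "background_hits", "background_size", "p_raw", "fdr",
               "significant")]
  rownames(out) <- NULL
  out
}
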