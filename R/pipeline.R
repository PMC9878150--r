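#' Assemble a pipeline configuration
#'
#' A plain list validated up front: input paths, thresholds and the output
#' directory. Configurations can also be read from JSON with
#' [read_pipeline_config()].
#'
#' @param genes,tes,groups,partition Paths to the gene annotation
#'   (GFF3/TSV), TE annotation (GFF3/TSV), homoeolog-group TSV and region
#'   partition TSV. Required for the annotation stages.
#' @param gene_models Optional gene-structure TSV (needed for exon/UTR
#'   contexts when `genes` is a TSV).
#' @param expression Optional TPM matrix TSV (required by the expression
#'   stages).
#' @param synteny Optional TSV `group_id`, `syntenic`.
#' @param tissue Optional TSV `sample`, `tissue` mapping expression
#'   columns to tissues.
#' @param gene_to_go,go_domains Optional GO mapping TSVs (required by the
#'   enrichment stage).
#' @param out_dir Output directory for the result tables.
#' @param expression_floor,min_tissues,min_cell,fdr Analysis thresholds.
#' @param seed Seed recorded in the manifest (used by synthetic mode).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(genes = NULL, tes = NULL, groups = NULL,
                            partition = NULL, gene_models = NULL,
                            expression = NULL, synteny = NULL,
                            tissue = NULL, gene_to_go = NULL,
                            go_domains = NULL, out_dir = "tebias_out",
                            expression_floor = 0.5, min_tissues = 6,
                            min_cell = 5, fdr = 0.05, seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from JSON
#'
#' @param path Path to a JSON object whose keys match the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x)
}

validate_pipeline_config <- function(cfg, stages) {
  need <- c("genes", "tes", "groups", "partition")
  if (any(c("overlaps", "classify", "categories", "screen", "enrich")
          %in% stages)) {
    for (f in need)
      if (is.null(cfg[[f]]))
        stop("configuration error: input '", f, "' is required")
  }
  if (any(c("categories", "screen", "enrich") %in% stages) &&
      is.null(cfg[["expression"]]))
    stop("configuration error: expression stages enabled but no ",
         "expression file configured")
  for (f in c(need, "gene_models", "expression", "synteny", "tissue",
              "gene_to_go", "go_domains")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("configuration error: file not found for '", f, "': ", cfg[[f]])
  }
  invisible(cfg)
}

# hash of the analysis-relevant configuration (output location excluded,
# so reruns into a different directory remain comparable)
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg[order(names(cfg))],
                              auto_unbox = TRUE, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

write_stage_table <- function(x, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# wheatTEbias ",
           as.character(utils::packageVersion("wheatTEbias"))),
    paste0("# config_hash=", config_hash(cfg))), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the analysis pipeline end to end
#'
#' Stages: `overlaps` (TE-in-gene calling in all four contexts and the
#' per-gene content table), `classify` (group morphism, region strata,
#' expression status and the conditional-binomial null report, overall
#' and per macro region), `categories` (triad expression categories and
#' eligibility), `screen` (superfamily and subfamily screens against the
#' balanced/suppressed/dominant comparisons) and `enrich` (GO SEA per
#' superfamily against the eligible-triad background). Each stage writes
#' a TSV to `out_dir` with metadata header lines (package version and
#' config hash), plus a JSON run manifest. Rerunning with identical
#' inputs and configuration is bit-identical.
#'
#' @param cfg A [pipeline_config()].
#' @param stages Character subset of
#'   `c("overlaps","classify","categories","screen","enrich")`.
#' @return Invisibly, a list of the in-memory stage outputs.
#' @export
run_pipeline <- function(cfg, stages = c("overlaps", "classify",
                                         "categories", "screen",
                                         "enrich")) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  validate_pipeline_config(cfg, stages)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  gm <- run_stage("inputs", read_gene_models(cfg$genes))
  genes <- gm$genes
  models <- gm$models
  if (!is.null(cfg$gene_models))
    models <- rbind(models, read_gene_model_tsv(cfg$gene_models))
  tes <- run_stage("inputs", read_te_annotations(cfg$tes))
  tes_rr <- repeat_regions(tes, quiet = TRUE)
  partition <- read_region_partition(cfg$partition)
  genes <- assign_chromosomal_region(genes, partition)
  members <- build_groups(read_homoeolog_group_table(cfg$groups), genes)

  ov <- run_stage("overlaps", {
    o <- find_te_insertions(genes, tes_rr, "gene_body")
    for (ctx in c("exon", "utr5", "utr3"))
      if (any(models$feature == ctx))
        o <- rbind(o, find_te_insertions(genes, tes_rr, ctx, models))
    o
  })
  content <- summarize_gene_te_content(genes$gene_id, ov, tes_rr)
  out$gene_content <- content
  if ("overlaps" %in% stages)
    write_stage_table(content, file.path(cfg$out_dir, "gene_te_content.tsv"),
                      cfg)

  expr <- NULL
  if (!is.null(cfg[["expression"]]))
    expr <- read_expression_matrix(cfg[["expression"]])

  if (any(c("classify", "categories", "screen", "enrich") %in% stages)) {
    gtab <- run_stage("classify",
                      homoeolog_group_table(members, content, genes, expr,
                                            cfg$expression_floor))
    out$groups <- gtab
    if ("classify" %in% stages) {
      write_stage_table(gtab, file.path(cfg$out_dir, "group_morphism.tsv"),
                        cfg)
      report <- list()
      for (k in 2:4) {
        for (stratum in c("all", "proximal", "distal")) {
          sub <- gtab[gtab$cardinality == k & gtab$expressed &
                        gtab$morphism != "no_te", ]
          if (stratum != "all")
            sub <- sub[sub$region_status %in% stratum, ]
          if (nrow(sub) < 10) next
          fit <- fit_morphism_null(sub$n_te_genes, k)
          report[[length(report) + 1]] <- data.frame(
            cardinality = k, stratum = stratum, n_groups = fit$n_groups,
            p = fit$p, expected_poly = unname(fit$expected["poly"]),
            observed_poly = unname(fit$observed["poly"]),
            predicted_poly_pct = unname(100 * fit$probs["poly"]),
            chi2 = fit$chi2, p_value = fit$p_value)
        }
      }
      null_report <- do.call(rbind, report)
      out$null_report <- null_report
      write_stage_table(null_report,
                        file.path(cfg$out_dir, "morphism_null.tsv"), cfg)
    }
  }

  if (any(c("categories", "screen", "enrich") %in% stages)) {
    tri_members <- members[members$cardinality == 3, ]
    tissue <- NULL
    if (!is.null(cfg$tissue)) {
      tt <- utils::read.delim(cfg$tissue, stringsAsFactors = FALSE)
      tissue <- tt$tissue[match(colnames(expr), tt$sample)]
    }
    triads <- run_stage("categories",
                        group_expression_summary(tri_members, expr,
                                                 cfg$expression_floor,
                                                 tissue))
    if (!is.null(cfg$synteny)) {
      syn <- utils::read.delim(cfg$synteny, stringsAsFactors = FALSE)
      triads$syntenic <- syn$syntenic[match(triads$group_id, syn$group_id)]
    } else {
      triads$syntenic <- TRUE
    }
    triads <- select_analysis_triads(triads, cfg$min_tissues)
    out$triads <- triads
    if ("categories" %in% stages)
      write_stage_table(triads, file.path(cfg$out_dir, "triad_categories.tsv"),
                        cfg)

    content_tri <- content[content$gene_id %in% tri_members$gene_id, ]
    long_pres <- function(col) {
      x <- content_tri[content_tri[[col]] != "", c("gene_id", col)]
      parts <- strsplit(x[[col]], ";")
      p <- data.frame(gene_id = rep(x$gene_id, lengths(parts)),
                      te_group = as.character(unlist(parts)),
                      stringsAsFactors = FALSE)
      p <- merge(p, tri_members[, c("gene_id", "group_id")], by = "gene_id")
      unique(p[, c("group_id", "te_group")])
    }
    pres_sf <- long_pres("superfamilies")
    pres_sub <- long_pres("subfamilies")
    eligible <- triads[triads$eligible %in% TRUE, ]
    universe <- eligible[eligible$group_id %in% unique(pres_sf$group_id), ]

    if ("screen" %in% stages) {
      pres_levels <- list(superfamily = pres_sf, subfamily = pres_sub)
      res <- run_stage("screen", {
        do.call(rbind, lapply(names(pres_levels), function(lvl) {
          do.call(rbind, lapply(
            c("balanced", "suppressed", "dominant"), function(cmp) {
              r <- screen_te_groups(universe[, c("group_id", "category")],
                                    pres_levels[[lvl]], cmp, cfg$min_cell)
              r$te_level <- lvl
              r
            }))
        }))
      })
      out$screens <- res
      write_stage_table(res, file.path(cfg$out_dir, "te_screens.tsv"), cfg)
    }

    if ("enrich" %in% stages && !is.null(cfg$gene_to_go)) {
      g2g <- utils::read.delim(cfg$gene_to_go, stringsAsFactors = FALSE)
      domains <- if (!is.null(cfg$go_domains))
        utils::read.delim(cfg$go_domains, stringsAsFactors = FALSE) else NULL
      term_map <- map_triads_to_go(tri_members, g2g)
      bg <- eligible$group_id
      enr <- run_stage("enrich", {
        do.call(rbind, lapply(sort(unique(pres_sf$te_group)), function(sf) {
          query <- intersect(unique(
            pres_sf$group_id[pres_sf$te_group == sf]), bg)
          res <- tryCatch(sea(query, bg, term_map, domains,
                              fdr_cutoff = cfg$fdr),
                          error = function(e) NULL)
          if (is.null(res)) return(NULL)
          res <- res[res$significant, , drop = FALSE]
          if (nrow(res) == 0) return(NULL)
          cbind(te_group = sf, res)
        }))
      })
      out$enrichment <- enr
      if (!is.null(enr))
        write_stage_table(enr, file.path(cfg$out_dir, "go_enrichment.tsv"),
                          cfg)
    }
  }

  manifest <- list(package = "wheatTEbias",
                   version = as.character(utils::packageVersion("wheatTEbias")),
                   config = unclass(cfg), config_hash = config_hash(cfg),
                   stages = stages)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(out)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic dataset), `annotate-overlaps`,
#' `classify-groups`, `assign-categories`, `screen`, `enrich` (single
#' stages) and `run-all`. Flags: `--config PATH` (JSON for
#' [pipeline_config()]), with per-run overrides `--min-cell`, `--fdr`,
#' `--seed`, `--out`.
#'
#' @param args Character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return Invisibly, the stage output list (or the dataset directory for
#'   `simulate`).
#' @export
tebias_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0)
    stop("usage: tebias <simulate|annotate-overlaps|classify-groups|",
         "assign-categories|screen|enrich|run-all> [options]")
  sub <- args[1]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--out", type = "character", default = NULL),
    optparse::make_option("--min-cell", type = "integer", default = NULL,
                          dest = "min_cell"),
    optparse::make_option("--fdr", type = "double", default = NULL),
    optparse::make_option("--n-triads", type = "integer", default = 2000,
                          dest = "n_triads")
  ))
  opt <- optparse::parse_args(parser, args[-1])
  if (sub == "simulate") {
    cfg <- simulation_config(
      seed = if (is.null(opt$seed)) 1 else opt$seed,
      n_dyads = max(1, round(opt$n_triads / 3)),
      n_triads = opt$n_triads,
      n_tetrads = max(1, round(opt$n_triads / 25)))
    dir <- if (is.null(opt$out)) "tebias_synth" else opt$out
    generate_dataset(cfg, dir)
    message("synthetic dataset written to ", dir)
    return(invisible(dir))
  }
  stage_map <- list(
    `annotate-overlaps` = "overlaps", `classify-groups` = "classify",
    `assign-categories` = "categories", screen = "screen",
    enrich = "enrich",
    `run-all` = c("overlaps", "classify", "categories", "screen", "enrich"))
  if (!sub %in% names(stage_map)) stop("unknown subcommand: ", sub)
  if (is.null(opt$config)) stop("--config is required for ", sub)
  cfg <- read_pipeline_config(opt$config)
  if (!is.null(opt$out)) cfg$out_dir <- opt$out
  if (!is.null(opt$min_cell)) cfg$min_cell <- opt$min_cell
  if (!is.null(opt$fdr)) cfg$fdr <- opt$fdr
  if (!is.null(opt$seed)) cfg$seed <- opt$seed
  invisible(run_pipeline(cfg, stage_map[[sub]]))
}
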