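#' Wicker three-letter TE classification codes
#'
#' The three-letter code carries the TE class (first letter: R = Class I
#' retrotransposon, D = Class II DNA transposon, X = unknown), the order
#' (second letter: L = LTR, I = LINE, S = SINE, T = TIR, H = Helitron,
#' X = unknown) and the superfamily (third letter). `XXX` is the bucket for
#' unclassified repeats and maps to unknown at every level.
#'
#' @return A data.frame with columns `code`, `te_class` (`"I"`, `"II"` or
#'   `"unknown"`), `te_order` (`"LTR"`, `"LINE"`, `"SINE"`, `"TIR"`,
#'   `"Helitron"` or `"unknown"`) and `superfamily` (common name, or
#'   `"unknown"`).
#' @export
wicker_codes <- function() {
  data.frame(
    code = c("RLG", "RLC", "RLX", "RIX", "SIX",
             "DTC", "DTM", "DTX", "DTH", "DTT", "DTA",
             "DXX", "DHH", "XXX"),
    te_class = c(rep("I", 5), rep("II", 8), "unknown"),
    te_order = c("LTR", "LTR", "LTR", "LINE", "SINE",
                 rep("TIR", 6), "unknown", "Helitron", "unknown"),
    superfamily = c("Gypsy", "Copia", "unknown", "unknown", "unknown",
                    "CACTA", "Mutator", "unknown", "Harbinger", "Mariner",
                    "hAT", "unknown", "Helitron", "unknown"),
    stringsAsFactors = FALSE
  )
}

#' Parse ClariTeRep-style TE subfamily names
#'
#' Names follow the pattern `<CODE>_<family>[.<subfamily>]`, e.g.
#' `RLC_famc1.6`: the first three letters are the Wicker superfamily code,
#' the token after the underscore (up to the dot) names the family, and an
#' optional trailing `.<n>` names a subfamily within the family. Unknown
#' codes do not error: they are kept verbatim with class/order/superfamily
#' `"unknown"`, matching the unclassified (`XXX`) bucket in the annotation.
#'
#' @param name Character vector of TE subfamily names.
#' @return A data.frame with one row per input name: `name`, `code`,
#'   `te_class`, `te_order`, `superfamily`, `family`, `subfamily`
#'   (`NA` when absent). Parsing is total and idempotent.
#' @examples
#' parse_te_code(c("RLC_famc1.6", "DTT_famn14", "XXX_famc13"))
#' @export
parse_te_code <- function(name) {
  stopifnot(is.character(name), all(nzchar(name)))
  code <- toupper(substr(name, 1L, 3L))
  wick <- wicker_codes()
  idx <- match(code, wick$code)
  unknown_code <- is.na(idx)
  if (any(unknown_code)) {
    warning(sum(unknown_code), " TE name(s) with unrecognized superfamily code; ",
            "kept with class/order/superfamily 'unknown'")
  }
  rest <- sub("^[^_]*_?", "", name)
  family <- ifelse(nzchar(rest), sub("\\..*$", "", rest), NA_character_)
  subfam <- ifelse(grepl("\\.", rest), sub("^[^.]*\\.", "", rest), NA_character_)
  data.frame(
    name = name,
    code = code,
    te_class = ifelse(unknown_code, "unknown", wick$te_class[idx]),
    te_order = ifelse(unknown_code, "unknown", wick$te_order[idx]),
    superfamily = ifelse(unknown_code, "unknown", wick$superfamily[idx]),
    family = family,
    subfamily = subfam,
    stringsAsFactors = FALSE
  )
}

#' Infer the wheat subgenome from a chromosome name
#'
#' Bread wheat chromosome names end in the subgenome letter (e.g. `chr1A`,
#' `5D`). Names without a trailing A/B/D give `NA`.
#'
#' @param chrom Character vector of chromosome names.
#' @return Character vector of `"A"`, `"B"`, `"D"` or `NA`.
#' @export
infer_subgenome <- function(chrom) {
  out <- rep(NA_character_, length(chrom))
  hit <- grepl("[ABD]$", chrom)
  out[hit] <- substr(chrom[hit], nchar(chrom[hit]), nchar(chrom[hit]))
  out
}

guess_format <- function(path) {
  if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) "gff3" else "tsv"
}

#' Read gene models from GFF3 or TSV
#'
#' GFF3 input uses `gene` features (attributes `ID` and optionally
#' `confidence`, HC/LC) plus `exon`, `five_prime_UTR` and `three_prime_UTR`
#' features tied to their gene through `Parent`. The TSV dialect is a
#' header-bearing table with columns `gene_id, chrom, start, stop, strand,
#' subgenome` (optional `confidence`); gene structure then comes from a
#' companion table read with [read_gene_model_tsv()]. Coordinates are
#' 1-based and inclusive throughout.
#'
#' Low-confidence (LC) genes are excluded by default because only
#' high-confidence models enter the analysis; set `include_lc = TRUE` to
#' keep them (they remain flagged in `confidence`).
#'
#' @param path Path to a GFF3 or TSV file.
#' @param format `"auto"` (by extension), `"gff3"` or `"tsv"`.
#' @param include_lc Keep low-confidence genes? Default `FALSE`.
#' @return A list with `genes` (data.frame: `gene_id`, `chrom`, `start`,
#'   `stop`, `strand`, `subgenome`, `confidence`) and `models` (data.frame:
#'   `gene_id`, `feature` in `exon`/`utr5`/`utr3`, `start`, `stop`; empty
#'   for TSV input).
#' @export
read_gene_models <- function(path, format = c("auto", "gff3", "tsv"),
                             include_lc = FALSE) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (format == "tsv") {
    genes <- utils::read.delim(path, stringsAsFactors = FALSE)
    req <- c("gene_id", "chrom", "start", "stop")
    if (!all(req %in% names(genes)))
      stop("gene TSV must have columns: ", paste(req, collapse = ", "))
    if (is.null(genes$strand)) genes$strand <- "*"
    if (is.null(genes$subgenome)) genes$subgenome <- infer_subgenome(genes$chrom)
    if (is.null(genes$confidence)) genes$confidence <- "HC"
    models <- data.frame(gene_id = character(), feature = character(),
                         start = integer(), stop = integer(),
                         stringsAsFactors = FALSE)
  } else {
    gr <- rtracklayer::import(path)
    type <- as.character(gr$type)
    gg <- gr[type == "gene"]
    conf <- if (!is.null(gg$confidence)) as.character(gg$confidence) else
      rep("HC", length(gg))
    conf[is.na(conf)] <- "HC"
    genes <- data.frame(
      gene_id = as.character(gg$ID),
      chrom = as.character(GenomicRanges::seqnames(gg)),
      start = GenomicRanges::start(gg),
      stop = GenomicRanges::end(gg),
      strand = as.character(GenomicRanges::strand(gg)),
      confidence = conf,
      stringsAsFactors = FALSE
    )
    genes$subgenome <- infer_subgenome(genes$chrom)
    feat_map <- c(exon = "exon", five_prime_UTR = "utr5",
                  three_prime_UTR = "utr3")
    fg <- gr[type %in% names(feat_map)]
    if (length(fg) > 0) {
      parent <- as.character(S4Vectors::unstrsplit(fg$Parent, ","))
      models <- data.frame(
        gene_id = parent,
        feature = unname(feat_map[as.character(fg$type)]),
        start = GenomicRanges::start(fg),
        stop = GenomicRanges::end(fg),
        stringsAsFactors = FALSE
      )
    } else {
      models <- data.frame(gene_id = character(), feature = character(),
                           start = integer(), stop = integer(),
                           stringsAsFactors = FALSE)
    }
  }
  bad <- genes$start > genes$stop
  if (any(bad))
    stop("malformed gene coordinates (start > stop): ",
         paste(utils::head(genes$gene_id[bad], 10), collapse = ", "))
  if (anyDuplicated(genes$gene_id))
    stop("duplicated gene ids in ", path)
  if (!include_lc) {
    n_lc <- sum(genes$confidence == "LC")
    if (n_lc > 0) message("excluding ", n_lc, " LC gene(s)")
    genes <- genes[genes$confidence != "LC", , drop = FALSE]
    models <- models[models$gene_id %in% genes$gene_id, , drop = FALSE]
  }
  rownames(genes) <- NULL
  rownames(models) <- NULL
  list(genes = genes, models = models)
}

#' Read a gene-structure TSV (exon/UTR intervals)
#'
#' Columns: `gene_id`, `feature` (one of `exon`, `utr5`, `utr3`), `start`,
#' `stop` (1-based inclusive).
#'
#' @param path Path to the TSV file.
#' @return A data.frame of intervals.
#' @export
read_gene_model_tsv <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "feature", "start", "stop")
  if (!all(req %in% names(m)))
    stop("gene model TSV must have columns: ", paste(req, collapse = ", "))
  bad <- !m$feature %in% c("exon", "utr5", "utr3")
  if (any(bad)) stop("unknown feature label(s): ",
                     paste(unique(m$feature[bad]), collapse = ", "))
  m
}

#' Read TE annotations from GFF3 or TSV
#'
#' Every record is kept in memory; downstream analysis is restricted to
#' records whose annotation status is `"repeat_region"` (nested repeats and
#' repeat fragments are discarded by [repeat_regions()]). GFF3 records carry
#' attributes `ID`, `Name` (the ClariTeRep subfamily name) and `status`;
#' when `status` is absent the feature type is used. The TSV dialect has
#' columns `te_id, chrom, start, stop, status, name`.
#'
#' @param path Path to a GFF3 or TSV file.
#' @param format `"auto"`, `"gff3"` or `"tsv"`.
#' @return A data.frame with columns `te_id`, `chrom`, `start`, `stop`,
#'   `status`, `name`, plus the parsed classification columns of
#'   [parse_te_code()] (`code`, `te_class`, `te_order`, `superfamily`,
#'   `family`, `subfamily`).
#' @export
read_te_annotations <- function(path, format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (format == "tsv") {
    tes <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = c(name = "character"))
    req <- c("te_id", "chrom", "start", "stop", "status", "name")
    if (!all(req %in% names(tes)))
      stop("TE TSV must have columns: ", paste(req, collapse = ", "))
  } else {
    gr <- rtracklayer::import(path)
    status <- if (!is.null(gr$status)) as.character(gr$status) else
      as.character(gr$type)
    tes <- data.frame(
      te_id = as.character(gr$ID),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      stop = GenomicRanges::end(gr),
      status = status,
      name = as.character(gr$Name),
      stringsAsFactors = FALSE
    )
  }
  if (nrow(tes) == 0) {
    cls <- parse_te_code("XXX_none")[0, -1]
    return(cbind(tes, cls))
  }
  bad <- tes$start > tes$stop
  if (any(bad))
    stop("malformed TE coordinates (start > stop): ",
         paste(utils::head(tes$te_id[bad], 10), collapse = ", "))
  cls <- parse_te_code(tes$name)
  tes <- cbind(tes, cls[, setdiff(names(cls), "name")])
  rownames(tes) <- NULL
  tes
}

#' Restrict TE annotations to "repeat region" records
#'
#' @param tes A TE table from [read_te_annotations()].
#' @param quiet Suppress the message reporting how many records were removed.
#' @return The subset with `status == "repeat_region"`.
#' @export
repeat_regions <- function(tes, quiet = FALSE) {
  keep <- tes$status == "repeat_region"
  if (!quiet && any(!keep))
    message("removed ", sum(!keep),
            " nested/fragment TE record(s); kept ", sum(keep))
  out <- tes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a chromosomal-region partition table
#'
#' Columns: `chrom`, `region` (R1/R2a/C/R2b/R3), `start`, `stop` (1-based
#' inclusive). Regions must tile each chromosome without gaps or overlaps.
#'
#' @param path Path to the TSV file.
#' @return A validated data.frame.
#' @export
read_region_partition <- function(path) {
  part <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("chrom", "region", "start", "stop")
  if (!all(req %in% names(part)))
    stop("partition TSV must have columns: ", paste(req, collapse = ", "))
  validate_region_partition(part)
  part
}

region_levels <- c("R1", "R2a", "C", "R2b", "R3")

validate_region_partition <- function(part) {
  bad <- !part$region %in% region_levels
  if (any(bad)) stop("unknown region label(s): ",
                     paste(unique(part$region[bad]), collapse = ", "))
  for (ch in unique(part$chrom)) {
    p <- part[part$chrom == ch, ]
    p <- p[order(p$start), ]
    if (nrow(p) > 1 && any(p$start[-1] != p$stop[-nrow(p)] + 1))
      stop("regions of ", ch, " do not tile the chromosome")
  }
  invisible(part)
}

#' Map fine region labels to the proximal/distal macro regions
#'
#' The pericentromeric regions R2a, C and R2b (TE-dense, low recombination)
#' form the proximal macro region; the chromosome ends R1 and R3 form the
#' distal macro region.
#'
#' @param region Character vector of R1/R2a/C/R2b/R3 labels.
#' @return `"proximal"` or `"distal"` per element.
#' @export
region_macro <- function(region) {
  bad <- !region %in% region_levels & !is.na(region)
  if (any(bad)) stop("unknown region label(s): ",
                     paste(unique(region[bad]), collapse = ", "))
  ifelse(is.na(region), NA_character_,
         ifelse(region %in% c("R2a", "C", "R2b"), "proximal", "distal"))
}

#' Assign genes to chromosomal regions
#'
#' A gene is assigned to the region containing its midpoint
#' `floor((start + stop) / 2)`. The midpoint rule is a package convention
#' for genes that straddle a region boundary: it is deterministic and
#' symmetric, and with integer flooring a midpoint always falls in exactly
#' one region (boundary midpoints land in the left region).
#'
#' @param genes A gene table (needs `gene_id`, `chrom`, `start`, `stop`).
#' @param partition A region partition from [read_region_partition()].
#' @return `genes` with `region` and `macro` columns added.
#' @export
assign_chromosomal_region <- function(genes, partition) {
  missing_chr <- setdiff(unique(genes$chrom), unique(partition$chrom))
  if (length(missing_chr) > 0)
    stop("chromosome(s) absent from region partition: ",
         paste(missing_chr, collapse = ", "))
  mid <- floor((genes$start + genes$stop) / 2)
  key_g <- genes$chrom
  region <- rep(NA_character_, nrow(genes))
  for (ch in unique(key_g)) {
    p <- partition[partition$chrom == ch, ]
    p <- p[order(p$start), ]
    sel <- which(key_g == ch)
    hit <- findInterval(mid[sel], p$start)
    ok <- hit >= 1 & mid[sel] <= p$stop[pmax(hit, 1)]
    region[sel[ok]] <- p$region[hit[ok]]
  }
  if (anyNA(region))
    stop("midpoint of ", sum(is.na(region)),
         " gene(s) outside the partitioned span of their chromosome")
  genes$region <- region
  genes$macro <- region_macro(region)
  genes
}

#' Read a homoeolog-group membership table
#'
#' Long-format TSV: one row per member gene, columns `group_id`, `gene_id`,
#' `subgenome`.
#'
#' @param path Path to the TSV file.
#' @return A data.frame.
#' @export
read_homoeolog_group_table <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("group_id", "gene_id", "subgenome")
  if (!all(req %in% names(g)))
    stop("group TSV must have columns: ", paste(req, collapse = ", "))
  g
}

#' Read a gene-by-sample TPM expression matrix
#'
#' TSV with a `gene_id` column followed by one numeric column per sample.
#'
#' @param path Path to the TSV file.
#' @return A numeric matrix with gene ids as rownames.
#' @export
read_expression_matrix <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene_id" %in% names(x)) stop("expression TSV must have a gene_id column")
  m <- as.matrix(x[, setdiff(names(x), "gene_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$gene_id
  m
}

#' Write gene / TE tables in the package TSV dialects
#'
#' Round-trip companions to [read_gene_models()] and
#' [read_te_annotations()]: writing a parsed table and re-reading it
#' reproduces identical records.
#'
#' @param genes,tes Parsed tables.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_tsv <- function(genes, path) {
  cols <- c("gene_id", "chrom", "start", "stop", "strand", "subgenome",
            "confidence")
  utils::write.table(genes[, intersect(cols, names(genes))], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_tsv
#' @export
write_te_tsv <- function(tes, path) {
  cols <- c("te_id", "chrom", "start", "stop", "status", "name")
  utils::write.table(tes[, intersect(cols, names(tes))], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
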