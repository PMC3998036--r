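#' Read per-transcript expression records
#'
#' Two dialects are supported. The generic TSV (the canonical entry point
#' for non-Cufflinks assemblers) is a header-ed tab-separated file with
#' columns `transcript_id`, `gene_id`, `condition`, `transcript_expr`,
#' `gene_expr` and optionally `iso_status`, `gene_status`, `pvalue`; one row
#' per transcript x condition. The `cufflinks_tracking` dialect reads an
#' isoforms.fpkm_tracking-like file with `tracking_id`, `gene_id` and per
#' condition `<cond>_FPKM` (optionally `<cond>_status`) columns, yielding one
#' record per transcript per condition. Cufflinks tracking files carry no
#' gene-level abundance, so either supply the matching gene-level tracking
#' file via `gene_path` or the per-gene sum of transcript FPKM is used.
#'
#' Missing expression values are coerced to 0 with a message (Cufflinks
#' emits zeros for unquantified models); duplicated (transcript, condition)
#' rows are an error.
#'
#' @param path Path to the expression table.
#' @param format `"generic_tsv"` or `"cufflinks_tracking"`.
#' @param conditions Character vector of condition labels expected in the
#'   file (generic) or used as column prefixes (cufflinks).
#' @param gene_path Optional gene-level tracking file (cufflinks dialect).
#' @return Data frame of expression records.
#' @export
read_expression <- function(path, format = c("generic_tsv", "cufflinks_tracking"),
                            conditions, gene_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("expression file not found: %s", path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (format == "generic_tsv") {
    need <- c("transcript_id", "gene_id", "condition",
              "transcript_expr", "gene_expr")
    miss <- setdiff(need, names(tab))
    if (length(miss) > 0) {
      stop(sprintf("generic expression TSV lacks column(s): %s",
                   paste(miss, collapse = ", ")))
    }
    extra <- setdiff(unique(tab$condition), conditions)
    if (length(extra) > 0) {
      stop(sprintf("unknown condition label(s): %s",
                   paste(extra, collapse = ", ")))
    }
    out <- data.frame(
      transcript_id = tab$transcript_id,
      gene_id = tab$gene_id,
      condition = tab$condition,
      transcript_expr = as.numeric(tab$transcript_expr),
      gene_expr = as.numeric(tab$gene_expr),
      iso_status = if ("iso_status" %in% names(tab)) tab$iso_status else NA_character_,
      gene_status = if ("gene_status" %in% names(tab)) tab$gene_status else NA_character_,
      pvalue = if ("pvalue" %in% names(tab)) as.numeric(tab$pvalue) else NA_real_
    )
  } else {
    id_col <- if ("tracking_id" %in% names(tab)) "tracking_id" else "transcript_id"
    if (!all(c(id_col, "gene_id") %in% names(tab))) {
      stop("cufflinks tracking file needs tracking_id and gene_id columns")
    }
    fpkm_cols <- paste0(conditions, "_FPKM")
    miss <- setdiff(fpkm_cols, names(tab))
    if (length(miss) > 0) {
      stop(sprintf("tracking file lacks FPKM column(s): %s",
                   paste(miss, collapse = ", ")))
    }
    gene_fpkm <- NULL
    if (!is.null(gene_path)) {
      gtab <- utils::read.delim(gene_path, stringsAsFactors = FALSE,
                                check.names = FALSE)
      gid_col <- if ("tracking_id" %in% names(gtab)) "tracking_id" else "gene_id"
      gene_fpkm <- gtab
      gene_fpkm$.gid <- gtab[[gid_col]]
    }
    pieces <- lapply(conditions, function(cond) {
      status_col <- paste0(cond, "_status")
      texpr <- as.numeric(tab[[paste0(cond, "_FPKM")]])
      if (!is.null(gene_fpkm)) {
        gcol <- paste0(cond, "_FPKM")
        gexpr <- as.numeric(gene_fpkm[[gcol]])[match(tab$gene_id, gene_fpkm$.gid)]
      } else {
        gexpr <- stats::ave(texpr, tab$gene_id, FUN = function(x) sum(x, na.rm = TRUE))
      }
      data.frame(
        transcript_id = tab[[id_col]],
        gene_id = tab$gene_id,
        condition = cond,
        transcript_expr = texpr,
        gene_expr = gexpr,
        iso_status = if (status_col %in% names(tab)) tab[[status_col]] else NA_character_,
        gene_status = NA_character_,
        pvalue = NA_real_
      )
    })
    out <- do.call(rbind, pieces)
  }
  n_missing <- sum(is.na(out$transcript_expr)) + sum(is.na(out$gene_expr))
  if (n_missing > 0) {
    message(sprintf("read_expression: coerced %d missing value(s) to 0", n_missing))
    out$transcript_expr[is.na(out$transcript_expr)] <- 0
    out$gene_expr[is.na(out$gene_expr)] <- 0
  }
  key <- paste(out$transcript_id, out$condition)
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate (transcript, condition) row(s): %s",
                 paste(utils::head(unique(key[duplicated(key)]), 3),
                       collapse = "; ")))
  }
  rownames(out) <- NULL
  out
}

#' Read an annotated start-codon table
#'
#' Either UCSC genePred/refGene column order (name, chrom, strand, txStart,
#' txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds; 0-based
#' half-open; an optional leading `bin` column is detected and dropped) or a
#' simple 4-column dialect (name, chrom, strand, start_codon_genomic,
#' 0-based). The genomic start-codon base is `cdsStart` on the plus strand
#' and `cdsEnd - 1` on the minus strand, i.e. always the first base of the
#' codon in transcript orientation. Non-coding entries (cdsStart == cdsEnd)
#' are dropped with a message.
#'
#' @param path Path to the table (no header for genePred; header optional
#'   for simple, detected by non-numeric 4th field).
#' @param dialect `"genepred"` or `"simple"`.
#' @return Data frame of CDS records: `name`, `chrom`, `strand`,
#'   `start_codon_genomic`.
#' @export
read_cds_table <- function(path, dialect = c("genepred", "simple")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("CDS table not found: %s", path))
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (dialect == "simple") {
    if (is.na(suppressWarnings(as.integer(tab[1, 4])))) {
      ## header row present
      tab <- tab[-1, , drop = FALSE]
    }
    out <- data.frame(
      name = tab[[1]], chrom = tab[[2]], strand = tab[[3]],
      start_codon_genomic = as.integer(tab[[4]])
    )
  } else {
    ## refGene dumps may carry a leading integer `bin` column
    if (ncol(tab) >= 10 && is.numeric(tab[[1]]) && !is.numeric(tab[[2]]) &&
        all(tab[[4]] %in% c("+", "-"))) {
      tab <- tab[, -1, drop = FALSE]
    }
    if (ncol(tab) < 10) stop("genePred table needs at least 10 columns")
    names(tab)[1:10] <- c("name", "chrom", "strand", "txStart", "txEnd",
                          "cdsStart", "cdsEnd", "exonCount",
                          "exonStarts", "exonEnds")
    ns <- lengths(strsplit(sub(",$", "", tab$exonStarts), ","))
    ne <- lengths(strsplit(sub(",$", "", tab$exonEnds), ","))
    bad <- which(ns != tab$exonCount | ne != tab$exonCount)
    if (length(bad) > 0) {
      stop(sprintf("genePred row %d: exonStarts/exonEnds length mismatch with exonCount",
                   bad[1]))
    }
    noncoding <- tab$cdsStart == tab$cdsEnd
    if (any(noncoding)) {
      message(sprintf("read_cds_table: dropped %d non-coding record(s)",
                      sum(noncoding)))
      tab <- tab[!noncoding, , drop = FALSE]
    }
    out <- data.frame(
      name = tab$name, chrom = tab$chrom, strand = tab$strand,
      start_codon_genomic = ifelse(tab$strand == "+",
                                   as.integer(tab$cdsStart),
                                   as.integer(tab$cdsEnd) - 1L)
    )
  }
  if (!all(out$strand %in% c("+", "-"))) {
    stop("CDS table strand column must be '+' or '-'")
  }
  rownames(out) <- NULL
  out
}
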