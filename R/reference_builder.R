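#' Build the hypothetical pre-RNA reference of a gene
#'
#' The pre-RNA is the per-gene merged exon model: the union of every
#' transcript's exons, with overlapping or book-ended intervals merged.
#' Its introns are exactly the maximal regions of the gene span that are
#' exonic in no transcript. A positive-length gap between merged exons is
#' the unit the intron-retention rule operates on, which is why book-ended
#' exons are merged rather than kept as a zero-length intron.
#'
#' @param g A [gene_model()].
#' @return A `reference_model`: list with `gene_id`, `chrom`, `strand`,
#'   `mode = "pre_rna"`, and `merged_exons` (sorted, disjoint, positive gaps).
#' @export
build_pre_rna <- function(g) {
  all_ex <- do.call(rbind, lapply(g$transcripts, `[[`, "exons"))
  merged <- merge_intervals(intervals(all_ex$start, all_ex$end))
  structure(
    list(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
         mode = "pre_rna", merged_exons = merged,
         source_transcript_id = NA_character_),
    class = "reference_model"
  )
}

#' Select the most-expressed transcript as the gene reference
#'
#' Useful in perturbation designs where deviation from the control condition
#' is of interest: the reference is the exon chain of the transcript with the
#' highest expression in the chosen condition. Ties break to the
#' lexicographically smallest transcript id. If every transcript has zero
#' expression in that condition, the pre-RNA is returned instead with a
#' warning.
#'
#' @param g A [gene_model()].
#' @param expression Expression record data frame (see [splice_dataset()]).
#' @param condition Condition label defining "most expressed".
#' @return A `reference_model` with `mode = "most_expressed"` (or the
#'   pre-RNA fallback).
#' @export
select_most_expressed <- function(g, expression, condition) {
  ids <- names(g$transcripts)
  rec <- expression[expression$condition == condition &
                      expression$transcript_id %in% ids, , drop = FALSE]
  miss <- setdiff(ids, rec$transcript_id)
  if (length(miss) > 0) {
    stop(sprintf("gene %s: no %s expression record for transcript(s) %s",
                 g$gene_id, condition, paste(miss, collapse = ", ")))
  }
  if (all(rec$transcript_expr == 0)) {
    warning(sprintf("gene %s: all transcripts unexpressed in %s; falling back to pre-RNA reference",
                    g$gene_id, condition), call. = FALSE)
    return(build_pre_rna(g))
  }
  rec <- rec[order(-rec$transcript_expr, rec$transcript_id), , drop = FALSE]
  top <- rec$transcript_id[1]
  structure(
    list(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
         mode = "most_expressed",
         merged_exons = g$transcripts[[top]]$exons,
         source_transcript_id = top),
    class = "reference_model"
  )
}

#' @export
print.reference_model <- function(x, ...) {
  src <- if (is.na(x$source_transcript_id)) "" else
    sprintf(" (from %s)", x$source_transcript_id)
  cat(sprintf("<reference_model %s [%s]%s, %d merged exon(s)>\n",
              x$gene_id, x$mode, src, nrow(x$merged_exons)))
  invisible(x)
}

## Introns of a reference model: gaps between merged exons.
reference_introns <- function(r) {
  n <- nrow(r$merged_exons)
  if (n < 2L) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = r$merged_exons$end[-n],
             end = r$merged_exons$start[-1L])
}
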