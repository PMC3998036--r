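STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Find the most upstream compatible annotated start codon
#'
#' A start codon from the annotation table is compatible with a transcript
#' when its genomic first base (in transcript orientation) maps into the
#' transcript's exons and the full codon -- three bases walked in transcript
#' space -- is present. Compatibility is positional: the annotation's own
#' downstream exon structure is not required to match, so novel isoforms
#' remain annotatable, and by default the mapped codon need not read ATG
#' (annotated non-ATG starts pass through; set `strict_atg` with a sequence
#' to require ATG).
#'
#' @param t A [transcript_model()].
#' @param cds CDS record table from [read_cds_table()].
#' @param strict_atg Require the mapped codon to read ATG.
#' @param seq Transcript sequence (required when `strict_atg = TRUE`).
#' @return Minimal compatible transcript coordinate, or `NA` if none.
#' @export
find_compatible_start <- function(t, cds, strict_atg = FALSE, seq = NULL) {
  cand <- cds[cds$chrom == t$chrom & cds$strand == t$strand, , drop = FALSE]
  if (nrow(cand) == 0L) return(NA_integer_)
  tpos <- genomic_to_transcript(t, cand$start_codon_genomic)
  tpos <- tpos[!is.na(tpos)]
  tpos <- tpos[tpos + 3L <= transcript_length(t)]
  if (strict_atg) {
    if (is.null(seq)) stop("strict_atg requires the transcript sequence")
    tpos <- tpos[substring(seq, tpos + 1L, tpos + 3L) == "ATG"]
  }
  if (length(tpos) == 0L) return(NA_integer_)
  min(tpos)
}

#' Scan for the first in-frame stop codon
#'
#' Walks codons 5' to 3' from the start position; the first TAA/TAG/TGA
#' encountered terminates the open reading frame.
#'
#' @param seq Transcript nucleotide string.
#' @param start_tpos 0-based transcript coordinate of the start codon's
#'   first base.
#' @return 0-based transcript coordinate of the stop codon's *last* base,
#'   or `NA` when no in-frame stop lies before the sequence end.
#' @export
scan_orf <- function(seq, start_tpos) {
  L <- nchar(seq)
  if (start_tpos < 0L || start_tpos > L - 3L) {
    stop(sprintf("start position %d leaves no room for a codon in %d nt",
                 start_tpos, L))
  }
  p <- start_tpos
  while (p + 3L <= L) {
    codon <- substring(seq, p + 1L, p + 3L)
    if (codon %in% STOP_CODONS) return(p + 2L)
    p <- p + 3L
  }
  NA_integer_
}

#' Annotate the ORF and NMD sensitivity of a transcript
#'
#' Composes start-codon lookup, ORF scanning and the premature termination
#' codon (PTC) rule: a transcript is marked NMD-sensitive when its stop
#' codon falls more than `ptc_threshold` nucleotides (default 50) upstream
#' of the final exon-exon junction. The distance is measured from the *last*
#' base of the stop codon to the last base of the penultimate exon in
#' transcript coordinates (`stop_to_junction = junction_tpos - stop_tpos`),
#' which makes the threshold boundary well defined; the threshold is
#' configurable to absorb the <= 2 nt difference to other conventions.
#' Single-exon transcripts have no junction and are never PTC-positive, and
#' transcripts without an in-frame stop are conservatively PTC-negative
#' with `status = "no_stop_found"`.
#'
#' @param t A [transcript_model()].
#' @param seqprov Sequence provider covering the transcript.
#' @param cds CDS record table.
#' @param ptc_threshold Distance threshold in nt (default 50; strict
#'   inequality, so a stop exactly 50 nt upstream is not a PTC).
#' @param strict_atg Passed to [find_compatible_start()].
#' @return One-row data frame: `transcript_id`, `gene_id`, `status`
#'   (`annotated`, `no_compatible_start` or `no_stop_found`), `start_tpos`,
#'   `stop_tpos`, `utr5_len`, `orf_len`, `utr3_len`, `junction_tpos`,
#'   `stop_to_junction`, `ptc`.
#' @export
annotate_orf <- function(t, seqprov, cds, ptc_threshold = 50,
                         strict_atg = FALSE) {
  L <- transcript_length(t)
  n_ex <- nrow(t$exons)
  junction <- if (n_ex > 1L) {
    widths <- t$exons$end - t$exons$start
    last <- if (t$strand == "+") n_ex else 1L
    L - widths[last] - 1L
  } else NA_integer_
  empty <- data.frame(
    transcript_id = t$transcript_id, gene_id = t$gene_id,
    status = "no_compatible_start",
    start_tpos = NA_integer_, stop_tpos = NA_integer_,
    utr5_len = NA_integer_, orf_len = NA_integer_, utr3_len = NA_integer_,
    junction_tpos = junction, stop_to_junction = NA_integer_, ptc = FALSE
  )
  seq <- transcript_sequence(t, seqprov)
  start <- find_compatible_start(t, cds, strict_atg = strict_atg, seq = seq)
  if (is.na(start)) return(empty)
  stop_t <- scan_orf(seq, start)
  if (is.na(stop_t)) {
    out <- empty
    out$status <- "no_stop_found"
    out$start_tpos <- start
    out$utr5_len <- start
    return(out)
  }
  stj <- if (is.na(junction)) NA_integer_ else junction - stop_t
  data.frame(
    transcript_id = t$transcript_id, gene_id = t$gene_id,
    status = "annotated",
    start_tpos = start, stop_tpos = stop_t,
    utr5_len = start,
    orf_len = stop_t - start + 1L,
    utr3_len = L - stop_t - 1L,
    junction_tpos = junction,
    stop_to_junction = stj,
    ptc = !is.na(stj) && stj > ptc_threshold
  )
}

#' Annotate ORFs for every transcript of a dataset
#'
#' @param d A [splice_dataset()] (or list of [gene_model()]s).
#' @param seqprov Sequence provider.
#' @param cds CDS record table.
#' @param ptc_threshold,strict_atg See [annotate_orf()].
#' @return Data frame with one row per transcript (see [annotate_orf()]),
#'   ordered by gene then transcript id.
#' @export
annotate_orfs <- function(d, seqprov, cds, ptc_threshold = 50,
                          strict_atg = FALSE) {
  genes <- if (inherits(d, "splice_dataset")) d$genes else d
  rows <- list()
  for (gid in sort(names(genes))) {
    g <- genes[[gid]]
    for (tid in sort(names(g$transcripts))) {
      rows[[length(rows) + 1L]] <- annotate_orf(
        g$transcripts[[tid]], seqprov, cds,
        ptc_threshold = ptc_threshold, strict_atg = strict_atg)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize PTC classes
#'
#' Tallies transcripts into PTC-negative, PTC-positive and
#' no-compatible-start classes. Transcripts whose ORF has no in-frame stop
#' count as PTC-negative (no PTC is demonstrable). Percentages are of the
#' total, rounded to one decimal.
#'
#' @param annotations Output of [annotate_orfs()].
#' @return Data frame: `class`, `count`, `percent`.
#' @export
summarize_ptc <- function(annotations) {
  n <- nrow(annotations)
  no_start <- sum(annotations$status == "no_compatible_start")
  ptc_pos <- sum(annotations$status != "no_compatible_start" & annotations$ptc)
  ptc_neg <- n - no_start - ptc_pos
  counts <- c("PTC-" = ptc_neg, "PTC+" = ptc_pos,
              "no_compatible_start" = no_start)
  pct <- if (n == 0L) c(0, 0, 0) else round(counts / n * 100, 1)
  data.frame(class = names(counts), count = as.integer(counts),
             percent = as.numeric(pct))
}
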