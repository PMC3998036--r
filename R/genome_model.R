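#' @importFrom stats setNames
NULL

## Internal convention: all coordinates are 0-based half-open [start, end).
## GTF/genePred converters at the I/O boundary are the only places that
## translate to/from 1-based inclusive.

#' Create an exon (interval) table
#'
#' Builds the canonical exon representation used throughout the package: a
#' data frame with integer `start` and `end` columns, 0-based half-open,
#' sorted by `start`.
#'
#' @param start,end Integer vectors of equal length; `start < end` pairwise.
#' @return A data frame with columns `start` and `end`.
#' @export
#' @examples
#' intervals(c(100, 300), c(200, 400))
intervals <- function(start, end) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(start) != length(end)) {
    stop("interval start/end length mismatch")
  }
  if (any(is.na(start)) || any(is.na(end))) {
    stop("interval coordinates must not be NA")
  }
  if (any(end <= start)) {
    stop("intervals must satisfy start < end")
  }
  o <- order(start, end)
  data.frame(start = start[o], end = end[o])
}

#' Construct a transcript model
#'
#' A transcript is an ordered chain of disjoint exons on one chromosome and
#' strand. Exons are sorted by genomic start; book-ended (abutting) exons are
#' merged with a warning since a zero-length intron is a file artifact, not
#' biology. Overlapping exons are a hard error.
#'
#' @param transcript_id,gene_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame with `start`/`end` (0-based half-open), e.g. from
#'   [intervals()].
#' @return An object of class `transcript_model`.
#' @export
#' @examples
#' t1 <- transcript_model("T1", "G1", "chr1", "+", intervals(100, 200))
#' transcript_length(t1)
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons) {
  if (!strand %in% c("+", "-")) {
    stop(sprintf("transcript %s: strand must be '+' or '-'", transcript_id))
  }
  if (!nzchar(chrom)) stop("chrom must be non-empty")
  exons <- intervals(exons$start, exons$end)
  if (nrow(exons) == 0L) {
    stop(sprintf("transcript %s has no exons", transcript_id))
  }
  n <- nrow(exons)
  if (n > 1L) {
    if (any(exons$start[-1L] < exons$end[-n])) {
      stop(sprintf("transcript %s has overlapping exons", transcript_id))
    }
    abut <- exons$start[-1L] == exons$end[-n]
    if (any(abut)) {
      warning(sprintf("transcript %s: merged %d book-ended exon pair(s)",
                      transcript_id, sum(abut)), call. = FALSE)
      exons <- merge_intervals(exons)
    }
  }
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
         strand = strand, exons = exons),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model %s (%s) %s%s, %d exon(s), %d nt>\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), transcript_length(x)))
  invisible(x)
}

## Merge sorted intervals, joining overlapping or book-ended neighbours.
merge_intervals <- function(iv) {
  if (nrow(iv) <= 1L) return(iv)
  r <- IRanges::reduce(IRanges::IRanges(start = iv$start + 1L, end = iv$end),
                       min.gapwidth = 1L)
  data.frame(start = IRanges::start(r) - 1L, end = IRanges::end(r))
}

#' Construct a gene model from transcripts
#'
#' All transcripts must share `gene_id`, `chrom` and `strand`; a conflict is
#' an input error (the merged pre-RNA is undefined across strands or
#' chromosomes).
#'
#' @param transcripts List of [transcript_model()] objects.
#' @return An object of class `gene_model` with the transcripts (named by
#'   transcript id) and the genomic `span` covered by their exons.
#' @export
gene_model <- function(transcripts) {
  if (length(transcripts) == 0L) stop("gene_model needs at least one transcript")
  gid <- unique(vapply(transcripts, `[[`, "", "gene_id"))
  chrom <- unique(vapply(transcripts, `[[`, "", "chrom"))
  strand <- unique(vapply(transcripts, `[[`, "", "strand"))
  if (length(gid) != 1L) {
    stop(sprintf("transcripts carry conflicting gene_ids: %s",
                 paste(gid, collapse = ", ")))
  }
  if (length(chrom) != 1L || length(strand) != 1L) {
    stop(sprintf("gene %s: transcripts on conflicting chrom/strand", gid))
  }
  names(transcripts) <- vapply(transcripts, `[[`, "", "transcript_id")
  starts <- vapply(transcripts, function(t) min(t$exons$start), integer(1))
  ends <- vapply(transcripts, function(t) max(t$exons$end), integer(1))
  structure(
    list(gene_id = gid, chrom = chrom, strand = strand,
         transcripts = transcripts,
         span = c(start = min(starts), end = max(ends))),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model %s %s%s [%d,%d), %d transcript(s)>\n",
              x$gene_id, x$chrom, x$strand, x$span[["start"]],
              x$span[["end"]], length(x$transcripts)))
  invisible(x)
}

#' Spliced length of a transcript
#'
#' @param t A [transcript_model()].
#' @return Integer: sum of exon lengths in nucleotides.
#' @export
transcript_length <- function(t) {
  sum(t$exons$end - t$exons$start)
}

#' Introns of a transcript
#'
#' @param t A [transcript_model()].
#' @return Data frame of intron intervals (0-based half-open) in genomic
#'   order; zero rows for single-exon transcripts.
#' @export
introns <- function(t) {
  n <- nrow(t$exons)
  if (n < 2L) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = t$exons$end[-n], end = t$exons$start[-1L])
}

#' Map a genomic position into transcript coordinates
#'
#' Transcript coordinates are 0-based and run 5' to 3' in transcript
#' orientation: position 0 is the transcript's first base, which on the minus
#' strand is the genomically 3'-most exonic base.
#'
#' @param t A [transcript_model()].
#' @param g Genomic position (0-based).
#' @return Integer transcript position, or `NA` when `g` is intronic or
#'   outside the transcript (not-mapped is a value, not an error).
#' @export
genomic_to_transcript <- function(t, g) {
  vapply(as.integer(g), function(gi) {
    hit <- which(t$exons$start <= gi & gi < t$exons$end)
    if (length(hit) == 0L) return(NA_integer_)
    before <- 0L
    if (hit > 1L) {
      before <- sum(t$exons$end[seq_len(hit - 1L)] -
                    t$exons$start[seq_len(hit - 1L)])
    }
    plus_pos <- before + (gi - t$exons$start[hit])
    if (t$strand == "+") plus_pos
    else transcript_length(t) - 1L - plus_pos
  }, integer(1))
}

#' Map a transcript position back to the genome
#'
#' Inverse of [genomic_to_transcript()] on its exonic domain.
#'
#' @param t A [transcript_model()].
#' @param tpos Transcript position(s), 0-based.
#' @return Genomic position(s); `NA` outside `[0, transcript_length)`.
#' @export
transcript_to_genomic <- function(t, tpos) {
  L <- transcript_length(t)
  widths <- t$exons$end - t$exons$start
  cum <- cumsum(widths)
  vapply(as.integer(tpos), function(p) {
    if (is.na(p) || p < 0L || p >= L) return(NA_integer_)
    pp <- if (t$strand == "+") p else L - 1L - p
    ex <- which(pp < cum)[1L]
    off <- pp - (if (ex > 1L) cum[ex - 1L] else 0L)
    t$exons$start[ex] + off
  }, integer(1))
}

#' Assemble a splice dataset
#'
#' Bundles gene models with per-condition expression records into the object
#' the classification and quantification layers operate on.
#'
#' @param genes List of [gene_model()] objects (named by gene id).
#' @param expression Data frame with columns `transcript_id`, `gene_id`,
#'   `condition`, `transcript_expr`, `gene_expr` and optionally `iso_status`,
#'   `gene_status`, `pvalue`.
#' @param conditions Character vector (usually length 2) of condition labels,
#'   in order; condition 1 is the reference condition.
#' @param assembler Free-text provenance string.
#' @return An object of class `splice_dataset`.
#' @export
splice_dataset <- function(genes, expression, conditions,
                           assembler = "unknown") {
  names(genes) <- vapply(genes, `[[`, "", "gene_id")
  known <- unlist(lapply(genes, function(g) names(g$transcripts)),
                  use.names = FALSE)
  if (nrow(expression) > 0) {
    bad <- setdiff(unique(expression$transcript_id), known)
    if (length(bad) > 0) {
      stop(sprintf("expression records reference unknown transcript(s): %s",
                   paste(utils::head(bad, 5), collapse = ", ")))
    }
    extra <- setdiff(unique(expression$condition), conditions)
    if (length(extra) > 0) {
      stop(sprintf("expression carries undeclared condition(s): %s",
                   paste(extra, collapse = ", ")))
    }
    if (any(expression$transcript_expr < 0) || any(expression$gene_expr < 0)) {
      stop("expression values must be non-negative")
    }
  }
  structure(
    list(genes = genes, expression = expression,
         conditions = conditions, assembler = assembler),
    class = "splice_dataset"
  )
}

#' @export
print.splice_dataset <- function(x, ...) {
  nt <- sum(vapply(x$genes, function(g) length(g$transcripts), integer(1)))
  cat(sprintf("<splice_dataset: %d gene(s), %d transcript(s), conditions %s>\n",
              length(x$genes), nt, paste(x$conditions, collapse = " vs ")))
  invisible(x)
}
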