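#' Map an isoform fraction to a grayscale colour
#'
#' Linear grayscale ramp used to colour browser tracks: fully expressed
#' isoforms (IF = 100) are black, unexpressed ones light grey. Channel value
#' is `round(200 * (1 - min(IF, 100) / 100))`, monotone non-increasing in
#' IF; values above 100 clamp to black, undefined IFs render light grey.
#'
#' @param IF Isoform fraction percentage (vectorized).
#' @return Integer matrix with columns `r`, `g`, `b` in `[0, 255]`.
#' @export
if_to_color <- function(IF) {
  IF[is.na(IF)] <- 0
  v <- as.integer(round(200 * (1 - pmin(IF, 100) / 100)))
  cbind(r = v, g = v, b = v)
}

#' Write a browser-ready GTF coloured by isoform fraction
#'
#' Emits, per transcript, one `transcript` line and one `exon` line per exon
#' (1-based inclusive coordinates) with `gene_id`, `transcript_id` and a
#' `color "R,G,B";` attribute encoding [if_to_color()] of that condition's
#' IF. GTF has no native colour column, so the colour rides in the attribute
#' field and a UCSC `track` header line opens the file; one file per
#' condition mirrors a per-condition browser track. Line order is
#' deterministic (gene, transcript, exon position), so reruns are
#' byte-identical.
#'
#' @param d A [splice_dataset()] (apply [filter_dataset()] beforehand if
#'   desired).
#' @param condition Condition whose IF values colour the track.
#' @param ifs Output of [compute_if()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(d, condition, ifs, path) {
  sub <- ifs[ifs$condition == condition, , drop = FALSE]
  lines <- sprintf('track name="splicewise_%s" description="transcripts coloured by isoform fraction (%s)" itemRgb=On',
                   condition, condition)
  for (gid in sort(names(d$genes))) {
    g <- d$genes[[gid]]
    for (tid in sort(names(g$transcripts))) {
      t <- g$transcripts[[tid]]
      ifv <- sub$IF[match(tid, sub$transcript_id)]
      col <- if_to_color(if (length(ifv) == 0L) NA_real_ else ifv)
      col_attr <- sprintf(' color "%d,%d,%d";', col[1, 1], col[1, 2], col[1, 3])
      attrs <- sprintf('gene_id "%s"; transcript_id "%s";%s',
                       t$gene_id, t$transcript_id, col_attr)
      lines <- c(lines,
                 sprintf("%s\tsplicewise\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                         t$chrom, min(t$exons$start) + 1L, max(t$exons$end),
                         t$strand, attrs),
                 gtf_exon_lines(t, extra_attr = col_attr))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
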