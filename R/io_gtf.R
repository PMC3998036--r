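#' Read transcript models from a GTF file
#'
#' Consumes only `exon` feature lines; other features (CDS, start_codon, ...)
#' are counted and reported via a message. Coordinates are converted from the
#' GTF 1-based inclusive convention to the internal 0-based half-open one.
#' Attribute parsing accepts both `key "value";` and `key value;` spellings,
#' since assembler dialects differ. UCSC `track` header lines and `#`
#' comments are skipped, so files written by [write_gtf()] read back.
#'
#' @param path Path to a GTF file.
#' @return A named list of [gene_model()] objects.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop(sprintf("GTF file not found: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & !grepl("^track([[:space:]]|$)", lines) &
    nzchar(trimws(lines))
  idx <- which(keep)
  skipped <- 0L
  rows <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L) {
      stop(sprintf("malformed GTF line %d: expected 9 tab-separated columns, got %d",
                   i, length(f)))
    }
    if (f[3] != "exon") {
      skipped <- skipped + 1L
      next
    }
    start1 <- suppressWarnings(as.integer(f[4]))
    end1 <- suppressWarnings(as.integer(f[5]))
    if (is.na(start1) || is.na(end1) || end1 < start1) {
      stop(sprintf("malformed GTF line %d: bad coordinates '%s'-'%s'",
                   i, f[4], f[5]))
    }
    attrs <- parse_gtf_attributes(f[9])
    if (is.na(attrs[["transcript_id"]]) || is.na(attrs[["gene_id"]])) {
      stop(sprintf("malformed GTF line %d: missing transcript_id/gene_id", i))
    }
    rows[[k]] <- data.frame(
      chrom = f[1], start = start1 - 1L, end = end1, strand = f[7],
      transcript_id = attrs[["transcript_id"]], gene_id = attrs[["gene_id"]]
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (skipped > 0L) {
    message(sprintf("read_gtf: ignored %d non-exon feature line(s)", skipped))
  }
  if (length(rows) == 0L) stop(sprintf("no exon features found in %s", path))
  tab <- do.call(rbind, rows)

  transcripts <- lapply(split(tab, tab$transcript_id), function(d) {
    if (length(unique(d$strand)) != 1L) {
      stop(sprintf("transcript %s has exons on mixed strands",
                   d$transcript_id[1]))
    }
    if (length(unique(d$chrom)) != 1L) {
      stop(sprintf("transcript %s has exons on multiple chromosomes",
                   d$transcript_id[1]))
    }
    transcript_model(d$transcript_id[1], d$gene_id[1], d$chrom[1],
                     d$strand[1], intervals(d$start, d$end))
  })
  by_gene <- split(transcripts,
                   vapply(transcripts, `[[`, "", "gene_id"))
  lapply(by_gene, gene_model)
}

## Parse a GTF column-9 attribute string into a named character vector.
## Accepts quoted and unquoted values; unknown keys are preserved.
parse_gtf_attributes <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  out <- c(transcript_id = NA_character_, gene_id = NA_character_)
  for (p in parts) {
    m <- regmatches(p, regexec('^([A-Za-z_][A-Za-z0-9_]*)[[:space:]]+"?([^"]*)"?$', p))[[1]]
    if (length(m) == 3L) out[m[2]] <- m[3]
  }
  out
}

#' Format an exon table as GTF feature lines
#' @keywords internal
gtf_exon_lines <- function(t, source = "splicewise", extra_attr = "") {
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";%s',
                   t$gene_id, t$transcript_id, extra_attr)
  sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
          t$chrom, source, t$exons$start + 1L, t$exons$end, t$strand, attrs)
}
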