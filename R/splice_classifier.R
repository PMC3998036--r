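## Event classes, in the fixed reporting order.
EVENT_CLASSES <- c("ESI", "MESI", "A5", "A3", "IR", "ATSS", "ATTS", "MEE")

new_splice_event <- function(gene_id, transcript_id, event_class, chrom,
                             strand, elements, flank_5 = NA_integer_,
                             flank_3 = NA_integer_,
                             reference_mode = NA_character_) {
  elements <- data.frame(start = as.integer(elements$start),
                         end = as.integer(elements$end))
  elements <- elements[order(elements$start), , drop = FALSE]
  rownames(elements) <- NULL
  structure(
    list(gene_id = gene_id, transcript_id = transcript_id,
         event_class = event_class, chrom = chrom, strand = strand,
         elements = elements, flank_5 = flank_5, flank_3 = flank_3,
         reference_mode = reference_mode),
    class = "splice_event"
  )
}

#' @export
print.splice_event <- function(x, ...) {
  cat(sprintf("<%s %s/%s %s>\n", x$event_class, x$gene_id, x$transcript_id,
              format_elements(x$chrom, x$elements)))
  invisible(x)
}

## Reference boundaries immediately flanking the event's element span,
## oriented 5'/3' along the transcript strand. Used downstream for motif
## extraction around the spliced element.
event_flanks <- function(elements, bounds, strand) {
  lo <- min(elements$start)
  hi <- max(elements$end)
  left <- bounds[bounds < lo]
  right <- bounds[bounds > hi]
  left <- if (length(left)) max(left) else NA_integer_
  right <- if (length(right)) min(right) else NA_integer_
  if (strand == "+") c(flank_5 = left, flank_3 = right)
  else c(flank_5 = right, flank_3 = left)
}

#' Classify the splicing of one transcript against a gene reference
#'
#' Implements the deterministic decision procedure that defines the event
#' taxonomy (orientation words are transcript-strand-relative):
#'
#' 1. **ATSS** -- if the transcript's first exon shares no base with the
#'    reference's first merged exon, one event whose elements are the maximal
#'    reference-exonic intervals strictly 5' of the transcription start.
#' 2. **ATTS** -- the symmetric rule at the 3' end.
#' 3. **IR** -- every reference intron fully contained in a single transcript
#'    exon yields one intron-retention event (element = the intron).
#' 4. **ESI/MESI** -- within the span between the transcript's first and last
#'    exon, each maximal run of k consecutive reference merged exons with no
#'    base overlap with the transcript: k = 1 gives an ESI with one element,
#'    k >= 2 one MESI with k elements.
#' 5. **A5/A3** -- a transcript exon boundary on its internal (spliced) side
#'    lying strictly inside a reference merged exon, with the remainder of
#'    that exon contained in the adjacent transcript intron, yields an
#'    alternative donor (A5) or acceptor (A3) event whose element is the
#'    reference-exonic sliver the transcript splices out. Terminal exons
#'    contribute only on their spliced side.
#'
#' Reference exons 5'/3' of an alternative start/termination are reported
#' inside the single ATSS/ATTS event, never double-counted as skipping. A
#' first exon that starts inside the reference first exon is not an ATSS
#' (assemblers trim transcript ends non-biologically).
#'
#' @param t A [transcript_model()].
#' @param r A `reference_model` for the same gene ([build_pre_rna()] or
#'   [select_most_expressed()]).
#' @return List of `splice_event` objects, ordered by genomic position.
#' @export
classify_transcript <- function(t, r) {
  if (!identical(t$gene_id, r$gene_id)) {
    stop(sprintf("transcript %s (gene %s) classified against reference for gene %s",
                 t$transcript_id, t$gene_id, r$gene_id))
  }
  ex_t <- t$exons
  ex_r <- r$merged_exons
  n_t <- nrow(ex_t)
  n_r <- nrow(ex_r)
  plus <- t$strand == "+"
  t_lo <- ex_t$start[1L]
  t_hi <- ex_t$end[n_t]
  bounds <- sort(unique(c(ex_r$start, ex_r$end)))
  events <- list()
  add <- function(cls, elements) {
    fl <- event_flanks(elements, bounds, t$strand)
    events[[length(events) + 1L]] <<- new_splice_event(
      t$gene_id, t$transcript_id, cls, t$chrom, t$strand, elements,
      fl[["flank_5"]], fl[["flank_3"]], r$mode)
  }
  overlaps <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1

  ## (1) ATSS / (2) ATTS
  t_first <- if (plus) 1L else n_t
  r_first <- if (plus) 1L else n_r
  t_last <- if (plus) n_t else 1L
  r_last <- if (plus) n_r else 1L
  if (!overlaps(ex_t$start[t_first], ex_t$end[t_first],
                ex_r$start[r_first], ex_r$end[r_first])) {
    el <- if (plus) clip_intervals(ex_r, -Inf, t_lo)
          else clip_intervals(ex_r, t_hi, Inf)
    if (nrow(el) > 0) add("ATSS", el)
  }
  if (!overlaps(ex_t$start[t_last], ex_t$end[t_last],
                ex_r$start[r_last], ex_r$end[r_last])) {
    el <- if (plus) clip_intervals(ex_r, t_hi, Inf)
          else clip_intervals(ex_r, -Inf, t_lo)
    if (nrow(el) > 0) add("ATTS", el)
  }

  ## (3) IR: reference introns bridged by one transcript exon
  ri <- reference_introns(r)
  for (i in seq_len(nrow(ri))) {
    hit <- which(ex_t$start <= ri$start[i] & ri$end[i] <= ex_t$end)
    if (length(hit) > 0) add("IR", data.frame(start = ri$start[i],
                                              end = ri$end[i]))
  }

  ## (4) ESI / MESI: skipped reference exons strictly within the span
  skipped <- integer(0)
  for (i in seq_len(n_r)) {
    if (ex_r$start[i] >= t_lo && ex_r$end[i] <= t_hi) {
      any_ov <- any(ex_t$start < ex_r$end[i] & ex_r$start[i] < ex_t$end)
      if (!any_ov) skipped <- c(skipped, i)
    }
  }
  if (length(skipped) > 0) {
    run_id <- cumsum(c(1L, diff(skipped) != 1L))
    for (run in split(skipped, run_id)) {
      el <- ex_r[run, , drop = FALSE]
      add(if (length(run) == 1L) "ESI" else "MESI", el)
    }
  }

  ## (5) A5 / A3: boundary slivers spliced out of a reference exon
  for (j in seq_len(n_t)) {
    if (j < n_t) {                         # genomic end-side boundary
      e <- ex_t$end[j]
      i <- which(ex_r$start < e & e < ex_r$end)
      if (length(i) == 1L && ex_t$start[j + 1L] >= ex_r$end[i]) {
        add(if (plus) "A5" else "A3",
            data.frame(start = e, end = ex_r$end[i]))
      }
    }
    if (j > 1L) {                          # genomic start-side boundary
      s <- ex_t$start[j]
      i <- which(ex_r$start < s & s < ex_r$end)
      if (length(i) == 1L && ex_t$end[j - 1L] <= ex_r$start[i]) {
        add(if (plus) "A3" else "A5",
            data.frame(start = ex_r$start[i], end = s))
      }
    }
  }

  order_events(events)
}

## Clip reference exons to the open genomic region (lo, hi); keeps maximal
## reference-exonic intervals strictly inside the region.
clip_intervals <- function(iv, lo, hi) {
  s <- pmax(iv$start, if (is.finite(lo)) as.integer(lo) else iv$start)
  e <- pmin(iv$end, if (is.finite(hi)) as.integer(hi) else iv$end)
  keep <- s < e
  data.frame(start = s[keep], end = e[keep])
}

order_events <- function(events) {
  if (length(events) == 0L) return(events)
  lo <- vapply(events, function(ev) min(ev$elements$start), integer(1))
  cls <- vapply(events, `[[`, "", "event_class")
  events[order(lo, match(cls, EVENT_CLASSES))]
}

#' Detect mutually exclusive exons between transcript pairs of a gene
#'
#' The pre-RNA contains both exons of a mutually exclusive pair, so
#' exclusivity can only be observed between transcripts: for each unordered
#' transcript pair, exon a of one and exon b of the other form an MEE when
#' they do not overlap, neither shares a base with any exon of the other
#' transcript, and both lie between a pair of exons with identical
#' coordinates in the two transcripts with no other exon of either between
#' those flanks. Events are deduplicated across pairs by element coordinates.
#'
#' @param g A [gene_model()] with at least two transcripts.
#' @return List of `splice_event` objects of class `"MEE"`; the
#'   `transcript_id` field holds both ids joined by `"|"`.
#' @export
detect_mee <- function(g) {
  trs <- g$transcripts
  if (length(trs) < 2L) return(list())
  events <- list()
  seen <- character(0)
  ids <- sort(names(trs))
  for (ai in seq_len(length(ids) - 1L)) {
    for (bi in seq(ai + 1L, length(ids))) {
      ta <- trs[[ids[ai]]]; tb <- trs[[ids[bi]]]
      exa <- ta$exons; exb <- tb$exons
      key_a <- paste(exa$start, exa$end)
      key_b <- paste(exb$start, exb$end)
      common <- exa[key_a %in% key_b, , drop = FALSE]
      if (nrow(common) < 2L) next
      ## exons private to each transcript at the base level
      priv_a <- which(vapply(seq_len(nrow(exa)), function(i)
        !any(exb$start < exa$end[i] & exa$start[i] < exb$end), logical(1)))
      priv_b <- which(vapply(seq_len(nrow(exb)), function(i)
        !any(exa$start < exb$end[i] & exb$start[i] < exa$end), logical(1)))
      for (i in priv_a) for (j in priv_b) {
        a <- exa[i, ]; b <- exb[j, ]
        if (a$start < b$end && b$start < a$end) next  # must not overlap
        lo <- min(a$start, b$start)
        hi <- max(a$end, b$end)
        lf <- common[common$end <= lo, , drop = FALSE]
        rf <- common[common$start >= hi, , drop = FALSE]
        if (nrow(lf) == 0L || nrow(rf) == 0L) next
        L <- max(lf$end); R <- min(rf$start)
        ## no other exon of either transcript between the innermost flanks
        between <- function(ex, keep_s, keep_e) {
          ov <- ex$start < R & ex$end > L
          drop <- ex$start == keep_s & ex$end == keep_e
          any(ov & !drop)
        }
        if (between(exa, a$start, a$end) || between(exb, b$start, b$end)) next
        el <- intervals(c(a$start, b$start), c(a$end, b$end))
        key <- paste(g$gene_id, paste(el$start, el$end, collapse = ","))
        if (key %in% seen) next
        seen <- c(seen, key)
        bounds <- sort(unique(c(exa$start, exa$end, exb$start, exb$end)))
        fl <- event_flanks(el, bounds, g$strand)
        events[[length(events) + 1L]] <- new_splice_event(
          g$gene_id, paste(ids[ai], ids[bi], sep = "|"), "MEE", g$chrom,
          g$strand, el, fl[["flank_5"]], fl[["flank_3"]], "transcript_pair")
      }
    }
  }
  order_events(events)
}

#' Classify all transcripts of a dataset
#'
#' Runs [classify_transcript()] for every transcript against its gene's
#' reference (the hypothetical pre-RNA or the most-expressed transcript in
#' the reference condition) and [detect_mee()] per gene, returning one event
#' table with a stable ordering (gene, transcript, genomic position).
#'
#' @param d A [splice_dataset()].
#' @param reference_mode `"pre_rna"` or `"most_expressed"`.
#' @param condition Condition defining the most-expressed reference;
#'   defaults to the dataset's first (reference) condition.
#' @return Event table; see [events_table()] for columns.
#' @export
classify_all <- function(d, reference_mode = c("pre_rna", "most_expressed"),
                         condition = NULL) {
  reference_mode <- match.arg(reference_mode)
  if (is.null(condition)) condition <- d$conditions[1]
  gene_ids <- sort(names(d$genes))
  all_events <- list()
  for (gid in gene_ids) {
    g <- d$genes[[gid]]
    r <- if (reference_mode == "pre_rna") build_pre_rna(g)
         else select_most_expressed(g, d$expression, condition)
    for (tid in sort(names(g$transcripts))) {
      ev <- classify_transcript(g$transcripts[[tid]], r)
      all_events <- c(all_events, ev)
    }
    all_events <- c(all_events, detect_mee(g))
  }
  events_table(all_events)
}

#' Serialize splice events into the event table
#'
#' Element coordinates are rendered 1-based inclusive (`chrom:start-end`,
#' semicolon-separated) for interoperability with browser tooling; internal
#' consumers should parse them back with [parse_elements()].
#'
#' @param events List of `splice_event` objects.
#' @return Data frame with columns `gene_id`, `transcript_id`,
#'   `event_class`, `chrom`, `strand`, `n_elements`, `elements`, `flank_5`,
#'   `flank_3`, `reference_mode`.
#' @export
events_table <- function(events) {
  if (length(events) == 0L) {
    return(data.frame(gene_id = character(0), transcript_id = character(0),
                      event_class = character(0), chrom = character(0),
                      strand = character(0), n_elements = integer(0),
                      elements = character(0), flank_5 = integer(0),
                      flank_3 = integer(0), reference_mode = character(0)))
  }
  tab <- do.call(rbind, lapply(events, function(ev) {
    data.frame(
      gene_id = ev$gene_id, transcript_id = ev$transcript_id,
      event_class = ev$event_class, chrom = ev$chrom, strand = ev$strand,
      n_elements = nrow(ev$elements),
      elements = format_elements(ev$chrom, ev$elements),
      flank_5 = ev$flank_5, flank_3 = ev$flank_3,
      reference_mode = ev$reference_mode
    )
  }))
  lo <- vapply(events, function(ev) min(ev$elements$start), integer(1))
  tab <- tab[order(tab$gene_id, tab$transcript_id, lo,
                   match(tab$event_class, EVENT_CLASSES)), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

format_elements <- function(chrom, elements) {
  paste(sprintf("%s:%d-%d", chrom, elements$start + 1L, elements$end),
        collapse = ";")
}

#' Parse an `elements` string back into 0-based half-open intervals
#' @param s Character scalar like `"chr1:301-400;chr1:501-600"`.
#' @return Data frame with `start` and `end` columns.
#' @export
parse_elements <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^.+:([0-9]+)-([0-9]+)$", parts))
  data.frame(start = vapply(m, function(x) as.integer(x[2]), integer(1)) - 1L,
             end = vapply(m, function(x) as.integer(x[3]), integer(1)))
}

#' Count events per class
#'
#' @param tab Event table from [classify_all()] or [events_table()].
#' @return Named integer vector over all eight classes, zero-filled.
#' @export
count_events <- function(tab) {
  counts <- table(factor(tab$event_class, levels = EVENT_CLASSES))
  stats::setNames(as.integer(counts), EVENT_CLASSES)
}

#' Write the event table as TSV
#' @param tab Event table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert event elements to BED6 records
#'
#' One BED line per element (0-based half-open), named `class:transcript_id`,
#' for downstream motif tools.
#'
#' @param tab Event table.
#' @return Data frame with BED6 columns.
#' @export
events_to_bed <- function(tab) {
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    el <- parse_elements(tab$elements[i])
    data.frame(chrom = tab$chrom[i], start = el$start, end = el$end,
               name = paste0(tab$event_class[i], ":", tab$transcript_id[i]),
               score = 0L, strand = tab$strand[i])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = integer(0), strand = character(0))
  }
  out
}
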