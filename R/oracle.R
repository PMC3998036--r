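## Brute-force re-implementation of the event taxonomy from exhaustive
## per-base membership vectors over the gene span. Deliberately independent
## of the interval algebra in classify_transcript()/detect_mee(): structure
## (exon runs, intron runs, boundaries) is re-derived from base-wise boolean
## scans. Used as the test oracle; quadratic/linear in span length, so keep
## spans modest (<= 100 kb).

runs_of <- function(v, offset) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start = starts[keep] + offset, end = ends[keep] + offset)
}

#' Oracle classification of one transcript by per-base scan
#'
#' Independent reference implementation of [classify_transcript()] working
#' on boolean base-membership vectors. Returns events comparable via
#' [event_signature()] (flank fields are not computed).
#'
#' @param t A [transcript_model()].
#' @param r A `reference_model`.
#' @return List of `splice_event` objects.
#' @export
oracle_classify <- function(t, r) {
  lo <- min(t$exons$start[1], r$merged_exons$start[1])
  hi <- max(t$exons$end[nrow(t$exons)],
            r$merged_exons$end[nrow(r$merged_exons)])
  n <- hi - lo
  tex <- logical(n)
  rex <- logical(n)
  for (i in seq_len(nrow(t$exons))) {
    tex[(t$exons$start[i] - lo + 1L):(t$exons$end[i] - lo)] <- TRUE
  }
  for (i in seq_len(nrow(r$merged_exons))) {
    rex[(r$merged_exons$start[i] - lo + 1L):(r$merged_exons$end[i] - lo)] <- TRUE
  }
  t_runs <- runs_of(tex, lo)
  r_runs <- runs_of(rex, lo)
  plus <- t$strand == "+"
  t_lo <- min(which(tex)) + lo - 1L
  t_hi <- max(which(tex)) + lo
  events <- list()
  add <- function(cls, el) {
    if (nrow(el) == 0L) return()
    events[[length(events) + 1L]] <<- new_splice_event(
      t$gene_id, t$transcript_id, cls, t$chrom, t$strand, el,
      reference_mode = r$mode)
  }
  rex_at <- function(g) {
    i <- g - lo + 1L
    i >= 1L && i <= n && rex[i]
  }
  tex_between <- function(a, b) {          # any t-exonic base in [a, b)
    if (b <= a) return(FALSE)
    any(tex[(a - lo + 1L):(b - lo)])
  }

  ## ATSS / ATTS by first/last run overlap
  t_first <- if (plus) 1L else nrow(t_runs)
  r_first <- if (plus) 1L else nrow(r_runs)
  t_last <- if (plus) nrow(t_runs) else 1L
  r_last <- if (plus) nrow(r_runs) else 1L
  ov <- function(i, j) t_runs$start[i] < r_runs$end[j] &&
    r_runs$start[j] < t_runs$end[i]
  if (!ov(t_first, r_first)) {
    mask <- rex & if (plus) (seq_len(n) + lo - 1L) < t_lo
                  else (seq_len(n) + lo - 1L) >= t_hi
    add("ATSS", runs_of(mask, lo))
  }
  if (!ov(t_last, r_last)) {
    mask <- rex & if (plus) (seq_len(n) + lo - 1L) >= t_hi
                  else (seq_len(n) + lo - 1L) < t_lo
    add("ATTS", runs_of(mask, lo))
  }

  ## IR: non-reference-exonic runs inside the reference span, all t-exonic
  r_span <- range(which(rex))
  inner <- !rex
  inner[seq_len(r_span[1])] <- FALSE
  if (r_span[2] < n) inner[seq(r_span[2], n)] <- FALSE
  inner_runs <- runs_of(inner, lo)
  for (k in seq_len(nrow(inner_runs))) {
    iv <- inner_runs[k, ]
    if (all(tex[(iv$start - lo + 1L):(iv$end - lo)])) {
      add("IR", data.frame(start = iv$start, end = iv$end))
    }
  }

  ## ESI / MESI: reference runs without any t base, inside the t span
  skipped <- which(vapply(seq_len(nrow(r_runs)), function(i) {
    r_runs$start[i] >= t_lo && r_runs$end[i] <= t_hi &&
      !tex_between(r_runs$start[i], r_runs$end[i])
  }, logical(1)))
  if (length(skipped) > 0) {
    for (grp in split(skipped, cumsum(c(1L, diff(skipped) != 1L)))) {
      add(if (length(grp) == 1L) "ESI" else "MESI",
          r_runs[grp, , drop = FALSE])
    }
  }

  ## A5 / A3 boundary slivers
  for (j in seq_len(nrow(t_runs))) {
    if (j < nrow(t_runs)) {
      e <- t_runs$end[j]
      if (rex_at(e) && rex_at(e - 1L)) {
        b <- e
        while (rex_at(b)) b <- b + 1L
        if (!tex_between(e, b)) {
          add(if (plus) "A5" else "A3", data.frame(start = e, end = b))
        }
      }
    }
    if (j > 1L) {
      s <- t_runs$start[j]
      if (rex_at(s) && rex_at(s - 1L)) {
        a <- s - 1L
        while (rex_at(a - 1L)) a <- a - 1L
        if (!tex_between(a, s)) {
          add(if (plus) "A3" else "A5", data.frame(start = a, end = s))
        }
      }
    }
  }
  order_events(events)
}

#' Oracle mutually-exclusive-exon detection by per-base scan
#'
#' Exhaustive pairwise brute force over all exon pairs of all transcript
#' pairs, with exclusivity and flank conditions evaluated on base-membership
#' vectors.
#'
#' @param g A [gene_model()].
#' @return List of `splice_event` objects of class `"MEE"`.
#' @export
oracle_mee <- function(g) {
  trs <- g$transcripts
  if (length(trs) < 2L) return(list())
  lo <- g$span[["start"]]
  n <- g$span[["end"]] - lo
  vecs <- lapply(trs, function(t) {
    v <- logical(n)
    for (i in seq_len(nrow(t$exons))) {
      v[(t$exons$start[i] - lo + 1L):(t$exons$end[i] - lo)] <- TRUE
    }
    v
  })
  ids <- sort(names(trs))
  events <- list()
  seen <- character(0)
  for (ai in seq_len(length(ids) - 1L)) for (bi in seq(ai + 1L, length(ids))) {
    va <- vecs[[ids[ai]]]; vb <- vecs[[ids[bi]]]
    runs_a <- runs_of(va, lo); runs_b <- runs_of(vb, lo)
    key_a <- paste(runs_a$start, runs_a$end)
    key_b <- paste(runs_b$start, runs_b$end)
    common <- runs_a[key_a %in% key_b, , drop = FALSE]
    if (nrow(common) < 2L) next
    base_free <- function(v, iv) !any(v[(iv$start - lo + 1L):(iv$end - lo)])
    for (i in seq_len(nrow(runs_a))) for (j in seq_len(nrow(runs_b))) {
      a <- runs_a[i, ]; b <- runs_b[j, ]
      if (!base_free(vb, a) || !base_free(va, b)) next
      if (a$start < b$end && b$start < a$end) next
      span_lo <- min(a$start, b$start); span_hi <- max(a$end, b$end)
      lf <- common$end[common$end <= span_lo]
      rf <- common$start[common$start >= span_hi]
      if (length(lf) == 0L || length(rf) == 0L) next
      L <- max(lf); R <- min(rf)
      region <- (va | vb)[(L - lo + 1L):(R - lo)]
      for (iv in list(a, b)) {
        region[(iv$start - L + 1L):(iv$end - L)] <- FALSE
      }
      if (any(region)) next
      el <- intervals(c(a$start, b$start), c(a$end, b$end))
      key <- paste(el$start, el$end, collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      events[[length(events) + 1L]] <- new_splice_event(
        g$gene_id, paste(ids[ai], ids[bi], sep = "|"), "MEE", g$chrom,
        g$strand, el, reference_mode = "transcript_pair")
    }
  }
  order_events(events)
}

#' Canonical comparable signature of a set of events
#'
#' Sorted strings of class, transcript and element coordinates; flank and
#' reference-mode fields are excluded so production and oracle outputs
#' compare directly.
#'
#' @param events List of `splice_event` objects.
#' @return Sorted character vector.
#' @export
event_signature <- function(events) {
  sort(vapply(events, function(ev) {
    paste0(ev$event_class, "|", ev$transcript_id, "|",
           paste(ev$elements$start, ev$elements$end, sep = "-",
                 collapse = ","))
  }, character(1)))
}
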