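## Deterministic synthetic-data generator. Produces coherent gene models,
## genome sequence, start-codon annotations and expression tables with
## planted splice events, planted ORF/PTC structure, planted switches and
## planted splice-site motifs -- every planted feature is recorded as ground
## truth so recovery can be asserted exactly.

BASES <- c("A", "C", "G", "T")

comp_chars <- function(x) chartr("ACGT", "TGCA", x)

rand_bases <- function(k) sample(BASES, k, replace = TRUE)

#' Describe a synthetic gene to plant
#'
#' The blueprint fixes the reference exon chain size, the multiset of splice
#' events to plant (each realized as one additional transcript derived from
#' the canonical full chain; MEE uses two), the coding structure planted on
#' the canonical transcript, and the expression profile. A blueprint is
#' validated for realizability: each internal event consumes a block of
#' internal reference exons and blocks are separated by one untouched exon,
#' which also guarantees that no unplanned mutually exclusive exon pair can
#' arise between the derived transcripts.
#'
#' @param planted_events Character vector over
#'   `c("ESI","MESI","A5","A3","IR","ATSS","ATTS","MEE")`.
#' @param planted_cds One of `"canonical_stop"`, `"ptc_at_distance"`,
#'   `"no_start"`, `"none"`.
#' @param ptc_distance Planted stop-to-junction distance in nt (for
#'   `"ptc_at_distance"`).
#' @param n_ref_exons Reference exon count; `NULL` auto-sizes to the events.
#' @param exon_len,intron_len Length ranges in nt.
#' @param switch_dif Planted switch magnitude in IF percentage points
#'   (0 = no switch; requires at least one alternative transcript).
#' @param gene_expr Total gene expression per condition (length 2).
#' @param seed Optional seed applied at the start of [simulate_gene()].
#' @return A `gene_blueprint` list.
#' @export
gene_blueprint <- function(planted_events = character(0),
                           planted_cds = "canonical_stop",
                           ptc_distance = 80L,
                           n_ref_exons = NULL,
                           exon_len = c(120L, 260L),
                           intron_len = c(80L, 200L),
                           switch_dif = 0,
                           gene_expr = c(100, 80),
                           seed = NULL) {
  bad <- setdiff(planted_events, EVENT_CLASSES)
  if (length(bad) > 0) {
    stop(sprintf("unknown event class(es): %s", paste(bad, collapse = ", ")))
  }
  if (sum(planted_events == "ATSS") > 1L || sum(planted_events == "ATTS") > 1L) {
    stop("unrealizable blueprint: at most one ATSS and one ATTS per gene")
  }
  if (!planted_cds %in% c("canonical_stop", "ptc_at_distance", "no_start", "none")) {
    stop("unknown planted_cds kind")
  }
  internal <- planted_events[planted_events %in%
                               c("ESI", "MESI", "A5", "A3", "IR", "MEE")]
  sizes <- c(ESI = 1L, MESI = 2L, A5 = 1L, A3 = 1L, IR = 2L, MEE = 2L)
  needed <- if (length(internal) == 0L) 0L else
    sum(sizes[internal]) + (length(internal) - 1L)
  min_n <- max(if (length(internal) > 0L) 2L + needed else 1L,
               if (any(planted_events %in% c("ATSS", "ATTS"))) 3L else 1L,
               if (planted_cds == "ptc_at_distance") 2L else 1L)
  if (is.null(n_ref_exons)) {
    n_ref_exons <- max(4L, min_n)
  } else if (n_ref_exons < min_n) {
    stop(sprintf("unrealizable blueprint: %d reference exons cannot host %s (need >= %d)",
                 n_ref_exons, paste(planted_events, collapse = "+"), min_n))
  }
  if (planted_cds == "ptc_at_distance" && is.null(ptc_distance)) {
    stop("ptc_at_distance requires ptc_distance")
  }
  if (switch_dif > 0 && length(planted_events) == 0L) {
    stop("unrealizable blueprint: a switch needs at least one alternative transcript")
  }
  structure(
    list(planted_events = planted_events, planted_cds = planted_cds,
         ptc_distance = as.integer(ptc_distance), n_ref_exons = n_ref_exons,
         exon_len = as.integer(exon_len), intron_len = as.integer(intron_len),
         switch_dif = switch_dif, gene_expr = gene_expr, seed = seed),
    class = "gene_blueprint"
  )
}

## Plant a dinucleotide motif at genomic positions [pos, pos+2) of the
## working genome vector, in transcript orientation given the strand.
plant_motif_sites <- function(genome, offset, sites, canonical_frac) {
  truth <- vector("list", nrow(sites))
  for (k in seq_len(nrow(sites))) {
    target <- sites$target[k]
    canonical <- stats::runif(1) < canonical_frac
    if (canonical) {
      din <- target
    } else {
      repeat {
        din <- paste(rand_bases(2L), collapse = "")
        if (din != target) break
      }
    }
    i <- sites$gpos[k] - offset + 1L
    genome[i] <- substring(din, 1L, 1L)
    genome[i + 1L] <- substring(din, 2L, 2L)
    truth[[k]] <- data.frame(side = sites$side[k], gpos = sites$gpos[k],
                             canonical = canonical)
  }
  list(genome = genome, truth = do.call(rbind, truth))
}

## Unique donor/acceptor motif sites over all introns of all transcripts.
## Genomic target strings already account for strand orientation.
collect_motif_sites <- function(transcripts, strand) {
  rows <- list()
  for (t in transcripts) {
    ivs <- introns(t)
    for (i in seq_len(nrow(ivs))) {
      if (strand == "+") {
        rows[[length(rows) + 1L]] <- data.frame(
          side = c("donor", "acceptor"),
          gpos = c(ivs$start[i], ivs$end[i] - 2L),
          target = c("GT", "AG"))
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          side = c("donor", "acceptor"),
          gpos = c(ivs$end[i] - 2L, ivs$start[i]),
          target = c("AC", "CT"))
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(side = character(0), gpos = integer(0),
                      target = character(0)))
  }
  out <- unique(do.call(rbind, rows))
  out[order(out$gpos), , drop = FALSE]
}

## Plant the coding sequence of the canonical transcript, respecting locked
## motif bases. Returns NULL if no feasible layout (caller retries).
plant_cds <- function(t, genome, offset, locked_g, kind, d, ptc_threshold = 50) {
  L <- transcript_length(t)
  n_ex <- nrow(t$exons)
  g_of <- transcript_to_genomic(t, 0:(L - 1L))
  plus <- t$strand == "+"
  widths <- t$exons$end - t$exons$start
  junction <- if (n_ex > 1L) L - widths[if (plus) n_ex else 1L] - 1L
              else NA_integer_

  read_t <- function(p) {
    ch <- genome[g_of[p + 1L] - offset + 1L]
    if (plus) ch else comp_chars(ch)
  }
  write_t <- function(p, x) {
    genome[g_of[p + 1L] - offset + 1L] <<- if (plus) x else comp_chars(x)
  }
  locked_t <- function(p) g_of[p + 1L] %in% locked_g

  if (kind == "ptc_at_distance") {
    if (n_ex < 2L) return(NULL)
    stop_tpos <- junction - d
    if (stop_tpos < 40L) return(NULL)
    frame0 <- (stop_tpos - 2L) %% 3L
    cand <- seq(frame0, stop_tpos - 8L, by = 3L)
    cand <- cand[cand >= 24L]
    if (length(cand) == 0L) return(NULL)
    start_tpos <- cand[1L]
  } else {
    start_tpos <- 24L + sample(0:15, 1L) * 3L
    low <- if (n_ex > 1L) junction + 1L else start_tpos + 6L
    k_min <- ceiling((low - start_tpos - 2L) / 3)
    k_max <- floor((L - 4L - start_tpos - 2L) / 3)
    if (k_max < k_min || k_max < 2L) return(NULL)
    k_min <- max(k_min, 2L)
    stop_tpos <- start_tpos + 2L + 3L * sample(k_min:k_max, 1L)
  }
  if (stop_tpos > L - 1L || start_tpos + 8L > stop_tpos) return(NULL)

  ## shift the start (in frame) off any locked motif base
  tries <- 0L
  while (any(vapply(start_tpos + 0:2, locked_t, logical(1)))) {
    start_tpos <- start_tpos + 3L
    tries <- tries + 1L
    if (tries > 10L || start_tpos + 8L > stop_tpos) return(NULL)
  }

  ## choose a stop codon consistent with locked bases
  stop_pos <- (stop_tpos - 2L):stop_tpos
  feasible <- STOP_CODONS[vapply(STOP_CODONS, function(cod) {
    all(vapply(1:3, function(i) {
      p <- stop_pos[i]
      !locked_t(p) || read_t(p) == substring(cod, i, i)
    }, logical(1)))
  }, logical(1))]
  if (length(feasible) == 0L) return(NULL)
  stop_codon <- feasible[1L]

  fill_codon <- function(p0, forbid_stop = TRUE, prefer = NULL) {
    pos <- p0 + 0:2
    lock <- vapply(pos, locked_t, logical(1))
    if (!is.null(prefer) && !any(lock)) {
      for (i in 1:3) write_t(pos[i], substring(prefer, i, i))
      return(invisible(NULL))
    }
    repeat {
      chars <- vapply(1:3, function(i) {
        if (lock[i]) read_t(pos[i]) else sample(BASES, 1L)
      }, character(1))
      codon <- paste(chars, collapse = "")
      if (!forbid_stop || !codon %in% STOP_CODONS) {
        for (i in 1:3) if (!lock[i]) write_t(pos[i], chars[i])
        return(invisible(NULL))
      }
    }
  }

  fill_codon(start_tpos, prefer = "ATG")
  p <- start_tpos + 3L
  while (p < stop_tpos - 2L) {
    fill_codon(p)
    p <- p + 3L
  }
  for (i in 1:3) {
    p_i <- stop_pos[i]
    if (!locked_t(p_i)) write_t(p_i, substring(stop_codon, i, i))
  }

  g_start <- g_of[start_tpos + 1L]
  g_stop <- g_of[stop_tpos + 1L]
  stj <- if (is.na(junction)) NA_integer_ else junction - stop_tpos
  list(
    genome = genome,
    genepred = data.frame(
      name = paste0(t$transcript_id, "_ann"),
      chrom = t$chrom, strand = t$strand,
      txStart = t$exons$start[1L], txEnd = t$exons$end[n_ex],
      cdsStart = if (plus) g_start else g_stop,
      cdsEnd = if (plus) g_stop + 1L else g_start + 1L,
      exonCount = n_ex,
      exonStarts = paste0(paste(t$exons$start, collapse = ","), ","),
      exonEnds = paste0(paste(t$exons$end, collapse = ","), ",")),
    truth = data.frame(
      transcript_id = t$transcript_id, status = "annotated",
      start_tpos = start_tpos, stop_tpos = stop_tpos,
      utr5_len = start_tpos, orf_len = stop_tpos - start_tpos + 1L,
      utr3_len = L - stop_tpos - 1L,
      junction_tpos = junction, stop_to_junction = stj,
      ptc = !is.na(stj) && stj > ptc_threshold)
  )
}

#' Simulate one gene with planted ground truth
#'
#' Builds a reference exon chain, a canonical transcript spanning it, one
#' derived transcript per planted event (two for MEE), a genome segment with
#' canonical GT/AG splice motifs planted at a configurable fraction of
#' donor/acceptor sites, a coding sequence planted on the canonical
#' transcript, and per-condition expression with the canonical transcript
#' most expressed in the first (reference) condition. Ground truth is
#' returned for every planted feature: splice events (as classified against
#' the canonical, most-expressed reference), the canonical ORF, the switch
#' (if planted) and every motif site.
#'
#' @param blueprint A [gene_blueprint()].
#' @param gene_id,chrom,strand,offset Placement of the gene; `strand = NULL`
#'   draws one at random.
#' @param conditions Two condition labels; the first is the reference.
#' @param canonical_frac Fraction of motif sites planted with the canonical
#'   dinucleotide (default 0.93).
#' @return List with `gene`, `seq` (segment covering `[offset, gene_end)`),
#'   `gene_end`, `canonical_id`, `genepred`, `expression`, `truth_events`,
#'   `truth_orf`, `truth_switch`, `motif_sites`.
#' @export
simulate_gene <- function(blueprint, gene_id = "G1", chrom = "chr1",
                          strand = NULL, offset = 0L,
                          conditions = c("WT", "KD"),
                          canonical_frac = 0.93) {
  if (!is.null(blueprint$seed)) set.seed(blueprint$seed)
  if (is.null(strand)) strand <- sample(c("+", "-"), 1L)
  offset <- as.integer(offset)

  for (attempt in 1:25) {
    res <- simulate_gene_once(blueprint, gene_id, chrom, strand, offset,
                              conditions, canonical_frac)
    if (!is.null(res)) return(res)
  }
  stop(sprintf("gene %s: could not realize blueprint (CDS placement kept colliding with planted motifs)",
               gene_id))
}

simulate_gene_once <- function(bp, gene_id, chrom, strand, offset,
                               conditions, canonical_frac) {
  n <- bp$n_ref_exons
  we <- sample(bp$exon_len[1]:bp$exon_len[2], n, replace = TRUE)
  wi <- if (n > 1L) sample(bp$intron_len[1]:bp$intron_len[2], n - 1L,
                           replace = TRUE) else integer(0)
  starts <- integer(n)
  starts[1L] <- offset
  if (n > 1L) {
    for (i in 2:n) starts[i] <- starts[i - 1L] + we[i - 1L] + wi[i - 1L]
  }
  ex <- data.frame(start = starts, end = starts + we)
  gene_end <- ex$end[n]
  plus <- strand == "+"

  canonical_id <- paste0(gene_id, ".1")
  trs <- list(transcript_model(canonical_id, gene_id, chrom, strand, ex))
  truth_events <- list()
  tcount <- 1L
  next_id <- function() {
    tcount <<- tcount + 1L
    paste0(gene_id, ".", tcount)
  }
  el_str <- function(iv) format_elements(chrom, iv)
  add_truth <- function(tid, cls, iv) {
    truth_events[[length(truth_events) + 1L]] <<- data.frame(
      gene_id = gene_id, transcript_id = tid, event_class = cls,
      chrom = chrom, strand = strand, elements = el_str(iv))
  }

  internal <- bp$planted_events[bp$planted_events %in%
                                  c("ESI", "MESI", "A5", "A3", "IR", "MEE")]
  sizes <- c(ESI = 1L, MESI = 2L, A5 = 1L, A3 = 1L, IR = 2L, MEE = 2L)
  cursor <- 2L
  for (evc in bp$planted_events) {
    if (evc == "ATSS") {
      idx <- if (plus) 1L else n
      tid <- next_id()
      trs[[length(trs) + 1L]] <- transcript_model(
        tid, gene_id, chrom, strand, ex[-idx, , drop = FALSE])
      add_truth(tid, "ATSS", ex[idx, , drop = FALSE])
      next
    }
    if (evc == "ATTS") {
      idx <- if (plus) n else 1L
      tid <- next_id()
      trs[[length(trs) + 1L]] <- transcript_model(
        tid, gene_id, chrom, strand, ex[-idx, , drop = FALSE])
      add_truth(tid, "ATTS", ex[idx, , drop = FALSE])
      next
    }
    i <- cursor
    cursor <- cursor + sizes[[evc]] + 1L
    if (evc == "ESI") {
      tid <- next_id()
      trs[[length(trs) + 1L]] <- transcript_model(
        tid, gene_id, chrom, strand, ex[-i, , drop = FALSE])
      add_truth(tid, "ESI", ex[i, , drop = FALSE])
    } else if (evc == "MESI") {
      tid <- next_id()
      trs[[length(trs) + 1L]] <- transcript_model(
        tid, gene_id, chrom, strand, ex[-c(i, i + 1L), , drop = FALSE])
      add_truth(tid, "MESI", ex[c(i, i + 1L), , drop = FALSE])
    } else if (evc == "IR") {
      alt <- ex[-(i + 1L), , drop = FALSE]
      alt$end[alt$start == ex$start[i]] <- ex$end[i + 1L]
      tid <- next_id()
      trs[[length(trs) + 1L]] <- transcript_model(tid, gene_id, chrom,
                                                  strand, alt)
      add_truth(tid, "IR",
                data.frame(start = ex$end[i], end = ex$start[i + 1L]))
    } else if (evc == "A5" || evc == "A3") {
      s <- sample(15:50, 1L)
      alt <- ex
      shrink_end <- (evc == "A5") == plus  # A5 on +, A3 on -: genomic end side
      if (shrink_end) {
        alt$end[i] <- ex$end[i] - s
        elem <- data.frame(start = alt$end[i], end = ex$end[i])
      } else {
        alt$start[i] <- ex$start[i] + s
        elem <- data.frame(start = ex$start[i], end = alt$start[i])
      }
      tid <- next_id()
      trs[[length(trs) + 1L]] <- transcript_model(tid, gene_id, chrom,
                                                  strand, alt)
      add_truth(tid, evc, elem)
    } else if (evc == "MEE") {
      tid_a <- next_id()
      trs[[length(trs) + 1L]] <- transcript_model(
        tid_a, gene_id, chrom, strand, ex[-(i + 1L), , drop = FALSE])
      tid_b <- next_id()
      trs[[length(trs) + 1L]] <- transcript_model(
        tid_b, gene_id, chrom, strand, ex[-i, , drop = FALSE])
      add_truth(tid_a, "ESI", ex[i + 1L, , drop = FALSE])
      add_truth(tid_b, "ESI", ex[i, , drop = FALSE])
      pair <- sort(c(tid_a, tid_b))
      add_truth(paste(pair, collapse = "|"), "MEE",
                ex[c(i, i + 1L), , drop = FALSE])
    }
  }
  gene <- gene_model(trs)

  ## genome segment with planted motifs, then planted CDS
  seg_len <- gene_end - offset
  genome <- rand_bases(seg_len)
  sites <- collect_motif_sites(trs, strand)
  motif_truth <- data.frame(side = character(0), gpos = integer(0),
                            canonical = logical(0))
  locked_g <- integer(0)
  if (nrow(sites) > 0) {
    pm <- plant_motif_sites(genome, offset, sites, canonical_frac)
    genome <- pm$genome
    motif_truth <- pm$truth
    locked_g <- sort(c(sites$gpos, sites$gpos + 1L))
  }

  genepred <- NULL
  truth_orf <- NULL
  if (bp$planted_cds %in% c("canonical_stop", "ptc_at_distance")) {
    pc <- plant_cds(trs[[1L]], genome, offset, locked_g, bp$planted_cds,
                    bp$ptc_distance)
    if (is.null(pc)) return(NULL)  # retry with a new layout
    genome <- pc$genome
    genepred <- pc$genepred
    truth_orf <- pc$truth
  } else if (bp$planted_cds == "no_start") {
    truth_orf <- data.frame(
      transcript_id = canonical_id, status = "no_compatible_start",
      start_tpos = NA_integer_, stop_tpos = NA_integer_,
      utr5_len = NA_integer_, orf_len = NA_integer_, utr3_len = NA_integer_,
      junction_tpos = NA_integer_, stop_to_junction = NA_integer_,
      ptc = FALSE)
  }

  ## expression: canonical most expressed in the reference condition
  ids <- names(gene$transcripts)
  k <- length(ids)
  ord <- c(canonical_id, setdiff(sort(ids), canonical_id))
  if (bp$switch_dif > 0 && k >= 2L) {
    sd <- bp$switch_dif
    if (k == 2L) {
      if1 <- c(60, 40)
      if2 <- c(60 - sd, 40 + sd)
    } else {
      rest <- rep(25 / (k - 2L), k - 2L)
      if1 <- c(60, 15, rest)
      if2 <- c(60 - sd, 15 + sd, rest)
    }
    truth_switch <- data.frame(gene_id = gene_id,
                               up_transcript_id = ord[2L],
                               down_transcript_id = canonical_id,
                               dIF = sd)
  } else {
    if1 <- if (k == 1L) 100 else c(55, rep(45 / (k - 1L), k - 1L))
    if2 <- if1
    truth_switch <- NULL
  }
  expression <- do.call(rbind, lapply(1:2, function(ci) {
    total <- bp$gene_expr[ci]
    shares <- if (ci == 1L) if1 else if2
    data.frame(transcript_id = ord, gene_id = gene_id,
               condition = conditions[ci],
               transcript_expr = shares / 100 * total,
               gene_expr = total, iso_status = "OK", gene_status = "OK",
               pvalue = NA_real_)
  }))

  list(gene = gene, seq = paste(genome, collapse = ""), gene_end = gene_end,
       canonical_id = canonical_id, genepred = genepred,
       expression = expression,
       truth_events = if (length(truth_events)) do.call(rbind, truth_events)
                      else NULL,
       truth_orf = truth_orf, truth_switch = truth_switch,
       motif_sites = motif_truth)
}
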