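#' Compute isoform fraction (IF) values
#'
#' For every transcript and condition, IF = transcript expression / gene
#' expression x 100, the percentage contribution of the isoform to its
#' parent gene's expression. When gene expression is zero the IF is
#' undefined (`if_defined = FALSE`, `IF = NA`) and the record is excluded
#' from dIF computation.
#'
#' @param d A [splice_dataset()], or an expression record data frame.
#' @return Data frame: `transcript_id`, `gene_id`, `condition`,
#'   `transcript_expr`, `gene_expr`, `IF`, `if_defined`.
#' @export
compute_if <- function(d) {
  expr <- if (inherits(d, "splice_dataset")) d$expression else d
  defined <- expr$gene_expr > 0
  n_undef <- sum(!defined)
  if (n_undef > 0) {
    message(sprintf("compute_if: %d record(s) with zero gene expression; IF undefined",
                    n_undef))
  }
  data.frame(
    transcript_id = expr$transcript_id,
    gene_id = expr$gene_id,
    condition = expr$condition,
    transcript_expr = expr$transcript_expr,
    gene_expr = expr$gene_expr,
    IF = ifelse(defined, expr$transcript_expr / expr$gene_expr * 100, NA_real_),
    if_defined = defined
  )
}

#' Compute delta-IF (dIF) between two conditions
#'
#' dIF = IF(condition 2) - IF(condition 1), a signed change in percentage
#' points. The sign matters: the transcript-switch definition pairs a large
#' positive with a large negative dIF within one gene. dIF is defined only
#' when both condition IFs are.
#'
#' @param ifs Output of [compute_if()].
#' @param conditions Character vector of length 2: `c(reference, contrast)`.
#' @return Data frame: `transcript_id`, `gene_id`, `IF1`, `IF2`, `dIF`,
#'   `dif_defined`, plus per-condition gene expression `gene_expr1`,
#'   `gene_expr2`.
#' @export
compute_dif <- function(ifs, conditions) {
  if (length(conditions) != 2L) stop("compute_dif needs exactly two conditions")
  a <- ifs[ifs$condition == conditions[1], , drop = FALSE]
  b <- ifs[ifs$condition == conditions[2], , drop = FALSE]
  if (nrow(a) == 0L || nrow(b) == 0L) {
    stop(sprintf("condition(s) missing from IF table: %s",
                 paste(conditions[c(nrow(a) == 0L, nrow(b) == 0L)],
                       collapse = ", ")))
  }
  ids <- union(a$transcript_id, b$transcript_id)
  ia <- match(ids, a$transcript_id)
  ib <- match(ids, b$transcript_id)
  ok <- !is.na(ia) & !is.na(ib) & a$if_defined[ia] & b$if_defined[ib]
  data.frame(
    transcript_id = ids,
    gene_id = ifelse(is.na(ia), b$gene_id[ib], a$gene_id[ia]),
    IF1 = a$IF[ia], IF2 = b$IF[ib],
    dIF = ifelse(ok, b$IF[ib] - a$IF[ia], NA_real_),
    dif_defined = ok,
    gene_expr1 = a$gene_expr[ia],
    gene_expr2 = b$gene_expr[ib]
  )
}

#' Filter a splice dataset
#'
#' Stringent optional pre-filters applied before classification or
#' quantification:
#' * `iso_ok` / `gene_ok`: keep transcripts whose quantification status
#'   (resp. their gene's) is `"OK"` in every condition;
#' * `expressed_isoforms` / `expressed_genes`: drop transcripts (genes) with
#'   expression <= 0 in *all* conditions (any-condition expression keeps);
#' * `single_exon`: drop single-exon transcripts.
#'
#' Genes left without transcripts are dropped; removal counts are reported
#' per filter via messages.
#'
#' @param d A [splice_dataset()].
#' @param filters Character vector, subset of `c("gene_ok", "iso_ok",
#'   "expressed_genes", "expressed_isoforms", "single_exon")`.
#' @return The filtered [splice_dataset()].
#' @export
filter_dataset <- function(d, filters = character(0)) {
  allowed <- c("gene_ok", "iso_ok", "expressed_genes",
               "expressed_isoforms", "single_exon")
  bad <- setdiff(filters, allowed)
  if (length(bad) > 0) stop(sprintf("unknown filter(s): %s",
                                    paste(bad, collapse = ", ")))
  expr <- d$expression
  keep_t <- unlist(lapply(d$genes, function(g) names(g$transcripts)),
                   use.names = FALSE)
  drop_gene <- character(0)

  drop_count <- function(filter, before, after) {
    message(sprintf("filter %s: removed %d transcript(s)", filter,
                    length(before) - length(after)))
  }
  if ("iso_ok" %in% filters) {
    if (all(is.na(expr$iso_status))) stop("iso_ok filter requested but iso_status absent")
    ok <- tapply(expr$iso_status == "OK", expr$transcript_id, all)
    after <- keep_t[keep_t %in% names(ok)[ok %in% TRUE]]
    drop_count("iso_ok", keep_t, after); keep_t <- after
  }
  if ("gene_ok" %in% filters) {
    if (all(is.na(expr$gene_status))) stop("gene_ok filter requested but gene_status absent")
    okg <- tapply(expr$gene_status == "OK", expr$gene_id, all)
    bad_genes <- names(okg)[!(okg %in% TRUE)]
    drop_gene <- union(drop_gene, bad_genes)
    after <- keep_t[!vapply(keep_t, function(id) {
      gid <- expr$gene_id[match(id, expr$transcript_id)]
      gid %in% bad_genes
    }, logical(1))]
    drop_count("gene_ok", keep_t, after); keep_t <- after
  }
  if ("expressed_isoforms" %in% filters) {
    anyexpr <- tapply(expr$transcript_expr > 0, expr$transcript_id, any)
    after <- keep_t[keep_t %in% names(anyexpr)[anyexpr %in% TRUE]]
    drop_count("expressed_isoforms", keep_t, after); keep_t <- after
  }
  if ("expressed_genes" %in% filters) {
    anyg <- tapply(expr$gene_expr > 0, expr$gene_id, any)
    bad_genes <- names(anyg)[!(anyg %in% TRUE)]
    drop_gene <- union(drop_gene, bad_genes)
    after <- keep_t[!vapply(keep_t, function(id) {
      gid <- expr$gene_id[match(id, expr$transcript_id)]
      gid %in% bad_genes
    }, logical(1))]
    drop_count("expressed_genes", keep_t, after); keep_t <- after
  }
  if ("single_exon" %in% filters) {
    multi <- unlist(lapply(d$genes, function(g)
      vapply(g$transcripts, function(t) nrow(t$exons) > 1L, logical(1))))
    names(multi) <- unlist(lapply(d$genes, function(g) names(g$transcripts)))
    after <- keep_t[multi[keep_t]]
    drop_count("single_exon", keep_t, after); keep_t <- after
  }

  genes <- lapply(d$genes, function(g) {
    if (g$gene_id %in% drop_gene) return(NULL)
    trs <- g$transcripts[names(g$transcripts) %in% keep_t]
    if (length(trs) == 0L) return(NULL)
    gene_model(trs)
  })
  genes <- genes[!vapply(genes, is.null, logical(1))]
  n_gone <- length(d$genes) - length(genes)
  if (n_gone > 0) message(sprintf("filter cascade: removed %d gene(s)", n_gone))
  expr <- expr[expr$transcript_id %in% keep_t &
                 expr$gene_id %in% names(genes), , drop = FALSE]
  splice_dataset(genes, expr, d$conditions, d$assembler)
}

#' Detect binary transcript switches
#'
#' Per gene: when at least one transcript has dIF >= tau and at least one
#' has dIF <= -tau, and the gene is expressed at or above `min_gene_expr`
#' in both conditions, one switch call is emitted pairing the most extreme
#' up- and down-regulated transcripts (ties break to the lexicographically
#' smaller transcript id). When ORF annotations are supplied, `nmd_gain`
#' flags switches where the down transcript is PTC-negative and the up
#' transcript PTC-positive -- an isoform switch into a nonsense-mediated
#' decay substrate.
#'
#' @param difs Output of [compute_dif()].
#' @param orf Optional ORF annotation table ([annotate_orfs()]).
#' @param tau dIF threshold in percentage points (> 0); default 25.
#' @param min_gene_expr Minimum gene expression in both conditions; default 1.
#' @return Data frame: `gene_id`, `up_transcript_id`, `down_transcript_id`,
#'   `dIF_up`, `dIF_down`, `nmd_gain`.
#' @export
detect_switches <- function(difs, orf = NULL, tau = 25, min_gene_expr = 1) {
  if (tau <= 0) stop("tau must be positive")
  d <- difs[difs$dif_defined, , drop = FALSE]
  d <- d[d$gene_expr1 >= min_gene_expr & d$gene_expr2 >= min_gene_expr, ,
         drop = FALSE]
  out <- list()
  for (gid in sort(unique(d$gene_id))) {
    gg <- d[d$gene_id == gid, , drop = FALSE]
    up <- gg[gg$dIF >= tau, , drop = FALSE]
    down <- gg[gg$dIF <= -tau, , drop = FALSE]
    if (nrow(up) == 0L || nrow(down) == 0L) next
    up <- up[order(-up$dIF, up$transcript_id), , drop = FALSE]
    down <- down[order(down$dIF, down$transcript_id), , drop = FALSE]
    nmd <- NA
    if (!is.null(orf)) {
      ptc_of <- function(id) {
        i <- match(id, orf$transcript_id)
        if (is.na(i)) NA else isTRUE(orf$ptc[i])
      }
      pu <- ptc_of(up$transcript_id[1]); pd <- ptc_of(down$transcript_id[1])
      nmd <- if (is.na(pu) || is.na(pd)) NA else (pu && !pd)
    }
    out[[length(out) + 1L]] <- data.frame(
      gene_id = gid,
      up_transcript_id = up$transcript_id[1],
      down_transcript_id = down$transcript_id[1],
      dIF_up = up$dIF[1], dIF_down = down$dIF[1],
      nmd_gain = nmd
    )
  }
  if (length(out) == 0L) {
    return(data.frame(gene_id = character(0), up_transcript_id = character(0),
                      down_transcript_id = character(0), dIF_up = numeric(0),
                      dIF_down = numeric(0), nmd_gain = logical(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare IF distributions of a transcript subset between conditions
#'
#' Restricts the IF table to a subset of transcripts (for example, all
#' transcripts with a retained intron, or all NMD-sensitive transcripts) and
#' compares the two condition-wise IF distributions with a two-sided
#' Mann-Whitney U (Wilcoxon rank-sum) test. With ties present the normal
#' approximation with continuity correction is used (the `stats::wilcox.test`
#' default).
#'
#' @param ifs Output of [compute_if()].
#' @param transcript_ids Subset of transcript ids.
#' @param conditions Character vector of length 2.
#' @return List: `if1`, `if2` (defined IF vectors per condition),
#'   `statistic` (U for condition 1 vs condition 2), `p_value`.
#' @export
subset_if_distributions <- function(ifs, transcript_ids, conditions) {
  if (length(transcript_ids) == 0L) stop("transcript subset is empty")
  sub <- ifs[ifs$transcript_id %in% transcript_ids & ifs$if_defined, ,
             drop = FALSE]
  if1 <- sub$IF[sub$condition == conditions[1]]
  if2 <- sub$IF[sub$condition == conditions[2]]
  if (length(if1) < 2L || length(if2) < 2L) {
    stop("need at least 2 defined IF values per condition")
  }
  wt <- suppressWarnings(stats::wilcox.test(if1, if2, alternative = "two.sided"))
  list(if1 = if1, if2 = if2,
       statistic = unname(wt$statistic), p_value = wt$p.value)
}
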