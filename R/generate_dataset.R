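#' Generate a full synthetic input set with ground truth
#'
#' Draws per-gene blueprints from a class mix, simulates every gene on one
#' chromosome ([simulate_gene()]), and returns the assembled
#' [splice_dataset()], sequence provider, start-codon table and ground-truth
#' tables. With `out_dir` set, the four standard input files (GTF, FASTA,
#' genePred, generic expression TSV) plus ground-truth sidecar TSVs are also
#' written, so the on-disk readers can be exercised round-trip. The output
#' is fully determined by `seed`.
#'
#' @param n_genes Number of genes (>= 1).
#' @param seed Integer seed.
#' @param class_mix Named numeric weights over the eight event classes;
#'   default equal weights.
#' @param switch_fraction Fraction of genes with a planted switch
#'   (`round(n_genes * switch_fraction)` genes, placed first).
#' @param switch_dif Planted switch magnitude in IF percentage points.
#' @param conditions Two condition labels.
#' @param canonical_frac Fraction of splice motif sites planted canonical.
#' @param events_per_gene Range of planted events per gene.
#' @param out_dir Optional output directory.
#' @return List: `dataset`, `seqprov`, `cds`, `truth` (list of `events`,
#'   `orf`, `switches`, `motifs`), `canonical` (gene -> canonical transcript
#'   id), `paths` (when written).
#' @export
generate_dataset <- function(n_genes, seed, class_mix = NULL,
                             switch_fraction = 0.1, switch_dif = 35,
                             conditions = c("WT", "KD"),
                             canonical_frac = 0.93,
                             events_per_gene = c(1L, 2L),
                             out_dir = NULL) {
  if (n_genes < 1L) stop("n_genes must be >= 1")
  set.seed(seed)
  if (is.null(class_mix)) {
    class_mix <- stats::setNames(rep(1, length(EVENT_CLASSES)), EVENT_CLASSES)
  }
  classes <- names(class_mix)
  n_switch <- round(n_genes * switch_fraction)

  chrom <- "chr1"
  cursor <- 200L
  segs <- list(paste(rand_bases(200L), collapse = ""))
  genes <- list()
  expr <- list(); gp <- list()
  t_ev <- list(); t_orf <- list(); t_sw <- list(); t_mot <- list()
  canonical <- character(0)
  cds_kinds <- c("canonical_stop", "ptc_at_distance", "no_start")

  for (gi in seq_len(n_genes)) {
    k_ev <- sample(events_per_gene[1]:events_per_gene[2], 1L)
    ev <- sample(classes, k_ev, replace = TRUE,
                 prob = as.numeric(class_mix))
    ## at most one alternative start and one alternative end per gene
    ev <- ev[!(duplicated(ev) & ev %in% c("ATSS", "ATTS"))]
    kind <- sample(cds_kinds, 1L, prob = c(0.6, 0.2, 0.2))
    d <- sample(c(20L, 49L, 50L, 51L, 60L, 90L), 1L)
    bp <- gene_blueprint(
      planted_events = ev, planted_cds = kind, ptc_distance = d,
      switch_dif = if (gi <= n_switch) switch_dif else 0)
    gid <- sprintf("G%04d", gi)
    sim <- simulate_gene(bp, gene_id = gid, chrom = chrom, offset = cursor,
                         conditions = conditions,
                         canonical_frac = canonical_frac)
    segs[[length(segs) + 1L]] <- sim$seq
    genes[[gid]] <- sim$gene
    expr[[gid]] <- sim$expression
    if (!is.null(sim$genepred)) gp[[gid]] <- sim$genepred
    if (!is.null(sim$truth_events)) t_ev[[gid]] <- sim$truth_events
    if (!is.null(sim$truth_orf)) {
      sim$truth_orf$gene_id <- gid
      t_orf[[gid]] <- sim$truth_orf
    }
    if (!is.null(sim$truth_switch)) t_sw[[gid]] <- sim$truth_switch
    if (nrow(sim$motif_sites) > 0) {
      sim$motif_sites$gene_id <- gid
      t_mot[[gid]] <- sim$motif_sites
    }
    canonical[gid] <- sim$canonical_id
    gap <- sample(150:350, 1L)
    segs[[length(segs) + 1L]] <- paste(rand_bases(gap), collapse = "")
    cursor <- sim$gene_end + gap
  }

  seqprov <- sequence_provider(stats::setNames(paste(unlist(segs),
                                                     collapse = ""), chrom))
  expression <- do.call(rbind, unname(expr))
  rownames(expression) <- NULL
  cds_gp <- if (length(gp)) do.call(rbind, unname(gp)) else NULL
  cds <- if (!is.null(cds_gp)) {
    data.frame(name = cds_gp$name, chrom = cds_gp$chrom,
               strand = cds_gp$strand,
               start_codon_genomic = ifelse(cds_gp$strand == "+",
                                            cds_gp$cdsStart,
                                            cds_gp$cdsEnd - 1L))
  } else {
    data.frame(name = character(0), chrom = character(0),
               strand = character(0), start_codon_genomic = integer(0))
  }
  dataset <- splice_dataset(genes, expression, conditions,
                            assembler = "splicewise-simulator")
  truth <- list(
    events = if (length(t_ev)) do.call(rbind, unname(t_ev)) else NULL,
    orf = if (length(t_orf)) do.call(rbind, unname(t_orf)) else NULL,
    switches = if (length(t_sw)) do.call(rbind, unname(t_sw)) else NULL,
    motifs = if (length(t_mot)) do.call(rbind, unname(t_mot)) else NULL
  )
  out <- list(dataset = dataset, seqprov = seqprov, cds = cds,
              genepred = cds_gp, truth = truth, canonical = canonical)
  if (!is.null(out_dir)) {
    out$paths <- write_simulated_inputs(out, out_dir)
  }
  out
}

## Write the simulated inputs in the standard on-disk formats.
write_simulated_inputs <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  paths <- list(gtf = p("transcripts.gtf"), fasta = p("genome.fa"),
                genepred = p("annotation.genepred"),
                expression = p("expression.tsv"))
  lines <- unlist(lapply(sim$dataset$genes, function(g)
    unlist(lapply(g$transcripts, gtf_exon_lines))), use.names = FALSE)
  writeLines(lines, paths$gtf)
  write_fasta(sim$seqprov, paths$fasta)
  if (!is.null(sim$genepred)) {
    utils::write.table(sim$genepred, paths$genepred, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  expr <- sim$dataset$expression
  utils::write.table(expr, paths$expression, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (nm in names(sim$truth)) {
    if (!is.null(sim$truth[[nm]])) {
      paths[[paste0("truth_", nm)]] <- p(sprintf("truth_%s.tsv", nm))
      utils::write.table(sim$truth[[nm]], paths[[paste0("truth_", nm)]],
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  paths
}

#' Write a sequence provider as FASTA
#' @param seqprov A `sequence_provider`.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqprov, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqprov)) {
    writeLines(paste0(">", nm), con)
    s <- unclass(seqprov)[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Simulate transcripts with planted coding structure
#'
#' Dedicated ORF fixture generator: `n` single-transcript genes with planted
#' start/stop codons covering canonical stops, premature stops at chosen
#' stop-to-junction distances (including the 49/50/51 nt boundary), missing
#' start annotations and occasional single-exon transcripts. Ground truth
#' carries every ORF field.
#'
#' @param n Number of transcripts.
#' @param seed Integer seed.
#' @param ptc_distances Stop-to-junction distances cycled through for
#'   premature-stop plants.
#' @return List: `genes`, `seqprov`, `cds`, `truth` (ORF table).
#' @export
simulate_orf_transcripts <- function(n, seed,
                                     ptc_distances = c(20L, 49L, 50L, 51L, 75L, 120L)) {
  set.seed(seed)
  kinds <- rep(c("canonical_stop", "ptc_at_distance", "canonical_stop",
                 "ptc_at_distance", "no_start"), length.out = n)
  chrom <- "chr1"
  cursor <- 100L
  segs <- list(paste(rand_bases(100L), collapse = ""))
  genes <- list(); gp <- list(); truth <- list()
  di <- 0L
  for (i in seq_len(n)) {
    kind <- kinds[i]
    if (kind == "ptc_at_distance") {
      di <- di + 1L
      d <- ptc_distances[(di - 1L) %% length(ptc_distances) + 1L]
    } else d <- 80L
    n_ex <- if (kind == "canonical_stop" && i %% 7L == 0L) 1L
            else sample(2:4, 1L)
    bp <- gene_blueprint(planted_cds = kind, ptc_distance = d,
                         n_ref_exons = n_ex,
                         exon_len = c(200L, 320L))
    gid <- sprintf("OG%04d", i)
    sim <- simulate_gene(bp, gene_id = gid, chrom = chrom, offset = cursor)
    genes[[gid]] <- sim$gene
    segs[[length(segs) + 1L]] <- sim$seq
    if (!is.null(sim$genepred)) gp[[gid]] <- sim$genepred
    if (!is.null(sim$truth_orf)) truth[[gid]] <- sim$truth_orf
    gap <- sample(100:200, 1L)
    segs[[length(segs) + 1L]] <- paste(rand_bases(gap), collapse = "")
    cursor <- sim$gene_end + gap
  }
  gp <- if (length(gp)) do.call(rbind, unname(gp)) else NULL
  cds <- if (!is.null(gp)) {
    data.frame(name = gp$name, chrom = gp$chrom, strand = gp$strand,
               start_codon_genomic = ifelse(gp$strand == "+", gp$cdsStart,
                                            gp$cdsEnd - 1L))
  } else NULL
  list(genes = genes,
       seqprov = sequence_provider(stats::setNames(
         paste(unlist(segs), collapse = ""), chrom)),
       cds = cds, genepred = gp,
       truth = do.call(rbind, unname(truth)))
}

#' Splice-site consensus report
#'
#' Extracts the first and last two intronic nucleotides (in transcript
#' orientation) of every distinct intron across all transcripts and reports
#' the percentage matching the hyper-conserved GT (donor) and AG (acceptor)
#' consensus -- the standard QC that assembled transcript models splice at
#' canonical sites. Introns shared by several transcripts are counted once.
#'
#' @param genes A [splice_dataset()] or list of [gene_model()]s.
#' @param seqprov Sequence provider.
#' @return Data frame: `site` (`donor_GT`, `acceptor_AG`), `n_introns`,
#'   `n_canonical`, `percent`.
#' @export
splice_site_report <- function(genes, seqprov) {
  if (inherits(genes, "splice_dataset")) genes <- genes$genes
  rows <- list()
  for (g in genes) {
    for (t in g$transcripts) {
      ivs <- introns(t)
      if (nrow(ivs) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = t$chrom, strand = t$strand,
        start = ivs$start, end = ivs$end)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(site = c("donor_GT", "acceptor_AG"),
                      n_introns = 0L, n_canonical = 0L, percent = NA_real_))
  }
  iv <- unique(do.call(rbind, rows))
  seqs <- unclass(seqprov)
  donor <- character(nrow(iv)); acceptor <- character(nrow(iv))
  for (i in seq_len(nrow(iv))) {
    s <- seqs[[iv$chrom[i]]]
    left <- substring(s, iv$start[i] + 1L, iv$start[i] + 2L)
    right <- substring(s, iv$end[i] - 1L, iv$end[i])
    if (iv$strand[i] == "+") {
      donor[i] <- left; acceptor[i] <- right
    } else {
      donor[i] <- reverse_complement(right)
      acceptor[i] <- reverse_complement(left)
    }
  }
  data.frame(
    site = c("donor_GT", "acceptor_AG"),
    n_introns = nrow(iv),
    n_canonical = c(sum(donor == "GT"), sum(acceptor == "AG")),
    percent = round(c(mean(donor == "GT"), mean(acceptor == "AG")) * 100, 2)
  )
}
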