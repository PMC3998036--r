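test_that("the most upstream compatible start codon wins", {
  t <- make_t(c(100, 300), c(200, 400))
  cds <- data.frame(name = c("A", "B", "C", "D"),
                    chrom = "chr1", strand = "+",
                    start_codon_genomic = c(140, 250, 340, 110))
  ## 250 is intronic -> excluded; 110 maps to tpos 10, most upstream
  expect_equal(find_compatible_start(t, cds), 10)
  ## wrong strand records never match
  cds$strand <- "-"
  expect_true(is.na(find_compatible_start(t, cds)))
  ## a start too close to the 3' end has no room for a full codon
  cds2 <- data.frame(name = "E", chrom = "chr1", strand = "+",
                     start_codon_genomic = 399)
  expect_true(is.na(find_compatible_start(t, cds2)))
})

test_that("ORF scanning finds the first in-frame stop", {
  expect_equal(scan_orf("ATGAAATAG", 0), 8)
  expect_true(is.na(scan_orf("ATGTAACCC", 1)))  # frame shift: TGT AAC CC
  expect_equal(scan_orf("ATGTGA", 0), 5)
  expect_error(scan_orf("ATG", 1), "no room")
})

test_that("the PTC call uses strict distance and needs a junction", {
  ## two 100-nt exons; junction at tpos 99; plant stops at distances 49/50/51
  for (d in c(49, 50, 51)) {
    stop_tpos <- 99 - d
    seq <- paste(rep("C", 200), collapse = "")
    start_tpos <- stop_tpos - 11
    substr(seq, start_tpos + 1, start_tpos + 3) <- "ATG"
    substr(seq, stop_tpos - 1, stop_tpos + 1) <- "TAA"
    chrom <- paste0(substr(seq, 1, 100),
                    paste(rep("G", 50), collapse = ""),
                    substr(seq, 101, 200))
    sp <- sequence_provider(c(chr1 = chrom))
    t <- make_t(c(0, 150), c(100, 250))
    cds <- data.frame(name = "A", chrom = "chr1", strand = "+",
                      start_codon_genomic = start_tpos)
    ann <- annotate_orf(t, sp, cds, ptc_threshold = 50)
    expect_equal(ann$status, "annotated")
    expect_equal(ann$stop_tpos, stop_tpos)
    expect_equal(ann$stop_to_junction, d)
    expect_equal(ann$ptc, d > 50, info = paste("distance", d))
  }
})

test_that("single-exon transcripts and canonical stops are never PTC", {
  seq <- paste0(paste(rep("C", 30), collapse = ""), "ATGAAATAG",
                paste(rep("C", 30), collapse = ""))
  sp <- sequence_provider(c(chr1 = seq))
  t1 <- make_t(0, nchar(seq))
  cds <- data.frame(name = "A", chrom = "chr1", strand = "+",
                    start_codon_genomic = 30)
  ann <- annotate_orf(t1, sp, cds)
  expect_equal(ann$status, "annotated")
  expect_false(ann$ptc)
  expect_true(is.na(ann$junction_tpos))
  ## length conservation
  expect_equal(ann$utr5_len + ann$orf_len + ann$utr3_len, transcript_length(t1))
})

test_that("missing starts and missing stops are conservative", {
  sp <- sequence_provider(c(chr1 = paste(rep("C", 400), collapse = "")))
  t <- make_t(c(0, 200), c(100, 300))
  ann <- annotate_orf(t, sp, data.frame(name = character(0),
                                        chrom = character(0),
                                        strand = character(0),
                                        start_codon_genomic = integer(0)))
  expect_equal(ann$status, "no_compatible_start")
  expect_false(ann$ptc)
  ## all-C sequence: no stop downstream of a compatible start
  cds <- data.frame(name = "A", chrom = "chr1", strand = "+",
                    start_codon_genomic = 30)
  ann2 <- annotate_orf(t, sp, cds)
  expect_equal(ann2$status, "no_stop_found")
  expect_false(ann2$ptc)
})

test_that("planted coding structure is recovered exactly, both strands", {
  sim <- suppressMessages(simulate_orf_transcripts(80, seed = 19))
  ann <- annotate_orfs(sim$genes, sim$seqprov, sim$cds)
  truth <- sim$truth
  m <- merge(truth, ann, by = "transcript_id", suffixes = c(".t", ".a"))
  expect_equal(nrow(m), nrow(truth))
  expect_equal(m$status.a, m$status.t)
  k <- m$status.t == "annotated"
  expect_true(any(k))
  for (col in c("start_tpos", "stop_tpos", "utr5_len", "orf_len",
                "utr3_len", "stop_to_junction")) {
    expect_equal(m[[paste0(col, ".a")]][k], m[[paste0(col, ".t")]][k],
                 info = col)
  }
  expect_equal(m$ptc.a, m$ptc.t)
  ## both strands actually exercised
  strands <- vapply(sim$genes, `[[`, "", "strand")
  expect_setequal(unique(strands), c("+", "-"))
  ## length conservation across all annotated fixtures
  lens <- vapply(sim$genes, function(g)
    transcript_length(g$transcripts[[1]]), integer(1))
  ann_k <- ann[ann$status == "annotated", ]
  expect_equal(ann_k$utr5_len + ann_k$orf_len + ann_k$utr3_len,
               unname(lens[ann_k$gene_id]))
})

test_that("a strand-mirrored gene yields identical transcript-space ORFs", {
  sim <- suppressMessages(simulate_orf_transcripts(6, seed = 23))
  for (gid in names(sim$genes)) {
    g <- sim$genes[[gid]]
    t <- g$transcripts[[1]]
    seq <- transcript_sequence(t, sim$seqprov)
    M <- max(t$exons$end) + 50L
    ex_m <- mirror_exons(t$exons, M)
    tm <- transcript_model(t$transcript_id, t$gene_id, "chrM", flip(t$strand),
                           ex_m)
    chrom_m <- reverse_complement(
      substring(unclass(sim$seqprov)[["chr1"]], 1, M))
    spm <- sequence_provider(c(chrM = chrom_m))
    expect_equal(transcript_sequence(tm, spm), seq)
    cds_g <- sim$cds[sim$cds$name == paste0(t$transcript_id, "_ann"), ]
    if (nrow(cds_g) == 1) {
      cds_m <- cds_g
      cds_m$chrom <- "chrM"
      cds_m$strand <- flip(cds_g$strand)
      cds_m$start_codon_genomic <- M - 1L - cds_g$start_codon_genomic
      a <- annotate_orf(t, sim$seqprov, cds_g)
      b <- annotate_orf(tm, spm, cds_m)
      expect_equal(b$start_tpos, a$start_tpos)
      expect_equal(b$stop_tpos, a$stop_tpos)
      expect_equal(b$ptc, a$ptc)
    }
  }
})

test_that("raising the PTC threshold never creates new PTC calls", {
  sim <- suppressMessages(simulate_orf_transcripts(40, seed = 29))
  prev <- NULL
  for (thr in c(0, 25, 50, 75, 200)) {
    ann <- annotate_orfs(sim$genes, sim$seqprov, sim$cds, ptc_threshold = thr)
    n <- sum(ann$ptc)
    if (!is.null(prev)) expect_lte(n, prev)
    prev <- n
  }
})

test_that("PTC summaries report counts and one-decimal percentages", {
  mk <- function(n_neg, n_pos, n_nostart) {
    data.frame(
      status = c(rep("annotated", n_neg + n_pos), rep("no_compatible_start", n_nostart)),
      ptc = c(rep(FALSE, n_neg), rep(TRUE, n_pos), rep(FALSE, n_nostart)))
  }
  s <- summarize_ptc(mk(8179, 642, 1287))
  expect_equal(s$percent, c(80.9, 6.4, 12.7))
  expect_equal(s$count, c(8179L, 642L, 1287L))
  s2 <- summarize_ptc(mk(1, 0, 0))
  expect_equal(s2$percent, c(100.0, 0.0, 0.0))
  s3 <- summarize_ptc(mk(0, 0, 0))
  expect_equal(s3$count, c(0L, 0L, 0L))
  expect_equal(s3$percent, c(0, 0, 0))
})
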