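test_that("blueprints validate realizability", {
  expect_error(gene_blueprint(c("ATSS", "ATSS")), "at most one ATSS")
  expect_error(gene_blueprint("ESI", n_ref_exons = 2), "unrealizable")
  expect_error(gene_blueprint(planted_cds = "ptc_at_distance",
                              ptc_distance = NULL), "ptc_distance")
  expect_error(gene_blueprint(switch_dif = 35), "alternative transcript")
  expect_error(gene_blueprint("XYZ"), "unknown event class")
})

test_that("each planted class is recovered by classification against the canonical reference", {
  set.seed(1)
  for (cls in c("ESI", "MESI", "A5", "A3", "IR", "ATSS", "ATTS")) {
    for (strand in c("+", "-")) {
      sim <- simulate_gene(gene_blueprint(cls), gene_id = "G1",
                           strand = strand, offset = 10L)
      g <- sim$gene
      r <- suppressWarnings(select_most_expressed(g, sim$expression, "WT"))
      expect_equal(r$source_transcript_id, sim$canonical_id)
      ev <- classify_transcript(g$transcripts[[2]], r)
      expect_length(ev, 1)
      expect_equal(ev[[1]]$event_class, cls, info = paste(cls, strand))
      expect_equal(events_table(ev)$elements, sim$truth_events$elements,
                   info = paste(cls, strand))
    }
  }
})

test_that("a planted MEE gives the pair plus the two implied skipping events", {
  set.seed(2)
  sim <- simulate_gene(gene_blueprint("MEE"), gene_id = "G1", strand = "+")
  g <- sim$gene
  mee <- detect_mee(g)
  expect_length(mee, 1)
  truth_mee <- sim$truth_events[sim$truth_events$event_class == "MEE", ]
  expect_equal(events_table(mee)$elements, truth_mee$elements)
  expect_equal(sum(sim$truth_events$event_class == "ESI"), 2)
})

test_that("the generator is deterministic given a seed", {
  a <- suppressMessages(generate_dataset(8, seed = 17, switch_fraction = 0.25))
  b <- suppressMessages(generate_dataset(8, seed = 17, switch_fraction = 0.25))
  expect_identical(unclass(a$seqprov), unclass(b$seqprov))
  expect_identical(a$truth, b$truth)
  expect_identical(a$dataset$expression, b$dataset$expression)
  ## and the on-disk form is byte-identical
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  suppressMessages(generate_dataset(5, seed = 17, out_dir = d1))
  suppressMessages(generate_dataset(5, seed = 17, out_dir = d2))
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("switch fraction and class mix shape the planted truth", {
  sim <- suppressMessages(generate_dataset(20, seed = 4, switch_fraction = 0.2))
  expect_equal(nrow(sim$truth$switches), 4)
  ir_only <- suppressMessages(generate_dataset(
    15, seed = 6, class_mix = c(IR = 1), switch_fraction = 0))
  expect_setequal(unique(ir_only$truth$events$event_class), "IR")
  expect_null(ir_only$truth$switches)
})

test_that("planted splice motifs are written at the planted rate", {
  sim <- suppressMessages(generate_dataset(40, seed = 8, canonical_frac = 0.9))
  rep <- splice_site_report(sim$dataset, sim$seqprov)
  expect_equal(rep$site, c("donor_GT", "acceptor_AG"))
  truth_rate <- mean(sim$truth$motifs$canonical)
  ## the report's per-intron rates should sit near the per-site planted rate
  expect_lt(max(abs(rep$percent / 100 - truth_rate)), 0.08)
  ## and a fully canonical genome reports 100%
  all_gt <- suppressMessages(generate_dataset(10, seed = 9, canonical_frac = 1))
  rep2 <- splice_site_report(all_gt$dataset, all_gt$seqprov)
  expect_equal(rep2$percent, c(100, 100))
})

test_that("planted PTC boundary distances land exactly", {
  set.seed(3)
  for (d in c(49L, 50L, 51L)) {
    sim <- simulate_gene(gene_blueprint(planted_cds = "ptc_at_distance",
                                        ptc_distance = d),
                         gene_id = "G1")
    expect_equal(sim$truth_orf$stop_to_junction, d)
    expect_equal(sim$truth_orf$ptc, d > 50)
  }
})
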