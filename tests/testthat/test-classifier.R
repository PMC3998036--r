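## The definitional cases against the four-exon reference
## E1=[100,200) E2=[300,400) E3=[500,600) E4=[700,800).
toy_cases <- list(
  ESI = list(t = list(c(100, 500, 700), c(200, 600, 800)),
             elements = data.frame(start = 300L, end = 400L)),
  MESI = list(t = list(c(100, 700), c(200, 800)),
              elements = data.frame(start = c(300L, 500L), end = c(400L, 600L))),
  IR = list(t = list(c(100, 300, 700), c(200, 600, 800)),
            elements = data.frame(start = 400L, end = 500L)),
  A5 = list(t = list(c(100, 300, 500, 700), c(180, 400, 600, 800)),
            elements = data.frame(start = 180L, end = 200L)),
  A3 = list(t = list(c(100, 320, 500, 700), c(200, 400, 600, 800)),
            elements = data.frame(start = 300L, end = 320L)),
  ATSS = list(t = list(c(300, 500, 700), c(400, 600, 800)),
              elements = data.frame(start = 100L, end = 200L)),
  ATTS = list(t = list(c(100, 300, 500), c(200, 400, 600)),
              elements = data.frame(start = 700L, end = 800L))
)

test_that("each definitional case yields exactly one event with exact elements", {
  r <- make_ref()
  for (cls in names(toy_cases)) {
    tc <- toy_cases[[cls]]
    ev <- classify_transcript(make_t(tc$t[[1]], tc$t[[2]]), r)
    expect_length(ev, 1)
    expect_equal(ev[[1]]$event_class, cls, info = cls)
    expect_equal(ev[[1]]$elements, tc$elements, info = cls)
  }
})

test_that("a transcript identical to its reference yields no events", {
  r <- make_ref()
  t <- make_t(ref_exons4$start, ref_exons4$end)
  expect_length(classify_transcript(t, r), 0)
  ## and via the pre-RNA of a single-transcript gene
  g <- gene_model(list(make_t(c(100, 300), c(200, 400), id = "T1")))
  expect_length(classify_transcript(g$transcripts$T1, build_pre_rna(g)), 0)
})

test_that("event classes are strand-relative: mirrored genes classify identically", {
  M <- 1000L
  r_plus <- make_ref()
  r_minus <- make_ref(mirror_exons(ref_exons4, M), strand = "-")
  for (cls in names(toy_cases)) {
    tc <- toy_cases[[cls]]
    ev_p <- classify_transcript(make_t(tc$t[[1]], tc$t[[2]]), r_plus)
    ex_m <- mirror_exons(data.frame(start = tc$t[[1]], end = tc$t[[2]]), M)
    ev_m <- classify_transcript(make_t(ex_m$start, ex_m$end, strand = "-"),
                                r_minus)
    expect_equal(ev_m[[1]]$event_class, ev_p[[1]]$event_class, info = cls)
    expect_equal(ev_m[[1]]$elements,
                 mirror_exons(ev_p[[1]]$elements, M)[, c("start", "end")],
                 ignore_attr = TRUE, info = cls)
  }
})

test_that("terminal coordinate wobble is not reported as an event", {
  r <- make_ref()
  ## first exon starts inside the reference first exon: no ATSS, no A3
  t <- make_t(c(150, 300, 500, 700), c(200, 400, 600, 800))
  expect_length(classify_transcript(t, r), 0)
  ## last exon ends early inside the reference last exon: no ATTS, no A5
  t2 <- make_t(c(100, 300, 500, 700), c(200, 400, 600, 750))
  expect_length(classify_transcript(t2, r), 0)
})

test_that("alternative starts spanning several reference exons give one multi-element event", {
  r <- make_ref()
  t <- make_t(c(500, 700), c(600, 800))
  ev <- classify_transcript(t, r)
  expect_length(ev, 1)
  expect_equal(ev[[1]]$event_class, "ATSS")
  expect_equal(ev[[1]]$elements,
               data.frame(start = c(100L, 300L), end = c(200L, 400L)))
})

test_that("combined events on one transcript are all reported", {
  r <- make_ref()
  ## ATSS (E1) + ESI (E3) together
  t <- make_t(c(300, 700), c(400, 800))
  ev <- classify_transcript(t, r)
  expect_equal(sort(vapply(ev, `[[`, "", "event_class")), c("ATSS", "ESI"))
})

test_that("mutually exclusive exons are found between transcripts, not vs the pre-RNA", {
  ta <- make_t(c(100, 300, 700), c(200, 400, 800), id = "Ta")
  tb <- make_t(c(100, 500, 700), c(200, 600, 800), id = "Tb")
  g <- gene_model(list(ta, tb))
  mee <- detect_mee(g)
  expect_length(mee, 1)
  expect_equal(mee[[1]]$elements,
               data.frame(start = c(300L, 500L), end = c(400L, 600L)))
  expect_equal(mee[[1]]$transcript_id, "Ta|Tb")
  ## vs the pre-RNA each shows an ESI, never exclusivity
  r <- build_pre_rna(g)
  expect_equal(vapply(classify_transcript(ta, r), `[[`, "", "event_class"), "ESI")

  ## a shared exon disqualifies the pair
  tc <- make_t(c(100, 300, 700), c(200, 400, 800), id = "Tc")
  expect_length(detect_mee(gene_model(list(ta, tc))), 0)
})

test_that("classification and MEE detection match the per-base oracle on random genes", {
  sim <- suppressMessages(generate_dataset(60, seed = 91))
  d <- sim$dataset
  for (gid in names(d$genes)) {
    g <- d$genes[[gid]]
    r_me <- suppressWarnings(select_most_expressed(g, d$expression, "WT"))
    r_pre <- build_pre_rna(g)
    for (t in g$transcripts) {
      expect_identical(event_signature(classify_transcript(t, r_me)),
                       event_signature(oracle_classify(t, r_me)))
      expect_identical(event_signature(classify_transcript(t, r_pre)),
                       event_signature(oracle_classify(t, r_pre)))
    }
    expect_identical(event_signature(detect_mee(g)),
                     event_signature(oracle_mee(g)))
  }
})

test_that("classify_all composes per-transcript events, MEE and is deterministic", {
  r <- make_ref()
  trs <- c(lapply(c("ESI", "MESI", "IR", "A5", "A3", "ATSS"), function(cls) {
    tc <- toy_cases[[cls]]
    make_t(tc$t[[1]], tc$t[[2]], id = paste0("T_", cls))
  }), list(make_t(ref_exons4$start, ref_exons4$end, id = "T_REF")))
  g <- gene_model(trs)
  ids <- names(g$transcripts)
  expr <- make_expr(ids, "G1", "WT",
                    ifelse(ids == "T_REF", 70, 5), gexpr = 100)
  d <- splice_dataset(list(g), expr, c("WT"))
  tab <- classify_all(d, "most_expressed")
  expect_equal(sort(tab$event_class),
               sort(c("ESI", "MESI", "IR", "A5", "A3", "ATSS")))
  counts <- count_events(tab)
  expect_equal(counts[["ESI"]], 1)
  expect_equal(counts[["ATTS"]], 0)
  expect_equal(counts[["MEE"]], 0)
  expect_length(counts, 8)
  ## byte-identical on rerun
  expect_identical(tab, classify_all(d, "most_expressed"))
})

test_that("single-transcript genes yield no events against their own pre-RNA", {
  g <- gene_model(list(make_t(c(100, 300), c(200, 400), id = "T1")))
  d <- splice_dataset(list(g), make_expr("T1", "G1", "WT", 5), "WT")
  tab <- classify_all(d, "pre_rna")
  expect_equal(nrow(tab), 0)
  expect_true(all(count_events(tab) == 0))
})

test_that("event tables serialize 1-based inclusive elements and parse back", {
  r <- make_ref()
  ev <- classify_transcript(make_t(c(100, 500, 700), c(200, 600, 800)), r)
  tab <- events_table(ev)
  expect_equal(tab$elements, "chr1:301-400")
  expect_equal(parse_elements(tab$elements),
               data.frame(start = 300L, end = 400L))
  bed <- events_to_bed(tab)
  expect_equal(bed$start, 300L)
  expect_equal(bed$name, "ESI:T")
})
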