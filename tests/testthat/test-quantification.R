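test_that("IF follows the percentage formula and flags undefined cases", {
  expr <- rbind(make_expr("T1", "G1", "WT", 30, gexpr = 120),
                make_expr("T2", "G2", "WT", 0, gexpr = 120),
                make_expr("T3", "G3", "WT", 10, gexpr = 0))
  ifs <- suppressMessages(compute_if(expr))
  expect_equal(ifs$IF[1], 25.0)
  expect_equal(ifs$IF[2], 0.0)
  expect_true(is.na(ifs$IF[3]))
  expect_false(ifs$if_defined[3])
})

test_that("dIF is the signed difference in percentage points", {
  expr <- rbind(make_expr("T1", "G1", "WT", 25, gexpr = 100),
                make_expr("T1", "G1", "KD", 60, gexpr = 100),
                make_expr("T2", "G1", "WT", 60, gexpr = 100),
                make_expr("T2", "G1", "KD", 25, gexpr = 100),
                make_expr("T3", "G2", "WT", 10, gexpr = 0),
                make_expr("T3", "G2", "KD", 10, gexpr = 100))
  difs <- suppressMessages(compute_dif(compute_if(expr), c("WT", "KD")))
  expect_equal(difs$dIF[difs$transcript_id == "T1"], 35)
  expect_equal(difs$dIF[difs$transcript_id == "T2"], -35)
  expect_true(is.na(difs$dIF[difs$transcript_id == "T3"]))
})

test_that("per-gene IFs sum to 100 and dIFs to 0 when gene_expr is the transcript sum", {
  sim <- suppressMessages(generate_dataset(40, seed = 5, switch_fraction = 0.25))
  ifs <- compute_if(sim$dataset)
  sums <- tapply(ifs$IF, paste(ifs$gene_id, ifs$condition), sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  difs <- compute_dif(ifs, c("WT", "KD"))
  dsums <- tapply(difs$dIF, difs$gene_id, sum)
  expect_true(all(abs(dsums) < 1e-9))
})

test_that("status and expression filters drop what they claim and cascade", {
  t1 <- make_t(c(100, 300), c(200, 400), id = "T1")
  t2 <- make_t(c(100, 500), c(200, 600), id = "T2")
  t3 <- make_t(100, 900, id = "T3", gene = "G2")
  g1 <- gene_model(list(t1, t2))
  g2 <- gene_model(list(t3))
  expr <- rbind(
    make_expr(c("T1", "T2"), "G1", "WT", c(5, 8), gexpr = 13,
              iso_status = c("OK", "LOWDATA")),
    make_expr(c("T1", "T2"), "G1", "KD", c(5, 8), gexpr = 13,
              iso_status = c("OK", "LOWDATA")),
    make_expr("T3", "G2", "WT", 0, gexpr = 0),
    make_expr("T3", "G2", "KD", 5, gexpr = 5))
  d <- splice_dataset(list(g1, g2), expr, c("WT", "KD"))

  f1 <- suppressMessages(filter_dataset(d, "iso_ok"))
  expect_false("T2" %in% unlist(lapply(f1$genes, function(g) names(g$transcripts))))

  ## any-condition rule: T3 expressed only in KD is kept
  f2 <- suppressMessages(filter_dataset(d, "expressed_isoforms"))
  expect_true("T3" %in% names(f2$genes$G2$transcripts))

  ## single_exon drops T3, which cascades to dropping G2 entirely
  f3 <- suppressMessages(filter_dataset(d, "single_exon"))
  expect_false("G2" %in% names(f3$genes))

  expect_error(filter_dataset(splice_dataset(list(g1),
    make_expr(c("T1", "T2"), "G1", "WT", c(1, 1), iso_status = NA), "WT"),
    "iso_ok"), "iso_status absent")
})

test_that("switch detection pairs extreme transcripts above the threshold", {
  mk_difs <- function(difs_by_t) {
    data.frame(transcript_id = names(difs_by_t), gene_id = "G1",
               IF1 = 50, IF2 = 50 + unlist(difs_by_t),
               dIF = unlist(difs_by_t), dif_defined = TRUE,
               gene_expr1 = 10, gene_expr2 = 10)
  }
  sw <- detect_switches(mk_difs(c(T1 = 35, T2 = -35)), tau = 25)
  expect_equal(nrow(sw), 1)
  expect_equal(sw$up_transcript_id, "T1")
  expect_equal(sw$down_transcript_id, "T2")

  expect_equal(nrow(detect_switches(mk_difs(c(T1 = 20, T2 = -35)), tau = 25)), 0)

  ## one call per gene pairing the extremes
  sw2 <- detect_switches(mk_difs(c(T1 = 30, T2 = 45, T3 = -28, T4 = -50)),
                         tau = 25)
  expect_equal(sw2$up_transcript_id, "T2")
  expect_equal(sw2$down_transcript_id, "T4")

  ## low gene expression suppresses the call
  low <- mk_difs(c(T1 = 35, T2 = -35))
  low$gene_expr2 <- 0.5
  expect_equal(nrow(detect_switches(low, tau = 25, min_gene_expr = 1)), 0)

  ## NMD gain: down transcript PTC-negative, up transcript PTC-positive
  orf <- data.frame(transcript_id = c("T1", "T2"), ptc = c(TRUE, FALSE))
  expect_true(detect_switches(mk_difs(c(T1 = 35, T2 = -35)), orf = orf,
                              tau = 25)$nmd_gain)
  orf2 <- data.frame(transcript_id = c("T1", "T2"), ptc = c(FALSE, FALSE))
  expect_false(detect_switches(mk_difs(c(T1 = 35, T2 = -35)), orf = orf2,
                               tau = 25)$nmd_gain)
})

test_that("raising the switch threshold never adds calls", {
  sim <- suppressMessages(generate_dataset(40, seed = 13, switch_fraction = 0.3))
  difs <- compute_dif(compute_if(sim$dataset), c("WT", "KD"))
  n_prev <- Inf
  for (tau in c(5, 15, 25, 34, 36, 60)) {
    n <- nrow(detect_switches(difs, tau = tau))
    expect_lte(n, n_prev)
    n_prev <- n
  }
  ## planted switches of 35 points are found at tau 25, gone at tau 40
  expect_equal(nrow(detect_switches(difs, tau = 25)),
               nrow(sim$truth$switches))
  expect_equal(nrow(detect_switches(difs, tau = 40)), 0)
})

test_that("switch calls do not depend on transcript insertion order", {
  difs <- data.frame(transcript_id = c("T3", "T1", "T2"), gene_id = "G1",
                     IF1 = 50, IF2 = 50, dIF = c(-35, 35, 35),
                     dif_defined = TRUE, gene_expr1 = 10, gene_expr2 = 10)
  a <- detect_switches(difs, tau = 25)
  b <- detect_switches(difs[c(2, 3, 1), ], tau = 25)
  expect_identical(a, b)
  expect_equal(a$up_transcript_id, "T1")  # tie on dIF breaks by id
})

test_that("subset IF comparison returns a two-sided rank-sum test", {
  ifs <- data.frame(
    transcript_id = rep(c("T1", "T2", "T3"), 2), gene_id = "G1",
    condition = rep(c("WT", "KD"), each = 3),
    transcript_expr = 1, gene_expr = 10,
    IF = c(10, 20, 30, 40, 50, 60), if_defined = TRUE)
  res <- subset_if_distributions(ifs, c("T1", "T2", "T3"), c("WT", "KD"))
  expect_equal(res$statistic, 0)  # every WT rank below every KD rank
  expect_equal(res$if1, c(10, 20, 30))

  ## identical distributions: two-sided p = 1
  ifs$IF <- rep(c(10, 20, 30), 2)
  res2 <- subset_if_distributions(ifs, c("T1", "T2", "T3"), c("WT", "KD"))
  expect_equal(res2$p_value, 1.0)

  expect_error(subset_if_distributions(ifs, character(0), c("WT", "KD")),
               "empty")
})
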