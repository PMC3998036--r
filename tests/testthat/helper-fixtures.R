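## Shared fixtures: the four-exon reference used by the definitional event
## cases, small builders, and a lazily-built large simulation shared by the
## acceptance checks.

ref_exons4 <- data.frame(start = c(100L, 300L, 500L, 700L),
                         end = c(200L, 400L, 600L, 800L))

make_ref <- function(exons = ref_exons4, strand = "+", mode = "pre_rna",
                     gene_id = "G1") {
  structure(list(gene_id = gene_id, chrom = "chr1", strand = strand,
                 mode = mode, merged_exons = exons,
                 source_transcript_id = NA_character_),
            class = "reference_model")
}

make_t <- function(starts, ends, strand = "+", id = "T", gene = "G1") {
  transcript_model(id, gene, "chr1", strand, intervals(starts, ends))
}

## Mirror a transcript/exon table about coordinate M and flip strand.
mirror_exons <- function(exons, M) {
  data.frame(start = M - exons$end, end = M - exons$start)[rev(seq_len(nrow(exons))), ]
}

flip <- function(strand) if (strand == "+") "-" else "+"

## Expression table builder: one row per transcript x condition.
make_expr <- function(ids, gene, cond, texpr, gexpr = sum(texpr),
                      iso_status = "OK") {
  data.frame(transcript_id = ids, gene_id = gene, condition = cond,
             transcript_expr = texpr, gene_expr = gexpr,
             iso_status = iso_status, gene_status = "OK", pvalue = NA_real_)
}

## The large planted simulation used across acceptance checks; built once.
.acc_cache <- new.env(parent = emptyenv())
acc_sim <- function() {
  if (is.null(.acc_cache$sim)) {
    .acc_cache$sim <- suppressMessages(
      generate_dataset(500, seed = 20240501, switch_fraction = 0.1))
  }
  .acc_cache$sim
}
acc_orf_sim <- function() {
  if (is.null(.acc_cache$orf)) {
    .acc_cache$orf <- suppressMessages(simulate_orf_transcripts(500, seed = 77))
  }
  .acc_cache$orf
}
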