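# splicewise

Alternative-splicing event classification, isoform-fraction statistics and
NMD prediction from assembled full-length transcripts.

RNA-seq assemblers (Cufflinks, StringTie, ...) output full-length transcript
models per gene, but not *what changed* between isoforms or conditions.
`splicewise` is for transcriptomics analysts who have a transcript GTF plus
per-condition expression estimates and want, per transcript:

* **classified splicing events with genomic coordinates** — single/multiple
  exon skipping/inclusion (ESI, MESI), alternative donor and acceptor sites
  (A5, A3), intron retention (IR), alternative first/last exon usage
  (ATSS, ATTS) and mutually exclusive exons (MEE), each reported with the
  coordinates of the spliced element(s) so the sequence underneath can be
  analysed downstream;
* **isoform fraction statistics** — IF = transcript expression / gene
  expression × 100, the signed between-condition change dIF, and binary
  transcript-switch calls (a gene where one isoform's dIF ≥ +τ while
  another's ≤ −τ, default τ = 25 percentage points);
* **ORF and NMD annotation** — the most upstream compatible annotated start
  codon is mapped into transcript coordinates, the first in-frame stop is
  located, 5′UTR/ORF/3′UTR lengths are derived, and the transcript is
  flagged as a candidate nonsense-mediated-decay substrate when the stop
  lies more than 50 nt (configurable) upstream of the final exon–exon
  junction;
* **browser tracks** — per-condition GTF files with transcripts
  colour-coded by their within-gene expression.

## The model in brief

For every gene a comparison reference is built: the **hypothetical pre-RNA**
(the union of all isoforms' exons, merged) or optionally the
**most-expressed transcript** in a chosen reference condition — useful in
perturbation designs where deviation from the control structure is of
interest, and required to observe intron retention (a retained intron is, by
construction, exonic in the pre-RNA union). Each transcript is then compared
to the reference with a deterministic interval-algebra decision procedure;
the event taxonomy and its per-rule definitions are documented in
`?classify_transcript` and in the methods vignette. MEE is detected between
transcript pairs, since the pre-RNA contains both exons of an exclusive pair
and can never show exclusivity.

Statistical testing of differential splicing is deliberately out of scope:
quantification-status flags and p-values from the upstream pipeline are
carried through, and dedicated count-based packages should be used for
formal testing. The one statistical procedure included is the two-sided
Mann–Whitney U comparison of condition-wise IF distributions over a
transcript subset (`subset_if_distributions()`), e.g. all IR-bearing or all
NMD-sensitive transcripts.

## Inputs

1. transcript models in GTF (`transcript_id` / `gene_id` attributes;
   quoted or unquoted values);
2. expression per transcript and condition — either a Cufflinks-style
   `*_FPKM`/`*_status` tracking table or the generic TSV with header
   `transcript_id  gene_id  condition  transcript_expr  gene_expr`
   (+ optional `iso_status`, `gene_status`, `pvalue`), one row per
   transcript × condition;
3. genome FASTA;
4. start-codon annotation in UCSC genePred (refGene column order) or a
   simple `name chrom strand start_codon_genomic` table (0-based; on the
   minus strand the genomically 3′-most base of the codon, i.e.
   `cdsEnd − 1`).

A deterministic simulator (`generate_dataset()`) writes all four coherently
with planted ground truth, and doubles as the package's test fixture
factory.

## Worked example

```r
library(splicewise)

# simulate a small coherent input set (or point the readers at your files)
sim <- generate_dataset(10, seed = 101, switch_fraction = 0.2,
                        out_dir = "demo")
genes <- read_gtf("demo/transcripts.gtf")
expr  <- read_expression("demo/expression.tsv", "generic_tsv", c("WT", "KD"))
d     <- splice_dataset(genes, expr, c("WT", "KD"))

events <- classify_all(d, reference_mode = "most_expressed")
count_events(events)
#>  ESI MESI   A5   A3   IR ATSS ATTS  MEE
#>    4    1    2    2    0    5    0    1

head(events[, c("transcript_id", "event_class", "elements")], 3)
#>   transcript_id event_class       elements
#> 1       G0001.2        ATSS chr1:1188-1394
#> 2       G0001.3          A3   chr1:664-686
#> 3       G0002.2          A3 chr1:2240-2273
```

Fifteen transcript-level events on this seed; each row carries the 1-based
inclusive genomic coordinates of its spliced element(s) — e.g. isoform
G0001.3 uses an alternative acceptor that splices out chr1:664-686.

```r
seqprov <- read_fasta("demo/genome.fa")
cds     <- read_cds_table("demo/annotation.genepred", "genepred")
orf     <- annotate_orfs(d, seqprov, cds, ptc_threshold = 50)
summarize_ptc(orf)
#>                 class count percent
#> 1                PTC-    13    54.2
#> 2                PTC+     4    16.7
#> 3 no_compatible_start     7    29.2

ifs  <- compute_if(d)
difs <- compute_dif(ifs, c("WT", "KD"))
detect_switches(difs, orf = orf, tau = 25, min_gene_expr = 1)
#>   gene_id up_transcript_id down_transcript_id dIF_up dIF_down nmd_gain
#> 1   G0001          G0001.2            G0001.1     35      -35    FALSE
#> 2   G0002          G0002.2            G0002.1     35      -35    FALSE
```

A switch row reads: in gene G0001, isoform `.2` gained 35 IF percentage
points between WT and KD while isoform `.1` lost 35 — a binary isoform
switch; `nmd_gain` would be `TRUE` if the rising isoform were PTC-positive
and the falling one PTC-negative, i.e. a switch into an NMD substrate.

The same pipeline runs from a shell via the installed script:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/splicewise.R", package="splicewise"))') \
  all --gtf demo/transcripts.gtf --expression demo/expression.tsv \
  --fasta demo/genome.fa --cds demo/annotation.genepred \
  --conditions WT,KD --out-dir results/
```

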