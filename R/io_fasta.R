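#' Read a genome FASTA into a sequence provider
#'
#' Headers are truncated at the first whitespace; sequences are upper-cased.
#' Duplicate chromosome names are an error.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return A named character vector, chromosome name -> sequence, of class
#'   `sequence_provider`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("[[:space:]].*$", "", names(ss))
  if (anyDuplicated(nm)) {
    stop(sprintf("duplicate FASTA header(s): %s",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  seqs <- toupper(as.character(ss))
  names(seqs) <- nm
  structure(seqs, class = "sequence_provider")
}

#' Build a sequence provider from in-memory sequences
#' @param seqs Named character vector, chromosome -> sequence.
#' @return A `sequence_provider`.
#' @export
sequence_provider <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("sequences must be named by chromosome")
  }
  structure(toupper(seqs), class = "sequence_provider")
}

#' Reverse complement of a nucleotide string
#' @param s Character scalar over {A,C,G,T,N}.
#' @return Reverse-complemented string.
#' @export
reverse_complement <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Spliced transcript sequence, 5' to 3' in transcript orientation
#'
#' Concatenates the exon substrings in genomic order and reverse-complements
#' the result for minus-strand transcripts.
#'
#' @param t A [transcript_model()].
#' @param seqprov A `sequence_provider` from [read_fasta()] or
#'   [sequence_provider()].
#' @return Nucleotide string of length [transcript_length()].
#' @export
transcript_sequence <- function(t, seqprov) {
  if (!t$chrom %in% names(seqprov)) {
    stop(sprintf("chromosome %s absent from sequence provider", t$chrom))
  }
  chromseq <- unclass(seqprov)[[t$chrom]]
  if (max(t$exons$end) > nchar(chromseq)) {
    stop(sprintf("transcript %s: exon beyond end of %s (%d > %d)",
                 t$transcript_id, t$chrom, max(t$exons$end), nchar(chromseq)))
  }
  plus <- paste(substring(chromseq, t$exons$start + 1L, t$exons$end),
                collapse = "")
  if (t$strand == "+") plus else reverse_complement(plus)
}
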