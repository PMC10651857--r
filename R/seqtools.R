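#' Load a genome FASTA
#'
#' Reads the genome into a `DNAStringSet`; sequence names are truncated at
#' the first whitespace so they match chromosome names in event tables.
#'
#' @param path FASTA file path.
#' @return `Biostrings::DNAStringSet`.
#' @export
load_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- vapply(strsplit(names(g), "\\s+"), `[`, "", 1L)
  g
}

#' Reverse complement
#'
#' @param dna character vector of DNA strings.
#' @return character vector.
#' @export
revcomp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(dna)))
}

#' Strand-aware exon DNA extraction
#'
#' Extracts the genomic substring `[start, end]` (1-based inclusive),
#' uppercased, and reverse-complements it when `strand` is `-`, so the
#' returned sequence always reads 5' to 3' in transcript orientation.
#'
#' @param genome `DNAStringSet` from [load_genome()].
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"+"` or `"-"`.
#' @return character scalar of length `end - start + 1`.
#' @export
extract_exon_dna <- function(genome, chrom, start, end, strand = "+") {
  strand <- normalize_strand(strand)
  if (!chrom %in% names(genome))
    stop("chromosome '", chrom, "' not in genome")
  len <- Biostrings::width(genome[chrom])
  if (start < 1 || end > len || start > end)
    stop(sprintf("interval %s:%d-%d outside chromosome bounds (1-%d)",
                 chrom, start, end, len))
  s <- Biostrings::subseq(genome[[chrom]], start, end)
  s <- Biostrings::DNAString(toupper(as.character(s)))
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Translate DNA in a given reading frame
#'
#' Frame `f` skips the first `f - 1` nucleotides, then translates complete
#' codons with the standard genetic code; 1-2 trailing nucleotides are
#' dropped. Stop codons become `*`; codons containing `N` (or other
#' ambiguity codes) become `X` and count as neither stop nor match
#' downstream.
#'
#' @param dna character scalar over A/C/G/T/N (case-insensitive).
#' @param frame 1, 2 or 3.
#' @return amino-acid string (possibly empty).
#' @export
translate_dna <- function(dna, frame = 1L) {
  stopifnot(frame %in% 1:3)
  dna <- toupper(dna)
  nc <- nchar(dna) - (frame - 1L)
  if (nc < 3L) return("")
  sub <- substr(dna, frame, frame - 1L + 3L * (nc %/% 3L))
  as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                     if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}

#' Assemble the spliced DNA of one isoform of an event
#'
#' Extracts each exon strand-aware and concatenates them in transcription
#' order (exons are stored in transcription order; on the `-` strand that
#' is descending genomic coordinates), yielding the isoform's mRNA-level
#' sequence 5' to 3'.
#'
#' @param event a `"splice_event"`.
#' @param genome `DNAStringSet`.
#' @param isoform 1 or 2.
#' @return character scalar.
#' @export
assemble_isoform_dna <- function(event, genome, isoform = 2L) {
  ex <- if (isoform == 1L) event$iso1_exons else event$iso2_exons
  paste(vapply(seq_len(nrow(ex)), function(i)
    extract_exon_dna(genome, event$chrom, ex$start[i], ex$end[i],
                     event$strand), ""), collapse = "")
}
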