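#' Translate both isoforms of an event in the predicted frame
#'
#' Assembles each isoform's exonic DNA (transcription order, strand-aware)
#' and translates it from the shared frame of the event's first 5' exon.
#' Translation does not halt at stop codons: internal `*` characters are
#' retained so the downstream decomposition can report sequence after a
#' stop; the first-stop position is reported separately.
#'
#' @param event a normalized `"splice_event"`.
#' @param frame `"1"`, `"2"` or `"3"` (refused for `"X"`).
#' @param genome `DNAStringSet`.
#' @return list `(aa_iso1, aa_iso2)`.
#' @export
translate_isoforms <- function(event, frame, genome) {
  frame <- as.character(frame)
  if (frame == "X") stop("cannot translate an event with unresolved frame")
  f <- as.integer(frame)
  list(aa_iso1 = translate_dna(assemble_isoform_dna(event, genome, 1L), f),
       aa_iso2 = translate_dna(assemble_isoform_dna(event, genome, 2L), f))
}

#' Four-segment decomposition of two isoform peptides
#'
#' Splits each peptide into `same_start` (longest common prefix), an
#' isoform-specific middle (either may be empty), and `same_end` (longest
#' common suffix of the post-prefix remainders, capped so segments never
#' overlap; ties favor the longer prefix). By construction
#' `same_start + diff_iso + same_end` reconstructs each input.
#'
#' @param aa_iso1,aa_iso2 peptides from the same frame (may contain `*`).
#' @return list: `same_start_aa, diff_aa_iso1, diff_aa_iso2, same_end_aa`.
#' @export
diff_isoforms <- function(aa_iso1, aa_iso2) {
  c1 <- strsplit(aa_iso1, "")[[1L]]
  c2 <- strsplit(aa_iso2, "")[[1L]]
  npre <- 0L
  kmax <- min(length(c1), length(c2))
  while (npre < kmax && c1[npre + 1L] == c2[npre + 1L]) npre <- npre + 1L
  r1 <- c1[seq_len(length(c1) - npre) + npre]
  r2 <- c2[seq_len(length(c2) - npre) + npre]
  nsuf <- 0L
  smax <- min(length(r1), length(r2))
  while (nsuf < smax &&
         r1[length(r1) - nsuf] == r2[length(r2) - nsuf]) nsuf <- nsuf + 1L
  list(same_start_aa = paste(c1[seq_len(npre)], collapse = ""),
       diff_aa_iso1 = paste(r1[seq_len(length(r1) - nsuf)], collapse = ""),
       diff_aa_iso2 = paste(r2[seq_len(length(r2) - nsuf)], collapse = ""),
       same_end_aa = if (nsuf)
         paste(r1[seq(length(r1) - nsuf + 1L, length(r1))], collapse = "")
       else "")
}

#' Frameshift detection
#'
#' The event introduces a frameshift when the total exonic length of the
#' two isoforms differs by a non-multiple of 3 (shared flanking exons
#' cancel, so this equals the middle-segment length difference; for intron
#' retention the "middle" is the retained intron, present only in
#' isoform 2).
#'
#' @param event a normalized `"splice_event"`.
#' @return logical.
#' @export
detect_frameshift <- function(event) {
  (exon_nt(event$iso2_exons) - exon_nt(event$iso1_exons)) %% 3L != 0L
}

#' Genomic coordinate of a residue's codon
#'
#' Walks the isoform's exon structure (transcription order, strand-aware)
#' to the first base of the codon encoding `residue_index`, where
#' translation starts at offset `frame - 1` of the assembled isoform DNA.
#' Used to place stop codons and peptide differences on the genome.
#'
#' @param event a normalized `"splice_event"`.
#' @param frame `"1"`, `"2"` or `"3"`.
#' @param residue_index 1-based residue position in the isoform's peptide.
#' @param isoform 1 or 2.
#' @return integer genomic coordinate.
#' @export
map_aa_to_genomic <- function(event, frame, residue_index, isoform = 2L) {
  f <- as.integer(as.character(frame))
  stopifnot(f %in% 1:3, residue_index >= 1)
  ex <- if (isoform == 1L) event$iso1_exons else event$iso2_exons
  offset <- (f - 1L) + 3L * (residue_index - 1L)   # 0-based transcript pos
  total <- exon_nt(ex)
  if (offset + 3L > total)
    stop("residue ", residue_index, " beyond the translated peptide")
  cum <- 0L
  for (i in seq_len(nrow(ex))) {
    len <- ex$end[i] - ex$start[i] + 1L
    if (offset < cum + len) {
      within <- offset - cum
      return(if (event$strand == "+") ex$start[i] + within
             else ex$end[i] - within)
    }
    cum <- cum + len
  }
  stop("internal error: exon walk exhausted")   # nocov
}

first_stop <- function(aa) {
  pos <- regexpr("*", aa, fixed = TRUE)
  if (pos < 0L) NA_integer_ else as.integer(pos)
}

#' Protein-level difference of one event
#'
#' Translates both isoforms in the predicted frame and decomposes the
#' difference: shared start, isoform-specific middles, shared end,
#' first-stop positions (residue index and genomic coordinate of the stop
#' codon's first base) and the frameshift flag.
#'
#' @param event a normalized `"splice_event"`.
#' @param frame `"1"`, `"2"` or `"3"`.
#' @param genome `DNAStringSet`.
#' @return one-row data frame: `event_id, aa_iso1, aa_iso2, same_start_aa,
#'   diff_aa_iso1, diff_aa_iso2, same_end_aa, stop_in_iso1, stop_in_iso2,
#'   stop_pos_iso1, stop_pos_iso2, stop_genomic_iso1, stop_genomic_iso2,
#'   frameshift`.
#' @export
protein_diff <- function(event, frame, genome) {
  aa <- translate_isoforms(event, frame, genome)
  d <- diff_isoforms(aa$aa_iso1, aa$aa_iso2)
  s1 <- first_stop(aa$aa_iso1)
  s2 <- first_stop(aa$aa_iso2)
  g1 <- if (is.na(s1)) NA_integer_ else
    map_aa_to_genomic(event, frame, s1, 1L)
  g2 <- if (is.na(s2)) NA_integer_ else
    map_aa_to_genomic(event, frame, s2, 2L)
  data.frame(event_id = event$event_id,
             aa_iso1 = aa$aa_iso1, aa_iso2 = aa$aa_iso2,
             same_start_aa = d$same_start_aa,
             diff_aa_iso1 = d$diff_aa_iso1, diff_aa_iso2 = d$diff_aa_iso2,
             same_end_aa = d$same_end_aa,
             stop_in_iso1 = !is.na(s1), stop_in_iso2 = !is.na(s2),
             stop_pos_iso1 = s1, stop_pos_iso2 = s2,
             stop_genomic_iso1 = g1, stop_genomic_iso2 = g2,
             frameshift = detect_frameshift(event))
}
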