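#' First shared 5' exon of an event
#'
#' The reading-frame prediction anchors on the first 5' exon of the event,
#' which is shared between the two isoforms (translating a single exon
#' keeps the chance of hitting multiple stop codons low). In transcription
#' order this is the first exon of each isoform; when the two first exons
#' differ in length but share their 5' boundary (alternative 5' splice
#' sites on the first exon; intron retention, where the spliced isoform's
#' first exon is a prefix of the merged exon), the shared 5' segment is
#' returned. If the isoforms share no 5' segment the event is unresolvable
#' and gets frame `"X"`.
#'
#' @param event a normalized `"splice_event"`.
#' @return list `(start, end)` or `NULL` when no shared 5' exon exists.
#' @export
first_5prime_exon <- function(event) {
  e1 <- event$iso1_exons[1L, ]
  e2 <- event$iso2_exons[1L, ]
  if (event$strand == "+") {
    if (e1$start != e2$start) return(NULL)
    list(start = e1$start, end = min(e1$end, e2$end))
  } else {
    if (e1$end != e2$end) return(NULL)
    list(start = max(e1$start, e2$start), end = e1$end)
  }
}

#' Reading frame by the single-open-reading-frame method
#'
#' Translates the exon in all three frames and calls a frame "open" when
#' its translation has at least one codon and no stop codon. The frame is
#' unambiguous if and only if exactly one frame is open; otherwise `"X"`.
#' No start codon is required: event exons are usually internal to the
#' transcript.
#'
#' @param dna first-exon DNA, transcript orientation.
#' @return `"1"`, `"2"`, `"3"` or `"X"`.
#' @export
orf_method <- function(dna) {
  peps <- vapply(1:3, function(f) translate_dna(dna, f), "")
  open <- nchar(peps) > 0L & !grepl("*", peps, fixed = TRUE)
  if (sum(open) == 1L) as.character(which(open)) else "X"
}

#' Reading frame by peptide matching to known proteins
#'
#' Translates the exon in all three frames, truncates each peptide at its
#' first stop codon (the stop excluded), and counts how many known
#' proteins of the gene contain the peptide as an exact substring. Queries
#' shorter than `min_match_len` residues are skipped (counted as zero
#' matches) to avoid spurious hits from short exons. The frame is called
#' when exactly one frame has a positive count and the other two have
#' zero.
#'
#' @param dna first-exon DNA, transcript orientation.
#' @param proteins character vector of known protein sequences of the gene.
#' @param min_match_len minimum query length in residues (default 7).
#' @return list: `frame` (`"1"`/`"2"`/`"3"`/`"X"`), `counts` (integer per
#'   frame).
#' @export
peptide_match_method <- function(dna, proteins, min_match_len = 7L) {
  counts <- integer(3L)
  if (length(proteins)) {
    for (f in 1:3) {
      pep <- translate_dna(dna, f)
      pep <- sub("\\*.*$", "", pep)
      if (nchar(pep) < min_match_len || grepl("X", pep, fixed = TRUE)) next
      counts[f] <- sum(vapply(proteins, function(p)
        grepl(pep, p, fixed = TRUE), NA))
    }
  }
  pos <- which(counts > 0L)
  list(frame = if (length(pos) == 1L) as.character(pos) else "X",
       counts = counts)
}

#' Combine the two frame-prediction methods
#'
#' Both methods agreeing on a frame, or exactly one of them calling a
#' frame, resolves the event. Both unresolved leaves `"X"`. A genuine
#' disagreement (never expected in practice) also yields `"X"`, flagged as
#' a conflict with a warning.
#'
#' @param orf_frame,peptide_frame frame calls (`"1"`/`"2"`/`"3"`/`"X"`).
#' @return list: `frame`, `resolved_by` (one of `both_agree`, `orf_only`,
#'   `peptide_only`, `unresolved`, `conflict`).
#' @export
combine_methods <- function(orf_frame, peptide_frame) {
  if (orf_frame != "X" && peptide_frame != "X") {
    if (orf_frame == peptide_frame)
      return(list(frame = orf_frame, resolved_by = "both_agree"))
    warning("conflicting frame predictions (ORF ", orf_frame, ", peptide ",
            peptide_frame, "); frame set to X")
    return(list(frame = "X", resolved_by = "conflict"))
  }
  if (orf_frame != "X") return(list(frame = orf_frame,
                                    resolved_by = "orf_only"))
  if (peptide_frame != "X") return(list(frame = peptide_frame,
                                        resolved_by = "peptide_only"))
  list(frame = "X", resolved_by = "unresolved")
}

#' Full-isoform fallback for still-ambiguous frames
#'
#' Counts internal stop codons of the full assembled isoform-2 DNA in all
#' three frames (a single terminal stop in the last codon position does
#' not count). If exactly one frame is free of internal stops it is
#' returned; otherwise `"X"`. Optionally requires isoform 1 to be free of
#' internal stops in the same frame as well.
#'
#' @param iso2_dna assembled isoform-2 DNA.
#' @param iso1_dna assembled isoform-1 DNA (used when
#'   `require_both = TRUE`).
#' @param require_both require zero internal stops in both isoforms.
#' @return `"1"`, `"2"`, `"3"` or `"X"`.
#' @export
fallback_full_isoform <- function(iso2_dna, iso1_dna = NULL,
                                  require_both = FALSE) {
  internal_stops <- function(dna, f) {
    pep <- translate_dna(dna, f)
    if (nchar(pep) == 0L) return(NA_integer_)
    stops <- gregexpr("*", pep, fixed = TRUE)[[1L]]
    stops <- stops[stops > 0L]
    sum(stops != nchar(pep))   # terminal stop does not count
  }
  ok <- vapply(1:3, function(f) {
    s2 <- internal_stops(iso2_dna, f)
    good <- !is.na(s2) && s2 == 0L
    if (good && require_both && !is.null(iso1_dna)) {
      s1 <- internal_stops(iso1_dna, f)
      good <- !is.na(s1) && s1 == 0L
    }
    good
  }, NA)
  if (sum(ok) == 1L) as.character(which(ok)) else "X"
}

#' Predict the reading frame of one event
#'
#' Runs the single-ORF and peptide-matching methods on the event's first
#' shared 5' exon, combines them, and when both are ambiguous falls back
#' to counting internal stop codons over the full assembled isoform.
#'
#' @param event a normalized `"splice_event"`.
#' @param genome `DNAStringSet`.
#' @param proteins_by_gene named list from [read_proteins()].
#' @param min_match_len see [peptide_match_method()].
#' @param fallback_both see `require_both` in [fallback_full_isoform()].
#' @return one-row data frame: `event_id, frame, orf_method_frame,
#'   peptide_method_frame, fallback_frame, resolved_by, match_f1, match_f2,
#'   match_f3`.
#' @export
predict_frame <- function(event, genome, proteins_by_gene,
                          min_match_len = 7L, fallback_both = FALSE) {
  fe <- first_5prime_exon(event)
  if (is.null(fe))
    return(data.frame(event_id = event$event_id, frame = "X",
                      orf_method_frame = "X", peptide_method_frame = "X",
                      fallback_frame = "X", resolved_by = "unresolved",
                      match_f1 = 0L, match_f2 = 0L, match_f3 = 0L))
  dna <- extract_exon_dna(genome, event$chrom, fe$start, fe$end,
                          event$strand)
  orf <- orf_method(dna)
  prot <- proteins_by_gene[[event$gene]]
  if (is.null(prot)) prot <- character(0)
  pep <- peptide_match_method(dna, prot, min_match_len)
  comb <- combine_methods(orf, pep$frame)
  fb <- "X"
  if (comb$resolved_by == "unresolved") {
    iso2 <- assemble_isoform_dna(event, genome, 2L)
    iso1 <- if (fallback_both) assemble_isoform_dna(event, genome, 1L)
            else NULL
    fb <- fallback_full_isoform(iso2, iso1, require_both = fallback_both)
    if (fb != "X") comb <- list(frame = fb, resolved_by = "fallback")
  }
  data.frame(event_id = event$event_id, frame = comb$frame,
             orf_method_frame = orf, peptide_method_frame = pep$frame,
             fallback_frame = fb, resolved_by = comb$resolved_by,
             match_f1 = pep$counts[1L], match_f2 = pep$counts[2L],
             match_f3 = pep$counts[3L])
}

#' Predict reading frames for a set of events
#'
#' @param events list of `"splice_event"`.
#' @param genome,proteins_by_gene,min_match_len,fallback_both see
#'   [predict_frame()].
#' @return data frame, one row per event; `frame_method` duplicates
#'   `resolved_by` for the results-table schema.
#' @export
predict_frames <- function(events, genome, proteins_by_gene,
                           min_match_len = 7L, fallback_both = FALSE) {
  out <- do.call(rbind, lapply(events, predict_frame, genome = genome,
                               proteins_by_gene = proteins_by_gene,
                               min_match_len = min_match_len,
                               fallback_both = fallback_both))
  rownames(out) <- NULL
  out$frame_method <- out$resolved_by
  out
}

#' Cross-tabulate the two frame-prediction methods
#'
#' 4x4 agreement matrix (frames 1-3 and X) of the single-ORF method versus
#' the peptide-matching method, the shape used to report how the two
#' methods complement each other.
#'
#' @param frames data frame from [predict_frames()].
#' @return table with ORF method in rows, peptide method in columns.
#' @export
frame_agreement_matrix <- function(frames) {
  lv <- c("1", "2", "3", "X")
  table(orf = factor(frames$orf_method_frame, levels = lv),
        peptide = factor(frames$peptide_method_frame, levels = lv))
}
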