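#' @importFrom stats qlogis plogis pnorm pchisq sd optim dbinom rbinom rbeta rnorm runif setNames
#' @importFrom utils read.delim write.table head
NULL

EVENT_TYPES <- c("exon_skip", "alt_3prime", "alt_5prime",
                 "intron_retention", "mutex_exons", "mult_exon_skip")

#' Construct an alternative-splicing event
#'
#' An event is a local pair of mutually exclusive exon-intron structures
#' ("isoform 1" and "isoform 2") of one gene. Exons are held as data frames
#' with integer `start`/`end` columns (1-based, inclusive, Ensembl-style) and
#' stored in transcription order: ascending genomic coordinates on the `+`
#' strand, descending on `-`. The constructor validates and normalizes the
#' isoform labels (see [normalize_isoforms()]).
#'
#' @param event_id opaque unique identifier, e.g. `"exon_skip.83079"`.
#' @param gene gene symbol or identifier.
#' @param event_type one of `exon_skip`, `alt_3prime`, `alt_5prime`,
#'   `intron_retention`, `mutex_exons`, `mult_exon_skip`.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param iso1_exons,iso2_exons data frames with columns `start`, `end`
#'   (any row order; they are sorted internally).
#' @param novel_iso1,novel_iso2 logical flags: isoform absent from the
#'   reference annotation (reported by the upstream detection tool).
#' @param normalize apply [normalize_isoforms()] (default `TRUE`).
#' @return an object of class `"splice_event"`.
#' @export
splice_event <- function(event_id, gene, event_type, chrom, strand,
                         iso1_exons, iso2_exons,
                         novel_iso1 = FALSE, novel_iso2 = FALSE,
                         normalize = TRUE) {
  strand <- normalize_strand(strand)
  if (!event_type %in% EVENT_TYPES)
    stop("event '", event_id, "': unknown event_type '", event_type, "'")
  iso1_exons <- check_exons(iso1_exons, event_id)
  iso2_exons <- check_exons(iso2_exons, event_id)
  ev <- structure(list(
    event_id = event_id, gene = gene, event_type = event_type,
    chrom = chrom, strand = strand,
    iso1_exons = order_exons(iso1_exons, strand),
    iso2_exons = order_exons(iso2_exons, strand),
    novel_iso1 = isTRUE(novel_iso1), novel_iso2 = isTRUE(novel_iso2),
    swapped = FALSE), class = "splice_event")
  if (normalize) ev <- normalize_isoforms(ev) else ev
}

normalize_strand <- function(strand) {
  strand <- gsub("−", "-", strand)   # unicode minus
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-', got '", strand, "'")
  strand
}

check_exons <- function(ex, event_id) {
  ex <- as.data.frame(ex)[, c("start", "end")]
  ex$start <- as.integer(ex$start); ex$end <- as.integer(ex$end)
  if (nrow(ex) == 0L) stop("event '", event_id, "': isoform with no exons")
  if (any(is.na(ex$start) | is.na(ex$end)))
    stop("event '", event_id, "': malformed exon coordinates")
  if (any(ex$end < ex$start))
    stop("event '", event_id, "': exon end < start")
  ex2 <- ex[order(ex$start), , drop = FALSE]
  if (nrow(ex2) > 1L && any(ex2$start[-1L] <= ex2$end[-nrow(ex2)]))
    stop("event '", event_id, "': overlapping exons within one isoform")
  ex
}

order_exons <- function(ex, strand) {
  ex <- ex[order(ex$start, decreasing = (strand == "-")), , drop = FALSE]
  rownames(ex) <- NULL
  ex
}

exon_nt <- function(ex) sum(ex$end - ex$start + 1L)

#' Normalize isoform labels of an event
#'
#' Enforces the event-local naming convention so that PSI (always computed
#' for isoform 2) has a consistent meaning across events:
#' * `exon_skip`, `mult_exon_skip`: isoform 2 is the exon-richer form;
#' * `alt_3prime`, `alt_5prime`: equal exon counts, isoform 2 is the
#'   nucleotide-longer form;
#' * `intron_retention`: isoform 2 is the merged (intron-retaining) form,
#'   so PSI measures the retention level;
#' * `mutex_exons`: isoform 1 carries the mutually exclusive exon with the
#'   smaller genomic start (either exclusive exon can be the longer one, or
#'   they can be the same length, so length cannot decide).
#'
#' Idempotent. When labels are swapped the `swapped` field is set so that the
#' per-sample isoform read counts can be swapped consistently before any
#' statistics (see [read_counts()]).
#'
#' @param event a `"splice_event"`.
#' @return the event, labels possibly swapped.
#' @export
normalize_isoforms <- function(event) {
  stopifnot(inherits(event, "splice_event"))
  n1 <- nrow(event$iso1_exons); n2 <- nrow(event$iso2_exons)
  swap <- switch(event$event_type,
    exon_skip = , mult_exon_skip = n1 > n2,
    alt_3prime = , alt_5prime = ,
    intron_retention = exon_nt(event$iso1_exons) > exon_nt(event$iso2_exons),
    mutex_exons = {
      excl <- mutex_exclusive_exons(event)
      excl$iso1_start > excl$iso2_start
    })
  if (isTRUE(swap)) {
    tmp <- event$iso1_exons
    event$iso1_exons <- event$iso2_exons
    event$iso2_exons <- tmp
    tmp <- event$novel_iso1
    event$novel_iso1 <- event$novel_iso2
    event$novel_iso2 <- tmp
    event$swapped <- !event$swapped
  }
  event
}

# identify the mutually exclusive (non-shared) exon of each isoform
mutex_exclusive_exons <- function(event) {
  key <- function(ex) paste(ex$start, ex$end, sep = "-")
  k1 <- key(event$iso1_exons); k2 <- key(event$iso2_exons)
  e1 <- event$iso1_exons[!(k1 %in% k2), , drop = FALSE]
  e2 <- event$iso2_exons[!(k2 %in% k1), , drop = FALSE]
  if (nrow(e1) != 1L || nrow(e2) != 1L)
    stop("event '", event$event_id,
         "': mutex_exons event must have exactly one exclusive exon per isoform")
  list(iso1_start = e1$start[1L], iso2_start = e2$start[1L])
}

#' @export
print.splice_event <- function(x, ...) {
  cat(sprintf("<splice_event> %s  (%s, %s, %s%s)\n", x$event_id, x$gene,
              x$event_type, x$chrom, x$strand))
  fmt <- function(ex) paste(sprintf("%d-%d", ex$start, ex$end), collapse = ";")
  cat("  iso1:", fmt(x$iso1_exons), if (x$novel_iso1) "[novel]", "\n")
  cat("  iso2:", fmt(x$iso2_exons), if (x$novel_iso2) "[novel]", "\n")
  invisible(x)
}

#' Percent-spliced-in from isoform read counts
#'
#' PSI is computed for isoform 2: `reads_iso2 / (reads_iso1 + reads_iso2)`,
#' so values near 1 indicate higher expression of isoform 2. The estimate is
#' set to missing (`NA`) when the total count is below `min_coverage`
#' (default 10) to avoid unstable ratios at low read support.
#'
#' @param reads_iso1,reads_iso2 non-negative integer vectors.
#' @param min_coverage minimum total count for a valid PSI.
#' @return numeric vector in `[0, 1]` with `NA` where coverage is too low.
#' @export
compute_psi <- function(reads_iso1, reads_iso2, min_coverage = 10L) {
  if (any(reads_iso1 < 0 | reads_iso2 < 0, na.rm = TRUE))
    stop("read counts must be non-negative")
  if (min_coverage < 1) stop("min_coverage must be >= 1")
  tot <- reads_iso1 + reads_iso2
  psi <- ifelse(tot >= min_coverage, reads_iso2 / tot, NA_real_)
  psi
}

#' Deterministic coordinate-based event name
#'
#' Builds a name that is unique per distinct (type, chromosome, strand,
#' exon coordinates) so that the same structural event gets the same name
#' across runs and datasets:
#' `"{type}:{chrom}:{strand}:{iso1 blocks}|{iso2 blocks}"` with exon blocks
#' `start-end` in ascending genomic order joined by commas.
#'
#' @param event a normalized `"splice_event"`.
#' @return character scalar.
#' @export
make_genomic_name <- function(event) {
  stopifnot(inherits(event, "splice_event"))
  blocks <- function(ex) {
    ex <- ex[order(ex$start), , drop = FALSE]
    paste(sprintf("%d-%d", ex$start, ex$end), collapse = ",")
  }
  sprintf("%s:%s:%s:%s|%s", event$event_type, event$chrom, event$strand,
          blocks(event$iso1_exons), blocks(event$iso2_exons))
}

parse_exon_blocks <- function(s) {
  parts <- strsplit(trimws(s), ";", fixed = TRUE)[[1L]]
  m <- regmatches(parts, regexec("^\\s*(\\d+)\\s*-\\s*(\\d+)\\s*$", parts))
  if (any(lengths(m) != 3L)) return(NULL)
  data.frame(start = as.integer(vapply(m, `[`, "", 2L)),
             end   = as.integer(vapply(m, `[`, "", 3L)))
}

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, ": missing required column(s): ", paste(miss, collapse = ", "))
  invisible(df)
}

#' Read an event-level table
#'
#' Reads the documented TSV interchange format (one row per event) and
#' returns a list of normalized [splice_event()] objects. Required columns:
#' `event_id, gene, event_type, chrom, strand, iso1_exons, iso2_exons`;
#' optional `novel_iso1, novel_iso2` (default `FALSE`). Exon lists are
#' written as `"start-end"` blocks joined by `;`, 1-based inclusive.
#'
#' @param path TSV file path.
#' @return named list of `"splice_event"` objects (names = event IDs).
#' @export
read_event_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  require_columns(df, c("event_id", "gene", "event_type", "chrom", "strand",
                        "iso1_exons", "iso2_exons"), "events table")
  if (is.null(df$novel_iso1)) df$novel_iso1 <- FALSE
  if (is.null(df$novel_iso2)) df$novel_iso2 <- FALSE
  if (anyDuplicated(df$event_id))
    stop("events table: duplicated event_id(s): ",
         paste(unique(df$event_id[duplicated(df$event_id)]), collapse = ", "))
  events <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    e1 <- parse_exon_blocks(df$iso1_exons[i])
    e2 <- parse_exon_blocks(df$iso2_exons[i])
    if (is.null(e1) || is.null(e2))
      stop("events table row ", i, " (", df$event_id[i],
           "): malformed exon coordinate block")
    events[[i]] <- splice_event(
      df$event_id[i], df$gene[i], df$event_type[i], as.character(df$chrom[i]),
      as.character(df$strand[i]), e1, e2,
      novel_iso1 = as.logical(df$novel_iso1[i]),
      novel_iso2 = as.logical(df$novel_iso2[i]))
  }
  names(events) <- df$event_id
  events
}

#' Write an event-level table
#'
#' Inverse of [read_event_table()]; exon blocks are written in transcription
#' order as stored.
#'
#' @param events list of `"splice_event"`.
#' @param path output TSV path.
#' @export
write_event_table <- function(events, path) {
  fmt <- function(ex) paste(sprintf("%d-%d", ex$start, ex$end), collapse = ";")
  df <- data.frame(
    event_id  = vapply(events, `[[`, "", "event_id"),
    gene      = vapply(events, `[[`, "", "gene"),
    event_type = vapply(events, `[[`, "", "event_type"),
    chrom     = vapply(events, `[[`, "", "chrom"),
    strand    = vapply(events, `[[`, "", "strand"),
    iso1_exons = vapply(events, function(e) fmt(e$iso1_exons), ""),
    iso2_exons = vapply(events, function(e) fmt(e$iso2_exons), ""),
    novel_iso1 = vapply(events, `[[`, NA, "novel_iso1"),
    novel_iso2 = vapply(events, `[[`, NA, "novel_iso2"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-level counts table
#'
#' Required columns: `event_id, sample_id, group, reads_iso1, reads_iso2`.
#' When `events` is supplied, counts of events whose isoform labels were
#' swapped during normalization are swapped accordingly, and PSI is computed
#' (missing below `min_coverage`).
#'
#' @param path TSV file path.
#' @param events optional list from [read_event_table()]; used to apply
#'   isoform-label swaps and to reject counts for unknown events.
#' @param min_coverage see [compute_psi()].
#' @return data frame with columns `event_id, sample_id, group, reads_iso1,
#'   reads_iso2, psi`.
#' @export
read_counts <- function(path, events = NULL, min_coverage = 10L) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  require_columns(df, c("event_id", "sample_id", "group",
                        "reads_iso1", "reads_iso2"), "counts table")
  df$reads_iso1 <- as.integer(df$reads_iso1)
  df$reads_iso2 <- as.integer(df$reads_iso2)
  if (any(is.na(df$reads_iso1) | is.na(df$reads_iso2)))
    stop("counts table: non-integer read counts")
  if (any(df$reads_iso1 < 0 | df$reads_iso2 < 0))
    stop("counts table: negative read counts")
  if (!is.null(events)) {
    unknown <- setdiff(unique(df$event_id), names(events))
    if (length(unknown))
      stop("counts table: unknown event_id(s): ",
           paste(utils::head(unknown, 5L), collapse = ", "))
    swapped <- names(events)[vapply(events, `[[`, NA, "swapped")]
    idx <- df$event_id %in% swapped
    if (any(idx)) {
      tmp <- df$reads_iso1[idx]
      df$reads_iso1[idx] <- df$reads_iso2[idx]
      df$reads_iso2[idx] <- tmp
    }
  }
  df$psi <- compute_psi(df$reads_iso1, df$reads_iso2, min_coverage)
  df
}

#' Write the final per-event results table
#'
#' One row per event, combining event identity, per-group PSI statistics,
#' beta-binomial test results, the predicted reading frame and the
#' protein-level decomposition. Events with unresolved frame (`"X"`) have
#' empty protein columns. Round-trips losslessly through [read.delim()].
#'
#' @param events list of `"splice_event"` (all events to report).
#' @param stats data frame from [summarize_events()] (may omit events that
#'   were filtered out before testing).
#' @param frames data frame from [predict_frames()] (optional).
#' @param diffs data frame of protein differences from [protein_diff()]
#'   rows (optional).
#' @param path output TSV path.
#' @return the combined data frame, invisibly.
#' @export
write_results_table <- function(events, stats, frames = NULL, diffs = NULL,
                                path) {
  ids <- vapply(events, `[[`, "", "event_id")
  check_ids <- function(df, what) {
    if (is.null(df)) return()
    orphan <- setdiff(df$event_id, ids)
    if (length(orphan))
      stop("results table: ", what, " rows for unknown event(s): ",
           paste(orphan, collapse = ", "))
  }
  check_ids(stats, "statistics"); check_ids(frames, "frame")
  check_ids(diffs, "protein-diff")
  out <- data.frame(
    event_id = ids,
    genomic_name = vapply(events, make_genomic_name, ""),
    gene = vapply(events, `[[`, "", "gene"),
    event_type = vapply(events, `[[`, "", "event_type"),
    chrom = vapply(events, `[[`, "", "chrom"),
    strand = vapply(events, `[[`, "", "strand"),
    stringsAsFactors = FALSE)
  take <- function(df, cols) {
    if (is.null(df)) {
      for (cl in cols) out[[cl]] <<- NA
    } else {
      m <- match(out$event_id, df$event_id)
      for (cl in cols) out[[cl]] <<- df[[cl]][m]
    }
  }
  take(stats, c("n_valid_case", "n_valid_control", "mean_psi_case",
                "mean_psi_control", "delta_psi", "p_value", "p_adj"))
  take(frames, c("frame", "frame_method"))
  take(diffs, c("aa_iso1", "aa_iso2", "same_start_aa", "diff_aa_iso1",
                "diff_aa_iso2", "same_end_aa", "stop_in_iso1", "stop_in_iso2",
                "frameshift"))
  out$frame[is.na(out$frame)] <- "X"
  blank <- out$frame == "X"
  for (cl in c("aa_iso1", "aa_iso2", "same_start_aa", "diff_aa_iso1",
               "diff_aa_iso2", "same_end_aa"))
    out[[cl]] <- ifelse(blank, "", ifelse(is.na(out[[cl]]), "", out[[cl]]))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Read gene models from a simplified annotation TSV
#'
#' Columns: `gene, biotype, transcript_id, exons` (blocks `"start-end"`
#' joined by `;`, ascending genomic order), `cds_start_offset` (nucleotides
#' from transcription start to translation start along the spliced
#' transcript; the 5'UTR length). One row per transcript.
#'
#' @param path TSV file path.
#' @return named list (by gene) of gene models: `list(gene, biotype,
#'   transcripts = list(list(transcript_id, exons, cds_start_offset)))`.
#' @export
read_gene_models <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  require_columns(df, c("gene", "biotype", "transcript_id", "exons",
                        "cds_start_offset"), "annotation table")
  out <- list()
  for (i in seq_len(nrow(df))) {
    g <- df$gene[i]
    ex <- parse_exon_blocks(df$exons[i])
    if (is.null(ex)) stop("annotation row ", i, ": malformed exon block")
    off <- as.integer(df$cds_start_offset[i])
    if (is.na(off) || off < 0)
      stop("annotation row ", i, ": cds_start_offset must be >= 0")
    tr <- list(transcript_id = df$transcript_id[i],
               exons = ex[order(ex$start), , drop = FALSE],
               cds_start_offset = off)
    if (is.null(out[[g]]))
      out[[g]] <- list(gene = g, biotype = df$biotype[i], transcripts = list())
    out[[g]]$transcripts[[tr$transcript_id]] <- tr
  }
  out
}

#' Read known protein sequences per gene
#'
#' FASTA of known protein products. The gene is taken from a `gene=XXX`
#' field in the header when present, otherwise from the first
#' whitespace-separated token.
#'
#' @param path FASTA path.
#' @param gene_pattern regex with one capture group extracting the gene
#'   from the full header line.
#' @return named list: gene -> character vector of protein sequences.
#' @export
read_proteins <- function(path, gene_pattern = "gene=(\\S+)") {
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  m <- regmatches(headers, regexec(gene_pattern, headers))
  gene <- vapply(seq_along(m), function(i) {
    if (length(m[[i]]) == 2L) m[[i]][2L] else strsplit(headers[i], "\\s+")[[1L]][1L]
  }, "")
  split(as.character(aa), gene)
}

#' Read a protein-domain table
#'
#' InterPro-style TSV with columns `gene, accession, name, aa_start, aa_end,
#' source_db` (1-based amino-acid coordinates on the protein).
#'
#' @param path TSV file path.
#' @return data frame.
#' @export
read_domains <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  require_columns(df, c("gene", "accession", "name", "aa_start", "aa_end",
                        "source_db"), "domains table")
  if (any(df$aa_end < df$aa_start)) stop("domains table: aa_end < aa_start")
  df
}

#' Read gene models from a GTF file
#'
#' Builds the same structure as [read_gene_models()] from a standard GTF:
#' transcripts and their exons from `exon` features, gene biotype from the
#' `gene_biotype` (or `gene_type`) attribute, and the 5'UTR length
#' (`cds_start_offset`) computed from `CDS` features as the spliced
#' distance from the transcript start to the first coding base. Requires
#' the rtracklayer package.
#'
#' @param path GTF file path.
#' @param gene_field attribute holding the gene identifier used by the
#'   event table (default `gene_name`, falling back to `gene_id`).
#' @return named list of gene models (see [read_gene_models()]).
#' @export
read_gene_models_gtf <- function(path, gene_field = "gene_name") {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("read_gene_models_gtf requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gtf")
  md <- as.data.frame(gr)
  gene_of <- function(d) {
    g <- d[[gene_field]]
    if (is.null(g)) g <- d$gene_id
    g
  }
  bio_col <- intersect(c("gene_biotype", "gene_type"), names(md))
  ex <- md[md$type == "exon", , drop = FALSE]
  cds <- md[md$type == "CDS", , drop = FALSE]
  out <- list()
  for (tid in unique(ex$transcript_id)) {
    te <- ex[ex$transcript_id == tid, , drop = FALSE]
    g <- gene_of(te)[1L]
    strand <- as.character(te$strand[1L])
    exons <- data.frame(start = te$start, end = te$end)
    exons <- exons[order(exons$start), , drop = FALSE]
    tc <- cds[cds$transcript_id == tid, , drop = FALSE]
    off <- 0L
    if (nrow(tc)) {
      cds_first <- if (strand == "-") max(tc$end) else min(tc$start)
      for (i in seq_len(nrow(exons))) {
        j <- if (strand == "-") nrow(exons) - i + 1L else i
        s <- exons$start[j]; e <- exons$end[j]
        if (cds_first >= s && cds_first <= e) {
          off <- off + (if (strand == "-") e - cds_first else cds_first - s)
          break
        }
        off <- off + (e - s + 1L)
      }
    }
    biotype <- if (length(bio_col)) te[[bio_col[1L]]][1L] else NA_character_
    if (is.null(out[[g]]))
      out[[g]] <- list(gene = g, biotype = biotype, transcripts = list())
    out[[g]]$transcripts[[tid]] <-
      list(transcript_id = tid, exons = exons,
           cds_start_offset = as.integer(off))
  }
  out
}
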