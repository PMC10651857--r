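#' @importFrom ggplot2 .data
NULL

#' Match an event to the best-fitting transcript of its gene
#'
#' Ranks transcripts by how well the event's first and last exons (the two
#' exons shared between the isoforms) match annotated exon boundaries:
#' both exons matching exactly beats one, which beats mere coordinate
#' overlap, which beats none. Ties are broken by total transcript exon
#' length (longest first), then lexicographic transcript ID.
#'
#' @param event a normalized `"splice_event"`.
#' @param gene_model entry of [read_gene_models()] for the event's gene.
#' @return list: `event_id, transcript_id` (NA when quality is `none`),
#'   `match_quality` in `{both_exons_exact, one_exon_exact, overlap_only,
#'   none}`.
#' @export
match_transcript <- function(event, gene_model) {
  if (is.null(gene_model) || !length(gene_model$transcripts))
    stop("gene '", event$gene, "' has no transcripts")
  ex <- event$iso2_exons
  flank <- rbind(ex[1L, ], ex[nrow(ex), ])
  score <- function(tr) {
    te <- tr$exons
    exact <- vapply(seq_len(nrow(flank)), function(i)
      any(te$start == flank$start[i] & te$end == flank$end[i]), NA)
    overlap <- vapply(seq_len(nrow(flank)), function(i)
      any(te$start <= flank$end[i] & te$end >= flank$start[i]), NA)
    if (all(exact)) 3L else if (any(exact)) 2L
    else if (any(overlap)) 1L else 0L
  }
  trs <- gene_model$transcripts
  sc <- vapply(trs, score, 0L)
  len <- vapply(trs, function(tr) as.numeric(exon_nt(tr$exons)), 0)
  ids <- vapply(trs, `[[`, "", "transcript_id")
  o <- order(-sc, -len, ids)
  best <- o[1L]
  quality <- c("none", "overlap_only", "one_exon_exact",
               "both_exons_exact")[sc[best] + 1L]
  list(event_id = event$event_id,
       transcript_id = if (sc[best] > 0L) unname(ids[best])
                       else NA_character_,
       match_quality = quality)
}

#' Merge same-accession domain records
#'
#' InterPro collates predictions from several member databases, so one
#' domain is typically reported multiple times with slightly different
#' boundaries. Records sharing an accession (falling back to the name when
#' the accession is missing) are merged by amino-acid interval union.
#'
#' @param domains data frame from [read_domains()] (one gene).
#' @return data frame: `accession, name, aa_start, aa_end`.
#' @export
collapse_domains <- function(domains) {
  key <- ifelse(is.na(domains$accession) | domains$accession == "",
                domains$name, domains$accession)
  parts <- split(seq_len(nrow(domains)), key)
  rows <- lapply(parts, function(idx) {
    ir <- IRanges::reduce(IRanges::IRanges(domains$aa_start[idx],
                                           domains$aa_end[idx]))
    data.frame(accession = domains$accession[idx[1L]],
               name = domains$name[idx[1L]],
               aa_start = IRanges::start(ir), aa_end = IRanges::end(ir))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Map protein domains onto collapsed transcript coordinates
#'
#' Converts amino-acid domain coordinates to nucleotide positions on the
#' intron-free (collapsed) transcript: `nt_start = offset + 3 (aa_start -
#' 1) + 1`, `nt_end = offset + 3 aa_end`, where `offset` is the 5'UTR
#' length (distance from transcription start to translation start).
#' Domains extending past the transcript are clipped with a warning.
#' Same-accession records are merged first (see [collapse_domains()]).
#'
#' @param domains data frame of domain records for the gene.
#' @param cds_start_offset 5'UTR length in nucleotides.
#' @param transcript_exons data frame `start, end` of the matched
#'   transcript's exons.
#' @return data frame: `accession, name, nt_start, nt_end`.
#' @export
domain_to_collapsed_coords <- function(domains, cds_start_offset,
                                       transcript_exons) {
  merged <- collapse_domains(domains)
  tlen <- exon_nt(transcript_exons)
  nt_start <- cds_start_offset + 3L * (merged$aa_start - 1L) + 1L
  nt_end <- cds_start_offset + 3L * merged$aa_end
  if (any(nt_end > tlen)) {
    warning("domain(s) extend past the transcript; clipped")
    nt_end <- pmin(nt_end, tlen)
    nt_start <- pmin(nt_start, tlen)
  }
  data.frame(accession = merged$accession, name = merged$name,
             nt_start = nt_start, nt_end = nt_end)
}

# residues whose codons draw any base from transcript nt range [lo, hi]
# (1-based on the assembled isoform, frame offset already removed)
residues_touched <- function(lo, hi, frame) {
  f <- as.integer(frame)
  r1 <- ceiling((lo - (f - 1L)) / 3)
  r2 <- ceiling((hi - (f - 1L)) / 3)
  c(max(1L, r1), r2)
}

#' Coordinate table underlying the zoomed-in event figure
#'
#' One row per exon per isoform with genomic extent and a fill class:
#' `"shared"` (light blue; every residue the exon contributes lies in the
#' shared-start or shared-end peptide segments) or `"altered"` (light
#' green). Stop-codon genomic positions are attached as an attribute. This
#' table, not the rendered pixels, is the tested contract of the figure.
#'
#' @param event a normalized `"splice_event"`.
#' @param diff one-row data frame from [protein_diff()], or `NULL` for
#'   events with unresolved frame (all exons drawn neutral).
#' @param frame frame used for `diff` (ignored when `diff` is `NULL`).
#' @return data frame: `isoform, exon, start, end, fill`; attribute
#'   `stops` = data frame `isoform, genomic`.
#' @export
event_figure_data <- function(event, diff = NULL, frame = NULL) {
  rows <- list()
  stops <- data.frame(isoform = integer(0), genomic = integer(0))
  for (iso in 1:2) {
    ex <- if (iso == 1L) event$iso1_exons else event$iso2_exons
    aa <- if (!is.null(diff)) diff[[paste0("aa_iso", iso)]] else NULL
    npre <- if (!is.null(diff)) nchar(diff$same_start_aa) else 0L
    nsuf <- if (!is.null(diff)) nchar(diff$same_end_aa) else 0L
    cum <- 0L
    for (i in seq_len(nrow(ex))) {
      len <- ex$end[i] - ex$start[i] + 1L
      fill <- "neutral"
      if (!is.null(diff) && nchar(aa)) {
        rr <- residues_touched(cum + 1L, cum + len, frame)
        lo <- rr[1L]; hi <- min(rr[2L], nchar(aa))
        if (hi < lo) {
          fill <- "shared"   # exon contributes no complete residue
        } else {
          # shared only when every contributed residue lies in the common
          # prefix or the common suffix of the two peptides
          res <- seq(lo, hi)
          fill <- if (all(res <= npre | res > nchar(aa) - nsuf)) "shared"
                  else "altered"
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        isoform = iso, exon = i, start = ex$start[i], end = ex$end[i],
        fill = fill)
      cum <- cum + len
    }
    if (!is.null(diff)) {
      g <- diff[[paste0("stop_genomic_iso", iso)]]
      if (!is.na(g))
        stops <- rbind(stops, data.frame(isoform = iso, genomic = g))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "stops") <- stops
  out
}

save_figure <- function(plot, out_prefix, width = 8, height = 5) {
  png_path <- paste0(out_prefix, ".png")
  svg_path <- paste0(out_prefix, ".svg")
  ggplot2::ggsave(png_path, plot, width = width, height = height, dpi = 120,
                  device = grDevices::png, type = "cairo")
  ggplot2::ggsave(svg_path, plot, width = width, height = height,
                  device = grDevices::svg)
  invisible(c(png_path, svg_path))
}

fill_palette <- c(shared = "#ADD8E6", altered = "#90EE90",
                  neutral = "grey80")

#' Render the zoomed-in event figure
#'
#' Two isoform tracks with exons colored light blue (same protein product)
#' or light green (altered peptide), red lines at the first stop codon per
#' isoform, a title carrying gene, event ID, chromosome, strand and
#' adjusted p-value, and a companion jitter panel of per-sample PSI by
#' group.
#'
#' @param event a normalized `"splice_event"`.
#' @param stats_row one-row data frame from [summarize_events()] (or NULL).
#' @param diff,frame see [event_figure_data()].
#' @param counts data frame from [read_counts()] (for the PSI panel; NULL
#'   skips the panel).
#' @param out_prefix output path without extension; `.png` and `.svg` are
#'   written.
#' @return paths of the written files, invisibly.
#' @export
render_event_figure <- function(event, stats_row = NULL, diff = NULL,
                                frame = NULL, counts = NULL, out_prefix) {
  fd <- event_figure_data(event, diff, frame)
  stops <- attr(fd, "stops")
  fd$y <- ifelse(fd$isoform == 1L, 2, 1)
  p <- ggplot2::ggplot(fd) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start - 0.5,
                                    xmax = .data$end + 0.5,
                                    ymin = .data$y - 0.3,
                                    ymax = .data$y + 0.3,
                                    fill = .data$fill), color = "grey30") +
    ggplot2::geom_segment(
      data = data.frame(y = c(1, 2),
                        x1 = tapply(fd$start, fd$isoform, min)[c("2", "1")],
                        x2 = tapply(fd$end, fd$isoform, max)[c("2", "1")]),
      ggplot2::aes(x = .data$x1, xend = .data$x2, y = .data$y,
                   yend = .data$y), linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = fill_palette, guide = "none") +
    ggplot2::scale_y_continuous(breaks = c(1, 2),
                                labels = c("isoform 2", "isoform 1"),
                                limits = c(0.5, 2.5)) +
    ggplot2::labs(
      x = paste0(event$chrom, " (", event$strand, ")"), y = NULL,
      title = sprintf("%s  %s  %s%s%s", event$gene, event$event_id,
                      event$chrom, event$strand,
                      if (!is.null(stats_row) && !is.na(stats_row$p_adj))
                        sprintf("  adj p = %.2g", stats_row$p_adj) else "")) +
    ggplot2::theme_minimal()
  if (nrow(stops)) {
    stops$y <- ifelse(stops$isoform == 1L, 2, 1)
    p <- p + ggplot2::geom_segment(
      data = stops,
      ggplot2::aes(x = .data$genomic, xend = .data$genomic,
                   y = .data$y - 0.4, yend = .data$y + 0.4),
      color = "red", linewidth = 1)
  }
  if (!is.null(counts)) {
    sub <- counts[counts$event_id == event$event_id & !is.na(counts$psi), ]
    pj <- ggplot2::ggplot(sub, ggplot2::aes(x = .data$group,
                                            y = .data$psi)) +
      ggplot2::geom_jitter(width = 0.15, height = 0, size = 1.2,
                           alpha = 0.7) +
      ggplot2::ylim(0, 1) +
      ggplot2::labs(x = NULL, y = "PSI (isoform 2)") +
      ggplot2::theme_minimal()
    p <- patchwork::wrap_plots(p, pj, widths = c(3, 1))
  }
  save_figure(p, out_prefix)
}

#' Coordinate table for the zoomed-out transcript-context figure
#'
#' The matched transcript's exons plus the event's two isoforms on shared
#' genomic coordinates.
#'
#' @param event a normalized `"splice_event"`.
#' @param transcript transcript entry (from the gene model) matched by
#'   [match_transcript()].
#' @return data frame: `track` (`transcript`/`iso1`/`iso2`), `start, end`.
#' @export
transcript_figure_data <- function(event, transcript) {
  te <- transcript$exons
  rbind(data.frame(track = "transcript", start = te$start, end = te$end),
        data.frame(track = "iso1", start = event$iso1_exons$start,
                   end = event$iso1_exons$end),
        data.frame(track = "iso2", start = event$iso2_exons$start,
                   end = event$iso2_exons$end))
}

#' Render the zoomed-out transcript-context figure
#'
#' @param event a normalized `"splice_event"`.
#' @param gene_model gene-model entry for the event's gene.
#' @param out_prefix output path without extension.
#' @return paths of the written files, invisibly; `NULL` (with a message)
#'   when no transcript matches.
#' @export
render_transcript_figure <- function(event, gene_model, out_prefix) {
  m <- match_transcript(event, gene_model)
  if (m$match_quality == "none") {
    message("event ", event$event_id, ": no matching transcript; ",
            "zoomed-out figure skipped")
    return(invisible(NULL))
  }
  tr <- gene_model$transcripts[[m$transcript_id]]
  fd <- transcript_figure_data(event, tr)
  fd$y <- match(fd$track, c("iso2", "iso1", "transcript"))
  p <- ggplot2::ggplot(fd) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start - 0.5,
                                    xmax = .data$end + 0.5,
                                    ymin = .data$y - 0.3,
                                    ymax = .data$y + 0.3),
                       fill = "steelblue", color = "grey30") +
    ggplot2::scale_y_continuous(breaks = 1:3,
                                labels = c("isoform 2", "isoform 1",
                                           m$transcript_id),
                                limits = c(0.5, 3.5)) +
    ggplot2::labs(x = paste0(event$chrom, " (", event$strand, ")"),
                  y = NULL,
                  title = sprintf("%s  %s  (%s)", event$gene,
                                  event$event_id, m$match_quality)) +
    ggplot2::theme_minimal()
  save_figure(p, out_prefix)
}

#' Coordinate table for the domain-alignment figure
#'
#' Collapses the matched transcript's exons (introns removed, cumulative
#' coordinates) and places merged protein domains on the same axis using
#' the 5'UTR offset. Event exons are located within the collapsed
#' coordinates by exact boundary match.
#'
#' @param event a normalized `"splice_event"`.
#' @param transcript transcript entry with `exons` and `cds_start_offset`.
#' @param domains data frame of domain records for the gene (may be empty).
#' @return list: `exons` (`exon, nt_start, nt_end, is_event_exon`),
#'   `domains` (`accession, name, nt_start, nt_end`).
#' @export
domain_figure_data <- function(event, transcript, domains) {
  te <- transcript$exons        # ascending genomic order
  if (event$strand == "-") te <- te[rev(seq_len(nrow(te))), , drop = FALSE]
  len <- te$end - te$start + 1L
  nt_end <- cumsum(len)
  nt_start <- nt_end - len + 1L
  ev <- rbind(event$iso1_exons, event$iso2_exons)
  is_event <- vapply(seq_len(nrow(te)), function(i)
    any(ev$start == te$start[i] & ev$end == te$end[i]), NA)
  exons <- data.frame(exon = seq_len(nrow(te)), nt_start = nt_start,
                      nt_end = nt_end, is_event_exon = is_event)
  doms <- if (nrow(domains))
    domain_to_collapsed_coords(domains, transcript$cds_start_offset, te)
  else data.frame(accession = character(0), name = character(0),
                  nt_start = integer(0), nt_end = integer(0))
  list(exons = exons, domains = doms)
}

#' Render the exon-to-protein-domain alignment figure
#'
#' Exons drawn end-to-end (introns removed) with domain tracks aligned by
#' collapsed transcript coordinates; event exons highlighted. With no
#' domain records the exon track is drawn alone (logged).
#'
#' @param event a normalized `"splice_event"`.
#' @param gene_model gene-model entry for the event's gene.
#' @param domains data frame from [read_domains()] (all genes; filtered
#'   internally).
#' @param out_prefix output path without extension.
#' @return paths of the written files, invisibly; `NULL` when no
#'   transcript matches.
#' @export
render_domain_figure <- function(event, gene_model, domains, out_prefix) {
  m <- match_transcript(event, gene_model)
  if (m$match_quality == "none") {
    message("event ", event$event_id, ": no matching transcript; ",
            "domain figure skipped")
    return(invisible(NULL))
  }
  tr <- gene_model$transcripts[[m$transcript_id]]
  gd <- domains[domains$gene == event$gene, , drop = FALSE]
  if (!nrow(gd))
    message("event ", event$event_id, ": no domain records; exon track only")
  fd <- domain_figure_data(event, tr, gd)
  fd$exons$fill <- ifelse(fd$exons$is_event_exon, "event", "other")
  p <- ggplot2::ggplot() +
    ggplot2::geom_rect(data = fd$exons,
                       ggplot2::aes(xmin = .data$nt_start - 0.5,
                                    xmax = .data$nt_end + 0.5,
                                    ymin = 0.7, ymax = 1.3,
                                    fill = .data$fill), color = "grey30") +
    ggplot2::scale_fill_manual(values = c(event = "orange",
                                          other = "steelblue"),
                               guide = "none") +
    ggplot2::labs(x = "collapsed transcript (nt)", y = NULL,
                  title = sprintf("%s  %s  domains", event$gene,
                                  event$event_id)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  if (nrow(fd$domains)) {
    fd$domains$y <- 1.6 + 0.35 * (as.integer(
      factor(fd$domains$accession)) - 1L)
    p <- p + ggplot2::geom_rect(
      data = fd$domains,
      ggplot2::aes(xmin = .data$nt_start, xmax = .data$nt_end,
                   ymin = .data$y - 0.12, ymax = .data$y + 0.12),
      fill = "darkred", alpha = 0.7) +
      ggplot2::geom_text(
        data = fd$domains,
        ggplot2::aes(x = (.data$nt_start + .data$nt_end) / 2, y = .data$y,
                     label = .data$name), vjust = -1, size = 2.5)
  }
  save_figure(p, out_prefix)
}
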