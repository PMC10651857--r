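#' Run the full splicing-consequence pipeline
#'
#' One call executing the whole analysis: read the six inputs, apply the
#' pre-test filters (protein-coding, missingness, PSI variability), fit
#' the two-group beta-binomial model per surviving event, adjust p-values
#' (Benjamini-Hochberg), predict reading frames, translate isoforms and
#' decompose protein differences, assign genomic event names, write the
#' output tables and (optionally) per-event figures. Frame prediction and
#' translation run by default only on statistically significant events;
#' `translate_all = TRUE` runs them on every event that passed the
#' filters.
#'
#' Outputs written to `out_dir`: `results.tsv` (one row per filtered
#' event; full schema), `stats.tsv`, `frames.tsv`, `funnel.tsv`, and a
#' `figures/` directory when `figures_top > 0` (the top events by
#' absolute delta PSI among significant events, zoomed-in + zoomed-out +
#' domain view each). Any fatal stage error removes partial outputs and
#' aborts naming the stage.
#'
#' @param events_path,counts_path,genome_path,annotation_path,
#'   proteins_path,domains_path input file paths (see the reader
#'   functions for formats).
#' @param out_dir output directory (created).
#' @param case,control group labels in the counts table.
#' @param alpha significance cutoff on BH-adjusted p-values.
#' @param config a [filter_config()].
#' @param min_match_len peptide-match query minimum (residues).
#' @param translate_all predict frames/translate all filtered events.
#' @param figures_top number of top-|delta PSI| significant events to
#'   plot (0 = no figures).
#' @param test `"wald"` or `"lrt"` group-effect test.
#' @return invisible list: `results`, `stats`, `frames`, `diffs`,
#'   `funnel`, `agreement` (frame-method matrix), `n_significant`,
#'   `frac_frames_resolved`.
#' @export
run_pipeline <- function(events_path, counts_path, genome_path,
                         annotation_path, proteins_path, domains_path,
                         out_dir, case = "case", control = "control",
                         alpha = 0.01, config = filter_config(),
                         min_match_len = 7L, translate_all = FALSE,
                         figures_top = 0L, test = "lrt") {
  stopifnot(alpha > 0, alpha < 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  stage <- "input"
  on.exit({
    if (!is.null(attr(stage, "failed"))) unlink(written, recursive = TRUE)
  }, add = TRUE)
  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e) {
      attr(stage, "failed") <<- TRUE
      unlink(written, recursive = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  inputs <- run_stage("read_inputs", {
    events <- read_event_table(events_path)
    counts <- read_counts(counts_path, events = events,
                          min_coverage = config$min_coverage)
    if (nrow(counts) == 0L) stop("counts table is empty")
    gm <- read_gene_models(annotation_path)
    genome <- load_genome(genome_path)
    proteins <- read_proteins(proteins_path)
    domains <- read_domains(domains_path)
    bad <- setdiff(unique(counts$group), c(case, control))
    if (length(bad))
      stop("unknown group label(s): ", paste(bad, collapse = ", "))
    list(events = events, counts = counts, gm = gm, genome = genome,
         proteins = proteins, domains = domains)
  })
  events <- inputs$events; counts <- inputs$counts

  filt <- run_stage("filtering",
    apply_filters(events, counts, inputs$gm, config,
                  groups = c(case, control)))
  message(paste(capture_funnel(filt$funnel), collapse = "\n"))
  kept <- filt$kept
  kept_events <- events[kept]
  kcounts <- counts[counts$event_id %in% kept, , drop = FALSE]

  stats <- run_stage("statistics", {
    fits <- fit_events(kcounts, event_ids = kept, case = case, test = test,
                       min_coverage = config$min_coverage)
    summarize_events(kcounts, fits, case = case, control = control,
                     alpha = alpha)
  })
  sig_ids <- stats$event_id[stats$significant]
  message(length(sig_ids), " significant events at adjusted alpha ", alpha)

  frame_ids <- if (translate_all) kept else sig_ids
  frames <- run_stage("frame_prediction", {
    if (length(frame_ids))
      predict_frames(events[frame_ids], inputs$genome, inputs$proteins,
                     min_match_len = min_match_len)
    else
      data.frame(event_id = character(0), frame = character(0),
                 orf_method_frame = character(0),
                 peptide_method_frame = character(0),
                 fallback_frame = character(0), resolved_by = character(0),
                 match_f1 = integer(0), match_f2 = integer(0),
                 match_f3 = integer(0), frame_method = character(0))
  })
  agreement <- frame_agreement_matrix(frames)
  resolved <- frames$event_id[frames$frame != "X"]
  frac_resolved <- if (nrow(frames)) length(resolved) / nrow(frames)
                   else NA_real_
  if (nrow(frames))
    message(sprintf("frames resolved for %d/%d events (%.1f%%)",
                    length(resolved), nrow(frames), 100 * frac_resolved))

  diffs <- run_stage("protein_diff", {
    if (length(resolved)) {
      rows <- lapply(resolved, function(id)
        protein_diff(events[[id]],
                     frames$frame[frames$event_id == id],
                     inputs$genome))
      do.call(rbind, rows)
    } else NULL
  })

  res <- run_stage("write_tables", {
    p1 <- file.path(out_dir, "results.tsv")
    p2 <- file.path(out_dir, "stats.tsv")
    p3 <- file.path(out_dir, "frames.tsv")
    p4 <- file.path(out_dir, "funnel.tsv")
    written <<- c(written, p1, p2, p3, p4)
    r <- write_results_table(kept_events, stats, frames, diffs, p1)
    write.table(stats, p2, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(frames, p3, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(filt$funnel, p4, sep = "\t", quote = FALSE,
                row.names = FALSE)
    r
  })

  if (figures_top > 0L && length(sig_ids)) {
    run_stage("figures", {
      figdir <- file.path(out_dir, "figures")
      dir.create(figdir, showWarnings = FALSE)
      written <<- c(written, figdir)
      sig <- stats[stats$significant, ]
      sig <- sig[order(-abs(sig$delta_psi)), ]
      top <- utils::head(sig$event_id, figures_top)
      for (id in top) {
        ev <- events[[id]]
        fr <- frames$frame[frames$event_id == id]
        dd <- if (length(fr) && fr != "X")
          diffs[diffs$event_id == id, , drop = FALSE] else NULL
        render_event_figure(ev, stats[stats$event_id == id, , drop = FALSE],
                            dd, fr, kcounts,
                            file.path(figdir, paste0(id, "_event")))
        gmod <- inputs$gm[[ev$gene]]
        if (!is.null(gmod)) {
          render_transcript_figure(ev, gmod,
            file.path(figdir, paste0(id, "_transcript")))
          render_domain_figure(ev, gmod, inputs$domains,
            file.path(figdir, paste0(id, "_domains")))
        }
      }
    })
  }
  invisible(list(results = res, stats = stats, frames = frames,
                 diffs = diffs, funnel = filt$funnel,
                 agreement = agreement, n_significant = length(sig_ids),
                 frac_frames_resolved = frac_resolved))
}

capture_funnel <- function(funnel) {
  c("filter funnel:",
    sprintf("  %-16s %6d -> %6d", funnel$stage, funnel$events_in,
            funnel$events_out))
}
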