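#' Pre-test filter configuration
#'
#' Thresholds for the three filters applied before differential testing.
#' Defaults follow common practice for bulk RNA-seq cohorts of 10-15
#' samples per group: at least 10 samples with valid PSI in every group,
#' overall PSI standard deviation of at least 0.05, and restriction to
#' protein-coding genes.
#'
#' @param min_valid_per_group minimum samples with non-missing PSI required
#'   in every group.
#' @param min_psi_sd minimum sample standard deviation of PSI pooled over
#'   all valid samples of the event.
#' @param min_coverage minimum total isoform reads for a valid PSI.
#' @param require_protein_coding drop events in non-protein-coding genes.
#' @return list of class `"filter_config"`.
#' @export
filter_config <- function(min_valid_per_group = 10L, min_psi_sd = 0.05,
                          min_coverage = 10L, require_protein_coding = TRUE) {
  stopifnot(min_valid_per_group >= 0, min_psi_sd >= 0, min_coverage >= 1)
  structure(list(min_valid_per_group = as.integer(min_valid_per_group),
                 min_psi_sd = min_psi_sd,
                 min_coverage = as.integer(min_coverage),
                 require_protein_coding = isTRUE(require_protein_coding)),
            class = "filter_config")
}

#' Missing-PSI filter
#'
#' Keeps an event only if the number of samples with valid (non-missing)
#' PSI reaches `min_valid_per_group` in every group. Events with too many
#' missing values carry little information and inflate the multiple-testing
#' burden.
#'
#' @param counts data frame from [read_counts()] (must have a `psi` column).
#' @param config a [filter_config()].
#' @param groups character vector of expected group labels; counts rows with
#'   any other label are a fatal error. Default: labels present in `counts`.
#' @return data frame: `event_id`, one `n_valid_<group>` column per group,
#'   `keep`.
#' @export
filter_missingness <- function(counts, config = filter_config(),
                               groups = NULL) {
  if (is.null(groups)) groups <- sort(unique(counts$group))
  bad <- setdiff(unique(counts$group), groups)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  ids <- sort(unique(counts$event_id))
  tab <- vapply(groups, function(g) {
    sub <- counts[counts$group == g, ]
    n <- tapply(!is.na(sub$psi), sub$event_id, sum)
    out <- setNames(integer(length(ids)), ids)
    out[names(n)] <- as.integer(n)
    out
  }, integer(length(ids)))
  tab <- matrix(tab, nrow = length(ids),
                dimnames = list(ids, paste0("n_valid_", groups)))
  res <- data.frame(event_id = ids, tab, row.names = NULL,
                    check.names = FALSE)
  res$keep <- apply(tab >= config$min_valid_per_group, 1L, all)
  res
}

#' PSI-variability filter
#'
#' Keeps an event only if the sample standard deviation (n-1 denominator)
#' of PSI, pooled over all valid samples of both groups, is at least
#' `min_psi_sd`. Pooling is deliberately agnostic: variability may arise
#' within or across groups. Events with fewer than two valid values have an
#' undefined SD and are dropped.
#'
#' @inheritParams filter_missingness
#' @return data frame: `event_id, psi_sd, keep`.
#' @export
filter_variability <- function(counts, config = filter_config()) {
  ids <- sort(unique(counts$event_id))
  sds <- vapply(ids, function(id) {
    v <- counts$psi[counts$event_id == id]
    v <- v[!is.na(v)]
    if (length(v) < 2L) NA_real_ else sd(v)
  }, 0)
  data.frame(event_id = ids, psi_sd = sds,
             keep = !is.na(sds) & sds >= config$min_psi_sd,
             row.names = NULL)
}

#' Protein-coding filter
#'
#' Keeps events whose gene is annotated as `protein_coding`. Non-coding RNA
#' undergoes extensive splicing without selective pressure to maintain an
#' open reading frame, so downstream translation is meaningless for it.
#' Genes absent from the annotation are treated as non-coding and dropped
#' with a warning (partial annotations stay usable).
#'
#' @param events list of `"splice_event"`.
#' @param gene_models list from [read_gene_models()].
#' @param config a [filter_config()]; with `require_protein_coding = FALSE`
#'   everything is kept.
#' @return data frame: `event_id, gene, biotype, keep`.
#' @export
filter_coding <- function(events, gene_models, config = filter_config()) {
  ids <- vapply(events, `[[`, "", "event_id")
  genes <- vapply(events, `[[`, "", "gene")
  biotype <- vapply(genes, function(g) {
    gm <- gene_models[[g]]
    if (is.null(gm)) NA_character_ else gm$biotype
  }, "")
  if (any(is.na(biotype)))
    warning("gene(s) absent from annotation treated as non-coding: ",
            paste(unique(genes[is.na(biotype)]), collapse = ", "))
  keep <- if (config$require_protein_coding)
    !is.na(biotype) & biotype == "protein_coding"
  else rep(TRUE, length(ids))
  data.frame(event_id = ids, gene = genes, biotype = biotype, keep = keep,
             row.names = NULL)
}

#' Apply all pre-test filters and report the funnel
#'
#' Applies the coding, missingness and variability filters (set membership
#' is order-independent; the funnel is reported in this order) and returns
#' the surviving event IDs together with a stage-by-stage count table.
#'
#' @param events list of `"splice_event"`.
#' @param counts data frame from [read_counts()].
#' @param gene_models list from [read_gene_models()].
#' @param config a [filter_config()].
#' @param groups expected group labels (see [filter_missingness()]).
#' @return list with `kept` (character vector of surviving event IDs),
#'   `funnel` (data frame `stage, events_in, events_out`), and the three
#'   per-filter tables.
#' @export
apply_filters <- function(events, counts, gene_models,
                          config = filter_config(), groups = NULL) {
  ids0 <- vapply(events, `[[`, "", "event_id")
  fc <- filter_coding(events, gene_models, config)
  keep1 <- fc$event_id[fc$keep]
  fm <- filter_missingness(counts[counts$event_id %in% keep1, , drop = FALSE],
                           config, groups)
  keep2 <- intersect(keep1, fm$event_id[fm$keep])
  fv <- filter_variability(counts[counts$event_id %in% keep2, , drop = FALSE],
                           config)
  keep3 <- intersect(keep2, fv$event_id[fv$keep])
  funnel <- data.frame(
    stage = c("input", "protein_coding", "missingness", "variability"),
    events_in = c(length(ids0), length(ids0), length(keep1), length(keep2)),
    events_out = c(length(ids0), length(keep1), length(keep2), length(keep3)))
  list(kept = keep3, funnel = funnel,
       coding = fc, missingness = fm, variability = fv)
}
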