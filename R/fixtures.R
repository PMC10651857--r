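#' Specification for the synthetic test fixture
#'
#' Describes a fully synthetic dataset — toy genome, gene models, known
#' proteins, protein domains, planted splicing events of all six types on
#' both strands, and per-sample isoform counts drawn from the two-group
#' beta-binomial model — whose ground truth (reading frames, peptides,
#' frameshifts, stop positions, group PSIs) is recorded alongside, so
#' every pipeline stage can be checked end-to-end without downloads.
#'
#' Defaults emulate a bulk RNA-seq case/control cohort: 14 case and 13
#' control samples, per-sample event coverage of 100-300 reads, planted
#' differential events at PSI 0.7 (case) versus 0.3 (control), null events
#' at PSI 0.5 in both groups, overdispersion 0.02, and half of the events
#' null. Genes are built from designed codon blocks so that each planted
#' event's true reading frame is discoverable (the other two frames are
#' poisoned with stop codons and match no known protein); a third of genes
#' are on the minus strand.
#'
#' @param seed integer seed; the fixture is a pure function of the spec.
#' @param events_per_type planted events per event type (6 types).
#' @param n_case,n_control samples per group.
#' @param coverage_range integer range of per-sample total reads.
#' @param psi_case,psi_control group PSIs of differential events.
#' @param psi_null shared PSI of null events.
#' @param phi beta-binomial overdispersion (both groups).
#' @param fraction_null fraction of planted events that are null.
#' @param n_noncoding extra non-protein-coding genes, each with one null
#'   event (exercises the coding filter).
#' @return list of class `"fixture_spec"`.
#' @export
fixture_spec <- function(seed = 1L, events_per_type = 12L, n_case = 14L,
                         n_control = 13L, coverage_range = c(100L, 300L),
                         psi_case = 0.7, psi_control = 0.3, psi_null = 0.5,
                         phi = 0.02, fraction_null = 0.5,
                         n_noncoding = 2L) {
  structure(as.list(environment()), class = "fixture_spec")
}

.codons_nostop <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

rcodons <- function(n) paste(sample(.codons_nostop, n, replace = TRUE),
                             collapse = "")

# sample() treats a length-1 x as 1:x; guard degenerate ranges
sample_range <- function(lo, hi, k) {
  if (lo == hi) rep.int(as.integer(lo), k)
  else sample(lo:hi, k, replace = TRUE)
}
rdna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")

# build one gene carrying one planted event; transcript-orientation blocks
# are laid out and sliced, then mapped to genomic coordinates by the caller
build_gene_blocks <- function(type, frame_true, fs_plan) {
  pick_mod <- function(base, mod3) base + ((mod3 - base) %% 3L)
  for (attempt in 1:200) {
    u <- sample(3:12, 1L)
    c0 <- pick_mod(30L + sample(0:8, 1L), c(0L, 2L, 1L)[frame_true])
    L2 <- sample(45:60, 1L)
    mids <- switch(type,
      exon_skip = list(L3 = pick_mod(sample(24:40, 1L),
                                     if (fs_plan) sample(1:2, 1L) else 0L)),
      mult_exon_skip = {
        L3 <- sample(24:40, 1L)
        L4 <- pick_mod(sample(24:40, 1L),
                       (if (fs_plan) sample(1:2, 1L) else 0L) - L3)
        list(L3 = L3, L4 = L4)
      },
      mutex_exons = {
        L3 <- sample(24:40, 1L)
        L4 <- pick_mod(sample(24:40, 1L),
                       L3 + (if (fs_plan) sample(1:2, 1L) else 0L))
        list(L3 = L3, L4 = L4)
      },
      intron_retention = list(LI = pick_mod(sample(60:84, 1L),
                              if (fs_plan) sample(1:2, 1L) else 0L)),
      alt_5prime = , alt_3prime =
        list(d = pick_mod(sample(9:21, 1L),
                          if (fs_plan) sample(1:2, 1L) else 0L)))
    L_last <- sample(30:45, 1L)
    # canonical coding exon lengths after the first exon's c0 nucleotides
    coding_lens <- switch(type,
      exon_skip = c(L2, mids$L3, L_last),
      mult_exon_skip = c(L2, mids$L3, mids$L4, L_last),
      mutex_exons = c(L2, mids$L3, L_last),
      intron_retention = , alt_5prime = , alt_3prime = c(L2, L_last))
    tail_coding <- 36L + (3L - (c0 + sum(coding_lens)) %% 3L) %% 3L
    total_cds <- c0 + sum(coding_lens) + tail_coding
    cds <- paste0("ATG", rcodons(total_cds / 3L - 1L))
    protein <- translate_dna(cds, 1L)
    utr5 <- rdna(u)
    utr3 <- rdna(sample(6:10, 1L))
    mrna <- paste0(utr5, cds, "TAA", utr3)
    # slice canonical exons out of the mRNA
    cuts <- cumsum(c(u + c0, coding_lens))
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, nchar(mrna))
    exon_seqs <- substring(mrna, starts, ends)
    nex <- length(exon_seqs)
    # interleave introns; for mutex add the alternative exon after the
    # canonical middle exon, flanked by its own introns
    blocks <- list()
    add <- function(name, seq, is_exon)
      blocks[[length(blocks) + 1L]] <<- list(name = name, seq = seq,
                                             exon = is_exon)
    for (i in seq_len(nex)) {
      add(paste0("X", i), exon_seqs[i], TRUE)
      if (i < nex) {
        ilen <- if (type == "intron_retention" && i == 2L) mids$LI
                else sample(60:90, 1L)
        add(paste0("I", i), rdna(ilen), FALSE)
        if (type == "mutex_exons" && i == 3L) {
          add("XM", rdna(mids$L4), TRUE)
          add("IM", rdna(sample(60:90, 1L)), FALSE)
        }
      }
    }
    x2 <- exon_seqs[2L]
    # the planted event's first shared 5' exon is X2: require the true
    # frame open and both other frames poisoned with stops, and no
    # off-frame peptide matching the canonical protein
    peps <- vapply(1:3, function(f) translate_dna(x2, f), "")
    stops <- grepl("*", peps, fixed = TRUE)
    if (stops[frame_true] || sum(!stops) != 1L) next
    off_ok <- TRUE
    for (f in setdiff(1:3, frame_true)) {
      q <- sub("\\*.*$", "", peps[f])
      if (nchar(q) >= 7L && grepl(q, protein, fixed = TRUE))
        off_ok <- FALSE
    }
    if (!off_ok) next
    return(list(blocks = blocks, protein = protein, u = u, c0 = c0,
                type = type, frame_true = frame_true, fs_plan = fs_plan,
                mids = mids, exon_seqs = exon_seqs))
  }
  stop("could not construct a gene satisfying the frame-uniqueness design")
}

# genomic layout of a gene's blocks: gene occupies [G, G + L - 1]; a block
# covering transcript-orientation positions [a, b] maps to genomic
# [G + a - 1, G + b - 1] on '+' and [G + L - b, G + L - a] on '-'
layout_blocks <- function(blocks, G, strand) {
  lens <- vapply(blocks, function(b) nchar(b$seq), 0L)
  b_end <- cumsum(lens)
  b_start <- b_end - lens + 1L
  L <- sum(lens)
  coords <- lapply(seq_along(blocks), function(i) {
    if (strand == "+") c(G + b_start[i] - 1L, G + b_end[i] - 1L)
    else c(G + L - b_end[i], G + L - b_start[i])
  })
  names(coords) <- vapply(blocks, `[[`, "", "name")
  list(coords = coords, L = L,
       gseq = if (strand == "+") paste(vapply(blocks, `[[`, "", "seq"),
                                       collapse = "")
              else revcomp(paste(vapply(blocks, `[[`, "", "seq"),
                                 collapse = "")))
}

# per-base genomic positions of an isoform, transcript order
posvec <- function(exons, strand) {
  unlist(lapply(seq_len(nrow(exons)), function(i)
    if (strand == "+") exons$start[i]:exons$end[i]
    else exons$end[i]:exons$start[i]))
}

#' Generate the synthetic fixture
#'
#' Writes `genome.fa`, `annotation.tsv`, `events.tsv`, `counts.tsv`,
#' `proteins.fa`, `domains.tsv` and `truth.tsv` into `dir`. Every second
#' event is written with its isoform columns (and count columns) in
#' unnormalized order to exercise label normalization and the consistent
#' count swap on read-back. Byte-identical output for identical specs.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return list: `dir`, file `paths`, `truth` data frame, the normalized
#'   `events`, and `spec`; invisibly.
#' @export
generate_fixture <- function(spec = fixture_spec(), dir = tempfile("fx")) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  types <- rep(EVENT_TYPES, each = spec$events_per_type)
  nev <- length(types)
  strands <- rep_len(c("+", "-", "+"), nev)
  frames <- rep_len(1:3, nev)
  fs_plan <- rep_len(c(FALSE, TRUE), nev)
  # alternate differential/null within each type, then trim to the exact
  # requested fraction
  n_diff <- round((1 - spec$fraction_null) * nev)
  differential <- rep_len(c(TRUE, FALSE), nev)
  excess <- sum(differential) - n_diff
  if (excess > 0L)
    differential[which(differential)[seq_len(excess)]] <- FALSE
  if (excess < 0L)
    differential[which(!differential)[seq_len(-excess)]] <- TRUE

  chroms <- paste0("chr", 1:3)
  cursor <- setNames(rep(1L, 3L), chroms)
  chrom_seq <- setNames(vector("list", 3L), chroms)
  events <- list(); truth <- list(); ann <- list(); prot <- list()
  doms <- list(); counts <- list()
  samples <- c(paste0("case_", seq_len(spec$n_case)),
               paste0("ctrl_", seq_len(spec$n_control)))
  groups <- c(rep("case", spec$n_case), rep("control", spec$n_control))

  for (i in seq_len(nev)) {
    type <- types[i]; strand <- strands[i]
    gene <- sprintf("GENE%03d", i)
    gb <- build_gene_blocks(type, frames[i], fs_plan[i])
    ch <- chroms[(i - 1L) %% 3L + 1L]
    pad <- rdna(sample(80:120, 1L))
    chrom_seq[[ch]] <- c(chrom_seq[[ch]], pad, "")
    G <- cursor[[ch]] + nchar(pad)
    lay <- layout_blocks(gb$blocks, G, strand)
    chrom_seq[[ch]][[length(chrom_seq[[ch]])]] <- lay$gseq
    cursor[[ch]] <- G + lay$L
    co <- lay$coords
    exdf <- function(...) {
      nm <- c(...)
      data.frame(start = vapply(nm, function(x) co[[x]][1L], 0L),
                 end = vapply(nm, function(x) co[[x]][2L], 0L))
    }
    seq_of <- setNames(lapply(gb$blocks, `[[`, "seq"),
                       vapply(gb$blocks, `[[`, "", "name"))
    d <- gb$mids$d
    # event isoforms: exon coordinate tables + transcript-orientation seqs
    iso <- switch(type,
      exon_skip = list(a = exdf("X2", "X4"), b = exdf("X2", "X3", "X4"),
        sa = paste0(seq_of$X2, seq_of$X4),
        sb = paste0(seq_of$X2, seq_of$X3, seq_of$X4)),
      mult_exon_skip = list(a = exdf("X2", "X5"),
        b = exdf("X2", "X3", "X4", "X5"),
        sa = paste0(seq_of$X2, seq_of$X5),
        sb = paste0(seq_of$X2, seq_of$X3, seq_of$X4, seq_of$X5)),
      mutex_exons = list(a = exdf("X2", "X3", "X4"),
        b = exdf("X2", "XM", "X4"),
        sa = paste0(seq_of$X2, seq_of$X3, seq_of$X4),
        sb = paste0(seq_of$X2, seq_of$XM, seq_of$X4)),
      intron_retention = list(a = exdf("X2", "X3"),
        b = data.frame(start = min(co$X2[1L], co$X3[1L]),
                       end = max(co$X2[2L], co$X3[2L])),
        sa = paste0(seq_of$X2, seq_of$X3),
        sb = paste0(seq_of$X2, seq_of$I2, seq_of$X3)),
      alt_5prime = {
        ext <- if (strand == "+")
          data.frame(start = c(co$X2[1L], co$X3[1L]),
                     end = c(co$X2[2L] + d, co$X3[2L]))
        else
          data.frame(start = c(co$X2[1L] - d, co$X3[1L]),
                     end = c(co$X2[2L], co$X3[2L]))
        list(a = exdf("X2", "X3"), b = ext,
             sa = paste0(seq_of$X2, seq_of$X3),
             sb = paste0(seq_of$X2, substr(seq_of$I2, 1L, d), seq_of$X3))
      },
      alt_3prime = {
        ilen <- nchar(seq_of$I2)
        ext <- if (strand == "+")
          data.frame(start = c(co$X2[1L], co$X3[1L] - d),
                     end = c(co$X2[2L], co$X3[2L]))
        else
          data.frame(start = c(co$X2[1L], co$X3[1L]),
                     end = c(co$X2[2L], co$X3[2L] + d))
        list(a = exdf("X2", "X3"), b = ext,
             sa = paste0(seq_of$X2, seq_of$X3),
             sb = paste0(seq_of$X2, substring(seq_of$I2, ilen - d + 1L),
                         seq_of$X3))
      })
    event_id <- sprintf("%s.%d", type, i)
    novel_b <- type %in% c("intron_retention", "alt_5prime", "alt_3prime",
                           "mutex_exons")
    ev <- splice_event(event_id, gene, type, ch, strand, iso$a, iso$b,
                       novel_iso1 = FALSE, novel_iso2 = novel_b)
    # identify which constructed isoform became isoform 1 after
    # normalization (mutex ordering depends on strand)
    key <- function(ex) paste(sort(paste(ex$start, ex$end)), collapse = "|")
    a_is_iso1 <- key(ev$iso1_exons) == key(order_exons(
      check_exons(iso$a, event_id), strand))
    s1 <- if (a_is_iso1) iso$sa else iso$sb
    s2 <- if (a_is_iso1) iso$sb else iso$sa
    f <- gb$frame_true
    aa1 <- translate_dna(s1, f); aa2 <- translate_dna(s2, f)
    st1 <- first_stop(aa1); st2 <- first_stop(aa2)
    pv1 <- posvec(ev$iso1_exons, strand); pv2 <- posvec(ev$iso2_exons, strand)
    stg <- function(st, pv) if (is.na(st)) NA_integer_ else
      pv[(f - 1L) + 3L * (st - 1L) + 1L]
    psi_case <- if (differential[i]) spec$psi_case else spec$psi_null
    psi_control <- if (differential[i]) spec$psi_control else spec$psi_null
    truth[[i]] <- data.frame(
      event_id = event_id, gene = gene, event_type = type, strand = strand,
      coding = TRUE, differential = differential[i],
      psi_case = psi_case, psi_control = psi_control,
      true_frame = as.character(f), aa_iso1 = aa1, aa_iso2 = aa2,
      frameshift = (nchar(s2) - nchar(s1)) %% 3L != 0L,
      stop_pos_iso1 = st1, stop_pos_iso2 = st2,
      stop_genomic_iso1 = stg(st1, pv1), stop_genomic_iso2 = stg(st2, pv2))
    events[[event_id]] <- ev
    # counts under the normalized isoform-2 PSI
    nvec <- sample_range(spec$coverage_range[1L], spec$coverage_range[2L],
                         length(samples))
    psi <- ifelse(groups == "case", psi_case, psi_control)
    y <- vapply(seq_along(nvec), function(k)
      rbetabinom(1L, nvec[k], psi[k], spec$phi), 0L)
    counts[[i]] <- data.frame(event_id = event_id, sample_id = samples,
                              group = groups, reads_iso1 = nvec - y,
                              reads_iso2 = y)
    # annotation: canonical transcript (exon blocks X1..Xn, not XM)
    can <- grep("^X\\d+$", names(co), value = TRUE)
    cex <- data.frame(start = vapply(can, function(x) co[[x]][1L], 0L),
                      end = vapply(can, function(x) co[[x]][2L], 0L))
    cex <- cex[order(cex$start), ]
    ann[[i]] <- data.frame(
      gene = gene, biotype = "protein_coding",
      transcript_id = paste0("TR_", gene),
      exons = paste(sprintf("%d-%d", cex$start, cex$end), collapse = ";"),
      cds_start_offset = gb$u)
    prot[[i]] <- setNames(gb$protein, sprintf("P_%s gene=%s", gene, gene))
    plen <- nchar(gb$protein)
    a1 <- sample(3:10, 1L); a2 <- min(plen - 2L, a1 + sample(10:20, 1L))
    doms[[i]] <- data.frame(
      gene = gene, accession = paste0("IPR_", gene),
      name = paste0("dom_", gene),
      aa_start = c(a1, max(1L, a1 - 2L)), aa_end = c(a2, a2 - 1L),
      source_db = c("dbA", "dbB"))
  }

  # extra non-coding genes with one null event each
  for (j in seq_len(spec$n_noncoding)) {
    i <- nev + j
    gene <- sprintf("NCGENE%02d", j)
    ch <- chroms[(i - 1L) %% 3L + 1L]
    exl <- c(sample(40:60, 1L), sample(30:50, 1L), sample(30:50, 1L))
    blocks <- list(list(name = "X1", seq = rdna(exl[1L]), exon = TRUE),
                   list(name = "I1", seq = rdna(70L), exon = FALSE),
                   list(name = "X2", seq = rdna(exl[2L]), exon = TRUE),
                   list(name = "I2", seq = rdna(70L), exon = FALSE),
                   list(name = "X3", seq = rdna(exl[3L]), exon = TRUE))
    pad <- rdna(sample(80:120, 1L))
    chrom_seq[[ch]] <- c(chrom_seq[[ch]], pad, "")
    G <- cursor[[ch]] + nchar(pad)
    lay <- layout_blocks(blocks, G, "+")
    chrom_seq[[ch]][[length(chrom_seq[[ch]])]] <- lay$gseq
    cursor[[ch]] <- G + lay$L
    co <- lay$coords
    ex <- function(...) data.frame(
      start = vapply(c(...), function(x) co[[x]][1L], 0L),
      end = vapply(c(...), function(x) co[[x]][2L], 0L))
    event_id <- paste0("exon_skip.nc", j)
    ev <- splice_event(event_id, gene, "exon_skip", ch, "+",
                       ex("X1", "X3"), ex("X1", "X2", "X3"))
    events[[event_id]] <- ev
    nvec <- sample_range(spec$coverage_range[1L], spec$coverage_range[2L],
                         length(samples))
    y <- vapply(nvec, function(n) rbetabinom(1L, n, spec$psi_null,
                                             spec$phi), 0L)
    counts[[i]] <- data.frame(event_id = event_id, sample_id = samples,
                              group = groups, reads_iso1 = nvec - y,
                              reads_iso2 = y)
    truth[[i]] <- data.frame(
      event_id = event_id, gene = gene, event_type = "exon_skip",
      strand = "+", coding = FALSE, differential = FALSE,
      psi_case = spec$psi_null, psi_control = spec$psi_null,
      true_frame = "X", aa_iso1 = NA_character_, aa_iso2 = NA_character_,
      frameshift = NA, stop_pos_iso1 = NA_integer_,
      stop_pos_iso2 = NA_integer_, stop_genomic_iso1 = NA_integer_,
      stop_genomic_iso2 = NA_integer_)
    ann[[i]] <- data.frame(gene = gene, biotype = "lncRNA",
                           transcript_id = paste0("TR_", gene),
                           exons = paste(sprintf("%d-%d",
                             sort(c(co$X1[1L], co$X2[1L], co$X3[1L])),
                             sort(c(co$X1[2L], co$X2[2L], co$X3[2L]))),
                             collapse = ";"),
                           cds_start_offset = 0L)
  }

  truth <- do.call(rbind, truth)
  counts <- do.call(rbind, counts)
  ann <- do.call(rbind, ann)

  # write files; every second event's isoform columns (and counts) are
  # stored unnormalized to exercise the label swap on read-back
  fmt <- function(ex) paste(sprintf("%d-%d", ex$start, ex$end),
                            collapse = ";")
  ids <- names(events)
  swap_out <- setNames(rep_len(c(FALSE, TRUE), length(ids)), ids)
  evdf <- do.call(rbind, lapply(ids, function(id) {
    e <- events[[id]]
    sw <- swap_out[[id]]
    data.frame(event_id = id, gene = e$gene, event_type = e$event_type,
               chrom = e$chrom, strand = e$strand,
               iso1_exons = fmt(if (sw) e$iso2_exons else e$iso1_exons),
               iso2_exons = fmt(if (sw) e$iso1_exons else e$iso2_exons),
               novel_iso1 = if (sw) e$novel_iso2 else e$novel_iso1,
               novel_iso2 = if (sw) e$novel_iso1 else e$novel_iso2)
  }))
  csw <- swap_out[counts$event_id]
  tmp <- counts$reads_iso1
  counts$reads_iso1[csw] <- counts$reads_iso2[csw]
  counts$reads_iso2[csw] <- tmp[csw]

  paths <- list(
    genome = file.path(dir, "genome.fa"),
    annotation = file.path(dir, "annotation.tsv"),
    events = file.path(dir, "events.tsv"),
    counts = file.path(dir, "counts.tsv"),
    proteins = file.path(dir, "proteins.fa"),
    domains = file.path(dir, "domains.tsv"),
    truth = file.path(dir, "truth.tsv"))
  gseqs <- Biostrings::DNAStringSet(vapply(chrom_seq, paste0, "",
                                           collapse = ""))
  names(gseqs) <- chroms
  Biostrings::writeXStringSet(gseqs, paths$genome, width = 70L)
  wt <- function(df, p) write.table(df, p, sep = "\t", quote = FALSE,
                                    row.names = FALSE)
  wt(ann, paths$annotation)
  wt(evdf, paths$events)
  wt(counts, paths$counts)
  pr <- do.call(c, prot)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(setNames(
    unname(pr), names(pr))), paths$proteins, width = 70L)
  wt(do.call(rbind, doms), paths$domains)
  wt(truth, paths$truth)
  invisible(list(dir = dir, paths = paths, truth = truth, events = events,
                 spec = spec))
}

#' Simulated null counts panel
#'
#' Independent events with the same PSI in both groups (drawn per event
#' from `psi_range`) and beta-binomial sampling noise — the design used to
#' check type-I-error calibration of the differential test.
#'
#' @param n_events number of null events.
#' @param n_case,n_control samples per group.
#' @param coverage_range per-sample total-read range (uniform integer).
#' @param phi overdispersion (both groups).
#' @param psi_range range of per-event shared PSI.
#' @param seed integer seed.
#' @return counts data frame as from [read_counts()] (with `psi`).
#' @export
generate_null_panel <- function(n_events = 2000L, n_case = 10L,
                                n_control = 10L,
                                coverage_range = c(20L, 300L), phi = 0.05,
                                psi_range = c(0.2, 0.8), seed = 1L) {
  set.seed(seed)
  ns <- n_case + n_control
  groups <- c(rep("case", n_case), rep("control", n_control))
  samples <- c(paste0("case_", seq_len(n_case)),
               paste0("ctrl_", seq_len(n_control)))
  rows <- lapply(seq_len(n_events), function(i) {
    psi <- runif(1L, psi_range[1L], psi_range[2L])
    nvec <- sample_range(coverage_range[1L], coverage_range[2L], ns)
    y <- rbetabinom(ns, nvec, psi, phi)
    data.frame(event_id = sprintf("null.%d", i), sample_id = samples,
               group = groups, reads_iso1 = nvec - y, reads_iso2 = y)
  })
  out <- do.call(rbind, rows)
  out$psi <- compute_psi(out$reads_iso1, out$reads_iso2)
  out
}

#' Simulated two-group differential panel
#'
#' Events with different group PSIs, used for parameter-recovery and power
#' checks of the beta-binomial test.
#'
#' @inheritParams generate_null_panel
#' @param psi_case,psi_control group PSIs (same for every event).
#' @return counts data frame.
#' @export
generate_diff_panel <- function(n_events = 200L, n_case = 10L,
                                n_control = 10L,
                                coverage_range = c(100L, 300L),
                                psi_case = 0.7, psi_control = 0.3,
                                phi = 0.02, seed = 1L) {
  set.seed(seed)
  ns <- n_case + n_control
  groups <- c(rep("case", n_case), rep("control", n_control))
  samples <- c(paste0("case_", seq_len(n_case)),
               paste0("ctrl_", seq_len(n_control)))
  rows <- lapply(seq_len(n_events), function(i) {
    nvec <- sample_range(coverage_range[1L], coverage_range[2L], ns)
    psi <- ifelse(groups == "case", psi_case, psi_control)
    y <- vapply(seq_len(ns), function(k)
      rbetabinom(1L, nvec[k], psi[k], phi), 0L)
    data.frame(event_id = sprintf("diff.%d", i), sample_id = samples,
               group = groups, reads_iso1 = nvec - y, reads_iso2 = y)
  })
  out <- do.call(rbind, rows)
  out$psi <- compute_psi(out$reads_iso1, out$reads_iso2)
  out
}
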