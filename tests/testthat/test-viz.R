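mk_event <- function(id = "e", type = "exon_skip", strand = "+") {
  splice_event(id, "G1", type, "chr1", strand,
               data.frame(start = c(100, 300), end = c(150, 350)),
               data.frame(start = c(100, 200, 300),
                          end = c(150, 250, 350)))
}

mk_gene_model <- function() {
  list(gene = "G1", biotype = "protein_coding", transcripts = list(
    T1 = list(transcript_id = "T1",
              exons = data.frame(start = c(50, 100, 200, 300),
                                 end = c(80, 150, 250, 350)),
              cds_start_offset = 12L),
    T2 = list(transcript_id = "T2",
              exons = data.frame(start = c(100, 300),
                                 end = c(150, 350)),
              cds_start_offset = 0L)))
}

test_that("transcript matching ranks exact flank matches and breaks ties", {
  ev <- mk_event()
  gm <- mk_gene_model()
  m <- match_transcript(ev, gm)
  # both T1 and T2 contain the flanks exactly; T1 is longer
  expect_equal(m$match_quality, "both_exons_exact")
  expect_equal(m$transcript_id, "T1")
  # no overlap at all
  gm2 <- list(gene = "G1", transcripts = list(
    TZ = list(transcript_id = "TZ",
              exons = data.frame(start = 5000, end = 5100),
              cds_start_offset = 0L)))
  m2 <- match_transcript(ev, gm2)
  expect_equal(m2$match_quality, "none")
  expect_true(is.na(m2$transcript_id))
  # one exact flank
  gm3 <- list(gene = "G1", transcripts = list(
    TY = list(transcript_id = "TY",
              exons = data.frame(start = c(100, 320), end = c(150, 360)),
              cds_start_offset = 0L)))
  expect_equal(match_transcript(ev, gm3)$match_quality, "one_exon_exact")
})

test_that("same-accession domains merge before coordinate conversion", {
  dom <- data.frame(gene = "G1", accession = c("IPR1", "IPR1", "IPR2"),
                    name = c("dom", "dom", "other"),
                    aa_start = c(5, 40, 100), aa_end = c(50, 60, 110),
                    source_db = c("a", "b", "a"))
  merged <- collapse_domains(dom)
  ipr1 <- merged[merged$accession == "IPR1", ]
  expect_equal(nrow(ipr1), 1)
  expect_equal(c(ipr1$aa_start, ipr1$aa_end), c(5, 60))
  expect_equal(nrow(merged), 2)
})

test_that("domain coordinates use the 5'UTR offset and clip at the end", {
  tex <- data.frame(start = c(1, 200), end = c(150, 400))   # 351 nt
  dom <- data.frame(gene = "G1", accession = "IPR1", name = "d",
                    aa_start = 1, aa_end = 10, source_db = "a")
  cc <- domain_to_collapsed_coords(dom, 60L, tex)
  expect_equal(c(cc$nt_start, cc$nt_end), c(61, 90))
  cc0 <- domain_to_collapsed_coords(within(dom, aa_end <- 1), 0L, tex)
  expect_equal(c(cc0$nt_start, cc0$nt_end), c(1, 3))
  expect_warning(
    ccl <- domain_to_collapsed_coords(within(dom, aa_end <- 200), 0L, tex),
    "clipped")
  expect_equal(ccl$nt_end, 351)
  # order preservation over random domains
  set.seed(31)
  aa <- sort(sample(1:100, 10))
  d2 <- data.frame(gene = "G1", accession = paste0("I", 1:10),
                   name = paste0("n", 1:10), aa_start = aa, aa_end = aa,
                   source_db = "a")
  c2 <- domain_to_collapsed_coords(d2, 9L,
                                   data.frame(start = 1, end = 400))
  expect_true(all(diff(c2$nt_start[order(match(c2$accession,
                                               d2$accession))]) > 0))
})

test_that("figure coordinate tables encode shared/altered exons and stops", {
  fx <- generate_fixture(fixture_spec(seed = 29, events_per_type = 2,
                                      n_case = 4, n_control = 4,
                                      n_noncoding = 0),
                         dir = file.path(tempdir(), "fx_viz"))
  ev <- read_event_table(fx$paths$events)
  g <- load_genome(fx$paths$genome)
  tt <- fx$truth
  # a truncating event: stop only in isoform 2
  idx <- which(!is.na(tt$stop_genomic_iso2) & is.na(tt$stop_genomic_iso1))
  expect_gt(length(idx), 0)
  i <- idx[1]
  e <- ev[[tt$event_id[i]]]
  d <- protein_diff(e, tt$true_frame[i], g)
  fd <- event_figure_data(e, d, tt$true_frame[i])
  stops <- attr(fd, "stops")
  expect_equal(nrow(stops), 1)
  expect_equal(stops$genomic, tt$stop_genomic_iso2[i])
  # the stop marker lies within an isoform-2 exon colored altered
  iso2 <- fd[fd$isoform == 2, ]
  hit <- iso2[stops$genomic >= iso2$start & stops$genomic <= iso2$end, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$fill, "altered")
  # an event with identical peptides is entirely shared
  same <- diff_isoforms("MKLV", "MKLV")
  dd <- data.frame(event_id = e$event_id, aa_iso1 = "MKLV",
                   aa_iso2 = "MKLV", same_start_aa = "MKLV",
                   diff_aa_iso1 = "", diff_aa_iso2 = "", same_end_aa = "",
                   stop_genomic_iso1 = NA, stop_genomic_iso2 = NA)
  fd2 <- event_figure_data(e, dd, "1")
  expect_true(all(fd2$fill == "shared"))
  # unresolved frame: neutral rendering, no stops
  fd3 <- event_figure_data(e, NULL, NULL)
  expect_true(all(fd3$fill == "neutral"))
  expect_equal(nrow(attr(fd3, "stops")), 0)
})

test_that("domain figure data aligns exons and domains on collapsed axis", {
  ev <- mk_event()
  tr <- mk_gene_model()$transcripts$T1
  dom <- data.frame(gene = "G1", accession = "IPR1", name = "d",
                    aa_start = 2, aa_end = 11, source_db = "a")
  fd <- domain_figure_data(ev, tr, dom)
  # collapsed length equals summed exon lengths
  expect_equal(max(fd$exons$nt_end),
               sum(tr$exons$end - tr$exons$start + 1))
  expect_true(all(diff(fd$exons$nt_start) > 0))
  expect_equal(sum(fd$exons$is_event_exon), 3)
  # offset 12, aa 2-11 -> nt 16..45
  expect_equal(c(fd$domains$nt_start, fd$domains$nt_end), c(16, 45))
})

test_that("figure rendering writes non-empty image files", {
  fx <- generate_fixture(fixture_spec(seed = 29, events_per_type = 1,
                                      n_case = 4, n_control = 4,
                                      n_noncoding = 0),
                         dir = file.path(tempdir(), "fx_render"))
  ev <- read_event_table(fx$paths$events)
  g <- load_genome(fx$paths$genome)
  cnt <- read_counts(fx$paths$counts, events = ev)
  gm <- read_gene_models(fx$paths$annotation)
  dom <- read_domains(fx$paths$domains)
  tt <- fx$truth[1, ]
  e <- ev[[tt$event_id]]
  d <- protein_diff(e, tt$true_frame, g)
  pre <- file.path(tempdir(), "fig_event")
  paths <- render_event_figure(e, NULL, d, tt$true_frame, cnt, pre)
  for (p in paths) expect_gt(file.size(p), 0)
  paths2 <- render_transcript_figure(e, gm[[e$gene]],
                                     file.path(tempdir(), "fig_tr"))
  for (p in paths2) expect_gt(file.size(p), 0)
  paths3 <- render_domain_figure(e, gm[[e$gene]], dom,
                                 file.path(tempdir(), "fig_dom"))
  for (p in paths3) expect_gt(file.size(p), 0)
})
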