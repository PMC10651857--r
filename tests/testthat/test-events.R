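test_that("isoform normalization follows the event-type conventions", {
  # exon skip: exon-richer isoform becomes isoform 2
  ev <- splice_event("es.1", "G1", "exon_skip", "chr1", "+",
                     data.frame(start = c(100, 200, 300),
                                end = c(150, 250, 350)),
                     data.frame(start = c(100, 300), end = c(150, 350)))
  expect_equal(nrow(ev$iso1_exons), 2)
  expect_equal(nrow(ev$iso2_exons), 3)
  expect_true(ev$swapped)

  # already normalized input is unchanged and normalization is idempotent
  ev2 <- splice_event("es.2", "G1", "exon_skip", "chr1", "+",
                      data.frame(start = c(100, 300), end = c(150, 350)),
                      data.frame(start = c(100, 200, 300),
                                 end = c(150, 250, 350)))
  expect_false(ev2$swapped)
  expect_identical(normalize_isoforms(ev2), ev2)

  # mutex: isoform 1 carries the genomically first exclusive exon,
  # even for equal-length exclusive exons
  mx <- splice_event("mx.1", "G2", "mutex_exons", "chr1", "+",
                     data.frame(start = c(100, 400, 600),
                                end = c(150, 450, 650)),
                     data.frame(start = c(100, 200, 600),
                                end = c(150, 250, 650)))
  expect_equal(mx$iso1_exons$start[2], 200)
  expect_true(mx$swapped)

  # intron retention: merged (nucleotide-longer) form is isoform 2
  ir <- splice_event("ir.1", "G3", "intron_retention", "chr1", "+",
                     data.frame(start = 100, end = 250),
                     data.frame(start = c(100, 200), end = c(150, 250)))
  expect_equal(nrow(ir$iso1_exons), 2)
  expect_equal(nrow(ir$iso2_exons), 1)
  expect_true(ir$swapped)

  # minus strand stores exons in transcription order (descending)
  mev <- splice_event("es.3", "G4", "exon_skip", "chr1", "-",
                      data.frame(start = c(100, 300), end = c(150, 350)),
                      data.frame(start = c(100, 200, 300),
                                 end = c(150, 250, 350)))
  expect_equal(mev$iso2_exons$start, c(300, 200, 100))
})

test_that("malformed events are rejected with the offending event named", {
  expect_error(
    splice_event("bad.1", "G", "exon_skip", "chr1", "+",
                 data.frame(start = 100, end = 50),
                 data.frame(start = c(100, 200), end = c(150, 250))),
    "bad.1")
  expect_error(
    splice_event("bad.2", "G", "unknown_type", "chr1", "+",
                 data.frame(start = 1, end = 2),
                 data.frame(start = 1, end = 2)),
    "event_type")
  expect_error(
    splice_event("bad.3", "G", "exon_skip", "chr1", "*",
                 data.frame(start = 1, end = 2),
                 data.frame(start = 1, end = 2)),
    "strand")
})

test_that("PSI follows the isoform-2 convention with a coverage floor", {
  expect_equal(compute_psi(5, 5, 10), 0.5)
  expect_true(is.na(compute_psi(5, 4, 10)))
  expect_equal(compute_psi(0, 10, 10), 1.0)
  expect_error(compute_psi(-1, 5), "non-negative")
  # scale invariance above the coverage floor
  for (k in c(2, 5, 17)) {
    expect_equal(compute_psi(7 * k, 13 * k, 10), compute_psi(7, 13, 10))
  }
})

test_that("genomic names are deterministic and injective", {
  ev <- splice_event("es.1", "G1", "exon_skip", "chr1", "+",
                     data.frame(start = c(100, 300), end = c(150, 350)),
                     data.frame(start = c(100, 200, 300),
                                 end = c(150, 250, 350)))
  expect_equal(make_genomic_name(ev),
               "exon_skip:chr1:+:100-150,300-350|100-150,200-250,300-350")
  # same structure, different id -> same name
  ev_b <- ev; ev_b$event_id <- "other.9"
  expect_equal(make_genomic_name(ev_b), make_genomic_name(ev))
  # same coordinates, different type -> different name
  ev_c <- splice_event("ir.7", "G1", "intron_retention", "chr1", "+",
                       data.frame(start = c(100, 300), end = c(150, 350)),
                       data.frame(start = 100, end = 350))
  expect_false(make_genomic_name(ev_c) == make_genomic_name(ev))
  # injectivity over a generated fixture
  fx <- generate_fixture(fixture_spec(seed = 3, events_per_type = 3,
                                      n_case = 4, n_control = 4,
                                      n_noncoding = 1),
                         dir = file.path(tempdir(), "fx_names"))
  nms <- vapply(fx$events, make_genomic_name, "")
  expect_equal(anyDuplicated(nms), 0L)
})

test_that("event and counts tables round-trip with consistent label swaps", {
  fx <- generate_fixture(fixture_spec(seed = 5, events_per_type = 2,
                                      n_case = 6, n_control = 6,
                                      n_noncoding = 0),
                         dir = file.path(tempdir(), "fx_rt"))
  ev <- read_event_table(fx$paths$events)
  expect_length(ev, 12)
  # half the stored rows are unnormalized on purpose; all read back
  # normalized
  expect_true(any(vapply(ev, `[[`, NA, "swapped")))
  for (e in ev) expect_false(normalize_isoforms(e)$swapped != e$swapped)
  # write of normalized events then re-read: no swaps the second time
  p2 <- file.path(tempdir(), "events_rt.tsv")
  write_event_table(ev, p2)
  ev2 <- read_event_table(p2)
  expect_false(any(vapply(ev2, `[[`, NA, "swapped")))
  for (id in names(ev)) {
    expect_identical(ev2[[id]]$iso1_exons, ev[[id]]$iso1_exons)
    expect_identical(ev2[[id]]$iso2_exons, ev[[id]]$iso2_exons)
  }
  # counts swap matches the event swap, so PSI means agree with the
  # planted group PSIs regardless of storage order
  cnt <- read_counts(fx$paths$counts, events = ev)
  tt <- fx$truth
  for (i in seq_len(nrow(tt))) {
    m <- mean(cnt$psi[cnt$event_id == tt$event_id[i] &
                        cnt$group == "case"], na.rm = TRUE)
    expect_lt(abs(m - tt$psi_case[i]), 0.15)
  }
})

test_that("reader errors name the problem", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("event_id\tgene\tevent_type\tchrom\tstrand\tiso1_exons",
               "x\tG\texon_skip\tchr1\t+\t1-2"), p)
  expect_error(read_event_table(p), "iso2_exons")
  writeLines(c(paste("event_id", "gene", "event_type", "chrom", "strand",
                     "iso1_exons", "iso2_exons", sep = "\t"),
               paste("x", "G", "exon_skip", "chr1", "+", "garbage",
                     "1-2;5-9", sep = "\t")), p)
  expect_error(read_event_table(p), "malformed")
  writeLines(c("event_id\tsample_id\tgroup\treads_iso1",
               "x\ts1\tcase\t5"), p)
  expect_error(read_counts(p), "reads_iso2")
})

test_that("results table blanks protein columns for frame X and rejects orphans", {
  ev <- list(splice_event("es.1", "G1", "exon_skip", "chr1", "+",
                          data.frame(start = c(100, 300),
                                     end = c(150, 350)),
                          data.frame(start = c(100, 200, 300),
                                     end = c(150, 250, 350))))
  stats <- data.frame(event_id = "es.1", n_valid_case = 10,
                      n_valid_control = 10, mean_psi_case = 0.6,
                      mean_psi_control = 0.4, delta_psi = 0.2,
                      p_value = 0.001, p_adj = 0.005)
  frames <- data.frame(event_id = "es.1", frame = "X",
                       frame_method = "unresolved")
  path <- tempfile(fileext = ".tsv")
  out <- write_results_table(ev, stats, frames, NULL, path)
  expect_equal(out$frame, "X")
  expect_equal(out$aa_iso1, "")
  back <- read.delim(path)
  expect_equal(back$event_id, "es.1")
  expect_equal(back$delta_psi, 0.2)
  bad_stats <- rbind(stats, within(stats, event_id <- "ghost.1"))
  expect_error(write_results_table(ev, bad_stats, NULL, NULL, path),
               "ghost.1")
})

test_that("GTF gene models carry exons, biotype and the 5'UTR offset", {
  gtf <- tempfile(fileext = ".gtf")
  attrs <- function(tid) sprintf(
    'gene_id "g1"; gene_name "GENE1"; gene_biotype "protein_coding"; transcript_id "%s";',
    tid)
  lines <- c(
    paste("chr1", "src", "exon", 100, 150, ".", "+", ".", attrs("t1"),
          sep = "\t"),
    paste("chr1", "src", "exon", 200, 260, ".", "+", ".", attrs("t1"),
          sep = "\t"),
    paste("chr1", "src", "CDS", 130, 150, ".", "+", ".", attrs("t1"),
          sep = "\t"),
    paste("chr1", "src", "CDS", 200, 230, ".", "+", ".", attrs("t1"),
          sep = "\t"),
    # minus-strand transcript: CDS starts at its highest coordinate
    paste("chr1", "src", "exon", 500, 560, ".", "-", ".", attrs("t2"),
          sep = "\t"),
    paste("chr1", "src", "exon", 600, 640, ".", "-", ".", attrs("t2"),
          sep = "\t"),
    paste("chr1", "src", "CDS", 520, 560, ".", "-", ".", attrs("t2"),
          sep = "\t"))
  writeLines(lines, gtf)
  gm <- read_gene_models_gtf(gtf)
  g <- gm$GENE1
  expect_equal(g$biotype, "protein_coding")
  expect_setequal(names(g$transcripts), c("t1", "t2"))
  expect_equal(g$transcripts$t1$exons,
               data.frame(start = c(100, 200), end = c(150, 260)))
  # 5'UTR of t1: bases 100..129 -> offset 30
  expect_equal(g$transcripts$t1$cds_start_offset, 30L)
  # t2 on '-': transcript starts at 640; 5'UTR = 640..561 spliced =
  # 41 exon bases, then 560 is coding
  expect_equal(g$transcripts$t2$cds_start_offset, 41L)
})
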