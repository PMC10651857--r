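# Independent oracles used to cross-check the implementation.

# beta-binomial mass by numeric integration of dbinom over the mixing
# beta density (independent of the lbeta-ratio route in the package)
oracle_bb_mass <- function(y, n, prob, phi) {
  if (phi == 0) return(dbinom(y, n, prob))
  a <- prob * (1 - phi) / phi
  b <- (1 - prob) * (1 - phi) / phi
  # integrate in the beta quantile scale so endpoint singularities of the
  # mixing density never enter the integrand
  integrate(function(u) dbinom(y, n, qbeta(u, a, b)), 0, 1,
            rel.tol = 1e-10, subdivisions = 500L)$value
}

# codon-by-codon translation with an explicit lookup table
oracle_translate <- function(dna, frame) {
  code <- Biostrings::GENETIC_CODE
  dna <- toupper(dna)
  s <- substring(dna, frame, nchar(dna))
  ncod <- nchar(s) %/% 3
  if (ncod == 0) return("")
  out <- character(ncod)
  for (i in seq_len(ncod)) {
    cod <- substr(s, 3 * i - 2, 3 * i)
    out[i] <- if (cod %in% names(code)) code[[cod]] else "X"
  }
  paste(out, collapse = "")
}

# brute-force single-ORF frame call: translate every frame, count stops
oracle_orf <- function(dna) {
  peps <- vapply(1:3, function(f) oracle_translate(dna, f), "")
  open <- nchar(peps) > 0 & !grepl("*", peps, fixed = TRUE)
  if (sum(open) == 1) as.character(which(open)) else "X"
}

# brute-force peptide-matching frame call: naive substring search of each
# frame's stop-truncated peptide against every protein
oracle_peptide <- function(dna, proteins, min_match_len = 7) {
  counts <- integer(3)
  for (f in 1:3) {
    pep <- oracle_translate(dna, f)
    stop_at <- regexpr("*", pep, fixed = TRUE)
    if (stop_at > 0) pep <- substr(pep, 1, stop_at - 1)
    if (nchar(pep) < min_match_len || grepl("X", pep, fixed = TRUE)) next
    for (p in proteins)
      if (length(grep(pep, p, fixed = TRUE))) counts[f] <- counts[f] + 1L
  }
  pos <- which(counts > 0)
  list(frame = if (length(pos) == 1) as.character(pos) else "X",
       counts = counts)
}

# naive per-base walk: genomic position of every base of an isoform in
# transcript order, then direct indexing for a residue's codon start
oracle_map_aa <- function(event, frame, residue, isoform) {
  ex <- if (isoform == 1) event$iso1_exons else event$iso2_exons
  pos <- integer(0)
  for (i in seq_len(nrow(ex))) {
    p <- ex$start[i]:ex$end[i]
    if (event$strand == "-") p <- rev(p)
    pos <- c(pos, p)
  }
  pos[(as.integer(frame) - 1) + 3 * (residue - 1) + 1]
}

# small deterministic genome for sequence-level tests
toy_genome <- function(seqs) {
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- names(seqs)
  g
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# random multi-exon event on either strand, for coordinate-walk checks
random_event <- function(id) {
  strand <- sample(c("+", "-"), 1)
  nex <- sample(1:4, 1)
  cur <- sample(50:150, 1)
  starts <- ends <- integer(nex)
  for (i in seq_len(nex)) {
    starts[i] <- cur
    ends[i] <- cur + sample(10:60, 1)
    cur <- ends[i] + sample(20:80, 1)
  }
  iso2 <- data.frame(start = starts, end = ends)
  iso1 <- iso2[unique(c(1, nex)), , drop = FALSE]
  splice_event(paste0("rnd.", id), "G", "exon_skip", "chrT", strand,
               iso1, iso2)
}
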