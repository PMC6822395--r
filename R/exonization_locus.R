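# A fully controlled single-locus fixture: a 5-exon plus-strand gene whose
# 4th intron carries an antisense nested host/guest TE cassette with two
# planted AG acceptors sharing one GT donor, a branch-point heptamer, a TSD
# and a poly-A(T) tail. Outside the planted motifs the cassette contains no
# AG or GT dinucleotide at all, so splice-site enumeration over the TE
# region is exhaustive and exact. Host/guest bodies here are constrained
# random sequence, not the simulator's consensi: the point of this locus is
# exact bookkeeping, not sequence realism.

# Random DNA containing no "AG" and no "GT" dinucleotide, given the
# preceding character; starts and ends with "C" so it can be concatenated
# after/before anything without creating either motif.
constrained_dna <- function(n) {
  stopifnot(n >= 2L)
  out <- character(n)
  out[1] <- "C"
  for (i in 2:(n - 1L)) {
    prev <- out[i - 1L]
    pool <- switch(prev, A = c("A", "C", "T"), G = c("A", "C", "G"),
                   c("A", "C", "G", "T"))
    out[i] <- sample(pool, 1L)
  }
  out[n] <- "C"
  s <- paste(out, collapse = "")
  if (!grepl("[^C]", s)) substr(s, 2L, 2L) <- "T"
  s
}

random_codons <- function(n) {
  bases <- c("A", "C", "G", "T")
  cods <- character(n)
  for (i in seq_len(n)) {
    repeat {
      cod <- paste(sample(bases, 3L, replace = TRUE), collapse = "")
      if (!(cod %in% STOP_CODONS)) break
    }
    cods[i] <- cod
  }
  paste(cods, collapse = "")
}

#' Simulate a controlled exonization locus
#'
#' Builds a single chromosome carrying one 5-exon plus-strand coding gene
#' whose 4th intron contains an antisense nested TE pair: a fragmented
#' MIR-like host interrupted by an AluSp-like guest with TSD and poly-A(T)
#' hallmarks. Two AG acceptors (inside the guest) share one GT donor
#' (inside the downstream host fragment); a branch-point heptamer sits in
#' the canonical 21-25 nt band upstream of the first acceptor, and a stop
#' cluster covering all three reading frames lies inside the candidate
#' exons so spliced-in variants truncate the reference peptide.
#'
#' @param seed RNG seed.
#' @param tsd_len,polya_len Hallmark lengths.
#' @return List with `genome`, `genes` (1 row), `repeats` (3 rows),
#'   `te_region` (host outer span, 0-based half-open), `intron` (the 4th
#'   intron's genomic interval), and `truth` (positions of the planted
#'   acceptors, donor, branch point, TSD and tail lengths).
#' @export
simulate_exonization_locus <- function(seed = 1L, tsd_len = 10L,
                                       polya_len = 14L) {
  set.seed(seed)

  # --- cassette, assembled left to right with offset bookkeeping ---
  pieces <- list(); labels <- character(0)
  add <- function(lab, s) {
    pieces[[length(pieces) + 1L]] <<- s
    labels[length(labels) + 1L] <<- lab
  }
  tsd <- constrained_dna(tsd_len)
  add("host_left", constrained_dna(120L))
  add("tsd1", tsd)
  add("polyT", strrep("T", polya_len))            # antisense poly-A tail
  add("g1", constrained_dna(40L))
  add("bp", "TTTTTAC")                            # branch adenosine at pos 6
  add("py", paste(sample(c("C", "T"), 20L, TRUE), collapse = ""))
  add("ag1", "AG")
  add("g2", constrained_dna(58L))
  add("ag2", "AG")
  add("g3", constrained_dna(20L))
  add("stops", "TAAATAAATAA")                     # stop in all three frames
  add("g4", constrained_dna(80L))
  add("tsd2", tsd)
  add("host_r1", constrained_dna(30L))
  add("gt", "GT")
  add("host_r2", constrained_dna(100L))
  lens <- vapply(pieces, nchar, 0L)
  off <- stats::setNames(cumsum(c(0L, lens))[seq_along(lens)], labels)
  cassette <- paste(unlist(pieces), collapse = "")
  stopifnot(!grepl("AG", substr(cassette, 1L, off[["ag1"]])),
            !grepl("GT", substr(cassette, 1L, off[["gt"]])))

  guest_start <- off[["polyT"]]
  guest_end <- off[["tsd2"]]
  ag1 <- off[["ag1"]]; ag2 <- off[["ag2"]]; gt <- off[["gt"]]
  bp <- off[["bp"]] + 5L                           # 0-based branch A

  # --- gene: mRNA built first, then split into five exons ---
  utr5 <- "CCTCCTCCT"
  n_codons <- 150L
  cds <- paste0("ATG", random_codons(n_codons), "TAA")
  utr3 <- random_dna(100L)
  mrna <- paste0(utr5, cds, utr3)
  bounds <- c(0L, 60L, 150L, 240L, 330L, nchar(mrna))
  exon_seqs <- substring(mrna, bounds[-6] + 1L, bounds[-1])
  intron_lens <- c(150L, 150L, 150L, NA)
  ipre <- 150L; ipost <- 150L

  gene_pieces <- character(0)
  exon_starts <- integer(5); exon_ends <- integer(5)
  pos <- 0L
  for (i in 1:5) {
    exon_starts[i] <- pos
    gene_pieces <- c(gene_pieces, exon_seqs[i])
    pos <- pos + nchar(exon_seqs[i])
    exon_ends[i] <- pos
    if (i < 5L) {
      iseq <- if (i < 4L) random_dna(intron_lens[i]) else
        paste0(random_dna(ipre), cassette, random_dna(ipost))
      if (i == 4L) cassette_rel <- pos + ipre
      gene_pieces <- c(gene_pieces, iseq)
      pos <- pos + nchar(iseq)
    }
  }
  gene_seq <- paste(gene_pieces, collapse = "")

  flank <- 300L
  chrom <- paste0(random_dna(flank), gene_seq, random_dna(flank))
  genome <- c(chrL = chrom)
  G <- flank                   # gene tx_start
  C <- G + cassette_rel        # cassette genomic offset

  genes <- data.frame(
    name = "NM_LOCUS1", name2 = "LOCUS1", chrom = "chrL", strand = "+",
    tx_start = G, tx_end = G + nchar(gene_seq),
    cds_start = G + 9L, cds_end = NA_integer_,
    exon_count = 5L,
    exon_starts = I(list(G + exon_starts)), exon_ends = I(list(G + exon_ends)),
    score = "0", cds_start_stat = "cmpl", cds_end_stat = "cmpl",
    exon_frames = "-1,-1,-1,-1,-1,", stringsAsFactors = FALSE)
  # genomic cds_end: position of the stop codon's end inside exon 5
  cds_mrna_end <- 9L + nchar(cds)
  genes$cds_end <- G + exon_starts[5] + (cds_mrna_end - bounds[5])

  feats <- data.frame(
    start = C + c(0L, guest_start, guest_end),
    end = C + c(guest_start, guest_end, nchar(cassette)),
    strand = "-", rep_name = c("MIR", "AluSp", "MIR"),
    rep_class = "SINE", rep_family = c("MIR", "Alu", "MIR"),
    rep_len = c(nchar(cassette) - (guest_end - guest_start),
                guest_end - guest_start,
                nchar(cassette) - (guest_end - guest_start)),
    frag_key = c("host", "guest", "host"), stringsAsFactors = FALSE)
  repeats <- abs_repeat_rows(
    within(feats, {start <- start - C; end <- end - C}),
    C, "chrL", c(1L, 2L, 1L), milli_div = c(300L, 100L, 300L))

  list(genome = genome, genes = genes, repeats = repeats,
       te_region = c(C, C + nchar(cassette)),
       intron = c(G + exon_ends[4], G + exon_starts[5]),
       truth = list(acceptors = C + c(ag1, ag2), donor = C + gt,
                    bp = C + bp, tsd = tsd, tsd_len = tsd_len,
                    polya_len = polya_len,
                    guest_span = C + c(guest_start, guest_end),
                    ref_peptide_len = n_codons + 1L))
}
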