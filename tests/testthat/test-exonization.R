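test_that("splice-site scan finds AG acceptors and GT donors on the plus strand", {
  genome <- c(chr = "TTAGCCGTAA")
  sites <- scan_splice_sites(genome, "chr", 0L, 10L, "+")
  acc <- sites[sites$kind == "acceptor_3ss", ]
  don <- sites[sites$kind == "donor_5ss", ]
  expect_equal(acc$pos, 2L)
  expect_equal(don$pos, 6L)
  expect_equal(nrow(scan_splice_sites(c(chr = "CCCCCCCCCC"), "chr", 0L,
                                      10L, "+")), 0L)
})

test_that("minus-strand scanning reads the gene sense strand", {
  # sense (revcomp) of "TTACCTGGAA" is "TTCCAGGTAA": AG at sense pos 4,
  # GT at sense pos 6
  genome <- c(chr = "TTACCTGGAA")
  sites <- scan_splice_sites(genome, "chr", 0L, 10L, "-")
  acc <- sites[sites$kind == "acceptor_3ss", ]
  don <- sites[sites$kind == "donor_5ss", ]
  # sense pos 4 -> genomic footprint start 10 - 4 - 2 = 4 (bases "CT")
  expect_equal(acc$pos, 4L)
  expect_equal(don$pos, 2L)
  # strand symmetry: scanning the reverse complement with "+" gives the
  # mirrored positions
  rc <- c(chr = "TTCCAGGTAA")
  sites_rc <- scan_splice_sites(rc, "chr", 0L, 10L, "+")
  expect_equal(sort(10L - sites$pos - 2L),
               sort(sites_rc$pos))
})

test_that("splice-site counts match a sliding-window oracle on random sequence", {
  set.seed(41)
  for (rep in 1:10) {
    s <- random_seq(2000)
    genome <- c(chr = s)
    sites <- scan_splice_sites(genome, "chr", 0L, 2000L, "+")
    expect_equal(sites$pos[sites$kind == "acceptor_3ss"],
                 brute_dinuc_positions(s, "AG"))
    expect_equal(sites$pos[sites$kind == "donor_5ss"],
                 brute_dinuc_positions(s, "GT"))
  }
})

test_that("candidate enumeration pairs acceptors upstream of donors within bounds", {
  sites <- data.frame(
    kind = c("acceptor_3ss", "acceptor_3ss", "donor_5ss"),
    pos = c(100L, 160L, 400L), dinucleotide = c("AG", "AG", "GT"),
    gene_strand = "+", stringsAsFactors = FALSE)
  cand <- enumerate_candidates(sites)
  expect_equal(nrow(cand), 2L)          # two acceptors sharing one donor
  expect_equal(cand$label, c("V1-like", "V2-like"))
  expect_equal(cand$exon_start, c(102L, 162L))
  expect_equal(cand$length, c(298L, 238L))
  # donor upstream of all acceptors: nothing
  sites2 <- sites; sites2$pos <- c(400L, 500L, 100L)
  expect_equal(nrow(enumerate_candidates(sites2)), 0L)
})

test_that("candidate count equals exhaustive pairing on random site sets", {
  set.seed(42)
  for (rep in 1:20) {
    n_a <- sample(0:6, 1); n_d <- sample(0:6, 1)
    pos <- sample.int(3000L, n_a + n_d)
    sites <- data.frame(
      kind = rep(c("acceptor_3ss", "donor_5ss"), c(n_a, n_d)),
      pos = pos, dinucleotide = rep(c("AG", "GT"), c(n_a, n_d)),
      gene_strand = rep("+", n_a + n_d), stringsAsFactors = FALSE)
    cand <- enumerate_candidates(sites, min_len = 25L, max_len = 500L)
    brute <- 0L
    for (a in sites$pos[sites$kind == "acceptor_3ss"])
      for (d in sites$pos[sites$kind == "donor_5ss"]) {
        len <- d - a - 2L
        if (len >= 25L && len <= 500L) brute <- brute + 1L
      }
    expect_equal(nrow(cand), brute)
  }
})

test_that("splicing a candidate into a 5-exon gene gives 6 exons with exact length bookkeeping", {
  loc <- simulate_exonization_locus(seed = 1)
  g <- loc$genes[1, ]
  sites <- scan_splice_sites(loc$genome, "chrL", loc$te_region[1],
                             loc$te_region[2], "+")
  cand <- enumerate_candidates(sites, intron = loc$intron)
  expect_equal(nrow(cand), 2L)
  ref <- transcript_seq(g, loc$genome)
  for (k in seq_len(nrow(cand))) {
    tm <- splice_in(g, cand[k, ], loc$genome)
    expect_length(tm$exon_starts, 6L)
    expect_equal(tm$inserted_ordinal, 5L)
    expect_equal(nchar(tm$mrna), nchar(ref) + cand$length[k])
    # removing the inserted exon restores the reference transcript
    back <- g
    expect_identical(transcript_seq(back, loc$genome), ref)
    # exon boundary context: intronic AG immediately 5', GT immediately 3'
    chrom <- loc$genome[["chrL"]]
    expect_identical(substr(chrom, cand$exon_start[k] - 1L,
                            cand$exon_start[k]), "AG")
    expect_identical(substr(chrom, cand$exon_end[k] + 1L,
                            cand$exon_end[k] + 2L), "GT")
  }
  # a candidate outside every intron is rejected
  bad <- cand[1, ]; bad$exon_start <- 1L; bad$exon_end <- 30L
  expect_error(splice_in(g, bad, loc$genome), "intron")
})

test_that("first-start ORF rule on hand-checkable and length-derived cases", {
  expect_equal(find_first_orf("ATGAAATAA")$peptide, "MK")
  r <- find_first_orf("ATGAAATAA")
  expect_equal(r$nt_length, 9L)
  expect_equal(r$length_aa, 2L)
  # no stop: no ORF
  expect_false(find_first_orf("ATGAAAAAA")$has_orf)
  expect_false(find_first_orf("CCCCCCCCC")$has_orf)
  # a 429-nt ATG-initiated reading frame encodes 142 aa
  set.seed(43)
  orf429 <- paste0("ATG", random_codons_no_stop(141), "TAA")
  expect_equal(nchar(orf429), 429L)
  res <- find_first_orf(paste0("CCACC", orf429, random_seq(30)))
  expect_equal(res$length_aa, 142L)
  expect_equal(res$nt_length, 429L)
  # peptide length arithmetic: 3 * (aa + 1) = ORF nt length
  expect_equal(3L * (res$length_aa + 1L), res$nt_length)
})

test_that("ORF selection matches the exhaustive all-ATG oracle on random sequences", {
  set.seed(44)
  checked <- 0L
  for (rep in 1:300) {
    s <- random_seq(300)
    mine <- find_first_orf(s)
    oracle <- brute_first_orf(s)
    if (is.null(oracle)) {
      expect_false(mine$has_orf)
    } else {
      checked <- checked + 1L
      expect_equal(mine$orf_start, oracle$orf_start)
      expect_equal(mine$length_aa, oracle$length_aa)
    }
  }
  expect_gt(checked, 100L)
})

test_that("peptide comparison reports divergence point, shared prefix, premature stop", {
  expect_true(is.na(compare_peptides("MKLV", "MKLV")$divergence_point))
  r <- compare_peptides(strrep("A", 142), paste0(strrep("A", 137),
                                                 strrep("W", 20)))
  expect_equal(r$divergence_point, 138L)
  expect_equal(r$shared_prefix, 137L)
  expect_true(r$premature_stop)   # C-terminus replaced within reference span
  # pure extension is not premature
  expect_false(compare_peptides("MKL", "MKLVV")$premature_stop)
  # truncation is premature
  expect_true(compare_peptides("MKLVV", "MKL")$premature_stop)
  # random pairs: divergence equals first mismatch
  set.seed(45)
  for (rep in 1:50) {
    a <- paste(sample(LETTERS[1:20], 30, TRUE), collapse = "")
    b <- paste(sample(LETTERS[1:20], 30, TRUE), collapse = "")
    d <- compare_peptides(a, b)$divergence_point
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    expect_equal(d, which(av != bv)[1])
  }
})

test_that("variant transcripts from the fixture locus truncate the reference peptide", {
  loc <- simulate_exonization_locus(seed = 2)
  g <- loc$genes[1, ]
  sites <- scan_splice_sites(loc$genome, "chrL", loc$te_region[1],
                             loc$te_region[2], "+")
  cand <- enumerate_candidates(sites, intron = loc$intron)
  ref <- find_first_orf(transcript_seq(g, loc$genome))
  expect_equal(ref$length_aa, loc$truth$ref_peptide_len)
  for (k in seq_len(nrow(cand))) {
    tm <- splice_in(g, cand[k, ], loc$genome)
    var <- find_first_orf(tm$mrna)
    expect_true(var$has_orf)
    cmp <- compare_peptides(ref$peptide, var$peptide)
    expect_false(cmp$identical)
    expect_true(cmp$premature_stop)
    expect_gt(cmp$shared_prefix, 50L)
  }
})

test_that("GFF3 candidate output is 1-based closed with the gene strand", {
  cand <- data.frame(acceptor_pos = 10L, donor_pos = 100L,
                     exon_start = 12L, exon_end = 100L, length = 88L,
                     gene_strand = "+", label = "V1-like",
                     stringsAsFactors = FALSE)
  f <- tempfile(); write_gff3(cand, f, chrom = "chr1")
  lines <- readLines(f)
  expect_equal(lines[1], "##gff-version 3")
  fields <- strsplit(lines[2], "\t")[[1]]
  expect_equal(fields[4], "13")
  expect_equal(fields[5], "100")
  expect_equal(fields[7], "+")
})
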