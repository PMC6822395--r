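# Fixture builders and independent brute-force oracles. Oracles are written
# as plainly as possible (per-base loops, exhaustive scans) and never share
# code with the implementation they check.

make_repeat_features <- function(n, chroms = c("chr1", "chr2"),
                                 names_pool = c("MIR", "AluSp", "AluSx3", "L1PA4"),
                                 class_pool = c(MIR = "SINE", AluSp = "SINE",
                                                AluSx3 = "SINE", L1PA4 = "LINE"),
                                 family_pool = c(MIR = "MIR", AluSp = "Alu",
                                                 AluSx3 = "Alu", L1PA4 = "L1")) {
  nm <- sample(names_pool, n, replace = TRUE)
  start <- sample.int(100000L, n)
  len <- sample(50:400, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len,
             strand = sample(c("+", "-"), n, replace = TRUE),
             rep_name = nm, rep_class = unname(class_pool[nm]),
             rep_family = unname(family_pool[nm]),
             rep_start = 1L, rep_end = len,
             rep_left = -sample.int(50L, n, replace = TRUE),
             frag_id = seq_len(n),
             milli_div = sample.int(400L, n),
             milli_del = 0L, milli_ins = 0L,
             sw_score = sample.int(5000L, n), geno_left = 0L,
             stringsAsFactors = FALSE)
}

make_gene_models <- function(n, chroms = c("chr1", "chr2")) {
  rows <- lapply(seq_len(n), function(i) {
    k <- sample(2:8, 1)
    len <- sample(80:300, k, replace = TRUE)
    gap <- sample(200:2000, k - 1, replace = TRUE)
    starts <- cumsum(c(sample.int(50000L, 1), len[-k] + gap))
    ends <- starts + len
    data.frame(name = sprintf("NM_%05d", i), name2 = sprintf("G%d", i),
               chrom = sample(chroms, 1),
               strand = sample(c("+", "-"), 1),
               tx_start = starts[1], tx_end = ends[k],
               cds_start = starts[1] + 5L, cds_end = ends[k] - 5L,
               exon_count = k,
               exon_starts = I(list(as.integer(starts))),
               exon_ends = I(list(as.integer(ends))),
               score = "0", cds_start_stat = "cmpl", cds_end_stat = "cmpl",
               exon_frames = paste0(paste(rep(-1, k), collapse = ","), ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Per-base genomic-context oracle for a span against one gene.
brute_context <- function(span_start, span_end, chrom, gene) {
  if (chrom != gene$chrom) return("intergenic")
  pos <- span_start:(span_end - 1L)
  if (!all(pos >= gene$tx_start & pos < gene$tx_end)) return("intergenic")
  starts <- gene$exon_starts[[1]]; ends <- gene$exon_ends[[1]]
  in_exon <- vapply(pos, function(p) any(p >= starts & p < ends), TRUE)
  if (any(in_exon)) "intragenic_exon_overlap" else "intragenic_intronic"
}

# Sliding-window splice-dinucleotide oracle on a sense-strand sequence.
brute_dinuc_positions <- function(sense, motif) {
  out <- integer(0)
  for (i in seq_len(nchar(sense) - 1L))
    if (substr(sense, i, i + 1L) == motif) out <- c(out, i - 1L)
  out
}

# Exhaustive all-ATG ORF oracle: returns the 5'-most ATG with an in-frame
# stop, its peptide length, or NULL.
brute_first_orf <- function(mrna) {
  L <- nchar(mrna)
  for (s in seq_len(L - 2L)) {
    if (substr(mrna, s, s + 2L) != "ATG") next
    p <- s
    while (p + 2L <= L) {
      cod <- substr(mrna, p, p + 2L)
      if (cod %in% c("TAA", "TAG", "TGA"))
        return(list(orf_start = s - 1L, length_aa = (p - s) / 3L))
      p <- p + 3L
    }
  }
  NULL
}

# Exhaustive branch-point oracle: scores every eligible adenosine directly
# from the model components and returns the best row.
brute_best_bp <- function(intron_seq, model) {
  L <- nchar(intron_seq)
  best <- NULL
  for (i in 6:(L - 1L)) {
    if (substr(intron_seq, i, i) != "A") next
    d <- L - i
    if (d < model$distance_window[1] || d > model$distance_window[2]) next
    w <- strsplit(substr(intron_seq, i - 5L, i + 1L), "")[[1]]
    ms <- 0
    for (k in 1:7) {
      ms <- ms + unname(if (w[k] %in% c("A", "C", "G", "T"))
        model$pwm[w[k], k] else min(model$pwm[, k]))
    }
    band <- model$canonical_band
    prior <- -model$dist_penalty *
      max(0, band[1] - d, d - band[2])
    between <- strsplit(substr(intron_seq, i + 1L, L - 2L), "")[[1]]
    pyf <- sum(between %in% c("C", "T")) / length(between)
    tot <- ms + prior + model$py_weight * pyf
    if (is.null(best) || tot > best$total ||
        (tot == best$total && d < best$d))
      best <- list(pos = i, d = d, total = tot)
  }
  best
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# A random intron ending in AG.
random_intron <- function(n) paste0(random_seq(n - 2L), "AG")

random_codons_no_stop <- function(n) {
  stops <- c("TAA", "TAG", "TGA")
  out <- character(n)
  for (i in seq_len(n)) {
    repeat {
      cod <- random_seq(3L)
      if (!(cod %in% stops)) break
    }
    out[i] <- cod
  }
  paste(out, collapse = "")
}
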