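# Synthetic-genome generator with a planted-truth manifest.
#
# The generator emulates the genomic configuration under study: an old,
# heavily diverged SINE (MIR-like "host") whose annotation is split into two
# fragments sharing one linkage id because a younger SINE (Alu-like "guest")
# retrotransposed into it, leaving the two hallmarks of target-primed reverse
# transcription: a target-site duplication (TSD) flanking the guest and a
# poly-A tail at its 3' end. Optionally, intronic antisense host/guest pairs
# carry planted splice signals (an AG acceptor in the guest, a downstream GT
# donor in the host, and a branch-point heptamer 21-25 nt upstream of the
# AG), mirroring an exonization-competent locus.

# Fixed toy consensi of realistic SINE lengths (host ~260 nt, guest ~300 nt).
# These are synthetic sequences, not database extracts.
HOST_CONSENSUS <- paste0(
  "AAAACTCCATGTGTAACTCCGGAAGTAGAATCTTGCACTCGGCCTTTCCATATCTCGTGAACCCCCTGCA",
  "CGCCCTAAAGTACAATTAGGATATTCATCCCTACACTGTATATGCCGAACGTTCTAATAAACGACTTAGC",
  "AACAAGTCGCCTAGAAAGGTACCGCTGGCATATCACGCCTCCCGCTTGCCGTCTTCAACTTCATGACCCT",
  "CGTGCATCACAAAGCCTCAAGCCGGAGTCTAGGCTTTGAAACAGCTGAAT")
GUEST_CONSENSUS <- paste0(
  "TATCCAGCCCTCTATTGTACTCCTATCTCAGCGCCTATGCCACTTCGACTGCGCGGTTAGGAGCAATAAG",
  "ATGTGCGTGGGCGCATGGGAGGCGCTGGCCATATTGTATGGAGGTAATCGTAAGGTCGCGGTTGGAGGTC",
  "CGCCACACAACTACTCTTTTAAACGGCTAGACGAGTACGGACAGACCACTTTGCGTGACTCGCGGAGTCT",
  "AGTCGATCTCAGGCACACAAATAAAACTGTGGCCTCTTCCCGCGGCCTGTATAGGTAGCTTACGCTTCAC",
  "CAGACCCTTCCCTCTCTGAT")

#' Configuration for the synthetic-genome generator
#'
#' Defaults describe the study conditions exercised throughout the package:
#' one ~1 Mb chromosome carrying MIR-like hosts at 30% divergence from
#' consensus (the divergence range reported for MIR), AluSp-like guests at
#' 10%, TSD lengths inside the 2-20 bp rule, and antisense intronic pairs
#' with planted splice signals.
#'
#' @param seed Integer RNG seed; the simulation is fully deterministic
#'   given the seed.
#' @param n_chroms,chrom_len Number of chromosomes and exact length of each
#'   (bp).
#' @param n_genes,exons_per_gene Gene models to plant (5 exons each by
#'   default, the configuration of the motivating locus).
#' @param n_host_te,n_guest_te Number of MIR-like host and Alu-like guest
#'   elements.
#' @param p_nested Fraction of guests planted inside a host; realized
#'   deterministically as `round(p_nested * min(n_guest_te, n_host_te))`
#'   nested pairs so planted counts are reproducible.
#' @param tsd_len_range Integer range for TSD lengths; must lie within
#'   \[2, 20\].
#' @param polya_len_range Integer range for poly-A tail lengths.
#' @param host_divergence,guest_divergence Per-site substitution
#'   probabilities applied to the consensi.
#' @param plant_splice_signals Embed AG/GT/branch-point motifs in antisense
#'   intronic nested pairs.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chroms = 1L,
                              chrom_len = 1000000L,
                              n_genes = 8L,
                              exons_per_gene = 5L,
                              n_host_te = 40L,
                              n_guest_te = 30L,
                              p_nested = 0.8,
                              tsd_len_range = c(4L, 16L),
                              polya_len_range = c(8L, 30L),
                              host_divergence = 0.30,
                              guest_divergence = 0.10,
                              plant_splice_signals = TRUE) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_len = as.integer(chrom_len),
              n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              n_host_te = as.integer(n_host_te),
              n_guest_te = as.integer(n_guest_te),
              p_nested = p_nested,
              tsd_len_range = as.integer(tsd_len_range),
              polya_len_range = as.integer(polya_len_range),
              host_divergence = host_divergence,
              guest_divergence = guest_divergence,
              plant_splice_signals = isTRUE(plant_splice_signals))
  stopifnot(cfg$n_chroms >= 1L, cfg$chrom_len > 0L,
            cfg$n_genes >= 0L, cfg$exons_per_gene >= 2L,
            cfg$n_host_te >= 0L, cfg$n_guest_te >= 0L,
            cfg$p_nested >= 0, cfg$p_nested <= 1,
            cfg$host_divergence >= 0, cfg$host_divergence <= 1,
            cfg$guest_divergence >= 0, cfg$guest_divergence <= 1,
            length(cfg$tsd_len_range) == 2L,
            cfg$tsd_len_range[1] >= 2L, cfg$tsd_len_range[2] <= 20L,
            cfg$tsd_len_range[1] <= cfg$tsd_len_range[2],
            cfg$polya_len_range[1] >= 1L,
            cfg$polya_len_range[1] <= cfg$polya_len_range[2])
  class(cfg) <- "sim_config"
  cfg
}

#' Apply substitution-only divergence to a sequence
#'
#' Each site is substituted independently with probability `rate`, always to
#' a different base, so length is preserved and `rate = 1` leaves no site
#' with its original base. Expected observed divergence equals `rate`.
#'
#' @param seq Nucleotide string.
#' @param rate Per-site substitution probability in \[0, 1\].
#' @param seed Optional seed for a private RNG stream; `NULL` (default)
#'   draws from the current stream.
#' @return The diverged sequence (same length).
#' @export
apply_divergence <- function(seq, rate, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  with_seed(seed, {
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    bases <- c("A", "C", "G", "T")
    hit <- which(stats::runif(length(chars)) < rate & chars %in% bases)
    if (length(hit)) {
      alt <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                    nrow = 3, dimnames = list(NULL, bases))
      pick <- sample.int(3L, length(hit), replace = TRUE)
      chars[hit] <- alt[cbind(pick, match(chars[hit], bases))]
    }
    paste(chars, collapse = "")
  })
}

# Longest exact flanking duplication around [start, end) (0-based) in `seq`;
# used at build time to certify that the planted TSD is the longest one.
longest_flank_dup <- function(seq, start, end, max_len = 20L) {
  left <- substr(seq, max(1L, start - max_len + 1L), start)
  right <- substr(seq, end + 1L, min(nchar(seq), end + max_len))
  k <- min(nchar(left), nchar(right))
  while (k >= 1L) {
    if (substr(left, nchar(left) - k + 1L, nchar(left)) ==
        substr(right, 1L, k)) return(k)
    k <- k - 1L
  }
  0L
}

# Build one nested host/guest cassette. Coordinates in the returned feature
# table are relative to the cassette start (0-based half-open). The guest
# body's 3'-terminal 12 nt are kept A-free so the planted poly-A tail length
# is unambiguous, and the insertion point is chosen so the planted TSD is
# the longest flanking duplication.
build_nested_cassette <- function(host_strand, guest_strand, tsd_len,
                                  polya_len, host_div, guest_div,
                                  splice_signals = FALSE) {
  hd <- apply_divergence(HOST_CONSENSUS, host_div)
  hg <- if (host_strand == "+") hd else revcomp(hd)
  m <- nchar(hg)
  gb <- apply_divergence(GUEST_CONSENSUS, guest_div)
  tail_zone <- substr(gb, nchar(gb) - 11L, nchar(gb))
  substr(gb, nchar(gb) - 11L, nchar(gb)) <- gsub("A", "C", tail_zone)
  guest_sense <- paste0(gb, strrep("A", polya_len))
  guestg <- if (guest_strand == "+") guest_sense else revcomp(guest_sense)
  gl <- nchar(guestg)

  for (try in 1:100) {
    p <- sample(40:(m - 40L - tsd_len), 1L)
    if (substr(hg, p, p) == substr(hg, p + 1L, p + 1L)) next
    tsd <- substr(hg, p + 1L, p + tsd_len)
    cassette <- paste0(substr(hg, 1L, p + tsd_len), guestg,
                       substr(hg, p + 1L, m))
    g_start <- p + tsd_len          # 0-based guest start
    g_end <- g_start + gl
    if (longest_flank_dup(cassette, g_start, g_end) == tsd_len) break
    if (try == 100L) stop("could not place TSD without spurious extension")
  }

  signals <- NULL
  if (splice_signals) {
    # Antisense pair read on the + (gene sense) strand: acceptor AG inside
    # the guest body, donor GT inside the downstream host fragment, and the
    # consensus branch-point heptamer with its adenosine 23 nt upstream of
    # the AG.
    ag <- g_start + polya_len + 80L            # 0-based pos of the A of AG
    substr(cassette, ag + 1L, ag + 2L) <- "AG"
    bp <- ag - 21L                             # 0-based pos of the BP A
    substr(cassette, bp - 4L, bp + 2L) <- "TTTTTAC"
    gt <- g_end + 30L                          # 0-based pos of the G of GT
    substr(cassette, gt + 1L, gt + 2L) <- "GT"
    signals <- list(acceptor_pos = ag, donor_pos = gt, bp_pos = bp)
  }

  feats <- data.frame(
    start = c(0L, g_start, g_end),
    end = c(g_start, g_end, g_end + (m - p)),
    strand = c(host_strand, guest_strand, host_strand),
    rep_name = c("MIR", "AluSp", "MIR"),
    rep_class = "SINE",
    rep_family = c("MIR", "Alu", "MIR"),
    rep_len = c(m, nchar(GUEST_CONSENSUS), m),
    frag_key = c("host", "guest", "host"),
    stringsAsFactors = FALSE)

  list(seq = cassette, feats = feats, tsd = tsd, tsd_len = tsd_len,
       polya_len = polya_len, guest_span = c(g_start, g_end),
       host_span = c(0L, g_end + (m - p)), signals = signals)
}

build_standalone <- function(kind, strand, cfg) {
  if (kind == "host") {
    s <- apply_divergence(HOST_CONSENSUS, cfg$host_divergence)
    body <- if (strand == "+") s else revcomp(s)
    info <- c("MIR", "SINE", "MIR")
    rep_len <- nchar(HOST_CONSENSUS)
  } else {
    gb <- apply_divergence(GUEST_CONSENSUS, cfg$guest_divergence)
    polya <- sample(cfg$polya_len_range[1]:cfg$polya_len_range[2], 1L)
    s <- paste0(gb, strrep("A", polya))
    body <- if (strand == "+") s else revcomp(s)
    info <- c("AluSp", "SINE", "Alu")
    rep_len <- nchar(GUEST_CONSENSUS)
  }
  feats <- data.frame(start = 0L, end = nchar(body), strand = strand,
                      rep_name = info[1], rep_class = info[2],
                      rep_family = info[3], rep_len = rep_len,
                      frag_key = "solo", stringsAsFactors = FALSE)
  list(seq = body, feats = feats)
}

# Build one gene item. If `cassette` is given it is embedded in the intron
# with genomic index `host_intron` (gene on + strand, so genomic order is
# transcription order).
build_gene_item <- function(name, strand, n_exons, cassette = NULL,
                            host_intron = 4L) {
  exon_len <- sample(90:180, n_exons, replace = TRUE)
  intron_len <- sample(600:1500, n_exons - 1L, replace = TRUE)
  cassette_off <- NA_integer_
  if (!is.null(cassette)) {
    host_intron <- min(host_intron, n_exons - 1L)
    clen <- nchar(cassette$seq)
    intron_len[host_intron] <- clen + sample(300:600, 1L)
    cassette_off <- sample(100:(intron_len[host_intron] - clen - 100L), 1L)
  }
  pieces <- character(0)
  starts <- integer(n_exons); ends <- integer(n_exons)
  pos <- 0L
  for (i in seq_len(n_exons)) {
    starts[i] <- pos
    pieces <- c(pieces, random_dna(exon_len[i]))
    pos <- pos + exon_len[i]
    ends[i] <- pos
    if (i < n_exons) {
      iseq <- random_dna(intron_len[i])
      if (!is.null(cassette) && i == host_intron) {
        substr(iseq, cassette_off + 1L,
               cassette_off + nchar(cassette$seq)) <- cassette$seq
      }
      pieces <- c(pieces, iseq)
      pos <- pos + intron_len[i]
    }
  }
  intron_starts <- ends[-n_exons]
  cass_rel <- if (is.null(cassette)) NA_integer_ else
    intron_starts[host_intron] + cassette_off
  list(seq = paste(pieces, collapse = ""), name = name, strand = strand,
       exon_starts = starts, exon_ends = ends,
       cassette_rel = cass_rel, host_intron = host_intron)
}

#' Simulate a genome with planted nested TE insertions
#'
#' Generates chromosome sequences, an rmsk-style repeat table, refGene-style
#' gene models, and a truth manifest recording every planted configuration.
#' Nested insertions are emitted as two host fragments sharing one `frag_id`
#' that flank the guest feature (the rmsk fragmentation signature); the
#' genome sequence carries the TSD copies and poly-A tail at each planted
#' locus. When `plant_splice_signals` is on, intronic antisense pairs carry
#' an AG acceptor in the guest, a downstream GT donor in the host, and a
#' branch-point heptamer 21-25 nt upstream of the AG.
#'
#' @param config A [simulation_config()] object.
#' @return A list of class `te_simulation` with elements `genome` (named
#'   character vector), `repeats` (repeat-feature data.frame, sorted by
#'   chromosome and start), `genes` (gene-model data.frame), `truth` (list
#'   with `planted_insertions`, `planted_exons`, `decoys`, `phyletic`),
#'   and `config`.
#' @export
simulate_te_genome <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  n_nested <- round(cfg$p_nested * min(cfg$n_guest_te, cfg$n_host_te))
  n_solo_host <- cfg$n_host_te - n_nested
  n_solo_guest <- cfg$n_guest_te - n_nested
  n_signal <- if (cfg$plant_splice_signals && cfg$exons_per_gene >= 2L)
    min(cfg$n_genes, n_nested) else 0L

  items <- list()
  # Nested cassettes: the first n_signal are intronic antisense pairs with
  # splice signals; the rest are intergenic with random strands.
  for (i in seq_len(n_nested)) {
    intronic <- i <= n_signal
    host_strand <- if (intronic) "-" else sample(c("+", "-"), 1L)
    guest_strand <- if (intronic) "-" else sample(c("+", "-"), 1L)
    cass <- build_nested_cassette(
      host_strand, guest_strand,
      tsd_len = sample(cfg$tsd_len_range[1]:cfg$tsd_len_range[2], 1L),
      polya_len = sample(cfg$polya_len_range[1]:cfg$polya_len_range[2], 1L),
      host_div = cfg$host_divergence, guest_div = cfg$guest_divergence,
      splice_signals = intronic)
    if (intronic) {
      items[[length(items) + 1L]] <- list(
        type = "gene", gene = build_gene_item(
          sprintf("NM_%06d", i), "+", cfg$exons_per_gene, cassette = cass),
        cassette = cass, insertion_id = i)
    } else {
      items[[length(items) + 1L]] <- list(type = "cassette", cassette = cass,
                                          insertion_id = i)
    }
  }
  for (i in seq_len(cfg$n_genes - n_signal)) {
    items[[length(items) + 1L]] <- list(
      type = "gene",
      gene = build_gene_item(sprintf("NM_%06d", n_signal + i),
                             sample(c("+", "-"), 1L), cfg$exons_per_gene))
  }
  for (i in seq_len(n_solo_host)) {
    items[[length(items) + 1L]] <-
      list(type = "solo", solo = build_standalone("host",
                                                  sample(c("+", "-"), 1L), cfg))
  }
  for (i in seq_len(n_solo_guest)) {
    items[[length(items) + 1L]] <-
      list(type = "solo", solo = build_standalone("guest",
                                                  sample(c("+", "-"), 1L), cfg))
  }

  # Assign items to chromosomes round-robin in random order, then lay each
  # chromosome out left to right with random gaps summing to chrom_len.
  if (length(items)) items <- items[sample.int(length(items))]
  chrom_of <- if (length(items))
    rep_len(seq_len(cfg$n_chroms), length(items)) else integer(0)

  genome <- character(cfg$n_chroms)
  names(genome) <- paste0("chr", seq_len(cfg$n_chroms))
  rep_rows <- list(); gene_rows <- list()
  ins_rows <- list(); exon_rows <- list(); decoy_rows <- list()
  frag_id <- 0L
  min_gap <- 60L

  for (cc in seq_len(cfg$n_chroms)) {
    idx <- which(chrom_of == cc)
    lens <- vapply(idx, function(j) nchar(
      if (items[[j]]$type == "gene") items[[j]]$gene$seq
      else if (items[[j]]$type == "cassette") items[[j]]$cassette$seq
      else items[[j]]$solo$seq), 0L)
    avail <- cfg$chrom_len - sum(lens)
    n_gap <- length(idx) + 1L
    if (avail < n_gap * min_gap)
      stop(sprintf("chromosome length %d too small to fit %d planted items",
                   cfg$chrom_len, length(idx)))
    w <- stats::runif(n_gap)
    gaps <- min_gap + floor((avail - n_gap * min_gap) * w / sum(w))
    gaps[n_gap] <- gaps[n_gap] + (avail - sum(gaps))
    chrom_name <- names(genome)[cc]
    pieces <- character(0)
    pos <- 0L
    for (k in seq_along(idx)) {
      pieces <- c(pieces, random_dna(gaps[k]))
      pos <- pos + gaps[k]
      it <- items[[idx[k]]]
      off <- pos
      if (it$type == "solo") {
        frag_id <- frag_id + 1L
        f <- it$solo$feats
        rep_rows[[length(rep_rows) + 1L]] <-
          abs_repeat_rows(f, off, chrom_name, frag_id,
                          milli_div = if (f$rep_name[1] == "MIR")
                            round(1000 * cfg$host_divergence) else
                            round(1000 * cfg$guest_divergence))
        decoy_rows[[length(decoy_rows) + 1L]] <- data.frame(
          chrom = chrom_name, start = off + f$start, end = off + f$end,
          rep_name = f$rep_name, strand = f$strand, stringsAsFactors = FALSE)
        pieces <- c(pieces, it$solo$seq)
        pos <- pos + nchar(it$solo$seq)
      } else {
        cass <- it$cassette
        gene <- if (it$type == "gene") it$gene else NULL
        cass_off <- if (!is.null(gene)) off + gene$cassette_rel else off
        if (!is.null(gene)) {
          n_ex <- length(gene$exon_starts)
          gene_rows[[length(gene_rows) + 1L]] <- data.frame(
            name = gene$name, name2 = gene$name, chrom = chrom_name,
            strand = gene$strand,
            tx_start = off, tx_end = off + nchar(gene$seq),
            cds_start = off + gene$exon_starts[1] + 9L,
            cds_end = off + gene$exon_ends[n_ex] - 9L,
            exon_count = n_ex,
            exon_starts = I(list(off + gene$exon_starts)),
            exon_ends = I(list(off + gene$exon_ends)),
            score = "0", cds_start_stat = "cmpl", cds_end_stat = "cmpl",
            exon_frames = paste0(paste(rep(-1L, n_ex), collapse = ","), ","),
            stringsAsFactors = FALSE)
        }
        if (!is.null(cass)) {
          host_id <- frag_id + 1L; guest_id <- frag_id + 2L
          frag_id <- frag_id + 2L
          f <- cass$feats
          ids <- ifelse(f$frag_key == "host", host_id, guest_id)
          mdv <- ifelse(f$frag_key == "host",
                        round(1000 * cfg$host_divergence),
                        round(1000 * cfg$guest_divergence))
          rep_rows[[length(rep_rows) + 1L]] <-
            abs_repeat_rows(f, cass_off, chrom_name, ids, milli_div = mdv)
          ins_rows[[length(ins_rows) + 1L]] <- data.frame(
            insertion_id = it$insertion_id, chrom = chrom_name,
            host_start = cass_off + cass$host_span[1],
            host_end = cass_off + cass$host_span[2],
            guest_start = cass_off + cass$guest_span[1],
            guest_end = cass_off + cass$guest_span[2],
            host_strand = f$strand[1], guest_strand = f$strand[2],
            relation = "nested", tsd = cass$tsd, tsd_len = cass$tsd_len,
            polya_len = cass$polya_len,
            host_frag_id = host_id, guest_frag_id = guest_id,
            gene = if (!is.null(gene)) gene$name else NA_character_,
            stringsAsFactors = FALSE)
          if (!is.null(cass$signals)) {
            exon_rows[[length(exon_rows) + 1L]] <- data.frame(
              gene = gene$name, chrom = chrom_name,
              intron_index = gene$host_intron,
              acceptor_pos = cass_off + cass$signals$acceptor_pos,
              donor_pos = cass_off + cass$signals$donor_pos,
              bp_pos = cass_off + cass$signals$bp_pos,
              stringsAsFactors = FALSE)
          }
        }
        body <- if (!is.null(gene)) gene$seq else cass$seq
        pieces <- c(pieces, body)
        pos <- pos + nchar(body)
      }
    }
    pieces <- c(pieces, random_dna(gaps[n_gap]))
    genome[cc] <- paste(pieces, collapse = "")
  }

  repeats <- if (length(rep_rows)) do.call(rbind, rep_rows)
             else empty_repeat_table()
  repeats <- repeats[order(repeats$chrom, repeats$start), , drop = FALSE]
  rownames(repeats) <- NULL
  genes <- if (length(gene_rows)) do.call(rbind, gene_rows)
           else empty_gene_table()
  rownames(genes) <- NULL
  truth <- list(
    planted_insertions = if (length(ins_rows)) do.call(rbind, ins_rows)
      else NULL,
    planted_exons = if (length(exon_rows)) do.call(rbind, exon_rows)
      else NULL,
    decoys = if (length(decoy_rows)) do.call(rbind, decoy_rows) else NULL,
    phyletic = NULL)
  # Each planted insertion is also assigned an origin branch on the packaged
  # primate fixture tree, for exercising the dating stage.
  if (!is.null(truth$planted_insertions)) {
    tree <- primate_fixture_tree()
    nodes <- c(seq_along(tree$tip.label),
               (length(tree$tip.label) + 1L):(length(tree$tip.label) +
                                              tree$Nnode))
    truth$phyletic <- data.frame(
      insertion_id = truth$planted_insertions$insertion_id,
      branch_child = sample(nodes, nrow(truth$planted_insertions),
                            replace = TRUE))
  }
  structure(list(genome = genome, repeats = repeats, genes = genes,
                 truth = truth, config = cfg),
            class = "te_simulation")
}

abs_repeat_rows <- function(f, off, chrom, frag_id, milli_div) {
  n <- nrow(f)
  data.frame(chrom = chrom, start = off + f$start, end = off + f$end,
             strand = f$strand, rep_name = f$rep_name,
             rep_class = f$rep_class, rep_family = f$rep_family,
             rep_start = 1L, rep_end = f$end - f$start,
             rep_left = -pmax(0L, f$rep_len - (f$end - f$start)),
             frag_id = as.integer(frag_id), milli_div = as.integer(milli_div),
             milli_del = 0L, milli_ins = 0L, sw_score = 1000L,
             geno_left = 0L, stringsAsFactors = FALSE)
}

#' Write a simulation's artifacts to disk
#'
#' Emits `genome.fa`, an rmsk-dialect `repeats.tsv`, a refGene-dialect
#' `genes.tsv`, and tab-separated truth-manifest tables
#' (`truth_insertions.tsv`, `truth_exons.tsv`, `truth_decoys.tsv`) with
#' header rows.
#'
#' @param sim A `te_simulation` from [simulate_te_genome()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "te_simulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_repeat_table(sim$repeats, file.path(dir, "repeats.tsv"))
  write_gene_table(sim$genes, file.path(dir, "genes.tsv"))
  wt <- function(df, f) if (!is.null(df))
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wt(sim$truth$planted_insertions, "truth_insertions.tsv")
  wt(sim$truth$planted_exons, "truth_exons.tsv")
  wt(sim$truth$decoys, "truth_decoys.tsv")
  invisible(dir)
}
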