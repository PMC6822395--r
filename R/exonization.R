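# Exonization-candidate prediction inside TE-derived intronic sequence:
# canonical splice-dinucleotide scanning on the gene's sense strand,
# acceptor/donor pairing into candidate exons (several acceptors sharing one
# donor give the multiple-variant situation), re-splicing of candidate
# transcripts, first-start ORF selection, and peptide-effect comparison.

#' Scan a region for canonical splice dinucleotides on the gene sense strand
#'
#' Finds every AG (3' splice acceptor) and GT (5' splice donor) read on the
#' gene's sense strand within `[start, end)`. For a minus-strand gene the
#' scan runs on the reverse complement, so an antisense TE can contribute
#' sites to the gene. Positions are reported as the 0-based genomic
#' coordinate of the lower base of the two-base footprint on the plus
#' strand.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param chrom,start,end Region to scan (0-based half-open).
#' @param gene_strand `"+"` or `"-"`: strand the dinucleotides are read on.
#' @return data.frame with `kind` (`acceptor_3ss`/`donor_5ss`), `pos`
#'   (footprint start), `dinucleotide`, `gene_strand`.
#' @export
scan_splice_sites <- function(genome, chrom, start, end, gene_strand = "+") {
  chrom_seq <- genome[[chrom]]
  if (is.null(chrom_seq)) stop("chromosome not in genome: ", chrom)
  stopifnot(start >= 0L, end <= nchar(chrom_seq), start < end,
            gene_strand %in% c("+", "-"))
  region <- substr(chrom_seq, start + 1L, end)
  sense <- if (gene_strand == "+") region else revcomp(region)
  hits <- function(motif) {
    m <- gregexpr(motif, sense, fixed = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m) - 1L  # 0-based sense pos
  }
  to_genomic <- function(i) {
    if (gene_strand == "+") start + i else end - i - 2L
  }
  ag <- hits("AG"); gt <- hits("GT")
  out <- data.frame(
    kind = c(rep("acceptor_3ss", length(ag)), rep("donor_5ss", length(gt))),
    pos = c(to_genomic(ag), to_genomic(gt)),
    dinucleotide = c(rep("AG", length(ag)), rep("GT", length(gt))),
    gene_strand = rep(gene_strand, length(ag) + length(gt)),
    stringsAsFactors = FALSE)
  out <- out[order(out$pos, out$kind), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pair splice sites into candidate exons
#'
#' All (acceptor, donor) pairs with the acceptor upstream of the donor in
#' transcript orientation and exon length within bounds become candidates;
#' several acceptors sharing one donor yield several candidates differing
#' only at their 5' end (the two-variant situation). The candidate exon is
#' the genomic interval strictly between the two dinucleotide footprints.
#'
#' @param sites Splice-site data.frame from [scan_splice_sites()], or a
#'   subset thereof.
#' @param intron Optional genomic interval `c(start, end)` the sites must
#'   lie in.
#' @param min_len,max_len Exon length bounds in bp (defaults 25 and 500).
#' @return data.frame with `acceptor_pos`, `donor_pos`, `exon_start`,
#'   `exon_end`, `length`, `gene_strand`, `label` (per shared donor, the
#'   longest candidate is `"V1-like"`, the next `"V2-like"`).
#' @export
enumerate_candidates <- function(sites, intron = NULL, min_len = 25L,
                                 max_len = 500L) {
  acc <- sites[sites$kind == "acceptor_3ss", , drop = FALSE]
  don <- sites[sites$kind == "donor_5ss", , drop = FALSE]
  if (!is.null(intron)) {
    keep <- function(df) df[df$pos >= intron[1] & df$pos + 2L <= intron[2], ,
                            drop = FALSE]
    acc <- keep(acc); don <- keep(don)
  }
  rows <- list()
  for (i in seq_len(nrow(acc))) for (j in seq_len(nrow(don))) {
    strand <- acc$gene_strand[i]
    if (strand == "+") {
      exon_start <- acc$pos[i] + 2L; exon_end <- don$pos[j]
    } else {
      exon_start <- don$pos[j] + 2L; exon_end <- acc$pos[i]
    }
    len <- exon_end - exon_start
    if (len < min_len || len > max_len) next
    rows[[length(rows) + 1L]] <- data.frame(
      acceptor_pos = acc$pos[i], donor_pos = don$pos[j],
      exon_start = exon_start, exon_end = exon_end, length = len,
      gene_strand = strand, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(acceptor_pos = integer(), donor_pos = integer(),
                      exon_start = integer(), exon_end = integer(),
                      length = integer(), gene_strand = character(),
                      label = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  res <- res[order(res$donor_pos, -res$length), , drop = FALSE]
  res$label <- NA_character_
  for (d in unique(res$donor_pos)) {
    ix <- which(res$donor_pos == d)
    if (length(ix) >= 1L) res$label[ix[1]] <- "V1-like"
    if (length(ix) >= 2L) res$label[ix[2]] <- "V2-like"
  }
  rownames(res) <- NULL
  res
}

#' Extract a spliced transcript sequence from a gene model
#'
#' @param gene One-row gene model.
#' @param genome Named character vector of chromosome sequences.
#' @return The mRNA sequence (reverse-complemented for minus-strand genes).
#' @export
transcript_seq <- function(gene, genome) {
  chrom_seq <- genome[[gene$chrom]]
  starts <- gene$exon_starts[[1]]; ends <- gene$exon_ends[[1]]
  ex <- substring(chrom_seq, starts + 1L, ends)
  mrna <- paste(ex, collapse = "")
  if (gene$strand == "-") revcomp(mrna) else mrna
}

#' Splice a candidate exon into a reference gene model
#'
#' Inserts the candidate exon at its genomic position between the two
#' reference exons flanking its intron and re-splices the mRNA from the
#' genome. Errors if the candidate does not fall inside any reference
#' intron.
#'
#' @param gene One-row gene model.
#' @param candidate One row of [enumerate_candidates()] output.
#' @param genome Named character vector of chromosome sequences.
#' @return A `transcript_model` list: `exon_starts`, `exon_ends`, `chrom`,
#'   `strand`, `mrna`, `inserted_ordinal` (transcript-order position of the
#'   new exon), `reference_name`.
#' @export
splice_in <- function(gene, candidate, genome) {
  starts <- gene$exon_starts[[1]]; ends <- gene$exon_ends[[1]]
  n <- length(starts)
  j <- which(ends[-n] <= candidate$exon_start &
             candidate$exon_end <= starts[-1])
  if (length(j) != 1L)
    stop("candidate exon is not inside any intron of ", gene$name)
  new_starts <- append(starts, candidate$exon_start, after = j)
  new_ends <- append(ends, candidate$exon_end, after = j)
  tm <- list(exon_starts = new_starts, exon_ends = new_ends,
             chrom = gene$chrom, strand = gene$strand,
             inserted_ordinal = if (gene$strand == "+") j + 1L
                                else (n + 1L) - j,
             reference_name = gene$name)
  tm$mrna <- transcript_seq(
    data.frame(chrom = gene$chrom, strand = gene$strand,
               exon_starts = I(list(new_starts)),
               exon_ends = I(list(new_ends)), stringsAsFactors = FALSE),
    genome)
  class(tm) <- "transcript_model"
  tm
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Find the first-starting open reading frame of an mRNA
#'
#' Among all ATG-initiated reading frames that reach an in-frame stop, the
#' one whose ATG is 5'-most is selected (sense strand only, standard
#' genetic code). The reported peptide excludes the stop codon.
#'
#' @param mrna Nucleotide string (length >= 6).
#' @return List with `has_orf`, `orf_start` (0-based position of the A of
#'   ATG), `orf_end` (0-based exclusive, including the stop codon),
#'   `nt_length`, `peptide`, `length_aa`.
#' @export
find_first_orf <- function(mrna) {
  stopifnot(nchar(mrna) >= 6L)
  mrna <- toupper(mrna)
  m <- gregexpr("ATG", mrna, fixed = TRUE)[[1]]
  none <- list(has_orf = FALSE, orf_start = NA_integer_,
               orf_end = NA_integer_, nt_length = NA_integer_,
               peptide = NA_character_, length_aa = NA_integer_)
  if (m[1] == -1L) return(none)
  L <- nchar(mrna)
  for (s in as.integer(m)) {           # 1-based ATG position, ascending
    cod_starts <- seq.int(s, L - 2L, by = 3L)
    codons <- substring(mrna, cod_starts, cod_starts + 2L)
    stop_i <- which(codons %in% STOP_CODONS)
    if (length(stop_i) == 0L) next
    k <- stop_i[1]
    orf_nt <- substr(mrna, s, s + 3L * k - 1L)
    pep <- translate_nt(substr(orf_nt, 1L, nchar(orf_nt) - 3L))
    return(list(has_orf = TRUE, orf_start = s - 1L,
                orf_end = s - 1L + 3L * k, nt_length = 3L * k,
                peptide = pep, length_aa = k - 1L))
  }
  none
}

#' Compare a variant peptide against a reference
#'
#' Reports the first differing amino-acid position, the shared-prefix
#' length, and whether the variant carries a premature stop: it terminates
#' earlier than the reference, or it diverges within the reference span so
#' its C-terminus derives from a new stop codon.
#'
#' @param reference,variant Amino-acid strings.
#' @return List with `identical`, `divergence_point` (1-based, `NA` when
#'   identical or when one peptide merely extends the other ... see
#'   details), `shared_prefix`, `premature_stop`.
#' @export
compare_peptides <- function(reference, variant) {
  if (identical(reference, variant))
    return(list(identical = TRUE, divergence_point = NA_integer_,
                shared_prefix = nchar(reference), premature_stop = FALSE))
  a <- strsplit(reference, "")[[1]]; b <- strsplit(variant, "")[[1]]
  k <- min(length(a), length(b))
  mism <- which(a[seq_len(k)] != b[seq_len(k)])
  d <- if (length(mism)) mism[1] else k + 1L
  shared <- d - 1L
  premature <- (length(b) < length(a)) || (d <= length(a))
  list(identical = FALSE, divergence_point = as.integer(d),
       shared_prefix = as.integer(shared), premature_stop = premature)
}

#' Write candidate exons as GFF3
#'
#' @param candidates data.frame from [enumerate_candidates()] plus a
#'   `chrom` column (recycled if length 1).
#' @param path Output path.
#' @param chrom Chromosome name used when `candidates` lacks a `chrom`
#'   column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(candidates, path, chrom = NULL) {
  chr <- if (!is.null(candidates$chrom)) candidates$chrom else chrom
  stopifnot(!is.null(chr))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(candidates)) {
    lines <- sprintf(
      "%s\tnestedTE\texon\t%d\t%d\t.\t%s\t.\tID=cand%d;label=%s",
      chr, candidates$exon_start + 1L, candidates$exon_end,
      candidates$gene_strand, seq_len(nrow(candidates)),
      ifelse(is.na(candidates$label), ".", candidates$label))
    writeLines(lines, con)
  }
  invisible(path)
}
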