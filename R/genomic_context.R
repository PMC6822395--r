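# Classification of TE combinations against gene models: intergenic vs
# intragenic, and intronic vs exon-overlapping, with strand-aware intron
# ordinals (the "4th intron" of a gene is counted in transcription order).

#' Intron ordinal containing a genomic position
#'
#' Returns the 1-based intron index in transcription order: for a minus
#' strand gene, intron 1 abuts the 5'-most exon in transcript order, i.e.
#' the genomically last exon. Positions inside an exon, or outside the
#' transcript span, return `NA`.
#'
#' @param gene One-row gene model (list or data.frame row with `strand`,
#'   `tx_start`, `tx_end`, and exon list columns).
#' @param position 0-based genomic position (bp).
#' @param transcription_order Index introns 5'→3' along the transcript
#'   (default); `FALSE` gives genomic left-to-right order.
#' @return Integer intron index, or `NA`.
#' @export
intron_of <- function(gene, position, transcription_order = TRUE) {
  starts <- gene$exon_starts[[1]]
  ends <- gene$exon_ends[[1]]
  if (position < gene$tx_start || position >= gene$tx_end)
    return(NA_integer_)
  if (any(position >= starts & position < ends)) return(NA_integer_)
  j <- sum(ends <= position)  # genomic intron index
  if (j < 1L || j > length(starts) - 1L) return(NA_integer_)
  n_introns <- length(starts) - 1L
  if (transcription_order && gene$strand == "-") n_introns - j + 1L else j
}

#' Classify TE combinations by genomic context
#'
#' A combination span (the outer envelope of host and guest) is
#' `intragenic` when fully contained in a gene's transcript interval;
#' within a gene it is `intragenic_intronic` when it overlaps no exon of
#' that gene (with the containing intron's transcription-order ordinal
#' reported) and `intragenic_exon_overlap` otherwise. Combinations
#' contained in no gene — including those on chromosomes absent from the
#' gene table, which are noted via a message — are `intergenic`. When
#' several genes contain a combination, one call is emitted per gene.
#'
#' @param combos Combination data.frame from [find_combinations()].
#' @param genes Gene-model data.frame from [read_gene_table()].
#' @param transcription_order Passed to [intron_of()].
#' @return A data.frame with `combo` (row index into `combos`), `chrom`,
#'   `start`, `end`, `status`, `gene`, `intron_index`.
#' @export
classify_context <- function(combos, genes, transcription_order = TRUE) {
  n <- nrow(combos)
  calls <- list()
  gene_chroms <- unique(genes$chrom)
  for (i in seq_len(n)) {
    span_start <- min(combos$host_start[i], combos$guest_start[i])
    span_end <- max(combos$host_end[i], combos$guest_end[i])
    chrom <- combos$chrom[i]
    if (!(chrom %in% gene_chroms) && nrow(genes) > 0L)
      message("chromosome ", chrom,
              " absent from gene table; classified intergenic")
    hit <- which(genes$chrom == chrom & genes$tx_start <= span_start &
                 span_end <= genes$tx_end)
    if (length(hit) == 0L) {
      calls[[length(calls) + 1L]] <- data.frame(
        combo = i, chrom = chrom, start = span_start, end = span_end,
        status = "intergenic", gene = NA_character_,
        intron_index = NA_integer_, stringsAsFactors = FALSE)
      next
    }
    for (g in hit) {
      starts <- genes$exon_starts[[g]]
      ends <- genes$exon_ends[[g]]
      exon_overlap <- any(pmax(starts, span_start) < pmin(ends, span_end))
      if (exon_overlap) {
        status <- "intragenic_exon_overlap"
        idx <- NA_integer_
      } else {
        status <- "intragenic_intronic"
        idx <- intron_of(genes[g, ], span_start,
                         transcription_order = transcription_order)
      }
      calls[[length(calls) + 1L]] <- data.frame(
        combo = i, chrom = chrom, start = span_start, end = span_end,
        status = status, gene = genes$name[g], intron_index = idx,
        stringsAsFactors = FALSE)
    }
  }
  if (length(calls) == 0L)
    return(data.frame(combo = integer(), chrom = character(),
                      start = integer(), end = integer(),
                      status = character(), gene = character(),
                      intron_index = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, calls)
  rownames(res) <- NULL
  res
}
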