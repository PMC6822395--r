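# Readers and writers for the annotation and sequence formats consumed by the
# rest of the package. One coordinate convention everywhere: 0-based,
# half-open intervals, as in the UCSC rmsk/refGene/BED dialects. Conversion to
# 1-based closed coordinates happens only at report boundaries.

RMSK_COLS <- c("sw_score", "milli_div", "milli_del", "milli_ins",
               "chrom", "start", "end", "geno_left", "strand",
               "rep_name", "rep_class", "rep_family",
               "rep_start", "rep_end", "rep_left", "frag_id")

REFGENE_COLS <- c("name", "chrom", "strand", "tx_start", "tx_end",
                  "cds_start", "cds_end", "exon_count",
                  "exon_starts_str", "exon_ends_str", "score", "name2",
                  "cds_start_stat", "cds_end_stat", "exon_frames")

#' Read a RepeatMasker annotation table (UCSC rmsk dialect)
#'
#' Parses the tab-separated `rmsk.txt` table dumped by the UCSC browser, with
#' or without the leading `bin` column (autodetected from the column count).
#' Gzip-compressed files are read transparently. Coordinates are kept 0-based
#' half-open, exactly as stored in the table.
#'
#' @param path Path to an `rmsk.txt` or `rmsk.txt.gz` file.
#' @return A data.frame of repeat features with columns `chrom`, `start`,
#'   `end`, `strand`, `rep_name`, `rep_class`, `rep_family`, `rep_start`,
#'   `rep_end`, `rep_left`, `frag_id`, `milli_div` (divergence from the repeat
#'   consensus in per mil) plus the remaining rmsk score columns. The rmsk
#'   `id` column, which links fragments of one original insertion, is kept as
#'   `frag_id`.
#' @export
read_repeat_table <- function(path) {
  lines <- read_table_lines(path)
  if (length(lines) == 0L) return(empty_repeat_table())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  ok <- nf == 16L | nf == 17L
  if (any(!ok)) {
    stop(sprintf("malformed rmsk line %d: expected 16 or 17 columns, found %d",
                 which(!ok)[1], nf[which(!ok)[1]]))
  }
  has_bin <- nf[1] == 17L
  if (any(nf != nf[1]))
    stop(sprintf("malformed rmsk line %d: inconsistent column count",
                 which(nf != nf[1])[1]))
  m <- do.call(rbind, fields)
  if (has_bin) m <- m[, -1, drop = FALSE]
  colnames(m) <- RMSK_COLS
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  int_cols <- c("sw_score", "milli_div", "milli_del", "milli_ins",
                "start", "end", "geno_left", "rep_start", "rep_end",
                "rep_left", "frag_id")
  for (cc in int_cols) df[[cc]] <- as.integer(df[[cc]])
  df$strand <- normalize_strand(df$strand)
  bad <- which(!(df$start >= 0L & df$start < df$end))
  if (length(bad))
    stop(sprintf("invalid interval on rmsk line %d: start=%d end=%d",
                 bad[1], df$start[bad[1]], df$end[bad[1]]))
  df[, c("chrom", "start", "end", "strand", "rep_name", "rep_class",
         "rep_family", "rep_start", "rep_end", "rep_left", "frag_id",
         "milli_div", "milli_del", "milli_ins", "sw_score", "geno_left")]
}

empty_repeat_table <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), rep_name = character(),
             rep_class = character(), rep_family = character(),
             rep_start = integer(), rep_end = integer(),
             rep_left = integer(), frag_id = integer(),
             milli_div = integer(), milli_del = integer(),
             milli_ins = integer(), sw_score = integer(),
             geno_left = integer(), stringsAsFactors = FALSE)
}

normalize_strand <- function(s) {
  # rmsk dumps use "+"/"-"; RepeatMasker .out files use "C" for the
  # complement strand, accepted here as a synonym.
  s[s == "C"] <- "-"
  bad <- which(!s %in% c("+", "-"))
  if (length(bad))
    stop(sprintf("unknown strand symbol %s on line %d",
                 dQuote(s[bad[1]]), bad[1]))
  s
}

read_table_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Write a repeat table in the rmsk dialect
#'
#' Inverse of [read_repeat_table()]: writes the 16-column (no `bin`)
#' tab-separated rmsk layout, so that write followed by read reproduces the
#' input field-for-field.
#'
#' @param features Repeat feature data.frame as returned by
#'   [read_repeat_table()].
#' @param path Output path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
write_repeat_table <- function(features, path) {
  out <- features[, RMSK_COLS]
  write_tsv_plain(out, path)
}

#' Read a gene-model table (UCSC refGene dialect)
#'
#' Parses the tab-separated `refGene.txt` table (with or without the leading
#' `bin` column; autodetected), expanding the comma-terminated
#' `exonStarts`/`exonEnds` strings into integer list columns. Exon invariants
#' (equal list lengths, sorted non-overlapping intervals inside the
#' transcript span) are validated on read.
#'
#' @param path Path to a `refGene.txt` or `refGene.txt.gz` file.
#' @return A data.frame with columns `name`, `name2`, `chrom`, `strand`,
#'   `tx_start`, `tx_end`, `cds_start`, `cds_end`, `exon_count`, and list
#'   columns `exon_starts`, `exon_ends` (0-based half-open).
#' @export
read_gene_table <- function(path) {
  lines <- read_table_lines(path)
  if (length(lines) == 0L) return(empty_gene_table())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  ok <- nf == 15L | nf == 16L
  if (any(!ok))
    stop(sprintf("malformed refGene line %d: expected 15 or 16 columns, found %d",
                 which(!ok)[1], nf[which(!ok)[1]]))
  has_bin <- nf[1] == 16L
  m <- do.call(rbind, fields)
  if (has_bin) m <- m[, -1, drop = FALSE]
  colnames(m) <- REFGENE_COLS
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  for (cc in c("tx_start", "tx_end", "cds_start", "cds_end", "exon_count"))
    df[[cc]] <- as.integer(df[[cc]])
  df$exon_starts <- parse_coord_list(df$exon_starts_str)
  df$exon_ends <- parse_coord_list(df$exon_ends_str)
  for (i in seq_len(nrow(df))) {
    validate_gene_model(df$exon_starts[[i]], df$exon_ends[[i]],
                        df$exon_count[i], df$tx_start[i], df$tx_end[i],
                        df$cds_start[i], df$cds_end[i], line = i)
  }
  df$exon_starts_str <- NULL
  df$exon_ends_str <- NULL
  df[, c("name", "name2", "chrom", "strand", "tx_start", "tx_end",
         "cds_start", "cds_end", "exon_count", "exon_starts", "exon_ends",
         "score", "cds_start_stat", "cds_end_stat", "exon_frames")]
}

empty_gene_table <- function() {
  data.frame(name = character(), name2 = character(), chrom = character(),
             strand = character(), tx_start = integer(), tx_end = integer(),
             cds_start = integer(), cds_end = integer(),
             exon_count = integer(),
             exon_starts = I(list()), exon_ends = I(list()),
             score = character(), cds_start_stat = character(),
             cds_end_stat = character(), exon_frames = character(),
             stringsAsFactors = FALSE)
}

parse_coord_list <- function(s) {
  I(lapply(strsplit(sub(",$", "", s), ",", fixed = TRUE),
           function(x) as.integer(x)))
}

validate_gene_model <- function(starts, ends, n, tx_start, tx_end,
                                cds_start, cds_end, line = NA) {
  where <- if (is.na(line)) "" else sprintf(" (line %d)", line)
  if (length(starts) != length(ends) || length(starts) != n)
    stop("exon list length mismatch", where)
  if (length(starts) < 1L) stop("gene model must have at least one exon", where)
  if (any(ends <= starts)) stop("empty or inverted exon interval", where)
  if (is.unsorted(starts, strictly = TRUE) ||
      any(starts[-1] < ends[-length(ends)]))
    stop("exons not sorted or overlapping", where)
  if (starts[1] < tx_start || ends[length(ends)] > tx_end)
    stop("exons outside transcript span", where)
  if (cds_start > cds_end) stop("cds_start > cds_end", where)
  invisible(TRUE)
}

#' Write a gene-model table in the refGene dialect
#'
#' Inverse of [read_gene_table()]; exon list columns are serialized back to
#' comma-terminated strings.
#'
#' @param genes Gene-model data.frame as returned by [read_gene_table()].
#' @param path Output path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  comma <- function(l) vapply(l, function(x) paste0(paste(x, collapse = ","), ","), "")
  out <- data.frame(name = genes$name, chrom = genes$chrom,
                    strand = genes$strand,
                    tx_start = genes$tx_start, tx_end = genes$tx_end,
                    cds_start = genes$cds_start, cds_end = genes$cds_end,
                    exon_count = genes$exon_count,
                    exon_starts = comma(genes$exon_starts),
                    exon_ends = comma(genes$exon_ends),
                    score = genes$score, name2 = genes$name2,
                    cds_start_stat = genes$cds_start_stat,
                    cds_end_stat = genes$cds_end_stat,
                    exon_frames = genes$exon_frames,
                    stringsAsFactors = FALSE)
  write_tsv_plain(out, path)
}

write_tsv_plain <- function(df, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path Path to a FASTA file (optionally gzipped).
#' @param on_invalid What to do with characters outside `A,C,G,T,N`:
#'   `"error"` rejects the file, `"mask"` replaces them with `N`.
#' @return Named character vector of upper-case sequences; names are the
#'   FASTA identifiers (first whitespace-delimited token).
#' @export
read_fasta <- function(path, on_invalid = c("error", "mask")) {
  on_invalid <- match.arg(on_invalid)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) stop("empty sequence in FASTA: ", path)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    if (on_invalid == "error")
      stop("non-ACGTN characters in FASTA record ", ids[which(bad)[1]])
    seqs <- gsub("[^ACGTN]", "N", seqs)
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write genomic features as BED6
#'
#' Emits `chrom`, `start`, `end`, `name`, `score`, `strand` with 0-based
#' half-open coordinates (the native BED convention).
#'
#' @param features data.frame with `chrom`, `start`, `end`, `strand`, and
#'   either `name` or `rep_name` for the name column.
#' @param path Output path.
#' @param score Score column value(s); default 0.
#' @return `path`, invisibly.
#' @export
write_bed <- function(features, path, score = 0L) {
  name <- if (!is.null(features$name)) features$name
          else if (!is.null(features$rep_name)) features$rep_name
          else "."
  out <- data.frame(chrom = features$chrom,
                    start = features$start, end = features$end,
                    name = name, score = score, strand = features$strand,
                    stringsAsFactors = FALSE)
  write_tsv_plain(out, path)
}

#' Convert 0-based half-open coordinates to 1-based closed (and back)
#'
#' Report-boundary helpers. `coords_to_1based()` maps an internal interval
#' `[start, end)` to the inclusive `start+1 .. end` convention used in
#' human-readable reports; `coords_to_0based()` is its inverse.
#'
#' @param df data.frame with integer `start` and `end` columns.
#' @return The data.frame with shifted coordinates.
#' @export
coords_to_1based <- function(df) {
  df$start <- df$start + 1L
  df
}

#' @rdname coords_to_1based
#' @export
coords_to_0based <- function(df) {
  df$start <- df$start - 1L
  df
}
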