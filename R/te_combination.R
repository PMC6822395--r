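# Core detection of combined ("together") TE configurations from
# repeat-annotation tables: reassembly of fragmented repeats via the rmsk
# linkage id, nested/adjacent pair extraction, orientation concordance, and
# the sequence hallmarks of target-primed reverse transcription (TSD and
# poly-A tail).

#' Reassemble annotation rows into repeat elements
#'
#' RepeatMasker splits one original insertion into several rows when a later
#' insertion interrupts it; rows of one insertion share the table's linkage
#' `id` (here `frag_id`). Rows are grouped by
#' `(chrom, frag_id, rep_name, strand)` into elements whose span is the
#' outer envelope of their fragments.
#'
#' @param repeats Repeat-feature data.frame (see [read_repeat_table()]).
#' @return A data.frame of elements with columns `chrom`, `start`, `end`
#'   (outer span), `strand`, `rep_name`, `rep_class`, `rep_family`,
#'   `frag_id`, `n_fragments`, `is_fragmented`, and a list column
#'   `fragments` holding each element's row intervals sorted by start.
#' @export
assemble_elements <- function(repeats) {
  if (nrow(repeats) == 0L) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      rep_name = character(), rep_class = character(),
                      rep_family = character(), frag_id = integer(),
                      n_fragments = integer(), is_fragmented = logical(),
                      stringsAsFactors = FALSE)
    out$fragments <- list()
    return(out)
  }
  key <- paste(repeats$chrom, repeats$frag_id, repeats$rep_name,
               repeats$strand, sep = "\r")
  groups <- split(seq_len(nrow(repeats)), key)
  rows <- lapply(groups, function(ix) {
    r <- repeats[ix, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    if (nrow(r) > 1L && any(r$start[-1] < r$end[-nrow(r)]))
      warning(sprintf("overlapping fragments for frag_id %d on %s; merged span kept",
                      r$frag_id[1], r$chrom[1]))
    data.frame(chrom = r$chrom[1], start = min(r$start), end = max(r$end),
               strand = r$strand[1], rep_name = r$rep_name[1],
               rep_class = r$rep_class[1], rep_family = r$rep_family[1],
               frag_id = r$frag_id[1], n_fragments = nrow(r),
               is_fragmented = nrow(r) > 1L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  frags <- lapply(groups, function(ix) {
    r <- repeats[ix, c("start", "end"), drop = FALSE]
    r[order(r$start), , drop = FALSE]
  })
  out$fragments <- frags
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count repeats by class and family
#'
#' Reports both element counts (fragments sharing one `frag_id` counted
#' once) and raw row counts for: all TEs, SINEs, AluSp elements, and MIR
#' elements.
#'
#' @param repeats Repeat-feature data.frame.
#' @return A list with integer vectors `elements` and `rows`, each with
#'   entries `total`, `SINE`, `AluSp`, `MIR`.
#' @export
count_repeat_classes <- function(repeats) {
  tally <- function(df) c(total = nrow(df),
                          SINE = sum(df$rep_class == "SINE"),
                          AluSp = sum(df$rep_name == "AluSp"),
                          MIR = sum(df$rep_name == "MIR"))
  list(elements = tally(assemble_elements(repeats)), rows = tally(repeats))
}

matches_query <- function(elements, query) {
  hit <- elements$rep_name == query | elements$rep_family == query
  if (!any(hit) && nrow(elements) > 0L)
    stop(sprintf("unknown query %s; available names: %s; families: %s",
                 dQuote(query),
                 paste(sort(unique(elements$rep_name)), collapse = ", "),
                 paste(sort(unique(elements$rep_family)), collapse = ", ")))
  hit
}

#' Find combined host/guest TE configurations
#'
#' Detects every pair in which a guest element and a host element are
#' together: `nested` pairs, where the guest lies strictly inside the outer
#' span of a fragmented host (fragments linked by `frag_id`), and
#' `adjacent` pairs, where the two assembled elements are consecutive on
#' the chromosome with a gap of at most `max_gap` bp. A pair is reported at
#' most once, nesting taking precedence.
#'
#' @param elements Assembled elements from [assemble_elements()].
#' @param query_host,query_guest Repeat name (e.g. `"MIR"`, `"AluSp"`) or
#'   family (e.g. `"Alu"`); exact, case-sensitive match against either
#'   column.
#' @param max_gap Maximum gap (bp) for the adjacent relation; default 0
#'   (touching).
#' @return A data.frame with one row per combination: `chrom`,
#'   `host_start`, `host_end`, `guest_start`, `guest_end`, `host_strand`,
#'   `guest_strand`, `host_name`, `guest_name`, `host_frag_id`,
#'   `guest_frag_id`, `relation`, `gap`, `same_orientation`.
#' @export
find_combinations <- function(elements, query_host = "MIR",
                              query_guest = "AluSp", max_gap = 0L) {
  stopifnot(max_gap >= 0L)
  hosts <- elements[matches_query(elements, query_host), , drop = FALSE]
  guests <- elements[matches_query(elements, query_guest), , drop = FALSE]
  out <- list()
  seen <- character(0)
  add <- function(h, g, relation, gap) {
    key <- paste(h$frag_id, g$frag_id, sep = "/")
    if (key %in% seen) return()
    seen <<- c(seen, key)
    out[[length(out) + 1L]] <<- data.frame(
      chrom = h$chrom, host_start = h$start, host_end = h$end,
      guest_start = g$start, guest_end = g$end,
      host_strand = h$strand, guest_strand = g$strand,
      host_name = h$rep_name, guest_name = g$rep_name,
      host_frag_id = h$frag_id, guest_frag_id = g$frag_id,
      relation = relation, gap = as.integer(gap),
      same_orientation = h$strand == g$strand, stringsAsFactors = FALSE)
  }
  # Nested: guest strictly inside the outer span of a fragmented host.
  for (i in seq_len(nrow(hosts))) {
    h <- hosts[i, ]
    if (!h$is_fragmented) next
    hit <- which(guests$chrom == h$chrom & guests$frag_id != h$frag_id &
                 guests$start > h$start & guests$end < h$end)
    for (j in hit) add(h, guests[j, ], "nested", 0L)
  }
  # Adjacent: consecutive assembled elements with gap <= max_gap. Ordering
  # is by element start per chromosome over all assembled elements.
  for (chrom in unique(elements$chrom)) {
    e <- elements[elements$chrom == chrom, , drop = FALSE]
    e <- e[order(e$start, e$end), , drop = FALSE]
    if (nrow(e) < 2L) next
    for (i in seq_len(nrow(e) - 1L)) {
      a <- e[i, ]; b <- e[i + 1L, ]
      gap <- b$start - a$end
      if (gap < 0L || gap > max_gap) next
      amatch_h <- a$rep_name == query_host | a$rep_family == query_host
      bmatch_g <- b$rep_name == query_guest | b$rep_family == query_guest
      amatch_g <- a$rep_name == query_guest | a$rep_family == query_guest
      bmatch_h <- b$rep_name == query_host | b$rep_family == query_host
      if (amatch_h && bmatch_g) add(a, b, "adjacent", gap)
      else if (amatch_g && bmatch_h) add(b, a, "adjacent", gap)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), host_start = integer(),
                      host_end = integer(), guest_start = integer(),
                      guest_end = integer(), host_strand = character(),
                      guest_strand = character(), host_name = character(),
                      guest_name = character(), host_frag_id = integer(),
                      guest_frag_id = integer(), relation = character(),
                      gap = integer(), same_orientation = logical(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$host_start, res$guest_start), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Orientation concordance of detected combinations
#'
#' @param combos Combination data.frame from [find_combinations()] (only
#'   the logical `same_orientation` column is used).
#' @return List with `total`, `same_orientation`, and `percent_same`
#'   (`round(100 * same / total)`; `NA` when `total` is 0).
#' @export
orientation_summary <- function(combos) {
  total <- nrow(combos)
  same <- sum(combos$same_orientation)
  list(total = total, same_orientation = same,
       percent_same = if (total == 0L) NA_real_
                      else round(100 * same / total))
}

#' Detect TPRT hallmarks around an element
#'
#' Searches for a target-site duplication — the longest exact (or
#' `max_mismatch`-tolerant) match between the sequence directly in front of
#' and directly behind the element, with length in `[min_len, max_len]` —
#' and measures the poly-A tail at the element's 3' end (a T-tract at the
#' genomic start for minus-strand elements). The tail is the maximal
#' terminal segment under an A-rich score (+1 per A, -4 per other base, so
#' any reported tract is at least 80% A); tracts shorter than
#' `min_polya` report 0. TSDs shorter than `confidence_len` are flagged
#' low-confidence, reflecting that very short flanking matches (the 2-20 bp
#' rule admits candidates of only 3 nt) may arise by chance.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param element One-row element (or any object with `chrom`, `start`,
#'   `end`, `strand`).
#' @param max_len,min_len TSD length bounds (default 20 and 2, the
#'   published TSD length rule).
#' @param max_mismatch Mismatches tolerated in the duplication (default 0).
#' @param min_polya Minimum reportable tail length (default 8).
#' @param confidence_len TSDs shorter than this are flagged (default 5).
#' @return List with `tsd` (string or `NA`), `tsd_len`, `tsd_mismatches`,
#'   `low_confidence`, `polya_len`.
#' @export
detect_tsd <- function(genome, element, max_len = 20L, min_len = 2L,
                       max_mismatch = 0L, min_polya = 8L,
                       confidence_len = 5L) {
  chrom_seq <- genome[[element$chrom]]
  if (is.null(chrom_seq)) stop("chromosome not in genome: ", element$chrom)
  s <- element$start; e <- element$end
  if (s < max_len || e + max_len > nchar(chrom_seq))
    stop("insufficient flank around element for TSD search")
  left <- substr(chrom_seq, s - max_len + 1L, s)
  right <- substr(chrom_seq, e + 1L, e + max_len)
  tsd <- NA_character_; tsd_len <- 0L; mism <- NA_integer_
  for (k in max_len:min_len) {
    a <- strsplit(substr(left, max_len - k + 1L, max_len), "")[[1]]
    b <- strsplit(substr(right, 1L, k), "")[[1]]
    mm <- sum(a != b)
    if (mm <= max_mismatch) {
      tsd <- substr(right, 1L, k); tsd_len <- k; mism <- mm
      break
    }
  }
  elem_seq <- substr(chrom_seq, s + 1L, e)
  polya <- polya_tail_length(elem_seq, element$strand, min_len = min_polya)
  list(tsd = tsd, tsd_len = tsd_len, tsd_mismatches = mism,
       low_confidence = !is.na(tsd) && tsd_len < confidence_len,
       polya_len = polya)
}

# Max-scoring terminal A-tract (T-tract at the start for "-" strand):
# score +1 per A, -4 per other base, scanned up to max_scan bases inward;
# ties go to the shorter tract.
polya_tail_length <- function(elem_seq, strand, min_len = 8L,
                              max_scan = 50L) {
  chars <- strsplit(elem_seq, "", fixed = TRUE)[[1]]
  if (strand == "-") {
    chars <- chars[seq_len(min(max_scan, length(chars)))]
    target <- "T"
  } else {
    chars <- rev(chars)[seq_len(min(max_scan, length(chars)))]
    target <- "A"
  }
  score <- cumsum(ifelse(chars == target, 1L, -4L))
  best <- which.max(score)
  if (score[best] < 1L) return(0L)
  len <- as.integer(best)
  if (len < min_len) 0L else len
}
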