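# Branch-point scoring: a position-weight-matrix over a 7-nt window whose
# 6th position is the branch adenosine, combined with a distance prior that
# is maximal 21-25 nt upstream of the 3' splice site and a polypyrimidine-
# tract term. This is a fully specified, reproducible scorer in the spirit
# of the published BP predictors, not a reimplementation of any of them.

# Mammalian-consensus-style base frequencies for the 7-nt window
# (yUnAy-like, branch adenosine at position 6).
BP_FREQS <- matrix(c(
  # pos1  pos2  pos3  pos4  pos5  pos6  pos7
  0.15, 0.15, 0.20, 0.20, 0.30, 0.97, 0.10,   # A
  0.30, 0.20, 0.25, 0.20, 0.20, 0.01, 0.40,   # C
  0.15, 0.15, 0.20, 0.15, 0.20, 0.01, 0.15,   # G
  0.40, 0.50, 0.35, 0.45, 0.30, 0.01, 0.35),  # T
  nrow = 4, byrow = TRUE, dimnames = list(c("A", "C", "G", "T"), NULL))

#' Branch-point scoring model
#'
#' Builds the scoring model: per-position log-odds (natural log against a
#' uniform background, with a pseudocount) over the 7-nt window, the search
#' window upstream of the 3' splice site, the canonical 21-25 nt distance
#' band, a linear penalty for distances outside the band, and the weight of
#' the polypyrimidine-tract term.
#'
#' @param pseudocount Added to each base frequency before log-odds.
#' @param distance_window Search interval (nt upstream of the 3'SS,
#'   measured from the branch adenosine to the end of the intron).
#' @param canonical_band Distance band in which the prior is maximal.
#' @param dist_penalty Score penalty per nt outside the canonical band.
#' @param py_weight Weight of the pyrimidine fraction between the branch
#'   adenosine and the 3'SS.
#' @return List of class `bp_model`.
#' @export
branchpoint_model <- function(pseudocount = 0.01,
                              distance_window = c(15L, 100L),
                              canonical_band = c(21L, 25L),
                              dist_penalty = 0.05,
                              py_weight = 1.0) {
  f <- BP_FREQS + pseudocount
  f <- sweep(f, 2, colSums(f), "/")
  pwm <- log(f / 0.25)
  stopifnot(all(is.finite(pwm)),
            all(apply(pwm, 2, which.max)[6] == 1L))  # BP column favors A
  structure(list(pwm = pwm, distance_window = as.integer(distance_window),
                 canonical_band = as.integer(canonical_band),
                 dist_penalty = dist_penalty, py_weight = py_weight),
            class = "bp_model")
}

bp_distance_prior <- function(d, model) {
  band <- model$canonical_band
  -model$dist_penalty * pmax(0L, pmax(band[1] - d, d - band[2]))
}

#' Score branch-point candidates in an intron
#'
#' Every adenosine whose distance to the 3' splice site lies in the model's
#' search window is scored:
#' `total_score = motif_score + distance_prior + py_weight * py_fraction`,
#' where the motif score sums the PWM over the 7-nt window ending one base
#' after the adenosine, the distance prior is maximal inside the 21-25 nt
#' band and non-increasing away from it, and `py_fraction` is the
#' pyrimidine fraction between the adenosine and the 3'SS AG. Distance is
#' counted from the branch adenosine through the final G of the intron.
#'
#' @param intron_seq Intron sequence ending with its 3' splice site
#'   (`"AG"` as the final two bases); an error otherwise.
#' @param model A [branchpoint_model()].
#' @return data.frame sorted by `total_score` (ties toward smaller
#'   distance): `bp_pos` (1-based position in `intron_seq`), `heptamer`,
#'   `motif_score`, `distance_to_3ss`, `py_fraction`, `total_score`,
#'   `in_canonical_band`. Empty when no adenosine lies in the window.
#' @export
score_branchpoints <- function(intron_seq, model = branchpoint_model()) {
  intron_seq <- toupper(intron_seq)
  L <- nchar(intron_seq)
  if (L < 2L || substr(intron_seq, L - 1L, L) != "AG")
    stop("intron sequence must end with its 3' splice site AG")
  chars <- strsplit(intron_seq, "", fixed = TRUE)[[1]]
  win <- model$distance_window
  pos <- which(chars == "A")
  d <- L - pos
  keep <- d >= win[1] & d <= win[2] & pos >= 6L & pos + 1L <= L
  pos <- pos[keep]; d <- d[keep]
  if (length(pos) == 0L) {
    return(data.frame(bp_pos = integer(), heptamer = character(),
                      motif_score = numeric(), distance_to_3ss = integer(),
                      py_fraction = numeric(), total_score = numeric(),
                      in_canonical_band = logical(),
                      stringsAsFactors = FALSE))
  }
  motif <- vapply(pos, function(i) {
    w <- chars[(i - 5L):(i + 1L)]
    sum(vapply(seq_len(7L), function(k) {
      if (w[k] %in% rownames(model$pwm)) model$pwm[w[k], k] else
        min(model$pwm[, k])  # N and friends score as the worst base
    }, 0))
  }, 0)
  pyf <- vapply(pos, function(i) {
    between <- chars[seq.int(i + 1L, L - 2L)]
    mean(between %in% c("C", "T"))
  }, 0)
  prior <- bp_distance_prior(d, model)
  total <- motif + prior + model$py_weight * pyf
  res <- data.frame(
    bp_pos = pos,
    heptamer = vapply(pos, function(i)
      paste(chars[(i - 5L):(i + 1L)], collapse = ""), ""),
    motif_score = motif, distance_to_3ss = d, py_fraction = pyf,
    total_score = total,
    in_canonical_band = d >= model$canonical_band[1] &
                        d <= model$canonical_band[2],
    stringsAsFactors = FALSE)
  res <- res[order(-res$total_score, res$distance_to_3ss), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Best branch-point prediction for an intron
#'
#' Head of the [score_branchpoints()] ranking; `NULL` when no adenosine
#' lies in the search window.
#'
#' @inheritParams score_branchpoints
#' @return One-row data.frame, or `NULL`.
#' @export
predict_best_branchpoint <- function(intron_seq, model = branchpoint_model()) {
  ranked <- score_branchpoints(intron_seq, model)
  if (nrow(ranked) == 0L) return(NULL)
  ranked[1L, , drop = FALSE]
}

#' Compare branch-point predictions across species
#'
#' Runs [predict_best_branchpoint()] on each taxon's intron and tabulates
#' nucleotide differences within the predicted heptamer windows, position
#' by position against the first taxon.
#'
#' @param aligned_introns Named character vector (or list) of per-taxon
#'   intron sequences, each ending with its 3'SS AG.
#' @param model A [branchpoint_model()].
#' @return List with `predictions` (one row per taxon; `taxon` column
#'   added) and `substitutions` (rows `window_pos`, `taxon`, `base`,
#'   `ref_base` for every within-window difference from the first taxon).
#' @export
compare_branchpoints_across_species <- function(aligned_introns,
                                                model = branchpoint_model()) {
  taxa <- names(aligned_introns)
  stopifnot(!is.null(taxa), all(nzchar(taxa)))
  preds <- lapply(taxa, function(tx) {
    p <- predict_best_branchpoint(aligned_introns[[tx]], model)
    if (is.null(p)) return(NULL)
    cbind(taxon = tx, p, stringsAsFactors = FALSE)
  })
  preds <- do.call(rbind, preds)
  subs <- data.frame(window_pos = integer(), taxon = character(),
                     base = character(), ref_base = character(),
                     stringsAsFactors = FALSE)
  if (!is.null(preds) && nrow(preds) >= 2L) {
    ref <- strsplit(preds$heptamer[1], "")[[1]]
    for (i in 2:nrow(preds)) {
      w <- strsplit(preds$heptamer[i], "")[[1]]
      diffpos <- which(w != ref)
      if (length(diffpos))
        subs <- rbind(subs, data.frame(window_pos = diffpos,
                                       taxon = preds$taxon[i],
                                       base = w[diffpos],
                                       ref_base = ref[diffpos],
                                       stringsAsFactors = FALSE))
    }
  }
  list(predictions = preds, substitutions = subs)
}
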