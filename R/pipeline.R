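# End-to-end driver: simulate -> count -> combinations -> genomic context
# -> exonization -> branch point, with a truth-vs-detected reconciliation
# table. Every stage is an exported function; this driver wires them
# together with one config and one seed so a full run is reproducible.

PIPELINE_KEYS <- c("seed", "n_chroms", "chrom_len", "n_genes",
                   "exons_per_gene", "n_host_te", "n_guest_te", "p_nested",
                   "tsd_len_range", "polya_len_range", "host_divergence",
                   "guest_divergence", "plant_splice_signals",
                   "query_host", "query_guest", "max_gap",
                   "min_exon_len", "max_exon_len", "out_dir",
                   "bp_distance_window", "bp_canonical_band",
                   "bp_dist_penalty", "bp_py_weight")

#' Read a pipeline configuration from YAML
#'
#' Keys mirror [simulation_config()] plus `query_host`, `query_guest`,
#' `max_gap`, `min_exon_len`, `max_exon_len`, `out_dir`. Unknown keys are
#' rejected.
#'
#' @param path YAML file.
#' @return A named list of settings for [run_te_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), PIPELINE_KEYS)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg
}

#' Run the full analysis pipeline on a synthetic genome
#'
#' Chains [simulate_te_genome()], [count_repeat_classes()],
#' [find_combinations()], [classify_context()], splice-site scanning and
#' candidate enumeration over each planted intronic TE pair,
#' [predict_best_branchpoint()] on each candidate's intron, and
#' [detect_tsd()] on each nested guest, then reconciles detected nested
#' combinations against the planted truth. With `out_dir` set, all tables
#' are written as tab-separated reports (plus the simulation artifacts);
#' reruns with the same settings are byte-identical.
#'
#' @param config A [simulation_config()]; or pass a list from
#'   [read_pipeline_config()] to `settings`.
#' @param settings Optional named list overriding `query_host`,
#'   `query_guest`, `max_gap`, `min_exon_len`, `max_exon_len`, `out_dir`
#'   and any [simulation_config()] field.
#' @param out_dir Optional output directory for reports.
#' @return List with `sim`, `counts`, `combos`, `orientation`, `context`,
#'   `candidates`, `branchpoints`, `hallmarks`, `reconciliation`,
#'   `summary`.
#' @export
run_te_pipeline <- function(config = simulation_config(), settings = list(),
                            out_dir = NULL) {
  sim_keys <- intersect(names(settings), names(formals(simulation_config)))
  if (length(sim_keys))
    config <- do.call(simulation_config,
                      utils::modifyList(unclass(config)[names(formals(simulation_config))],
                                        settings[sim_keys]))
  opt <- function(key, default)
    if (!is.null(settings[[key]])) settings[[key]] else default
  query_host <- opt("query_host", "MIR")
  query_guest <- opt("query_guest", "AluSp")
  max_gap <- opt("max_gap", 0L)
  min_exon_len <- opt("min_exon_len", 25L)
  max_exon_len <- opt("max_exon_len", 500L)
  bp_model <- branchpoint_model(
    distance_window = opt("bp_distance_window", c(15L, 100L)),
    canonical_band = opt("bp_canonical_band", c(21L, 25L)),
    dist_penalty = opt("bp_dist_penalty", 0.05),
    py_weight = opt("bp_py_weight", 1.0))
  out_dir <- if (!is.null(out_dir)) out_dir else settings$out_dir

  sim <- simulate_te_genome(config)
  counts <- count_repeat_classes(sim$repeats)
  elements <- assemble_elements(sim$repeats)
  combos <- find_combinations(elements, query_host, query_guest, max_gap)
  orientation <- orientation_summary(combos)
  context <- classify_context(combos, sim$genes)

  candidates <- list(); bps <- list()
  truth_ex <- sim$truth$planted_exons
  ins <- sim$truth$planted_insertions
  if (!is.null(truth_ex)) for (i in seq_len(nrow(truth_ex))) {
    gene <- sim$genes[sim$genes$name == truth_ex$gene[i], ]
    host <- ins[!is.na(ins$gene) & ins$gene == truth_ex$gene[i], ]
    sites <- scan_splice_sites(sim$genome, truth_ex$chrom[i],
                               host$host_start, host$host_end,
                               gene_strand = gene$strand)
    j <- truth_ex$intron_index[i]
    intron <- c(gene$exon_ends[[1]][j], gene$exon_starts[[1]][j + 1L])
    cand <- enumerate_candidates(sites, intron = intron,
                                 min_len = min_exon_len,
                                 max_len = max_exon_len)
    if (nrow(cand)) {
      cand$gene <- gene$name
      cand$chrom <- truth_ex$chrom[i]
      cand$intron_index <- j
      candidates[[length(candidates) + 1L]] <- cand
      for (k in seq_len(nrow(cand))) {
        iseq <- substr(sim$genome[[truth_ex$chrom[i]]], intron[1] + 1L,
                       cand$acceptor_pos[k] + 2L)
        best <- predict_best_branchpoint(iseq, bp_model)
        if (!is.null(best)) {
          best$gene <- gene$name
          best$acceptor_pos <- cand$acceptor_pos[k]
          best$bp_genomic <- intron[1] + best$bp_pos - 1L
          bps[[length(bps) + 1L]] <- best
        }
      }
    }
  }
  candidates <- if (length(candidates)) do.call(rbind, candidates) else NULL
  bps <- if (length(bps)) do.call(rbind, bps) else NULL

  hallmarks <- NULL
  if (!is.null(ins) && nrow(ins)) {
    hl <- lapply(seq_len(nrow(ins)), function(i) {
      h <- detect_tsd(sim$genome,
                      list(chrom = ins$chrom[i], start = ins$guest_start[i],
                           end = ins$guest_end[i],
                           strand = ins$guest_strand[i]))
      data.frame(insertion_id = ins$insertion_id[i], tsd = h$tsd,
                 tsd_len = h$tsd_len, polya_len = h$polya_len,
                 low_confidence = h$low_confidence,
                 stringsAsFactors = FALSE)
    })
    hallmarks <- do.call(rbind, hl)
  }

  nested <- combos[combos$relation == "nested", , drop = FALSE]
  reconciliation <- if (!is.null(ins)) {
    key_t <- paste(ins$chrom, ins$guest_start, ins$guest_end)
    key_d <- paste(nested$chrom, nested$guest_start, nested$guest_end)
    data.frame(planted = nrow(ins), detected = nrow(nested),
               matched = sum(key_t %in% key_d),
               recall = if (nrow(ins)) sum(key_t %in% key_d) / nrow(ins)
                        else NA_real_,
               precision = if (nrow(nested))
                 sum(key_d %in% key_t) / nrow(nested) else NA_real_)
  } else {
    data.frame(planted = 0L, detected = nrow(nested), matched = 0L,
               recall = NA_real_, precision = NA_real_)
  }

  summary <- list(seed = config$seed,
                  element_counts = counts$elements,
                  row_counts = counts$rows,
                  combinations = nrow(combos),
                  nested = nrow(nested),
                  percent_same_orientation = orientation$percent_same,
                  intragenic_intronic =
                    sum(context$status == "intragenic_intronic"),
                  exonization_candidates =
                    if (is.null(candidates)) 0L else nrow(candidates),
                  recall = reconciliation$recall,
                  precision = reconciliation$precision)

  res <- list(sim = sim, counts = counts, combos = combos,
              orientation = orientation, context = context,
              candidates = candidates, branchpoints = bps,
              hallmarks = hallmarks, reconciliation = reconciliation,
              summary = summary)
  if (!is.null(out_dir)) write_pipeline_reports(res, out_dir)
  res
}

write_pipeline_reports <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_simulation(res$sim, out_dir)
  wt <- function(df, f) if (!is.null(df) && nrow(df))
    utils::write.table(df, file.path(out_dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wt(res$combos, "combinations.tsv")
  wt(res$context, "context.tsv")
  wt(res$candidates, "candidates.tsv")
  wt(res$branchpoints, "branchpoints.tsv")
  wt(res$hallmarks, "hallmarks.tsv")
  wt(res$reconciliation, "reconciliation.tsv")
  if (!is.null(res$combos) && nrow(res$combos)) {
    spans <- data.frame(chrom = res$combos$chrom,
                        start = pmin(res$combos$host_start,
                                     res$combos$guest_start),
                        end = pmax(res$combos$host_end,
                                   res$combos$guest_end),
                        name = paste0(res$combos$host_name, "_",
                                      res$combos$guest_name),
                        strand = res$combos$host_strand,
                        stringsAsFactors = FALSE)
    write_bed(spans, file.path(out_dir, "combinations.bed"))
  }
  yaml::write_yaml(res$summary, file.path(out_dir, "summary.yaml"))
  invisible(out_dir)
}
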