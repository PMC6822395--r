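test_that("element assembly groups rows by linkage id", {
  set.seed(1)
  feats <- make_repeat_features(10)          # all distinct frag_ids
  el <- assemble_elements(feats)
  expect_equal(nrow(el), 10L)
  expect_false(any(el$is_fragmented))

  # a fragmented MIR around an AluSp: one element with two fragments
  mir <- make_repeat_features(2, chroms = "chr1")
  mir$rep_name <- "MIR"; mir$rep_class <- "SINE"; mir$rep_family <- "MIR"
  mir$strand <- "-"; mir$frag_id <- 99L
  mir$start <- c(1000L, 1500L); mir$end <- c(1200L, 1700L)
  alu <- make_repeat_features(1, chroms = "chr1")
  alu$rep_name <- "AluSp"; alu$rep_family <- "Alu"; alu$strand <- "-"
  alu$start <- 1200L; alu$end <- 1500L; alu$frag_id <- 100L
  el2 <- assemble_elements(rbind(mir, alu))
  expect_equal(nrow(el2), 2L)
  m <- el2[el2$rep_name == "MIR", ]
  expect_true(m$is_fragmented)
  expect_equal(c(m$start, m$end), c(1000L, 1700L))
})

test_that("element count equals distinct grouping keys on random tables", {
  for (seed in 1:5) {
    set.seed(seed)
    feats <- make_repeat_features(60)
    feats$frag_id <- sample.int(40L, 60L, replace = TRUE)
    el <- suppressWarnings(assemble_elements(feats))
    keys <- unique(paste(feats$chrom, feats$frag_id, feats$rep_name,
                         feats$strand))
    expect_equal(nrow(el), length(keys))
  }
})

test_that("overlapping fragments in one group warn but keep merged span", {
  feats <- make_repeat_features(2, chroms = "chr1")
  feats$rep_name <- "MIR"; feats$rep_family <- "MIR"
  feats$strand <- "+"; feats$frag_id <- 1L
  feats$start <- c(100L, 150L); feats$end <- c(200L, 250L)
  expect_warning(el <- assemble_elements(feats), "overlap")
  expect_equal(c(el$start, el$end), c(100L, 250L))
})

test_that("class counts distinguish elements from rows", {
  set.seed(2)
  feats <- make_repeat_features(10)
  feats$rep_name <- rep(c("MIR", "AluSp", "L1PA4"), c(5, 3, 2))
  feats$rep_class <- rep(c("SINE", "SINE", "LINE"), c(5, 3, 2))
  feats$rep_family <- rep(c("MIR", "Alu", "L1"), c(5, 3, 2))
  feats$frag_id <- 1:10
  cnt <- count_repeat_classes(feats)
  expect_equal(cnt$elements[["total"]], 10L)
  expect_equal(cnt$elements[["SINE"]], 8L)
  expect_equal(cnt$elements[["MIR"]], 5L)
  expect_equal(cnt$elements[["AluSp"]], 3L)

  # two MIR rows sharing a frag_id: one element, two rows
  two <- feats[1:2, ]
  two$chrom <- "chr1"; two$strand <- "+"; two$frag_id <- 1L
  two$start <- c(10L, 500L); two$end <- c(100L, 700L)
  cnt2 <- count_repeat_classes(two)
  expect_equal(cnt2$elements[["MIR"]], 1L)
  expect_equal(cnt2$rows[["MIR"]], 2L)

  empty <- feats[0, ]
  cnt0 <- count_repeat_classes(empty)
  expect_true(all(cnt0$elements == 0L) && all(cnt0$rows == 0L))
})

nested_fixture <- function() {
  df <- make_repeat_features(3, chroms = "chr1")
  df$rep_name <- c("MIR", "AluSp", "MIR")
  df$rep_class <- "SINE"
  df$rep_family <- c("MIR", "Alu", "MIR")
  df$strand <- "-"
  df$start <- c(1000L, 1200L, 1520L)
  df$end <- c(1210L, 1510L, 1700L)
  df$frag_id <- c(7L, 8L, 7L)
  df
}

test_that("an antisense guest inside a fragmented antisense host is one nested, same-orientation combination", {
  el <- assemble_elements(nested_fixture())
  co <- find_combinations(el, "MIR", "AluSp")
  expect_equal(nrow(co), 1L)
  expect_equal(co$relation, "nested")
  expect_true(co$same_orientation)
  # family queries match too
  co2 <- find_combinations(el, "MIR", "Alu")
  expect_equal(co2$relation, "nested")
})

test_that("a lone element with no neighbor within max_gap yields nothing", {
  set.seed(3)
  df <- make_repeat_features(2, chroms = "chr1")
  df$rep_name <- c("MIR", "AluSp"); df$rep_family <- c("MIR", "Alu")
  df$start <- c(1000L, 5000L); df$end <- c(1260L, 5300L)
  df$frag_id <- 1:2
  el <- assemble_elements(df)
  expect_equal(nrow(find_combinations(el, "MIR", "AluSp", max_gap = 10L)),
               0L)
  # but a touching pair is adjacent in either order
  df$start <- c(1000L, 1260L); df$end <- c(1260L, 1560L)
  el2 <- assemble_elements(df)
  co <- find_combinations(el2, "MIR", "AluSp", max_gap = 0L)
  expect_equal(co$relation, "adjacent")
  expect_equal(co$gap, 0L)
})

test_that("unknown query names are rejected with available names listed", {
  el <- assemble_elements(nested_fixture())
  expect_error(find_combinations(el, "MIRb", "AluSp"), "available")
})

test_that("combination detection is invariant under row shuffling and nested/adjacent are disjoint", {
  sim <- simulate_te_genome(simulation_config(
    seed = 8, chrom_len = 150000L, n_genes = 2L, n_host_te = 8L,
    n_guest_te = 6L, p_nested = 0.8))
  el <- assemble_elements(sim$repeats)
  co <- find_combinations(el, "MIR", "AluSp", max_gap = 50L)
  set.seed(1)
  shuffled <- sim$repeats[sample.int(nrow(sim$repeats)), ]
  co2 <- find_combinations(assemble_elements(shuffled), "MIR", "AluSp",
                           max_gap = 50L)
  expect_equal(co, co2)
  # disjoint relations partition the total
  expect_equal(sum(co$relation == "nested") +
               sum(co$relation == "adjacent"), nrow(co))
  expect_false(any(duplicated(paste(co$host_frag_id, co$guest_frag_id))))
})

test_that("orientation summary reproduces the published percentage and partitions", {
  combos <- data.frame(same_orientation = rep(c(TRUE, FALSE),
                                              c(125L, 209L - 125L)))
  s <- orientation_summary(combos)
  expect_equal(s$total, 209L)
  expect_equal(s$same_orientation, 125L)
  expect_equal(s$percent_same, 60)
  expect_true(is.na(orientation_summary(combos[0, , drop = FALSE])$percent_same))
  set.seed(4)
  r <- data.frame(same_orientation = sample(c(TRUE, FALSE), 37, TRUE))
  sr <- orientation_summary(r)
  expect_equal(sr$same_orientation + sum(!r$same_orientation), sr$total)
})

test_that("TSD and poly-A detection recover planted hallmarks exactly", {
  sim <- simulate_te_genome(simulation_config(
    seed = 9, chrom_len = 150000L, n_genes = 2L, n_host_te = 8L,
    n_guest_te = 6L, p_nested = 0.8))
  ins <- sim$truth$planted_insertions
  for (i in seq_len(nrow(ins))) {
    h <- detect_tsd(sim$genome,
                    list(chrom = ins$chrom[i], start = ins$guest_start[i],
                         end = ins$guest_end[i],
                         strand = ins$guest_strand[i]))
    expect_equal(h$tsd_len, ins$tsd_len[i])
    expect_identical(h$tsd, ins$tsd[i])
    expect_equal(h$tsd_mismatches, 0L)
    expect_equal(h$polya_len, ins$polya_len[i])
  }
})

test_that("TSD absence, short low-confidence TSDs, and flank errors", {
  # flanks engineered with no duplication of length >= 2
  genome <- c(chr = paste0(strrep("C", 30), strrep("G", 10), strrep("T", 30)))
  h <- detect_tsd(genome, list(chrom = "chr", start = 30L, end = 40L,
                               strand = "+"))
  expect_true(is.na(h$tsd))
  expect_equal(h$tsd_len, 0L)

  # exactly three matched terminal nucleotides: detected but low-confidence
  genome2 <- c(chr = paste0(strrep("C", 27), "TGA", strrep("G", 10),
                            "TGA", strrep("C", 27)))
  h2 <- detect_tsd(genome2, list(chrom = "chr", start = 30L, end = 40L,
                                 strand = "+"))
  expect_equal(h2$tsd_len, 3L)
  expect_true(h2$low_confidence)

  expect_error(
    detect_tsd(genome, list(chrom = "chr", start = 5L, end = 40L,
                            strand = "+")),
    "flank")
})

test_that("deleting the guest and re-joining host fragments restores a contiguous host", {
  sim <- simulate_te_genome(simulation_config(
    seed = 10, chrom_len = 150000L, n_genes = 2L, n_host_te = 8L,
    n_guest_te = 6L, p_nested = 0.8))
  el <- assemble_elements(sim$repeats)
  co <- find_combinations(el, "MIR", "AluSp")
  nested <- co[co$relation == "nested", ]
  for (i in seq_len(nrow(nested))) {
    host <- el[el$frag_id == nested$host_frag_id[i] &
               el$rep_name == "MIR", ]
    frags <- host$fragments[[1]]
    total_frag_len <- sum(frags$end - frags$start)
    outer <- host$end - host$start
    guest_len <- nested$guest_end[i] - nested$guest_start[i]
    expect_equal(outer - guest_len, total_frag_len)
  }
})
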