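hominoids <- c("human", "chimpanzee", "gibbon")
owm <- c("rhesus_macaque", "crab_eating_macaque", "african_green_monkey",
         "colobus_monkey")
nwm <- c("marmoset", "squirrel_monkey")
prosimian <- "ring_tailed_lemur"

test_that("the fixture tree is ultrametric with the configured calibrations", {
  tr <- primate_fixture_tree()
  expect_s3_class(tr, "phylo")
  expect_equal(sort(tr$tip.label), sort(c(hominoids, owm, nwm, prosimian)))
  ages <- node_ages(tr)
  expect_equal(max(ages), 63)
  expect_equal(unname(ages[ape::getMRCA(tr, c(hominoids, owm))]), 25)
  expect_equal(unname(ages[ape::getMRCA(tr, c(hominoids, owm, nwm))]), 40)
  expect_true(all(abs(ages[seq_along(tr$tip.label)]) < 1e-9))
})

test_that("a catarrhine-only insertion dates to the 25-40 myr window", {
  tr <- primate_fixture_tree()
  prof <- phyletic_profile(present = c(hominoids, owm),
                           absent = c(nwm, prosimian))
  w <- infer_integration_window(tr, prof)
  expect_equal(w$lower_age, 25)
  expect_equal(w$upper_age, 40)
  expect_false(w$open_upper)
  expect_setequal(w$clade_leaves, c(hominoids, owm))
})

test_that("an insertion present in all surveyed primates dates beyond the 63 myr root", {
  tr <- primate_fixture_tree()
  w <- infer_integration_window(tr, phyletic_profile(present = tr$tip.label))
  expect_equal(w$lower_age, 63)
  expect_true(w$open_upper)
  expect_equal(w$upper_age, Inf)
})

test_that("a single-carrier insertion dates between 0 and its parent node age", {
  tr <- primate_fixture_tree()
  w <- infer_integration_window(tr, phyletic_profile(
    present = "human", absent = setdiff(tr$tip.label, "human")))
  expect_equal(w$lower_age, 0)
  expect_equal(w$upper_age, 6)      # human-chimpanzee split
})

test_that("non-monophyletic presence violates the single-gain model", {
  tr <- primate_fixture_tree()
  prof <- phyletic_profile(present = c("human", "marmoset"),
                           absent = setdiff(tr$tip.label,
                                            c("human", "marmoset")))
  expect_error(infer_integration_window(tr, prof), "monophyletic")
  expect_error(infer_integration_window(
    tr, setNames(character(0), character(0))), "presence")
})

test_that("unknown leaves are excluded from the monophyly test", {
  tr <- primate_fixture_tree()
  # absence unresolved in gibbon: catarrhine window still inferred
  prof <- phyletic_profile(present = c("human", "chimpanzee", owm),
                           absent = c(nwm, prosimian),
                           unknown = "gibbon")
  w <- infer_integration_window(tr, prof)
  expect_equal(w$lower_age, 25)
  expect_equal(w$upper_age, 40)
})

test_that("inference is invariant under profile order and leaf rotation", {
  tr <- primate_fixture_tree()
  prof <- phyletic_profile(present = c(hominoids, owm),
                           absent = c(nwm, prosimian))
  set.seed(61)
  w1 <- infer_integration_window(tr, prof)
  w2 <- infer_integration_window(tr, prof[sample(length(prof))])
  expect_equal(w1$lower_age, w2$lower_age)
  expect_equal(w1$upper_age, w2$upper_age)
  rot <- ape::ladderize(tr)
  w3 <- infer_integration_window(rot, prof)
  expect_equal(w3$lower_age, w1$lower_age)
  expect_equal(w3$upper_age, w1$upper_age)
})

test_that("planting on every branch and descending to the leaves recovers that branch", {
  tr <- primate_fixture_tree()
  ntip <- length(tr$tip.label)
  ages <- node_ages(tr)
  for (child in setdiff(seq_len(ntip + tr$Nnode), ntip + 1L)) {
    prof <- simulate_phyletic_profile(tr, child)
    w <- infer_integration_window(tr, prof)
    expect_equal(unname(w$branch["child"]), child)
    expect_equal(w$lower_age, unname(ages[child]))
    parent <- tr$edge[tr$edge[, 2] == child, 1]
    expect_equal(w$upper_age, unname(ages[parent]))
  }
  # the root itself gives the open-above window
  w_root <- infer_integration_window(
    tr, simulate_phyletic_profile(tr, ntip + 1L))
  expect_true(w_root$open_upper)
})

test_that("newick trees are read with ages from branch lengths or node labels", {
  tr <- primate_fixture_tree()
  f <- tempfile(fileext = ".nwk")
  ape::write.tree(tr, f)
  tr2 <- read_species_tree(f)
  expect_equal(sort(tr2$tip.label), sort(tr$tip.label))
  expect_equal(max(node_ages(tr2)), 63)
  # node-label dialect: topology with internal ages, no branch lengths
  f2 <- tempfile(fileext = ".nwk")
  writeLines("((A,B)10,C)30;", f2)
  tr3 <- read_species_tree(f2)
  ages <- node_ages(tr3)
  expect_equal(unname(ages[ape::getMRCA(tr3, c("A", "B"))]), 10)
  expect_equal(max(ages), 30)
})

test_that("amplicon-size profiles classify by nearest expectation", {
  bands <- c(human = 1810, marmoset = 1790, lemur = 1550, colobus = NA)
  prof <- profile_from_amplicons(bands, expected_with = 1800,
                                 expected_without = 1540, tolerance = 30)
  expect_equal(unname(prof), c("present", "present", "absent", "unknown"))
  # a band near neither expectation is unknown (flagged for sequencing)
  expect_equal(unname(profile_from_amplicons(
    c(x = 1650), 1800, 1540, 30)), "unknown")
  expect_error(profile_from_amplicons(bands, 1800, 1780, 30), "overlap")
  # random tables agree with a brute nearest-expectation rule
  set.seed(62)
  for (rep in 1:50) {
    b <- sample(1400:1900, 1)
    got <- unname(profile_from_amplicons(c(t = b), 1800, 1540, 40))
    want <- if (abs(b - 1800) <= 40) "present"
            else if (abs(b - 1540) <= 40) "absent" else "unknown"
    expect_equal(got, want)
  }
})
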