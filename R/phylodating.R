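# Dating of an insertion from its presence/absence profile across taxa on a
# calibrated ultrametric species tree, under a single-gain (Dollo)
# assumption: the insertion arose once on the stem branch of the minimal
# clade containing all carriers and is never precisely excised, so the
# integration time window is bounded by the ages of the two nodes flanking
# that branch.

#' Calibrated 10-leaf primate fixture tree
#'
#' An ultrametric tree of the ten surveyed primates: three hominoids
#' (human, chimpanzee, gibbon), four Old World monkeys (rhesus and
#' crab-eating macaques, African green monkey, colobus), two New World
#' monkeys (marmoset, squirrel monkey), and a prosimian (ring-tailed
#' lemur). The three calibrations that matter for dating the studied
#' insertions are arguments: the root (simian/prosimian) age, the
#' catarrhine/platyrrhine split, and the hominoid/cercopithecoid split.
#' Remaining node ages are fixed round figures from the primate literature
#' and only have to respect the ordering constraints.
#'
#' @param root_age Age of the root, millions of years (myr).
#' @param catarrhine_platyrrhine Age of the catarrhine/platyrrhine split.
#' @param hominoid_cercopithecoid Age of the hominoid/Old-World-monkey
#'   split.
#' @return An `ape::phylo` ultrametric tree with branch lengths in myr.
#' @export
primate_fixture_tree <- function(root_age = 63,
                                 catarrhine_platyrrhine = 40,
                                 hominoid_cercopithecoid = 25) {
  ages <- list(hc = 6, hcg = 20, mac = 5, cerc = 13, owm = 18, nwm = 20,
               cat = hominoid_cercopithecoid,
               simian = catarrhine_platyrrhine, root = root_age)
  stopifnot(ages$hcg < ages$cat, ages$owm < ages$cat,
            ages$cat < ages$simian, ages$nwm < ages$simian,
            ages$simian < ages$root)
  nwk <- sprintf(paste0(
    "(((((human:%g,chimpanzee:%g):%g,gibbon:%g):%g,",
    "(((rhesus_macaque:%g,crab_eating_macaque:%g):%g,",
    "african_green_monkey:%g):%g,colobus_monkey:%g):%g):%g,",
    "(marmoset:%g,squirrel_monkey:%g):%g):%g,ring_tailed_lemur:%g);"),
    ages$hc, ages$hc, ages$hcg - ages$hc, ages$hcg, ages$cat - ages$hcg,
    ages$mac, ages$mac, ages$cerc - ages$mac, ages$cerc,
    ages$owm - ages$cerc, ages$owm, ages$cat - ages$owm,
    ages$simian - ages$cat, ages$nwm, ages$nwm, ages$simian - ages$nwm,
    ages$root - ages$simian, ages$root)
  ape::read.tree(text = nwk)
}

#' Node ages of an ultrametric tree
#'
#' @param tree An `ape::phylo` tree with branch lengths in time units.
#' @return Numeric vector of ages indexed by node number (tips first, at
#'   age 0 up to rounding).
#' @export
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  ages <- max(depth) - depth
  tip_ages <- ages[seq_along(tree$tip.label)]
  if (any(abs(tip_ages) > 1e-6 * max(ages)))
    stop("tree is not ultrametric: tips are not contemporaneous")
  ages
}

#' Read a calibrated species tree from Newick
#'
#' Accepts either dialect for node ages: branch lengths summing to an
#' ultrametric tree (the default), or numeric internal-node labels giving
#' ages directly (in which case branch lengths are rebuilt from the
#' labels).
#'
#' @param path Newick file.
#' @param ages_from `"auto"` (labels when every internal node carries a
#'   numeric label, branch lengths otherwise), `"branch_lengths"`, or
#'   `"labels"`.
#' @return An `ape::phylo` tree with branch lengths in age units.
#' @export
read_species_tree <- function(path,
                              ages_from = c("auto", "branch_lengths",
                                            "labels")) {
  ages_from <- match.arg(ages_from)
  tree <- ape::read.tree(path)
  labs <- suppressWarnings(as.numeric(tree$node.label))
  has_labels <- length(labs) == tree$Nnode && !anyNA(labs)
  use_labels <- switch(ages_from,
                       auto = has_labels && is.null(tree$edge.length),
                       branch_lengths = FALSE,
                       labels = TRUE)
  if (use_labels) {
    if (!has_labels)
      stop("internal nodes do not all carry numeric age labels")
    ntip <- length(tree$tip.label)
    age <- c(rep(0, ntip), labs)
    tree$edge.length <- age[tree$edge[, 1]] - age[tree$edge[, 2]]
    if (any(tree$edge.length < 0))
      stop("node-label ages are not non-decreasing toward the root")
  }
  if (is.null(tree$edge.length))
    stop("tree has neither branch lengths nor numeric node-label ages")
  tree
}

#' Build a presence/absence profile
#'
#' @param present,absent,unknown Character vectors of leaf names.
#' @return Named character vector over `{present, absent, unknown}`.
#' @export
phyletic_profile <- function(present, absent = character(0),
                             unknown = character(0)) {
  stopifnot(length(present) >= 1L,
            !anyDuplicated(c(present, absent, unknown)))
  stats::setNames(
    rep(c("present", "absent", "unknown"),
        c(length(present), length(absent), length(unknown))),
    c(present, absent, unknown))
}

#' Infer the integration window of an insertion
#'
#' Under the single-gain model the insertion arose on the stem branch of
#' the minimal clade containing every carrier leaf: the window's lower age
#' is that clade's crown-node age and its upper age is the age of the
#' clade's parent node (open when the clade is the whole tree). Leaves
#' marked `unknown` are excluded from the monophyly test; an `absent` leaf
#' inside the carrier clade violates the single-gain model and raises an
#' error.
#'
#' @param tree Calibrated ultrametric `ape::phylo` tree.
#' @param profile Named vector from [phyletic_profile()] (or any named
#'   vector over `present`/`absent`/`unknown`).
#' @return List of class `integration_window`: `branch` (parent and child
#'   node numbers; parent `NA` at the root), `clade_leaves`, `lower_age`,
#'   `upper_age` (`Inf` when open), `open_upper`.
#' @export
infer_integration_window <- function(tree, profile) {
  stopifnot(inherits(tree, "phylo"))
  bad <- setdiff(names(profile), tree$tip.label)
  if (length(bad))
    stop("profile leaves not in tree: ", paste(bad, collapse = ", "))
  present <- names(profile)[profile == "present"]
  absent <- names(profile)[profile == "absent"]
  if (length(present) == 0L) stop("empty presence set")
  ages <- node_ages(tree)
  ntip <- length(tree$tip.label)
  if (length(present) == 1L) {
    node <- match(present, tree$tip.label)
  } else {
    node <- ape::getMRCA(tree, present)
  }
  clade_tips <- if (node <= ntip) tree$tip.label[node] else
    ape::extract.clade(tree, node)$tip.label
  viol <- intersect(clade_tips, absent)
  if (length(viol))
    stop("presence set is not monophyletic (single-gain model violated); ",
         "absent leaves inside the carrier clade: ",
         paste(viol, collapse = ", "))
  parent <- tree$edge[tree$edge[, 2] == node, 1]
  upper <- if (length(parent) == 0L) Inf else ages[parent]
  structure(list(branch = c(parent = if (length(parent)) parent else NA,
                            child = node),
                 clade_leaves = clade_tips,
                 lower_age = unname(ages[node]), upper_age = unname(upper),
                 open_upper = !is.finite(upper)),
            class = "integration_window")
}

#' @export
print.integration_window <- function(x, ...) {
  up <- if (x$open_upper) "open (older than the root)" else
    sprintf("%.6g myr", x$upper_age)
  cat(sprintf("Integration window: %.6g myr (crown of %d carrier leaves) to %s\n",
              x$lower_age, length(x$clade_leaves), up))
  invisible(x)
}

#' Classify taxa from amplicon sizes
#'
#' PCR band sizes alone can mislead (absence of one element can be masked
#' by a different insertion of similar size), so classification is against
#' the two expected amplicon sizes: within `tolerance` of `expected_with`
#' is `present`, within `tolerance` of `expected_without` is `absent`, and
#' anything else is `unknown` (flagged for sequencing).
#'
#' @param bands Named numeric vector of amplicon sizes (bp); `NA` for no
#'   band.
#' @param expected_with,expected_without Expected sizes with and without
#'   the insertion; `expected_with` must be larger.
#' @param tolerance Size tolerance (bp); the two acceptance intervals must
#'   not overlap.
#' @return Named character vector over `{present, absent, unknown}`.
#' @export
profile_from_amplicons <- function(bands, expected_with, expected_without,
                                   tolerance = 30) {
  stopifnot(expected_with > expected_without)
  if (expected_with - tolerance <= expected_without + tolerance)
    stop("tolerance intervals overlap; reduce tolerance")
  cls <- function(b) {
    if (is.na(b)) return("unknown")
    if (abs(b - expected_with) <= tolerance) return("present")
    if (abs(b - expected_without) <= tolerance) return("absent")
    "unknown"
  }
  vapply(bands, cls, "")
}

#' Generate a leaf profile by descent from a planted origin branch
#'
#' Marks as `present` every leaf descending from `branch_child` (the child
#' node of the branch on which the insertion is planted) and every other
#' leaf `absent` — the forward model inverted by
#' [infer_integration_window()].
#'
#' @param tree `ape::phylo` tree.
#' @param branch_child Node number of the planted branch's child (a tip
#'   number plants on a terminal branch).
#' @return Named character vector over `{present, absent}`.
#' @export
simulate_phyletic_profile <- function(tree, branch_child) {
  ntip <- length(tree$tip.label)
  carriers <- if (branch_child <= ntip) tree$tip.label[branch_child] else
    ape::extract.clade(tree, branch_child)$tip.label
  phyletic_profile(present = carriers,
                   absent = setdiff(tree$tip.label, carriers))
}
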