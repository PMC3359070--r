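#' Classify an inferred tree into long-branch artefact classes
#'
#' Assigns exactly one of `correct`, `class_I`, `class_II`, `class_III`,
#' `other` to an inferred tree relative to the generating topology and its
#' focal elements, by fixed precedence:
#'
#' 1. `correct` — the unrooted topologies are identical (RF distance 0).
#' 2. `class_III` (kind A only) — the two long terminal leaves are adjacent
#'    (form a cherry) in the inferred tree: mutual attraction of long
#'    terminal branches through convergent chance similarity, the
#'    Felsenstein case.
#' 3. `class_I` (kind B only) — the two focal short terminal leaves are
#'    adjacent in the inferred tree: erroneous grouping driven by shared
#'    ancestral states (symplesiomorphy).
#' 4. `class_II` — a single focal long element (a long terminal leaf for
#'    kind A; an internally intact long-branch clade for kind B) is
#'    misplaced: removing it makes the inferred tree's restriction
#'    identical to the true tree's restriction (signal erosion / taxon
#'    slippage). Compound errors never qualify, since removing one element
#'    cannot repair the rest of the tree.
#' 5. `other` — anything else, e.g. scrambled background taxa.
#'
#' "Attraction"/"grouping" is operationalized as unrooted adjacency — the
#' two leaves sharing an internal vertex — the strictest reading computable
#' without assuming a root placement.
#'
#' @param spec A [topology_spec()] consistent with `true_tree`.
#' @param true_tree The generating `phylo` topology.
#' @param inferred The inferred `phylo` tree (same leaf set).
#' @return A single character value, one of
#'   `c("correct", "class_I", "class_II", "class_III", "other")`.
#' @examples
#' tr <- build_topology_a(0.5, 0.1)
#' classify_tree(topology_spec("A"), tr, tr)  # "correct"
#' @export
classify_tree <- function(spec, true_tree, inferred) {
  stopifnot(inherits(spec, "topology_spec"))
  l1 <- sort(true_tree$tip.label); l2 <- sort(inferred$tip.label)
  if (!identical(l1, l2))
    stop("leaf sets differ; only in true tree: {",
         paste(setdiff(l1, l2), collapse = ", "), "}, only in inferred: {",
         paste(setdiff(l2, l1), collapse = ", "), "}", call. = FALSE)
  focal <- unlist(spec$focal_long, use.names = FALSE)
  if (!all(focal %in% l1))
    stop("spec's focal elements are not all leaves of the true tree",
         call. = FALSE)

  if (rf_distance(true_tree, inferred) == 0) return("correct")

  if (spec$kind == "A" && leaves_adjacent(inferred, spec$focal_long))
    return("class_III")

  if (spec$kind == "B" && leaves_adjacent(inferred, spec$focal_short_pair))
    return("class_I")

  if (is_single_misplacement(spec, true_tree, inferred)) return("class_II")
  "other"
}

# some focal long element whose removal restores the true restricted
# topology; compound errors never qualify because removing one element
# cannot repair the rest of the tree. (For kind B a clade regrafted onto a
# focal terminal edge is restorable by removing either long element --
# outside the two clades only three subtree units remain, so the
# restriction is the same trichotomy both ways -- which is why the rule is
# existential rather than "exactly one".)
is_single_misplacement <- function(spec, true_tree, inferred) {
  elements <- if (spec$kind == "A") as.list(spec$focal_long) else spec$focal_long
  for (el in elements) {
    if (spec$kind == "B") {
      # the clade must be internally intact and monophyletic in the
      # inferred tree before its removal can count as a single misplacement
      if (!is_intact_clade(inferred, el, true_tree)) next
    }
    keep <- setdiff(true_tree$tip.label, el)
    if (rf_distance(prune_taxa(true_tree, keep),
                    prune_taxa(inferred, keep)) == 0)
      return(TRUE)
  }
  FALSE
}

is_intact_clade <- function(tree, leaves, true_tree) {
  key <- split_key(leaves, tree$tip.label)
  if (!(key %in% tree_bipartitions(tree))) return(FALSE)
  if (length(leaves) < 4) return(TRUE)
  rf_distance(prune_taxa(tree, leaves), prune_taxa(true_tree, leaves)) == 0
}

#' Classify many inferred trees at once
#'
#' @param spec A [topology_spec()].
#' @param true_tree The generating topology.
#' @param inferred_trees A list of `phylo` objects (or a `multiPhylo`).
#' @return A tibble with columns `tree_index` and `class`.
#' @export
classify_trees <- function(spec, true_tree, inferred_trees) {
  cls <- vapply(inferred_trees, function(tr) classify_tree(spec, true_tree, tr),
                character(1))
  tibble::tibble(tree_index = seq_along(cls), class = cls)
}

#' The error-class levels in canonical order
#' @return Character vector of the five class labels.
#' @export
error_classes <- function() {
  c("correct", "class_I", "class_II", "class_III", "other")
}
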