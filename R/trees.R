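#' Model tree builders, Newick I/O and split algebra
#'
#' Trees are plain [ape::phylo] objects, always treated as unrooted; the
#' serialization root is an arbitrary internal node. Branch lengths are in
#' expected substitutions per site.
#'
#' @name trees
NULL

#' Build model topology A (long terminal branches)
#'
#' An 11-leaf unrooted tree, leaves `t1...t11`, designed to probe signal
#' erosion (class II) and mutual attraction of long terminal branches
#' (class III, the Felsenstein case). Leaves `t3` and `t7` carry the long
#' terminal branches; each sits in a cherry with a short partner (`t4`,
#' `t8`), whose stem edge has length `sib`. `t3` and `t7` are separated by
#' more than one internal edge. All remaining edges have the constant
#' background length `rb`. `t11` is the designated outgroup (metadata only;
#' all computation is on the unrooted tree).
#'
#' @param ltb Length of the two long terminal branches (substitutions/site).
#' @param sib Length of the two short internal (cherry stem) branches.
#' @param rb Background branch length for all remaining edges.
#' @return An unrooted `phylo` object with 11 leaves.
#' @examples
#' tr <- build_topology_a(ltb = 0.5, sib = 0.1)
#' @seealso [build_topology_b()], [topology_spec()]
#' @export
build_topology_a <- function(ltb, sib, rb = 0.05) {
  check_branch_length(ltb, "ltb")
  check_branch_length(sib, "sib")
  check_branch_length(rb, "rb")
  txt <- sprintf(
    "((((t1:%s,t2:%s):%s,(t3:%s,t4:%s):%s):%s,((t5:%s,t6:%s):%s,(t7:%s,t8:%s):%s):%s):%s,(t9:%s,t10:%s):%s,t11:%s);",
    fmt_bl(rb), fmt_bl(rb), fmt_bl(rb), fmt_bl(ltb), fmt_bl(rb), fmt_bl(sib),
    fmt_bl(rb), fmt_bl(rb), fmt_bl(rb), fmt_bl(rb), fmt_bl(ltb), fmt_bl(rb),
    fmt_bl(sib), fmt_bl(rb), fmt_bl(rb), fmt_bl(rb), fmt_bl(rb), fmt_bl(rb),
    fmt_bl(rb))
  ape::read.tree(text = txt)
}

#' Build model topology B (long internal branches)
#'
#' An 11-leaf unrooted tree designed to probe the symplesiomorphy-driven
#' class I effect: a short central internal edge of length `sib` joins two
#' internal nodes, each bearing one short terminal leaf (`t5`, `t6`) and a
#' background clade attached through a long internal edge of length `lib`
#' (a 4-leaf clade on one side, 5-leaf on the other). `t5` and `t6` are
#' *not* sisters in the true tree; the class I artefact groups them.
#'
#' @param lib Length of the two long internal branches.
#' @param sib Length of the short central internal branch.
#' @param rb Background branch length for all remaining edges.
#' @return An unrooted `phylo` object with 11 leaves.
#' @export
build_topology_b <- function(lib, sib, rb = 0.05) {
  check_branch_length(lib, "lib")
  check_branch_length(sib, "sib")
  check_branch_length(rb, "rb")
  txt <- sprintf(
    "(((t1:%s,t2:%s):%s,(t3:%s,t4:%s):%s):%s,t5:%s,(((t7:%s,t8:%s):%s,(t9:%s,(t10:%s,t11:%s):%s):%s):%s,t6:%s):%s);",
    fmt_bl(rb), fmt_bl(rb), fmt_bl(rb), fmt_bl(rb), fmt_bl(rb), fmt_bl(rb),
    fmt_bl(lib), fmt_bl(rb), fmt_bl(rb), fmt_bl(rb), fmt_bl(rb), fmt_bl(rb),
    fmt_bl(rb), fmt_bl(rb), fmt_bl(rb), fmt_bl(rb), fmt_bl(lib), fmt_bl(rb),
    fmt_bl(sib))
  ape::read.tree(text = txt)
}

check_branch_length <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop("branch length `", name, "` must be a single finite value >= 0 (got ",
         deparse(x), ")", call. = FALSE)
  invisible(x)
}

fmt_bl <- function(x) sprintf("%.10g", x)

#' Focal-element metadata for the model topologies
#'
#' Records which tree elements the artefact classifier inspects: the two
#' long elements (terminal leaves `t3`/`t7` for kind A; the leaf sets of the
#' two clades behind the long internal edges for kind B), the focal short
#' pair flanking the central edge (kind B only), and the designated
#' outgroup. The defaults match [build_topology_a()] / [build_topology_b()];
#' all fields can be overridden to classify against alternative shapes.
#'
#' @param kind `"A"` or `"B"`.
#' @param focal_long For kind A a character vector of the two long-branch
#'   leaves; for kind B a list of two character vectors, the leaf sets of
#'   the clades subtended by the long internal edges.
#' @param focal_short_pair Kind B only: the two short terminal leaves
#'   flanking the central internal edge.
#' @param outgroup Designated outgroup label (reporting metadata only).
#' @return An object of class `topology_spec`.
#' @export
topology_spec <- function(kind = c("A", "B"),
                          focal_long = NULL,
                          focal_short_pair = NULL,
                          outgroup = "t11") {
  kind <- match.arg(kind)
  if (is.null(focal_long)) {
    focal_long <- if (kind == "A") c("t3", "t7") else
      list(c("t1", "t2", "t3", "t4"), c("t7", "t8", "t9", "t10", "t11"))
  }
  if (kind == "A" && !is.null(focal_short_pair))
    stop("`focal_short_pair` is defined only for kind B", call. = FALSE)
  if (kind == "B" && is.null(focal_short_pair))
    focal_short_pair <- c("t5", "t6")
  structure(
    list(kind = kind, focal_long = focal_long,
         focal_short_pair = focal_short_pair, outgroup = outgroup),
    class = "topology_spec")
}

#' @export
print.topology_spec <- function(x, ...) {
  cat("Topology spec (kind ", x$kind, ")\n", sep = "")
  if (x$kind == "A") {
    cat("  long terminal leaves:", paste(x$focal_long, collapse = ", "), "\n")
  } else {
    cat("  long internal clades:",
        paste(vapply(x$focal_long, function(s) paste0("{", paste(s, collapse = ","), "}"), ""),
              collapse = " and "), "\n")
    cat("  focal short pair:", paste(x$focal_short_pair, collapse = ", "), "\n")
  }
  cat("  outgroup:", x$outgroup, "\n")
  invisible(x)
}

#' Parse a Newick string
#'
#' Thin wrapper over [ape::read.tree()] adding the structural checks the
#' rest of the package relies on: balanced parentheses (reported with the
#' character position of the first imbalance), a terminating semicolon, and
#' unique non-empty leaf labels.
#'
#' @param text A single Newick string.
#' @return A `phylo` object.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("unbalanced ')' at character ", i, " of Newick string", call. = FALSE)
    }
  }
  if (depth > 0L)
    stop("unbalanced '(': ", depth, " unclosed at end of Newick string (length ",
         length(chars), ")", call. = FALSE)
  if (!grepl(";\\s*$", text))
    stop("Newick string lacks terminating ';' (at character ",
         nchar(text) + 1L, ")", call. = FALSE)
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse Newick string", call. = FALSE)
  if (anyDuplicated(tr$tip.label)) {
    dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
    stop("duplicate leaf label(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(tr$tip.label)))
    stop("empty leaf label in Newick string", call. = FALSE)
  tr
}

#' Serialize a tree to Newick
#'
#' Branch lengths are always written, with 10 significant digits; internal
#' node labels are omitted.
#'
#' @param tree A `phylo` object.
#' @return A single Newick string ending in `;`.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tree$node.label <- NULL
  ape::write.tree(tree, digits = 10)
}

#' Nontrivial bipartitions of an unrooted tree
#'
#' Returns the splits induced by internal edges, each in a canonical string
#' key: the side *not* containing the lexicographically smallest leaf,
#' sorted and joined with `"|"`. Trivial splits (single leaves) are
#' excluded, so a fully resolved unrooted n-leaf tree yields n - 3 keys.
#'
#' @param tree A `phylo` object (>= 3 leaves).
#' @param lengths If `TRUE`, return the corresponding internal edge lengths
#'   as a names attribute-compatible numeric vector attached as
#'   `attr(,"lengths")`.
#' @return Character vector of canonical split keys.
#' @export
tree_bipartitions <- function(tree, lengths = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (n < 3L) stop("tree must have >= 3 leaves", call. = FALSE)
  tree <- ape::unroot(tree)
  edge <- tree$edge
  internal <- edge[, 2] > n
  if (!any(internal)) {
    out <- character(0)
    if (lengths) attr(out, "lengths") <- numeric(0)
    return(out)
  }
  # tips below each internal edge's child, via one postorder accumulation
  po <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) below[[i]] <- i
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  labs <- tree$tip.label
  keys <- character(0); lens <- numeric(0)
  for (k in which(internal)) {
    side <- labs[below[[edge[k, 2]]]]
    keys <- c(keys, split_key(side, labs))
    lens <- c(lens, tree$edge.length[k])
  }
  ord <- order(keys)
  out <- keys[ord]
  if (lengths) attr(out, "lengths") <- lens[ord]
  out
}

# canonical key: the side not containing the smallest label, sorted
split_key <- function(side, all_labels) {
  smallest <- min(all_labels)
  if (smallest %in% side) side <- setdiff(all_labels, side)
  paste(sort(side), collapse = "|")
}

#' Length of the edge inducing a given split
#'
#' Looks up the internal edge whose bipartition equals `side` vs the rest,
#' or the terminal edge if `side` is a single leaf.
#'
#' @param tree A `phylo` object.
#' @param side Character vector of leaf labels on one side of the split.
#' @return The edge length, or `NA` if no edge induces that split.
#' @export
split_edge_length <- function(tree, side) {
  labs <- tree$tip.label
  if (!all(side %in% labs))
    stop("unknown label(s): ", paste(setdiff(side, labs), collapse = ", "),
         call. = FALSE)
  if (length(side) == 1L || length(side) == length(labs) - 1L) {
    tip <- if (length(side) == 1L) side else setdiff(labs, side)
    i <- match(tip, labs)
    k <- which(tree$edge[, 2] == i)
    return(tree$edge.length[k])
  }
  bp <- tree_bipartitions(tree, lengths = TRUE)
  key <- split_key(side, labs)
  hit <- match(key, bp)
  if (is.na(hit)) NA_real_ else attr(bp, "lengths")[hit]
}

#' Robinson-Foulds distance
#'
#' Size of the symmetric difference of the two trees' nontrivial
#' bipartition sets; 0 iff the unrooted topologies are identical.
#'
#' @param tree1,tree2 `phylo` objects on the same leaf set.
#' @return Non-negative integer count.
#' @export
rf_distance <- function(tree1, tree2) {
  l1 <- sort(tree1$tip.label); l2 <- sort(tree2$tip.label)
  if (!identical(l1, l2)) {
    stop("leaf sets differ; only in tree1: {",
         paste(setdiff(l1, l2), collapse = ", "), "}, only in tree2: {",
         paste(setdiff(l2, l1), collapse = ", "), "}", call. = FALSE)
  }
  b1 <- tree_bipartitions(tree1)
  b2 <- tree_bipartitions(tree2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Restrict a tree to a subset of leaves
#'
#' Drops all other leaves, suppressing the resulting degree-2 nodes and
#' summing their incident edge lengths, so path lengths among kept leaves
#' are preserved.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of leaf labels to retain (>= 3).
#' @return A `phylo` object on `keep`.
#' @export
prune_taxa <- function(tree, keep) {
  labs <- tree$tip.label
  unknown <- setdiff(keep, labs)
  if (length(unknown))
    stop("unknown label(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  if (length(keep) < 3L) stop("need at least 3 leaves to keep", call. = FALSE)
  ape::unroot(ape::keep.tip(tree, keep))
}

#' Test whether two leaves are adjacent (form a cherry)
#'
#' Two leaves of an unrooted binary tree are adjacent iff they share an
#' internal vertex, i.e. the split separating exactly that pair exists (or
#' the tree has only 3 leaves).
#'
#' @param tree A `phylo` object.
#' @param pair Character vector of two leaf labels.
#' @return Logical.
#' @export
leaves_adjacent <- function(tree, pair) {
  stopifnot(length(pair) == 2L)
  n <- length(tree$tip.label)
  if (n <= 3L) return(TRUE)
  key <- split_key(pair, tree$tip.label)
  key %in% tree_bipartitions(tree)
}
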