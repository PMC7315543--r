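#' Parse a rooted Newick tree with branch lengths
#'
#' Reads a Newick string (or a file containing one) into a validated
#' simulation tree.  Parsing itself is delegated to [ape::read.tree()]; on top
#' of that the function enforces the contracts the simulator needs: branch
#' lengths on every edge, unique non-empty leaf names, and non-negative
#' lengths.  Node depths (distance from the root along branch lengths, in
#' expected substitutions per site) are computed on construction.  A basal
#' root edge (e.g. `"((A:1,B:1):0.5);"`) is kept and treated as a single
#' ancestral lineage preceding the first split.
#'
#' @param text A Newick string ending in `;`.
#' @param path Alternatively, a file to read the string from.
#' @return An object of class `"sim_tree"`: a list with the underlying
#'   `phylo` object (`$phy`), an edge table (`$edges`: `edge_id`, `parent`,
#'   `child`, `length`, `pdepth`, `cdepth`, `label`), `$node_depth`,
#'   `$max_depth` and `$n_leaves`.
#' @examples
#' tr <- parse_newick("(A:1.0,B:1.0);")
#' tr$n_leaves
#' @export
parse_newick <- function(text = NULL, path = NULL) {
  if (is.null(text)) {
    if (is.null(path)) stop("supply a Newick string or a file path", call. = FALSE)
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  text <- trimws(text)
  .check_newick_syntax(text)
  if (!grepl("(", text, fixed = TRUE)) {
    # single taxon, no branching: representable, but nothing can evolve
    lab <- sub(":.*$", "", sub(";\\s*$", "", text))
    return(structure(
      list(phy = NULL,
           edges = data.frame(edge_id = integer(0), parent = integer(0),
                              child = integer(0), length = numeric(0),
                              pdepth = numeric(0), cdepth = numeric(0),
                              label = character(0), stringsAsFactors = FALSE),
           node_depth = 0, root_edge = 0, max_depth = 0, n_leaves = 1L),
      class = "sim_tree"))
  }
  phy <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(phy) || !inherits(phy, "phylo"))
    stop("Newick parse error: string could not be parsed as a tree", call. = FALSE)
  .as_sim_tree(phy)
}

# Pre-scan for structural problems so errors can name a position; ape's own
# messages are position-free.
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick parse error: unmatched ')' at position ", i, call. = FALSE)
    }
  }
  if (depth > 0L)
    stop("Newick parse error: ", depth, " unclosed '(' by position ",
         length(chars), call. = FALSE)
  if (length(chars) == 0L || chars[length(chars)] != ";")
    stop("Newick parse error: missing terminating ';' at position ",
         length(chars) + 1L, call. = FALSE)
  invisible(TRUE)
}

.as_sim_tree <- function(phy) {
  n_tip <- length(phy$tip.label)
  if (n_tip < 1L) stop("tree has no leaves", call. = FALSE)
  if (any(!nzchar(phy$tip.label)))
    stop("empty leaf name in tree", call. = FALSE)
  dup <- phy$tip.label[duplicated(phy$tip.label)]
  if (length(dup) > 0L)
    stop("duplicate leaf name(s): ", paste(unique(dup), collapse = ", "), call. = FALSE)
  n_edge <- nrow(phy$edge)
  if (is.null(phy$edge.length) || length(phy$edge.length) != n_edge ||
      anyNA(phy$edge.length))
    stop("missing branch length on one or more edges; ",
         "all non-root edges must carry an explicit length", call. = FALSE)
  if (any(phy$edge.length < 0))
    stop("negative branch length", call. = FALSE)

  root_edge <- if (!is.null(phy$root.edge) && is.finite(phy$root.edge) &&
                   phy$root.edge > 0) phy$root.edge else 0
  root_node <- n_tip + 1L
  depth <- ape::node.depth.edgelength(phy) + root_edge

  edges <- data.frame(
    edge_id = seq_len(n_edge),
    parent  = phy$edge[, 1L],
    child   = phy$edge[, 2L],
    length  = phy$edge.length,
    pdepth  = depth[phy$edge[, 1L]],
    cdepth  = depth[phy$edge[, 2L]],
    label   = ifelse(phy$edge[, 2L] <= n_tip, phy$tip.label[phy$edge[, 2L]], NA_character_),
    stringsAsFactors = FALSE
  )
  if (root_edge > 0) {
    edges <- rbind(
      data.frame(edge_id = 0L, parent = 0L, child = root_node,
                 length = root_edge, pdepth = 0, cdepth = root_edge,
                 label = NA_character_, stringsAsFactors = FALSE),
      edges
    )
  }
  structure(
    list(phy = phy, edges = edges, node_depth = depth,
         root_edge = root_edge, max_depth = max(depth),
         n_leaves = n_tip),
    class = "sim_tree"
  )
}

#' @export
print.sim_tree <- function(x, ...) {
  cat("<sim_tree> ", x$n_leaves, " leaves, depth ", format(x$max_depth),
      " substitutions/site\n", sep = "")
  invisible(x)
}

#' Serialize a simulation tree back to Newick
#'
#' @param tree A `sim_tree`.
#' @return A Newick string.
#' @export
write_newick <- function(tree) {
  phy <- tree$phy
  if (tree$root_edge > 0) phy$root.edge <- tree$root_edge
  ape::write.tree(phy)
}

#' Rescale all branch lengths of a tree
#'
#' Multiplies every branch length by `coefficient` (e.g. 0.5 halves all
#' branches, reducing the number of polymorphisms in the simulated
#' alignment).  Topology is unchanged; depths are recomputed.
#'
#' @param tree A `sim_tree`.
#' @param coefficient Positive real multiplier.
#' @return A new `sim_tree`.
#' @export
rescale_tree <- function(tree, coefficient) {
  if (!is.numeric(coefficient) || length(coefficient) != 1L ||
      !is.finite(coefficient) || coefficient <= 0)
    stop("rescaling coefficient must be a single positive number", call. = FALSE)
  phy <- tree$phy
  phy$edge.length <- phy$edge.length * coefficient
  if (tree$root_edge > 0) phy$root.edge <- tree$root_edge * coefficient
  .as_sim_tree(phy)
}

#' Decompose a tree into time segments of co-existing branches
#'
#' The depth axis `[0, max depth]` is cut at every distinct node depth, giving
#' maximal intervals within which the set of living branches is constant.
#' Recombination is only permitted between branches of the same segment.
#' Each member branch overlaps the full segment, so its overlap length equals
#' the segment width; branches of zero overlap are excluded.  Leaves of a
#' non-ultrametric tree simply stop appearing in segments deeper than the
#' leaf.
#'
#' @param tree A `sim_tree`.
#' @param tol Depth comparison tolerance; node depths closer than this are
#'   merged into one boundary.
#' @return A list of segments, each a list with `start`, `end`, `edge_id`
#'   (integer vector of member branches) and `l` (per-member overlap length).
#' @examples
#' segs <- time_segments(parse_newick("(A:2,(B:1,C:1):1);"))
#' length(segs)  # two segments: [0,1) and [1,2)
#' @export
time_segments <- function(tree, tol = 1e-9) {
  if (nrow(tree$edges) == 0L)
    stop("single-node tree: nothing to simulate", call. = FALSE)
  depths <- sort(unique(c(0, tree$edges$pdepth, tree$edges$cdepth)))
  # merge boundaries within tol
  keep <- c(TRUE, diff(depths) > tol)
  depths <- depths[keep]
  if (length(depths) < 2L) return(list())
  segs <- vector("list", length(depths) - 1L)
  for (i in seq_len(length(depths) - 1L)) {
    s <- depths[i]; e <- depths[i + 1L]
    memb <- which(tree$edges$pdepth <= s + tol & tree$edges$cdepth >= e - tol)
    segs[[i]] <- list(
      start = s, end = e,
      edge_id = tree$edges$edge_id[memb],
      l = pmin(tree$edges$cdepth[memb], e) - pmax(tree$edges$pdepth[memb], s)
    )
  }
  segs
}
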