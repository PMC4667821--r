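#' Read a time-scaled ultrametric tree
#'
#' Reads a rooted, fully bifurcating, ultrametric phylogeny with branch
#' lengths in relative time units from a Newick or NEXUS file and validates
#' it. Node ages are defined as the maximum root-to-tip distance minus the
#' root-to-node distance, so tips sit at age 0 and the root at
#' \code{root_age()}.
#'
#' @param path Path to the tree file.
#' @param format Either \code{"newick"} or \code{"nexus"}.
#' @param resolve_polytomies If \code{TRUE}, polytomies are resolved
#'   randomly into bifurcations with zero-length branches (plus the tied-age
#'   jitter applied downstream by [divergence_times()]). By default
#'   polytomies are an error.
#' @param tol Relative ultrametricity tolerance: the spread of root-to-tip
#'   distances may not exceed \code{tol} times the maximum distance.
#' @return An object of class \code{phylo} that has passed
#'   [validate_timetree()].
#' @seealso [divergence_times()], [induced_subtree()], [write_timetree()]
#' @export
read_timetree <- function(path, format = c("newick", "nexus"),
                          resolve_polytomies = FALSE, tol = 1e-6) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("cannot read tree file: ", path, call. = FALSE)
  }
  tree <- switch(format,
    newick = ape::read.tree(path),
    nexus  = ape::read.nexus(path)
  )
  if (inherits(tree, "multiPhylo")) {
    if (length(tree) != 1L) {
      stop("file contains ", length(tree), " trees; expected exactly one",
           call. = FALSE)
    }
    tree <- tree[[1L]]
  }
  if (is.null(tree)) stop("could not parse tree in ", path, call. = FALSE)
  if (resolve_polytomies &&
        (!ape::is.binary(tree) || !ape::is.rooted(tree))) {
    tree <- ape::multi2di(tree, random = TRUE)
  }
  validate_timetree(tree, tol = tol)
}

#' Validate a time tree
#'
#' Checks the invariants a time-scaled tree must satisfy before any
#' divergence-time analysis: at least two uniquely labelled tips, branch
#' lengths present, a fully bifurcating rooted topology, and ultrametricity
#' within a relative tolerance. Within tolerance, tip ages are treated as
#' exactly 0 (ages are recomputed from the maximal root-to-tip distance).
#'
#' @inheritParams read_timetree
#' @param tree A \code{phylo} object.
#' @return The tree, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_timetree <- function(tree, tol = 1e-6) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  n <- length(tree$tip.label)
  if (n < 2L) stop("tree has fewer than 2 tips", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("tree has negative branch lengths", call. = FALSE)
  }
  if (!ape::is.binary(tree) || !ape::is.rooted(tree)) {
    tab <- tabulate(tree$edge[, 1L])
    poly <- which(tab > 2L)
    stop("tree is not a rooted bifurcating tree",
         if (length(poly)) paste0(" (polytomy at node ",
                                  paste(poly, collapse = ", "), ")"),
         call. = FALSE)
  }
  depth <- ape::node.depth.edgelength(tree)
  tip_depth <- depth[seq_len(n)]
  root_age <- max(tip_depth)
  if (root_age <= 0) stop("tree has zero total depth", call. = FALSE)
  rel_err <- (root_age - tip_depth) / root_age
  if (any(rel_err > tol)) {
    worst <- which.max(rel_err)
    stop("tree is not ultrametric (tip '", tree$tip.label[worst],
         "' deviates by relative ", format(rel_err[worst], digits = 3),
         " > tolerance ", tol, ")", call. = FALSE)
  }
  invisible(tree)
}

#' Age of the root of an ultrametric tree
#'
#' @param tree A validated time tree.
#' @return The root age (maximum root-to-tip path length), a positive scalar
#'   in the tree's relative time units.
#' @export
root_age <- function(tree) {
  max(ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)])
}

#' Ages of all nodes of an ultrametric tree
#'
#' @param tree A validated time tree.
#' @return Numeric vector of length \code{Ntip + Nnode} indexed like
#'   \code{ape} node numbers; tip entries are snapped to exactly 0.
#' @export
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  n <- length(tree$tip.label)
  ages <- max(depth[seq_len(n)]) - depth
  ages[seq_len(n)] <- 0
  ages
}

#' Ordered divergence times of a tree
#'
#' Extracts the ages of all internal nodes, sorted oldest first:
#' \eqn{t_1 > t_2 > \ldots > t_{s-1}} for a tree with \eqn{s} tips, with
#' \eqn{t_1} the root age. Exact ties (common in files rounded to few
#' digits) are broken deterministically by subtracting \eqn{k \epsilon}
#' (\eqn{\epsilon = 10^{-9}} root age, \eqn{k} the 0-based occurrence index
#' within the tied group) so the ordering is strict, as the birth--death
#' likelihood of ordered times assumes.
#'
#' @param tree A validated time tree with at least 2 tips.
#' @return Numeric vector of length \code{Ntip - 1}, strictly decreasing.
#' @export
divergence_times <- function(tree) {
  validate_timetree(tree)
  n <- length(tree$tip.label)
  ages <- node_ages(tree)[n + seq_len(tree$Nnode)]
  times <- sort(ages, decreasing = TRUE)
  eps <- 1e-9 * times[1L]
  dup <- duplicated(times)
  if (any(dup)) {
    k <- stats::ave(times, match(times, unique(times)),
                    FUN = function(x) seq_along(x) - 1)
    times <- sort(times - k * eps, decreasing = TRUE)
  }
  stopifnot(all(diff(times) < 0))
  times
}

#' Induced subtree of a species subset
#'
#' Returns the subtree spanned by the given tips, with unary internal nodes
#' suppressed, so that each internal node age equals the MRCA age of the
#' corresponding tip pair in the parent tree.
#'
#' @param tree A validated time tree.
#' @param members Character vector of tip labels, at least 2, all present in
#'   the tree.
#' @return A \code{phylo} time tree on \code{members}.
#' @export
induced_subtree <- function(tree, members) {
  members <- unique(as.character(members))
  unknown <- setdiff(members, tree$tip.label)
  if (length(unknown)) {
    stop("unknown species label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (length(members) < 2L) {
    stop("need at least 2 member species", call. = FALSE)
  }
  ape::keep.tip(tree, members)
}

#' Write a time tree to file
#'
#' Writes Newick or a NEXUS trees block with enough digits that reading the
#' file back reproduces node ages to within 1e-9.
#'
#' @inheritParams read_timetree
#' @param tree A validated time tree.
#' @return The path, invisibly.
#' @export
write_timetree <- function(tree, path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  validate_timetree(tree)
  switch(format,
    newick = ape::write.tree(tree, file = path, digits = 12),
    nexus  = ape::write.nexus(tree, file = path, translate = FALSE)
  )
  invisible(path)
}
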