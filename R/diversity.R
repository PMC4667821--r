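#' Faith's phylogenetic diversity
#'
#' Sum of the branch lengths of the minimum spanning path connecting the
#' member species on the phylogeny, i.e. the total branch length of the
#' induced subtree with unary nodes suppressed. This is the unrooted
#' convention: the edge below the members' MRCA is not counted unless it
#' lies on a path between two members (on a suppressed-root subtree it
#' never does). For the full tip set it equals the total branch length of
#' the tree.
#'
#' @param tree A validated ultrametric time tree.
#' @param members Character vector of at least 2 tip labels.
#' @return Summed branch length in the tree's time units.
#' @export
faith_pd <- function(tree, members) {
  sub <- induced_subtree(tree, members)
  sum(sub$edge.length)
}

#' Average taxonomic distinctness
#'
#' Mean patristic (path-length) distance over all unordered pairs of member
#' species, computed on the time-scaled molecular phylogeny. On an
#' ultrametric tree each pairwise distance is twice the age of the pair's
#' MRCA, so AvTD equals twice the mean MRCA age; it is insensitive to
#' species richness under uniform random sampling, unlike PD.
#'
#' The mean is taken over pairs. (A per-species reading of "averaged across
#' all species" would rescale every community's value by the constant
#' \eqn{(s-1)/s} factor linking the two denominators, leaving ranks and
#' correlations unchanged.)
#'
#' @inheritParams faith_pd
#' @return Mean pairwise distance in the tree's time units.
#' @export
avtd <- function(tree, members) {
  members <- unique(as.character(members))
  if (length(members) < 2L) stop("need at least 2 members", call. = FALSE)
  unknown <- setdiff(members, tree$tip.label)
  if (length(unknown)) {
    stop("unknown species label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(members, tree$tip.label)
  ages <- node_ages(tree)
  m <- ape::mrca(tree)[idx, idx, drop = FALSE]
  2 * mean(ages[m[upper.tri(m)]])
}

#' Phylogenetic skew
#'
#' \eqn{PS = \hat\rho_E / \rho_0}: the ratio of the effective sampling
#' proportion (the sampling fraction that best explains the community's
#' divergence times under the meta-community birth--death model) to the
#' actual sampling proportion (community size over meta-community size).
#' PS near 1 is consistent with uniform random sampling of the
#' meta-community; PS far above 1 indicates members concentrated in few
#' clades (young pairwise divergences). Its reciprocal is the
#' phylogenetic-clade evenness, \eqn{PE = 1/PS}.
#'
#' @param rhoE Effective sampling proportion in (0, 1].
#' @param rho0 Actual sampling proportion in (0, 1].
#' @return A positive scalar.
#' @export
phylogenetic_skew <- function(rhoE, rho0) {
  stopifnot(rhoE > 0, rhoE <= 1, rho0 <= 1)
  if (rho0 <= 0) stop("rho0 must be positive", call. = FALSE)
  rhoE / rho0
}

#' All diversity indices for one community
#'
#' Assembles species richness (SR), Faith's PD, AvTD, the actual and
#' effective sampling proportions, phylogenetic skew (PS) and
#' phylogenetic-clade evenness (PE) for one community of species drawn from
#' a meta-community tree. PD and AvTD need at least 2 members; PS and PE
#' are only computed for communities with at least \code{min_sr_ps} members
#' (default 11, i.e. more than 10 species) because the effective sampling
#' proportion is badly biased in small samples — smaller communities get
#' \code{NA} with a flag.
#'
#' @param tree The meta-community time tree.
#' @param members Tip labels of the community, at least 2.
#' @param meta_params [bd_params()] with the meta-community
#'   speciation/extinction estimates (its \code{rho} slot is ignored; the
#'   effective proportion is re-estimated here).
#' @param S_meta Meta-community size (number of species in the pool);
#'   defaults to the number of tips of \code{tree}.
#' @param min_sr_ps Minimum richness for the PS/PE fit.
#' @return A one-row \code{data.frame} with columns \code{sr}, \code{pd},
#'   \code{avtd}, \code{rho0}, \code{rhoE}, \code{ps}, \code{pe},
#'   \code{flags} (semicolon-separated; \code{""} when clean).
#' @export
community_indices <- function(tree, members, meta_params,
                              S_meta = length(tree$tip.label),
                              min_sr_ps = 11L) {
  members <- unique(as.character(members))
  sr <- length(members)
  if (sr < 2L) stop("need at least 2 members", call. = FALSE)
  if (sr > S_meta) stop("community larger than meta-community", call. = FALSE)
  pd <- faith_pd(tree, members)
  av <- avtd(tree, members)
  rho0 <- sr / S_meta
  rhoE <- ps <- pe <- NA_real_
  flags <- character(0)
  if (sr >= min_sr_ps) {
    sub <- induced_subtree(tree, members)
    fit <- fit_sampling_proportion(divergence_times(sub),
                                   lam = meta_params$lam,
                                   mu = meta_params$mu)
    rhoE <- fit$params$rho
    ps <- phylogenetic_skew(rhoE, rho0)
    pe <- 1 / ps
    if (fit$boundary) {
      flags <- c(flags, if (rhoE >= 0.5) "rho_boundary_upper"
                        else "rho_boundary_lower")
    }
  } else {
    flags <- c(flags, "below_min_sr")
  }
  data.frame(sr = sr, pd = pd, avtd = av, rho0 = rho0, rhoE = rhoE,
             ps = ps, pe = pe, flags = paste(flags, collapse = ";"),
             stringsAsFactors = FALSE)
}
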