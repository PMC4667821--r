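# Brute-force oracles used to cross-check the implementation. They are
# deliberately written from first principles (paths, explicit matrices,
# literal formula evaluation) and never call the code paths they validate.

# a random ultrametric tree from the coalescent, independent of the
# package's own simulator
random_ultrametric_tree <- function(n) {
  tr <- ape::rcoal(n)
  tr$tip.label <- paste0("sp", seq_len(n))
  tr
}

# root-to-tip edge incidence: logical matrix [tip, edge], TRUE when the
# edge lies on the path from the root to that tip
.edge_incidence <- function(tree) {
  n <- length(tree$tip.label)
  parent <- integer(max(tree$edge))
  edge_of <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  edge_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  root <- n + 1L
  inc <- matrix(FALSE, n, nrow(tree$edge))
  for (tip in seq_len(n)) {
    v <- tip
    while (v != root) {
      inc[tip, edge_of[v]] <- TRUE
      v <- parent[v]
    }
  }
  inc
}

# Faith's PD by brute force: union over all member pairs of the edges on
# the path between them (path edges = symmetric difference of the two
# root-to-tip edge sets)
pd_oracle <- function(tree, members, inc = .edge_incidence(tree)) {
  idx <- match(members, tree$tip.label)
  used <- rep(FALSE, ncol(inc))
  for (i in seq_along(idx)) {
    for (j in seq_len(i - 1L)) {
      used <- used | xor(inc[idx[i], ], inc[idx[j], ])
    }
  }
  sum(tree$edge.length[used])
}

# AvTD by brute force: mean of the explicit patristic distance matrix
avtd_oracle <- function(tree, members) {
  d <- ape::cophenetic.phylo(tree)[members, members]
  mean(d[upper.tri(d)])
}

# MRCA ages of all tip pairs from root-to-tip node paths: the deepest
# (most recent) node shared by both paths
mrca_age_oracle <- function(tree) {
  n <- length(tree$tip.label)
  ages <- phyloskew::node_ages(tree)
  paths <- lapply(seq_len(n), function(tip) ape::nodepath(tree, n + 1L, tip))
  out <- matrix(NA_real_, n, n, dimnames = list(tree$tip.label,
                                                tree$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      shared <- intersect(paths[[i]], paths[[j]])
      out[i, j] <- min(ages[shared])
    }
  }
  out
}

# literal term-by-term evaluation of the ordered-divergence-times
# likelihood, re-deriving every factor from the printed formulae
loglik_oracle <- function(times, lam, mu, rho) {
  s <- length(times) + 1
  t1 <- times[1]
  P0 <- function(t) {
    rho * (lam - mu) / (rho * lam + (lam * (1 - rho) - mu) * exp((mu - lam) * t))
  }
  p1 <- function(t) (1 / rho) * P0(t)^2 * exp((mu - lam) * t)
  v <- function(t) 1 - (1 / rho) * P0(t) * exp((mu - lam) * t)
  total <- lfactorial(s - 2)
  for (tj in times[-1]) {
    total <- total + log(lam * p1(tj) / v(t1))
  }
  total
}

# small fixed example tree used across files
toy_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")
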