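#' Draw node ages from the conditional birth--death density
#'
#' Draws i.i.d. node ages on \eqn{(0, t_1)} from the density
#' \eqn{\lambda p_1(t) / v_{t_1}} by inverse-CDF sampling: the CDF is
#' \eqn{v_t / v_{t_1}} and \eqn{v_t} inverts in closed form,
#' \deqn{w = \frac{\rho\lambda (1 - q)}{\rho\lambda + q(\lambda(1-\rho)-\mu)},
#'   \quad t = \frac{-\log w}{\lambda - \mu}}
#' for target CDF value \eqn{q}. Uses the current RNG stream.
#'
#' @param n Number of ages to draw.
#' @param params A [bd_params()] object.
#' @param t1 Conditioning root age, > 0.
#' @return Numeric vector of \code{n} ages in (0, t1).
#' @export
simulate_node_ages <- function(n, params, t1) {
  stopifnot(inherits(params, "bd_params"), t1 > 0, n >= 0)
  if (n == 0L) return(numeric(0))
  lam <- params$lam; mu <- params$mu; rho <- params$rho
  q <- stats::runif(n) * bd_v(t1, params)
  b <- lam * (1 - rho) - mu
  w <- rho * lam * (1 - q) / (rho * lam + q * b)
  -log(w) / (lam - mu)
}

# forward Gillespie birth-death from 2 lineages until n_target are extant;
# extinct runs are rejected and restarted
.draw_root_age <- function(n_target, lam, mu, max_tries = 1000L) {
  for (try in seq_len(max_tries)) {
    k <- 2L
    t <- 0
    repeat {
      t <- t + stats::rexp(1L, rate = k * (lam + mu))
      if (stats::runif(1L) < lam / (lam + mu)) k <- k + 1L else k <- k - 1L
      if (k >= n_target) return(t)
      if (k == 0L) break
    }
  }
  stop("forward process went extinct in all ", max_tries, " tries",
       call. = FALSE)
}

#' Simulate an ultrametric birth--death time tree
#'
#' Ages-first simulation matching the likelihood of ordered divergence
#' times exactly: given the root age \eqn{t_1}, the remaining
#' \eqn{n - 2} node ages are drawn i.i.d. from the conditional density
#' \eqn{\lambda p_1(t)/v_{t_1}} ([simulate_node_ages()]), and the topology
#' is built backward in time by merging a uniformly chosen pair of lineages
#' at each successive age. For the constant-rate reconstructed process all
#' ranked labeled topologies are equally likely given the ages, so the
#' uniform pairing reproduces the model the likelihood inverts — simulator
#' and likelihood are mutually validating.
#'
#' By default the root age is drawn by rejection from the forward process
#' (a Gillespie birth--death run from 2 lineages until
#' \code{round(n_tips / rho)} survive); pass \code{root_age} to fix it,
#' e.g. \code{root_age = 1} for unit-scale tests.
#'
#' @param n_tips Number of tips, >= 3.
#' @param params A [bd_params()] object (the generating rates).
#' @param seed Integer seed; mandatory so every tree is reproducible. The
#'   caller's RNG state is restored afterwards.
#' @param root_age Optional fixed root age; \code{NULL} draws it.
#' @return A validated \code{phylo} time tree with tips
#'   \code{t1 ... t<n_tips>}.
#' @export
simulate_timetree <- function(n_tips, params, seed, root_age = NULL) {
  stopifnot(inherits(params, "bd_params"), n_tips >= 3L)
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  .with_fixed_seed(as.integer(seed), {
    t1 <- if (is.null(root_age)) {
      .draw_root_age(max(n_tips, round(n_tips / params$rho)),
                     params$lam, params$mu)
    } else {
      stopifnot(root_age > 0)
      root_age
    }
    inner <- simulate_node_ages(n_tips - 2L, params, t1)
    ages <- c(sort(inner), t1)       # merge youngest first, root last
    label <- paste0("t", seq_len(n_tips))
    height <- numeric(n_tips)
    nwk <- label
    fmt <- function(x) sprintf("%.12g", x)
    for (a in ages) {
      pick <- sample.int(length(nwk), 2L)
      merged <- sprintf("(%s:%s,%s:%s)",
                        nwk[pick[1L]], fmt(a - height[pick[1L]]),
                        nwk[pick[2L]], fmt(a - height[pick[2L]]))
      nwk <- c(nwk[-pick], merged)
      height <- c(height[-pick], a)
    }
    tree <- ape::read.tree(text = paste0(nwk, ";"))
    validate_timetree(tree)
  })
}

#' Random (uniform) community sample from a meta-community
#'
#' Includes each tip of the meta-community tree independently with
#' probability \code{rho0} — the null model under which the effective
#' sampling proportion matches the actual one and PS is centred on 1. With
#' \code{min_size > 0} the draw is repeated (up to \code{max_tries} times)
#' until at least that many species are included, for calibration runs that
#' need the community to pass the cell richness filter.
#'
#' @param tree The meta-community time tree.
#' @param rho0 Inclusion probability in (0, 1].
#' @param seed Optional integer seed; \code{NULL} uses (and advances) the
#'   current RNG stream.
#' @param min_size Minimum community size, 0 to disable resampling.
#' @param max_tries Resampling budget before giving up.
#' @return Character vector of member tip labels.
#' @export
sample_community_random <- function(tree, rho0, seed = NULL, min_size = 0L,
                                    max_tries = 1000L) {
  stopifnot(rho0 > 0, rho0 <= 1)
  draw <- function() {
    for (i in seq_len(max_tries)) {
      m <- tree$tip.label[stats::runif(length(tree$tip.label)) < rho0]
      if (length(m) >= min_size) return(m)
    }
    stop("could not reach ", min_size, " members in ", max_tries,
         " draws at rho0 = ", rho0, call. = FALSE)
  }
  if (is.null(seed)) draw() else .with_fixed_seed(as.integer(seed), draw())
}

#' Tips descending from a clade's root node
#'
#' @param tree A time tree.
#' @param node An internal node number (\code{ape} numbering:
#'   \code{Ntip + 1 ... Ntip + Nnode}).
#' @return Character vector of tip labels in the clade.
#' @export
clade_tips <- function(tree, node) {
  n <- length(tree$tip.label)
  if (!is.numeric(node) || node < n + 1L || node > n + tree$Nnode) {
    stop("unknown clade id: ", node, call. = FALSE)
  }
  ape::extract.clade(tree, node)$tip.label
}

#' Clade-biased community sample
#'
#' Emulates a phylogenetically skewed community: tips inside the named
#' clades are included independently with probability \code{p_in}, all
#' other tips with \code{p_out < p_in}. With \code{p_in = p_out} this
#' reduces to [sample_community_random()]; with \code{p_out = 0} members
#' come exclusively from the named clades, the most extreme skew.
#'
#' @inheritParams sample_community_random
#' @param clades Integer vector of internal node numbers defining the
#'   favored clades.
#' @param p_in,p_out Inclusion probabilities, \code{p_in >= p_out}.
#' @return Character vector of member tip labels.
#' @export
sample_community_clade_biased <- function(tree, clades, p_in, p_out,
                                          seed = NULL, min_size = 0L,
                                          max_tries = 1000L) {
  stopifnot(p_in >= p_out, p_in > 0, p_in <= 1, p_out >= 0)
  inside <- unique(unlist(lapply(clades, function(nd) clade_tips(tree, nd))))
  p <- ifelse(tree$tip.label %in% inside, p_in, p_out)
  draw <- function() {
    for (i in seq_len(max_tries)) {
      m <- tree$tip.label[stats::runif(length(p)) < p]
      if (length(m) >= min_size) return(m)
    }
    stop("could not reach ", min_size, " members in ", max_tries, " draws",
         call. = FALSE)
  }
  if (is.null(seed)) draw() else .with_fixed_seed(as.integer(seed), draw())
}

#' Pick a skew clade of a target size
#'
#' Deterministically selects the internal node whose clade size is closest
#' to \code{fraction} of the tips (ties broken by the lower node number) —
#' a convenient default "favored clade" for planted-skew scenarios.
#'
#' @param tree A time tree.
#' @param fraction Target clade size as a fraction of the tip count.
#' @return An internal node number.
#' @export
pick_skew_clade <- function(tree, fraction = 0.25) {
  n <- length(tree$tip.label)
  sizes <- vapply(n + seq_len(tree$Nnode), function(nd) {
    length(clade_tips(tree, nd))
  }, integer(1))
  n + which.min(abs(sizes - fraction * n))
}

#' Scenario for a synthetic occurrence grid
#'
#' Bundles and validates the knobs of the grid generator. Defaults mirror
#' a global shark-scale analysis at desk scale: a 236-species meta-community
#' evolving at speciation rate 17 and extinction rate 6 per unit relative
#' time (the meta-tree maximum-likelihood estimates), 100 grid cells split
#' evenly between tropical (|latitude| < 23.5 deg) and temperate bands, an
#' expected per-cell sampling fraction of 0.2 (about 47 species per cell,
#' comfortably above the >10-species filter), and full planted skew: every
#' tropical cell draws its species clade-biased, every temperate cell
#' uniformly.
#'
#' @param n_species Meta-community size.
#' @param bd [bd_params()] for the meta-tree simulation.
#' @param n_cells Number of grid cells (<= 360 so cells get distinct
#'   longitudes).
#' @param latitudes Optional numeric vector of cell latitudes (length
#'   \code{n_cells}); \code{NULL} draws half uniformly in the tropical band
#'   [-23, 23] and half in the temperate bands +/-[40, 60].
#' @param skew_clades Internal node numbers of the favored clades;
#'   \code{NULL} auto-picks one clade of about a quarter of the tips via
#'   [pick_skew_clade()].
#' @param skew_strength Probability in [0, 1] that a tropical cell is drawn
#'   clade-biased rather than uniformly; 0 makes tropical and temperate
#'   cells exchangeable.
#' @param base_rho0 Expected per-cell sampling fraction in (0, 1).
#' @param seed Mandatory integer seed; all randomness flows from it.
#' @return A list of class \code{grid_scenario}.
#' @export
grid_scenario <- function(n_species = 236L, bd = bd_params(17, 6, 1),
                          n_cells = 100L, latitudes = NULL,
                          skew_clades = NULL, skew_strength = 1,
                          base_rho0 = 0.2, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  stopifnot(inherits(bd, "bd_params"), n_species >= 10L,
            n_cells >= 2L, n_cells <= 360L,
            skew_strength >= 0, skew_strength <= 1,
            base_rho0 > 0, base_rho0 < 1)
  if (!is.null(latitudes) && length(latitudes) != n_cells) {
    stop("latitudes must have length n_cells", call. = FALSE)
  }
  structure(list(n_species = as.integer(n_species), bd = bd,
                 n_cells = as.integer(n_cells), latitudes = latitudes,
                 skew_clades = skew_clades, skew_strength = skew_strength,
                 base_rho0 = base_rho0, seed = as.integer(seed)),
            class = "grid_scenario")
}

#' Generate a synthetic occurrence grid with planted latitudinal skew
#'
#' Simulates a meta-community tree (unless one is supplied), then fills
#' each grid cell with a community: tropical cells (|latitude| < 23.5 deg)
#' are drawn clade-biased with probability \code{skew_strength} and
#' uniformly otherwise; temperate cells are always drawn uniformly. The
#' clade-biased inclusion probabilities are chosen so the expected
#' community size matches \code{base_rho0 * n_species} (inside/outside odds
#' about 20:1, capped at 0.95 inside). Every cell is resampled until it
#' holds at least 11 species so all cells pass the richness filter. A
#' ground-truth sidecar records each cell's generating mode for
#' planted-signal tests.
#'
#' @param scenario A [grid_scenario()].
#' @param tree Optional pre-built meta-community tree whose tip count is
#'   \code{scenario$n_species}; \code{NULL} simulates one from
#'   \code{scenario$bd} and \code{scenario$seed}.
#' @param dir Optional directory; when given, \code{occurrences.csv} and
#'   \code{truth.csv} are written there, each with the seed in a
#'   \code{#}-comment header (read back with
#'   \code{read.csv(comment.char = "#")}).
#' @return A list with \code{tree}, \code{occurrences} (data frame:
#'   species, latitude, longitude), \code{truth} (data frame: cell_lat,
#'   cell_lon, latitude, regime, mode, clade) and \code{scenario}.
#' @export
generate_grid <- function(scenario, tree = NULL, dir = NULL) {
  stopifnot(inherits(scenario, "grid_scenario"))
  sc <- scenario
  if (is.null(tree)) {
    tree <- simulate_timetree(sc$n_species, sc$bd, seed = sc$seed)
  } else if (length(tree$tip.label) != sc$n_species) {
    stop("tree tip count does not match scenario n_species", call. = FALSE)
  }
  .with_fixed_seed(sc$seed + 1L, {
    lats <- sc$latitudes
    if (is.null(lats)) {
      n_trop <- sc$n_cells %/% 2L
      n_temp <- sc$n_cells - n_trop
      lats <- c(stats::runif(n_trop, -23, 23),
                stats::runif(n_temp, 40, 60) *
                  sample(c(-1, 1), n_temp, replace = TRUE))
    }
    lons <- -180 + (seq_len(sc$n_cells) - 1L) %% 360 + 0.5

    clades <- sc$skew_clades
    if (is.null(clades)) clades <- pick_skew_clade(tree)
    inside <- unique(unlist(lapply(clades, function(nd) clade_tips(tree, nd))))
    f_in <- length(inside) / sc$n_species
    ratio <- 20
    p_out <- sc$base_rho0 / (f_in * ratio + (1 - f_in))
    p_in <- min(0.95, ratio * p_out)
    p_out <- max(0, (sc$base_rho0 - f_in * p_in) / (1 - f_in))

    occ <- vector("list", sc$n_cells)
    truth <- vector("list", sc$n_cells)
    for (i in seq_len(sc$n_cells)) {
      tropical <- abs(lats[i]) < 23.5
      clade_mode <- tropical && stats::runif(1L) < sc$skew_strength
      members <- if (clade_mode) {
        sample_community_clade_biased(tree, clades, p_in, p_out,
                                      min_size = 11L)
      } else {
        sample_community_random(tree, sc$base_rho0, min_size = 11L)
      }
      occ[[i]] <- data.frame(species = members, latitude = lats[i],
                             longitude = lons[i], stringsAsFactors = FALSE)
      truth[[i]] <- data.frame(
        cell_lat = floor(lats[i]), cell_lon = floor(lons[i]),
        latitude = lats[i],
        regime = if (tropical) "tropical" else "temperate",
        mode = if (clade_mode) "clade" else "random",
        clade = paste(clades, collapse = "+"),
        stringsAsFactors = FALSE
      )
    }
    occurrences <- do.call(rbind, occ)
    truth <- do.call(rbind, truth)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      .write_commented_csv(occurrences, file.path(dir, "occurrences.csv"),
                           sc$seed)
      .write_commented_csv(truth, file.path(dir, "truth.csv"), sc$seed)
    }
    list(tree = tree, occurrences = occurrences, truth = truth,
         scenario = sc)
  })
}

.write_commented_csv <- function(df, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# seed: ", seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
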