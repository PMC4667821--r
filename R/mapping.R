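#' Rasterize occurrence records to a 1x1 degree presence grid
#'
#' Each record (species, latitude, longitude) is assigned to the integer
#' grid cell \code{(floor(latitude), floor(longitude))}; cell \code{(i, j)}
#' covers \code{[i, i+1) x [j, j+1)} degrees. Duplicate presences of a
#' species in a cell collapse to one (presence, not abundance). When a
#' reference tree is supplied, records for species absent from it are
#' dropped with a message and counted in the \code{n_dropped} attribute.
#'
#' @param records A \code{data.frame} with columns \code{species},
#'   \code{latitude} in [-90, 90) and \code{longitude} in [-180, 180).
#' @param tree Optional reference time tree used to screen species names.
#' @return A \code{data.frame} of class \code{occurrence_grid} with one row
#'   per (cell, species) presence: columns \code{cell_lat}, \code{cell_lon},
#'   \code{species}; attribute \code{n_dropped} counts discarded records of
#'   unknown species.
#' @export
build_grid <- function(records, tree = NULL) {
  need <- c("species", "latitude", "longitude")
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lat <- records$latitude
  lon <- records$longitude
  bad <- which(!is.finite(lat) | lat < -90 | lat >= 90 |
                 !is.finite(lon) | lon < -180 | lon >= 180)
  if (length(bad)) {
    stop("out-of-range coordinates at row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ...", call. = FALSE)
  }
  species <- as.character(records$species)
  n_dropped <- 0L
  if (!is.null(tree)) {
    known <- species %in% tree$tip.label
    n_dropped <- sum(!known)
    if (n_dropped) {
      message(n_dropped, " record(s) of species absent from the tree dropped")
      species <- species[known]
      lat <- lat[known]
      lon <- lon[known]
    }
  }
  g <- unique(data.frame(cell_lat = floor(lat), cell_lon = floor(lon),
                         species = species, stringsAsFactors = FALSE))
  g <- g[order(g$cell_lat, g$cell_lon, g$species), , drop = FALSE]
  rownames(g) <- NULL
  structure(g, class = c("occurrence_grid", "data.frame"),
            n_dropped = n_dropped)
}

#' Drop species-poor cells
#'
#' Retains exactly the cells holding at least \code{min_sr} species. The
#' default keeps cells with more than 10 species, the threshold below which
#' the small-sample bias of the effective-sampling-proportion estimate
#' makes PS unreliable.
#'
#' @param grid An [build_grid()] occurrence grid.
#' @param min_sr Minimum species richness for a cell to be kept.
#' @return The filtered \code{occurrence_grid}.
#' @export
filter_cells <- function(grid, min_sr = 11L) {
  key <- paste(grid$cell_lat, grid$cell_lon, sep = "/")
  keep <- key %in% names(which(table(key) >= min_sr))
  out <- grid[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("occurrence_grid", "data.frame"),
            n_dropped = attr(grid, "n_dropped"))
}

#' Per-cell diversity index table
#'
#' Runs [community_indices()] for every cell of an occurrence grid against
#' a meta-community tree, producing the per-cell table that downstream
#' ranking, priority selection and correlation summaries consume.
#'
#' @param grid An occurrence grid (typically already passed through
#'   [filter_cells()]); cells with fewer than 2 species are skipped with a
#'   warning.
#' @param tree The meta-community time tree.
#' @param meta_params [bd_params()] with the meta-community rate estimates,
#'   e.g. from [fit_speciation_extinction()] on the tree's own divergence
#'   times.
#' @param S_meta Meta-community size; defaults to the tree's tip count.
#' @param min_sr_ps Minimum richness for the PS/PE fit (see
#'   [community_indices()]).
#' @return A \code{data.frame} with columns \code{cell_lat}, \code{cell_lon},
#'   \code{sr}, \code{pd}, \code{avtd}, \code{rho0}, \code{rhoE}, \code{ps},
#'   \code{pe}, \code{flags}, one row per cell.
#' @export
cell_index_table <- function(grid, tree, meta_params,
                             S_meta = length(tree$tip.label),
                             min_sr_ps = 11L) {
  cells <- unique(grid[c("cell_lat", "cell_lon")])
  if (nrow(cells) == 0L) stop("empty grid", call. = FALSE)
  rows <- vector("list", nrow(cells))
  skipped <- 0L
  for (i in seq_len(nrow(cells))) {
    sel <- grid$cell_lat == cells$cell_lat[i] &
      grid$cell_lon == cells$cell_lon[i]
    members <- grid$species[sel]
    if (length(unique(members)) < 2L) {
      skipped <- skipped + 1L
      next
    }
    ci <- community_indices(tree, members, meta_params,
                            S_meta = S_meta, min_sr_ps = min_sr_ps)
    rows[[i]] <- cbind(cells[i, , drop = FALSE], ci)
  }
  if (skipped) warning(skipped, " cell(s) with < 2 species skipped")
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Percentile ranks with mid-rank ties
#'
#' Maps values to ranks in [0, 100], each rank the average of the fraction
#' of values strictly below and the fraction at-or-below (the mid-rank
#' convention), i.e. \code{100 * (rank - 0.5) / n} with average ranks for
#' ties. Order-preserving and invariant under strictly increasing
#' transforms of the values.
#'
#' @param values Numeric vector (NA values get NA ranks).
#' @return Numeric vector of percentile ranks in [0, 100].
#' @export
percentile_rank <- function(values) {
  out <- rep(NA_real_, length(values))
  ok <- !is.na(values)
  n <- sum(ok)
  if (n == 0L) return(out)
  out[ok] <- 100 * (rank(values[ok], ties.method = "average") - 0.5) / n
  out
}

#' Select top-percentile priority cells
#'
#' Flags, for each of PD, AvTD, PE and SR, the cells whose value falls in
#' the top \code{1 - quantile} fraction: the threshold is the k-th largest
#' value with \code{k = ceiling((1 - quantile) * n)}, and every cell at or
#' above it is flagged (ties at the threshold included, so a flag set can
#' exceed k). The phylogenetic priority set is the union of the PD, AvTD
#' and PE flags; the full priority set additionally unions the SR flags.
#' A constant index column makes every cell pass its degenerate threshold;
#' a warning is emitted.
#'
#' @param index_table A [cell_index_table()] data frame (already filtered to
#'   cells with PS/PE available).
#' @param quantile Percentile cutoff as a fraction; 0.95 selects the top 5%.
#' @return The table with added logical columns \code{pd_top},
#'   \code{avtd_top}, \code{pe_top}, \code{sr_top},
#'   \code{phylogenetic_priority} and \code{full_priority}.
#' @export
select_priority <- function(index_table, quantile = 0.95) {
  if (nrow(index_table) == 0L) stop("empty index table", call. = FALSE)
  if (quantile <= 0 || quantile >= 1) {
    stop("quantile must be in (0, 1)", call. = FALSE)
  }
  flag_top <- function(x, label) {
    ok <- !is.na(x)
    n <- sum(ok)
    if (n == 0L) return(rep(FALSE, length(x)))
    # guard the ceiling against floating-point excess in (1 - quantile) * n
    k <- max(1L, ceiling((1 - quantile) * n - 1e-9))
    thr <- sort(x[ok], decreasing = TRUE)[k]
    if (length(unique(x[ok])) == 1L) {
      warning("index '", label, "' is constant; all cells flagged")
    }
    !is.na(x) & x >= thr
  }
  out <- index_table
  out$pd_top <- flag_top(out$pd, "pd")
  out$avtd_top <- flag_top(out$avtd, "avtd")
  out$pe_top <- flag_top(out$pe, "pe")
  out$sr_top <- flag_top(out$sr, "sr")
  out$phylogenetic_priority <- out$pd_top | out$avtd_top | out$pe_top
  out$full_priority <- out$phylogenetic_priority | out$sr_top
  out
}

#' Pearson correlations among the diversity indices
#'
#' Symmetric Pearson correlation matrix over SR, PD, AvTD and PE across
#' cells, with unit diagonal. A zero-variance column yields NA entries and
#' a warning.
#'
#' @param index_table A [cell_index_table()] data frame with at least 3
#'   complete rows.
#' @return A 4x4 named correlation matrix.
#' @export
correlate_indices <- function(index_table) {
  cols <- c("sr", "pd", "avtd", "pe")
  m <- as.matrix(index_table[, cols])
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3L) stop("need at least 3 complete cells", call. = FALSE)
  degenerate <- cols[apply(m, 2L, function(x) stats::var(x) == 0)]
  if (length(degenerate)) {
    warning("zero-variance column(s): ", paste(degenerate, collapse = ", "))
  }
  suppressWarnings(stats::cor(m, method = "pearson"))
}

#' Latitudinal profile of a diversity index
#'
#' Bins cells into latitude bands, reports per-band means and counts, and
#' fits locally weighted scatterplot smoothing (LOWESS, span 2/3, tricube
#' weights) trends of the index against absolute and signed cell latitude.
#' Cell latitude is taken at the cell center (\code{cell_lat + 0.5}).
#'
#' @param index_table A [cell_index_table()] data frame.
#' @param index Name of the index column to profile (e.g. \code{"pe"}).
#' @param bin_width Width of the latitude bands in degrees.
#' @return A list with \code{bins} (data frame: \code{lat_mid},
#'   \code{mean}, \code{n}; empty bands omitted), \code{lowess_abs} and
#'   \code{lowess_signed} (each a list of \code{x}, \code{y}), and
#'   \code{cor_abs}, the Pearson correlation of the index with absolute
#'   latitude.
#' @export
latitude_profile <- function(index_table, index, bin_width = 10) {
  if (!index %in% names(index_table)) {
    stop("no column '", index, "' in the index table", call. = FALSE)
  }
  lat <- index_table$cell_lat + 0.5
  val <- index_table[[index]]
  ok <- !is.na(val)
  lat <- lat[ok]; val <- val[ok]
  if (!length(val)) stop("no non-missing values for '", index, "'",
                         call. = FALSE)
  band <- floor(lat / bin_width) * bin_width
  agg <- stats::aggregate(val, by = list(band = band),
                          FUN = function(x) c(mean = mean(x), n = length(x)))
  bins <- data.frame(lat_mid = agg$band + bin_width / 2,
                     mean = agg$x[, "mean"], n = agg$x[, "n"])
  list(
    bins = bins,
    lowess_abs = stats::lowess(abs(lat), val, f = 2 / 3),
    lowess_signed = stats::lowess(lat, val, f = 2 / 3),
    cor_abs = if (length(val) >= 3 && stats::var(val) > 0 &&
                    stats::var(abs(lat)) > 0)
      stats::cor(abs(lat), val) else NA_real_
  )
}

#' Write a cell index table as CSV
#'
#' Emits the per-cell table with a stable column order
#' (cell_lat, cell_lon, sr, pd, avtd, rho0, rhoE, ps, pe, flags, plus any
#' priority flag columns present).
#'
#' @param index_table A [cell_index_table()] data frame.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_index_table <- function(index_table, path) {
  lead <- c("cell_lat", "cell_lon", "sr", "pd", "avtd", "rho0", "rhoE",
            "ps", "pe", "flags")
  cols <- c(intersect(lead, names(index_table)),
            setdiff(names(index_table), lead))
  utils::write.csv(index_table[, cols], path, row.names = FALSE)
  invisible(path)
}
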