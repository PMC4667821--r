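test_that("records rasterize to floor-indexed presence cells", {
  rec <- data.frame(
    species = c("X", "X", "Y", "Y", "Z"),
    latitude = c(10.5, 10.9, 10.5, -0.2, 10.5),
    longitude = c(-75.2, -75.9, -75.2, 5.0, -75.2)
  )
  g <- build_grid(rec)
  expect_s3_class(g, "occurrence_grid")
  # X twice in cell (10, -76) collapses to a single presence
  expect_equal(nrow(g[g$species == "X", ]), 1L)
  expect_equal(g[g$species == "X", c("cell_lat", "cell_lon")],
               data.frame(cell_lat = 10, cell_lon = -76),
               ignore_attr = TRUE)
  expect_equal(sort(unique(paste(g$cell_lat, g$cell_lon))),
               sort(c("10 -76", "-1 5")))

  # idempotence: duplicating every record changes nothing
  expect_equal(as.data.frame(build_grid(rbind(rec, rec))), as.data.frame(g))

  bad <- data.frame(species = "X", latitude = 95, longitude = 0)
  expect_error(build_grid(bad), "out-of-range.*row")
})

test_that("a hand-built occurrence table yields the expected cell sets", {
  rec <- expand.grid(species = paste0("s", 1:5),
                     cell = c("a", "b", "c"), stringsAsFactors = FALSE)
  rec$latitude <- c(a = 0.5, b = 20.5, c = -45.5)[rec$cell]
  rec$longitude <- c(a = 0.5, b = 100.5, c = -10.5)[rec$cell]
  rec <- rec[-c(1, 7, 8), ]            # knock a few presences out
  g <- build_grid(rec)
  sets <- split(g$species, paste(g$cell_lat, g$cell_lon))
  expect_equal(sets[["0 0"]], c("s2", "s3", "s4", "s5"))
  expect_equal(sets[["20 100"]], c("s1", "s4", "s5"))
  expect_equal(sets[["-46 -11"]], paste0("s", 1:5))
})

test_that("species unknown to the tree are dropped and counted", {
  tr <- toy_tree()
  rec <- data.frame(species = c("A", "B", "Q"), latitude = 1.1,
                    longitude = 2.2)
  expect_message(g <- build_grid(rec, tree = tr), "1 record")
  expect_equal(attr(g, "n_dropped"), 1L)
  expect_setequal(g$species, c("A", "B"))
})

test_that("cell filter keeps exactly the cells above the richness cutoff", {
  rec <- rbind(
    data.frame(species = paste0("a", 1:10), latitude = 0.5, longitude = 0.5),
    data.frame(species = paste0("b", 1:11), latitude = 5.5, longitude = 5.5),
    data.frame(species = paste0("c", 1:30), latitude = 9.5, longitude = 9.5)
  )
  g <- filter_cells(build_grid(rec))
  kept <- unique(g[c("cell_lat", "cell_lon")])
  expect_equal(nrow(kept), 2L)               # the 10-species cell is gone
  expect_false(any(kept$cell_lat == 0))

  counts <- table(paste(g$cell_lat, g$cell_lon))
  expect_true(all(counts >= 11))
  expect_equal(sum(counts), 11 + 30)
})

test_that("percentile ranks use the mid-rank convention", {
  expect_equal(percentile_rank(c(1, 2, 3, 4)), c(12.5, 37.5, 62.5, 87.5))
  expect_equal(percentile_rank(rep(7, 5)), rep(50, 5))
  set.seed(701)
  x <- rnorm(50)
  r <- percentile_rank(x)
  expect_equal(order(r), order(x))
  expect_equal(r, percentile_rank(exp(x)))   # increasing-transform invariant
  expect_equal(percentile_rank(c(1, NA, 2)), c(25, NA, 75))
})

test_that("priority selection flags the top tail, ties included", {
  tab <- data.frame(cell_lat = 0:99, cell_lon = 0, sr = 1:100,
                    pd = 100:1, avtd = seq(0.5, 50, 0.5), pe = runif(100))
  set.seed(702)
  tab$pe <- rnorm(100)
  pri <- select_priority(tab, quantile = 0.95)
  expect_equal(sum(pri$sr_top), 5L)
  expect_equal(sum(pri$pd_top), 5L)
  expect_equal(sum(pri$avtd_top), 5L)
  expect_equal(sum(pri$pe_top), 5L)
  expect_true(all(pri$sr[pri$sr_top] >= 96))
  expect_true(all(pri$full_priority[pri$phylogenetic_priority]))

  # nesting: a laxer cutoff can only add cells
  pri90 <- select_priority(tab, quantile = 0.90)
  for (col in c("pd_top", "avtd_top", "pe_top", "sr_top")) {
    expect_true(all(pri90[[col]][pri[[col]]]))
  }

  const <- tab
  const$avtd <- 1
  expect_warning(pri_const <- select_priority(const), "constant")
  expect_true(all(pri_const$avtd_top))

  expect_error(select_priority(tab[0, ]), "empty")
})

test_that("disjoint richness and evenness hotspots enlarge the full union", {
  n <- 60
  mid_peak <- c(rep(1, 3), 10, 11, 12, rep(2, n - 6))
  tab <- data.frame(cell_lat = seq_len(n), cell_lon = 0,
                    sr = c(rep(10, n - 3), 50, 60, 70),
                    pd = mid_peak, avtd = mid_peak / 10,
                    pe = c(5, 4, 3, rep(1, n - 3)))
  pri <- select_priority(tab)
  expect_gt(sum(pri$full_priority), sum(pri$phylogenetic_priority))
})

test_that("index correlations form a valid Pearson matrix", {
  set.seed(703)
  tab <- data.frame(cell_lat = 1:40, cell_lon = 0, sr = rpois(40, 30))
  tab$pd <- 2 * tab$sr                        # planted exact dependence
  tab$avtd <- rnorm(40, 5)
  tab$pe <- rnorm(40, 1)
  m <- correlate_indices(tab)
  expect_equal(diag(m), c(sr = 1, pd = 1, avtd = 1, pe = 1))
  expect_equal(m, t(m))
  expect_equal(m["sr", "pd"], 1, tolerance = 1e-12)

  tab$avtd <- 3
  expect_warning(m2 <- correlate_indices(tab), "zero-variance")
  expect_true(is.na(m2["avtd", "pe"]))
  expect_error(correlate_indices(tab[1:2, ]), "at least 3")
})

test_that("latitude profiles expose planted gradients and symmetry", {
  lat <- seq(-59.5, 59.5, by = 1)
  tab <- data.frame(cell_lat = floor(lat), cell_lon = 0,
                    pe = abs(lat) / 60)
  prof <- latitude_profile(tab, "pe")
  expect_gt(prof$cor_abs, 0.99)
  expect_equal(nrow(prof$bins), 12L)
  expect_true(all(prof$bins$n == 10))
  # construction symmetric north/south: mirrored bands agree
  south <- prof$bins$mean[prof$bins$lat_mid < 0]
  north <- prof$bins$mean[prof$bins$lat_mid > 0]
  expect_equal(rev(south), north, tolerance = 1e-12)

  one_bin <- data.frame(cell_lat = c(3, 5, 7), cell_lon = 0, pe = c(1, 2, 6))
  p1 <- latitude_profile(one_bin, "pe")
  expect_equal(nrow(p1$bins), 1L)
  expect_equal(p1$bins$mean, 3)
  expect_error(latitude_profile(one_bin, "nope"), "no column")
})

test_that("the index table round-trips through CSV with stable columns", {
  tr <- simulate_timetree(40, bd_params(8, 2, 1), seed = 704)
  rec <- rbind(
    data.frame(species = tr$tip.label[1:15], latitude = 0.5, longitude = 0.5),
    data.frame(species = tr$tip.label[20:39], latitude = 50.5,
               longitude = 10.5)
  )
  g <- filter_cells(build_grid(rec, tree = tr))
  tab <- cell_index_table(g, tr, bd_params(8, 2, 1))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$sr, c(15L, 20L))
  expect_equal(tab$rho0, c(15, 20) / 40)

  path <- withr::local_tempfile(fileext = ".csv")
  write_index_table(tab, path)
  back <- utils::read.csv(path)
  expect_equal(names(back)[1:10],
               c("cell_lat", "cell_lon", "sr", "pd", "avtd", "rho0",
                 "rhoE", "ps", "pe", "flags"))
  expect_equal(back$ps, tab$ps, tolerance = 1e-12)
})
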