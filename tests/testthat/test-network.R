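test_that("matrix and edge-list formats read the same network", {
  mat_file <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",a1,a2", "p1,3,0", "p2,1,2"), mat_file)
  edge_file <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("plant,pollinator,count", "p1,a1,3", "p2,a1,1", "p2,a2,2"),
             edge_file)

  n1 <- read_network(mat_file, "matrix_csv", site_id = "S1",
                     treatment = "restored", period = "2012-09")
  n2 <- read_network(edge_file, "edge_list_csv", site_id = "S1",
                     treatment = "restored", period = "2012-09")

  expect_equal(length(n1$plant_ids) + length(n1$pollinator_ids), 4)
  expect_equal(sum(n1$counts > 0), 3)
  expect_equal(sum(n1$counts), 6)
  expect_equal(n1$counts[n2$plant_ids, n2$pollinator_ids], n2$counts)
})

test_that("reading a written network round-trips bit-exactly", {
  set.seed(7)
  net <- make_net(random_count_matrix(4, 5))
  for (fmt in c("matrix_csv", "edge_list_csv")) {
    f <- withr::local_tempfile(fileext = ".csv")
    write_network(net, f, fmt)
    back <- read_network(f, fmt, site_id = net$site_id,
                         treatment = net$treatment, period = net$period)
    expect_identical(back$counts[net$plant_ids, net$pollinator_ids] * 1,
                     net$counts * 1, label = fmt)
  }
})

test_that("invalid inputs are rejected at construction and read time", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("plant,pollinator,count", "p1,a1,-1"), f)
  expect_error(read_network(f, "edge_list_csv"), "negative")
  expect_error(make_net(matrix(c(-1, 2, 0, 1), 2, 2)), "non-negative")
  expect_error(make_net(matrix(c(0.5, 2, 0, 1), 2, 2)), "integral")
  expect_error(make_net(matrix(1, 2, 2), plants = c("x", "x")), "duplicated")
  expect_error(make_net(matrix(1, 2, 2), plants = c("x", "a1")), "duplicated")
  expect_error(make_net(matrix(1, 1, 1), treatment = "mowed"), "treatment")
})

test_that("guild filter removes vertebrates and orphaned plants, keeps order", {
  meta <- dplyr::bind_rows(
    default_meta <- tibble::tibble(
      species_id = c("p1", "p2", "a1", "a2", "a3", "gecko"),
      guild = c("plant", "plant", rep("pollinator", 4)),
      taxon_group = c("Angiospermae", "Angiospermae", "Insecta", "Insecta",
                      "Insecta", "Gekkonidae"),
      is_vertebrate = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)))
  m <- rbind(c(1, 2, 0, 5), c(0, 0, 3, 0))
  net <- make_net(m, plants = c("p1", "p2"),
                  polls = c("a1", "a2", "a3", "gecko"), species_meta = meta)

  kept <- filter_guild(net, exclude_vertebrates = TRUE)
  expect_identical(kept$pollinator_ids, c("a1", "a2", "a3"))
  expect_identical(kept$plant_ids, c("p1", "p2"))

  # p2 interacts only via the gecko in this variant -> dropped with it
  m2 <- rbind(c(1, 2, 0, 5), c(0, 0, 0, 3))
  net2 <- make_net(m2, plants = c("p1", "p2"),
                   polls = c("a1", "a2", "a3", "gecko"), species_meta = meta)
  expect_identical(filter_guild(net2, TRUE)$plant_ids, "p1")

  expect_identical(filter_guild(net, exclude_vertebrates = FALSE), net)

  meta_bird <- tibble::tibble(species_id = c("p1", "bird"),
                              guild = c("plant", "pollinator"),
                              taxon_group = c(NA, "Nectariniidae"),
                              is_vertebrate = c(FALSE, TRUE))
  only_bird <- make_net(matrix(4, 1, 1), plants = "p1", polls = "bird",
                        species_meta = meta_bird)
  expect_error(filter_guild(only_bird, TRUE), "no invertebrate")

  no_meta <- make_net(m, plants = c("p1", "p2"),
                      polls = c("a1", "a2", "a3", "gecko"),
                      species_meta = meta[1:4, ])
  expect_error(filter_guild(no_meta, TRUE), "metadata")
})

test_that("largest component keeps the block with most species", {
  # block A: 3 plants x 4 pollinators; block B: 1 plant x 1 pollinator
  m <- matrix(0, 4, 5)
  m[1:3, 1:4] <- matrix(c(1, 1, 0, 0, 1, 1, 1, 0, 1, 2, 0, 1), 3, 4)
  m[4, 5] <- 9
  net <- make_net(m)
  lc <- largest_component(net)
  expect_equal(length(lc$plant_ids) + length(lc$pollinator_ids), 7)
  expect_false("p4" %in% lc$plant_ids)
  # idempotent, identity on connected networks
  expect_identical(largest_component(lc), lc)
})

test_that("component ties break by total interaction count", {
  # two 1x1 components with equal species count, unequal weight
  m <- matrix(0, 2, 2)
  m[1, 1] <- 2
  m[2, 2] <- 7
  net <- make_net(m)
  memb <- components_oracle(net$counts)   # graph-traversal oracle
  expect_equal(max(memb), 2)
  lc <- largest_component(net)
  expect_identical(lc$plant_ids, "p2")
  expect_identical(lc$pollinator_ids, "a2")
})

test_that("seasonal pooling sums counts on the species union", {
  sep <- make_net(matrix(c(1, 0), 1, 2), plants = "p1",
                  polls = c("a1", "a2"), period = "2012-09")
  oct <- make_net(matrix(c(2, 1), 1, 2), plants = "p1",
                  polls = c("a1", "a2"), period = "2012-10")
  nov <- make_net(matrix(1, 1, 1), plants = "p1", polls = "a1",
                  period = "2012-11")
  dec <- make_net(matrix(1, 1, 1), plants = "p1", polls = "a1",
                  period = "2012-12")
  jan <- make_net(matrix(c(4, 5), 2, 1), plants = c("p1", "pjan"),
                  polls = "a1", period = "2013-01")
  feb <- make_net(matrix(1, 1, 1), plants = "p1", polls = "a1",
                  period = "2013-02")
  mar <- make_net(matrix(1, 1, 1), plants = "p1", polls = "a1",
                  period = "2013-03")
  apr <- make_net(matrix(1, 1, 1), plants = "p1", polls = "a1",
                  period = "2013-04")
  seasons <- pool_season(list(sep, oct, nov, dec, jan, feb, mar, apr))

  expect_equal(seasons$early$counts["p1", c("a1", "a2")], c(a1 = 5, a2 = 1))
  # a species present only in January appears in the late network only
  expect_false("pjan" %in% seasons$early$plant_ids)
  expect_true("pjan" %in% seasons$late$plant_ids)
  # conservation: pooled totals equal the sum of monthly totals
  monthly <- sum(vapply(list(sep, oct, nov, dec, jan, feb, mar, apr),
                        function(n) sum(n$counts), numeric(1)))
  expect_equal(sum(seasons$early$counts) + sum(seasons$late$counts), monthly)

  may <- make_net(matrix(1, 1, 1), plants = "p1", polls = "a1",
                  period = "2013-05")
  expect_error(pool_season(list(sep, may)), "September-April")
  expect_warning(pool_season(list(sep, jan)), "missing months")
})

test_that("a default synthetic month-level dataset pools to 16 networks", {
  ds <- generate_dataset(small_design(seed = 3,
                                      n_sites_per_treatment = 4))
  expect_length(ds$networks, 64)
  season <- pool_dataset(ds)
  expect_length(season$networks, 16)
  counts <- table(vapply(season$networks, `[[`, character(1), "treatment"))
  expect_equal(as.integer(counts[c("restored", "unrestored")]), c(8L, 8L))
})

test_that("a manifest round-trips a small dataset from disk", {
  dir <- withr::local_tempdir()
  nets <- list(
    make_net(rbind(c(2, 1), c(0, 3)), site = "S1", treatment = "restored",
             period = "2012-09"),
    make_net(rbind(c(1, 0), c(4, 2)), site = "S1", treatment = "restored",
             period = "2013-01"))
  for (i in seq_along(nets)) {
    write_network(nets[[i]], file.path(dir, paste0("net", i, ".csv")))
  }
  writeLines(c(
    "networks:",
    "  - {path: net1.csv, site: S1, treatment: restored, month: 2012-09}",
    "  - {path: net2.csv, site: S1, treatment: restored, month: 2013-01}"),
    file.path(dir, "manifest.yaml"))
  ds <- read_dataset(file.path(dir, "manifest.yaml"))
  expect_length(ds$networks, 2)
  expect_identical(ds$networks[[1]]$counts * 1, nets[[1]]$counts * 1)
  expect_identical(ds$networks[[2]]$period, "2013-01")

  # same manifest as JSON
  writeLines(paste0(
    '{"networks": [',
    '{"path": "net1.csv", "site": "S1", "treatment": "restored",',
    ' "month": "2012-09"},',
    '{"path": "net2.csv", "site": "S1", "treatment": "restored",',
    ' "month": "2013-01"}]}'),
    file.path(dir, "manifest.json"))
  ds2 <- read_dataset(file.path(dir, "manifest.json"))
  expect_identical(lapply(ds2$networks, `[[`, "counts"),
                   lapply(ds$networks, `[[`, "counts"))
})
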