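test_that("stem basal area follows the closed form", {
  expect_equal(stemBasalArea(30), pi * 0.15^2, tolerance = 1e-12)
  expect_equal(stemBasalArea(100 / sqrt(pi)), 0.25, tolerance = 1e-12)
  expect_error(stemBasalArea(0), "positive")
  expect_error(stemBasalArea(-3), "positive")
})

test_that("expansion factor uses the concentric circle the DBH qualifies for", {
  expect_equal(expansionFactor(30), 10000 / (pi * 15^2), tolerance = 1e-9)
  expect_equal(expansionFactor(15), 10000 / (pi * 10^2), tolerance = 1e-9)
  expect_equal(expansionFactor(8), 10000 / (pi * 5^2), tolerance = 1e-9)
  # numeric values from the circle areas
  expect_equal(expansionFactor(c(30, 15, 8)),
               c(14.14710605, 31.83098862, 127.32395447), tolerance = 1e-7)
  # boundary: 29.9 falls on the 10 m circle
  expect_equal(expansionFactor(29.9), 10000 / (pi * 10^2), tolerance = 1e-9)
  expect_error(expansionFactor(7.9), "census")
})

test_that("cluster filter rejects with one deterministic reason each", {
  st <- rbind(clean_stems("A"), clean_stems("B"), clean_stems("C"),
              clean_stems("D"), clean_stems("E"))
  st$slopover_flag[st$cluster_id == "B" & st$subplot_id == 2] <- TRUE
  st$species[st$cluster_id == "C"][1] <- "Deciduous spp."
  st$landuse_class[st$cluster_id == "D"] <- "Cropland"
  st <- st[!(st$cluster_id == "E" & st$subplot_id == 3), ]  # 2 subplots only
  flt <- filterClusters(st, filterConfig())
  rej <- flt$rejections[order(flt$rejections$cluster_id), ]
  expect_equal(rej$cluster_id, c("B", "C", "D", "E"))
  expect_equal(rej$reason, c("slopover", "non_species_taxon",
                             "landuse", "subplot_count"))
  expect_setequal(unique(flt$stems$cluster_id), "A")
})

test_that("clean tables pass untouched and full rejection errors", {
  st <- rbind(clean_stems("A"), clean_stems("B"))
  flt <- filterClusters(st)
  expect_equal(nrow(flt$rejections), 0L)
  expect_equal(nrow(flt$stems), nrow(st))
  bad <- clean_stems("A")
  bad$slopover_flag <- TRUE
  expect_error(filterClusters(bad), "empty sample")
})

test_that("bare genus names and synonym mapping are handled", {
  st <- rbind(clean_stems("A", species = c("Fagus", "Picea orientalis",
                                           "Carpinus betulus")),
              clean_stems("B"))
  expect_equal(filterClusters(st)$rejections$reason, "non_species_taxon")
  syn <- c("Fagus" = "Fagus orientalis")
  expect_equal(nrow(filterClusters(st, filterConfig(synonyms = syn))$rejections),
               0L)
})

test_that("community matrix entries match the per-stem closed form", {
  st <- clean_stems("A", dbh = c(30, 20, 12))
  cm <- buildCommunityMatrix(st)
  expect_equal(baMatrix(cm)["A", "Fagus orientalis"],
               stemBasalArea(30) * expansionFactor(30) / 3,
               tolerance = 1e-12)
  expect_equal(unname(baMatrix(cm)["A", "Fagus orientalis"]),
               0.070686 * 14.1471 / 3, tolerance = 1e-4)
  # dead stems do not contribute
  st2 <- rbind(st, transform(clean_stems("A", dbh = c(40, 40, 40)),
                             status = "dead"))
  cm2 <- buildCommunityMatrix(st2)
  expect_equal(baMatrix(cm2), baMatrix(cm))
})

test_that("community matrix is order-invariant, linear and conservative", {
  set.seed(42)
  st <- do.call(rbind, lapply(sprintf("C%02d", 1:6), function(id)
    clean_stems(id, dbh = round(runif(3, 8, 60), 1))))
  cm <- buildCommunityMatrix(st)
  cm_shuf <- buildCommunityMatrix(st[sample.int(nrow(st)), ])
  expect_equal(baMatrix(cm), baMatrix(cm_shuf))
  cm_dbl <- buildCommunityMatrix(rbind(st, st))
  expect_equal(baMatrix(cm_dbl), 2 * baMatrix(cm))
  # conservation: per-sample total equals a brute-force per-stem loop
  for (id in unique(st$cluster_id)) {
    rows <- st[st$cluster_id == id & st$status == "living", ]
    tot <- 0
    for (r in seq_len(nrow(rows)))
      tot <- tot + stemBasalArea(rows$dbh_cm[r]) *
        expansionFactor(rows$dbh_cm[r]) / 3
    expect_equal(unname(rowSums(baMatrix(cm))[id]), tot, tolerance = 1e-9)
  }
})

test_that("samples with no living stems are dropped and logged", {
  st <- rbind(clean_stems("A"),
              transform(clean_stems("B"), status = "dead"))
  cm <- buildCommunityMatrix(st)
  expect_equal(rownames(baMatrix(cm)), "A")
  expect_equal(attr(cm, "dropped"), "B")
})

test_that("subplot elevation is the median over intersected cells", {
  const <- list(ncols = 4, nrows = 4, xll = 0, yll = 0, cellsize = 30,
                nodata = -9999, z = matrix(1500, 4, 4))
  expect_equal(sampleElevation(const, c(60, 60), 15, 5), 1500)
  g33 <- list(ncols = 3, nrows = 3, xll = 0, yll = 0, cellsize = 30,
              nodata = -9999, z = matrix(1:9, 3, 3, byrow = TRUE))
  # circle strictly inside the centre cell (value 5)
  expect_equal(sampleElevation(g33, c(45, 45), 10, 0), 5)
  # r = 18 reaches the lateral cells but not the diagonal ones:
  # cells {4,5,6}, median 5
  expect_equal(sampleElevation(g33, c(45, 45), 18, 0), 5)
  # brute-force cell-circle oracle on an asymmetric circle
  ctr <- c(50, 40); r <- 25
  hit <- c()
  for (row in 1:3) for (col in 1:3) {
    x0 <- (col - 1) * 30; y0 <- (3 - row) * 30
    dx <- max(x0 - ctr[1], 0, ctr[1] - (x0 + 30))
    dy <- max(y0 - ctr[2], 0, ctr[2] - (y0 + 30))
    if (dx^2 + dy^2 <= r^2) hit <- c(hit, g33$z[row, col])
  }
  expect_equal(sampleElevation(g33, ctr, r, 0), median(hit))
  expect_error(sampleElevation(g33, c(1000, 1000), 15, 0), "outside")
  gna <- g33; gna$z[] <- -9999
  expect_error(sampleElevation(gna, c(45, 45), 10, 0), "no-data")
})

test_that("ascii raster and stem table round-trip through disk", {
  r <- list(ncols = 5, nrows = 3, xll = 10, yll = 20, cellsize = 30,
            nodata = -9999, z = matrix(round(runif(15), 3), 3, 5))
  f <- tempfile(fileext = ".asc")
  writeAsciiRaster(r, f)
  r2 <- readAsciiRaster(f)
  expect_equal(r2$z, r$z)
  expect_equal(r2$xll, r$xll)
  st <- clean_stems("A")
  st$x <- 1:3; st$y <- 4:6; st$gps_error_m <- 5
  f2 <- tempfile(fileext = ".csv")
  writeStemTable(st, f2)
  expect_equal(readStemTable(f2)$dbh_cm, st$dbh_cm)
})
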