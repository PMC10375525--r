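test_that("ring_radius inverts the chord formula and matches measured spacings", {
  # closed-form checks
  expect_equal(ring_radius(6, 1.3), 1.3)          # hexagon: radius = side
  expect_equal(ring_radius(4, 2), 2 / sqrt(2))    # square
  expect_equal(ring_radius(17, 1.95), 1.95 / (2 * sin(pi / 17)))
  expect_equal(ring_radius(17, 1.95), 5.306, tolerance = 1e-3)

  # oracle: place the points, measure adjacent distances
  for (n in c(3, 5, 17)) {
    spec <- ring_array_spec(n, 1.95, n_layers = 1)
    pts <- build_disk(spec, label = "d")
    d <- sqrt(diff(pts$x_nm)^2 + diff(pts$y_nm)^2 + diff(pts$z_nm)^2)
    expect_equal(d, rep(1.95, n - 1), tolerance = 1e-6)
  }

  expect_error(ring_radius(1, 1))
  expect_error(ring_radius(17, 0))
  expect_error(ring_array_spec(nn_spacing = -1))
  expect_error(ring_array_spec(n_layers = 3))
})

test_that("build_disk places the right number of equidistant sites per layer", {
  spec <- cptmv_spec()
  disk <- build_disk(spec, label = "donor")
  expect_equal(nrow(disk), 34)  # 17 sites x 2 layers per assembly

  # within each layer, all sites equidistant from the disk axis
  r <- ring_radius(17, 1.95)
  for (l in 1:2) {
    lay <- disk[disk$layer_index == l, ]
    expect_equal(sqrt(lay$x_nm^2 + lay$y_nm^2), rep(r, 17), tolerance = 1e-9)
  }

  # single layer at arbitrary centre: all points at ring_radius from centre
  ctr <- c(3, -2, 1)
  one <- build_disk(ring_array_spec(9, 1.2, n_layers = 1), center = ctr)
  expect_equal(sqrt((one$x_nm - ctr[1])^2 + (one$y_nm - ctr[2])^2 +
                      (one$z_nm - ctr[3])^2),
               rep(ring_radius(9, 1.2), 9), tolerance = 1e-9)

  # degenerate layer separation with no azimuthal offset: layers coincide
  flat <- build_disk(ring_array_spec(17, 1.95, 2, 0, 0), label = "d")
  l1 <- flat[flat$layer_index == 1, c("x_nm", "y_nm", "z_nm")]
  l2 <- flat[flat$layer_index == 2, c("x_nm", "y_nm", "z_nm")]
  expect_equal(unname(as.matrix(l1)), unname(as.matrix(l2)))
})

test_that("couple_disks calibrates the closest pair and reproduces the distance range", {
  geom <- couple_disks(cptmv_spec(), cptmv_spec(), closest_pair = 7.5)
  expect_equal(geom$center_separation, 7.5 + 2 * ring_radius(17, 1.95),
               tolerance = 1e-9)
  expect_equal(geom$center_separation, 18.11, tolerance = 1e-3)

  d <- inter_disk_distances(geom)
  expect_equal(min(d), 7.5, tolerance = 1e-6)
  expect_true(all(d >= 7.5 - 1e-6))
  # furthest donor-acceptor pair ~29 nm
  expect_equal(round(max(d)), 29)

  # single-site "disks": centre separation equals the target distance
  tiny <- ring_array_spec(2, 1e-6, n_layers = 1)
  g1 <- couple_disks(tiny, tiny, closest_pair = 7.5)
  expect_equal(min(inter_disk_distances(g1)), 7.5, tolerance = 1e-6)
  expect_equal(g1$center_separation, 7.5, tolerance = 1e-5)

  expect_error(couple_disks(cptmv_spec(), cptmv_spec(), closest_pair = -1))
})

test_that("couple_disks calibration holds over random geometries (property)", {
  set.seed(11)
  for (i in 1:25) {
    g <- random_coupled_geometry()
    expect_equal(min(inter_disk_distances(g)), g$closest_pair,
                 tolerance = 1e-6)
  }
  # mixed layer counts force the numeric calibration path
  set.seed(12)
  g <- couple_disks(ring_array_spec(7, 1.3, 2, 3.1),
                    ring_array_spec(11, 2.2, 1, 0), closest_pair = 6)
  expect_equal(min(inter_disk_distances(g)), 6, tolerance = 1e-6)
})

test_that("pathway_table computes normalized 1/R^6 weights sorted by distance", {
  # two-site rings colinear with the coupling axis give the four pair
  # distances R, R+2r, R+2r, R+4r; with r = R/2 that is R, 2R, 2R, 3R
  spec1 <- ring_array_spec(2, 6, n_layers = 1)  # radius 3
  g <- couple_disks(spec1, spec1, closest_pair = 6)
  tab <- pathway_table(g)
  expect_equal(tab$R_nm, c(6, 12, 12, 18), tolerance = 1e-9)
  expect_equal(sum(tab$weight), 1, tolerance = 1e-12)
  # analytic 1/R^6 ratio for a distance doubling: 64/65 vs 1/65
  expect_equal(tab$weight[1] / sum(tab$weight[1:2]), 64 / 65,
               tolerance = 1e-9)

  # equal distances share weight equally
  sq <- ring_array_spec(2, 4, n_layers = 1)  # two sites, symmetric coupling
  gq <- couple_disks(sq, sq, closest_pair = 5)
  tq <- pathway_table(gq)
  eq <- tq[abs(tq$R_nm - min(tq$R_nm)) < 1e-9, ]
  expect_true(all(abs(eq$weight - eq$weight[1]) < 1e-12))

  # full coupled-disk model: the multi-pathway bound
  full <- pathway_table(couple_disks())
  expect_equal(nrow(full), 34 * 34)
  expect_lte(max(full$weight), 0.12)
  expect_equal(full$R_nm, sort(full$R_nm))

  # top_k renormalises over the nearest subset (the 25-pair variant)
  top25 <- pathway_table(couple_disks(), top_k = 25)
  expect_equal(nrow(top25), 25)
  expect_equal(sum(top25$weight), 1, tolerance = 1e-12)
  expect_lte(max(top25$weight), 0.12)
  expect_error(pathway_table(couple_disks(), top_k = 1e6))
})

test_that("pathway weights sum to one and decrease with distance (property)", {
  set.seed(21)
  for (i in 1:25) {
    tab <- pathway_table(random_coupled_geometry())
    expect_equal(sum(tab$weight), 1, tolerance = 1e-12)
    expect_true(all(tab$weight >= 0))
    # strictly decreasing in distance wherever distances are distinct
    dR <- diff(tab$R_nm); dw <- diff(tab$weight)
    distinct <- dR > 1e-9
    expect_true(all(dw[distinct] < 0))
    expect_true(all(abs(dw[!distinct]) < 1e-12))
  }
})

test_that("rate_fold_change follows the inverse sixth power", {
  expect_equal(rate_fold_change(7.5, 3), (7.5 / 3)^6)
  expect_gt(rate_fold_change(7.5, 3), 200)
  expect_equal(rate_fold_change(2, 1), 64)
  expect_equal(rate_fold_change(5, 5), 1)
  # chain property: fold(a,b) * fold(b,c) = fold(a,c)
  set.seed(31)
  for (i in 1:20) {
    abc <- stats::runif(3, 0.5, 30)
    expect_equal(rate_fold_change(abc[1], abc[2]) *
                   rate_fold_change(abc[2], abc[3]),
                 rate_fold_change(abc[1], abc[3]),
                 tolerance = 1e-9)
  }
  expect_error(rate_fold_change(0, 1))
  expect_error(rate_fold_change(1, -2))
})

test_that("modified monomer counts reproduce the labelling stoichiometry", {
  m31 <- modified_monomer_count(0.31, 34)
  expect_equal(m31$expected, 10.54)
  expect_equal(round(m31$expected, 1), 10.5)
  m91 <- modified_monomer_count(0.91, 34)
  expect_equal(m91$nearest, 31)
  expect_equal(modified_monomer_count(0, 34)$expected, 0)
  expect_error(modified_monomer_count(1.2, 34))
  expect_error(modified_monomer_count(-0.1, 34))
})

test_that("geometry and pathway tables export as readable delimited text", {
  geom <- couple_disks()
  f1 <- withr::local_tempfile(fileext = ".tsv")
  write_geometry(geom, f1)
  back <- utils::read.delim(f1)
  expect_equal(nrow(back), 68)
  expect_named(back, c("disk_label", "layer_index", "site_index",
                       "x_nm", "y_nm", "z_nm"))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_geometry(pathway_table(geom), f2)
  ptab <- utils::read.delim(f2)
  expect_equal(ptab$R_nm, sort(ptab$R_nm))
  expect_equal(sum(ptab$weight), 1, tolerance = 1e-6)
})
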