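test_that("equal-conductivity spheres solution matches the closed form", {
  hm <- head_model(conductivities = c(0.33, 0.33, 0.33))
  mon <- default_montage()
  set.seed(11)
  for (i in 1:4) {
    r0 <- stats::runif(3, -1, 1)
    r0 <- r0 / sqrt(sum(r0^2)) * stats::runif(1, 5, 70)
    m <- stats::rnorm(3)
    p <- dipole_patch("V1", 1, r0, m / sqrt(sum(m^2)),
                      weights = sqrt(sum(m^2)))
    got <- dipole_potential(hm, p, mon)
    want <- homogeneous_sphere_potential(92, 0.33, r0, m, mon$positions)
    expect_lt(max(abs(got - want)) / max(abs(want)), 1e-3)
  }
})

test_that("radial gains reduce to (2n+1)/n for a homogeneous sphere", {
  hm <- head_model(conductivities = c(0.4, 0.4, 0.4))
  n <- 1:30
  expect_equal(mfvep:::radial_gains(hm, 30), (2 * n + 1) / n, tolerance = 1e-10)
})

test_that("potentials are axisymmetric, average-referenced, and superpose", {
  hm <- head_model()
  mon <- default_montage()
  # radial dipole on z-axis with electrodes on rings of constant polar
  # angle: the potential must be constant within each ring
  ring <- do.call(rbind, lapply(c(0.2, 0.5, 0.8), function(z) {
    phi <- seq(0, 2 * pi, length.out = 9)[-9]
    cbind(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
  }))
  rmon <- structure(list(labels = sprintf("R%02d", seq_len(nrow(ring))),
                         positions = ring), class = "electrode_montage")
  p <- dipole_patch("V1", 1, c(0, 0, 45), c(0, 0, 1))
  vr <- dipole_potential(hm, p, rmon)
  for (zz in c(0.2, 0.5, 0.8)) {
    expect_lt(diff(range(vr[abs(ring[, 3] - zz) < 1e-9])),
              1e-10 * max(abs(vr)))
  }
  v <- dipole_potential(hm, p, mon)
  expect_lt(abs(mean(v)), 1e-12 * max(abs(v)))
  # linearity in moment and additivity over dipoles
  p2 <- dipole_patch("V1", 1, c(10, -20, 30), c(1, 0, 0))
  v2 <- dipole_potential(hm, p2, mon)
  p2s <- dipole_patch("V1", 1, c(10, -20, 30), c(1, 0, 0), weights = 3.5)
  expect_equal(dipole_potential(hm, p2s, mon), 3.5 * v2, tolerance = 1e-12)
  both <- dipole_patch("V1", 1, rbind(c(0, 0, 45), c(10, -20, 30)),
                       rbind(c(0, 0, 1), c(1, 0, 0)))
  expect_equal(dipole_potential(hm, both, mon), v + v2, tolerance = 1e-12)
})

test_that("dipoles outside the brain shell are rejected", {
  hm <- head_model()
  mon <- default_montage()
  p <- dipole_patch("V1", 1, c(0, 0, 85), c(0, 0, 1))
  expect_error(dipole_potential(hm, p, mon), "brain shell")
  expect_error(head_model(shell_radii = c(85, 80, 92)), "increasing")
})

test_that("generated retinotopy carries the V1 cruciform signatures", {
  mon <- fix_montage()
  pm <- fix_predictions()
  v1 <- pm$values["V1", , ]
  # upper-field and mirrored lower-field wedges are anti-correlated
  for (w in 1:8) expect_lt(stats::cor(v1[w, ], v1[17 - w, ]), 0)
  # lateralization grows towards the vertical meridian, much more for V1
  # than for V3
  li <- function(a) vapply(1:16, function(w)
    lateralization_index(pm$values[a, w, ], mon), numeric(1))
  vert <- c(4, 5, 12, 13); horiz <- c(1, 8, 9, 16)
  d_v1 <- mean(li("V1")[vert]) - mean(li("V1")[horiz])
  d_v3 <- mean(li("V3")[vert]) - mean(li("V3")[horiz])
  expect_gt(d_v1, 0)
  expect_lt(abs(d_v3), d_v1 / 2)
})

test_that("prediction matrix geometry, identifiability and linearity", {
  hm <- fix_head()
  mon <- fix_montage()
  pats <- retinotopic_patches(hm)
  expect_length(pats, 8 * 16)
  pm <- fix_predictions()
  expect_identical(dim(pm$values), c(8L, 16L, 128L))
  expect_length(stack_regressor(pm, "V1"), 2048L)
  # every topography is average-referenced
  expect_lt(max(abs(apply(pm$values, c(1, 2), mean))), 1e-12 * max(abs(pm$values)))
  # areas are mutually identifiable
  S <- sapply(pm$area_names, function(a) stack_regressor(pm, a))
  cc <- stats::cor(S)
  expect_lt(max(abs(cc[row(cc) != col(cc)])), 0.95)
  # single-dipole patch equals the bare dipole potential
  p1 <- dipole_patch("X", 1, c(0, -40, 20), c(0, 1, 0))
  pm1 <- build_prediction_matrix(list(p1), hm, mon)
  expect_equal(as.numeric(pm1$values["X", 1, ]),
               as.numeric(dipole_potential(hm, p1, mon)), tolerance = 1e-12)
  # doubling moments doubles topographies
  p2 <- dipole_patch("X", 1, c(0, -40, 20), c(0, 1, 0), weights = 2)
  pm2 <- build_prediction_matrix(list(p2), hm, mon)
  expect_equal(pm2$values, 2 * pm1$values, tolerance = 1e-12)
  # missing pairs are reported
  expect_error(build_prediction_matrix(pats[-3], hm, mon), "missing")
})

test_that("prediction matrix text round trip and validation", {
  sm <- fix_small()
  mon <- sm$montage
  pm <- sm$pm
  path <- withr::local_tempfile(fileext = ".tsv")
  write_prediction_matrix(pm, path)
  rt <- load_prediction_matrix(path, mon)
  expect_equal(rt$values, pm$values, tolerance = 1e-12)

  # permuted channel columns are re-aligned to the montage order
  tab <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  perm <- c(1, 2, 2 + sample(16))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tab[, perm], path2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  rt2 <- load_prediction_matrix(path2, mon)
  expect_equal(rt2$values, pm$values, tolerance = 1e-12)

  # a missing area is an error naming the gap
  tab_v1 <- tab[tab$area != "V2", ]
  path3 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tab_v1, path3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_no_error(load_prediction_matrix(path3, mon))  # V1 alone is complete
  tab_bad <- tab[-2, ]  # drop one wedge of V1
  path4 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tab_bad, path4, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_prediction_matrix(path4, mon), "V1")
})

test_that("montage files round trip with unit normalization", {
  mon <- default_montage(8)
  path <- withr::local_tempfile(fileext = ".sfp")
  write_montage(mon, path)
  rt <- read_montage(path)
  expect_equal(rt$positions, mon$positions, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(rt$labels, mon$labels)
})
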