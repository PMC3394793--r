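## small helpers to build explicit frames
mk_frame <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(id = i, x = r$p[1], y = r$p[2], z = r$p[3],
               element = r$el, role = r$role, molecule = r$mol,
               h_parent = r$hp %||% NA_integer_)
  }))
  df
}

test_that("hydrogen-bond detection applies both criteria strictly", {
  crit <- hbond_criteria()   # 0.35 nm, 30 degrees
  lin <- function(da) mk_frame(
    list(p = c(0, 0, 0), el = "N", role = "donor", mol = "protein"),
    list(p = c(0.10, 0, 0), el = "H", role = "donor_H", mol = "protein",
         hp = 1),
    list(p = c(da, 0, 0), el = "O", role = "acceptor", mol = "drug"))
  hit <- detect_hbonds(lin(0.29), 1, 2, 3, crit)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$deviation, 0, tolerance = 1e-9)
  expect_equal(nrow(detect_hbonds(lin(0.40), 1, 2, 3, crit)), 0L)
  expect_equal(nrow(detect_hbonds(lin(0.35), 1, 2, 3, crit)), 0L)  # strict
  ## a hydrogen without its donor parent is an input error
  bad <- lin(0.29); bad$h_parent[2] <- NA
  expect_error(detect_hbonds(bad, 1, 2, 3, crit), "donor parent")
})

test_that("water bridges require simultaneous bonds to both molecules", {
  ang <- 104.5 * pi / 180
  u2 <- c(cos(ang), sin(ang), 0)
  bridge <- mk_frame(
    list(p = c(0, 0, 0), el = "O", role = "water_O", mol = "water"),
    list(p = c(0.096, 0, 0), el = "H", role = "water_H", mol = "water",
         hp = 1),
    list(p = 0.096 * u2, el = "H", role = "water_H", mol = "water", hp = 1),
    list(p = c(0.28, 0, 0), el = "O", role = "acceptor", mol = "protein"),
    list(p = 0.28 * u2, el = "O", role = "acceptor", mol = "drug"))
  expect_equal(detect_water_bridges(bridge), 1L)
  ## water bonded to the protein only
  protein_only <- bridge[-5, ]
  expect_equal(detect_water_bridges(protein_only), 0L)
  ## two chained waters do not form a bridge
  chain <- mk_frame(
    list(p = c(0, 0, 0), el = "O", role = "acceptor", mol = "protein"),
    list(p = c(0.28, 0, 0), el = "O", role = "water_O", mol = "water"),
    list(p = c(0.28 + 0.096, 0, 0), el = "H", role = "water_H",
         mol = "water", hp = 2),
    list(p = c(0.56, 0, 0), el = "O", role = "water_O", mol = "water"),
    list(p = c(0.56 + 0.096, 0, 0), el = "H", role = "water_H",
         mol = "water", hp = 4),
    list(p = c(0.84, 0, 0), el = "O", role = "acceptor", mol = "drug"))
  ## water 2 bonds water 4 and water 4 bonds the drug: no single-water bridge
  expect_equal(detect_water_bridges(chain), 0L)
})

test_that("hydrophobic pair counting is strict at the cutoff", {
  fr <- mk_frame(
    list(p = c(0, 0, 0), el = "C", role = "apolar_C", mol = "protein"),
    list(p = c(0.40, 0, 0), el = "C", role = "apolar_C", mol = "drug"),
    list(p = c(5, 0, 0), el = "C", role = "apolar_C", mol = "drug"))
  expect_equal(count_hydrophobic_pairs(fr), 1L)
  fr$x[2] <- 0.45
  expect_equal(count_hydrophobic_pairs(fr), 0L)   # exactly at cutoff: out
  expect_warning(
    n0 <- count_hydrophobic_pairs(fr[fr$molecule == "drug", ]), "empty")
  expect_equal(n0, 0L)
})

test_that("detectors reproduce planted scenes and are rigid-motion invariant", {
  sc <- build_planted_scene(3, 2, 5, seed = 17)
  cc <- count_contacts(sc$atoms, sc$criteria, sc$hydrophobic_cutoff)
  expect_equal(unname(cc), c(3, 2, 5))
  ## global rotation + translation leaves every count unchanged
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
              byrow = TRUE)
  xyz <- as.matrix(sc$atoms[, c("x", "y", "z")]) %*% t(R)
  moved <- sc$atoms
  moved[, c("x", "y", "z")] <- sweep(xyz, 2, c(1.5, -2, 0.3), `+`)
  cc2 <- count_contacts(moved, sc$criteria, sc$hydrophobic_cutoff)
  expect_equal(cc2, cc)
})

test_that("contact profiles bin frames by control parameter", {
  sc1 <- build_planted_scene(2, 1, 3, seed = 61)
  sc2 <- build_planted_scene(1, 1, 3, seed = 62)   # one hydrogen bond lost
  frames <- c(replicate(3, sc1$atoms, simplify = FALSE),
              replicate(3, sc2$atoms, simplify = FALSE))
  lam_tags <- c(0.30, 0.31, 0.32, 0.60, 0.61, 0.62)
  prof <- profile_vs_lambda(frames, lam_tags,
                            bins = make_xi_bins(c(0.3, 0.65), 0.05))
  expect_s3_class(prof, "contact_profile")
  expect_equal(prof$hbond_counts, c(2, 1))
  expect_equal(prof$water_bridge_counts, c(1, 1))
  expect_equal(prof$hydrophobic_counts, c(3, 3))
  ## permuting frame order leaves the profile unchanged
  perm <- c(4, 1, 6, 2, 3, 5)
  prof2 <- profile_vs_lambda(frames[perm], lam_tags[perm],
                             bins = make_xi_bins(c(0.3, 0.65), 0.05))
  expect_equal(prof2, prof)
  expect_error(profile_vs_lambda(frames, rep(9, 6),
                                 bins = make_xi_bins(c(0.3, 0.65), 0.05)),
               "no frames")
})

test_that("radius of gyration agrees with brute-force evaluation", {
  expect_equal(radius_of_gyration(c(1, 2, 3)), 0)
  two <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_equal(radius_of_gyration(two), 0.5)
  s <- 0.7
  square <- rbind(c(0, 0, 0), c(s, 0, 0), c(s, s, 0), c(0, s, 0))
  expect_equal(radius_of_gyration(square), s / sqrt(2))
  ## brute force with unequal masses
  set.seed(71)
  coords <- matrix(rnorm(15), 5)
  m <- runif(5, 1, 16)
  com <- colSums(coords * m) / sum(m)
  brute <- sqrt(sum(m * rowSums(sweep(coords, 2, com)^2)) / sum(m))
  expect_equal(radius_of_gyration(coords, m), brute)
  expect_error(radius_of_gyration(two, c(0, 0)), "zero total mass")
})

test_that("dihedral angles follow the IUPAC convention", {
  p1 <- c(-0.5, 1, 0); p2 <- c(0, 0, 0); p3 <- c(1, 0, 0)
  expect_equal(dihedral_angle(p1, p2, p3, c(1.5, 1, 0)), 0)      # cis
  expect_equal(dihedral_angle(p1, p2, p3, c(1.5, -1, 0)), 180)   # trans
  ## rotating the far atom about the bond axis from cis by a set angle
  rot_x <- function(p, th) {
    th <- th * pi / 180
    c(p[1], cos(th) * p[2] - sin(th) * p[3], sin(th) * p[2] + cos(th) * p[3])
  }
  p4_cis <- c(1.5, 1, 0)
  got <- dihedral_angle(p1, p2, p3, rot_x(p4_cis, 60))
  expect_equal(abs(got), 60, tolerance = 1e-9)
  ## cross-check the full signed value against an independent implementation
  skip_if_not_installed("bio3d")
  expect_equal(got, as.numeric(
    bio3d::torsion.xyz(c(p1, p2, p3, rot_x(p4_cis, 60)))),
    tolerance = 1e-6)
  set.seed(81)
  for (i in 1:10) {
    p <- matrix(rnorm(12), 4, 3)
    expect_equal(dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ]),
                 as.numeric(bio3d::torsion.xyz(as.numeric(t(p)))),
                 tolerance = 1e-6)
  }
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                              c(3, 1, 0)), "collinear")
})

test_that("torsion histograms find the planted peaks", {
  ## constant series: one peak at the 60-degree bin
  h1 <- dihedral_histogram(rep(60, 500), bin_width = 10)
  expect_length(h1$peaks, 1L)
  expect_lte(abs(h1$peaks - 60), 5)   # the bin containing 60 degrees
  expect_equal(sum(h1$counts), 500)
  ## two-state series hopping between +60 and -60
  set.seed(91)
  state <- rep(c(60, -60), each = 250) + rnorm(500, 0, 4)
  h2 <- dihedral_histogram(dihedral_series(seq_len(500), state), 10)
  expect_equal(sum(h2$counts), 500)
  expect_true(any(abs(h2$peaks - 60) <= 10))
  expect_true(any(abs(h2$peaks + 60) <= 10))
  expect_equal(length(h2$peaks), 2L)
  ## uniform angles: no peak above the prominence threshold
  h3 <- dihedral_histogram(seq(-179, 180, by = 1), bin_width = 10)
  expect_length(h3$peaks, 0L)
})
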