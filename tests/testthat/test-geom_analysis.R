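test_that("BLA of a constructed alternating chain is the length difference", {
  topo <- polyene_topology()
  X <- make_polyene(single = 1.45, double = 1.35)
  expect_equal(compute_bla(X, topo), 0.10, tolerance = 1e-10)
  Xeq <- make_polyene(single = 1.40, double = 1.40)
  expect_equal(compute_bla(Xeq, topo), 0, tolerance = 1e-10)
})

test_that("BLA matches direct arithmetic over the bond lists", {
  topo <- polyene_topology()
  set.seed(21)
  X <- make_polyene() + matrix(rnorm(66, sd = 0.05), 22, 3)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  s <- mean(apply(topo$single_bonds, 1, function(b) d(b[1], b[2])))
  dd <- mean(apply(topo$double_bonds, 1, function(b) d(b[1], b[2])))
  expect_equal(compute_bla(X, topo), s - dd, tolerance = 1e-12)
})

test_that("dihedrals: planar trans is 180, planar cis is 0, sign is IUPAC", {
  Xt <- build_chain_geometry(rep(1.4, 3), rep(120, 2), 180)
  expect_equal(compute_dihedral(Xt, 1:4), 180, tolerance = 1e-10)
  Xc <- build_chain_geometry(rep(1.4, 3), rep(120, 2), 0)
  expect_equal(compute_dihedral(Xc, 1:4), 0, tolerance = 1e-10)
  for (phi in c(-150, -60, 45, 90, 135)) {
    X <- build_chain_geometry(rep(1.4, 3), rep(115, 2), phi)
    expect_equal(compute_dihedral(X, 1:4), phi, tolerance = 1e-8)
  }
})

test_that("dihedral matches an independent atan2 cross-product evaluation", {
  set.seed(31)
  for (r in 1:10) {
    X <- matrix(rnorm(12), 4, 3)
    ref <- local({  # independent vector-algebra formula
      b1 <- X[2, ] - X[1, ]; b2 <- X[3, ] - X[2, ]; b3 <- X[4, ] - X[3, ]
      cp <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                             u[3] * v[1] - u[1] * v[3],
                             u[1] * v[2] - u[2] * v[1])
      n1 <- cp(b1, b2); n2 <- cp(b2, b3)
      atan2(sum(cp(n1, n2) * b2 / sqrt(sum(b2^2))), sum(n1 * n2)) * 180 / pi
    })
    got <- compute_dihedral(X, 1:4)
    if (ref <= -180) ref <- ref + 360
    expect_equal(got, ref, tolerance = 1e-9)
  }
})

test_that("collinear triples raise an undefined-torsion error", {
  X <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0))
  expect_error(compute_dihedral(X, 1:4), "collinear")
})

test_that("distortion index: planar 0, perpendicular 1, term-by-term oracle", {
  expect_equal(distortion_index(angles = rep(180, 9)), 0)
  expect_equal(distortion_index(angles = c(0, 180, 0, 180)), 0)
  expect_equal(distortion_index(angles = rep(90, 4)), 1)
  set.seed(41)
  ang <- runif(9, -180, 180)
  expect_equal(distortion_index(angles = ang),
               sum(1 - abs(cos(ang * pi / 180))) / 9, tolerance = 1e-12)
  expect_error(distortion_index(angles = numeric(0)), "empty")
})

test_that("descriptors are invariant under rigid rotation and translation", {
  topo <- polyene_topology()
  set.seed(51)
  X <- make_polyene(dihedrals = runif(19, 150, 210))
  g0 <- geometry_descriptors(X, topo)
  for (s in 1:3) {
    g1 <- geometry_descriptors(rigid_transform(X, seed = s), topo)
    expect_equal(g1$bla, g0$bla, tolerance = 1e-9)
    expect_equal(g1$dd, g0$dd, tolerance = 1e-7)
    expect_equal(g1$D_Lum, g0$D_Lum, tolerance = 1e-9)
  }
})

test_that("D over all dd lies between D_Lum and D_Strom (mean form)", {
  topo <- polyene_topology()
  set.seed(61)
  X <- make_polyene(dihedrals = runif(19, 120, 240))
  g <- geometry_descriptors(X, topo)
  expect_true(setequal(c(topo$lumenal, topo$stromal),
                       names(topo$dihedrals_d)))
  expect_length(intersect(topo$lumenal, topo$stromal), 0)
  expect_gte(g$D, min(g$D_Lum, g$D_Strom) - 1e-12)
  expect_lte(g$D, max(g$D_Lum, g$D_Strom) + 1e-12)
})

test_that("conformer classification follows ds2 with the 90-degree tie-break", {
  expect_equal(classify_conformer(178), "s-trans")
  expect_equal(classify_conformer(5), "s-cis")
  expect_equal(classify_conformer(90), "s-trans")
  expect_equal(classify_conformer(c(-170, -30)), c("s-trans", "s-cis"))
})

test_that("hop-channel summary reproduces the within-cutoff percentage", {
  # 38 negative-BLA channel hops, 33 of them within 2 ps
  set.seed(71)
  hops <- data.frame(
    time_fs = c(runif(33, 0, 2000), runif(5, 2001, 15000)),
    bla = runif(38, -0.06, -0.021),
    d_lum = runif(38, 0, 0.09),
    conformer = "s-trans")
  ch <- characterize_hops(hops)
  expect_equal(ch$summary$n_bla, 38L)
  expect_equal(ch$summary$n_bla_within, 33L)
  expect_equal(ch$summary$pct_bla_within, 87)
  # no hops: zero-row summary, not an error
  empty <- characterize_hops(hops[0, ])
  expect_equal(nrow(empty$table), 0L)
})

test_that("hop-channel counts agree with an independent filter", {
  set.seed(81)
  n <- 300
  hops <- data.frame(time_fs = runif(n, 0, 15000),
                     bla = rnorm(n, -0.01, 0.02),
                     d_lum = pmax(0, rnorm(n, 0.08, 0.05)),
                     conformer = sample(c("s-trans", "s-cis"), n, TRUE))
  ch <- characterize_hops(hops)
  for (conf in unique(hops$conformer)) {
    h <- hops[hops$conformer == conf, ]
    nb <- sum(h$bla < -0.02)
    nd <- sum(h$d_lum > 0.10 & h$bla >= -0.02)
    row <- ch$summary[ch$summary$conformer == conf, ]
    expect_equal(row$n_bla, nb)
    expect_equal(row$n_distortion, nd)
    expect_equal(row$n_bla_within, sum(h$bla < -0.02 & h$time_fs <= 2000))
  }
})

test_that("photoisomerization detection finds settled basin switches only", {
  set.seed(91)
  wiggly <- 180 + 20 * sin(seq(0, 20, by = 0.1)) + rnorm(201, sd = 3)
  expect_equal(nrow(detect_photoisomerization(wiggly)), 0L)
  switch1 <- c(rep(178, 50), rep(4, 50))
  ev <- detect_photoisomerization(switch1)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$from, "trans")
  expect_equal(ev$to, "cis")
  # brief excursions below the dwell window do not count
  blip <- c(rep(178, 50), rep(4, 3), rep(178, 50))
  expect_equal(nrow(detect_photoisomerization(blip, dwell = 10)), 0L)
})

test_that("photoisomerization matches a brute-force basin-tracking oracle", {
  set.seed(101)
  for (r in 1:5) {
    series <- 180 + cumsum(rnorm(400, sd = 12))
    series <- ((series + 180) %% 360) - 180
    got <- nrow(detect_photoisomerization(series, dwell = 8))
    # oracle: walk the basin labels, count confirmed switches
    basin <- ifelse(abs(series) > 90, "t", "c")
    cur <- basin[1]; cnt <- 0L; i <- 2L
    while (i <= length(basin)) {
      if (basin[i] != cur) {
        j <- i
        while (j < length(basin) && basin[j + 1] == basin[i]) j <- j + 1
        if (j - i + 1 >= 8) { cnt <- cnt + 1L; cur <- basin[i] }
        i <- j + 1
      } else i <- i + 1
    }
    expect_equal(got, cnt)
  }
})

test_that("topology files round-trip and validate", {
  topo <- polyene_topology()
  path <- tempfile(fileext = ".yaml")
  write_topology(topo, path)
  t2 <- read_topology(path)
  expect_equal(t2$single_bonds, topo$single_bonds)
  expect_equal(t2$dihedrals_d, topo$dihedrals_d)
  expect_error(conjugation_topology(cbind(1, 30), cbind(1, 2),
                                    list(ds1 = 1:4), list(dd1 = 1:4),
                                    lumenal = "dd1", stromal = character(0),
                                    n_atoms = 10),
               "out of range")
})
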