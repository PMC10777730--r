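sphere_area <- function(r, rp = 0.14) 4 * pi * (r + rp)^2

test_that("isolated spheres are exact at any dot count", {
  f <- bead_frame(matrix(0, 1, 3), radii = 0.235)
  for (nd in c(96, 960, 3840)) {
    expect_equal(sum(shrake_rupley(f, 0.14, nd)), sphere_area(0.235),
                 tolerance = 1e-12)
  }
  # two beads farther apart than 2(r + rp): no occlusion
  f2 <- bead_frame(rbind(c(0, 0, 0), c(1, 0, 0)), radii = 0.235)
  expect_equal(sum(shrake_rupley(f2, 0.14, 960)), 2 * sphere_area(0.235),
               tolerance = 1e-12)
})

test_that("two overlapping spheres match the spherical-cap closed form", {
  r <- 0.235; rp <- 0.14; R <- r + rp; d <- 0.375
  f <- bead_frame(rbind(c(0, 0, 0), c(d, 0, 0)), radii = r)
  exact <- 2 * (4 * pi * R^2 - 2 * pi * R * (R - d / 2))
  a960 <- sum(shrake_rupley(f, rp, 960))
  expect_equal(a960, exact, tolerance = 0.01)
  # and against a high-dot-count run
  a_hi <- sum(shrake_rupley(f, rp, 7680))
  expect_equal(a_hi, exact, tolerance = 0.003)
  expect_lt(abs(a_hi - exact), abs(a960 - exact) + 0.01 * exact)
})

test_that("masked APR area is the masked sum of per-bead areas", {
  set.seed(3)
  f <- random_cluster(10)
  per_bead <- shrake_rupley(f, 0.14, 960)
  mask <- sample(c(TRUE, FALSE), 10, replace = TRUE)
  out <- apr_sasa(f, mask, 0.14, 960)
  expect_equal(unname(out["apr"]), sum(per_bead[mask]))
  expect_equal(unname(out["total"]), sum(per_bead))
  expect_lte(out["apr"], out["total"])
  # degenerate masks
  expect_equal(unname(apr_sasa(f, rep(TRUE, 10), 0.14, 960)["apr"]),
               unname(out["total"]))
  expect_equal(unname(apr_sasa(f, rep(FALSE, 10), 0.14, 960)["apr"]), 0)
  expect_error(apr_sasa(f, rep(TRUE, 4), 0.14, 960), "length")
})

test_that("occlusion is monotone and areas partition exactly", {
  set.seed(5)
  for (i in 1:15) {
    n <- sample(5:20, 1)
    f <- random_cluster(n)
    a <- shrake_rupley(f, 0.14, 240)
    # add one occluding bead: no area can increase
    f2 <- bead_frame(rbind(f$coordinates, rnorm(3, 0, 0.3)), radii = 0.235)
    a2 <- shrake_rupley(f2, 0.14, 240)
    expect_true(all(a2[seq_len(n)] <= a + 1e-12))
    # group additivity: any partition sums to the total
    grp <- sample(1:3, n, replace = TRUE)
    parts <- vapply(1:3, function(g)
      sum(apr_sasa(f, grp == g, 0.14, 240)["apr"]), 1)
    expect_equal(sum(parts), sum(a), tolerance = 1e-10)
  }
})

test_that("dot-count convergence is within 1% on random clusters", {
  set.seed(9)
  for (i in 1:5) {
    f <- random_cluster(12)
    a1 <- sum(shrake_rupley(f, 0.14, 960))
    a2 <- sum(shrake_rupley(f, 0.14, 3840))
    expect_lt(abs(a2 - a1) / a2, 0.01)
  }
})

test_that("molecule tags control surface and occluder sets", {
  coords <- rbind(c(0, 0, 0), c(0.3, 0, 0), c(-0.3, 0, 0))
  # excipient occludes the protein but contributes no area
  f <- bead_frame(coords, radii = 0.235,
                  molecule_tag = c("protein", "excipient", "solvent"))
  a <- shrake_rupley(f, 0.14, 960)
  expect_length(a, 1)                           # protein bead only
  expect_lt(sum(a), sphere_area(0.235))         # excipient occluded it
  # solvent ignored by default: adding solvent changes nothing
  f_nosolv <- bead_frame(coords[1:2, ], radii = 0.235,
                         molecule_tag = c("protein", "excipient"))
  expect_equal(sum(a), sum(shrake_rupley(f_nosolv, 0.14, 960)))
  # include_solvent makes the solvent bead occlude too
  a_s <- shrake_rupley(f, 0.14, 960, include_solvent = TRUE)
  expect_lt(sum(a_s), sum(a))
  # protein-only occluders ignore the excipient
  a_p <- shrake_rupley(f, 0.14, 960, occluders = "protein")
  expect_equal(sum(a_p), sphere_area(0.235), tolerance = 1e-12)
  # empty surface set
  f_e <- bead_frame(coords, radii = 0.235, molecule_tag = "excipient")
  expect_length(shrake_rupley(f_e, 0.14, 960), 0)
})

test_that("trajectory series, stride and replicate shielding behave", {
  f <- random_cluster(8)
  traj <- bead_trajectory(rep(list(f), 10))
  s <- trajectory_sasa(traj, rep(TRUE, 8), n_dots = 240)
  expect_equal(nrow(s), 10)
  expect_true(all(abs(s$total - s$total[1]) < 1e-12))
  expect_equal(attr(s, "mean_total"),
               unname(apr_sasa(f, rep(TRUE, 8), 0.14, 240)["total"]))
  s2 <- trajectory_sasa(traj, rep(TRUE, 8), n_dots = 240, stride = 2)
  expect_equal(nrow(s2), 5)
  expect_error(bead_trajectory(list()), "at least one frame")
  expect_error(trajectory_sasa(traj, rep(TRUE, 8), stride = 0), "stride")

  # shielding arithmetic
  mk <- function(v, sys) sasa_series(rep(v + 5, 3), rep(v, 3),
                                     system_id = sys)
  ctrl <- list(mk(50, "ctrl"), mk(50, "ctrl"))
  same <- shielding(ctrl, ctrl)
  expect_equal(same$delta_apr_sasa, 0)
  expect_equal(same$percent_reduction, 0)
  tr <- list(mk(40, "t"), mk(40, "t"))
  sh <- shielding(ctrl, tr)
  expect_equal(sh$delta_apr_sasa, 10)
  expect_equal(sh$percent_reduction, 20)
  expect_error(shielding(list(), tr), "empty control")
})

test_that("SASA series round-trip through tidy CSV", {
  set.seed(1)
  s1 <- sasa_series(runif(4, 60, 70), runif(4, 10, 20),
                    system_id = "ctrl", replicate_id = 1)
  s2 <- sasa_series(runif(4, 60, 70), runif(4, 10, 20),
                    system_id = "psbn", replicate_id = 2)
  csv <- tempfile(fileext = ".csv")
  write_sasa_csv(list(s1, s2), csv)
  back <- read_sasa_csv(csv)
  expect_length(back, 2)
  m <- vapply(back, attr, numeric(1), "mean_apr")
  expect_setequal(round(unname(m), 10),
                  round(c(attr(s1, "mean_apr"), attr(s2, "mean_apr")), 10))
  expect_error(sasa_series(c(1, 2), c(2, 1.5)), "apr <= total")
})

test_that("concentration and excipient counts follow the mass budget", {
  expect_equal(concentration(1, 30841.5), 0.0538, tolerance = 1e-3)
  expect_equal(concentration(0, 100), 0)
  # 1 molecule per 1.6606 nm^3 is 1 M
  expect_equal(concentration(1, 1.6606), 1000, tolerance = 1e-4)
  expect_error(concentration(1, 0), "positive")

  expect_equal(as.integer(excipient_count(0, 734, 1e6)), 0L)
  # exact division: mass ratio equals k x MW
  expect_equal(as.integer(excipient_count(0.001, 500, 500 * 7 / 0.001)), 7L)
  # 0.1% w/w against a 233,000 4-water-bead mass budget, vs a hand budget
  water_mass <- 233000 * 4 * 18.015
  k <- excipient_count(0.001, 734, water_mass)
  expect_equal(as.integer(k), as.integer(round(0.001 * water_mass / 734)))
  expect_identical(attr(k, "rounding"), "nearest")
  expect_error(excipient_count(0.001, 0, 100), "positive")
})

test_that("GRO and PDB frames round-trip with tags and radii", {
  f <- bead_frame(matrix(round(rnorm(9), 3), 3, 3) + 3, radii = 0.235,
                  residue_index = c(1L, 1L, 2L),
                  molecule_tag = c("protein", "protein", "excipient"))
  g <- tempfile(fileext = ".gro")
  write_gro(f, g)
  back <- read_gro(g)
  expect_s3_class(back, "bead_frame")
  expect_equal(back$coordinates, f$coordinates, ignore_attr = TRUE,
               tolerance = 1e-3)
  expect_equal(back$molecule_tag, f$molecule_tag)
  # appended frames become a trajectory
  write_gro(f, g, append = TRUE)
  traj <- read_gro(g)
  expect_s3_class(traj, "bead_trajectory")
  expect_length(traj, 2)

  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            1:2, 1:2, c(1.0, 4.7), c(0, 0), c(0, 0)),
    "HETATM    3  C1  LIG A   3       9.400   0.000   0.000  1.00  0.00",
    "END"), pdb)
  fp <- read_pdb_frame(pdb)
  expect_equal(fp$coordinates[, 1], c(0.1, 0.47, 0.94), ignore_attr = TRUE)
  expect_equal(fp$molecule_tag, c("protein", "protein", "excipient"))
  # custom tag map overrides
  fp2 <- read_pdb_frame(pdb, tag_map = c(LIG = "ion"))
  expect_equal(fp2$molecule_tag[3], "ion")
})
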