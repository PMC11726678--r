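test_that("bond angles reproduce elementary geometries", {
  expect_equal(bond_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  expect_equal(bond_angle(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0)), 180)
  ## equilateral triangle
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  expect_equal(bond_angle(tri[2, ], tri[1, ], tri[3, ]), 60, tolerance = 1e-12)
  expect_error(bond_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), "coincident")
})

test_that("dihedrals reproduce planar cis/trans and error on collinearity", {
  cis <- rbind(c(1, 1, 0), c(1, 0, 0), c(-1, 0, 0), c(-1, 1, 0))
  expect_equal(dihedral(cis[1, ], cis[2, ], cis[3, ], cis[4, ]), 0)
  trans <- rbind(c(1, 1, 0), c(1, 0, 0), c(-1, 0, 0), c(-1, -1, 0))
  expect_equal(abs(dihedral(trans[1, ], trans[2, ], trans[3, ], trans[4, ])),
               180)
  expect_error(
    dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)), "collinear")
})

test_that("dihedral and angle agree with the rotation-matrix oracle and are
           invariant under rigid motions", {
  set.seed(41)
  max_dev <- 0
  for (i in 1:100) {
    pts <- matrix(stats::runif(12, -2, 2), 4, 3)
    ## skip near-degenerate draws
    ref <- tryCatch(dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                    error = function(e) NULL)
    if (is.null(ref)) next
    expect_equal(ref, oracle_dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                 tolerance = 1e-9)
    R <- random_rotation()
    shift <- stats::rnorm(3)
    rp <- t(R %*% t(pts)) + rep(shift, each = 4)
    dev <- abs(dihedral(rp[1, ], rp[2, ], rp[3, ], rp[4, ]) - ref)
    max_dev <- max(max_dev, dev,
                   abs(bond_angle(rp[1, ], rp[2, ], rp[3, ]) -
                         bond_angle(pts[1, ], pts[2, ], pts[3, ])))
  }
  expect_lt(max_dev, 1e-9)
})

test_that("fragment construction round-trips the requested internal
           coordinates", {
  sel <- default_atom_selection()
  ics <- internal_coord_set(theta = 10, alpha = 30, omega = 90,
                            gamma = 120, gamma_prime = 120)
  m <- internal_coords(build_fragment(ics), sel)
  for (p in c("theta", "alpha", "omega", "gamma", "gamma_prime"))
    expect_equal(m[[p]], ics[[p]], tolerance = 1e-6)
  ## 1000 random internal-coordinate sets under a fixed seed
  set.seed(7)
  worst <- 0
  for (i in 1:1000) {
    ics <- internal_coord_set(stats::runif(1, 0.5, 179.5),
                              stats::runif(1, 0.5, 179.5),
                              stats::runif(1, 0.5, 179.5),
                              stats::runif(1, 30, 175),
                              stats::runif(1, 30, 175))
    m <- internal_coords(build_fragment(ics), sel)
    worst <- max(worst, abs(m$theta - ics$theta), abs(m$alpha - ics$alpha),
                 abs(m$omega - ics$omega), abs(m$gamma - ics$gamma),
                 abs(m$gamma_prime - ics$gamma_prime))
  }
  expect_lt(worst, 1e-6)
})

test_that("degenerate bond-angle requests are perturbed rather than failing", {
  sel <- default_atom_selection()
  ## gamma_prime = 180 makes the theta-dependent dihedral undefined;
  ## the builder perturbs the angle by 1e-4 degrees
  xyz <- build_fragment(internal_coord_set(180, 30, 90, 120, 180))
  m <- internal_coords(xyz, sel)
  expect_equal(m$gamma_prime, 180, tolerance = 1e-3)
  expect_equal(m$theta, 180, tolerance = 1e-3)
  expect_error(build_fragment(internal_coord_set(10, 30, 90, 120, 181)))
})

test_that("measured internal coordinates of generated frames stay in
           [0, 180]", {
  tr <- generate_trajectory(quick_kin(), quick_mot(), seed = 5)
  ic <- internal_coords(tr)
  for (p in c("theta", "alpha", "omega", "gamma", "gamma_prime")) {
    expect_true(all(ic[[p]] >= 0))
    expect_true(all(ic[[p]] <= 180))
  }
  ## frame accessor agrees with the vectorized path
  m <- internal_coords(get_frame(tr, 10))
  expect_equal(m$theta, ic$theta[10], tolerance = 1e-9)
  ## trans template region at start
  expect_true(ic$theta[1] > 150)
})

test_that("selections reject duplicate indices and out-of-range atoms", {
  expect_error(atom_selection(c(1, 1, 2, 3), c(1, 2, 3, 4), c(1, 2, 3, 4),
                              c(1, 2, 3), c(1, 2, 3)), "duplicate")
  sel <- default_atom_selection()
  expect_error(internal_coords(matrix(0, 5, 3), sel), "out of range")
})
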