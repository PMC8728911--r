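test_that("wrap_angle applies the periodic convention on (-180, 180]", {
  expect_equal(wrap_angle(190), -170)
  expect_equal(wrap_angle(-190), 170)
  expect_equal(wrap_angle(180), 180)
  expect_equal(wrap_angle(-180), 180)
  expect_equal(wrap_angle(0), 0)
  set.seed(1)
  x <- runif(500, -1e4, 1e4)
  w <- wrap_angle(x)
  expect_true(all(w > -180 & w <= 180))
  expect_equal((w - x) %% 360, rep(0, 500))
  expect_equal(wrap_angle(w), w)  # idempotent
})

test_that("dihedral matches planar cases and the rotation-construction oracle", {
  expect_equal(dihedral(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)), 0)
  expect_equal(dihedral(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(-1, 0, 0)), 180)
  set.seed(7)
  for (k in 1:200) {
    p <- matrix(rnorm(12, sd = 2), 4, 3)
    d <- tryCatch(dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                  error = function(e) NA)
    if (is.na(d)) next
    expect_equal(d, oracle_dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-9)
  }
})

test_that("dihedral is symmetric under atom-order reversal and flips under mirror", {
  set.seed(8)
  for (k in 1:1000) {
    p <- matrix(rnorm(12), 4, 3)
    d1 <- dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
    d2 <- dihedral(p[4, ], p[3, ], p[2, ], p[1, ])
    expect_equal(wrap_angle(d1 - d2), 0, tolerance = 1e-9)
  }
  set.seed(9)
  p <- matrix(rnorm(12), 4, 3)
  pm <- p
  pm[, 3] <- -pm[, 3]
  expect_equal(dihedral(pm[1, ], pm[2, ], pm[3, ], pm[4, ]),
               -dihedral(p[1, ], p[2, ], p[3, ], p[4, ]), tolerance = 1e-9)
})

test_that("degenerate point configurations raise explicit errors", {
  o <- c(0, 0, 0)
  expect_error(dihedral(o, o, c(1, 0, 0), c(1, 1, 0)), "degenerate")
  expect_error(dihedral(c(2, 0, 0), c(1, 0, 0), o, c(0, 1, 0)), "degenerate")
  expect_error(planar_angle(o, o, c(1, 0, 0)), "degenerate")
})

test_that("planar_angle matches arccos oracle and trivial cases", {
  expect_equal(planar_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  expect_equal(planar_angle(c(1, 0, 0), c(0, 0, 0), c(-1, 0, 0)), 180)
  set.seed(10)
  for (k in 1:100) {
    p <- matrix(rnorm(9), 3, 3)
    expect_equal(planar_angle(p[1, ], p[2, ], p[3, ]),
                 oracle_planar(p[1, ], p[2, ], p[3, ]), tolerance = 1e-9)
  }
})

test_that("compute_backbone_angles composes the atom-tuple definitions", {
  set.seed(21)
  ch <- random_chain(5)
  at <- compute_backbone_angles(ch)
  co <- ch$coords
  for (i in 2:4) {
    expect_equal(at$phi[i],
                 dihedral(co[i - 1, "C", ], co[i, "N", ], co[i, "CA", ], co[i, "C", ]))
    expect_equal(at$psi[i],
                 dihedral(co[i, "N", ], co[i, "CA", ], co[i, "C", ], co[i + 1, "N", ]))
    expect_equal(at$theta[i],
                 planar_angle(co[i - 1, "CA", ], co[i, "CA", ], co[i + 1, "CA", ]))
  }
  for (i in 2:3)
    expect_equal(at$tau[i],
                 dihedral(co[i - 1, "CA", ], co[i, "CA", ], co[i + 1, "CA", ],
                          co[i + 2, "CA", ]))
  # undefined-flag pattern
  expect_true(is.na(at$phi[1]))
  expect_true(is.na(at$psi[5]))
  expect_true(all(is.na(at$theta[c(1, 5)])))
  expect_true(all(is.na(at$tau[c(1, 4, 5)])))
  expect_true(all(at$theta[2:4] >= 0 & at$theta[2:4] <= 180))
})

test_that("a single-residue chain has all four angles undefined", {
  co <- array(NA_real_, dim = c(1, 4, 3))
  co[1, 1:3, ] <- rbind(c(0, 0, 0), c(1.46, 0, 0), c(2, 1.3, 0))
  at <- compute_backbone_angles(backbone_chain("A", co))
  expect_true(all(is.na(c(at$phi, at$psi, at$theta, at$tau))))
})

test_that("missing backbone atoms degrade to undefined angles, not errors", {
  set.seed(22)
  ch <- random_chain(6)
  ch$coords[3, "N", ] <- NA_real_
  at <- compute_backbone_angles(ch)
  expect_true(is.na(at$phi[3]))  # needs N_3
  expect_true(is.na(at$psi[3]))
  expect_true(is.na(at$psi[2]))  # needs N_3
  expect_false(is.na(at$theta[3]))  # CA atoms intact
})

test_that("backbone angles are invariant under rigid motion", {
  set.seed(23)
  ch <- random_chain(8)
  at1 <- compute_backbone_angles(ch)
  at2 <- compute_backbone_angles(transform_chain(ch, random_rigid()))
  for (col in c("phi", "psi", "theta", "tau"))
    expect_equal(at2[[col]], at1[[col]], tolerance = 1e-6)
})

test_that("angle tables round-trip through TSV with NA markers", {
  set.seed(24)
  at <- compute_backbone_angles(random_chain(7))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_angle_table(at, path)
  back <- read_angle_table(path)
  expect_equal(back$aa, at$aa)
  expect_equal(back$phi, at$phi, tolerance = 1e-5)
  expect_equal(is.na(back$tau), is.na(at$tau))
  expect_true(any(grepl("\tNA", readLines(path))))
})

test_that("backbone chains round-trip through PDB files", {
  set.seed(25)
  ch <- random_chain(6)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_chain(ch, path)
  back <- read_pdb_chain(path)
  expect_equal(back$sequence, ch$sequence)
  expect_equal(back$coords, ch$coords, tolerance = 1e-3)  # PDB prints 3 dp
  at1 <- compute_backbone_angles(ch)
  at2 <- compute_backbone_angles(back)
  expect_equal(at2$phi, at1$phi, tolerance = 0.1)
})
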