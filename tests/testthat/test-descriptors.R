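test_that("geometric descriptors recover declared fixture parameters exactly", {
  f <- build_paddlewheel_fixture(fixture_spec(rh_rh = 2.45, donor_tilt = 0,
                                              bite_angle = 125))
  topo <- detect_paddlewheel(f$geometry)
  expect_equal(rh_rh_distance(f$geometry, topo), 2.45, tolerance = 1e-9)
  expect_equal(mean_rh_rh_donor_angle(f$geometry, topo), 90, tolerance = 1e-9)
  expect_equal(mean_bite_angle(f$geometry, topo), 125, tolerance = 1e-9)

  # +5 degree tilt toward the far Rh closes the Rh-Rh-donor angle to 85
  ft <- build_paddlewheel_fixture(fixture_spec(rh_rh = 2.45, donor_tilt = 5,
                                               bite_angle = 125))
  tt <- detect_paddlewheel(ft$geometry)
  expect_equal(mean_rh_rh_donor_angle(ft$geometry, tt), 85, tolerance = 1e-9)

  fc <- build_paddlewheel_fixture(fixture_spec(carbene = TRUE,
                                               carbene_angle = 118))
  tc <- detect_paddlewheel(fc$geometry)
  expect_equal(carbene_angle(fc$geometry, tc), 118, tolerance = 1e-9)
})

test_that("geometric descriptors are invariant under rigid motion and permutation", {
  f <- build_paddlewheel_fixture(fixture_spec(rh_rh = 2.47, donor_tilt = 3,
                                              bite_angle = 123, carbene = TRUE,
                                              carbene_angle = 119))
  ref_g <- f$geometry
  ref_t <- detect_paddlewheel(ref_g)
  ref <- c(r = rh_rh_distance(ref_g, ref_t),
           ang = mean_rh_rh_donor_angle(ref_g, ref_t),
           bite = mean_bite_angle(ref_g, ref_t),
           carb = carbene_angle(ref_g, ref_t))
  expect_equal(unname(ref), c(2.47, 87, 123, 119), tolerance = 1e-9)
  set.seed(99)
  for (i in 1:20) {
    g <- rigid_transform(permute_geometry(ref_g)$geometry)
    t_ <- detect_paddlewheel(g)
    got <- c(r = rh_rh_distance(g, t_),
             ang = mean_rh_rh_donor_angle(g, t_),
             bite = mean_bite_angle(g, t_),
             carb = carbene_angle(g, t_))
    expect_equal(got, ref, tolerance = 1e-8)
  }
})

test_that("carbene angle handles exact and collinear placements", {
  fb <- build_paddlewheel_fixture(fixture_spec(carbene = TRUE,
                                               carbene_angle = 120))
  topo <- detect_paddlewheel(fb$geometry)
  expect_equal(carbene_angle(fb$geometry, topo), 120, tolerance = 1e-9)

  # collinear carbonyl carbons are pure coordinate geometry: move the two
  # neighbours onto a line through the carbene carbon and reuse the topology
  coords <- fb$geometry$coords
  cc <- topo$carbene$c_carbene
  nb <- topo$carbene$c_neighbors
  dir <- c(1, 0, 0.2); dir <- dir / sqrt(sum(dir^2))
  coords[nb[1L], ] <- coords[cc, ] + 1.48 * dir
  coords[nb[2L], ] <- coords[cc, ] - 1.48 * dir
  g180 <- molecular_geometry(fb$geometry$elements, coords)
  expect_equal(carbene_angle(g180, topo), 180, tolerance = 1e-9)

  f <- build_paddlewheel_fixture(fixture_spec(carbene = FALSE))
  expect_error(carbene_angle(f$geometry, detect_paddlewheel(f$geometry)),
               "no carbene")
})

test_that("distance-weighted volume matches closed-form values and is additive", {
  # single H (vdW 1.20) at 1.0 A from the focus, k = l = 3: 1.2^3 / 1 = 1.728
  g1 <- molecular_geometry(c("Rh", "H"), rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_equal(distance_weighted_volume(g1, focus = 1L, k = 3, l = 3), 1.728,
               tolerance = 1e-12)
  # same atom at 2.0 A: 1.728 / 8 = 0.216
  g2 <- molecular_geometry(c("Rh", "H"), rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(distance_weighted_volume(g2, 1L), 0.216, tolerance = 1e-12)
  # two identical atoms at 2.0 A: contributions add
  g3 <- molecular_geometry(c("Rh", "H", "H"),
                           rbind(c(0, 0, 0), c(2, 0, 0), c(-2, 0, 0)))
  expect_equal(distance_weighted_volume(g3, 1L), 0.432, tolerance = 1e-12)
  # exclusion removes a contribution
  expect_equal(distance_weighted_volume(g3, 1L, exclude = 3L), 0.216,
               tolerance = 1e-12)
})

test_that("distance-weighted volume strictly decreases as any atom moves away", {
  set.seed(17)
  for (rep in 1:100) {
    n <- sample(3:8, 1L)
    coords <- matrix(runif(3L * n, -4, 4), n, 3L)
    coords[, 1L] <- coords[, 1L] + 3 * seq_len(n)  # avoid clashes
    els <- sample(c("C", "N", "O", "H", "F"), n, replace = TRUE)
    g <- molecular_geometry(c("Rh", els), rbind(c(-5, 0, 0), coords))
    v0 <- distance_weighted_volume(g, 1L)
    # push one random atom radially away from the focus
    i <- sample(2:(n + 1L), 1L)
    d <- g$coords[i, ] - g$coords[1L, ]
    coords2 <- g$coords
    coords2[i, ] <- g$coords[1L, ] + d * (1 + runif(1L, 0.05, 0.5))
    g2 <- molecular_geometry(g$elements, coords2)
    expect_lt(distance_weighted_volume(g2, 1L), v0)
  }
})

test_that("He8 probe geometry satisfies its closed-form invariants at defaults", {
  f <- build_paddlewheel_fixture(fixture_spec(rh_rh = 2.45, carbene = TRUE))
  s <- strip_carbene(f$geometry, detect_paddlewheel(f$geometry))
  probe <- build_he8_probe(s$topology, s$geometry)
  rh_a <- s$topology$rh_indices["rh_a"]
  d_rh <- sqrt(rowSums((probe$positions -
                          rep(s$geometry$coords[rh_a, ], each = 8L))^2))
  expect_equal(d_rh, rep(sqrt(1.9^2 + 2.5^2), 8L), tolerance = 1e-9)
  chord <- sqrt(sum((probe$positions[1L, ] - probe$positions[2L, ])^2))
  expect_equal(chord, 2 * 2.5 * sin(pi / 8), tolerance = 1e-9)
})

test_that("He8 probe is planar, equidistant, evenly spaced for random orientations", {
  set.seed(23)
  f <- build_paddlewheel_fixture(fixture_spec(rh_rh = 2.42, donor_tilt = 2,
                                              carbene = TRUE))
  base <- strip_carbene(f$geometry, detect_paddlewheel(f$geometry))$geometry
  for (i in 1:20) {
    g <- rigid_transform(base)
    t_ <- detect_paddlewheel(g)
    # identify the carbene-binding Rh from the original labelling: both work,
    # the probe invariants hold for either axial face
    probe <- build_he8_probe(t_, g, distance = 1.9, radius = 2.5)
    centered <- probe$positions - rep(probe$center, each = 8L)
    # planarity: no displacement along the axis
    expect_lt(max(abs(centered %*% probe$axis)), 1e-9)
    # equidistance from the ring centre
    expect_equal(sqrt(rowSums(centered^2)), rep(2.5, 8L), tolerance = 1e-9)
    # adjacent spacing equals the regular-octagon chord
    adj <- sqrt(rowSums((probe$positions - probe$positions[c(2:8, 1L), ])^2))
    expect_equal(adj, rep(2 * 2.5 * sin(pi / 8), 8L), tolerance = 1e-9)
  }
})

test_that("He8 probe positions co-rotate rigidly with the complex", {
  f <- build_paddlewheel_fixture(fixture_spec(carbene = TRUE))
  s <- strip_carbene(f$geometry, detect_paddlewheel(f$geometry))
  p0 <- build_he8_probe(s$topology, s$geometry)
  set.seed(5)
  rot <- random_rotation(); shift <- c(3, -2, 7)
  g2 <- molecular_geometry(s$geometry$elements,
                           s$geometry$coords %*% t(rot) +
                             matrix(shift, n_atoms(s$geometry), 3L, byrow = TRUE))
  # atom order is unchanged, so the stripped topology still applies
  p2 <- build_he8_probe(s$topology, g2)
  expect_equal(p2$positions,
               p0$positions %*% t(rot) + matrix(shift, 8L, 3L, byrow = TRUE),
               tolerance = 1e-8)
})

test_that("probe construction requires a stripped geometry", {
  f <- build_paddlewheel_fixture(fixture_spec(carbene = TRUE))
  topo <- detect_paddlewheel(f$geometry)
  expect_error(build_he8_probe(topo, f$geometry), "strip the carbene")
})

test_that("energy assemblies convert stated a.u. inputs to kcal/mol", {
  expect_equal(he8_interaction_energy(-10.0, -2.0, -7.5), -313.7547,
               tolerance = 1e-4)
  expect_equal(he8_interaction_energy(-9.5, -2.0, -7.5), 0)
  expect_equal(he8_interaction_energy(-9.0, -2.0, -7.5), 313.7547,
               tolerance = 1e-4)
  expect_error(he8_interaction_energy(-10, NULL, -7.5), "precondition")

  expect_equal(coordination_energy(-100.0, -50.0, -120.0, -29.9), -62.7509,
               tolerance = 1e-4)
  expect_equal(coordination_energy(-100.0, -50.0, -120.0, -30.0), 0)
  expect_equal(coordination_energy(-120.0, -29.9, -100.0, -50.0), 62.7509,
               tolerance = 1e-4)
  expect_error(coordination_energy(-100, -50, NULL, -30), "precondition")
})

test_that("frontier-orbital and charge descriptors follow their definitions", {
  expect_equal(fmo_gap(-0.20, -0.05), 0.15)
  expect_equal(fmo_gap(-0.20, -0.20), 0)
  expect_error(fmo_gap(-0.05, -0.20), "lumo < homo")

  f <- build_paddlewheel_fixture(fixture_spec())
  topo <- detect_paddlewheel(f$geometry)
  n <- n_atoms(f$geometry)
  ch <- rep(0, n)
  ch[topo$rh_indices] <- c(0.50, 0.54)
  p <- qc_properties(charges = ch, homo = -0.2, lumo = -0.1)
  expect_equal(rh_charge(p, topo), 0.52)

  # four ligands with declared sums
  sums <- c(-0.2, -0.2, -0.4, -0.4)
  for (li in 1:4) {
    atoms <- topo$ligands[[li]]
    ch[atoms] <- sums[li] / length(atoms)
  }
  p2 <- qc_properties(charges = ch, homo = -0.2, lumo = -0.1)
  expect_equal(mean_ligand_charge(p2, topo), -0.30, tolerance = 1e-12)
  # value is stable under atom permutation
  pm <- permute_geometry(f$geometry)
  t2 <- detect_paddlewheel(pm$geometry)
  inv <- order(pm$perm)  # original index -> new index
  p3 <- qc_properties(charges = ch[pm$perm], homo = -0.2, lumo = -0.1)
  expect_equal(mean_ligand_charge(p3, t2), -0.30, tolerance = 1e-12)

  short <- qc_properties(charges = c(0.1, 0.2), homo = -0.2, lumo = -0.1)
  expect_error(rh_charge(short, topo), "shorter")
  nochg <- qc_properties(homo = -0.2, lumo = -0.1)
  expect_error(rh_charge(nochg, topo), "charges absent")
})

test_that("the assembled record carries 14 internally consistent descriptors", {
  cat_ <- test_catalyst()
  rec <- compute_descriptor_record(cat_$id, cat_$geom1, cat_$props1,
                                   cat_$geom2, cat_$props2, cat_$aux)
  expect_length(rec$values, 14L)
  expect_named(rec$values, descriptor_names())
  expect_true(all(is.finite(rec$values)))
  v <- rec$values
  expect_equal(unname(v["de_fmo_1"]), unname(v["lumo_1"] - v["homo_1"]),
               tolerance = 1e-12)
  # every geometric field matches the builder parameters
  expect_equal(unname(v[c("r_rhrh_1", "r_rhrh_2", "ang_rhrhl_1", "ang_rhrhl_2",
                          "bite_angle_1", "carbene_angle_2")]),
               c(2.45, 2.47, 88, 87, 125, 118), tolerance = 1e-9)
  # energies reproduce the synthetic aux construction
  expect_equal(unname(v["he8"]),
               he8_interaction_energy(cat_$aux$e_he8_complex, cat_$aux$e_he8_ring,
                                      cat_$aux$e_stripped))
  expect_equal(unname(v["de_coord"]),
               coordination_energy(cat_$props1$total_energy, cat_$aux$e_diazo,
                                   cat_$props2$total_energy, cat_$aux$e_n2))
})

test_that("record assembly rejects swapped or incomplete inputs with the descriptor named", {
  cat_ <- test_catalyst()
  expect_error(compute_descriptor_record("x", cat_$geom2, cat_$props1,
                                         cat_$geom2, cat_$props2, cat_$aux),
               "must not contain a carbene")
  expect_error(compute_descriptor_record("x", cat_$geom1, cat_$props1,
                                         cat_$geom1, cat_$props2, cat_$aux),
               "must contain a carbene")
  aux_bad <- cat_$aux
  aux_bad$e_he8_ring <- NULL
  expect_error(compute_descriptor_record("x", cat_$geom1, cat_$props1,
                                         cat_$geom2, cat_$props2, aux_bad),
               "'he8'")
  p1 <- cat_$props1; p1$homo <- NULL
  expect_error(compute_descriptor_record("x", cat_$geom1, p1,
                                         cat_$geom2, cat_$props2, cat_$aux),
               "'homo_1'")
})

test_that("wv in the record is computed on the stripped carbene complex, Rh excluded", {
  cat_ <- test_catalyst()
  rec <- compute_descriptor_record(cat_$id, cat_$geom1, cat_$props1,
                                   cat_$geom2, cat_$props2, cat_$aux)
  s <- strip_carbene(cat_$geom2, detect_paddlewheel(cat_$geom2))
  manual <- distance_weighted_volume(s$geometry,
                                     focus = s$topology$rh_indices["rh_a"],
                                     exclude = s$topology$rh_indices)
  expect_equal(unname(rec$values["wv"]), manual, tolerance = 1e-12)
})
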