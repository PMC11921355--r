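synthetic_ligand <- function(seed = 1, ring_sequence = c("DELTA", "M", "G")) {
  b <- build_synthetic_complex(synthetic_complex_spec(
    seed = seed, ring_sequence = ring_sequence))
  select_residues(model_frame(b$model), het = TRUE)
}

test_that("ring perception finds all three rings and flags the Delta end", {
  lig <- synthetic_ligand(seed = 8)
  rings <- detect_sugar_rings(lig)
  expect_equal(length(rings), 3L)
  unsat <- vapply(rings, function(r) isTRUE(as.logical(r$unsaturated)), TRUE)
  expect_equal(sum(unsat), 1L)
  expect_equal(rings[[which(unsat)]]$epimer, "DELTA")
})

test_that("a lone ideal chair ring is perceived with consistent labels", {
  ring <- generate_ideal_ring("G")
  atoms <- plyase:::atoms_from_coords(ring$coords, "LGU", "B", 1L, het = TRUE)
  atoms$serial <- seq_len(nrow(atoms))
  got <- detect_sugar_rings(atoms)
  expect_equal(length(got), 1L)
  expect_equal(got[[1]]$coords[rownames(ring$coords), ], ring$coords,
               tolerance = 1e-9)
  expect_equal(got[[1]]$epimer, "G")
})

test_that("perception is invariant under atom shuffling and rigid motion", {
  lig <- synthetic_ligand(seed = 12)
  set.seed(12)
  shuffled <- lig[sample(nrow(lig)), ]
  tf <- random_rigid_transform()
  moved <- plyase:::set_coords(lig, apply_transform(plyase:::coords_matrix(lig), tf))
  for (variant in list(shuffled, moved)) {
    rings <- detect_sugar_rings(variant)
    expect_equal(length(rings), 3L)
    expect_setequal(vapply(rings, function(r) r$epimer, ""), c("DELTA", "M", "G"))
  }
})

test_that("subsites run -1, +1, +2 from the unsaturated nonreducing end", {
  rings <- detect_sugar_rings(synthetic_ligand(seed = 3))
  ch <- assign_subsites(rings)
  expect_equal(ch$subsites, c(-1L, 1L, 2L))
  expect_equal(vapply(ch$rings, function(r) r$epimer, ""), c("DELTA", "M", "G"))
  # input order must not matter: orientation comes from the C1 -> O4 links
  ch2 <- assign_subsites(rev(rings))
  expect_equal(vapply(ch2$rings, function(r) r$residue$res_seq, 0L),
               vapply(ch$rings, function(r) r$residue$res_seq, 0L))
  expect_equal(ch2$subsites, ch$subsites)
})

test_that("a single saturated ring gets subsite -1 with a warning", {
  ring <- generate_ideal_ring("M")
  atoms <- plyase:::atoms_from_coords(ring$coords, "BEM", "B", 1L, het = TRUE)
  atoms$serial <- seq_len(nrow(atoms))
  rings <- detect_sugar_rings(atoms)
  expect_warning(ch <- assign_subsites(rings), "not unsaturated")
  expect_equal(ch$subsites, -1L)
})

test_that("epimer classification and epimerization are mutually consistent", {
  m <- generate_ideal_ring("M")
  expect_equal(classify_epimer_c5(m), "M")
  g <- epimerize_c5(m)
  expect_equal(g$epimer, "G")
  expect_equal(classify_epimer_c5(g), "G")
  expect_equal(classify_epimer_c5(generate_ideal_ring("DELTA")), "DELTA")
  expect_error(epimerize_c5(generate_ideal_ring("DELTA")), "unsaturated|DELTA")
})

test_that("double epimerization is the identity and ring atoms never move", {
  m <- place_c5_proton(generate_ideal_ring("M"))
  g <- epimerize_c5(m)
  back <- epimerize_c5(g)
  expect_equal(back$coords, m$coords, tolerance = 1e-9)
  expect_equal(back$h5, m$h5, tolerance = 1e-9)
  ring_atoms <- c("C1", "C2", "C3", "C4", "C5", "O5", "O4")
  expect_equal(g$coords[ring_atoms, ], m$coords[ring_atoms, ], tolerance = 1e-12)
  # bond lengths preserved through the carboxylate rotation
  d <- function(r, a, b) sqrt(sum((r$coords[a, ] - r$coords[b, ])^2))
  expect_equal(d(g, "C5", "C6"), d(m, "C5", "C6"), tolerance = 1e-9)
  expect_equal(d(g, "C6", "O6A"), d(m, "C6", "O6A"), tolerance = 1e-9)
})

test_that("H5 sits 1.09 A from C5 along the fourth tetrahedral direction", {
  # exact tetrahedral symmetry case: C5 at origin, neighbours at three of
  # the four tetrahedral unit directions
  t1 <- c(1, 1, 1) / sqrt(3)
  t2 <- c(1, -1, -1) / sqrt(3)
  t3 <- c(-1, 1, -1) / sqrt(3)
  t4 <- c(-1, -1, 1) / sqrt(3)
  coords <- rbind(C1 = 2 * t4, C2 = c(3, 3, 0), C3 = c(3, 0, 3),
                  C4 = 1.52 * t1, C5 = c(0, 0, 0), O5 = 1.43 * t2,
                  C6 = 1.52 * t3)
  ring <- plyase:::sugar_ring(coords, serials = seq_len(7),
                              residue = list(chain = "B", res_seq = 1L,
                                             i_code = "", res_name = "BEM"),
                              unsaturated = FALSE)
  ring <- place_c5_proton(ring)
  expect_equal(sqrt(sum((ring$h5 - coords["C5", ])^2)), 1.09, tolerance = 1e-9)
  expect_equal(ring$h5 / 1.09, t4, tolerance = 1e-9)
  for (nb in list(t1 * 1.52, t2 * 1.43, t3 * 1.52)) {
    ang <- acos(sum((ring$h5 / sqrt(sum(ring$h5^2))) * nb / sqrt(sum(nb^2)))) * 180 / pi
    expect_equal(ang, 109.47, tolerance = 0.5)
  }
})

test_that("H5 placement is equivariant under rigid motion", {
  set.seed(7)
  ring <- generate_ideal_ring("G")
  h0 <- place_c5_proton(ring)$h5
  for (k in 1:5) {
    tf <- random_rigid_transform()
    moved <- ring
    moved$coords <- apply_transform(ring$coords, tf)
    expect_equal(place_c5_proton(moved)$h5, apply_transform(h0, tf),
                 tolerance = 1e-10)
  }
})

test_that("H5 on an ideal G ring lies opposite the neighbour centroid plane", {
  ring <- place_c5_proton(generate_ideal_ring("G"))
  c5 <- ring$coords["C5", ]
  expect_equal(sqrt(sum((ring$h5 - c5)^2)), 1.09, tolerance = 1e-9)
  cen <- colMeans(ring$coords[c("C4", "O5", "C6"), ])
  # H5 and the neighbour centroid on opposite sides of C5
  expect_lt(sum((ring$h5 - c5) * (cen - c5)), 0)
})

test_that("unsaturated rings refuse a proton and H5 errors are explicit", {
  expect_error(place_c5_proton(generate_ideal_ring("DELTA")), "no C5 proton")
  ring <- generate_ideal_ring("M")
  ring$coords <- ring$coords[setdiff(rownames(ring$coords), "C6"), ]
  expect_error(place_c5_proton(ring), "C6")
})

test_that("the computed H5 can be appended to the complex and re-parsed", {
  b <- build_synthetic_complex(synthetic_complex_spec(seed = 9))
  m <- measure_complex(b$model, his_res = 226, tyr_res = 280)
  atoms <- append_h5_atom(model_frame(b$model), m$ring)
  expect_equal(sum(atoms$atom_name == "H5"), 1L)
  re <- parse_structure(write_structure(structure_model(atoms)))
  h5row <- model_frame(re)[model_frame(re)$atom_name == "H5", ]
  expect_equal(h5row$element, "H")
  expect_equal(c(h5row$x, h5row$y, h5row$z), unname(round(m$ring$h5, 3)))
})
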