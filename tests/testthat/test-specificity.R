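test_that("distances are measured exactly on constructed geometry", {
  b <- build_synthetic_complex(synthetic_complex_spec(
    seed = 21, target_d_his = 2.8, target_d_tyr = 2.1))
  d <- measure_synthetic(b$model)
  expect_equal(unname(d["his"]), 2.8, tolerance = 1e-6)
  expect_equal(unname(d["tyr"]), 2.1, tolerance = 1e-6)
})

test_that("distances are invariant under whole-complex translation", {
  b <- build_synthetic_complex(synthetic_complex_spec(seed = 22))
  d0 <- measure_synthetic(b$model)
  shifted <- b$model
  shifted$frames[[1]] <- plyase:::set_coords(
    model_frame(b$model),
    sweep(plyase:::coords_matrix(model_frame(b$model)), 2, c(11, -7, 3), "+"))
  expect_equal(measure_synthetic(shifted), d0, tolerance = 1e-9)
})

test_that("min(NE2, ND1) never exceeds the NE2-only distance", {
  for (seed in c(2, 14, 33)) {
    b <- build_synthetic_complex(synthetic_complex_spec(seed = seed))
    m_ne2 <- measure_complex(b$model, his_res = 226, tyr_res = 280,
                             his_atom = "NE2")$distances
    m_min <- measure_complex(b$model, his_res = 226, tyr_res = 280,
                             his_atom = "min")$distances
    expect_lte(m_min$distance[m_min$residue == "HIS"],
               m_ne2$distance[m_ne2$residue == "HIS"])
  }
})

test_that("missing reference atoms are reported by residue and atom", {
  b <- build_synthetic_complex(synthetic_complex_spec(seed = 2))
  atoms <- model_frame(b$model)
  atoms <- atoms[!(atoms$res_seq == 280 & atoms$atom_name == "OH"), ]
  expect_error(catalytic_site(atoms, 226, 280), "OH")
})

test_that("the distance rule reproduces the published-style calls", {
  # VBAly15A-style quadruple
  call <- classify_specificity(d_tyr_m = 2.1, d_his_g = 2.8,
                               d_his_m = 5.1, d_tyr_g = 4.4, epsilon = 0.1)
  expect_equal(call$label, "polyM")
  expect_equal(call$margin, 0.7, tolerance = 1e-12)
  # smallest-margin enzyme (A1-IV'): Tyr G ties His G at 1.8
  call2 <- classify_specificity(d_tyr_m = 1.6, d_his_g = 1.8,
                                d_his_m = 4.0, d_tyr_g = 1.8, epsilon = 0.1)
  expect_equal(call2$label, "polyM")
  expect_equal(call2$margin, 0.2, tolerance = 1e-12)
})

test_that("exact ties are dual and the rule is M/G symmetric", {
  tie <- classify_specificity(d_tyr_m = 2.0, d_his_g = 2.0,
                              d_his_m = 5.0, d_tyr_g = 5.0, epsilon = 0.1)
  expect_equal(tie$label, "dual")
  set.seed(55)
  for (k in 1:25) {
    d <- runif(4, 1.5, 6)
    a <- classify_specificity(d[1], d[2], d[3], d[4], epsilon = 0.1)
    b <- classify_specificity(d_tyr_m = d[4], d_his_g = d[3],
                              d_his_m = d[2], d_tyr_g = d[1], epsilon = 0.1)
    flip <- c(polyM = "polyG", polyG = "polyM", dual = "dual")
    expect_equal(b$label, unname(flip[a$label]))
  }
})

test_that("adding a constant to all four distances never changes the label", {
  set.seed(77)
  for (k in 1:25) {
    d <- runif(4, 1.5, 6)
    shift <- runif(1, 0, 10)
    a <- classify_specificity(d[1], d[2], d[3], d[4])
    b <- classify_specificity(d[1] + shift, d[2] + shift,
                              d[3] + shift, d[4] + shift)
    expect_equal(b$label, a$label)
    expect_equal(b$margin, a$margin, tolerance = 1e-9)
  }
})

test_that("invalid distances raise domain errors", {
  expect_error(classify_specificity(-1, 2, 3, 4), "non-negative")
  expect_error(classify_specificity(NaN, 2, 3, 4), "finite")
})

test_that("single-frame trajectories agree with direct measurement", {
  b <- build_synthetic_complex(synthetic_complex_spec(seed = 13))
  site <- catalytic_site(b$model, 226, 280)
  ser <- distance_series(b$model, site)
  expect_equal(nrow(ser), 1L)
  d <- measure_synthetic(b$model)
  expect_equal(ser$d_his, unname(d["his"]), tolerance = 1e-12)
  expect_equal(ser$d_tyr, unname(d["tyr"]), tolerance = 1e-12)
})

test_that("constant and linearly ramped trajectories give expected series", {
  b <- build_synthetic_complex(synthetic_complex_spec(
    seed = 25, global_transform = NULL))
  atoms <- model_frame(b$model)
  site <- catalytic_site(b$model, 226, 280)

  const <- structure_model(list(atoms, atoms, atoms))
  s1 <- distance_series(const, site)
  expect_equal(s1$d_tyr, rep(s1$d_tyr[1], 3))
  expect_equal(stats::var(s1$d_his), 0)

  # translate the ligand along the Tyr(OH) -> H5 axis, 0.1 A per frame
  m0 <- measure_complex(b$model, his_res = 226, tyr_res = 280)
  oh <- plyase:::atom_xyz(atoms, "A", 280, "OH")
  axis <- (m0$ring$h5 - oh) / sqrt(sum((m0$ring$h5 - oh)^2))
  frames <- lapply(0:3, function(k) {
    a <- atoms
    lig <- a$het
    xyz <- plyase:::coords_matrix(a)
    xyz[lig, ] <- sweep(xyz[lig, ], 2, 0.1 * k * axis, "+")
    plyase:::set_coords(a, xyz)
  })
  s2 <- distance_series(structure_model(frames), site)
  expect_equal(diff(s2$d_tyr), rep(0.1, 3), tolerance = 1e-6)

  summ <- attr(s2, "summary")
  expect_equal(summ$min[summ$residue == "TYR"], s2$d_tyr[1], tolerance = 1e-12)
  expect_equal(summ$max[summ$residue == "TYR"], s2$d_tyr[4], tolerance = 1e-12)
})

test_that("jittered trajectories match per-frame single measurements", {
  b <- build_synthetic_complex(synthetic_complex_spec(seed = 26))
  frames <- lapply(1:4, function(k)
    model_frame(perturb_coordinates(b$model, sd = 0.05, seed = 1000 + k)))
  traj <- structure_model(frames)
  site <- catalytic_site(traj, 226, 280)
  ser <- distance_series(traj, site)
  for (k in 1:4) {
    single <- measure_synthetic(structure_model(frames[[k]]))
    expect_equal(ser$d_his[k], unname(single["his"]), tolerance = 1e-12)
    expect_equal(ser$d_tyr[k], unname(single["tyr"]), tolerance = 1e-12)
  }
})

test_that("missing atoms in a frame are reported with the frame index", {
  b <- build_synthetic_complex(synthetic_complex_spec(seed = 27))
  atoms <- model_frame(b$model)
  broken <- atoms[!(atoms$res_seq == 280 & atoms$atom_name == "OH"), ]
  traj <- structure_model(list(atoms, broken))
  site <- catalytic_site(b$model, 226, 280)
  expect_error(distance_series(traj, site), "frame 2")
})

test_that("hydrogen-bond contacts follow the distance cutoff", {
  b <- build_synthetic_complex(synthetic_complex_spec(
    seed = 30, global_transform = NULL))
  atoms <- model_frame(b$model)
  lig <- select_residues(atoms, het = TRUE)
  # place an Arg NH1 2.9 A from the +2 ring's O4
  o4 <- plyase:::atom_xyz(lig, "B", 3L, "O4")
  arg <- data.frame(serial = max(atoms$serial) + 1L, atom_name = "NH1",
                    alt_loc = "", res_name = "ARG", chain = "A",
                    res_seq = 114L, i_code = "", x = o4[1] + 2.9, y = o4[2],
                    z = o4[3], occ = 1, b = 0, element = "N", het = FALSE,
                    stringsAsFactors = FALSE)
  withArg <- structure_model(rbind(atoms, arg))
  hits <- detect_hbond_contacts(withArg)
  found <- hits[hits$res_seq == 114, ]
  expect_true(nrow(found) >= 1)
  expect_true(any(found$ligand_atom == "O4" & abs(found$distance - 2.9) < 1e-9))

  expect_equal(nrow(detect_hbond_contacts(withArg, d_max = 0)), 0L)

  # move the residue to 5 A from O4 along whichever direction clears the
  # rest of the ligand: the contact disappears at the default cutoff
  ligxyz <- plyase:::coords_matrix(lig[lig$element %in% c("N", "O"), ])
  dirs <- expand.grid(x = -1:1, y = -1:1, z = -1:1)
  dirs <- as.matrix(dirs[rowSums(dirs^2) > 0, ])
  dirs <- dirs / sqrt(rowSums(dirs^2))
  clearance <- apply(dirs, 1, function(d)
    min(sqrt(rowSums(sweep(ligxyz, 2, o4 + 5 * d)^2))))
  dbest <- dirs[which.max(clearance), ]
  expect_gt(max(clearance), 3.5)  # the probe point really is clear
  far <- arg
  far$x <- o4[1] + 5 * dbest[1]
  far$y <- o4[2] + 5 * dbest[2]
  far$z <- o4[3] + 5 * dbest[3]
  tmp <- detect_hbond_contacts(structure_model(rbind(atoms, far)))
  expect_false(any(tmp$res_seq == 114))
})

test_that("the donor angle criterion filters contacts when H is present", {
  # donor N with an H pointing away from the acceptor fails the angle test
  base <- data.frame(serial = 1:3,
                     atom_name = c("N", "H", "O1"), alt_loc = "",
                     res_name = c("GLY", "GLY", "LIG"), chain = c("A", "A", "B"),
                     res_seq = c(1L, 1L, 1L), i_code = "",
                     x = c(0, -1, 3), y = 0, z = 0, occ = 1, b = 0,
                     element = c("N", "H", "O"), het = c(FALSE, FALSE, TRUE),
                     stringsAsFactors = FALSE)
  expect_equal(nrow(detect_hbond_contacts(structure_model(base))), 0L)
  toward <- base; toward$x[2] <- 1  # H between donor and acceptor
  expect_equal(nrow(detect_hbond_contacts(structure_model(toward))), 1L)
})

test_that("specificity reports round-trip through TSV", {
  tab <- pl15_reference_distances()
  rep1 <- classify_distance_table(tab)
  expect_equal(nrow(rep1), 8L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_specificity_report(rep1, path)
  rep2 <- read_specificity_report(path)
  expect_equal(as.data.frame(rep2), as.data.frame(rep1), tolerance = 1e-9)
  # pretty rendering uses "-" for missing metadata
  rep1$enzyme[1] <- NA
  expect_match(format_specificity_report(rep1), "-")
})
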