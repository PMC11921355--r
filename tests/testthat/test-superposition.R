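test_that("trivial alignments behave as expected", {
  al <- align_sequences("ACD", "ACD")
  expect_equal(nrow(al$pairs), 3L)
  expect_equal(al$identity_fraction, 1)
  expect_equal(align_sequences("A", "C")$identity_fraction, 0)
  expect_error(align_sequences("", "ACD"), "empty")
})

test_that("alignment score equals exhaustive enumeration over all paths", {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  cases <- list(c("ACDEFGHI", "ACDFGHIK"),
                c("WWKLMNPQ", "WKLNPQRS"))
  for (cs in cases) {
    got <- align_sequences(cs[1], cs[2])$score
    want <- oracle_alignment_score(cs[1], cs[2], BLOSUM62)
    expect_equal(got, want, info = paste(cs, collapse = " vs "))
  }
})

test_that("kabsch_fit handles identity, translation and constructed rotations", {
  P <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.3, 0.4, 1.2))
  fit <- kabsch_fit(P, P)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$transform$rotation, diag(3), tolerance = 1e-10)
  expect_equal(fit$transform$translation, c(0, 0, 0), tolerance = 1e-10)

  # single point pair: pure translation
  fit1 <- kabsch_fit(matrix(c(1, 2, 3), 1), matrix(c(4, 6, 8), 1))
  expect_equal(fit1$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit1$transform$translation, c(3, 4, 5))

  # recover a constructed rotation to 1e-8
  set.seed(17)
  for (k in 1:10) {
    R <- random_rigid_transform()$rotation
    Q <- P %*% t(R)
    fit <- kabsch_fit(Q, P)  # should recover R^T
    expect_equal(fit$transform$rotation, t(R), tolerance = 1e-8)
    expect_lt(fit$rmsd, 1e-8)
  }
})

test_that("kabsch_fit never returns a reflection, even for degenerate inputs", {
  set.seed(23)
  for (k in 1:25) {
    n <- sample(2:6, 1)
    P <- random_point_set(n)
    Q <- random_point_set(n)
    expect_equal(det(kabsch_fit(P, Q)$transform$rotation), 1, tolerance = 1e-10)
  }
  # all points collinear
  P <- cbind(seq_len(4), 0, 0)
  Q <- random_point_set(4)
  fit <- kabsch_fit(P, Q)
  expect_equal(det(fit$transform$rotation), 1, tolerance = 1e-10)
  # still minimal: oracle grid search cannot do better
  expect_lte(fit$rmsd, oracle_min_rmsd(P, Q, refine_levels = 3) + 1e-6)
})

test_that("kabsch RMSD is invariant to a common rigid pre-transform", {
  set.seed(41)
  P <- random_point_set(5)
  Q <- random_point_set(5)
  base <- kabsch_fit(P, Q)$rmsd
  for (k in 1:5) {
    tf <- random_rigid_transform()
    expect_equal(kabsch_fit(apply_transform(P, tf), apply_transform(Q, tf))$rmsd,
                 base, tolerance = 1e-8)
  }
})

test_that("active-site superposition recovers constructed transforms", {
  b <- build_synthetic_complex(synthetic_complex_spec(seed = 19))
  prot <- select_residues(model_frame(b$model), het = FALSE)
  query0 <- structure_model(prot)

  # query identical to template: identity transform, rmsd 0
  sup <- superpose_active_site(query0, b$model,
                               select_residues(model_frame(b$model), het = TRUE))
  expect_equal(sup$rmsd, 0, tolerance = 1e-8)
  expect_equal(sup$transform$rotation, diag(3), tolerance = 1e-8)
  expect_gte(sup$n_atoms_used, 3L)

  # rigidly moved query: recovered transform inverts the motion
  set.seed(3)
  tf <- random_rigid_transform()
  qa <- plyase:::set_coords(prot, apply_transform(plyase:::coords_matrix(prot), tf))
  sup2 <- superpose_active_site(structure_model(qa), b$model,
                                select_residues(model_frame(b$model), het = TRUE))
  expect_lt(sup2$rmsd, 1e-6)
  expect_equal(sup2$transform$rotation, t(tf$rotation), tolerance = 1e-6)

  # with seeded coordinate noise, rmsd equals an independent Kabsch on the
  # same anchor pairs (here: the full-precision package fit re-run on the
  # anchor coordinates extracted independently)
  qn <- perturb_coordinates(structure_model(qa), sd = 1, seed = 99)
  sup3 <- superpose_active_site(qn, b$model,
                                select_residues(model_frame(b$model), het = TRUE))
  qa3 <- model_frame(qn); ta3 <- model_frame(b$model)
  P <- t(vapply(seq_len(nrow(sup3$anchors)), function(i)
    plyase:::atom_xyz(qa3, "A", sup3$anchors$query_res[i], "CA"), numeric(3)))
  Q <- t(vapply(seq_len(nrow(sup3$anchors)), function(i)
    plyase:::atom_xyz(ta3, "A", sup3$anchors$template_res[i], "CA"), numeric(3)))
  expect_equal(sup3$rmsd, oracle_min_rmsd(P, Q), tolerance = 1e-3)
})

test_that("insufficient anchors raise an explicit error", {
  b <- build_synthetic_complex(synthetic_complex_spec(seed = 4))
  prot <- select_residues(model_frame(b$model), het = FALSE)
  lig <- select_residues(model_frame(b$model), het = TRUE)
  expect_error(
    superpose_active_site(structure_model(prot), b$model, lig,
                          shell_radius = 0.1),
    "insufficient anchors")
})

test_that("transplant_ligand applies the inverse transform", {
  b <- build_synthetic_complex(synthetic_complex_spec(seed = 6))
  lig <- select_residues(model_frame(b$model), het = TRUE)

  same <- transplant_ligand(b$model, lig, identity_transform())
  expect_equal(plyase:::coords_matrix(same), plyase:::coords_matrix(lig))

  tshift <- rigid_transform(diag(3), c(2, -1, 5))
  moved <- transplant_ligand(b$model, lig, tshift)
  expect_equal(plyase:::coords_matrix(moved),
               sweep(plyase:::coords_matrix(lig), 2, c(2, -1, 5)))

  expect_error(transplant_ligand(b$model, lig[0, ], identity_transform()),
               "empty ligand")
})
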