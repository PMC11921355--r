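# Seeded generator of idealized trisaccharide-enzyme complexes with known
# ground-truth geometry. Rings are built from idealized internal coordinates
# (chair pyranoses, planar 4-deoxy-unsaturated ring), not copied from any
# deposited structure, so the whole pipeline is testable offline.

RING_CODES <- c(DELTA = "DEH", M = "BEM", G = "LGU")

.ring_cache <- new.env(parent = emptyenv())

with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Solve for a closed six-ring with prescribed bond lengths, vertex angles and
# torsion pattern by penalised least squares from a NeRF initial guess.
solve_ring_cycle <- function(bonds, angles, torsions, wb = 200, wa = 10, wt = 1) {
  nxt <- function(i) (i %% 6L) + 1L
  prv <- function(i) ((i - 2L) %% 6L) + 1L
  obj <- function(p) {
    X <- matrix(p, 6L, 3L)
    e <- 0
    for (i in 1:6) {
      e <- e + wb * (vnorm(X[nxt(i), ] - X[i, ]) - bonds[i])^2
      e <- e + wa * ((angle_deg(X[prv(i), ], X[i, ], X[nxt(i), ]) -
                        angles[i]) * pi / 180)^2
      dt <- (torsion_deg(X[prv(i), ], X[i, ], X[nxt(i), ], X[nxt(nxt(i)), ]) -
               torsions[i] + 180) %% 360 - 180
      e <- e + wt * (dt * pi / 180)^2
    }
    e
  }
  X <- matrix(0, 6L, 3L)
  X[2L, ] <- c(bonds[1L], 0, 0)
  th <- angles[2L] * pi / 180
  X[3L, ] <- X[2L, ] + bonds[2L] * c(cos(pi - th), sin(pi - th), 0)
  X[4L, ] <- nerf_place(X[1L, ], X[2L, ], X[3L, ], bonds[3L], angles[3L], torsions[2L])
  X[5L, ] <- nerf_place(X[2L, ], X[3L, ], X[4L, ], bonds[4L], angles[4L], torsions[3L])
  X[6L, ] <- nerf_place(X[3L, ], X[4L, ], X[5L, ], bonds[5L], angles[5L], torsions[4L])
  fit <- stats::optim(as.numeric(X), obj, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-15))
  matrix(fit$par, 6L, 3L, dimnames = list(c("C1", "C2", "C3", "C4", "C5", "O5"),
                                          c("x", "y", "z")))
}

equatorial_choice <- function(dirs, origin, centroid, reach) {
  d1 <- vnorm(origin + reach * dirs[[1L]] - centroid)
  if (d1 >= vnorm(origin + reach * dirs[[2L]] - centroid)) dirs[[1L]] else dirs[[2L]]
}

build_ring_template <- function(epimer) {
  if (epimer %in% c("M", "G")) {
    X <- solve_ring_cycle(
      bonds = c(1.52, 1.52, 1.52, 1.52, 1.43, 1.43),
      angles = c(110, 111, 111, 111, 110, 112),
      torsions = c(-55, 55, -55, 55, -55, 55))
  } else if (epimer == "DELTA") {
    X <- solve_ring_cycle(
      bonds = c(1.52, 1.51, 1.50, 1.33, 1.36, 1.43),
      angles = c(110, 110, 112, 120, 120, 115),
      torsions = c(-45, 50, -25, 0, 5, 15))
  } else stop("unknown epimer: ", epimer, call. = FALSE)
  cen <- colMeans(X)
  coords <- X

  if (epimer == "DELTA") {
    # sp2 C5: carboxylate in the C4=C5/O5 plane; no O4 (4-deoxy)
    c5 <- X["C5", ]
    d <- unitv(-(unitv(X["C4", ] - c5) + unitv(X["O5", ] - c5)))
    c6 <- c5 + 1.48 * d
    coords <- rbind(coords, C6 = c6)
  } else {
    # O4 on C4, equatorial-like
    c4 <- X["C4", ]
    dirs <- tetrahedral_directions(unitv(X["C3", ] - c4), unitv(X["C5", ] - c4))
    o4 <- c4 + 1.43 * equatorial_choice(dirs, c4, cen, 1.43)
    coords <- rbind(coords, O4 = o4)
    # C6 on C5 with epimer-consistent chirality under the package calibration
    c5 <- X["C5", ]
    dirs <- tetrahedral_directions(unitv(X["C4", ] - c5), unitv(X["O5", ] - c5))
    want <- if (epimer == "M") EPIMER_TRIPLE_SIGN_M else -EPIMER_TRIPLE_SIGN_M
    picked <- NULL
    for (d in dirs) {
      s <- sign(sum(vcross(X["C4", ] - c5, X["O5", ] - c5) * d))
      if (s == want) picked <- d
    }
    if (is.null(picked)) stop("internal: chirality selection failed")
    c6 <- c5 + 1.52 * picked
    coords <- rbind(coords, C6 = c6)
  }
  # planar carboxylate oxygens on C6
  u <- unitv(coords["C5", ] - coords["C6", ])
  w <- perp_vector(u)
  ca <- cos(117 * pi / 180); sa <- sin(117 * pi / 180)
  coords <- rbind(coords,
                  O6A = coords["C6", ] + 1.25 * (ca * u + sa * w),
                  O6B = coords["C6", ] + 1.25 * (ca * u - sa * w))
  coords
}

#' Generate an idealized uronate ring
#'
#' Chair-geometry pyranose (C-C 1.52 A, C-O 1.43 A, near-tetrahedral angles,
#' alternating ring torsions of about +/-55 deg) carrying the carboxylate
#' C6/O6A/O6B and, for saturated rings, the O4 hydroxyl/link oxygen. The C6
#' orientation at C5 follows the requested epimer under the package's
#' chirality calibration. `DELTA` rings are built planar about a 1.33 A
#' C4=C5 double bond with no O4. Internal coordinates are idealized, not
#' copied from any deposited structure.
#'
#' @param epimer `"M"`, `"G"` or `"DELTA"`.
#' @param transform Optional [rigid_transform()] applied to the template.
#' @return A `sugar_ring` with labelled coordinates.
#' @export
generate_ideal_ring <- function(epimer = c("M", "G", "DELTA"),
                                transform = NULL) {
  epimer <- match.arg(epimer)
  key <- paste0("ring_", epimer)
  if (is.null(.ring_cache[[key]]))
    .ring_cache[[key]] <- build_ring_template(epimer)
  coords <- .ring_cache[[key]]
  if (!is.null(transform)) coords <- apply_transform(coords, transform)
  ring <- sugar_ring(coords,
                     serials = stats::setNames(seq_len(nrow(coords)), rownames(coords)),
                     residue = list(chain = "B", res_seq = 1L, i_code = "",
                                    res_name = RING_CODES[[epimer]]),
                     unsaturated = epimer == "DELTA")
  ring$epimer <- classify_epimer_c5(ring)
  ring
}

# local heavy-atom templates for toy catalytic residues: reference atom at
# the origin, body extending along +x (side chain + C-alpha only)
toy_tyr_template <- function() {
  cen <- c(1.39 + 1.38, 0, 0)
  hex <- function(deg) cen + 1.39 * c(cos(deg * pi / 180), sin(deg * pi / 180), 0)
  cg <- hex(0)
  cb <- cg + 1.51 * c(0.5, 0.75, 0.43)
  rbind(OH = c(0, 0, 0), CZ = hex(180), CE1 = hex(120), CD1 = hex(60),
        CG = cg, CD2 = hex(-60), CE2 = hex(-120), CB = cb,
        CA = cb + 1.53 * c(0.6, 0.7, -0.39))
}

toy_his_template <- function() {
  r <- 1.37 / (2 * sin(36 * pi / 180))
  cen <- c(r, 0, 0)
  pent <- function(deg) cen + r * c(cos(deg * pi / 180), sin(deg * pi / 180), 0)
  cg <- pent(-36)
  cb <- cg + 1.50 * c(0.55, -0.65, 0.52)
  rbind(NE2 = c(0, 0, 0), CE1 = pent(108), ND1 = pent(36), CG = cg,
        CD2 = pent(-108), CB = cb, CA = cb + 1.53 * c(0.65, -0.6, -0.47))
}

place_toy_residue <- function(template, target, direction) {
  R <- rotation_between(c(1, 0, 0), direction)
  sweep(template %*% t(R), 2L, target, "+")
}

atoms_from_coords <- function(coords, res_name, chain, res_seq, het) {
  data.frame(serial = 0L, atom_name = rownames(coords), alt_loc = "",
             res_name = res_name, chain = chain, res_seq = res_seq,
             i_code = "", x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
             occ = 1, b = 0,
             element = vapply(rownames(coords), guess_element, character(1L)),
             het = het, stringsAsFactors = FALSE, row.names = NULL)
}

#' Specification for a synthetic enzyme-trisaccharide complex
#'
#' Defaults describe the stated world of the characterised polyM enzymes:
#' an unsaturated-terminated trisaccharide (DELTA at the nonreducing -1
#' subsite) with an M-type +1 sugar, the catalytic Tyr-OH 2.1 A and His-NE2
#' 5.1 A from the +1 C5 proton. `target_d_his`/`target_d_tyr` are exact
#' pre-noise placement distances; `noise_sd` is the per-coordinate Gaussian
#' jitter applied afterwards.
#'
#' @param seed Integer seed; the build is fully deterministic given it.
#' @param ring_sequence Character vector over `M`, `G`, `DELTA` from the
#'   nonreducing end (`DELTA` allowed only first).
#' @param target_d_his,target_d_tyr Target His-NE2 / Tyr-OH -> H5(+1)
#'   distances, A (must exceed 1.5 A to be placeable without clash).
#' @param noise_sd Gaussian coordinate noise s.d., A.
#' @param global_transform A [rigid_transform()], `"random"` (seeded), or
#'   `NULL` for none.
#' @return An object of class `synthetic_complex_spec`.
#' @export
synthetic_complex_spec <- function(seed = 1L,
                                   ring_sequence = c("DELTA", "M", "G"),
                                   target_d_his = 5.1, target_d_tyr = 2.1,
                                   noise_sd = 0, global_transform = "random") {
  ring_sequence <- match.arg(ring_sequence, c("M", "G", "DELTA"),
                             several.ok = TRUE)
  if (length(ring_sequence) < 1L) stop("ring_sequence must be non-empty", call. = FALSE)
  if ("DELTA" %in% ring_sequence[-1L])
    stop("DELTA ring only allowed at the nonreducing (first) position", call. = FALSE)
  if (any(c(target_d_his, target_d_tyr) <= 1.0))
    stop("target distances must exceed 1.0 A", call. = FALSE)
  if (any(c(target_d_his, target_d_tyr) < 1.5))
    stop("target distance below 1.5 A would clash with the +1 sugar", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(seed = as.integer(seed), ring_sequence = ring_sequence,
                 target_d_his = target_d_his, target_d_tyr = target_d_tyr,
                 noise_sd = noise_sd, global_transform = global_transform),
            class = "synthetic_complex_spec")
}

#' Build a synthetic complex with ground-truth geometry
#'
#' Assembles the trisaccharide by C1 -> O4 glycosidic links (1.41 A,
#' tetrahedral link geometry), places toy His (imidazole heavy atoms) and
#' Tyr (phenol heavy atoms) so the NE2 -> H5(+1) and OH -> H5(+1) distances
#' equal the `spec` object's targets exactly, then applies seeded Gaussian
#' noise and the
#' global transform. Ground truth is recorded pre-noise. The toy protein also
#' carries three glycine C-alpha anchors flanking the site (author numbers
#' 100/150/300; His 226, Tyr 280, chain A) so alignment-guided superposition
#' has at least three anchors.
#'
#' @param spec A [synthetic_complex_spec()].
#' @return List with `model` (a single-frame [structure_model()]),
#'   `ground_truth` (targets, +1 epimer, pre-noise H5) and `spec`.
#' @export
build_synthetic_complex <- function(spec = synthetic_complex_spec()) {
  stopifnot(inherits(spec, "synthetic_complex_spec"))
  n <- length(spec$ring_sequence)
  rings <- lapply(spec$ring_sequence, function(e) {
    generate_ideal_ring(e)$coords
  })

  # chain assembly: seat ring i+1 so its O4 caps the free anomeric
  # direction of ring i
  for (i in seq_len(n - 1L)) {
    prev <- rings[[i]]
    c1 <- prev["C1", ]
    dirs <- tetrahedral_directions(unitv(prev["O5", ] - c1),
                                   unitv(prev["C2", ] - c1))
    a1 <- equatorial_choice(dirs, c1, colMeans(prev[c("C1", "C2", "C3", "C4", "C5", "O5"), ]), 1.41)
    o4t <- c1 + 1.41 * a1
    c4t <- nerf_place(prev["O5", ], c1, o4t, 1.43, 117, -100)
    c5t <- nerf_place(c1, o4t, c4t, 1.52, 111, -120)
    nxt <- rings[[i + 1L]]
    fit <- kabsch_fit(nxt[c("O4", "C4", "C5"), ], rbind(o4t, c4t, c5t))
    rings[[i + 1L]] <- apply_transform(nxt, fit$transform)
  }

  lig_atoms <- do.call(rbind, lapply(seq_len(n), function(i)
    atoms_from_coords(rings[[i]], RING_CODES[[spec$ring_sequence[i]]],
                      "B", i, het = TRUE)))

  ground_truth <- list(d_his = spec$target_d_his, d_tyr = spec$target_d_tyr,
                       plus1_epimer = if (n >= 2L) spec$ring_sequence[2L] else NA)
  prot_atoms <- NULL
  if (n >= 2L) {
    if (spec$ring_sequence[2L] == "DELTA")
      stop("+1 ring must be saturated to place the C5 proton", call. = FALSE)
    X <- rings[[2L]]
    c5 <- X["C5", ]
    u <- unitv(X["C4", ] - c5) + unitv(X["O5", ] - c5) + unitv(X["C6", ] - c5)
    h5 <- c5 + C5_H_BOND * unitv(-u)
    e0 <- unitv(h5 - c5)
    w <- perp_vector(e0)
    e_tyr <- drop(rotation_about_axis(w, 25) %*% e0)
    e_his <- drop(rotation_about_axis(w, -25) %*% e0)
    tyr <- place_toy_residue(toy_tyr_template(), h5 + spec$target_d_tyr * e_tyr,
                             e_tyr)
    his <- place_toy_residue(toy_his_template(), h5 + spec$target_d_his * e_his,
                             e_his)
    lig_heavy <- do.call(rbind, rings)
    cen <- colMeans(lig_heavy)
    axis <- unitv(rings[[n]]["C1", ] - rings[[1L]]["C1", ])
    p0 <- perp_vector(axis)
    gly <- lapply(c(0, 120, 240), function(th)
      cen + 6.5 * drop(rotation_about_axis(axis, th) %*% p0))
    prot_atoms <- rbind(
      atoms_from_coords(matrix(gly[[1L]], 1L, 3L, dimnames = list("CA", NULL)),
                        "GLY", "A", 100L, het = FALSE),
      atoms_from_coords(matrix(gly[[2L]], 1L, 3L, dimnames = list("CA", NULL)),
                        "GLY", "A", 150L, het = FALSE),
      atoms_from_coords(his, "HIS", "A", 226L, het = FALSE),
      atoms_from_coords(tyr, "TYR", "A", 280L, het = FALSE),
      atoms_from_coords(matrix(gly[[3L]], 1L, 3L, dimnames = list("CA", NULL)),
                        "GLY", "A", 300L, het = FALSE))
    ground_truth$h5 <- h5
    ground_truth$label <- NA_character_
  }

  atoms <- rbind(prot_atoms, lig_atoms)
  atoms$serial <- seq_len(nrow(atoms))
  model <- structure_model(atoms, title = sprintf(
    "synthetic complex seed %d (%s)", spec$seed,
    paste(spec$ring_sequence, collapse = "-")))

  with_local_seed(spec$seed, {
    if (spec$noise_sd > 0)
      model <- perturb_coordinates(model, spec$noise_sd)
    tf <- spec$global_transform
    if (identical(tf, "random")) tf <- random_rigid_transform()
    if (inherits(tf, "rigid_transform")) {
      model$frames <- lapply(model$frames, function(a)
        set_coords(a, apply_transform(coords_matrix(a), tf)))
      ground_truth$global_transform <- tf
    }
  })
  list(model = model, ground_truth = ground_truth, spec = spec)
}

#' Add i.i.d. Gaussian coordinate noise to every atom
#'
#' @param model A [structure_model()].
#' @param sd Per-coordinate standard deviation, A.
#' @param seed Optional seed (RNG state is restored afterwards); with
#'   `NULL` the current stream is used.
#' @return The perturbed model.
#' @export
perturb_coordinates <- function(model, sd, seed = NULL) {
  stopifnot(inherits(model, "structure_model"), sd >= 0)
  if (sd == 0) return(model)
  with_local_seed(seed, {
    model$frames <- lapply(model$frames, function(a) {
      m <- coords_matrix(a)
      set_coords(a, m + matrix(stats::rnorm(length(m), sd = sd), nrow(m), 3L))
    })
    model
  })
}

#' Build the M-type / G-type complex pair of a four-distance scenario
#'
#' The distance rule compares two complexes of one enzyme: one with an
#' M-type and one with a G-type sugar at +1. This helper builds both from
#' one seed, with the Delta-X-G trisaccharide carrying the requested +1
#' epimer, and records the rule's ground-truth label.
#'
#' @param seed Integer seed.
#' @param d_his_m,d_his_g,d_tyr_m,d_tyr_g Target distances, A.
#' @param noise_sd Per-coordinate noise, A.
#' @param epsilon Tie tolerance used for the ground-truth label.
#' @return List with `m`, `g` (each as [build_synthetic_complex()] output)
#'   and `label` (rule applied to the noise-free targets).
#' @export
build_synthetic_pair <- function(seed = 1L, d_his_m = 5.1, d_his_g = 2.8,
                                 d_tyr_m = 2.1, d_tyr_g = 4.4, noise_sd = 0,
                                 epsilon = 0.1) {
  m <- build_synthetic_complex(synthetic_complex_spec(
    seed = seed, ring_sequence = c("DELTA", "M", "G"),
    target_d_his = d_his_m, target_d_tyr = d_tyr_m, noise_sd = noise_sd))
  g <- build_synthetic_complex(synthetic_complex_spec(
    seed = seed + 1000003L, ring_sequence = c("DELTA", "G", "G"),
    target_d_his = d_his_g, target_d_tyr = d_tyr_g, noise_sd = noise_sd))
  truth <- classify_specificity(d_tyr_m = d_tyr_m, d_his_g = d_his_g,
                                d_his_m = d_his_m, d_tyr_g = d_tyr_g,
                                epsilon = epsilon)
  list(m = m, g = g, label = truth$label, truth = truth)
}
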