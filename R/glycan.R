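# Sugar-ring perception and +1-subsite geometry.
#
# Alginate-derived ligands are chains of uronate pyranoses: each ring is a
# 6-cycle of five carbons plus the ring oxygen O5, carries a carboxylate C6
# at C5, and links C1 -> O4 to the next ring toward the reducing end. The
# ring produced by beta-elimination at the new nonreducing end is
# 4-deoxy-unsaturated (C4=C5, no O4).

BOND_CUTOFF <- 1.75       # heavy-atom C/O bond threshold (connectivity fallback), A
GLYCO_LINK_CUTOFF <- 1.95 # C1-O4 glycosidic link cutoff (covalent radii + 0.45), A
UNSAT_C4C5_MAX <- 1.42    # C4=C5 double-bond detection threshold, A
C5_H_BOND <- 1.09         # aliphatic C-H bond length, A

RING_ATOM_NAMES <- c("C1", "C2", "C3", "C4", "C5", "O5")
EXTRA_ATOM_NAMES <- c("C6", "O4", "O6A", "O6B")

# Calibration of the C5 chirality sign, fixed once for the whole package:
# sign(det[C5->C4, C5->O5, C5->C6]) > 0 is labelled M (mannuronate-like),
# < 0 is G (guluronate-like). The synthetic ring generator places C6 in
# accordance with this constant, so generator and classifier agree by
# construction.
EPIMER_TRIPLE_SIGN_M <- 1

heavy_co <- function(atoms) atoms$element %in% c("C", "O")

bond_matrix <- function(xyz) {
  d <- as.matrix(stats::dist(xyz))
  d > 0 & d < BOND_CUTOFF
}

sugar_ring <- function(coords, serials, residue, unsaturated, epimer = "UNKNOWN",
                       h5 = NULL) {
  structure(list(coords = coords, serials = serials, residue = residue,
                 unsaturated = unsaturated, epimer = epimer, h5 = h5),
            class = "sugar_ring")
}

#' @export
print.sugar_ring <- function(x, ...) {
  cat(sprintf("sugar_ring %s %s%d: epimer %s%s%s\n",
              x$residue$res_name, x$residue$chain, x$residue$res_seq,
              x$epimer, if (x$unsaturated) " (unsaturated)" else "",
              if (!is.null(x$h5)) " [H5 placed]" else ""))
  invisible(x)
}

ring_atom <- function(ring, name) {
  if (!name %in% rownames(ring$coords)) return(NULL)
  ring$coords[name, ]
}

# Find all six-membered cycles of five carbons + one oxygen in a bonded
# C/O graph. Returns list of integer index vectors ordered around the cycle
# starting at the oxygen.
find_pyranose_cycles <- function(xyz, elements) {
  n <- nrow(xyz)
  if (n < 6L) return(list())
  B <- bond_matrix(xyz)
  nb <- lapply(seq_len(n), function(i) which(B[i, ]))
  cycles <- list()
  seen <- character()
  for (o in which(elements == "O")) {
    cn <- nb[[o]][elements[nb[[o]]] == "C"]
    if (length(cn) < 2L) next
    for (a in cn) for (b in cn) {
      if (a >= b) next
      # carbon-only simple paths a -> x -> y -> z with z adjacent to b,
      # closing the 6-cycle o-a-x-y-z-b (iterative DFS)
      todo <- list(a)
      while (length(todo) > 0L) {
        path <- todo[[length(todo)]]
        todo[[length(todo)]] <- NULL
        last <- path[length(path)]
        if (length(path) == 4L) {
          if (b %in% nb[[last]]) {
            cyc <- c(o, path, b)
            key <- paste(sort(cyc), collapse = "-")
            if (!key %in% seen) {
              seen <- c(seen, key)
              cycles[[length(cycles) + 1L]] <- cyc
            }
          }
          next
        }
        nxt <- nb[[last]]
        nxt <- nxt[elements[nxt] == "C" & !(nxt %in% path) & nxt != b & nxt != o]
        for (v in nxt) todo[[length(todo) + 1L]] <- c(path, v)
      }
    }
  }
  cycles
}

finish_ring <- function(coords, serials, residue) {
  d45 <- vnorm(coords["C4", ] - coords["C5", ])
  # unsaturation only when BOTH signals agree: short C4-C5 and missing O4.
  # The conjunction is what makes the flag robust to coordinate noise: the
  # 4-deoxy ring is always caught by its absent O4, while a saturated ring
  # (which always carries O4) can never be mislabelled by a fluctuating
  # bond length alone.
  unsat <- d45 < UNSAT_C4C5_MAX && !("O4" %in% rownames(coords))
  attr(unsat, "c4c5_short") <- d45 < UNSAT_C4C5_MAX
  attr(unsat, "o4_absent") <- !("O4" %in% rownames(coords))
  ring <- sugar_ring(coords, serials, residue, unsaturated = unsat)
  ring$epimer <- classify_epimer_c5(ring)
  ring
}

# primary perception path: trust standard carbohydrate atom names within
# each hetero residue (C1..C5, O5 complete)
perceive_rings_by_name <- function(ligand) {
  keys <- residue_key(ligand)
  out <- list()
  for (k in unique(keys)) {
    res <- ligand[keys == k, , drop = FALSE]
    if (!all(RING_ATOM_NAMES %in% res$atom_name)) next
    take <- c(RING_ATOM_NAMES, intersect(EXTRA_ATOM_NAMES, res$atom_name))
    idx <- match(take, res$atom_name)
    coords <- coords_matrix(res)[idx, , drop = FALSE]
    rownames(coords) <- take
    out[[length(out) + 1L]] <- finish_ring(
      coords, stats::setNames(res$serial[idx], take),
      residue = list(chain = res$chain[1L], res_seq = res$res_seq[1L],
                     i_code = res$i_code[1L], res_name = res$res_name[1L]))
  }
  out
}

#' Perceive sugar rings in a bound oligosaccharide
#'
#' When the ligand residues carry standard carbohydrate atom names (a
#' complete C1-C5, O5 set per residue), rings are read directly from the
#' names -- the robust path for curated PDB carbohydrates and for noisy
#' snapshots, where distance thresholds are unreliable. Otherwise the rings
#' are perceived from heavy-atom connectivity (C/O pairs closer than 1.75 A
#' are bonded; ligand CONECT records are never trusted): six-membered cycles
#' of five carbons plus the ring oxygen, with C5 identified as the
#' ring-oxygen neighbour bearing the exocyclic carboxylate carbon. A ring is
#' flagged unsaturated (the 4-deoxy-hexenuronate formed by beta-elimination)
#' when its C4-C5 bond is short (< 1.42 A) and it lacks an O4 substituent.
#'
#' @param ligand Atom table of the ligand residues (e.g. from
#'   [select_residues()] or [transplant_ligand()]).
#' @return List of `sugar_ring` objects (possibly empty), each carrying
#'   labelled coordinates, serials, residue identity, unsaturation flag, and
#'   C5 epimer classification.
#' @export
detect_sugar_rings <- function(ligand) {
  if (nrow(ligand) == 0L) return(list())
  named <- perceive_rings_by_name(ligand)
  if (length(named) > 0L) return(named)
  co <- ligand[heavy_co(ligand), , drop = FALSE]
  if (nrow(co) < 6L) return(list())
  xyz <- coords_matrix(co)
  cycles <- find_pyranose_cycles(xyz, co$element)
  if (length(cycles) == 0L) return(list())

  counts <- table(unlist(cycles))
  shared <- as.integer(names(counts)[counts > 1L])
  if (length(shared) > 0L)
    stop("ambiguous ring perception: atom serial(s) ",
         paste(co$serial[shared], collapse = ", "),
         " belong to more than one candidate ring", call. = FALSE)

  B <- bond_matrix(xyz)
  lapply(cycles, function(cyc) {
    o <- cyc[1L]
    ring_c <- cyc[-1L]
    # orient: C5 = oxygen neighbour with exocyclic carbon
    ends <- ring_c[B[o, ring_c]]
    has_exo_c <- vapply(ends, function(i) {
      exo <- which(B[i, ] & co$element == "C")
      any(!exo %in% cyc)
    }, logical(1L))
    if (sum(has_exo_c) == 1L) {
      c5 <- ends[has_exo_c]; c1 <- ends[!has_exo_c]
    } else if ("C5" %in% co$atom_name[ends]) {
      c5 <- ends[co$atom_name[ends] == "C5"][1L]
      c1 <- setdiff(ends, c5)[1L]
    } else {
      stop("cannot orient ring (no unique carboxylate-bearing C5); atom serials: ",
           paste(co$serial[cyc], collapse = ", "), call. = FALSE)
    }
    # walk C1 -> C2 -> C3 -> C4 -> C5 around the cycle
    order_idx <- c1
    prev <- o
    while (order_idx[length(order_idx)] != c5) {
      cur <- order_idx[length(order_idx)]
      nxt <- setdiff(ring_c[B[cur, ring_c]], c(prev, order_idx))
      if (length(nxt) != 1L)
        stop("inconsistent ring connectivity; atom serials: ",
             paste(co$serial[cyc], collapse = ", "), call. = FALSE)
      prev <- cur
      order_idx <- c(order_idx, nxt)
    }
    idx <- c(order_idx, o)
    names(idx) <- c("C1", "C2", "C3", "C4", "C5", "O5")

    # exocyclic substituents
    c6 <- {
      exo <- unname(which(B[idx[["C5"]], ] & co$element == "C"))
      exo <- exo[!exo %in% idx]
      if (length(exo) >= 1L) exo[1L] else NA_integer_
    }
    o4 <- {
      exo <- unname(which(B[idx[["C4"]], ] & co$element == "O"))
      exo <- exo[!exo %in% idx]
      if (length(exo) >= 1L) exo[1L] else NA_integer_
    }
    extra <- c(C6 = c6, O4 = o4)
    if (!is.na(c6)) {
      oc <- unname(which(B[c6, ] & co$element == "O"))
      oc <- oc[!oc %in% idx]
      if (length(oc) >= 1L) extra <- c(extra, O6A = oc[1L])
      if (length(oc) >= 2L) extra <- c(extra, O6B = oc[2L])
    }
    all_idx <- c(idx, extra[!is.na(extra)])
    coords <- xyz[all_idx, , drop = FALSE]
    rownames(coords) <- names(all_idx)
    serials <- stats::setNames(co$serial[all_idx], names(all_idx))

    # residue identity from the majority of ring atoms
    rk <- residue_key(co[idx, , drop = FALSE])
    maj <- names(sort(table(rk), decreasing = TRUE))[1L]
    row <- co[idx, , drop = FALSE][match(maj, rk), ]
    finish_ring(coords, serials,
                residue = list(chain = row$chain, res_seq = row$res_seq,
                               i_code = row$i_code, res_name = row$res_name))
  })
}

#' Classify the C5 epimer of a perceived sugar ring
#'
#' Saturated uronate rings differ at C5: mannuronate (M) and guluronate (G)
#' are C5 epimers. The label is read from the sign of the scalar triple
#' product of the three C5 bond vectors (to C4, O5 and C6), under a
#' calibration constant fixed once package-wide. Unsaturated rings are
#' `DELTA`; a missing carboxylate C6 gives `UNKNOWN` (reported, not fatal).
#'
#' @param ring A `sugar_ring`.
#' @return One of `"M"`, `"G"`, `"DELTA"`, `"UNKNOWN"`.
#' @export
classify_epimer_c5 <- function(ring) {
  stopifnot(inherits(ring, "sugar_ring"))
  if (isTRUE(as.logical(ring$unsaturated))) return("DELTA")
  c5 <- ring_atom(ring, "C5"); c6 <- ring_atom(ring, "C6")
  if (is.null(c6)) return("UNKNOWN")
  v1 <- ring_atom(ring, "C4") - c5
  v2 <- ring_atom(ring, "O5") - c5
  v3 <- c6 - c5
  s <- sign(sum(vcross(v1, v2) * v3))
  if (s == 0) return("UNKNOWN")
  if (s == EPIMER_TRIPLE_SIGN_M) "M" else "G"
}

#' Place the C5 proton geometrically
#'
#' The catalytic base abstracts the proton on C5 of the +1 sugar; crystal
#' and predicted structures carry no reliable hydrogens, so H5 is always
#' recomputed: `H5 = C5 + 1.09 A * unit(-(u_C4 + u_O5 + u_C6))`, the fourth
#' tetrahedral direction opposite the resultant of the three heavy-atom
#' bond vectors. Any hydrogen present in the input is ignored.
#'
#' @param ring A saturated `sugar_ring` with C4, O5 and C6 resolved.
#' @return The ring with `$h5` set (position in Angstrom).
#' @export
place_c5_proton <- function(ring) {
  stopifnot(inherits(ring, "sugar_ring"))
  if (isTRUE(as.logical(ring$unsaturated)))
    stop("unsaturated ring has no C5 proton", call. = FALSE)
  c5 <- ring_atom(ring, "C5"); c6 <- ring_atom(ring, "C6")
  if (is.null(c6)) stop("carboxylate C6 not resolved; cannot place H5",
                        call. = FALSE)
  u <- unitv(ring_atom(ring, "C4") - c5) + unitv(ring_atom(ring, "O5") - c5) +
    unitv(c6 - c5)
  if (vnorm(u) < 1e-6)
    stop("degenerate C5 neighbour geometry; cannot place H5", call. = FALSE)
  ring$h5 <- c5 + C5_H_BOND * unitv(-u)
  ring
}

#' Swap the C5 configuration of a ring (M <-> G)
#'
#' The H5 direction and the carboxylate direction at C5 are exchanged: the
#' C6 group is rigidly rotated onto the former H5 direction (bond lengths
#' preserved) and H5 is re-placed along the former C6 direction. Applying
#' the operation twice restores the original coordinates.
#'
#' @param ring A saturated `sugar_ring`.
#' @return The epimerised ring, with the epimer label flipped.
#' @export
epimerize_c5 <- function(ring) {
  stopifnot(inherits(ring, "sugar_ring"))
  if (isTRUE(as.logical(ring$unsaturated)))
    stop("cannot epimerise an unsaturated (DELTA) ring", call. = FALSE)
  if (is.null(ring$h5)) ring <- place_c5_proton(ring)
  c5 <- ring_atom(ring, "C5")
  u6 <- unitv(ring_atom(ring, "C6") - c5)
  uh <- unitv(ring$h5 - c5)
  R <- rotation_between(u6, uh)
  for (nm in c("C6", "O6A", "O6B")) {
    if (nm %in% rownames(ring$coords))
      ring$coords[nm, ] <- drop(R %*% (ring$coords[nm, ] - c5)) + c5
  }
  ring$h5 <- c5 + C5_H_BOND * u6
  ring$epimer <- switch(ring$epimer, M = "G", G = "M", ring$epimer)
  ring
}

#' Assign binding subsites along an oligosaccharide chain
#'
#' Rings are ordered by their glycosidic links (C1 of ring i bonded to O4 of
#' ring i+1, nonreducing to reducing end); the exolytic lyase attacks the
#' nonreducing terminus, so the unsaturated terminal ring is subsite -1 and
#' successive rings toward the reducing end are +1, +2, ... (the scissile
#' bond lies between -1 and +1). The assignment depends only on connectivity
#' and unsaturation, never on the input ordering or global frame. If no ring
#' is unsaturated, the nonreducing terminus is still -1, with a warning.
#'
#' @param rings List of `sugar_ring`s from [detect_sugar_rings()].
#' @return An `oligosaccharide_chain`: list with `rings` (ordered from the
#'   nonreducing end), `subsites` (integer vector, one per ring), and
#'   `links` (data frame of C1 -> O4 connections).
#' @export
assign_subsites <- function(rings) {
  stopifnot(length(rings) >= 1L,
            all(vapply(rings, inherits, TRUE, "sugar_ring")))
  n <- length(rings)
  links <- NULL
  if (n > 1L) {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      o4 <- ring_atom(rings[[j]], "O4")
      if (is.null(o4)) next
      if (vnorm(ring_atom(rings[[i]], "C1") - o4) < GLYCO_LINK_CUTOFF)
        links <- rbind(links, data.frame(from = i, to = j))
    }
  }
  out_deg <- tabulate(if (is.null(links)) integer() else links$from, n)
  in_deg <- tabulate(if (is.null(links)) integer() else links$to, n)
  if (any(out_deg > 1L) || any(in_deg > 1L))
    stop("branched oligosaccharide topology is not supported", call. = FALSE)
  start <- which(in_deg == 0L & (out_deg > 0L | n == 1L))
  if (n > 1L && (length(start) != 1L || sum(out_deg) != n - 1L))
    stop("rings do not form a single unbranched chain", call. = FALSE)
  if (n == 1L) start <- 1L
  order_idx <- start
  while (length(order_idx) < n) {
    nxt <- links$to[links$from == order_idx[length(order_idx)]]
    if (length(nxt) != 1L)
      stop("rings do not form a single unbranched chain", call. = FALSE)
    order_idx <- c(order_idx, nxt)
  }
  ordered <- rings[order_idx]
  if (!isTRUE(as.logical(ordered[[1L]]$unsaturated)))
    warning("nonreducing terminal ring is not unsaturated; assigning subsite -1 anyway",
            call. = FALSE)
  subsites <- c(-1L, seq_len(n - 1L))
  structure(list(rings = ordered, subsites = subsites, links = links),
            class = "oligosaccharide_chain")
}

#' @export
print.oligosaccharide_chain <- function(x, ...) {
  lab <- vapply(x$rings, function(r) r$epimer, character(1L))
  cat("oligosaccharide_chain:",
      paste(sprintf("%+d:%s", x$subsites, lab), collapse = " -> "), "\n")
  invisible(x)
}

#' Fetch the ring at a given subsite
#'
#' @param chain An `oligosaccharide_chain`.
#' @param subsite Integer subsite (e.g. `1` for +1).
#' @return The `sugar_ring` at that subsite.
#' @export
subsite_ring <- function(chain, subsite = 1L) {
  stopifnot(inherits(chain, "oligosaccharide_chain"))
  i <- which(chain$subsites == subsite)
  if (length(i) != 1L) stop("no ring at subsite ", subsite, call. = FALSE)
  chain$rings[[i]]
}

#' Append the computed H5 proton to an atom table
#'
#' @param atoms Atom table containing the ring's residue.
#' @param ring A `sugar_ring` with `$h5` placed.
#' @return The atom table with one added hydrogen record (atom name `H5`).
#' @export
append_h5_atom <- function(atoms, ring) {
  if (is.null(ring$h5)) stop("H5 has not been placed on this ring", call. = FALSE)
  row <- data.frame(serial = max(atoms$serial) + 1L, atom_name = "H5",
                    alt_loc = "", res_name = ring$residue$res_name,
                    chain = ring$residue$chain, res_seq = ring$residue$res_seq,
                    i_code = ring$residue$i_code, x = ring$h5[1L],
                    y = ring$h5[2L], z = ring$h5[3L], occ = 1, b = 0,
                    element = "H", het = TRUE, stringsAsFactors = FALSE)
  rbind(atoms, row)
}
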