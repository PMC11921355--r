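#' Global pairwise sequence alignment
#'
#' Needleman-Wunsch global alignment with BLOSUM62 and affine gap costs
#' (via Biostrings), returning the aligned residue-position pairs used to
#' anchor active-site superposition.
#'
#' @param a,b [protein_sequence()] objects or plain one-letter strings.
#' @param gap_open,gap_extend Affine gap penalties (a gap of length L costs
#'   `gap_open + L * gap_extend`).
#' @param substitution_matrix Name of a substitution matrix shipped with
#'   Biostrings.
#' @return An object of class `alignment_map`: list with `pairs` (data frame
#'   of 1-based positions `a_pos`, `b_pos` and residues), `score`, and
#'   `identity_fraction` (identical / aligned pairs).
#' @export
align_sequences <- function(a, b, gap_open = 10, gap_extend = 0.5,
                            substitution_matrix = "BLOSUM62") {
  sa <- if (inherits(a, "protein_sequence")) a$residues else as.character(a)
  sb <- if (inherits(b, "protein_sequence")) b$residues else as.character(b)
  if (!nzchar(sa) || !nzchar(sb)) stop("empty sequence", call. = FALSE)
  mat <- get(data(list = substitution_matrix,
                  package = "Biostrings", envir = environment()))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sa), Biostrings::AAString(sb),
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  gp <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  gs <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  ia <- cumsum(gp != "-")
  ib <- cumsum(gs != "-")
  both <- gp != "-" & gs != "-"
  pairs <- data.frame(a_pos = ia[both], b_pos = ib[both],
                      a_res = gp[both], b_res = gs[both],
                      stringsAsFactors = FALSE)
  idf <- if (nrow(pairs) > 0L) mean(pairs$a_res == pairs$b_res) else 0
  structure(list(pairs = pairs, score = Biostrings::score(pa),
                 identity_fraction = idf),
            class = "alignment_map")
}

#' @export
print.alignment_map <- function(x, ...) {
  cat(sprintf("alignment_map: %d aligned pairs, score %.1f, identity %.1f%%\n",
              nrow(x$pairs), x$score, 100 * x$identity_fraction))
  invisible(x)
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimising the RMSD between two
#' paired point sets, `x -> R x + t` mapping `P` onto `Q`. Reflections are
#' excluded: with a rank-deficient (e.g. collinear) covariance the sign of the
#' smallest singular vector is flipped so the determinant stays +1.
#'
#' @param P,Q n x 3 matrices of paired coordinates (n >= 1).
#' @return List with `transform` (a [rigid_transform()]), `rmsd` (Angstrom)
#'   and `n` (number of point pairs).
#' @export
kabsch_fit <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  stopifnot(ncol(P) == 3L, ncol(Q) == 3L, nrow(P) == nrow(Q), nrow(P) >= 1L)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- cq - drop(R %*% cp)
  tf <- rigid_transform(R, tr)
  dev <- apply_transform(P, tf) - Q
  list(transform = tf, rmsd = sqrt(mean(rowSums(dev^2))), n = nrow(P))
}

resolve_ligand <- function(atoms, ligand) {
  if (is.data.frame(ligand)) return(ligand)
  if (is.list(ligand))
    return(select_residues(atoms, chain = ligand$chain, res_seq = ligand$res_seq))
  stop("ligand must be an atom table or a list(chain=, res_seq=) selector",
       call. = FALSE)
}

# author residue ids, ordered as extract_sequence orders them
standard_residue_ids <- function(atoms, chain_id) {
  atoms <- atoms[atoms$chain == chain_id, , drop = FALSE]
  key <- paste(atoms$res_seq, atoms$i_code)
  first <- atoms[!duplicated(key), , drop = FALSE]
  first <- first[order(first$res_seq, first$i_code), , drop = FALSE]
  first <- first[!first$het & first$res_name %in% names(AA3TO1), , drop = FALSE]
  first[, c("res_seq", "i_code", "res_name")]
}

default_protein_chain <- function(atoms) {
  for (ch in sort(unique(atoms$chain))) {
    ok <- tryCatch(nrow(standard_residue_ids(atoms, ch)) > 0,
                   error = function(e) FALSE)
    if (isTRUE(ok)) return(ch)
  }
  stop("no chain with standard amino-acid residues", call. = FALSE)
}

#' Active-site superposition of a query enzyme onto a template complex
#'
#' Anchors are the C-alpha atoms of alignment-matched residues whose template
#' C-alpha lies within `shell_radius` of any ligand atom; a Kabsch fit on
#' those pairs returns the transform taking the query into the template frame.
#' This reproduces, as reusable code, the viewer-based structure alignment a
#' practitioner would perform to seat a query enzyme on a solved complex.
#'
#' @param query,template [structure_model()]s (template carries the ligand).
#' @param ligand Ligand atoms in the template frame: an atom table or a
#'   `list(chain=, res_seq=)` selector.
#' @param shell_radius Anchor shell around ligand atoms, Angstrom.
#' @param query_chain,template_chain Protein chains (default: first chain
#'   with standard residues).
#' @param map Optional precomputed [align_sequences()] result.
#' @return List with `transform` (query -> template frame), `rmsd`,
#'   `n_atoms_used`, and the anchor residue pairs.
#' @export
superpose_active_site <- function(query, template, ligand, shell_radius = 8,
                                  query_chain = NULL, template_chain = NULL,
                                  map = NULL) {
  qa <- model_frame(query); ta <- model_frame(template)
  if (is.null(query_chain)) query_chain <- default_protein_chain(qa)
  if (is.null(template_chain)) template_chain <- default_protein_chain(ta)
  lig <- resolve_ligand(ta, ligand)
  if (nrow(lig) == 0L) stop("empty ligand selection", call. = FALSE)
  if (is.null(map))
    map <- align_sequences(extract_sequence(query, query_chain),
                           extract_sequence(template, template_chain))
  qres <- standard_residue_ids(qa, query_chain)
  tres <- standard_residue_ids(ta, template_chain)

  lxyz <- coords_matrix(lig)
  P <- NULL; Q <- NULL; used <- list()
  for (k in seq_len(nrow(map$pairs))) {
    qi <- map$pairs$a_pos[k]; ti <- map$pairs$b_pos[k]
    tca <- tryCatch(atom_xyz(ta, template_chain, tres$res_seq[ti], "CA",
                             tres$i_code[ti]), error = function(e) NULL)
    if (is.null(tca)) next
    dmin <- sqrt(min(rowSums(sweep(lxyz, 2L, tca)^2)))
    if (dmin > shell_radius) next
    qca <- tryCatch(atom_xyz(qa, query_chain, qres$res_seq[qi], "CA",
                             qres$i_code[qi]), error = function(e) NULL)
    if (is.null(qca)) next
    P <- rbind(P, qca); Q <- rbind(Q, tca)
    used[[length(used) + 1L]] <- data.frame(
      query_res = qres$res_seq[qi], template_res = tres$res_seq[ti])
  }
  if (is.null(P) || nrow(P) < 3L)
    stop(sprintf(paste0("insufficient anchors: %d aligned C-alpha pair(s) ",
                        "within %.1f A of the ligand (need >= 3)"),
                 if (is.null(P)) 0L else nrow(P), shell_radius), call. = FALSE)
  fit <- kabsch_fit(P, Q)
  list(transform = fit$transform, rmsd = fit$rmsd, n_atoms_used = fit$n,
       anchors = do.call(rbind, used))
}

#' Transplant the template ligand into the query frame
#'
#' Applies the inverse of the query-to-template transform to the template's
#' ligand atoms so the ligand sits in query coordinates at the same subsites.
#'
#' @param template [structure_model()] holding the ligand.
#' @param ligand Atom table or `list(chain=, res_seq=)` selector.
#' @param transform The query-to-template [rigid_transform()] from
#'   [superpose_active_site()].
#' @return The ligand atom table with coordinates in the query frame.
#' @export
transplant_ligand <- function(template, ligand, transform) {
  ta <- model_frame(template)
  lig <- resolve_ligand(ta, ligand)
  if (nrow(lig) == 0L) stop("empty ligand selection", call. = FALSE)
  inv <- invert_transform(transform)
  set_coords(lig, apply_transform(coords_matrix(lig), inv))
}

#' Combine protein and ligand atoms into one single-frame model
#'
#' @param model A [structure_model()] (first frame is used).
#' @param ligand_atoms Atom table to append (e.g. from [transplant_ligand()]).
#' @return A single-frame [structure_model()].
#' @export
add_ligand <- function(model, ligand_atoms) {
  atoms <- rbind(model_frame(model), ligand_atoms)
  atoms$serial <- seq_len(nrow(atoms))
  structure_model(atoms, title = model$title)
}
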