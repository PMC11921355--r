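# End-to-end pipeline: query enzyme + two template complexes -> four
# catalytic distances -> specificity call.

#' Locate the catalytic His/Tyr automatically
#'
#' Nearest His side-chain nitrogen (NE2/ND1) and nearest Tyr OH to the +1
#' ring's C5, both required within `max_dist`; mirrors the conserved
#' active-site architecture of the family.
#'
#' @param model A [structure_model()] or atom table.
#' @param plus1_ring The +1 `sugar_ring`.
#' @param chain Protein chain (default: first with standard residues).
#' @param max_dist Search radius around C5, A.
#' @param his_atom His reference-atom mode passed to [catalytic_site()].
#' @return A [catalytic_site()].
#' @export
find_catalytic_site <- function(model, plus1_ring, chain = NULL, max_dist = 6,
                                his_atom = "NE2") {
  atoms <- if (inherits(model, "structure_model")) model_frame(model) else model
  if (is.null(chain)) chain <- default_protein_chain(atoms)
  c5 <- ring_atom(plus1_ring, "C5")
  nearest <- function(res_name, atom_names) {
    sel <- atoms[atoms$chain == chain & atoms$res_name == res_name &
                   atoms$atom_name %in% atom_names, , drop = FALSE]
    if (nrow(sel) == 0L) return(NULL)
    d <- sqrt(rowSums(sweep(coords_matrix(sel), 2L, c5)^2))
    if (min(d) > max_dist) return(NULL)
    sel$res_seq[which.min(d)]
  }
  his <- nearest("HIS", c("NE2", "ND1"))
  tyr <- nearest("TYR", "OH")
  if (is.null(his) || is.null(tyr))
    stop(sprintf("no catalytic %s within %.1f A of the +1 C5",
                 paste(c("His", "Tyr")[c(is.null(his), is.null(tyr))],
                       collapse = " and "), max_dist), call. = FALSE)
  catalytic_site(atoms, his, tyr, chain = chain, his_atom = his_atom)
}

#' Measure the catalytic distances of one complex
#'
#' Perceives the ligand rings, assigns subsites, places H5 on the ring at
#' `subsite`, and measures the His/Tyr distances. This is the single-complex
#' core that [run_pipeline()] applies once per template.
#'
#' @param model A single-frame [structure_model()] of the complex.
#' @param ligand `list(chain=, res_seq=)` selector or atom table; `NULL`
#'   uses all HETATM records.
#' @param his_res,tyr_res Catalytic residue numbers, or `NULL` for automatic
#'   proximity search.
#' @param chain Protein chain.
#' @param his_atom His reference-atom mode.
#' @param subsite Subsite of the measured ring (default +1).
#' @return List with `distances` (data frame), `site`, `ring` (H5 placed),
#'   `chain` (the `oligosaccharide_chain`).
#' @export
measure_complex <- function(model, ligand = NULL, his_res = NULL,
                            tyr_res = NULL, chain = NULL, his_atom = "NE2",
                            subsite = 1L) {
  atoms <- model_frame(model)
  lig <- if (is.null(ligand)) select_residues(atoms, het = TRUE)
  else resolve_ligand(atoms, ligand)
  rings <- detect_sugar_rings(lig)
  if (length(rings) == 0L) stop("no sugar ring perceived in the ligand",
                                call. = FALSE)
  och <- assign_subsites(rings)
  ring <- place_c5_proton(subsite_ring(och, subsite))
  site <- if (is.null(his_res) || is.null(tyr_res))
    find_catalytic_site(atoms, ring, chain = chain, his_atom = his_atom)
  else catalytic_site(atoms, his_res, tyr_res, chain = chain,
                      his_atom = his_atom)
  list(distances = measure_catalytic_distances(atoms, site, ring),
       site = site, ring = ring, chain = och)
}

#' Pipeline configuration
#'
#' @param query Path to the query enzyme PDB (or a [structure_model()]).
#' @param template_m,template_g Paths to (or models of) the template
#'   complexes holding the M-type and G-type trisaccharides.
#' @param ligand_m,ligand_g `list(chain=, res_seq=)` ligand selectors, or
#'   `NULL` for all HETATM residues of each template.
#' @param his_res,tyr_res Catalytic residue numbers in the query, or `NULL`
#'   for automatic proximity search.
#' @param chain Query protein chain, or `NULL` for the first protein chain.
#' @param shell_radius Anchor shell for superposition, A.
#' @param his_atom His reference atom (`"NE2"`, `"ND1"`, `"min"`).
#' @param epsilon Tie tolerance of the classification rule, A.
#' @param fine_tune Refit the transplanted ligand's +1 ring onto the
#'   template's +1 ring with a second Kabsch pass (off by default).
#' @param out_dir Directory for constructed-complex PDBs and the report, or
#'   `NULL` to skip writing.
#' @param enzyme Label used in the report.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(query, template_m, template_g, ligand_m = NULL,
                            ligand_g = NULL, his_res = NULL, tyr_res = NULL,
                            chain = NULL, shell_radius = 8, his_atom = "NE2",
                            epsilon = 0.1, fine_tune = FALSE, out_dir = NULL,
                            enzyme = "query") {
  structure(list(query = query, template_m = template_m,
                 template_g = template_g, ligand_m = ligand_m,
                 ligand_g = ligand_g, his_res = his_res, tyr_res = tyr_res,
                 chain = chain, shell_radius = shell_radius,
                 his_atom = his_atom, epsilon = epsilon,
                 fine_tune = fine_tune, out_dir = out_dir, enzyme = enzyme),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path JSON file with fields named as the [pipeline_config()]
#'   arguments (the config dialect shared with the command-line interface).
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0L)
    stop("unknown config field(s): ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(pipeline_config, raw)
}

as_model <- function(x) {
  if (inherits(x, "structure_model")) x else parse_structure(x, is_path = TRUE)
}

# optional second Kabsch refit of the transplanted ligand: +1-ring atoms of
# the transplant against the corresponding template +1-ring atoms mapped to
# the query frame (corrects small anchor-shell mismatch)
fine_tune_ligand <- function(lig_q, template, ligand, transform) {
  ta <- model_frame(template)
  lig_t <- resolve_ligand(ta, ligand)
  rings_t <- detect_sugar_rings(lig_t)
  oct_ <- suppressWarnings(assign_subsites(rings_t))
  ring_t <- subsite_ring(oct_, 1L)
  rings_q <- detect_sugar_rings(lig_q)
  ocq <- suppressWarnings(assign_subsites(rings_q))
  ring_q <- subsite_ring(ocq, 1L)
  common <- intersect(rownames(ring_q$coords), rownames(ring_t$coords))
  target <- apply_transform(ring_t$coords[common, , drop = FALSE],
                            invert_transform(transform))
  fit <- kabsch_fit(ring_q$coords[common, , drop = FALSE], target)
  set_coords(lig_q, apply_transform(coords_matrix(lig_q), fit$transform))
}

run_one_template <- function(query, template, ligand, config) {
  lig <- if (is.null(ligand)) select_residues(model_frame(template), het = TRUE)
  else resolve_ligand(model_frame(template), ligand)
  sup <- superpose_active_site(query, template, lig,
                               shell_radius = config$shell_radius,
                               query_chain = config$chain)
  lig_q <- transplant_ligand(template, lig, sup$transform)
  lig_q$serial <- max(model_frame(query)$serial) + seq_len(nrow(lig_q))
  if (isTRUE(config$fine_tune))
    lig_q <- fine_tune_ligand(lig_q, template, lig, sup$transform)
  complex <- add_ligand(query, lig_q)
  meas <- measure_complex(complex, ligand = lig_q, his_res = config$his_res,
                          tyr_res = config$tyr_res, chain = config$chain,
                          his_atom = config$his_atom)
  c(meas, list(superposition = sup, complex = complex))
}

#' Run the full specificity pipeline for one query enzyme
#'
#' For each template (M-type and G-type complex): superpose the query onto
#' the template active site, transplant the trisaccharide into the query
#' frame, perceive rings and subsites, place the C5 proton on the +1 sugar,
#' and measure the His/Tyr distances; then classify specificity from the
#' four distances. Deterministic: identical inputs and configuration give
#' identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result`: `call` (the
#'   [classify_specificity()] result), `report` (one-row
#'   `specificity_report`), `m`, `g` (per-template stage outputs).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  query <- as_model(config$query)
  stage <- function(tag, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", tag, conditionMessage(e)), call. = FALSE))
  }
  tm <- stage("template-m", as_model(config$template_m))
  tg <- stage("template-g", as_model(config$template_g))
  resm <- stage("measure-m", run_one_template(query, tm, config$ligand_m, config))
  resg <- stage("measure-g", run_one_template(query, tg, config$ligand_g, config))
  dm <- resm$distances; dg <- resg$distances
  call <- classify_specificity(
    d_tyr_m = dm$distance[dm$residue == "TYR"],
    d_his_g = dg$distance[dg$residue == "HIS"],
    d_his_m = dm$distance[dm$residue == "HIS"],
    d_tyr_g = dg$distance[dg$residue == "TYR"],
    epsilon = config$epsilon)
  report <- build_specificity_report(
    call, enzyme = config$enzyme,
    base_res = sprintf("H%d", resm$site$his_res),
    acid_res = sprintf("Y%d", resm$site$tyr_res))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_structure(resm$complex,
                    file.path(config$out_dir,
                              paste0(config$enzyme, "_complex_M.pdb")))
    write_structure(resg$complex,
                    file.path(config$out_dir,
                              paste0(config$enzyme, "_complex_G.pdb")))
    write_specificity_report(report,
                             file.path(config$out_dir,
                                       paste0(config$enzyme, "_report.tsv")))
  }
  structure(list(call = call, report = report, m = resm, g = resg),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}
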