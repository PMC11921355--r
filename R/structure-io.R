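#' @importFrom utils head tail
NULL

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLU = "E",
  GLN = "Q", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V")

# ExPASy-style average residue masses (Da); water closes the chain.
AA_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.0153

empty_atom_table <- function() {
  data.frame(serial = integer(), atom_name = character(), alt_loc = character(),
             res_name = character(), chain = character(), res_seq = integer(),
             i_code = character(), x = numeric(), y = numeric(), z = numeric(),
             occ = numeric(), b = numeric(), element = character(),
             het = logical(), stringsAsFactors = FALSE)
}

#' Atomic structure model
#'
#' A parsed structure: one or more frames (PDB `MODEL` blocks), each an atom
#' table with author numbering preserved. This is the container consumed by
#' every downstream stage (superposition, ring perception, distance analysis).
#'
#' @param frames A list of atom tables (data frames with columns `serial`,
#'   `atom_name`, `alt_loc`, `res_name`, `chain`, `res_seq`, `i_code`, `x`,
#'   `y`, `z`, `occ`, `b`, `element`, `het`).
#' @param title Free-text metadata.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(frames, title = "") {
  if (is.data.frame(frames)) frames <- list(frames)
  stopifnot(length(frames) >= 1L, all(vapply(frames, is.data.frame, TRUE)))
  structure(list(frames = frames, title = title), class = "structure_model")
}

#' @rdname structure_model
#' @param model A `structure_model`.
#' @param i Frame index.
#' @export
model_frame <- function(model, i = 1L) {
  stopifnot(inherits(model, "structure_model"))
  if (i < 1L || i > length(model$frames)) stop("no such frame: ", i, call. = FALSE)
  model$frames[[i]]
}

#' @rdname structure_model
#' @export
n_frames <- function(model) length(model$frames)

#' @export
print.structure_model <- function(x, ...) {
  a <- x$frames[[1L]]
  cat(sprintf("structure_model: %d frame(s), %d atoms, %d residues, chains: %s\n",
              length(x$frames), nrow(a),
              length(unique(residue_key(a))),
              paste(sort(unique(a$chain)), collapse = " ")))
  if (nzchar(x$title)) cat("  title:", x$title, "\n")
  invisible(x)
}

residue_key <- function(atoms) {
  paste(atoms$chain, atoms$res_seq, atoms$i_code, sep = "|")
}

guess_element <- function(atom_name) {
  nm <- gsub("[0-9']", "", atom_name)
  if (!nzchar(nm)) return("")
  toupper(substr(nm, 1L, 1L))
}

# Alt-loc policy: within each (residue, atom name), keep the conformer with
# the highest occupancy; ties broken in favour of alt-loc 'A', then first seen.
resolve_altlocs <- function(atoms) {
  if (!any(nzchar(atoms$alt_loc))) return(atoms)
  grp <- paste(residue_key(atoms), atoms$atom_name, sep = "@")
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), grp), function(idx) {
    if (length(idx) == 1L) return(idx)
    occ <- atoms$occ[idx]
    best <- idx[occ == max(occ)]
    if (length(best) > 1L) {
      is_a <- atoms$alt_loc[best] == "A"
      if (any(is_a)) best <- best[is_a]
    }
    best[1L]
  }), use.names = FALSE)
  out <- atoms[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Parse a PDB-format structure
#'
#' Reads `ATOM`/`HETATM` records with author numbering and insertion codes
#' preserved verbatim; `MODEL`/`ENDMDL` blocks become frames (trajectory
#' snapshots). Alternate locations are collapsed to the highest-occupancy
#' conformer (ties: 'A', then first seen). Hydrogens present in the input are
#' retained, but the +1-sugar C5 proton is always recomputed downstream.
#'
#' @param text PDB content: a single string, a character vector of lines, or
#'   a file path (when `is_path = TRUE` or the string names an existing file
#'   without newline characters).
#' @param is_path Force interpretation of `text` as a file path.
#' @return A [structure_model()].
#' @export
parse_structure <- function(text, is_path = FALSE) {
  if (length(text) == 1L && (is_path || (!grepl("\n", text) && file.exists(text))))
    text <- readLines(text, warn = FALSE)
  if (length(text) == 1L && grepl("\n", text))
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]

  rec <- substr(text, 1L, 6L)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  title <- paste(trimws(substr(text[rec == "TITLE "], 11L, 80L)), collapse = " ")

  # frame id per line: MODEL opens a new block; atoms outside any MODEL
  # block belong to frame 1
  frame_id <- cumsum(rec == "MODEL ")
  frame_id[frame_id == 0L] <- 1L

  num_field <- function(lines, from, to, linenos, what, default = NA_real_) {
    s <- trimws(substr(lines, from, to))
    v <- suppressWarnings(as.numeric(s))
    blank <- !nzchar(s)
    if (!is.na(default)) v[blank] <- default
    bad <- which((is.na(v) | !is.finite(v)) & (!blank | is.na(default)))
    if (length(bad) > 0L)
      stop(sprintf("malformed %s field at line %d: '%s'", what,
                   linenos[bad[1L]], s[bad[1L]]), call. = FALSE)
    v
  }

  parse_block <- function(idx) {
    lines <- formatC(text[idx], width = 80L, flag = "-")
    nm <- trimws(substr(lines, 13L, 16L))
    el <- trimws(substr(lines, 77L, 78L))
    noel <- !nzchar(el)
    if (any(noel)) el[noel] <- vapply(nm[noel], guess_element, character(1L))
    data.frame(
      serial = as.integer(num_field(lines, 7L, 11L, idx, "serial")),
      atom_name = nm,
      alt_loc = trimws(substr(lines, 17L, 17L)),
      res_name = trimws(substr(lines, 18L, 20L)),
      chain = substr(lines, 22L, 22L),
      res_seq = as.integer(num_field(lines, 23L, 26L, idx, "residue number")),
      i_code = trimws(substr(lines, 27L, 27L)),
      x = num_field(lines, 31L, 38L, idx, "x coordinate"),
      y = num_field(lines, 39L, 46L, idx, "y coordinate"),
      z = num_field(lines, 47L, 54L, idx, "z coordinate"),
      occ = num_field(lines, 55L, 60L, idx, "occupancy", default = 1),
      b = num_field(lines, 61L, 66L, idx, "B-factor", default = 0),
      element = el,
      het = substr(lines, 1L, 6L) == "HETATM",
      stringsAsFactors = FALSE)
  }

  atom_idx <- which(is_atom)
  frames <- lapply(split(atom_idx, frame_id[atom_idx]), parse_block)
  names(frames) <- NULL
  if (length(frames) == 0L)
    stop("no ATOM/HETATM records found (empty structure)", call. = FALSE)
  frames <- lapply(frames, function(a) {
    rownames(a) <- NULL
    resolve_altlocs(a)
  })
  structure_model(frames, title = title)
}

format_pdb_atom_name <- function(name, element) {
  # Standard PDB alignment: 1-2 character elements right-justified in
  # columns 13-14; short organic atom names get a leading space.
  if (nchar(name) >= 4L) return(substr(name, 1L, 4L))
  if (nchar(element) == 2L) formatC(name, width = -4L)
  else formatC(paste0(" ", name), width = -4L)
}

#' Write a structure as PDB text
#'
#' Emits fixed-width `ATOM`/`HETATM` records (coordinates to 3 decimals),
#' with `MODEL`/`ENDMDL` wrappers for multi-frame models and a terminal
#' `END`. Round-trips through [parse_structure()].
#'
#' @param model A [structure_model()].
#' @param path Optional file path; when given, the text is also written there.
#' @return The PDB text as a single string (invisibly when `path` is given).
#' @export
write_structure <- function(model, path = NULL) {
  stopifnot(inherits(model, "structure_model"))
  fmt_frame <- function(atoms) {
    if (any(abs(c(atoms$x, atoms$y, atoms$z)) >= 10000))
      stop("coordinate magnitude >= 10000 A cannot be formatted in PDB fields",
           call. = FALSE)
    vapply(seq_len(nrow(atoms)), function(i) {
      a <- atoms[i, ]
      sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
              if (a$het) "HETATM" else "ATOM", a$serial %% 100000L,
              format_pdb_atom_name(a$atom_name, a$element),
              a$alt_loc, a$res_name, a$chain, a$res_seq %% 10000L, a$i_code,
              a$x, a$y, a$z, a$occ, a$b, a$element)
    }, character(1L))
  }
  lines <- character()
  if (nzchar(model$title)) lines <- sprintf("TITLE     %s", model$title)
  multi <- length(model$frames) > 1L
  for (k in seq_along(model$frames)) {
    if (multi) lines <- c(lines, sprintf("MODEL %8d", k))
    lines <- c(lines, fmt_frame(model$frames[[k]]))
    if (multi) lines <- c(lines, "ENDMDL")
  }
  lines <- c(lines, "END")
  out <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(out))
  }
  out
}

#' Select residues from a frame
#'
#' @param atoms An atom table (one frame of a [structure_model()]).
#' @param chain Chain identifier(s), or `NULL` for any.
#' @param res_seq Author residue number(s), or `NULL` for any.
#' @param het `NULL` for any, otherwise select HETATM (`TRUE`) or ATOM rows.
#' @return The matching subset of the atom table.
#' @export
select_residues <- function(atoms, chain = NULL, res_seq = NULL, het = NULL) {
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(chain)) keep <- keep & atoms$chain %in% chain
  if (!is.null(res_seq)) keep <- keep & atoms$res_seq %in% res_seq
  if (!is.null(het)) keep <- keep & atoms$het == het
  out <- atoms[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

atom_xyz <- function(atoms, chain, res_seq, atom_name, i_code = "") {
  hit <- which(atoms$chain == chain & atoms$res_seq == res_seq &
                 atoms$i_code == i_code & atoms$atom_name == atom_name)
  if (length(hit) == 0L)
    stop(sprintf("atom %s not found in residue %s%d%s", atom_name, chain,
                 res_seq, i_code), call. = FALSE)
  c(atoms$x[hit[1L]], atoms$y[hit[1L]], atoms$z[hit[1L]])
}

coords_matrix <- function(atoms) {
  m <- cbind(atoms$x, atoms$y, atoms$z)
  colnames(m) <- c("x", "y", "z")
  m
}

set_coords <- function(atoms, m) {
  atoms$x <- m[, 1L]; atoms$y <- m[, 2L]; atoms$z <- m[, 3L]
  atoms
}

#' Protein sequence
#'
#' @param residues One-letter amino-acid string (standard 20 codes only).
#' @param id Sequence identifier.
#' @return An object of class `protein_sequence`.
#' @export
protein_sequence <- function(residues, id = "") {
  residues <- toupper(as.character(residues))
  if (!nzchar(residues)) stop("empty protein sequence", call. = FALSE)
  bad <- setdiff(strsplit(residues, "")[[1L]], names(AA_RESIDUE_MASS))
  if (length(bad) > 0L)
    stop("non-standard amino-acid code(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  structure(list(residues = residues, id = id), class = "protein_sequence")
}

#' @export
as.character.protein_sequence <- function(x, ...) x$residues

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("protein_sequence %s (%d aa)\n", x$id, nchar(x$residues)))
  invisible(x)
}

#' Extract a chain's amino-acid sequence
#'
#' One-letter sequence ordered by author numbering (`res_seq`, then insertion
#' code). Hetero and non-standard residues are skipped, since the sequence is
#' only used for alignment-guided superposition over standard residues.
#'
#' @param model A [structure_model()].
#' @param chain_id Chain identifier.
#' @param frame Frame index.
#' @return A [protein_sequence()].
#' @export
extract_sequence <- function(model, chain_id, frame = 1L) {
  atoms <- model_frame(model, frame)
  atoms <- atoms[atoms$chain == chain_id, , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no such chain: ", chain_id, call. = FALSE)
  key <- paste(atoms$res_seq, atoms$i_code)
  first <- atoms[!duplicated(key), , drop = FALSE]
  first <- first[order(first$res_seq, first$i_code), , drop = FALSE]
  keep <- !first$het & first$res_name %in% names(AA3TO1)
  if (!any(keep))
    stop("chain ", chain_id, " has no standard amino-acid residues", call. = FALSE)
  protein_sequence(paste(AA3TO1[first$res_name[keep]], collapse = ""),
                   id = chain_id)
}

#' Theoretical protein molecular weight
#'
#' Average-isotopic molecular weight: the sum of conventional average residue
#' masses plus one water (18.0153 Da) for the chain termini. This matches the
#' convention of common web calculators and yields e.g. 75.07 Da for "G".
#'
#' @param seq A [protein_sequence()] or a plain one-letter string.
#' @return Mass in Dalton.
#' @export
protein_mw <- function(seq) {
  if (inherits(seq, "protein_sequence")) seq <- seq$residues
  seq <- toupper(as.character(seq))
  if (length(seq) != 1L || !nzchar(seq))
    stop("empty protein sequence", call. = FALSE)
  aa <- strsplit(seq, "")[[1L]]
  bad <- setdiff(aa, names(AA_RESIDUE_MASS))
  if (length(bad) > 0L)
    stop("non-standard amino-acid code(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  sum(AA_RESIDUE_MASS[aa]) + WATER_MASS
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file path.
#' @return A list of [protein_sequence()] objects, named by record id.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  out <- lapply(seq_along(set), function(i)
    protein_sequence(as.character(set[[i]]), id = names(set)[i]))
  names(out) <- names(set)
  out
}
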