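#!/usr/bin/env Rscript

# Optional helper (requires network access; nothing in the package core or
# test suite depends on it): downloads the two template complexes used for
# ligand transplantation and the flagship enzyme's deposited sequence.
#
#   Rscript scripts/fetch_inputs.R [outdir]
#
# Inputs fetched:
#   3AFL.pdb — exolytic PL15 lyase with the bound Delta-G-G trisaccharide
#   4OJZ.pdb — PL17 lyase complex with the M-type unsaturated trisaccharide
#   WP_023403303.1.fasta — the studied enzyme's protein sequence (for
#                          protein_mw and alignment-guided superposition)

outdir <- commandArgs(trailingOnly = TRUE)
outdir <- if (length(outdir) >= 1) outdir[[1]] else "inputs"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

fetch <- function(url, dest) {
  message("fetching ", url)
  utils::download.file(url, file.path(outdir, dest), quiet = TRUE)
}

fetch("https://files.rcsb.org/download/3AFL.pdb", "3AFL.pdb")
fetch("https://files.rcsb.org/download/4OJZ.pdb", "4OJZ.pdb")
fetch(paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi?",
             "db=protein&id=WP_023403303.1&rettype=fasta&retmode=text"),
      "WP_023403303.1.fasta")
message("done; files in ", normalizePath(outdir))
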