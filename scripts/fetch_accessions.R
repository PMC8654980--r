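#!/usr/bin/env Rscript
# Optional: fetch the deposited huntingtin-HAP40 coordinate files used by the
# accession-based validation tests (network required).  Writes Calpha-only
# PDB files under tests/testthat/accessions/.
#
# The matching cross-link tables (XlinkX output for the Q23 / Q54 / delta-exon-1
# samples, filtered at score > 40) are distributed as a spreadsheet in the
# publication supplement and cannot be fetched programmatically: export each
# sample to tests/testthat/accessions/crosslinks_<sample>.csv with columns
# chain_a,res_a,chain_b,res_b,score (sample names: q23, q54, dexon1).

suppressPackageStartupMessages(library(flexcore))

dest <- file.path("tests", "testthat", "accessions")
dir.create(dest, showWarnings = FALSE, recursive = TRUE)

fetch_ca <- function(id) {
  url <- sprintf("https://files.rcsb.org/download/%s.cif", toupper(id))
  tmp <- tempfile(fileext = ".cif")
  message("fetching ", url)
  utils::download.file(url, tmp, quiet = TRUE)
  st <- read_structure(tmp, format = "mmcif")
  a <- st$atoms[st$atoms$present, , drop = FALSE]
  out <- file.path(dest, sprintf("%s_ca.pdb", tolower(id)))
  write_ca_pdb(as.matrix(a[, c("x", "y", "z")]),
               a[, c("chain", "resno", "resname")], out)
  message("wrote ", out, " (", nrow(a), " residues)")
}

fetch_ca("6X9O")
fetch_ca("6EZ8")
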