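#' Read a protein structure (PDB or minimal mmCIF)
#'
#' Reads the first model only, keeps ATOM records with blank or 'A'
#' altloc, orders residues by (residue number, insertion code) and stores
#' the B-factor column as per-residue pLDDT when `is_model = TRUE`
#' (AlphaFold-style models keep confidence there; for experimental
#' structures pass `is_model = FALSE` and `plddt` is left absent).
#'
#' @param path PDB (`.pdb`, `.ent`) or mmCIF (`.cif`) file. mmCIF support
#'   is minimal: only the `atom_site` loop is interpreted; other blocks
#'   are ignored.
#' @param chain Chain identifier; default: the first chain in the file.
#' @param id Identifier for the returned structure (default: file stem).
#' @param is_model Interpret B-factors as pLDDT (default TRUE).
#' @return A [protein_structure()] with CA (mandatory) and N/C where present.
#' @export
read_structure <- function(path, chain = NULL, id = NULL, is_model = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  is_cif <- grepl("\\.cif$", path, ignore.case = TRUE)
  pdb <- if (is_cif) suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
         else bio3d::read.pdb(path, verbose = FALSE, multi = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  chains <- unique(at$chain)
  if (is.null(chain)) {
    chain <- chains[1L]
  } else if (!chain %in% chains) {
    stop("chain '", chain, "' not found; available chains: ",
         paste(chains, collapse = ", "))
  }
  at <- at[at$chain == chain, , drop = FALSE]
  alt <- at$alt
  alt[is.na(alt)] <- ""
  at <- at[alt %in% c("", "A"), , drop = FALSE]
  at$insert[is.na(at$insert)] <- ""
  ca <- at[at$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) stop("no CA atoms in chain ", chain, " of ", path)
  ord <- order(ca$resno, ca$insert)
  ca <- ca[ord, , drop = FALSE]
  key <- paste(ca$resno, ca$insert)
  ca <- ca[!duplicated(key), , drop = FALSE]
  key <- paste(ca$resno, ca$insert)

  pick <- function(elety) {
    sub <- at[at$elety == elety, , drop = FALSE]
    m <- matrix(NA_real_, nrow(ca), 3L)
    if (nrow(sub) > 0L) {
      idx <- match(paste(sub$resno, sub$insert), key)
      keep <- !is.na(idx) & !duplicated(idx)
      m[idx[keep], ] <- as.matrix(sub[keep, c("x", "y", "z")])
    }
    if (all(is.na(m))) NULL else m
  }
  aa <- bio3d::aa321(ca$resid)
  aa[is.na(aa) | aa == ""] <- "X"
  if (is.null(id)) id <- sub("\\.[^.]+$", "", basename(path))
  protein_structure(
    id = id,
    ca = as.matrix(ca[, c("x", "y", "z")]),
    aa = aa,
    resno = ca$resno,
    n_atoms = pick("N"),
    c_atoms = pick("C"),
    plddt = if (is_model) as.numeric(ca$b) else NULL
  )
}

.pdb_atom_line <- function(serial, elety, resid, chain, resno, xyz, b) {
  # columns per the PDB v3 fixed-width ATOM record
  name <- if (nchar(elety) < 4L) sprintf(" %-3s", elety) else elety
  sprintf("ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, resid, chain, resno, xyz[1], xyz[2], xyz[3],
          1.00, b, substr(trimws(elety), 1L, 1L))
}

#' Write a ProteinStructure as a minimal PDB file
#'
#' Emits ATOM records for N, CA and C (where present), chain "A", with
#' pLDDT in the B-factor column (0 when absent).
#'
#' @param s A `ProteinStructure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(s, path) {
  stopifnot(inherits(s, "ProteinStructure"))
  aa3 <- bio3d::aa123(s$aa)
  aa3[is.na(aa3)] <- "UNK"
  b <- if (is.null(s$plddt)) rep(0, length(s$resno)) else s$plddt
  lines <- character(0)
  serial <- 0L
  for (i in seq_along(s$resno)) {
    for (ety in c("N", "CA", "C")) {
      xyz <- switch(ety, N = s$n[i, ], CA = s$ca[i, ], C = s$c[i, ])
      if (is.null(xyz) || anyNA(xyz)) next
      serial <- serial + 1L
      lines <- c(lines, .pdb_atom_line(serial, ety, aa3[i], "A",
                                       s$resno[i], xyz, b[i]))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a ProteinStructure as a minimal mmCIF file (atom_site loop only)
#'
#' @inheritParams write_structure_pdb
#' @return `path`, invisibly.
#' @export
write_structure_cif <- function(s, path) {
  stopifnot(inherits(s, "ProteinStructure"))
  aa3 <- bio3d::aa123(s$aa)
  aa3[is.na(aa3)] <- "UNK"
  b <- if (is.null(s$plddt)) rep(0, length(s$resno)) else s$plddt
  hdr <- c(
    paste0("data_", gsub("[^A-Za-z0-9_]", "_", s$id)),
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num"
  )
  rows <- character(0)
  serial <- 0L
  for (i in seq_along(s$resno)) {
    for (ety in c("N", "CA", "C")) {
      xyz <- switch(ety, N = s$n[i, ], CA = s$ca[i, ], C = s$c[i, ])
      if (is.null(xyz) || anyNA(xyz)) next
      serial <- serial + 1L
      rows <- c(rows, sprintf(
        "ATOM %d %s %s . %s A 1 %d ? %.3f %.3f %.3f 1.00 %.2f %d %s A %s 1",
        serial, substr(ety, 1L, 1L), ety, aa3[i], s$resno[i],
        xyz[1], xyz[2], xyz[3], b[i], s$resno[i], aa3[i], ety))
    }
  }
  writeLines(c(hdr, rows, "#"), path)
  invisible(path)
}
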