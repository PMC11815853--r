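# Heterogeneous protein-ligand complex representation: residues, ligand
# atoms, metal ions, and residue-atom minimum-distance pair enumeration.

# Ligand element vocabulary accepted by the scoring heads.
SCORING_ELEMENTS <- c("H", "B", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I")

# Biologically common cations recognised as metal ions by default.
DEFAULT_METALS <- c("Zn", "Mg", "Ca", "Mn", "Fe", "Ni", "Cu", "Co", "K", "Na")

AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

WATER_RESIDUES <- c("HOH", "WAT", "DOD", "H2O")

#' Normalize a chemical element symbol
#'
#' Upper-cases the first letter and lower-cases the rest, so SDF/PDB
#' spellings such as `"CL"` or `"zn"` become `"Cl"` and `"Zn"`.
#' @param x character vector of element symbols
#' @return character vector of normalized symbols
#' @export
normalize_element <- function(x) {
  x <- trimws(x)
  paste0(toupper(substr(x, 1L, 1L)), tolower(substr(x, 2L, nchar(x))))
}

#' Construct a residue
#'
#' @param chain_id chain identifier
#' @param seq_index author residue number (metadata only; internal indexing
#'   is positional)
#' @param aa_code one-letter amino-acid code; non-standard residues use "X"
#' @param heavy_atom_coords numeric matrix (n x 3) of heavy-atom coordinates
#'   in Angstrom
#' @return an object of class `nmdn_residue`
#' @export
nmdn_residue <- function(chain_id, seq_index, aa_code, heavy_atom_coords) {
  heavy_atom_coords <- matrix(as.numeric(heavy_atom_coords), ncol = 3L)
  if (nrow(heavy_atom_coords) == 0L)
    stop("residue must have at least one heavy atom")
  if (!all(is.finite(heavy_atom_coords)))
    stop("residue coordinates must be finite")
  if (!(aa_code %in% c(unname(AA_THREE_TO_ONE), "X")))
    stop("aa_code must be a standard one-letter code or 'X', got: ", aa_code)
  structure(
    list(chain_id = as.character(chain_id), seq_index = as.integer(seq_index),
         aa_code = aa_code, heavy_atom_coords = heavy_atom_coords),
    class = "nmdn_residue"
  )
}

#' Construct a protein-ligand complex
#'
#' The heterogeneous representation of one pose: an ordered residue list,
#' ligand atoms (elements + coordinates), and optional metal ions.
#'
#' @param residues list of [nmdn_residue()] objects
#' @param lig_elements character vector of ligand element symbols
#' @param lig_coords numeric matrix (n_atoms x 3), Angstrom
#' @param metal_elements character vector of metal element symbols (may be
#'   empty)
#' @param metal_coords numeric matrix (n_metals x 3)
#' @param pose_id identifier, unique within a batch
#' @param lig_bonds optional integer matrix (n_bonds x 3): atom1, atom2,
#'   bond order; used by symmetry-aware RMSD
#' @return an object of class `nmdn_complex`
#' @export
nmdn_complex <- function(residues, lig_elements, lig_coords,
                         metal_elements = character(0),
                         metal_coords = matrix(numeric(0), 0L, 3L),
                         pose_id = "pose", lig_bonds = NULL) {
  if (length(residues) < 1L) stop("complex needs at least one residue")
  if (length(lig_elements) < 1L) stop("complex needs at least one ligand atom")
  lig_coords <- matrix(as.numeric(lig_coords), ncol = 3L)
  metal_coords <- matrix(as.numeric(metal_coords), ncol = 3L)
  stopifnot(nrow(lig_coords) == length(lig_elements),
            nrow(metal_coords) == length(metal_elements))
  if (!all(is.finite(lig_coords))) stop("ligand coordinates must be finite")
  lig_elements <- normalize_element(lig_elements)
  bad <- setdiff(unique(lig_elements), SCORING_ELEMENTS)
  if (length(bad) > 0L)
    stop("unsupported ligand element(s) for scoring: ", paste(bad, collapse = ", "))
  structure(
    list(residues = residues,
         lig_elements = lig_elements, lig_coords = lig_coords,
         metal_elements = normalize_element(metal_elements),
         metal_coords = metal_coords,
         pose_id = as.character(pose_id), lig_bonds = lig_bonds),
    class = "nmdn_complex"
  )
}

#' @export
print.nmdn_complex <- function(x, ...) {
  cat(sprintf("<nmdn_complex '%s': %d residues, %d ligand atoms, %d metal ions>\n",
              x$pose_id, length(x$residues), length(x$lig_elements),
              length(x$metal_elements)))
  invisible(x)
}

element_from_pdb_row <- function(elesy, elety) {
  e <- trimws(elesy)
  if (nzchar(e)) return(normalize_element(e))
  # fall back to the atom name with digits stripped
  nm <- gsub("[0-9']", "", trimws(elety))
  if (nchar(nm) >= 2L && normalize_element(nm) %in% c(DEFAULT_METALS, "Cl", "Br"))
    return(normalize_element(nm))
  normalize_element(substr(nm, 1L, 1L))
}

#' Load a protein (and its metal ions) from a PDB file
#'
#' Parses standard ATOM/HETATM records. Alternate locations are resolved to
#' the highest-occupancy copy of each atom; waters and non-metal
#' heteroatoms are dropped; single-atom HETATM records whose element is in
#' `metal_list` become metal ions. Only heavy atoms (non-hydrogen) are kept
#' for residues, since crystal structures usually lack hydrogens.
#'
#' @param path PDB file path
#' @param metal_list character vector of element symbols recognised as
#'   metal ions
#' @return list with `residues` (list of [nmdn_residue()]),
#'   `metal_elements`, `metal_coords`
#' @export
load_protein <- function(path, metal_list = DEFAULT_METALS) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, verbose = FALSE,
                                                   rm.alt = FALSE)),
                  error = function(e) stop("PDB parse error for '", path, "': ",
                                           conditionMessage(e)))
  at <- pdb$atom
  metal_list <- normalize_element(metal_list)

  # resolve altLoc: keep the highest-occupancy copy per atom site,
  # preserving file order
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "|")
  ord <- order(match(key, unique(key)), -occ)
  rows_keep <- sort(ord[!duplicated(key[ord])])
  at <- at[rows_keep, , drop = FALSE]

  elem <- vapply(seq_len(nrow(at)),
                 function(i) element_from_pdb_row(at$elesy[i], at$elety[i]),
                 character(1))

  is_atom <- at$type == "ATOM"
  is_het <- at$type == "HETATM"
  is_water <- toupper(trimws(at$resid)) %in% WATER_RESIDUES

  # residues: ATOM records plus HETATM amino acids (e.g. MSE), heavy atoms only
  is_aa_het <- is_het & toupper(trimws(at$resid)) %in% names(AA_THREE_TO_ONE)
  res_rows <- (is_atom | is_aa_het) & !is_water & !(elem %in% c("H", "D"))

  ra <- at[res_rows, , drop = FALSE]
  if (nrow(ra) == 0L) stop("empty protein: no standard residues found in ", path)
  rkey <- paste(ra$chain, ra$resno, ra$insert, sep = "|")
  # preserve file order of residues
  ukeys <- unique(rkey)
  residues <- vector("list", length(ukeys))
  for (ii in seq_along(ukeys)) {
    rows <- which(rkey == ukeys[ii])
    resid3 <- toupper(trimws(ra$resid[rows[1L]]))
    aa1 <- if (resid3 %in% names(AA_THREE_TO_ONE)) AA_THREE_TO_ONE[[resid3]] else "X"
    residues[[ii]] <- nmdn_residue(
      chain_id = ra$chain[rows[1L]], seq_index = ra$resno[rows[1L]],
      aa_code = aa1,
      heavy_atom_coords = cbind(ra$x[rows], ra$y[rows], ra$z[rows])
    )
  }

  # metals: single-atom HETATM residues with a recognised element
  met_rows <- which(is_het & !is_water & elem %in% metal_list)
  metal_elements <- character(0)
  metal_coords <- matrix(numeric(0), 0L, 3L)
  if (length(met_rows) > 0L) {
    mkey <- paste(at$chain[met_rows], at$resno[met_rows], at$insert[met_rows],
                  sep = "|")
    single <- met_rows[table(mkey)[mkey] == 1L]
    metal_elements <- elem[single]
    metal_coords <- cbind(at$x[single], at$y[single], at$z[single])
  }

  list(residues = residues, metal_elements = metal_elements,
       metal_coords = metal_coords)
}

parse_v3000_record <- function(lines) {
  ai <- grep("M  V30 BEGIN ATOM", lines, fixed = TRUE)
  ae <- grep("M  V30 END ATOM", lines, fixed = TRUE)
  if (length(ai) != 1L || length(ae) != 1L) stop("malformed V3000 atom block")
  atoms <- lines[(ai + 1L):(ae - 1L)]
  toks <- strsplit(trimws(sub("^M  V30 ", "", atoms)), "\\s+")
  elements <- vapply(toks, function(t) t[2L], character(1))
  coords <- t(vapply(toks, function(t) as.numeric(t[3:5]), numeric(3)))
  bi <- grep("M  V30 BEGIN BOND", lines, fixed = TRUE)
  be <- grep("M  V30 END BOND", lines, fixed = TRUE)
  bonds <- NULL
  if (length(bi) == 1L && length(be) == 1L && be > bi + 1L) {
    btoks <- strsplit(trimws(sub("^M  V30 ", "", lines[(bi + 1L):(be - 1L)])), "\\s+")
    bonds <- t(vapply(btoks, function(t) as.integer(t[c(3L, 4L, 2L)]), integer(3)))
    colnames(bonds) <- c("atom1", "atom2", "order")
  }
  list(elements = elements, coords = coords, bonds = bonds,
       title = trimws(lines[1L]))
}

#' Load ligand poses from a multi-record SDF file
#'
#' Each SDF record becomes one pose (elements, 3D coordinates, bonds);
#' element symbols are normalized (`"CL"` to `"Cl"`). Records with elements
#' outside the scoring vocabulary (H, B, C, N, O, F, P, S, Cl, Br, I) are
#' rejected with a diagnostic and skipped, mirroring the exclusion of
#' metal-containing ligands from training data. Records without 3D
#' coordinates raise an error.
#'
#' @param path SDF file (V2000 or V3000 records)
#' @return list of poses; each pose is a list with `elements`, `coords`,
#'   `bonds`, `title`. Rejected records are reported via the `rejected`
#'   attribute (data frame: record index, offending elements).
#' @export
load_ligand_poses <- function(path) {
  if (!file.exists(path)) stop("cannot read SDF file: ", path)
  txt <- readLines(path, warn = FALSE)
  # split into records at $$$$
  ends <- grep("^\\$\\$\\$\\$", txt)
  if (length(ends) == 0L) ends <- length(txt)
  starts <- c(1L, head(ends, -1L) + 1L)
  raw_records <- Map(function(s, e) txt[s:e], starts, ends)
  raw_records <- Filter(function(r) any(nzchar(trimws(r))), raw_records)

  parse_one <- function(lines, irec) {
    if (any(grepl("V3000", lines[1:min(4L, length(lines))]))) {
      return(parse_v3000_record(lines))
    }
    # V2000: counts line is line 4
    if (length(lines) < 4L) stop("SDF record ", irec, " is truncated")
    counts <- lines[4L]
    natoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
    nbonds <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
    if (is.na(natoms) || natoms < 1L)
      stop("SDF record ", irec, " has an unreadable counts line")
    ablock <- lines[5:(4L + natoms)]
    coords <- t(vapply(ablock, function(l) {
      as.numeric(c(substr(l, 1L, 10L), substr(l, 11L, 20L), substr(l, 21L, 30L)))
    }, numeric(3)))
    dimnames(coords) <- NULL
    elements <- trimws(substr(ablock, 32L, 34L))
    bonds <- NULL
    if (!is.na(nbonds) && nbonds > 0L) {
      bblock <- lines[(5L + natoms):(4L + natoms + nbonds)]
      bonds <- cbind(atom1 = as.integer(substr(bblock, 1L, 3L)),
                     atom2 = as.integer(substr(bblock, 4L, 6L)),
                     order = as.integer(substr(bblock, 7L, 9L)))
    }
    list(elements = elements, coords = coords, bonds = bonds,
         title = trimws(lines[1L]))
  }

  poses <- list()
  rejected <- data.frame(record = integer(0), elements = character(0),
                         stringsAsFactors = FALSE)
  for (irec in seq_along(raw_records)) {
    p <- parse_one(raw_records[[irec]], irec)
    p$elements <- normalize_element(p$elements)
    if (!all(is.finite(p$coords)))
      stop("SDF record ", irec, " has non-finite coordinates")
    if (all(abs(p$coords[, 3L]) < 1e-9) && nrow(p$coords) > 3L)
      stop("SDF record ", irec, " appears to be 2D-only (all z coordinates zero)")
    bad <- setdiff(unique(p$elements), SCORING_ELEMENTS)
    if (length(bad) > 0L) {
      warning("SDF record ", irec, " rejected: unsupported element(s) ",
              paste(bad, collapse = ", "), call. = FALSE)
      rejected <- rbind(rejected,
                        data.frame(record = irec,
                                   elements = paste(bad, collapse = ","),
                                   stringsAsFactors = FALSE))
      next
    }
    poses[[length(poses) + 1L]] <- p
  }
  attr(poses, "rejected") <- rejected
  poses
}

#' Enumerate residue-atom and metal-atom pairs within a cutoff
#'
#' The protein-ligand distance `d_ij` is the minimum over the residue's
#' heavy atoms of the Euclidean distance to ligand atom `j`; metal-ligand
#' distances are point-to-point. Pairs at distance greater than `cutoff`
#' are excluded. An empty pair set is valid (its score contribution is 0).
#'
#' @param complex an [nmdn_complex()]
#' @param cutoff distance cutoff in Angstrom (default 9)
#' @param include_hydrogens include ligand hydrogen atoms (default TRUE;
#'   protein hydrogens are never used)
#' @return object of class `nmdn_pairset`: list with data frames `pl`
#'   (columns i, j, d) and `ml` (columns k, j, d), plus `cutoff`, `pose_id`
#' @export
enumerate_pairs <- function(complex, cutoff = 9.0, include_hydrogens = TRUE) {
  stopifnot(inherits(complex, "nmdn_complex"), cutoff > 0)
  lig_idx <- seq_along(complex$lig_elements)
  if (!include_hydrogens) lig_idx <- lig_idx[complex$lig_elements != "H"]
  L <- complex$lig_coords[lig_idx, , drop = FALSE]

  pl <- data.frame(i = integer(0), j = integer(0), d = numeric(0))
  if (length(lig_idx) > 0L) {
    # stack all residue heavy atoms, then take per-residue minima
    n_per <- vapply(complex$residues, function(r) nrow(r$heavy_atom_coords),
                    integer(1))
    A <- do.call(rbind, lapply(complex$residues, `[[`, "heavy_atom_coords"))
    ridx <- rep(seq_along(complex$residues), n_per)
    D2 <- outer(rowSums(A^2), rowSums(L^2), "+") - 2 * (A %*% t(L))
    D2[D2 < 0] <- 0
    # min over the atoms of each residue
    minD2 <- do.call(rbind, lapply(split.data.frame(D2, ridx), function(m) {
      apply(m, 2L, min)
    }))
    D <- sqrt(minD2)
    hit <- which(D <= cutoff & D > 0, arr.ind = TRUE)
    if (nrow(hit) > 0L) {
      pl <- data.frame(i = as.integer(hit[, 1L]),
                       j = as.integer(lig_idx[hit[, 2L]]),
                       d = D[hit])
      pl <- pl[order(pl$i, pl$j), , drop = FALSE]
      rownames(pl) <- NULL
    }
  }

  ml <- data.frame(k = integer(0), j = integer(0), d = numeric(0))
  if (length(complex$metal_elements) > 0L && length(lig_idx) > 0L) {
    M <- complex$metal_coords
    D2 <- outer(rowSums(M^2), rowSums(L^2), "+") - 2 * (M %*% t(L))
    D2[D2 < 0] <- 0
    D <- sqrt(D2)
    hit <- which(D <= cutoff & D > 0, arr.ind = TRUE)
    if (nrow(hit) > 0L) {
      ml <- data.frame(k = as.integer(hit[, 1L]),
                       j = as.integer(lig_idx[hit[, 2L]]),
                       d = D[hit])
      ml <- ml[order(ml$k, ml$j), , drop = FALSE]
      rownames(ml) <- NULL
    }
  }

  structure(list(pl = pl, ml = ml, cutoff = cutoff, pose_id = complex$pose_id),
            class = "nmdn_pairset")
}

#' @export
print.nmdn_pairset <- function(x, ...) {
  cat(sprintf("<nmdn_pairset '%s': %d protein-ligand, %d metal-ligand pairs (cutoff %.1f A)>\n",
              x$pose_id, nrow(x$pl), nrow(x$ml), x$cutoff))
  invisible(x)
}

#' Export a pair set as TSV (pose_id, kind, i, j, d)
#' @param pairs an `nmdn_pairset`
#' @param path output file
#' @export
write_pairset_tsv <- function(pairs, path) {
  stopifnot(inherits(pairs, "nmdn_pairset"))
  pl <- pairs$pl; ml <- pairs$ml
  out <- rbind(
    if (nrow(pl)) data.frame(pose_id = pairs$pose_id, kind = "PL",
                             i = pl$i, j = pl$j, d = pl$d),
    if (nrow(ml)) data.frame(pose_id = pairs$pose_id, kind = "ML",
                             i = ml$k, j = ml$j, d = ml$d)
  )
  if (is.null(out)) out <- data.frame(pose_id = character(0), kind = character(0),
                                      i = integer(0), j = integer(0), d = numeric(0))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
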