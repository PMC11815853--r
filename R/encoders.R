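# Embedding providers. Residue/ligand-atom/metal embeddings enter the
# scoring heads through a uniform contract: a provider turns an
# nmdn_complex into an EmbeddingSet (three matrices). Pretrained encoders
# are consumed via a precomputed keyed archive; the baseline featurizer is
# a deterministic, trainable lookup so the full stack runs offline.

#' Create the deterministic baseline embedding provider
#'
#' Residue embeddings are a learnable lookup over the 21 amino-acid codes
#' (20 standard + "X"); ligand-atom embeddings are an element lookup plus a
#' learnable linear refinement over rotation-invariant local geometry
#' (distance statistics to the other ligand atoms); metal embeddings are an
#' element lookup. All tables are initialized deterministically from
#' `seed`, so identical inputs and seed give bitwise-identical embeddings.
#'
#' @param dims integer vector `c(D_prot, D_lig, D_metal)` (default 64 each)
#' @param metal_list metal element vocabulary
#' @param seed integer seed for table initialization
#' @return provider object of class `nmdn_encoder`
#' @export
baseline_encoder <- function(dims = c(64L, 64L, 64L),
                             metal_list = DEFAULT_METALS, seed = 1L) {
  stopifnot(length(dims) == 3L, all(dims >= 1L))
  aa_levels <- c(unname(AA_THREE_TO_ONE), "X")
  set.seed(seed)
  aa_table <- matrix(stats::rnorm(length(aa_levels) * dims[1L], sd = 1),
                     nrow = length(aa_levels),
                     dimnames = list(aa_levels, NULL))
  elem_table <- matrix(stats::rnorm(length(SCORING_ELEMENTS) * dims[2L], sd = 1),
                       nrow = length(SCORING_ELEMENTS),
                       dimnames = list(SCORING_ELEMENTS, NULL))
  metal_list <- normalize_element(metal_list)
  metal_table <- matrix(stats::rnorm(length(metal_list) * dims[3L], sd = 1),
                        nrow = length(metal_list),
                        dimnames = list(metal_list, NULL))
  # geometry refinement starts as the zero map: pure lookup until trained
  geom_W <- matrix(0, nrow = 4L, ncol = dims[2L])
  structure(
    list(provider_id = "baseline", dims = as.integer(dims),
         aa_table = aa_table, elem_table = elem_table,
         metal_table = metal_table, geom_W = geom_W,
         trainable = list(residue = FALSE, ligand = TRUE, metal = TRUE),
         seed = as.integer(seed)),
    class = "nmdn_encoder"
  )
}

#' Trainability flags of an embedding provider
#'
#' By default the residue provider is frozen (pretrained protein language
#' models are not fine-tuned here) while ligand and metal providers are
#' trainable. Overrides are honored.
#'
#' @param provider an `nmdn_encoder` (or archive provider)
#' @param residue,ligand,metal optional logical overrides
#' @return named list of logical flags
#' @export
finetune_flags <- function(provider, residue = NULL, ligand = NULL, metal = NULL) {
  fl <- provider$trainable
  if (is.null(fl)) fl <- list(residue = FALSE, ligand = FALSE, metal = FALSE)
  if (!is.null(residue)) fl$residue <- isTRUE(residue)
  if (!is.null(ligand)) fl$ligand <- isTRUE(ligand)
  if (!is.null(metal)) fl$metal <- isTRUE(metal)
  fl
}

# rotation-invariant per-atom geometry features: mean and min distance to
# the other ligand atoms, neighbor counts within 2 and 4 Angstrom
ligand_geom_features <- function(coords) {
  n <- nrow(coords)
  if (n == 1L) return(matrix(0, 1L, 4L))
  D2 <- outer(rowSums(coords^2), rowSums(coords^2), "+") - 2 * (coords %*% t(coords))
  D2[D2 < 0] <- 0
  D <- sqrt(D2)
  diag(D) <- NA
  cbind(rowMeans(D, na.rm = TRUE),
        apply(D, 1L, min, na.rm = TRUE),
        rowSums(D < 2, na.rm = TRUE),
        rowSums(D < 4, na.rm = TRUE))
}

#' Embed a complex with the baseline provider
#'
#' @param provider an `nmdn_encoder` from [baseline_encoder()]
#' @param complex an [nmdn_complex()]
#' @return an `nmdn_embeddings` object: list with `residue_emb`
#'   (N_prot x D_prot), `ligand_emb` (N_lig x D_lig), `metal_emb`
#'   (N_metal x D_metal), `provider_id`
#' @export
embed_with_baseline <- function(provider, complex) {
  stopifnot(inherits(provider, "nmdn_encoder"), inherits(complex, "nmdn_complex"))
  aa <- vapply(complex$residues, `[[`, character(1), "aa_code")
  bad_aa <- setdiff(unique(aa), rownames(provider$aa_table))
  if (length(bad_aa)) stop("unknown amino-acid code(s): ", paste(bad_aa, collapse = ", "))
  residue_emb <- provider$aa_table[aa, , drop = FALSE]

  el <- complex$lig_elements
  bad_el <- setdiff(unique(el), rownames(provider$elem_table))
  if (length(bad_el)) stop("unknown ligand element(s): ", paste(bad_el, collapse = ", "))
  gf <- ligand_geom_features(complex$lig_coords)
  ligand_emb <- provider$elem_table[el, , drop = FALSE] + gf %*% provider$geom_W

  if (length(complex$metal_elements) > 0L) {
    bad_m <- setdiff(unique(complex$metal_elements), rownames(provider$metal_table))
    if (length(bad_m)) stop("unknown metal element(s): ", paste(bad_m, collapse = ", "))
    metal_emb <- provider$metal_table[complex$metal_elements, , drop = FALSE]
  } else {
    metal_emb <- matrix(numeric(0), 0L, provider$dims[3L])
  }
  new_embeddings(residue_emb, ligand_emb, metal_emb, provider$provider_id,
                 complex)
}

new_embeddings <- function(residue_emb, ligand_emb, metal_emb, provider_id,
                           complex) {
  if (nrow(residue_emb) != length(complex$residues))
    stop("residue embedding rows (", nrow(residue_emb),
         ") do not match residue count (", length(complex$residues), ")")
  if (nrow(ligand_emb) != length(complex$lig_elements))
    stop("ligand embedding rows (", nrow(ligand_emb),
         ") do not match ligand atom count (", length(complex$lig_elements), ")")
  if (nrow(metal_emb) != length(complex$metal_elements))
    stop("metal embedding rows (", nrow(metal_emb),
         ") do not match metal count (", length(complex$metal_elements), ")")
  if (!all(is.finite(residue_emb)) || !all(is.finite(ligand_emb)) ||
      !all(is.finite(metal_emb)))
    stop("embeddings must be finite")
  structure(list(residue_emb = unname(residue_emb),
                 ligand_emb = unname(ligand_emb),
                 metal_emb = unname(metal_emb),
                 provider_id = provider_id),
            class = "nmdn_embeddings")
}

#' Load precomputed embeddings from a keyed directory archive
#'
#' The archive is a directory with subdirectories `protein/`, `ligand/` and
#' `metal/`, each holding `<id>.tsv` numeric matrices (one row per entity,
#' in complex order). This is the on-disk contract for embeddings computed
#' by external pretrained encoders (e.g. a 1280-dimensional protein
#' language model); any embedding width is accepted, but row counts must
#' match the complex.
#'
#' @param archive_dir archive directory
#' @param complex the [nmdn_complex()] the embeddings belong to
#' @param protein_id,ligand_id,metal_id keys within the archive groups;
#'   `metal_id` may be NULL when the complex has no metals
#' @return an `nmdn_embeddings` object
#' @export
load_precomputed_embeddings <- function(archive_dir, complex,
                                        protein_id, ligand_id,
                                        metal_id = NULL) {
  stopifnot(inherits(complex, "nmdn_complex"))
  read_key <- function(group, id) {
    f <- file.path(archive_dir, group, paste0(id, ".tsv"))
    if (!file.exists(f)) stop("archive key not found: ", group, "/", id)
    as.matrix(utils::read.table(f, sep = "\t", header = FALSE))
  }
  residue_emb <- read_key("protein", protein_id)
  ligand_emb <- read_key("ligand", ligand_id)
  if (length(complex$metal_elements) > 0L) {
    if (is.null(metal_id)) stop("complex has metals but no metal_id given")
    metal_emb <- read_key("metal", metal_id)
  } else {
    metal_emb <- matrix(numeric(0), 0L, 1L)
    if (nrow(residue_emb) > 0L) metal_emb <- matrix(numeric(0), 0L, ncol(residue_emb))
  }
  new_embeddings(residue_emb, ligand_emb, metal_emb,
                 provider_id = paste0("archive:", basename(archive_dir)),
                 complex)
}

#' Write an embedding archive entry
#'
#' Companion writer for the keyed directory archive consumed by
#' [load_precomputed_embeddings()].
#' @param archive_dir archive directory (created if missing)
#' @param group one of "protein", "ligand", "metal"
#' @param id key
#' @param mat numeric matrix
#' @export
write_embedding_archive <- function(archive_dir, group, id, mat) {
  stopifnot(group %in% c("protein", "ligand", "metal"))
  dir.create(file.path(archive_dir, group), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(mat, file.path(archive_dir, group, paste0(id, ".tsv")),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(file.path(archive_dir, group, paste0(id, ".tsv")))
}
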