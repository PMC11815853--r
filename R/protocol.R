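# End-to-end protocol over externally generated pose files: score every
# pose of each protein-ligand pair with the NMDN score, select the top-1
# pose, and predict its binding affinity. Pose generation itself (e.g. by
# a diffusion docking model, which typically samples 10 poses per pair) is
# outside the package; the file contract is one multi-record SDF per pair.

#' Build per-pose complexes from a protein and an SDF pose file
#'
#' @param protein result of [load_protein()] (or a PDB path)
#' @param poses result of [load_ligand_poses()] (or an SDF path)
#' @param pair_id identifier prefix for pose_ids
#' @return list of [nmdn_complex()] objects, one per accepted pose
#' @export
build_pose_complexes <- function(protein, poses, pair_id = "pair") {
  if (is.character(protein)) protein <- load_protein(protein)
  if (is.character(poses)) poses <- load_ligand_poses(poses)
  lapply(seq_along(poses), function(pi) {
    p <- poses[[pi]]
    nmdn_complex(protein$residues, p$elements, p$coords,
                 protein$metal_elements, protein$metal_coords,
                 pose_id = sprintf("%s/pose%02d", pair_id, pi),
                 lig_bonds = p$bonds)
  })
}

#' Run the scoring protocol over protein-ligand pairs
#'
#' For every pair: all poses are scored with the aggregated NMDN score,
#' the top-1 pose is selected (deterministic tie-break on pose_id), and
#' the binding affinity of the selected pose is predicted with the
#' interaction module. Pairs whose poses are all rejected (e.g.
#' unsupported elements) are marked failed and the run continues.
#'
#' @param pairs data frame with columns `pair_id`, `protein` (PDB path),
#'   `poses` (SDF path); or a single pair given as `protein`/`poses` paths
#' @param model a fitted `nmdn_model` (or checkpoint path)
#' @param extras named list of [ligand_extras()] keyed by pair_id, or a
#'   CSV path for [read_ligand_extras()]; missing entries default to zeros
#' @return data frame with one row per pair: `pair_id`, `selected_pose`,
#'   `nmdn_score`, `nmdn_pl`, `nmdn_ml`, `pkd`, `n_poses`, `status`; the
#'   per-pose score tables are attached as the `pose_scores` attribute
#' @export
run_protocol <- function(pairs, model, extras = NULL) {
  if (is.character(model)) model <- load_checkpoint(model)
  if (is.character(extras)) extras <- read_ligand_extras(extras)
  stopifnot(all(c("pair_id", "protein", "poses") %in% names(pairs)))
  rows <- list()
  pose_scores <- list()
  for (ri in seq_len(nrow(pairs))) {
    pid <- pairs$pair_id[ri]
    row <- data.frame(pair_id = pid, selected_pose = NA_character_,
                      nmdn_score = NA_real_, nmdn_pl = NA_real_,
                      nmdn_ml = NA_real_, pkd = NA_real_,
                      n_poses = 0L, status = "failed",
                      stringsAsFactors = FALSE)
    res <- tryCatch({
      cxs <- build_pose_complexes(pairs$protein[ri], pairs$poses[ri],
                                  pair_id = pid)
      if (length(cxs) == 0L) stop("all poses rejected")
      scores <- lapply(cxs, function(cx)
        predict(model, cx, type = "nmdn"))
      tab <- data.frame(
        pose_id = vapply(scores, `[[`, character(1), "pose_id"),
        score = vapply(scores, `[[`, numeric(1), "nmdn_score"),
        pl = vapply(scores, `[[`, numeric(1), "nmdn_pl_total"),
        ml = vapply(scores, `[[`, numeric(1), "nmdn_ml_total"),
        stringsAsFactors = FALSE)
      sel <- select_top_pose(tab)
      si <- match(sel, tab$pose_id)
      ex <- if (!is.null(extras) && pid %in% names(extras)) extras[[pid]]
            else ligand_extras()
      aff <- predict(model, cxs[[si]], type = "pkd", extras = ex)
      list(tab = tab, sel = sel, si = si, aff = aff)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("pair ", pid, " failed: ", conditionMessage(res), call. = FALSE)
      rows[[ri]] <- row
      next
    }
    row$selected_pose <- res$sel
    row$nmdn_score <- res$tab$score[res$si]
    row$nmdn_pl <- res$tab$pl[res$si]
    row$nmdn_ml <- res$tab$ml[res$si]
    row$pkd <- res$aff$pkd
    row$n_poses <- nrow(res$tab)
    row$status <- "ok"
    rows[[ri]] <- row
    pose_scores[[pid]] <- res$tab
  }
  out <- do.call(rbind, rows)
  attr(out, "pose_scores") <- pose_scores
  out
}
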