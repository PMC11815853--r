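# Pose-selection and virtual-screening evaluation metrics.

#' Enrichment factor of a screening run
#'
#' `top_fraction` mode (default, used for top-x% reports): the fraction of
#' actives among the top `ceiling(fraction * N)` ligands by score, divided
#' by the overall active fraction. `fpr` mode: the true-positive rate at
#' the score threshold where the false-positive rate equals `fraction`,
#' divided by `fraction` (ROC enrichment). Ties are broken by ranking
#' first on score (descending) and then on ligand_id, i.e. a stable,
#' documented order.
#'
#' @param table data frame with columns `ligand_id`, `score`, `is_active`
#' @param fraction top fraction / false-positive rate (0 < fraction < 1)
#' @param mode "top_fraction" or "fpr"
#' @return the enrichment factor
#' @export
enrichment_factor <- function(table, fraction = 0.01,
                              mode = c("top_fraction", "fpr")) {
  mode <- match.arg(mode)
  stopifnot(fraction > 0, fraction < 1,
            all(c("ligand_id", "score", "is_active") %in% names(table)))
  if (anyDuplicated(table$ligand_id)) stop("ligand_ids must be unique")
  n_active <- sum(table$is_active)
  if (n_active == 0L) stop("enrichment factor undefined: no actives in table")
  N <- nrow(table)
  ord <- order(-table$score, table$ligand_id)
  act <- table$is_active[ord]
  if (mode == "top_fraction") {
    n_top <- ceiling(fraction * N)
    hits <- sum(act[seq_len(n_top)])
    (hits / n_top) / (n_active / N)
  } else {
    n_inactive <- N - n_active
    if (n_inactive == 0L) stop("fpr mode needs at least one inactive")
    n_fp <- ceiling(fraction * n_inactive)
    cum_fp <- cumsum(!act)
    cut <- which(cum_fp >= n_fp)[1L]
    if (is.na(cut)) cut <- N
    tpr <- sum(act[seq_len(cut)]) / n_active
    tpr / fraction
  }
}

#' Docking success rate
#'
#' The fraction of systems for which at least one of the top-`top_k`
#' scored poses lies within `threshold` Angstrom RMSD of the reference
#' pose, plus the median RMSD of the top-1 poses.
#'
#' @param table data frame with columns `system_id`, `pose_id`, `score`,
#'   `rmsd` (NA allowed; poses with missing RMSD never count as successes)
#' @param threshold RMSD success threshold, Angstrom (default 2)
#' @param top_k number of top-scored poses considered (default 1)
#' @return list with `rate`, `median_top1_rmsd`, `n_systems`
#' @export
docking_success <- function(table, threshold = 2.0, top_k = 1L) {
  stopifnot(all(c("system_id", "pose_id", "score", "rmsd") %in% names(table)))
  if (any(!is.na(table$rmsd) & table$rmsd < 0)) stop("rmsd must be non-negative")
  split_tab <- split(table, table$system_id)
  succ <- vapply(split_tab, function(tb) {
    ord <- order(-tb$score, tb$pose_id)
    top <- tb$rmsd[ord][seq_len(min(top_k, nrow(tb)))]
    any(!is.na(top) & top <= threshold)
  }, logical(1))
  top1 <- vapply(split_tab, function(tb) {
    tb$rmsd[order(-tb$score, tb$pose_id)][1L]
  }, numeric(1))
  list(rate = mean(succ), median_top1_rmsd = stats::median(top1, na.rm = TRUE),
       n_systems = length(split_tab))
}

#' Scoring and ranking power across targets
#'
#' Per-target Pearson and Spearman correlations between predicted and
#' experimental affinities, and their averages across targets; the
#' weighted averages use the per-target ligand counts as weights.
#'
#' @param pred predicted scores
#' @param label experimental affinities
#' @param target target identifier per ligand (single target if missing)
#' @return list with the per-target table and the unweighted / weighted
#'   average correlations
#' @export
ranking_powers <- function(pred, label, target = NULL) {
  stopifnot(length(pred) == length(label))
  if (is.null(target)) target <- rep("all", length(pred))
  sp <- split(data.frame(pred = pred, label = label), target)
  tab <- do.call(rbind, lapply(names(sp), function(tg) {
    d <- sp[[tg]]
    data.frame(target = tg, n = nrow(d),
               pearson = stats::cor(d$pred, d$label, method = "pearson"),
               spearman = stats::cor(d$pred, d$label, method = "spearman"))
  }))
  w <- tab$n / sum(tab$n)
  list(per_target = tab,
       mean_pearson = mean(tab$pearson),
       mean_spearman = mean(tab$spearman),
       weighted_pearson = sum(w * tab$pearson),
       weighted_spearman = sum(w * tab$spearman))
}

#' Select the top-scored pose
#'
#' Argmax of the score with a deterministic tie-break on pose_id
#' (lexicographically first wins), so the result does not depend on input
#' order.
#' @param poses data frame with columns `pose_id`, `score`
#' @return the selected pose_id
#' @export
select_top_pose <- function(poses) {
  stopifnot(all(c("pose_id", "score") %in% names(poses)), nrow(poses) >= 1L)
  ord <- order(-poses$score, as.character(poses$pose_id))
  poses$pose_id[ord][1L]
}

#' Combined two-score top-fraction selection
#'
#' Takes the union of the per-score top `per_score_fraction` sets (half
#' the total budget from each score). When the union falls short of
#' `ceiling(total_fraction * N)` unique ligands because the two top sets
#' overlap, ligands are appended one at a time, alternating between the
#' two scores in rank order (first score first), until the target count is
#' reached exactly.
#'
#' @param table data frame with columns `ligand_id`, `score1`, `score2`
#' @param total_fraction total selection budget (default 0.01)
#' @param per_score_fraction per-score top fraction (default 0.005)
#' @return character vector of selected ligand_ids (length
#'   `ceiling(total_fraction * N)`)
#' @export
combined_selection <- function(table, total_fraction = 0.01,
                               per_score_fraction = 0.005) {
  stopifnot(all(c("ligand_id", "score1", "score2") %in% names(table)))
  if (anyDuplicated(table$ligand_id)) stop("ligand_ids must be unique")
  N <- nrow(table)
  target_n <- ceiling(total_fraction * N)
  k <- max(1L, floor(per_score_fraction * N))
  r1 <- table$ligand_id[order(-table$score1, table$ligand_id)]
  r2 <- table$ligand_id[order(-table$score2, table$ligand_id)]
  selected <- unique(c(r1[seq_len(k)], r2[seq_len(k)]))
  if (length(selected) > target_n) return(selected[seq_len(target_n)])
  p1 <- k; p2 <- k; turn <- 1L
  while (length(selected) < target_n) {
    if (turn == 1L) {
      while (p1 < N && r1[p1 + 1L] %in% selected) p1 <- p1 + 1L
      if (p1 < N) { p1 <- p1 + 1L; selected <- c(selected, r1[p1]) }
    } else {
      while (p2 < N && r2[p2 + 1L] %in% selected) p2 <- p2 + 1L
      if (p2 < N) { p2 <- p2 + 1L; selected <- c(selected, r2[p2]) }
    }
    turn <- 3L - turn
    if (p1 >= N && p2 >= N) break
  }
  selected
}

#' Heavy-atom RMSD between two ligand poses
#'
#' Computed without superposition (docking convention: both poses live in
#' the protein frame). With `symmetry_aware = TRUE` the RMSD is minimized
#' over the automorphisms of the molecular graph (element-colored), so
#' that, e.g., a benzene ring rotated by 60 degrees in its plane scores 0.
#'
#' @param coords_a,coords_b n x 3 coordinate matrices, same atom order
#' @param elements element symbols (length n); hydrogens are excluded
#' @param bonds integer matrix (n_bonds x >= 2): atom index pairs; required
#'   for `symmetry_aware`
#' @param symmetry_aware minimize over graph automorphisms (default FALSE)
#' @return RMSD in Angstrom
#' @export
ligand_rmsd <- function(coords_a, coords_b, elements = NULL, bonds = NULL,
                        symmetry_aware = FALSE) {
  coords_a <- matrix(as.numeric(coords_a), ncol = 3L)
  coords_b <- matrix(as.numeric(coords_b), ncol = 3L)
  stopifnot(nrow(coords_a) == nrow(coords_b))
  n <- nrow(coords_a)
  heavy <- if (is.null(elements)) rep(TRUE, n) else normalize_element(elements) != "H"
  plain <- {
    d <- coords_a[heavy, , drop = FALSE] - coords_b[heavy, , drop = FALSE]
    sqrt(mean(rowSums(d^2)))
  }
  if (!symmetry_aware) return(plain)
  if (is.null(bonds)) stop("symmetry_aware RMSD needs the bond list")
  el <- if (is.null(elements)) rep("C", n) else normalize_element(elements)
  g <- igraph::graph_from_edgelist(cbind(bonds[, 1L], bonds[, 2L]),
                                   directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  colors <- as.integer(factor(el))
  autos <- igraph::graph.get.isomorphisms.vf2(g, g, vertex.color1 = colors,
                                              vertex.color2 = colors)
  best <- plain
  ha <- coords_a[heavy, , drop = FALSE]
  for (p in autos) {
    perm <- as.integer(p)
    # permuted pose b: atom perm[v] of b plays the role of atom v
    hb <- coords_b[perm, , drop = FALSE][heavy, , drop = FALSE]
    d <- ha - hb
    best <- min(best, sqrt(mean(rowSums(d^2))))
  }
  best
}
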