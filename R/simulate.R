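#' Default branching trajectory tree
#'
#' A 2D tree of 13 line segments, one per canonical retinal cell type,
#' approximating the known developmental trajectories: NE at the root,
#' NE -> RPE, NE -> ERPC, ERPC -> {NRPC, LRPC}, NRPC -> {RGC, HC, AC},
#' LRPC -> {PRP, BP, MC}, PRP -> {C, R}. Each branch carries a pseudotime
#' interval `[t0, t1]` within global pseudotime `[0, 1]`; the four
#' developmental stages are the quarters of that axis, so early types
#' (NE, ERPC, RGC) populate stages I--II and terminal types (C, R, BP, MC)
#' stages III--IV.
#'
#' @return A data.frame with columns `type`, `parent`, `x0`, `y0`, `x1`,
#'   `y1`, `t0`, `t1`.
#' @export
default_branch_tree <- function() {
  tree <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
type  parent x0  y0   x1  y1   t0   t1
NE    NA     0.0 0.0  1.0 0.0  0.00 0.28
RPE   NE     1.0 0.0  1.6 1.4  0.05 0.50
ERPC  NE     1.0 0.0  2.0 -0.8 0.03 0.35
NRPC  ERPC   2.0 -0.8 3.0 -1.4 0.15 0.60
RGC   NRPC   3.0 -1.4 4.0 -2.2 0.15 0.45
HC    NRPC   3.0 -1.4 4.0 -0.9 0.28 0.60
AC    NRPC   3.0 -1.4 3.8 -0.2 0.50 0.80
LRPC  ERPC   2.0 -0.8 3.0 0.2  0.25 0.60
PRP   LRPC   3.0 0.2  3.6 1.2  0.50 0.82
C     PRP    3.6 1.2  4.2 2.0  0.75 1.00
R     PRP    3.6 1.2  4.6 1.4  0.75 1.00
BP    LRPC   3.0 0.2  4.4 0.0  0.78 1.00
MC    LRPC   3.0 0.2  4.0 0.8  0.78 1.00
")
  tree
}

#' Synthetic dataset configuration
#'
#' Defines the two-condition, four-stage synthetic dataset: cells on a
#' branching 2D trajectory tree with condition-specific Gaussian jitter
#' (organoid dispersion double the native default, emulating relaxed spatial
#' control), stage labels drawn from pseudotime windows with an
#' organoid-only probability of being drawn one stage off (relaxed temporal
#' control), and negative-binomial counts with planted per-type marker
#' boosts and organoid-only perturbations.
#'
#' @param branch_tree tree as from [default_branch_tree()].
#' @param sigma_native,sigma_organoid isotropic Gaussian jitter SDs around
#'   the branch, per condition (embedding units).
#' @param cells_per_condition_stage cells generated per condition x stage.
#' @param stage_window named list mapping stage to its pseudotime interval.
#' @param n_genes number of genes.
#' @param markers_per_type planted marker genes per cell type.
#' @param marker_log_fold natural-log boost of a marker in its own type.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param perturbed_tf_fraction fraction of each type's markers receiving an
#'   organoid-only perturbation.
#' @param perturb_log_fold natural-log size of the planted perturbation;
#'   directions alternate up/down within a type.
#' @param mixing_excess_organoid probability that an organoid cell's
#'   position/type is drawn from a stage window adjacent to its recorded
#'   stage.
#' @param abundance_multiplier data.frame (`type`, `stage`, `condition`,
#'   `mult`) of branch-weight multipliers; the default gives organoid PRP a
#'   1.5x excess at stages II--III (premature photoreceptor precursors).
#' @param lib_size_meanlog,lib_size_sdlog log-normal library-size model.
#' @param cycle_fraction fraction of progenitor (ERPC/LRPC/NRPC) cells
#'   assigned an active cell-cycle phase (split evenly S vs G2-M), with
#'   phase marker genes boosted by `marker_log_fold`.
#' @param cycle_markers_per_phase planted S and G2-M marker genes.
#' @param seed integer seed; all generator randomness flows from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(branch_tree = default_branch_tree(),
                         sigma_native = 0.3, sigma_organoid = 0.6,
                         cells_per_condition_stage = 500L,
                         stage_window = list(I = c(0, 0.25), II = c(0.25, 0.5),
                                             III = c(0.5, 0.75), IV = c(0.75, 1)),
                         n_genes = 600L, markers_per_type = 10L,
                         marker_log_fold = 1.5, nb_dispersion = 0.5,
                         perturbed_tf_fraction = 0.2, perturb_log_fold = 1.0,
                         mixing_excess_organoid = 0.15,
                         abundance_multiplier = data.frame(
                           type = "PRP", stage = c("II", "III"),
                           condition = "organoid", mult = 1.5),
                         lib_size_meanlog = log(5000), lib_size_sdlog = 0.3,
                         cycle_fraction = 0.3, cycle_markers_per_phase = 10L,
                         seed = 1L) {
  if (!nrow(branch_tree)) abort_validation("branch tree is empty")
  if (sigma_native < 0 || sigma_organoid < 0) {
    abort_validation("jitter sigmas must be >= 0")
  }
  if (mixing_excess_organoid < 0 || mixing_excess_organoid > 1) {
    abort_validation("mixing_excess_organoid must be in [0, 1]")
  }
  if (perturbed_tf_fraction < 0 || perturbed_tf_fraction > 1) {
    abort_validation("perturbed_tf_fraction must be in [0, 1]")
  }
  if (cycle_fraction < 0 || cycle_fraction > 1) {
    abort_validation("cycle_fraction must be in [0, 1]")
  }
  # connectivity: every non-root branch must start where its parent ends
  roots <- is.na(branch_tree$parent)
  if (sum(roots) != 1L) abort_validation("branch tree needs exactly one root")
  for (i in which(!roots)) {
    p <- match(branch_tree$parent[i], branch_tree$type)
    if (is.na(p)) {
      abort_validation("branch '", branch_tree$type[i],
                       "' has unknown parent '", branch_tree$parent[i], "'")
    }
    if (branch_tree$x0[i] != branch_tree$x1[p] ||
        branch_tree$y0[i] != branch_tree$y1[p]) {
      abort_validation("branch '", branch_tree$type[i],
                       "' does not start at its parent's end point")
    }
  }
  structure(list(branch_tree = branch_tree, sigma_native = sigma_native,
                 sigma_organoid = sigma_organoid,
                 cells_per_condition_stage = as.integer(cells_per_condition_stage),
                 stage_window = stage_window, n_genes = as.integer(n_genes),
                 markers_per_type = as.integer(markers_per_type),
                 marker_log_fold = marker_log_fold,
                 nb_dispersion = nb_dispersion,
                 perturbed_tf_fraction = perturbed_tf_fraction,
                 perturb_log_fold = perturb_log_fold,
                 mixing_excess_organoid = mixing_excess_organoid,
                 abundance_multiplier = abundance_multiplier,
                 lib_size_meanlog = lib_size_meanlog,
                 lib_size_sdlog = lib_size_sdlog,
                 cycle_fraction = cycle_fraction,
                 cycle_markers_per_phase = as.integer(cycle_markers_per_phase),
                 seed = as.integer(seed)),
            class = "synth_config")
}

stage_of_pseudotime <- function(t, windows) {
  out <- rep(NA_character_, length(t))
  for (s in names(windows)) {
    w <- windows[[s]]
    out[t >= w[1L] & t < w[2L]] <- s
  }
  out[t >= windows[[length(windows)]][1L]] <- names(windows)[length(windows)]
  out
}

#' Place cells on the branching manifold
#'
#' Each cell is placed uniformly (in pseudotime) along a branch whose
#' pseudotime interval overlaps the cell's stage window, then jittered with
#' the condition's isotropic Gaussian sigma. The branch label is the cell
#' type. Organoid cells draw their position from a window one stage off the
#' recorded stage with probability `mixing_excess_organoid`, so organoid
#' stages mix cell types from adjacent windows. Cell counts per
#' condition x stage are exactly `cells_per_condition_stage`.
#'
#' @param cfg a [synth_config()].
#' @return List with `table` (a [cell_table()] with embedding and labels,
#'   counts all zero until [generate_counts()]) and `truth` (per-cell
#'   pseudotime, branch and window stage).
#' @export
generate_manifold <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(stage_seed(cfg$seed, "simulate"))
  tree <- cfg$branch_tree
  windows <- cfg$stage_window
  stages <- names(windows)
  n_per <- cfg$cells_per_condition_stage
  rows <- list()
  for (cond in CONDITION_LEVELS) {
    sigma <- if (cond == "native") cfg$sigma_native else cfg$sigma_organoid
    for (si in seq_along(stages)) {
      s <- stages[[si]]
      eff <- rep(si, n_per)
      if (cond == "organoid" && cfg$mixing_excess_organoid > 0) {
        # a mis-assigned cell is drawn from an adjacent stage window; interior
        # stages pick either neighbour, boundary stages have only one
        shift <- runif(n_per) < cfg$mixing_excess_organoid
        dir <- ifelse(runif(n_per) < 0.5, -1L, 1L)
        if (si == 1L) dir <- rep(1L, n_per)
        if (si == length(stages)) dir <- rep(-1L, n_per)
        eff <- ifelse(shift, si + dir, eff)
      }
      t_cell <- numeric(n_per)
      branch <- integer(n_per)
      for (ei in unique(eff)) {
        idx <- which(eff == ei)
        w <- windows[[ei]]
        lo <- pmax(tree$t0, w[1L])
        hi <- pmin(tree$t1, w[2L])
        weight <- pmax(0, hi - lo)
        mult <- rep(1, nrow(tree))
        am <- cfg$abundance_multiplier
        if (!is.null(am) && nrow(am)) {
          for (k in seq_len(nrow(am))) {
            if (am$condition[k] == cond && am$stage[k] == s) {
              mult[tree$type == am$type[k]] <- am$mult[k]
            }
          }
        }
        weight <- weight * mult
        if (all(weight <= 0)) {
          abort_validation("no branch overlaps stage window ", stages[[ei]])
        }
        b <- sample.int(nrow(tree), length(idx), replace = TRUE,
                        prob = weight)
        branch[idx] <- b
        t_cell[idx] <- runif(length(idx), lo[b], hi[b])
      }
      frac <- (t_cell - tree$t0[branch]) / (tree$t1[branch] - tree$t0[branch])
      x <- tree$x0[branch] + frac * (tree$x1[branch] - tree$x0[branch])
      y <- tree$y0[branch] + frac * (tree$y1[branch] - tree$y0[branch])
      if (sigma > 0) {
        x <- x + rnorm(n_per, 0, sigma)
        y <- y + rnorm(n_per, 0, sigma)
      }
      rows[[paste(cond, s)]] <- data.frame(
        condition = cond, stage = s, type = tree$type[branch],
        pseudotime = t_cell, x = x, y = y, stringsAsFactors = FALSE)
    }
  }
  cells <- do.call(rbind, rows)
  rownames(cells) <- NULL
  n <- nrow(cells)
  cells$cell_id <- sprintf("cell_%05d", seq_len(n))
  # cluster = (type, recorded stage): pure-by-construction input clustering
  cells$cluster <- as.integer(factor(paste(cells$type, cells$stage),
                                     levels = sort(unique(paste(cells$type, cells$stage)))))
  gene_ids <- sprintf("g%04d", seq_len(cfg$n_genes))
  counts <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                 x = numeric(0), dims = c(n, cfg$n_genes))
  table <- cell_table(counts, gene_ids, cells$cell_id, cells$condition,
                      cells$stage, cells$cluster, cell_type = cells$type,
                      embedding = cbind(x = cells$x, y = cells$y))
  truth <- list(cells = data.frame(cell_id = cells$cell_id,
                                   pseudotime = cells$pseudotime,
                                   branch = cells$type,
                                   window_stage = stage_of_pseudotime(
                                     cells$pseudotime, windows),
                                   recorded_stage = cells$stage,
                                   stringsAsFactors = FALSE))
  list(table = table, truth = truth)
}

#' Fill in negative-binomial counts with planted effects
#'
#' Per-gene baseline means are log-normal weights scaled by a log-normal
#' per-cell library factor. A marker gene's mean is multiplied by
#' `exp(marker_log_fold)` in cells of its type; a planted perturbed gene's
#' mean is multiplied by `exp(+-perturb_log_fold)` in organoid cells of the
#' targeted type; cell-cycle phase markers are boosted in cells assigned
#' that phase. Counts are negative binomial with the configured dispersion.
#'
#' @param manifold output of [generate_manifold()].
#' @param cfg the same [synth_config()].
#' @return List with `table` (counts filled) and `truth` extended with
#'   `markers`, `perturbations`, `cycle_markers`, per-cell `phase`, and
#'   `tf_genes` (the planted type-specific regulator panel = the markers).
#' @export
generate_counts <- function(manifold, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  table <- manifold$table
  truth <- manifold$truth
  set.seed(stage_seed(cfg$seed, "counts"))
  n <- table$n_cells
  g <- cfg$n_genes
  types <- RETINAL_CELL_TYPES
  need <- length(types) * cfg$markers_per_type + 2L * cfg$cycle_markers_per_phase
  if (g < need + 10L) {
    abort_validation("n_genes too small for the planted gene panels (need > ",
                     need + 10L, ")")
  }
  gene_ids <- table$gene_ids
  marker_idx <- matrix(seq_len(length(types) * cfg$markers_per_type),
                       nrow = cfg$markers_per_type)
  colnames(marker_idx) <- types
  markers <- data.frame(gene = gene_ids[as.vector(marker_idx)],
                        cell_type = rep(types, each = cfg$markers_per_type),
                        stringsAsFactors = FALSE)
  cyc_start <- length(types) * cfg$markers_per_type
  s_idx <- cyc_start + seq_len(cfg$cycle_markers_per_phase)
  g2m_idx <- cyc_start + cfg$cycle_markers_per_phase +
    seq_len(cfg$cycle_markers_per_phase)
  cycle_markers <- data.frame(
    gene = gene_ids[c(s_idx, g2m_idx)],
    phase = rep(c("S", "G2-M"), each = cfg$cycle_markers_per_phase),
    stringsAsFactors = FALSE)

  # organoid-only perturbations on a fraction of each type's markers,
  # alternating direction
  k_pert <- round(cfg$perturbed_tf_fraction * cfg$markers_per_type)
  pert <- NULL
  if (k_pert > 0 && cfg$perturb_log_fold != 0) {
    pert <- do.call(rbind, lapply(types, function(ty) {
      gi <- marker_idx[seq_len(k_pert), ty]
      data.frame(gene = gene_ids[gi], cell_type = ty,
                 direction = rep_len(c("up", "down"), k_pert),
                 log_fold = cfg$perturb_log_fold, stringsAsFactors = FALSE)
    }))
  } else if (k_pert > 0) {
    pert <- do.call(rbind, lapply(types, function(ty) {
      gi <- marker_idx[seq_len(k_pert), ty]
      data.frame(gene = gene_ids[gi], cell_type = ty,
                 direction = rep_len(c("up", "down"), k_pert),
                 log_fold = 0, stringsAsFactors = FALSE)
    }))
  }

  # cell-cycle phases for progenitors
  phase <- rep("none", n)
  prog <- table$cell_type %in% c("ERPC", "LRPC", "NRPC")
  cycling <- prog & runif(n) < cfg$cycle_fraction
  phase[cycling] <- sample(c("S", "G2-M"), sum(cycling), replace = TRUE)

  base_w <- rlnorm(g, meanlog = 0, sdlog = 1.2)
  base_p <- base_w / sum(base_w)
  lib <- rlnorm(n, cfg$lib_size_meanlog, cfg$lib_size_sdlog)

  counts <- matrix(0L, n, g)
  size <- 1 / cfg$nb_dispersion
  boost <- exp(cfg$marker_log_fold)
  for (ty in types) {
    idx <- which(table$cell_type == ty)
    if (!length(idx)) next
    mult <- rep(1, g)
    mult[marker_idx[, ty]] <- boost
    mu_row <- base_p * mult
    for (cond in CONDITION_LEVELS) {
      ci <- idx[table$condition[idx] == cond]
      if (!length(ci)) next
      mult_c <- mu_row
      if (cond == "organoid" && !is.null(pert)) {
        pr <- pert[pert$cell_type == ty & pert$log_fold != 0, , drop = FALSE]
        if (nrow(pr)) {
          gi <- match(pr$gene, gene_ids)
          mult_c[gi] <- mult_c[gi] *
            exp(ifelse(pr$direction == "up", 1, -1) * pr$log_fold)
        }
      }
      for (ph in c("none", "S", "G2-M")) {
        pi <- ci[phase[ci] == ph]
        if (!length(pi)) next
        mult_p <- mult_c
        if (ph == "S") mult_p[s_idx] <- mult_p[s_idx] * boost
        if (ph == "G2-M") mult_p[g2m_idx] <- mult_p[g2m_idx] * boost
        mu <- outer(lib[pi], mult_p)
        counts[pi, ] <- rnbinom(length(mu), mu = mu, size = size)
      }
    }
  }
  out <- cell_table(counts, gene_ids, table$cell_ids, table$condition,
                    table$stage, table$cluster, cell_type = table$cell_type,
                    embedding = table$embedding)
  truth$markers <- markers
  truth$perturbations <- pert
  truth$cycle_markers <- cycle_markers
  truth$cells$phase <- phase
  truth$tf_genes <- markers$gene
  list(table = out, truth = truth)
}

#' Generate a complete synthetic two-condition dataset
#'
#' Convenience wrapper: [generate_manifold()] then [generate_counts()].
#'
#' @param cfg a [synth_config()].
#' @return List with `table` and `truth`.
#' @export
simulate_retina <- function(cfg = synth_config()) {
  generate_counts(generate_manifold(cfg), cfg)
}

#' Build marker signature sets from generator ground truth
#'
#' @param truth the `truth` component of [simulate_retina()].
#' @param include_cycle also include the S and G2-M phase signatures.
#' @return A named list of gene vectors usable as a signature set or GMT.
#' @export
truth_signatures <- function(truth, include_cycle = TRUE) {
  sets <- split(truth$markers$gene, truth$markers$cell_type)
  sets <- sets[intersect(RETINAL_CELL_TYPES, names(sets))]
  if (include_cycle && !is.null(truth$cycle_markers)) {
    sets <- c(sets, split(truth$cycle_markers$gene, truth$cycle_markers$phase))
  }
  sets
}
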