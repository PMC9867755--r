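#' Euclidean distance in 2D embedding space
#'
#' @param p1,p2 numeric length-2 vectors (x, y).
#' @return `sqrt((x1-x2)^2 + (y1-y2)^2)`.
#' @export
euclid_2d <- function(p1, p2) {
  stopifnot(length(p1) == 2L, length(p2) == 2L,
            all(is.finite(p1)), all(is.finite(p2)))
  sqrt((p1[1L] - p2[1L])^2 + (p1[2L] - p2[2L])^2)
}

#' Mean distance to the n nearest neighbours, for n = 1..n_max
#'
#' For each query point, distances to all other points in the pool are
#' sorted ascending (self excluded) and the value at n is the mean of the
#' first n.
#'
#' @param points numeric matrix (pool x 2) of 2D coordinates.
#' @param query_indices rows of `points` to evaluate (default all).
#' @param n_max largest neighbour count; must be < number of pool points.
#' @return Numeric matrix (queries x n_max): entry `[q, n]` is query q's
#'   mean distance to its n nearest neighbours.
#' @export
knn_mean_distance <- function(points, query_indices = seq_len(nrow(points)),
                              n_max) {
  points <- as.matrix(points)
  n_pool <- nrow(points)
  if (n_pool < n_max + 1L) {
    abort_validation("need at least n_max + 1 = ", n_max + 1L,
                     " points, got ", n_pool)
  }
  out <- matrix(NA_real_, length(query_indices), n_max)
  px <- points[, 1L]; py <- points[, 2L]
  for (qi in seq_along(query_indices)) {
    q <- query_indices[[qi]]
    d <- sqrt((px - px[q])^2 + (py - py[q])^2)
    d <- sort(d[-q], partial = n_max)[seq_len(n_max)]
    out[qi, ] <- cumsum(sort(d)) / seq_len(n_max)
  }
  out
}

#' Trajectory-width curves on the 2D embedding
#'
#' Per replicate: (1) within each developmental stage, the more populated
#' condition is down-sampled without replacement to equalize counts; (2)
#' `n_cells_width` cells are sampled per condition from the balanced pool;
#' (3) each sampled cell's mean distance to its n nearest neighbours
#' (n = 1..n_max) is computed within the balanced pool of its own condition;
#' (4) the per-n curve is the mean over sampled cells. The aggregate curve
#' is the mean across replicates; the envelope is the pointwise min/max.
#'
#' @param table a [cell_table()] with an embedding and both conditions.
#' @param cfg a [pipeline_config()]; uses `n_cells_width`, `n_max`,
#'   `width_replicates`, `rng_seed`.
#' @return A `width_curve_set`: list with `curves` (long data.frame:
#'   condition, replicate, n, mean_distance), `summary` (condition, n, mean,
#'   lo, hi) and `params`.
#' @export
trajectory_width <- function(table, cfg = pipeline_config()) {
  stopifnot(inherits(table, "cell_table"))
  if (is.null(table$embedding)) abort_validation("table has no embedding")
  conds <- CONDITION_LEVELS
  if (!all(conds %in% table$condition)) {
    abort_validation("both conditions must be present")
  }
  set.seed(stage_seed(cfg$rng_seed, "width"))
  stages <- intersect(STAGE_LEVELS, unique(table$stage))
  curves <- list()
  for (rep_i in seq_len(cfg$width_replicates)) {
    # stage-balanced pools, fresh draw per replicate; blocks are ordered by
    # coordinates so the seeded draw is invariant to cell storage order
    pool <- list(native = integer(0), organoid = integer(0))
    for (s in stages) {
      idx <- lapply(conds, function(co) {
        i <- which(table$condition == co & table$stage == s)
        i[order(table$embedding[i, 1L], table$embedding[i, 2L])]
      })
      names(idx) <- conds
      m <- min(lengths(idx))
      for (co in conds) {
        keep <- if (length(idx[[co]]) > m)
          idx[[co]][sample.int(length(idx[[co]]), m)] else idx[[co]]
        pool[[co]] <- c(pool[[co]], keep)
      }
    }
    for (co in conds) {
      pts <- table$embedding[pool[[co]], , drop = FALSE]
      n_pool <- nrow(pts)
      n_max <- cfg$n_max
      if (n_pool < n_max + 1L) {
        log_msg("pool for ", co, " has ", n_pool,
                " cells; capping n_max at ", n_pool - 1L)
        n_max <- n_pool - 1L
      }
      if (n_pool < cfg$n_cells_width) {
        abort_validation("condition ", co, " has only ", n_pool,
                         " cells after stage balancing; need ",
                         cfg$n_cells_width)
      }
      q <- sample.int(n_pool, cfg$n_cells_width)
      m <- knn_mean_distance(pts, q, n_max)
      curves[[paste(co, rep_i)]] <- data.frame(
        condition = co, replicate = rep_i, n = seq_len(n_max),
        mean_distance = colMeans(m), stringsAsFactors = FALSE)
    }
  }
  curves <- do.call(rbind, curves)
  rownames(curves) <- NULL
  summ <- do.call(rbind, lapply(split(
    curves, list(curves$condition, curves$n), drop = TRUE), function(d)
      data.frame(condition = d$condition[1L], n = d$n[1L],
                 mean = mean(d$mean_distance), lo = min(d$mean_distance),
                 hi = max(d$mean_distance), stringsAsFactors = FALSE)))
  summ <- summ[order(summ$condition, summ$n), ]
  rownames(summ) <- NULL
  structure(list(curves = curves, summary = summ,
                 params = list(n_cells = cfg$n_cells_width, n_max = cfg$n_max,
                               replicates = cfg$width_replicates,
                               seed = cfg$rng_seed)),
            class = "width_curve_set")
}

#' Within-stage cell-type diversity by pair resampling
#'
#' Per down-sampling replicate: condition x stage cell counts are equalized
#' by randomly dropping cells from the more populated condition; then, for
#' each condition x stage, `entropy_pairs` unordered pairs of two distinct
#' cells are drawn uniformly (with replacement across pairs) and the sample
#' value is the fraction of pairs whose two cells share a cell-type label --
#' a "1 - entropy"-like concentration statistic whose large-sample
#' expectation is the unbiased Simpson index `sum n_i (n_i - 1) / (N (N-1))`.
#' Higher values mean less diverse.
#'
#' @param table a [cell_table()] with `cell_type` labels.
#' @param cfg a [pipeline_config()]; uses `entropy_pairs`,
#'   `entropy_replicates`, `rng_seed`.
#' @return A `diversity_estimate`: list with `samples` (condition, stage,
#'   replicate, value) and `params`.
#' @export
stage_diversity <- function(table, cfg = pipeline_config()) {
  stopifnot(inherits(table, "cell_table"))
  if (is.null(table$cell_type)) abort_validation("table has no cell_type labels")
  set.seed(stage_seed(cfg$rng_seed, "entropy"))
  stages <- intersect(STAGE_LEVELS, unique(table$stage))
  conds <- CONDITION_LEVELS
  for (s in stages) for (co in conds) {
    if (sum(table$condition == co & table$stage == s) < 2L) {
      abort_validation("condition ", co, ", stage ", s,
                       " has fewer than 2 cells")
    }
  }
  out <- vector("list", cfg$entropy_replicates * length(stages) * length(conds))
  k <- 0L
  for (rep_i in seq_len(cfg$entropy_replicates)) {
    for (s in stages) {
      idx <- lapply(conds, function(co)
        which(table$condition == co & table$stage == s))
      names(idx) <- conds
      m <- min(lengths(idx))
      for (co in conds) {
        # sorted labels make the seeded draw invariant to storage order:
        # the statistic only sees the block's label multiset
        block <- sort(table$cell_type[idx[[co]]])
        labels <- if (length(block) > m)
          block[sample.int(length(block), m)] else block
        a <- sample.int(m, cfg$entropy_pairs, replace = TRUE)
        b <- sample.int(m - 1L, cfg$entropy_pairs, replace = TRUE)
        b <- b + (b >= a)  # second cell distinct from the first
        value <- mean(labels[a] == labels[b])
        k <- k + 1L
        out[[k]] <- data.frame(condition = co, stage = s, replicate = rep_i,
                               value = value, stringsAsFactors = FALSE)
      }
    }
  }
  samples <- do.call(rbind, out)
  structure(list(samples = samples,
                 params = list(pairs = cfg$entropy_pairs,
                               replicates = cfg$entropy_replicates,
                               seed = cfg$rng_seed)),
            class = "diversity_estimate")
}
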