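#' Pipeline configuration with protocol defaults
#'
#' Collects every tunable protocol parameter with its default. Defaults:
#' 500 cells per condition for width curves over n = 1..50 nearest
#' neighbours with 5 down-sampling replicates; 1000 sampled pairs and
#' 100 down-sampling replicates for within-stage diversity; differential
#' expression kept at natural-log fold change >= 0.25 with p <= 0.001
#' (cell-type-specifying) and BH q <= 0.01 (condition contrasts);
#' transcription-factor specificity fold 1.5; profile-correlation threshold
#' r > 0.60; bootstrap 1000 resamples at 99% confidence; 20 principal
#' components ahead of the 3D palette embedding.
#'
#' @param n_cells_width cells sampled per condition for the width curves.
#' @param n_max largest neighbour count n.
#' @param width_replicates down-sampling replicates for the width curves.
#' @param entropy_pairs cell pairs drawn per diversity sample.
#' @param entropy_replicates down-sampling replicates for diversity.
#' @param logfc_min minimum natural-log fold change for specifying genes.
#' @param p_max p-value cutoff for specifying genes.
#' @param q_max BH q-value cutoff for condition contrasts.
#' @param tf_fold specificity fold for transcription factors.
#' @param r_threshold per-gene profile correlation threshold.
#' @param bootstrap_n bootstrap resamples.
#' @param ci_level bootstrap confidence level.
#' @param n_pcs principal components kept before the 3D embedding.
#' @param pseudocount added to mean fractions before log ratios.
#' @param norm_scale scale inside `log1p(norm_scale * fraction)` scoring
#'   normalization.
#' @param margin_min minimum top-vs-second score margin for a confident
#'   cell-type call.
#' @param keep_p enrichment p-value retention cutoff.
#' @param rng_seed integer seed recorded in every output.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_cells_width = 500L, n_max = 50L,
                            width_replicates = 5L, entropy_pairs = 1000L,
                            entropy_replicates = 100L, logfc_min = 0.25,
                            p_max = 0.001, q_max = 0.01, tf_fold = 1.5,
                            r_threshold = 0.60, bootstrap_n = 1000L,
                            ci_level = 0.99, n_pcs = 20L,
                            pseudocount = 1e-9, norm_scale = 1e4,
                            margin_min = 0.05, keep_p = 0.01,
                            rng_seed = 1L) {
  cfg <- list(n_cells_width = as.integer(n_cells_width),
              n_max = as.integer(n_max),
              width_replicates = as.integer(width_replicates),
              entropy_pairs = as.integer(entropy_pairs),
              entropy_replicates = as.integer(entropy_replicates),
              logfc_min = logfc_min, p_max = p_max, q_max = q_max,
              tf_fold = tf_fold, r_threshold = r_threshold,
              bootstrap_n = as.integer(bootstrap_n), ci_level = ci_level,
              n_pcs = as.integer(n_pcs), pseudocount = pseudocount,
              norm_scale = norm_scale, margin_min = margin_min,
              keep_p = keep_p, rng_seed = as.integer(rng_seed))
  counts <- c("n_cells_width", "n_max", "width_replicates", "entropy_pairs",
              "entropy_replicates", "bootstrap_n", "n_pcs")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1L) {
      abort_validation(nm, " must be a positive integer")
    }
  }
  for (nm in c("p_max", "q_max", "ci_level", "keep_p")) {
    if (cfg[[nm]] <= 0 || cfg[[nm]] > 1) {
      abort_validation(nm, " must be in (0, 1]")
    }
  }
  if (cfg$logfc_min < 0) abort_validation("logfc_min must be >= 0")
  if (cfg$tf_fold < 1) abort_validation("tf_fold must be >= 1")
  if (cfg$r_threshold < -1 || cfg$r_threshold > 1) {
    abort_validation("r_threshold must be in [-1, 1]")
  }
  if (is.na(cfg$rng_seed)) abort_validation("rng_seed is required")
  structure(cfg, class = "pipeline_config")
}
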