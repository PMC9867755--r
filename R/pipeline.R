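#' Run the full comparative pipeline from a YAML config
#'
#' Chains all analysis stages on either a synthetic dataset (config block
#' `synthetic:`) or a 10x-style MTX bundle (config block `inputs:` with
#' `matrix`, `genes`, `barcodes`, `metadata`, and `signatures` GMT), and
#' writes every stage output as TSV plus a machine-readable JSON manifest.
#' Re-running with the same config and seed reproduces all stochastic
#' outputs bit-for-bit. `rng_seed` is required.
#'
#' Stages: simulate (or load), annotate (signature scoring, cell-type and
#' cycle-phase assignment), width (trajectory-width curves), entropy
#' (within-stage diversity), de (cell-type-specifying genes, condition
#' contrasts, TF specificity), enrich (per-type hypergeometric enrichment),
#' palette (found-entity similarity colours), correlate (native vs organoid
#' profile correlation).
#'
#' @param config path to a YAML config file, or an equivalent named list.
#' @param outdir output directory; overrides the config's `outdir`.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  cfg_in <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg_in$rng_seed)) {
    abort_validation("config must set rng_seed")
  }
  outdir <- outdir %||% cfg_in$outdir %||% "retcomp_out"
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  params <- cfg_in$params %||% list()
  params$rng_seed <- cfg_in$rng_seed
  cfg <- do.call(pipeline_config, params)
  manifest <- list(seed = cfg$rng_seed, stages = list())
  tsv <- function(d, name) {
    path <- file.path(outdir, name)
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  run_stage <- function(name, fn) {
    files <- tryCatch(fn(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- list(files = basename(unlist(files)))
    log_msg("stage ", name, " done")
  }

  truth <- NULL
  table <- NULL
  signatures <- NULL
  if (!is.null(cfg_in$synthetic)) {
    run_stage("simulate", function() {
      sc_args <- cfg_in$synthetic
      sc_args$seed <- cfg$rng_seed
      sc <- do.call(synth_config, sc_args)
      sim <- simulate_retina(sc)
      table <<- sim$table
      truth <<- sim$truth
      signatures <<- truth_signatures(truth)
      bundle <- write_cell_table(table, file.path(outdir, "synthetic"))
      c(bundle,
        tsv(truth$cells, "ground_truth_cells.tsv"),
        tsv(truth$markers, "ground_truth_markers.tsv"),
        if (!is.null(truth$perturbations))
          tsv(truth$perturbations, "ground_truth_perturbations.tsv"))
    })
  } else if (!is.null(cfg_in$inputs)) {
    run_stage("load", function() {
      inp <- cfg_in$inputs
      table <<- load_cell_table(inp$matrix, inp$genes, inp$barcodes,
                                inp$metadata)
      if (is.null(inp$signatures)) {
        abort_validation("inputs block requires a 'signatures' GMT path")
      }
      signatures <<- read_gmt(inp$signatures)
      character(0)
    })
  } else {
    abort_validation("config needs a 'synthetic' or 'inputs' block")
  }

  expr <- normalize_fraction_umi(table)
  assigned_type <- table$cell_type

  run_stage("annotate", function() {
    scores <- score_signatures(expr, signatures, by = "cluster",
                               cluster = table$cluster,
                               norm_scale = cfg$norm_scale)
    assign <- assign_cell_types(scores, margin_min = cfg$margin_min)
    assigned_type <<- assign$label[match(as.character(table$cluster),
                                         assign$id)]
    files <- tsv(assign, "cell_type_assignments.tsv")
    if (all(c("S", "G2-M") %in% names(signatures))) {
      phase <- assign_cycle_phase(expr, signatures,
                                  norm_scale = cfg$norm_scale)
      files <- c(files, tsv(phase, "cycle_phase.tsv"))
    }
    files
  })

  run_stage("width", function() {
    w <- trajectory_width(table, cfg)
    c(tsv(w$curves, "width_curves.tsv"), tsv(w$summary, "width_summary.tsv"))
  })

  run_stage("entropy", function() {
    d <- stage_diversity(table, cfg)
    tsv(d$samples, "diversity.tsv")
  })

  specifying <- NULL
  run_stage("de", function() {
    specifying <<- cell_type_specifying(expr, assigned_type, cfg)
    contrasts <- condition_contrast(expr, assigned_type, table$condition, cfg)
    files <- c(tsv(specifying, "specifying_genes.tsv"),
               tsv(contrasts, "condition_contrasts.tsv"))
    tf_genes <- if (!is.null(truth)) truth$tf_genes else cfg_in$tf_list
    if (!is.null(tf_genes)) {
      tfl <- if (length(tf_genes) == 1L && file.exists(tf_genes))
        read_gene_list(tf_genes) else gene_list("tf", tf_genes)
      tfa <- tf_specificity(expr, assigned_type, specifying, tfl,
                            fold = cfg$tf_fold,
                            pseudocount = cfg$pseudocount)
      files <- c(files, tsv(tfa, "tf_annotation.tsv"))
    }
    files
  })

  enrichment <- NULL
  run_stage("enrich", function() {
    sets <- if (!is.null(cfg_in$gene_sets)) read_gmt(cfg_in$gene_sets)
      else signatures
    universe <- gene_list("detected", table$gene_ids)
    if (is.null(specifying) || !nrow(specifying)) {
      log_msg("no specifying genes; enrichment skipped")
      return(character(0))
    }
    per_type <- split(specifying$gene, specifying$cell_type)
    rows <- lapply(names(per_type), function(ty)
      enrich_collection(gene_list(ty, per_type[[ty]]), sets, universe,
                        keep_p = cfg$keep_p))
    enrichment <<- do.call(rbind, rows)
    tsv(enrichment, "enrichment.tsv")
  })

  run_stage("palette", function() {
    if (is.null(enrichment) || nrow(enrichment) < 2L) {
      log_msg("fewer than 2 enrichment results; palette skipped")
      return(character(0))
    }
    pal <- palette_from_enrichment(enrichment, n_pcs = cfg$n_pcs,
                                   seed = cfg$rng_seed)
    tsv(pal, "palette.tsv")
  })

  run_stage("correlate", function() {
    genes <- gene_list("profiled",
                       if (!is.null(truth)) truth$markers$gene
                       else table$gene_ids)
    keep_nat <- table$condition == "native"
    sub <- function(sel) {
      e <- expr
      e$values <- expr$values[sel, , drop = FALSE]
      e$cell_ids <- expr$cell_ids[sel]
      e$zero_count_cells <- intersect(expr$zero_count_cells, e$cell_ids)
      e
    }
    pa <- mean_profile_matrix(sub(keep_nat), assigned_type[keep_nat], genes)
    pb <- mean_profile_matrix(sub(!keep_nat), assigned_type[!keep_nat], genes)
    pc <- profile_correlation(pa, pb, r_threshold = cfg$r_threshold)
    summary <- list(median_r = pc$median_r, n_above = pc$n_above,
                    percent_above = pc$percent_above,
                    n_zero_variance = pc$n_zero_variance, seed = cfg$rng_seed)
    path <- file.path(outdir, "correlation_summary.json")
    jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA)
    c(tsv(pc$per_gene, "correlations.tsv"), path)
  })

  manifest$package_version <- as.character(utils::packageVersion("retcomp"))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  writeLines(paste0("seed\t", cfg$rng_seed), file.path(outdir, "seed.log"))
  invisible(manifest)
}
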