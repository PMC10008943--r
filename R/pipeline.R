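# End-to-end orchestration: simulate (or load) -> batch adjust -> DEG ->
# core genes -> NMF subtyping -> signature/D.score -> stratify -> response
# association. One master seed; per-stage streams derived deterministically.
# A run manifest (resolved config, input digests, stage status, outputs) is
# written even on failure.

#' Default pipeline configuration
#'
#' Returns the configuration list used by [run_pipeline()]; any element can
#' be overridden. The `simulate` block holds the synthetic meta-cohort
#' parameters; set `expression`/`annotations`/`depression_genes` paths
#' instead to run on existing files.
#'
#' @param seed Master seed.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    simulate = list(enabled = TRUE, n_per_batch = 60, n_batches = 3,
                    n_genes = 500, n_core = 33, effect_sd = 1.0,
                    batch_sd = 0.5, noise_sd = 1.0, healthy_fraction = 0.25,
                    n_depression_extra = 120),
    expression = NULL, annotations = NULL, depression_genes = NULL,
    inflammation_panel = NULL,
    deg = list(p_adj = 0.05, min_lfc = 0.2),
    nmf = list(k = 2, k_range = NULL, n_runs = 30, max_iter = 2000,
               tol = 1e-6, nonneg_mode = "offset"),
    dscore = list(split = "median"),
    response = list(simulate = TRUE, beta0 = -0.85, beta1 = 1.5)
  )
}

read_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_config()
  modifyList(base, config)
}

file_digest <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

#' Run the subtyping pipeline end to end
#'
#' Executes the stages in dependency order, writing flat TSV/JSON outputs
#' plus a run-manifest JSON into `out_dir`. With `resume = TRUE` a stage is
#' skipped when its outputs exist and its recorded input digests are
#' unchanged. All randomness flows from `config$seed`.
#'
#' @param config Configuration list (see [default_config()]) or path to a
#'   YAML file.
#' @param out_dir Output directory (created if needed).
#' @param resume Skip stages whose outputs are present and up to date.
#' @return The run manifest (invisibly a list; also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config = default_config(), out_dir = "ibddep_run",
                         resume = FALSE) {
  cfg <- read_config(if (is.list(config)) config else config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed
  path <- function(f) file.path(out_dir, f)

  old_manifest <- NULL
  if (resume && file.exists(path("manifest.json"))) {
    old_manifest <- jsonlite::read_json(path("manifest.json"),
                                        simplifyVector = TRUE)
  }
  manifest <- list(config = cfg, seed = seed, stages = list(),
                   input_digests = list())
  write_manifest <- function() {
    jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, force = TRUE, digits = NA)
  }

  stage_env <- new.env(parent = emptyenv())
  run_stage <- function(name, inputs, outputs, fun) {
    in_digest <- file_digest(inputs)
    old <- old_manifest$stages[[name]]
    if (resume && !is.null(old) && identical(old$status, "completed") &&
        all(file.exists(unlist(old$outputs))) &&
        identical(old$input_digests, in_digest)) {
      manifest$stages[[name]] <<- old
      manifest$stages[[name]]$status <<- "skipped"
      message("stage ", name, ": up to date, skipped")
      return(invisible(NULL))
    }
    res <- tryCatch({
      fun()
      list(status = "completed")
    }, error = function(e) list(status = "failed", error = conditionMessage(e)))
    manifest$stages[[name]] <<- c(res, list(outputs = outputs,
                                            input_digests = in_digest))
    if (res$status == "failed") {
      write_manifest()
      stop("stage '", name, "' failed: ", res$error, call. = FALSE)
    }
    invisible(NULL)
  }

  # ---- inputs / simulation -------------------------------------------------
  run_stage("inputs", character(0),
            c(path("expression.tsv"), path("annotations.tsv"),
              path("depression_genes.txt")), function() {
    if (isTRUE(cfg$simulate$enabled) && is.null(cfg$expression)) {
      sp <- cfg$simulate
      sim <- simulate_ibd_cohorts(
        n_per_batch = sp$n_per_batch, n_batches = sp$n_batches,
        n_genes = sp$n_genes, n_core = sp$n_core, effect_sd = sp$effect_sd,
        batch_sd = sp$batch_sd, noise_sd = sp$noise_sd,
        healthy_fraction = sp$healthy_fraction,
        seed = derive_seed(seed, "stage_simulate"))
      stage_env$x <- sim$expression
      stage_env$ann <- sim$annotations
      stage_env$truth <- sim$truth
      # depression list: planted core genes plus random decoys
      set.seed(derive_seed(seed, "stage_depression_list"))
      decoys <- sample(setdiff(rownames(sim$expression),
                               sim$truth$core_genes$gene_id),
                       min(sp$n_depression_extra,
                           nrow(sim$expression) - sp$n_core))
      stage_env$depression_genes <- c(sim$truth$core_genes$gene_id, decoys)
      stage_env$panel <- sim$truth$core_genes$gene_id[
        sim$truth$core_genes$effect > 0]
      jsonlite::write_json(sim$truth, path("ground_truth.json"),
                           auto_unbox = TRUE, digits = NA)
    } else {
      if (is.null(cfg$expression) || is.null(cfg$annotations)) {
        stop("expression and annotations paths are required when simulation is disabled")
      }
      stage_env$x <- read_expression(cfg$expression)
      stage_env$ann <- read_annotations(cfg$annotations)
      if (!is.null(cfg$depression_genes)) {
        stage_env$depression_genes <-
          if (length(cfg$depression_genes) == 1 &&
              file.exists(cfg$depression_genes)) {
            readLines(cfg$depression_genes)
          } else cfg$depression_genes
      }
      stage_env$panel <- cfg$inflammation_panel
    }
    write_expression(stage_env$x, path("expression.tsv"))
    write_annotations(stage_env$ann, path("annotations.tsv"))
    if (!is.null(stage_env$depression_genes)) {
      writeLines(stage_env$depression_genes, path("depression_genes.txt"))
    }
  })

  # ---- batch adjustment ----------------------------------------------------
  run_stage("batch_adjust", path("expression.tsv"),
            path("expression_adjusted.tsv"), function() {
    stage_env$x_adj <- combat_adjust(stage_env$x, stage_env$ann)
    write_expression(stage_env$x_adj, path("expression_adjusted.tsv"))
  })

  # ---- cohort-level DEGs and core genes ------------------------------------
  run_stage("deg", path("expression_adjusted.tsv"), path("deg.tsv"),
            function() {
    ann <- stage_env$ann
    healthy <- ann$sample_id[ann$condition == "healthy"]
    ibd <- ann$sample_id[ann$condition == "IBD"]
    stage_env$deg <- moderated_ttest(stage_env$x_adj, healthy, ibd)
    utils::write.table(stage_env$deg, path("deg.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })

  run_stage("core_genes", path("deg.tsv"), path("core_genes.txt"),
            function() {
    if (is.null(stage_env$depression_genes)) {
      stop("depression gene list is required for the core-gene intersection")
    }
    degs <- select_degs(stage_env$deg, p_adj_max = cfg$deg$p_adj,
                        abs_lfc_min = cfg$deg$min_lfc)
    core <- intersect_core_genes(degs, stage_env$depression_genes)
    if (!length(core)) stop("empty core-gene panel; cannot subtype")
    stage_env$core <- core
    writeLines(core, path("core_genes.txt"))
  })

  # ---- NMF consensus subtyping --------------------------------------------
  run_stage("subtype", c(path("expression_adjusted.tsv"),
                         path("core_genes.txt")),
            c(path("subtypes.tsv"), path("consensus.tsv"),
              path("rank_diagnostics.json")), function() {
    ann <- stage_env$ann
    ibd <- ann$sample_id[ann$condition == "IBD"]
    a <- to_nonnegative(stage_env$x_adj[stage_env$core, ibd, drop = FALSE],
                        mode = cfg$nmf$nonneg_mode)
    nmf_seed <- derive_seed(seed, "stage_subtype")
    if (!is.null(cfg$nmf$k_range)) {
      sel <- select_rank(a, k_range = cfg$nmf$k_range,
                         n_runs = cfg$nmf$n_runs, seed = nmf_seed,
                         max_iter = cfg$nmf$max_iter, tol = cfg$nmf$tol)
      stage_env$consensus <- sel$results[[paste0("k", sel$k)]]
      diag_out <- list(k = sel$k, diagnostics = sel$diagnostics,
                       low_confidence = sel$low_confidence)
    } else {
      stage_env$consensus <- consensus_cluster(
        a, k = cfg$nmf$k, n_runs = cfg$nmf$n_runs, seed = nmf_seed,
        max_iter = cfg$nmf$max_iter, tol = cfg$nmf$tol)
      diag_out <- list(k = cfg$nmf$k,
                       cophenetic = stage_env$consensus$cophenetic,
                       dispersion = stage_env$consensus$dispersion,
                       silhouette = stage_env$consensus$silhouette)
    }
    if (stage_env$consensus$k != 2) {
      stop("selected rank is not 2; subtype orientation undefined")
    }
    panel <- stage_env$panel
    if (is.null(panel) || !length(panel)) panel <- stage_env$core
    stage_env$subtypes <- assign_subtypes(stage_env$consensus,
                                          stage_env$x_adj, panel)
    utils::write.table(
      data.frame(sample_id = names(stage_env$subtypes),
                 subtype = stage_env$subtypes),
      path("subtypes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(stage_env$consensus$consensus, path("consensus.tsv"),
                       sep = "\t", quote = FALSE)
    jsonlite::write_json(diag_out, path("rank_diagnostics.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  # ---- signature genes and D.score ----------------------------------------
  run_stage("dscore", c(path("expression_adjusted.tsv"), path("subtypes.tsv")),
            c(path("signature_genes.txt"), path("dscore.tsv")), function() {
    ibd <- names(stage_env$subtypes)
    sig <- signature_degs(stage_env$x_adj[, ibd, drop = FALSE],
                          stage_env$subtypes,
                          p_adj_max = cfg$deg$p_adj,
                          abs_lfc_min = cfg$deg$min_lfc)
    if (length(sig) < 3) stop("fewer than 3 signature genes")
    writeLines(sig, path("signature_genes.txt"))
    sc <- compute_dscore(stage_env$x_adj[sig, ibd, drop = FALSE],
                         stage_env$subtypes)
    stage_env$scores <- stratify(sc, rule = cfg$dscore$split)
    utils::write.table(stage_env$scores, path("dscore.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })

  # ---- response association ------------------------------------------------
  run_stage("response", path("dscore.tsv"), path("association.json"),
            function() {
    sc <- stage_env$scores
    resp <- if (isTRUE(cfg$response$simulate)) {
      simulate_response(stats::setNames(sc$dscore, sc$sample_id),
                        beta0 = cfg$response$beta0,
                        beta1 = cfg$response$beta1,
                        seed = derive_seed(seed, "stage_response"))
    } else {
      stats::setNames(stage_env$ann$response, stage_env$ann$sample_id)[
        sc$sample_id]
    }
    assoc <- response_association(stats::setNames(sc$stratum, sc$sample_id),
                                  resp)
    jsonlite::write_json(
      list(table = assoc$table, statistic = assoc$statistic,
           p_value = assoc$p_value, odds_ratio = assoc$odds_ratio),
      path("association.json"), auto_unbox = TRUE, digits = NA, force = TRUE)
  })

  manifest$input_digests <- file_digest(c(path("expression.tsv"),
                                          path("annotations.tsv"),
                                          path("depression_genes.txt")))
  write_manifest()
  invisible(manifest)
}
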