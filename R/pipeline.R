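#' Default pipeline configuration
#'
#' One nested list drives every stage; stage defaults equal the analysis
#' defaults used throughout the package (QC thresholds per modality, the
#' eight-term composition model, LTSR > 0.9 / proportion > 0.05
#' significance, MYH threshold 0.5, 5% ligand-receptor filter).
#'
#' @param out_dir artifact directory
#' @param seed global seed; every stage draws from a named substream
#' @return configuration list
#' @export
default_run_config <- function(out_dir = tempfile("myoaging_run_"), seed = 1) {
  list(
    seed = seed,
    out_dir = out_dir,
    stages = c(simulate = TRUE, qc = TRUE, composition = TRUE, deg = TRUE,
               fibertype = TRUE, cross_species = TRUE, interactions = TRUE),
    composition_truth = list(n_cell_types = 8, n_donors = 20,
                             libraries_per_donor = 2,
                             planted_cell_type = 1, planted_age_logfc = 1.0),
    expression_truth = list(n_genes = 120, n_cells_per_sample = 100,
                            n_deg = 10, deg_log2fc = 1.5),
    deg = list(covariates = c("chemistry", "modality"),
               ltsr_cutoff = 0.9, prop_cutoff = 0.05),
    qc = list(max_doublet_score = 0.4),
    fibertype = list(threshold = 0.5, unclassified_cutoff = 0.75,
                     test = "mannwhitney"),
    cross_species = list(retention = 0.7, n_noise = 5, alpha = 0.05),
    interactions = list(threshold = 0.05)
  )
}

read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_run_config()
  utils::modifyList(base, cfg)
}

validate_run_config <- function(config) {
  req <- c("seed", "out_dir", "stages")
  if (!all(req %in% names(config))) {
    stop("invalid config: missing ", paste(setdiff(req, names(config)), collapse = ", "))
  }
  if (!is.numeric(config$seed)) stop("invalid config: seed must be numeric")
  invisible(config)
}

#' Run the full synthetic analysis pipeline
#'
#' Executes simulate, qc, composition, deg, fibertype, cross_species and
#' interactions in dependency order, writing each stage's tables under
#' `config$out_dir` with stable formatting so identical (config, seed)
#' runs are byte-identical. Every stage's randomness comes from a named
#' substream of the global seed.
#'
#' @param config list from [default_run_config()] (or a YAML file read by
#'   the same schema)
#' @return a run report (list, also written as run_report.json):
#'   per-stage row counts, parameter echo, seed, package version, timing
#' @export
run_pipeline <- function(config = default_run_config()) {
  validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed,
                 version = as.character(utils::packageVersion("myoaging")),
                 stages = list())
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    if (!isTRUE(config$stages[[name]])) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    report$stages[[name]] <<- c(res, list(seconds = round(proc.time()[["elapsed"]] - t0, 2)))
    invisible(NULL)
  }

  run_stage("simulate", function() {
    ct_cfg <- config$composition_truth
    logfc <- rep(0, ct_cfg$n_cell_types)
    logfc[ct_cfg$planted_cell_type] <- ct_cfg$planted_age_logfc
    ctruth <- composition_truth(
      cell_types = paste0("CT", seq_len(ct_cfg$n_cell_types)),
      n_donors = ct_cfg$n_donors,
      libraries_per_donor = ct_cfg$libraries_per_donor,
      age_logfc = logfc)
    sim <- simulate_composition(ctruth, derive_seed(config$seed, "simulate_composition"))
    write_tsv_stable(sim$composition, file.path(config$out_dir, "composition.tsv"))
    write_tsv_stable(sim$samples, file.path(config$out_dir, "samples.tsv"))
    write_tsv_stable(
      data.frame(cell_type = ctruth$cell_types,
                 baseline_log_abundance = unname(ctruth$baseline_log_abundance),
                 age_logfc = unname(ctruth$age_logfc)),
      file.path(config$out_dir, "composition_truth.tsv"))

    ex_cfg <- config$expression_truth
    etruth <- expression_truth(
      n_genes = ex_cfg$n_genes,
      n_cells_per_sample = ex_cfg$n_cells_per_sample,
      deg_indices = seq_len(ex_cfg$n_deg),
      deg_log2fc = ex_cfg$deg_log2fc)
    sce <- simulate_expression(etruth, sim$samples,
                               derive_seed(config$seed, "simulate_expression"))
    write_mtx_dir(sce, file.path(config$out_dir, "counts"))

    fx <- make_fixture_tables(derive_seed(config$seed, "fixtures"),
                              genes = sprintf("gene%04d", seq_len(ex_cfg$n_genes)))
    write_tsv_stable(fx$homologs, file.path(config$out_dir, "homologs.tsv"))
    write_gmt(fx$gene_sets, file.path(config$out_dir, "gene_sets.gmt"))
    write_tsv_stable(fx$lr_pairs, file.path(config$out_dir, "lr_pairs.tsv"))

    state$sim <- sim; state$sce <- sce; state$fixtures <- fx
    list(n_libraries = nrow(sim$samples), n_cells = ncol(sce),
         n_genes = nrow(sce))
  })

  run_stage("qc", function() {
    sce <- state$sce
    metrics <- compute_qc_metrics(sce)
    kept <- character()
    removed <- c(doublet = 0, genes = 0, counts = 0, mito = 0)
    for (mod in unique(SummarizedExperiment::colData(sce)$modality)) {
      idx <- SummarizedExperiment::colData(sce)$modality == mod
      # synthetic libraries are far shallower than real tissue data, so the
      # depth bounds are opened up while the strict doublet/mito rules apply
      p <- qc_params(mod, min_genes = 1, max_genes = 1e9,
                     min_counts = 1, max_counts = 1e9,
                     max_doublet_score = config$qc$max_doublet_score)
      fr <- filter_cells(sce[, idx], metrics[idx, , drop = FALSE], p)
      kept <- c(kept, fr$report$kept_barcodes)
      removed <- removed + fr$report$removed
    }
    state$sce_qc <- sce[, colnames(sce) %in% kept]
    qc_tab <- metrics
    qc_tab$kept <- metrics$barcode %in% kept
    write_tsv_stable(qc_tab, file.path(config$out_dir, "qc_metrics.tsv"))
    list(n_input = ncol(sce), n_kept = length(kept),
         removed = as.list(removed))
  })

  run_stage("composition", function() {
    fit <- fit_composition_glmm(state$sim$composition, state$sim$samples)
    eff <- celltype_age_effects(fit)
    write_tsv_stable(eff, file.path(config$out_dir, "composition_effects.tsv"))
    state$composition_effects <- eff
    list(n_cell_types = nrow(eff), converged = fit$converged,
         n_significant = sum(eff$significant))
  })

  run_stage("deg", function() {
    sce <- if (!is.null(state$sce_qc)) state$sce_qc else state$sce
    genes <- grep("^gene", rownames(sce), value = TRUE)
    fits <- fit_aging_degs(sce, covariates = config$deg$covariates,
                           genes = genes)
    degs <- call_aging_degs(fits, ltsr_cutoff = config$deg$ltsr_cutoff,
                            prop_cutoff = config$deg$prop_cutoff)
    write_tsv_stable(degs, file.path(config$out_dir, "aging_degs.tsv"))
    state$degs <- degs
    list(n_genes = nrow(degs), n_significant = sum(degs$significant))
  })

  run_stage("fibertype", function() {
    sce <- if (!is.null(state$sce_qc)) state$sce_qc else state$sce
    norm <- normalize_log(SummarizedExperiment::assay(sce, "counts"))
    expr <- t(as.matrix(norm[c("MYH7", "MYH2", "MYH1"), , drop = FALSE]))
    calls <- classify_myonuclei(expr, threshold = config$fibertype$threshold)
    cd <- SummarizedExperiment::colData(sce)
    props <- donor_proportions(calls, cd$donor, cd$age_group,
                               unclassified_cutoff = config$fibertype$unclassified_cutoff)
    write_tsv_stable(calls, file.path(config$out_dir, "myonuclei_calls.tsv"))
    write_tsv_stable(props, file.path(config$out_dir, "myonuclei_proportions.tsv"))
    use <- props[!props$excluded, ]
    tests <- lapply(setdiff(MYH_CLASSES, "unclassified"), function(cl) {
      x <- use[[cl]][use$age_group == "young"]
      y <- use[[cl]][use$age_group == "aged"]
      if (length(x) < 2 || length(y) < 2) return(NULL)
      r <- compare_age_groups(x, y, test = config$fibertype$test)
      data.frame(class = cl, statistic = r$statistic, p_value = r$p_value,
                 stringsAsFactors = FALSE)
    })
    tests <- do.call(rbind, tests)
    if (!is.null(tests)) {
      write_tsv_stable(tests, file.path(config$out_dir, "myonuclei_age_tests.tsv"))
    }
    list(n_nuclei = nrow(calls), n_donors = nrow(props),
         n_excluded_donors = sum(props$excluded))
  })

  run_stage("cross_species", function() {
    degs <- state$degs
    fx <- state$fixtures
    sig <- degs[degs$significant, ]
    human_sets <- data.frame(cell_type = "all",
                             direction = ifelse(sig$logfc_age >= 0, "up", "down"),
                             gene = sig$gene, stringsAsFactors = FALSE)
    # synthetic mouse DEG sets: homolog-mapped human calls with partial
    # retention plus noise genes (known overlap by construction)
    cs_seed <- derive_seed(config$seed, "cross_species")
    mouse_sets <- with_seed(cs_seed, {
      per_dir <- lapply(c("up", "down"), function(dr) {
        h <- human_sets$gene[human_sets$direction == dr]
        h <- h[stats::runif(length(h)) < config$cross_species$retention]
        mg <- map_homologs(h, fx$homologs)$mapped
        if (length(mg) == 0) return(NULL)
        data.frame(cell_type = "all", direction = dr, gene = mg,
                   stringsAsFactors = FALSE)
      })
      noise <- paste0("m", sample(sprintf("gene%04d",
                                          seq_len(config$expression_truth$n_genes)),
                                  config$cross_species$n_noise))
      rbind(do.call(rbind, per_dir),
            data.frame(cell_type = "all", direction = "up", gene = noise,
                       stringsAsFactors = FALSE))
    })
    jac <- cross_species_jaccard(human_sets, mouse_sets, fx$homologs)
    write_tsv_stable(jac, file.path(config$out_dir, "cross_species_jaccard.tsv"))

    universe_h <- degs$gene[degs$prop_expressed > 0.05]
    enr <- lapply(c("up", "down"), function(dr) {
      h <- human_sets$gene[human_sets$direction == dr]
      r <- ora_hypergeometric(h, fx$gene_sets, universe_h)
      r$cell_type <- "all"; r$direction <- dr
      r
    })
    enr_h <- do.call(rbind, enr)
    universe_m <- map_homologs(universe_h, fx$homologs)$mapped
    pathways_m <- lapply(fx$gene_sets, function(g) map_homologs(g, fx$homologs)$mapped)
    enr_m <- do.call(rbind, lapply(c("up", "down"), function(dr) {
      mset <- mouse_sets$gene[mouse_sets$direction == dr]
      mset <- intersect(mset, universe_m)
      r <- ora_hypergeometric(mset, pathways_m, universe_m)
      r$cell_type <- "all"; r$direction <- dr
      r
    }))
    write_tsv_stable(enr_h, file.path(config$out_dir, "enrichment_human.tsv"))
    write_tsv_stable(enr_m, file.path(config$out_dir, "enrichment_mouse.tsv"))
    co <- coenrichment_score(enr_h, enr_m, alpha = config$cross_species$alpha)
    write_tsv_stable(co, file.path(config$out_dir, "coenrichment.tsv"))
    list(n_jaccard_rows = nrow(jac), n_coenriched = sum(co$n_celltypes > 0))
  })

  run_stage("interactions", function() {
    sce <- if (!is.null(state$sce_qc)) state$sce_qc else state$sce
    props <- expression_proportion(sce)
    calls <- filter_interactions(state$fixtures$lr_pairs, props,
                                 threshold = config$interactions$threshold)
    write_tsv_stable(calls, file.path(config$out_dir, "interaction_calls.tsv"))
    list(n_calls = nrow(calls), n_retained = sum(calls$retained))
  })

  jsonlite::write_json(report, file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
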