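#' Pipeline configuration
#'
#' Collects every stage parameter and input of the end-to-end analysis. Two
#' input modes: synthetic (default; `sim` drives the generator) or file-based
#' (paths to metabolome/transcriptome matrix + metadata TSVs in the layout
#' written by [write_omics_tsv()]).
#'
#' One global `seed` fans out to per-stage seeds by a fixed counter scheme
#' (seed + 0 generator, +1/+2 forests, +3 k-means, +4 PLS-DA validation), so
#' stages stay reproducible without sharing random-number state.
#'
#' @param outdir output directory (created if needed).
#' @param seed global integer seed.
#' @param sim a [sim_config()] (its own seed is overridden by `seed`).
#' @param metabolome_path,metabolome_metadata,transcriptome_path,transcriptome_metadata
#'   optional TSV paths; when all four are given, files replace the generator.
#' @param annotation optional named list (term -> feature/gene ids) or GMT
#'   path, used by the cascade and enrichment stages.
#' @param edges optional edge-list data.frame or TSV path for hub ranking.
#' @param n_trees,n_importance_repeats forest settings.
#' @param vip_threshold,p_threshold DAM rule.
#' @param lfc_threshold,fdr_threshold DEG rule.
#' @param top_k cascade candidate count.
#' @param kmeans_k expression-pattern count.
#' @param power,min_module_size,merge_cut_height,cut_height network settings.
#' @param importance_quantile,consistency_threshold categorization settings.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1L, sim = sim_config(),
                            metabolome_path = NULL, metabolome_metadata = NULL,
                            transcriptome_path = NULL,
                            transcriptome_metadata = NULL,
                            annotation = NULL, edges = NULL,
                            n_trees = 1000, n_importance_repeats = 10,
                            vip_threshold = 1.0, p_threshold = 0.05,
                            lfc_threshold = 1, fdr_threshold = 0.05,
                            top_k = 100, kmeans_k = 12,
                            power = 9, min_module_size = 50,
                            merge_cut_height = 0.25, cut_height = 0.97,
                            importance_quantile = 0.8,
                            consistency_threshold = 0.8) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  class(cfg) <- "pipeline_config"
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes generate/load -> differential metabolites (PLS-DA + t-tests, per
#' genotype, extreme vs control temperature) -> differential genes (edgeR,
#' same contrast) -> Venn overlap and k-means expression patterns ->
#' genotype-stratified random forests with consistency categorization ->
#' biomarker cascade -> co-expression modules with biomarker traits ->
#' hub ranking and enrichment (when edge list / annotation inputs are
#' present) -> a convergence table of items supported by at least two
#' evidence streams. Every table is written as TSV (JSON for nested
#' results) under `config$outdir`, and a JSON manifest records parameters,
#' derived seeds, per-stage status and output paths.
#'
#' A stage failure halts the run with the stage name, after writing the
#' manifest with the failure recorded.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly (list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  path <- function(...) file.path(config$outdir, ...)
  manifest <- list(package = "thermomark",
                   version = as.character(utils::packageVersion("thermomark")),
                   seed = config$seed,
                   seed_scheme = "seed+0 generator, +1/+2 forests (sensitive/tolerant), +3 kmeans, +4 validation",
                   parameters = config[!(names(config) %in%
                                           c("annotation", "edges", "sim"))],
                   sim = if (is.null(config$metabolome_path)) unclass(config$sim),
                   stages = list(), outputs = list())
  manifest$parameters$outdir <- NULL
  env <- new.env()

  stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
      jsonlite::write_json(manifest, path("manifest.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(res),
           call. = FALSE)
    }
    manifest$stages[[name]] <<- list(status = "ok")
    res
  }

  ## -- data ------------------------------------------------------------
  stage("data", function() {
    if (!is.null(config$metabolome_path)) {
      env$met <- read_omics_tsv(config$metabolome_path,
                                config$metabolome_metadata, "metabolome")
      env$txn <- read_omics_tsv(config$transcriptome_path,
                                config$transcriptome_metadata, "transcriptome")
      env$truth <- NULL
    } else {
      sim <- config$sim
      sim$seed <- config$seed
      ds <- simulate_dataset(sim)
      env$met <- ds$metabolome
      env$txn <- ds$transcriptome
      env$truth <- ds$truth
      write_truth_json(ds$truth, path("truth.json"))
    }
    write_omics_tsv(env$met, path("metabolome.tsv"),
                    path("metabolome_metadata.tsv"))
    write_omics_tsv(env$txn, path("transcriptome.tsv"),
                    path("transcriptome_metadata.tsv"))
    manifest$outputs$metabolome <<- path("metabolome.tsv")
    manifest$outputs$transcriptome <<- path("transcriptome.tsv")
  })

  md_m <- env$met$metadata
  temps <- sort(unique(md_m$temperature_C))
  t_lo <- temps[1]; t_hi <- temps[length(temps)]
  genotypes <- sort(unique(md_m$genotype))

  ## -- differential metabolites ---------------------------------------
  stage("dam", function() {
    env$dams <- list()
    for (g in genotypes) {
      keep <- md_m$genotype == g & md_m$temperature_C %in% c(t_lo, t_hi)
      sub <- subset_samples(env$met, keep)
      cls <- factor(sub$metadata$temperature_C)
      fit <- plsda(sub, cls, n_components = 2)
      a_ids <- sub$metadata$sample_id[sub$metadata$temperature_C == t_lo]
      b_ids <- sub$metadata$sample_id[sub$metadata$temperature_C == t_hi]
      tests <- univariate_tests(sub, a_ids, b_ids)
      dams <- select_dams(fit, tests, config$vip_threshold,
                          config$p_threshold)
      env$dams[[g]] <- dams
      write_tsv(dams, path(sprintf("dam_%s.tsv", g)))
    }
    manifest$outputs$dam <<- path(sprintf("dam_%s.tsv", genotypes))
  })

  ## -- differential genes ----------------------------------------------
  stage("deg", function() {
    md_t <- env$txn$metadata
    env$degs <- list()
    for (g in genotypes) {
      a_ids <- md_t$sample_id[md_t$genotype == g & md_t$temperature_C == t_lo]
      b_ids <- md_t$sample_id[md_t$genotype == g & md_t$temperature_C == t_hi]
      degs <- select_degs(env$txn, a_ids, b_ids,
                          config$lfc_threshold, config$fdr_threshold)
      env$degs[[g]] <- degs
      write_tsv(degs, path(sprintf("deg_%s.tsv", g)))
    }
    sets <- lapply(env$degs, function(d) d$feature_id[d$selected])
    venn <- venn_overlap(sets)
    jsonlite::write_json(venn, path("deg_venn.json"), digits = NA)
    union_degs <- unique(unlist(sets))
    if (length(union_degs) > config$kmeans_k) {
      km <- kmeans_patterns(env$txn$values[union_degs, , drop = FALSE],
                            k = config$kmeans_k, seed = config$seed + 3L)
      write_tsv(data.frame(gene_id = names(km$cluster),
                           cluster = as.integer(km$cluster)),
                path("deg_kmeans.tsv"))
    }
    manifest$outputs$deg <<- path(sprintf("deg_%s.tsv", genotypes))
  })

  ## -- forests + consistency -------------------------------------------
  stage("forest", function() {
    profs <- list()
    for (i in seq_along(genotypes)) {
      g <- genotypes[i]
      fc <- forest_config(config$n_trees, config$n_importance_repeats,
                          seed = config$seed + i)
      forest <- temperature_forest(subset_genotype(env$met, g), fc)
      profs[[g]] <- mda_importance(forest)
      write_tsv(cbind(profs[[g]], genotype = g,
                      oob_accuracy = attr(profs[[g]], "oob_accuracy")),
                path(sprintf("importance_%s.tsv", g)))
    }
    ga <- setdiff(genotypes, "tolerant")[1]
    gb <- if ("tolerant" %in% genotypes) "tolerant" else genotypes[2]
    env$report <- categorize_features(
      profs[[ga]], profs[[gb]],
      importance_quantile = config$importance_quantile,
      consistency_threshold = config$consistency_threshold)
    write_tsv(env$report$features, path("consistency.tsv"))
    jsonlite::write_json(
      list(spearman_rho = env$report$spearman_rho,
           spearman_p = env$report$spearman_p,
           category_counts = as.list(env$report$category_counts)),
      path("consistency_summary.json"), auto_unbox = TRUE, digits = NA)
    manifest$outputs$consistency <<- path("consistency.tsv")
  })

  ## -- biomarker cascade -------------------------------------------------
  stage("cascade", function() {
    model <- if ("tolerant" %in% genotypes) "tolerant" else "b"
    cand <- top_candidates(env$report, k = config$top_k, model = model)
    panel <- expression_filter(cand, env$met,
                               p_threshold = config$p_threshold,
                               tolerant = if ("tolerant" %in% genotypes)
                                 "tolerant" else genotypes[2],
                               sensitive = if ("sensitive" %in% genotypes)
                                 "sensitive" else genotypes[1],
                               control_temperature = t_lo)
    ann <- config$annotation
    if (is.character(ann) && length(ann) == 1) ann <- read_gmt(ann)
    if (!is.null(ann)) panel <- annotate_panel(panel, ann)
    env$panel <- panel
    write_tsv(panel, path("biomarker_panel.tsv"))
    manifest$outputs$panel <<- path("biomarker_panel.tsv")
  })

  ## -- co-expression modules + traits ------------------------------------
  stage("modules", function() {
    ms <- coexpression_modules(env$txn, power = config$power,
                               min_module_size = config$min_module_size,
                               merge_cut_height = config$merge_cut_height,
                               cut_height = config$cut_height)
    trait_ids <- utils::head(env$panel$feature_id, 9)
    if (length(trait_ids) >= 1 && nrow(ms$eigengenes) >= 1) {
      traits <- align_traits(env$met, trait_ids, env$txn$metadata)
      ms$trait_cor <- module_trait_correlation(ms$eigengenes, traits)
      mt <- expand.grid(module = rownames(ms$trait_cor$r),
                        trait = colnames(ms$trait_cor$r),
                        stringsAsFactors = FALSE)
      mt$r <- as.vector(ms$trait_cor$r)
      mt$p <- as.vector(ms$trait_cor$p)
      write_tsv(mt, path("module_trait.tsv"))
    }
    env$modules <- ms
    write_tsv(data.frame(gene_id = names(ms$labels),
                         module = unname(ms$labels)),
              path("module_labels.tsv"))
    write_tsv(data.frame(module = rownames(ms$eigengenes), ms$eigengenes,
                         check.names = FALSE),
              path("module_eigengenes.tsv"))
    manifest$outputs$modules <<- path("module_labels.tsv")
  })

  ## -- hubs (optional: needs an interaction edge list) -------------------
  stage("hubs", function() {
    if (is.null(config$edges)) {
      manifest$stages$hubs <<- list(status = "skipped (no edge list)")
      return(invisible(NULL))
    }
    graph <- if (is.character(config$edges)) read_edge_list(config$edges)
             else interaction_graph(config$edges)
    kim <- intramodular_connectivity(env$modules$adjacency,
                                     env$modules$labels)
    focus <- focus_module(env$modules)
    hubs <- degree_rank(graph, top_n = 50,
                        module_filter = if (is.null(focus)) NULL
                        else names(env$modules$labels)[
                          env$modules$labels == focus])
    hubs$kim <- kim$kim[match(hubs$gene_id, kim$gene_id)]
    hubs$module <- kim$module[match(hubs$gene_id, kim$gene_id)]
    env$hubs <- hubs
    write_tsv(hubs, path("hubs.tsv"))
    manifest$outputs$hubs <<- path("hubs.tsv")
  })

  ## -- enrichment (optional: needs annotation) ----------------------------
  stage("enrichment", function() {
    ann <- config$annotation
    if (is.character(ann) && length(ann) == 1) ann <- read_gmt(ann)
    if (is.null(ann)) {
      manifest$stages$enrichment <<- list(status = "skipped (no annotation)")
      return(invisible(NULL))
    }
    mods <- setdiff(unique(env$modules$labels), "grey")
    if (!length(mods)) {
      manifest$stages$enrichment <<- list(status = "skipped (no modules)")
      return(invisible(NULL))
    }
    res <- lapply(mods, function(m) {
      genes <- names(env$modules$labels)[env$modules$labels == m]
      cbind(module = m,
            suppressWarnings(enrich(genes, ann,
                                    universe = names(env$modules$labels))))
    })
    env$enrichment <- do.call(rbind, res)
    write_tsv(env$enrichment, path("enrichment.tsv"))
    manifest$outputs$enrichment <<- path("enrichment.tsv")
  })

  ## -- convergence -------------------------------------------------------
  stage("convergence", function() {
    gb <- if ("tolerant" %in% genotypes) "tolerant" else genotypes[2]
    streams <- list(
      dam = env$dams[[gb]]$feature_id[env$dams[[gb]]$selected],
      rf_category = env$report$features$feature_id[
        env$report$features$category %in% c("shared", paste0(gb, "_favored"))],
      panel = env$panel$feature_id,
      deg = env$degs[[gb]]$feature_id[env$degs[[gb]]$selected],
      module = names(env$modules$labels)[env$modules$labels != "grey"],
      hub = if (!is.null(env$hubs)) env$hubs$gene_id else character(),
      enriched_term = if (!is.null(env$enrichment))
        unique(env$enrichment$term[env$enrichment$padj < 0.05])
        else character(),
      panel_category = if (!is.null(env$panel$categories))
        setdiff(unique(unlist(strsplit(env$panel$categories, ";"))),
                "unclassified")
        else character())
    items <- unique(unlist(streams))
    hits <- vapply(items, function(it)
      sum(vapply(streams, function(s) it %in% s, logical(1))), integer(1))
    supp <- vapply(items, function(it)
      paste(names(streams)[vapply(streams, function(s) it %in% s,
                                  logical(1))], collapse = ";"), character(1))
    conv <- data.frame(item = items, n_streams = hits, streams = supp,
                       stringsAsFactors = FALSE)
    conv <- conv[conv$n_streams >= 2, , drop = FALSE]
    conv <- conv[order(-conv$n_streams, conv$item), , drop = FALSE]
    write_tsv(conv, path("convergence.tsv"))
    env$convergence <- conv
    manifest$outputs$convergence <<- path("convergence.tsv")
  })

  jsonlite::write_json(manifest, path("manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

# the module most strongly correlated (|r|) with any trait, else the largest
focus_module <- function(module_set) {
  if (nrow(module_set$eigengenes) == 0) return(NULL)
  if (!is.null(module_set$trait_cor))
    return(rownames(module_set$trait_cor$r)[
      which.max(apply(abs(module_set$trait_cor$r), 1, max))])
  rownames(module_set$eigengenes)[1]
}
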