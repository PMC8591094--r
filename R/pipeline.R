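# End-to-end pipeline orchestration: simulate (or load) inputs, then
# de -> seeds -> network -> cluster -> score -> classify -> survive ->
# enrich, writing one artifact set per stage plus a manifest.

pipeline_known_keys <- c(
  "simulate", "rng_seed", "fc_cut", "q_cut", "hops", "min_nodes",
  "expansion", "inflation", "self_loop_weight", "prune_threshold",
  "max_iter", "tol", "svm_cost", "synthetic", "paths", "linear_input")

#' Build and validate a pipeline configuration
#'
#' Unknown keys are rejected so a typo cannot silently fall back to a
#' default. In simulation mode (`simulate = TRUE`, the default) all inputs
#' are generated from the `synthetic` spec; otherwise `paths` must name
#' `expression`, `classes`, `cna`, `edges` and (optionally) `clinical` and
#' `annotations` files.
#'
#' @param ... Configuration values overriding the defaults; see
#'   [synthetic_spec()] for the `synthetic` block and [mcl_cluster()] for
#'   the clustering parameters.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  unknown <- setdiff(names(user), pipeline_known_keys)
  if (length(unknown))
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  cfg <- list(simulate = TRUE, rng_seed = 1L, fc_cut = 2, q_cut = 0.05,
              hops = 1L, min_nodes = 3L, expansion = 2L, inflation = 2.0,
              self_loop_weight = 1.0, prune_threshold = 1e-5,
              max_iter = 200L, tol = 1e-8, svm_cost = 1,
              synthetic = list(), paths = list(), linear_input = FALSE)
  cfg[names(user)] <- user
  cfg$synthetic <- do.call(synthetic_spec,
                           c(cfg$synthetic,
                             if (is.null(cfg$synthetic$rng_seed))
                               list(rng_seed = cfg$rng_seed)))
  if (!cfg$simulate) {
    need <- c("expression", "classes", "cna", "edges")
    miss <- setdiff(need, names(cfg$paths))
    if (length(miss))
      stopf("paths must name input file(s): %s", paste(miss, collapse = ", "))
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file path.
#' @return A validated [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full subnetwork-marker pipeline
#'
#' Executes every stage in order, writing each stage's artifacts under
#' `out_dir` and a `manifest.json` recording parameters and MD5 hashes of
#' all inputs and outputs. The manifest carries no timestamps, so two runs
#' with identical configuration and inputs produce byte-identical output
#' trees. A stage failure halts the run with the stage name in the error;
#' artifacts of completed stages are retained.
#'
#' In simulation mode three cohorts are generated from the same planted
#' truth: a training cohort (classifier and subnetwork definitions), an
#' independent validation cohort (classification evaluation and risk-model
#' fitting on its cases), and an external cohort (frozen-coefficient
#' survival validation). The true risk driving simulated survival is the
#' mean expression of the planted differential genes, signed by their
#' planted direction.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of in-memory stage results plus
#'   `manifest_path`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(parameters = unclass(config)[
    setdiff(pipeline_known_keys, c("paths", "synthetic"))])
  manifest$parameters$synthetic <- unclass(config$synthetic)
  stages <- list()
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stopf("pipeline halted at stage '%s': %s", name, conditionMessage(e))
    })
  }

  # -- inputs ----------------------------------------------------------
  inputs <- run_stage("simulate", function() {
    if (config$simulate) {
      spec <- config$synthetic
      train <- gen_expression(spec, cohort = "train")
      valid <- gen_expression(spec, de_truth = train$de_truth,
                              cohort = "valid")
      extern <- gen_expression(spec, de_truth = train$de_truth,
                               cohort = "extern")
      ppi <- gen_ppi(spec, train$de_truth)
      dir.create(file.path(out_dir, "inputs"), showWarnings = FALSE)
      write_expression(train$expr, file.path(out_dir, "inputs", "expression_train.tsv"))
      writeLines(ppi$cna_genes, file.path(out_dir, "inputs", "cna_genes.txt"))
      utils::write.table(ppi$edges, file.path(out_dir, "inputs", "interactions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
      list(train = train$expr, valid = valid$expr, extern = extern$expr,
           de_truth = train$de_truth, cna = ppi$cna_genes,
           edges = ppi$edges, blocks = ppi$blocks)
    } else {
      p <- config$paths
      for (f in unlist(p)) if (!file.exists(f)) stopf("input file not found: %s", f)
      expr <- read_expression(p$expression, p$classes,
                              linear_input = config$linear_input)
      list(train = expr, valid = expr, extern = NULL,
           de_truth = NULL,
           cna = read_gene_list(p$cna),
           edges = read_edge_list(p$edges, dialect = p$edges_dialect %||% "tsv2"),
           clinical = if (!is.null(p$clinical)) read_clinical(p$clinical),
           annotations = if (!is.null(p$annotations)) read_gmt(p$annotations))
    }
  })
  stages$inputs <- inputs

  # -- differential expression and seeds -------------------------------
  de <- run_stage("de", function() {
    res <- differential_expression(inputs$train)
    res$selected <- res$gene %in% select_degs(res, config$fc_cut, config$q_cut)
    utils::write.table(res, file.path(out_dir, "differential_expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res
  })
  stages$de <- de
  seeds <- run_stage("seeds", function() {
    degs <- de$gene[de$selected]
    if (!length(degs)) stopf("no differentially expressed genes")
    s <- suppressMessages(intersect_seeds(degs, inputs$cna))
    if (!length(s)) stopf("empty seed set: DEG and CNA lists are disjoint")
    writeLines(s, file.path(out_dir, "seed_genes.txt"))
    s
  })
  stages$seeds <- seeds

  # -- network + clustering --------------------------------------------
  net <- run_stage("network", function() {
    g <- expand_network(seeds, inputs$edges, hops = config$hops)
    write_network(g, file.path(out_dir, "network.sif"))
    g
  })
  stages$network <- net
  subnets <- run_stage("cluster", function() {
    mcl <- mcl_cluster(net, expansion = config$expansion,
                       inflation = config$inflation,
                       self_loop_weight = config$self_loop_weight,
                       prune_threshold = config$prune_threshold,
                       max_iter = config$max_iter, tol = config$tol)
    memb <- data.frame(node = names(mcl$membership),
                       cluster_id = unname(mcl$membership),
                       is_seed = names(mcl$membership) %in% seeds)
    utils::write.table(memb, file.path(out_dir, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sn <- filter_subnetworks(mcl, seeds, min_nodes = config$min_nodes)
    sn <- assign_directions(sn, inputs$train)
    write_subnetworks(sn, file.path(out_dir, "subnetworks.gmt"))
    attr(sn, "n_clusters") <- length(mcl$clusters)
    sn
  })
  stages$subnetworks <- subnets

  # -- scoring ----------------------------------------------------------
  scores <- run_stage("score", function() {
    sc <- list(train = score_cohort(subnets, inputs$train),
               valid = score_cohort(subnets, inputs$valid))
    if (!is.null(inputs$extern))
      sc$extern <- score_cohort(subnets, inputs$extern)
    utils::write.table(data.frame(subnetwork = rownames(sc$train), sc$train,
                                  check.names = FALSE),
                       file.path(out_dir, "scores_train.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sc
  })
  stages$scores <- scores

  # -- classification ---------------------------------------------------
  eval_res <- run_stage("classify", function() {
    model <- train_svm(scores$train, inputs$train$class_labels,
                       cost = config$svm_cost)
    ev <- evaluate(model, scores$valid, inputs$valid$class_labels)
    metrics <- ev[c("tp", "fn", "fp", "tn", "accuracy", "sensitivity",
                    "specificity", "auc")]
    metrics$auc_ci <- ev$auc_ci
    jsonlite::write_json(metrics, file.path(out_dir, "classification.json"),
                         auto_unbox = TRUE, digits = NA)
    pca <- pca_project(scores$train)
    utils::write.table(data.frame(sample = rownames(pca$coords), pca$coords),
                       file.path(out_dir, "pca_train.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ev
  })
  stages$classification <- eval_res

  # -- survival ---------------------------------------------------------
  surv <- run_stage("survive", function() {
    if (config$simulate) {
      spec <- config$synthetic
      true_risk_of <- function(expr) {
        z <- zscore(expr)$values
        tr <- inputs$de_truth[inputs$de_truth$gene %in% rownames(z), ]
        colSums(z[tr$gene, , drop = FALSE] * tr$sign) / nrow(tr)
      }
      cases_v <- names(inputs$valid$class_labels)[
        inputs$valid$class_labels == "case"]
      clin_v <- gen_survival(true_risk_of(inputs$valid)[cases_v], spec)
      cases_e <- names(inputs$extern$class_labels)[
        inputs$extern$class_labels == "case"]
      spec_e <- spec; spec_e$rng_seed <- spec$rng_seed + 1L
      clin_e <- gen_survival(true_risk_of(inputs$extern)[cases_e], spec_e)
    } else {
      if (is.null(inputs$clinical)) return(NULL)
      clin_v <- inputs$clinical
      clin_e <- NULL
    }
    sc_v <- scores$valid[, clin_v$sample, drop = FALSE]
    model <- fit_risk_model(sc_v, clin_v)
    rs <- risk_score(sc_v, model)
    groups <- stratify_median(rs, model$threshold)
    km <- km_logrank(clin_v, groups)
    utils::write.table(model$fit_table, file.path(out_dir, "cox_subnetworks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(sample = names(rs), risk = unname(rs),
                                  group = unname(groups)),
                       file.path(out_dir, "risk_groups.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(km$curves, file.path(out_dir, "km_curves.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out <- list(model = model, risk = rs, groups = groups, km = km)
    if (!is.null(clin_e)) {
      out$external <- external_validation(
        scores$extern[, clin_e$sample, drop = FALSE], model, clin_e)
      out$external_clinical <- clin_e
    }
    jsonlite::write_json(
      list(logrank_chisq = km$chisq, logrank_p = km$p_value,
           external_logrank_p = if (!is.null(out$external))
             out$external$km$p_value),
      file.path(out_dir, "logrank.json"), auto_unbox = TRUE, digits = NA)
    out
  })
  stages$survival <- surv

  # -- enrichment -------------------------------------------------------
  enr <- run_stage("enrich", function() {
    sets <- if (config$simulate) {
      split(names(inputs$blocks), paste0("block_", inputs$blocks))
    } else inputs$annotations
    if (is.null(sets)) return(NULL)
    query <- unique(unlist(lapply(subnets, `[[`, "members")))
    res <- enrich(query, sets,
                  background = unique(rownames(inputs$train$values)))
    utils::write.table(res, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res
  })
  stages$enrichment <- enr

  # -- manifest ---------------------------------------------------------
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  manifest$files <- lapply(files, function(f) {
    list(path = f, md5 = unname(tools::md5sum(file.path(out_dir, f))))
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  stages$manifest_path <- file.path(out_dir, "manifest.json")
  invisible(stages)
}
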