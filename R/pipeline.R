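#' Write simulated studies to plain-text files
#'
#' One TSV per study (probes x samples), one annotation TSV per study
#' (`probe_id`, comma-joined RefSeq set), one labels TSV
#' (`study_id`, `sample_id`, `label`), and a GMT file of the planted gene
#' sets when a configuration is supplied.
#'
#' @param studies List of [study_matrix()] objects.
#' @param dir Output directory (created if needed).
#' @param cfg Optional [sim_config()] used to also write `planted_sets.gmt`.
#' @return `dir`, invisibly.
#' @export
write_studies <- function(studies, dir, cfg = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labs <- purrr::map_dfr(studies, function(s)
    tibble::tibble(study_id = s$study_id, sample_id = colnames(s$values),
                   label = s$labels))
  utils::write.table(labs, file.path(dir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (s in studies) {
    utils::write.table(
      data.frame(probe_id = rownames(s$values), s$values, check.names = FALSE),
      file.path(dir, paste0(s$study_id, "_expression.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    ann <- tibble::tibble(
      probe_id = rownames(s$values),
      refseq = vapply(s$annotations, paste, "", collapse = ","))
    utils::write.table(ann, file.path(dir, paste0(s$study_id, "_annotation.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(cfg)) {
    sets <- planted_gene_sets(cfg)
    write_gmt(sets, file.path(dir, "planted_sets.gmt"))
  }
  invisible(dir)
}

#' Read one study from its expression and annotation TSVs
#'
#' @param study_id Study name.
#' @param expression_tsv Probes x samples TSV with a `probe_id` column.
#' @param annotation_tsv TSV with columns `probe_id`, `refseq` (comma-joined).
#' @param labels Per-sample labels in column order.
#' @return A [study_matrix()].
#' @export
read_study <- function(study_id, expression_tsv, annotation_tsv, labels) {
  ex <- utils::read.delim(expression_tsv, check.names = FALSE)
  vals <- as.matrix(ex[, -1, drop = FALSE])
  rownames(vals) <- ex$probe_id
  ann <- utils::read.delim(annotation_tsv, stringsAsFactors = FALSE)
  ann_list <- stats::setNames(strsplit(ann$refseq, ","), ann$probe_id)
  study_matrix(study_id, vals, ann_list, labels)
}

#' Configuration for an end-to-end meta-analysis run
#'
#' @param sim A [sim_config()] for the synthetic studies.
#' @param n_delta NSC threshold-grid size.
#' @param C DWD penalty (`NULL` = per-step heuristic).
#' @param plan Merge order (`NULL` = descending study size).
#' @param filter_prop Non-specific variance filter for the DE stage.
#' @param gsea_B Permutation draws for the set test.
#' @param cross_study Compute the pre/post cross-study accuracy matrices
#'   (the most expensive stage)?
#' @return A `meta_run_config` list.
#' @export
meta_config <- function(sim = sim_config(), n_delta = 30, C = NULL,
                        plan = NULL, filter_prop = 0.2, gsea_B = 2000,
                        cross_study = TRUE) {
  stopifnot(inherits(sim, "sim_config"))
  structure(list(sim = sim, n_delta = n_delta, C = C, plan = plan,
                 filter_prop = filter_prop, gsea_B = gsea_B,
                 cross_study = cross_study),
            class = "meta_run_config")
}

#' Run the meta-analysis pipeline end to end
#'
#' simulate -> collapse probes -> intersect features -> merge -> quantile
#' normalize -> sequential DWD integration -> NSC leave-one-out CV ->
#' cross-study matrices (pre/post integration) -> moderated-t differential
#' expression -> competitive gene-set test on the planted sets. All stage
#' outputs can be persisted under one run directory; rerunning with the same
#' configuration (which contains the seed) reproduces the report exactly.
#'
#' @param config A [meta_config()].
#' @param out_dir Optional directory for persisted stage outputs and
#'   `report.json`.
#' @return A `meta_report` list (see fields in the report JSON).
#' @export
run_meta <- function(config = meta_config(), out_dir = NULL) {
  stopifnot(inherits(config, "meta_run_config"))
  t0 <- Sys.time()
  studies <- simulate_studies(config$sim)
  mapped <- lapply(studies, collapse_probes)
  probe_counts <- purrr::map_dfr(mapped, function(m) tibble::tibble(
    study_id = m$study_id,
    probes_in = attr(m, "n_probes_in"),
    features_out = nrow(m$values),
    probes_dropped = attr(m, "n_dropped")))

  single_study <- length(mapped) < 2
  if (single_study) {
    message("single study: feature intersection and DWD integration skipped")
    shared <- rownames(mapped[[1]]$values)
    merged <- merge_studies(mapped)
  } else {
    mapped <- intersect_features(mapped)
    shared <- attr(mapped, "shared_features")
    merged <- merge_studies(mapped)
  }
  normalized <- quantile_normalize(merged)

  if (single_study) {
    integrated <- normalized
    provenance <- tibble::tibble()
  } else {
    integrated <- sequential_merge(normalized, plan = config$plan, C = config$C)
    provenance <- attr(integrated, "provenance")
  }

  cv <- nsc_loocv(integrated$values, integrated$labels, n_delta = config$n_delta)
  signature <- nsc_active_genes(cv$model, cv$chosen_delta)

  cross <- NULL
  if (config$cross_study) {
    pre <- cross_study_matrix(split_merged(normalized), n_delta = config$n_delta)
    post <- cross_study_matrix(split_merged(integrated), n_delta = config$n_delta)
    cross <- dplyr::bind_rows(
      dplyr::mutate(pre, stage = "before_dwd", .before = 1),
      dplyr::mutate(post, stage = "after_dwd", .before = 1))
  }

  de <- moderated_t_table(integrated$values, integrated$labels, "PTC",
                          filter_prop = config$filter_prop)
  tt <- stats::setNames(de$t, de$feature)
  sets <- planted_gene_sets(config$sim)
  gsea <- set_test(tt, sets, direction = attr(sets, "direction"),
                   B = config$gsea_B, seed = config$sim$seed)

  report <- structure(list(
    seed = config$sim$seed,
    n_studies = length(studies),
    probe_counts = probe_counts,
    n_shared_features = length(shared),
    integration = provenance,
    chosen_delta = cv$chosen_delta,
    n_active_genes = length(signature),
    signature = signature,
    loocv_accuracy = cv$accuracy,
    cross_study = cross,
    top_gene = de$feature[1],
    top_gene_logfc = de$logfc[1],
    de_table = de,
    set_test = gsea,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "meta_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_studies(studies, file.path(out_dir, "input"), config$sim)
    utils::write.table(
      data.frame(feature = rownames(integrated$values), integrated$values,
                 check.names = FALSE),
      file.path(out_dir, "integrated_expression.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(de, file.path(out_dir, "de_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(gsea, file.path(out_dir, "set_test.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(cross))
      utils::write.table(cross, file.path(out_dir, "cross_study.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    .write_json(report_to_json(report), file.path(out_dir, "report.json"))
  }
  report
}

#' @export
print.meta_report <- function(x, ...) {
  cat("<meta_report> ", x$n_studies, " studies, ", x$n_shared_features,
      " shared features\n  loocv accuracy ", format(x$loocv_accuracy),
      " with ", x$n_active_genes, " active gene(s); top DE feature ",
      x$top_gene, " (logFC ", format(round(x$top_gene_logfc, 2)), ")\n",
      sep = "")
  invisible(x)
}

# stable, fully numeric/character representation of a report for JSON output
report_to_json <- function(report) {
  squash <- function(x) {
    if (inherits(x, "data.frame")) lapply(as.list(x), squash) else x
  }
  out <- lapply(report, squash)
  out$elapsed_s <- NULL   # timing is the one legitimately non-reproducible field
  out
}

#' Configuration for the qPCR validation arm
#'
#' @param qpcr A [qpcr_config()] for the synthetic plate.
#' @param policy Threshold policy for [roc_threshold()].
#' @param threshold Fixed decision threshold on the normalised expression; if
#'   given, ROC selection is skipped and this value is applied directly.
#' @return A `qpcr_run_config` list.
#' @export
qpcr_run_config <- function(qpcr = qpcr_config(), policy = "max-sens",
                            threshold = NULL) {
  stopifnot(inherits(qpcr, "qpcr_config"))
  structure(list(qpcr = qpcr, policy = policy, threshold = threshold),
            class = "qpcr_run_config")
}

#' Run the qPCR validation arm end to end
#'
#' simulate plate -> geNorm stability ranking of the candidate reference
#' assays -> relative quantification of the target against the most stable
#' reference -> ROC threshold selection (PTC vs everything else) -> confusion
#' metrics.
#'
#' @param config A [qpcr_run_config()].
#' @param out_dir Optional directory for persisted outputs and `report.json`.
#' @return A `qpcr_report` list.
#' @export
run_qpcr <- function(config = qpcr_run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "qpcr_run_config"))
  cfg <- config$qpcr
  ct <- simulate_qpcr(cfg)

  refs <- cfg$assays$assay[cfg$assays$role == "reference"]
  target <- cfg$assays$assay[cfg$assays$role == "target"]
  mean_ct <- .mean_ct(dplyr::filter(ct, .data$assay %in% refs))
  qmat <- mean_ct %>%
    dplyr::mutate(q = 2^-.data$ct) %>%
    dplyr::select("sample_id", "assay", "q") %>%
    tidyr::pivot_wider(names_from = "assay", values_from = "q")
  stability <- genorm_stability(as.matrix(qmat[refs]))
  reference <- attr(stability, "chosen")

  quant <- relative_quantity(ct, target, reference)
  truth <- quant$entity
  if (is.null(config$threshold)) {
    roc <- roc_threshold(quant$quantity, truth, "PTC", policy = config$policy)
    threshold <- roc$threshold
  } else {
    roc <- roc_threshold(quant$quantity, truth, "PTC", policy = config$policy)
    threshold <- config$threshold
  }
  predicted <- quant$quantity > threshold
  metrics <- confusion_metrics(predicted, truth, "PTC")
  # fold change as a ratio of geometric means: the natural summary for
  # log2-scale qPCR quantities, and unbiased for a planted log2 shift
  fold <- 2^(mean(log2(quant$quantity[truth == "PTC"])) -
             mean(log2(quant$quantity[truth != "PTC"])))
  pval <- stats::t.test(log2(quantity) ~ truth == "PTC", data = quant)$p.value
  per_entity <- quant %>%
    dplyr::group_by(.data$entity) %>%
    dplyr::summarise(n = dplyr::n(),
                     median_quantity = stats::median(.data$quantity),
                     n_called_positive = sum(.data$quantity > threshold),
                     .groups = "drop")

  report <- structure(list(
    seed = cfg$seed,
    n_samples = nrow(quant),
    reference_assay = reference,
    stability = stability,
    threshold = threshold,
    policy = config$policy,
    fold_change_ptc = fold,
    p_value_log2 = pval,
    metrics = metrics,
    per_entity = per_entity,
    auc = roc$auc
  ), class = "qpcr_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_ct_table(ct, file.path(out_dir, "ct_table.csv"))
    utils::write.table(quant, file.path(out_dir, "normalised_expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(roc$roc, file.path(out_dir, "roc_points.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .write_json(report_to_json(unclass(report)), file.path(out_dir, "report.json"))
  }
  report
}

#' @export
print.qpcr_report <- function(x, ...) {
  cat("<qpcr_report> ", x$n_samples, " samples; reference ", x$reference_assay,
      "; threshold ", format(round(x$threshold, 3)),
      "; PTC fold-change ", format(round(x$fold_change_ptc, 1)),
      "\n  sens ", format(x$metrics$sens), ", spec ",
      format(round(x$metrics$spec, 3)), ", accuracy ",
      format(round(100 * x$metrics$accuracy, 1)), "%\n", sep = "")
  invisible(x)
}

#' Load a run configuration from YAML
#'
#' The YAML file holds a `kind` field (`"meta"` or `"qpcr"`) and nested
#' blocks passed to the respective constructors ([sim_config()] /
#' [meta_config()] or [qpcr_config()] / [qpcr_run_config()]).
#'
#' @param path YAML path.
#' @return A `meta_run_config` or `qpcr_run_config`.
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  kind <- y$kind %||% "meta"
  if (kind == "meta") {
    sim <- do.call(sim_config, y$sim %||% list())
    do.call(meta_config, c(list(sim = sim), y$analysis %||% list()))
  } else if (kind == "qpcr") {
    qp <- y$qpcr %||% list()
    if (!is.null(qp$entity_counts)) qp$entity_counts <- unlist(qp$entity_counts)
    if (!is.null(qp$assays)) qp$assays <- dplyr::bind_rows(qp$assays)
    qpcr <- do.call(qpcr_config, qp)
    do.call(qpcr_run_config, c(list(qpcr = qpcr), y$analysis %||% list()))
  } else stop("unknown config kind: ", kind)
}
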