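#' Configure the synthetic multi-study generator
#'
#' Builds a validated configuration for [simulate_studies()]. The defaults
#' emulate the shape of the motivating meta-analysis cohort: four Affymetrix
#' studies totalling 47 carcinoma (PTC) and 52 benign samples, one dominant
#' marker gene at log2 fold-change 3.3, one 20-gene up-regulated
#' extracellular-matrix-like set at +1.5, six 15-gene down-regulated
#' metabolic-like sets at -1, strong per-study per-gene additive dataset bias,
#' and partially overlapping probe universes with duplicate probes.
#'
#' @param n_studies Number of studies.
#' @param n_ptc,n_benign Integer vectors of per-study class sizes (length
#'   `n_studies`).
#' @param n_genes Size of the shared gene universe.
#' @param platform_coverage Fraction of the universe covered per study, in
#'   (0, 1]. Planted marker and pathway genes are always covered so the planted
#'   structure survives the cross-study feature intersection.
#' @param duplicate_probe_rate Fraction of covered genes carried by two probes
#'   (both probes annotate to the identical RefSeq set).
#' @param multi_refseq_rate Fraction of genes whose annotation set holds two
#'   RefSeq-like identifiers (exercises set-keyed matching).
#' @param marker_spec Data frame with columns `gene`, `logfc`: planted marker
#'   effects (added to PTC samples only).
#' @param pathway_spec Data frame with columns `set_id`, `gene`, `logfc`:
#'   planted co-regulated set membership and common effects.
#' @param batch_sd SD of the per-study per-gene additive dataset bias
#'   (log2 units).
#' @param noise_sd Residual per-probe-per-sample SD (log2 units).
#' @param baseline_mean,baseline_sd Gene baseline distribution (log2 units).
#' @param seed Integer seed fixing the full output bit-for-bit.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_studies = 4,
                       n_ptc = c(9, 8, 23, 7),
                       n_benign = c(9, 8, 28, 7),
                       n_genes = 2000,
                       platform_coverage = 0.85,
                       duplicate_probe_rate = 0.10,
                       multi_refseq_rate = 0.10,
                       marker_spec = default_marker_spec(),
                       pathway_spec = default_pathway_spec(),
                       batch_sd = 1.0,
                       noise_sd = 0.5,
                       baseline_mean = 8,
                       baseline_sd = 1.5,
                       seed = 1L) {
  stopifnot(n_studies >= 1,
            length(n_ptc) == n_studies, length(n_benign) == n_studies,
            all(n_ptc >= 0), all(n_benign >= 0),
            n_genes >= 1,
            platform_coverage > 0, platform_coverage <= 1,
            duplicate_probe_rate >= 0, duplicate_probe_rate <= 1,
            multi_refseq_rate >= 0, multi_refseq_rate <= 1,
            batch_sd >= 0, noise_sd >= 0, baseline_sd >= 0)
  genes <- sprintf("g%04d", seq_len(n_genes))
  marker_spec <- tibble::as_tibble(marker_spec)
  pathway_spec <- tibble::as_tibble(pathway_spec)
  if (nrow(marker_spec) && !all(marker_spec$gene %in% genes))
    stop("marker genes must lie inside the gene universe")
  if (nrow(pathway_spec) && !all(pathway_spec$gene %in% genes))
    stop("pathway genes must lie inside the gene universe")
  structure(
    list(n_studies = n_studies, n_ptc = as.integer(n_ptc),
         n_benign = as.integer(n_benign), n_genes = as.integer(n_genes),
         genes = genes,
         platform_coverage = platform_coverage,
         duplicate_probe_rate = duplicate_probe_rate,
         multi_refseq_rate = multi_refseq_rate,
         marker_spec = marker_spec, pathway_spec = pathway_spec,
         batch_sd = batch_sd, noise_sd = noise_sd,
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Default planted marker: one gene at log2 fold-change 3.3
#' @return Tibble with columns `gene`, `logfc`.
#' @export
default_marker_spec <- function() {
  tibble::tibble(gene = "g0001", logfc = 3.3)
}

#' Default planted gene sets
#'
#' One 20-gene up-regulated "ECM-like" set at +1.5 and six 15-gene
#' down-regulated "metabolic-like" sets at -1, on disjoint genes following the
#' marker.
#' @return Tibble with columns `set_id`, `gene`, `logfc`.
#' @export
default_pathway_spec <- function() {
  ecm <- tibble::tibble(set_id = "ecm_like",
                        gene = sprintf("g%04d", 2:21), logfc = 1.5)
  met <- purrr::map_dfr(1:6, function(k) {
    start <- 22L + (k - 1L) * 15L
    tibble::tibble(set_id = sprintf("metabolic_%d", k),
                   gene = sprintf("g%04d", start:(start + 14L)), logfc = -1)
  })
  dplyr::bind_rows(ecm, met)
}

# per-gene RefSeq-like annotation sets, shared by all studies
.refseq_universe <- function(cfg) {
  multi <- stats::runif(cfg$n_genes) < cfg$multi_refseq_rate
  ann <- lapply(seq_len(cfg$n_genes), function(i) {
    ids <- sprintf("NM_%06d", 100000L + i)
    if (multi[i]) ids <- c(ids, sprintf("NM_%06d", 500000L + i))
    ids
  })
  names(ann) <- cfg$genes
  ann
}

# combined per-gene PTC effect vector over the universe
.class_effects <- function(cfg) {
  eff <- stats::setNames(numeric(cfg$n_genes), cfg$genes)
  if (nrow(cfg$pathway_spec)) eff[cfg$pathway_spec$gene] <- cfg$pathway_spec$logfc
  if (nrow(cfg$marker_spec)) eff[cfg$marker_spec$gene] <- cfg$marker_spec$logfc
  eff
}

#' Generate synthetic multi-study expression data
#'
#' Draws one [study_matrix()] per study under the model
#' `value = baseline + class effect (PTC only) + study bias + noise`, where the
#' study bias is an additive per-gene per-study shift `~ Normal(0, batch_sd^2)`
#' (a location bias of exactly the kind mean-subtraction along a DWD direction
#' can remove), and noise is independent per probe and sample. Each study
#' covers a seeded random subset of the gene universe (planted genes always
#' included) and a fraction of covered genes is carried by two probes with
#' identical annotation sets.
#'
#' @param cfg A [sim_config()].
#' @param classifier_bound If `TRUE` (default), reject configurations in which
#'   any study has fewer than 2 samples in a class, since such a study cannot
#'   enter classifier fitting.
#' @return Named list of [study_matrix()] objects. The same `cfg` (including
#'   seed) always yields bit-identical output.
#' @export
simulate_studies <- function(cfg, classifier_bound = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  if (classifier_bound && any(cfg$n_ptc < 2 | cfg$n_benign < 2))
    stop("classifier-bound generation requires >= 2 samples per class in every study")
  withr::with_seed(cfg$seed, {
    ann <- .refseq_universe(cfg)
    baseline <- stats::setNames(
      stats::rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd), cfg$genes)
    effects <- .class_effects(cfg)
    planted <- unique(c(cfg$marker_spec$gene, cfg$pathway_spec$gene))
    studies <- lapply(seq_len(cfg$n_studies), function(s) {
      sid <- sprintf("study%d", s)
      n_cov <- max(round(cfg$platform_coverage * cfg$n_genes), length(planted))
      free <- setdiff(cfg$genes, planted)
      covered <- sort(c(planted, sample(free, n_cov - length(planted))))
      dup <- covered[stats::runif(length(covered)) < cfg$duplicate_probe_rate]
      probe_gene <- c(covered, dup)
      probe_ids <- sprintf("%s_p%05d", sid, seq_along(probe_gene))
      n_s <- cfg$n_ptc[s] + cfg$n_benign[s]
      labels <- c(rep("PTC", cfg$n_ptc[s]), rep("benign", cfg$n_benign[s]))
      bias <- stats::setNames(stats::rnorm(cfg$n_genes, 0, cfg$batch_sd), cfg$genes)
      gene_signal <- outer(baseline[probe_gene] + bias[probe_gene],
                           rep(1, n_s)) +
        outer(effects[probe_gene], as.numeric(labels == "PTC"))
      noise <- matrix(stats::rnorm(length(gene_signal), 0, cfg$noise_sd),
                      nrow = nrow(gene_signal))
      values <- gene_signal + noise
      dimnames(values) <- list(probe_ids, sprintf("%s_s%03d", sid, seq_len(n_s)))
      study_matrix(sid, values, stats::setNames(ann[probe_gene], probe_ids), labels)
    })
    stats::setNames(studies, vapply(studies, `[[`, "", "study_id"))
  })
}

#' Planted gene sets keyed by feature key
#'
#' Translates the configuration's pathway specification (plus, optionally, a
#' singleton marker set) into the feature-key space used after probe collapse,
#' for use with [set_test()].
#'
#' @param cfg A [sim_config()].
#' @return Named list of character vectors of feature keys, with a `direction`
#'   attribute (`"up"`/`"down"`) per set from the sign of the planted effect.
#' @export
planted_gene_sets <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ann <- withr::with_seed(cfg$seed, .refseq_universe(cfg))
  keys <- vapply(ann, feature_key, "")
  sets <- split(unname(keys[cfg$pathway_spec$gene]), cfg$pathway_spec$set_id)
  dirs <- vapply(split(cfg$pathway_spec$logfc, cfg$pathway_spec$set_id),
                 function(e) if (mean(e) >= 0) "up" else "down", "")
  attr(sets, "direction") <- dirs[names(sets)]
  sets
}

#' Configure the synthetic qPCR plate generator
#'
#' Defaults emulate the validation cohort of the motivating study: 82 thyroid
#' samples over 7 histological entities (19 PTC), one target assay elevated
#' 36-fold in PTC, and three candidate reference (housekeeping) assays of
#' graded stability, one of them nearly noise-free so stability ranking has a
#' planted winner. Measured in triplicate on the Ct scale.
#'
#' @param entity_counts Named integer vector of per-entity sample counts.
#' @param assays Data frame with columns `assay`, `role` (`"target"` or
#'   `"reference"`), `base_ct` (assay-specific Ct at unit template quantity)
#'   and `stability_sd` (log2 SD of sample-to-sample variability of reference
#'   transcript abundance; ignored for the target).
#' @param target_effect log2 elevation of the target in PTC samples.
#' @param target_sd log2 SD of biological target variability across samples.
#' @param loading_sd log2 SD of the per-sample loading/cellularity factor
#'   shared by all assays (what reference normalisation removes).
#' @param replicate_sd Ct-scale SD of replicate noise.
#' @param n_replicates Replicates per sample and assay.
#' @param seed Integer seed.
#' @return A `qpcr_config` list.
#' @export
qpcr_config <- function(entity_counts = c(PTC = 19, NG = 14, FTA = 11, FTC = 10,
                                          MTC = 9, ATC = 9, normal = 10),
                        assays = default_qpcr_assays(),
                        target_effect = log2(36),
                        target_sd = 1.0,
                        loading_sd = 0.5,
                        replicate_sd = 0.15,
                        n_replicates = 3,
                        seed = 1L) {
  assays <- tibble::as_tibble(assays)
  stopifnot(all(entity_counts >= 0), !is.null(names(entity_counts)),
            all(c("assay", "role", "base_ct", "stability_sd") %in% names(assays)),
            all(assays$role %in% c("target", "reference")),
            replicate_sd >= 0, target_sd >= 0, loading_sd >= 0,
            n_replicates >= 1)
  if (sum(assays$role == "reference") < 2)
    stop("at least 2 reference assays are required")
  if (sum(assays$role == "target") != 1)
    stop("exactly one target assay is required")
  structure(
    list(entity_counts = entity_counts, assays = assays,
         target_effect = target_effect, target_sd = target_sd,
         loading_sd = loading_sd, replicate_sd = replicate_sd,
         n_replicates = as.integer(n_replicates), seed = as.integer(seed)),
    class = "qpcr_config"
  )
}

#' Default qPCR assay panel
#'
#' One target plus three housekeeping candidates with stability SDs
#' (0.05, 0.3, 0.6) so the geNorm ranking has a planted order.
#' @return Tibble with columns `assay`, `role`, `base_ct`, `stability_sd`.
#' @export
default_qpcr_assays <- function() {
  tibble::tibble(
    assay = c("marker", "hk1", "hk2", "hk3"),
    role = c("target", "reference", "reference", "reference"),
    base_ct = c(26, 20, 22, 23),
    stability_sd = c(NA, 0.05, 0.3, 0.6)
  )
}

#' Generate a synthetic qPCR Ct table
#'
#' Each sample carries a loading factor shared by all its assays; each
#' reference assay adds its own log2 stability noise; the target quantity is
#' multiplied by `2^target_effect` in PTC samples. Ct values follow
#' `Ct = base_ct - log2(quantity) + Normal(0, replicate_sd^2)` per replicate.
#'
#' @param cfg A [qpcr_config()].
#' @return Tibble with columns `sample_id`, `entity`, `assay`, `replicate`,
#'   `ct`. Deterministic given `cfg`.
#' @export
simulate_qpcr <- function(cfg) {
  stopifnot(inherits(cfg, "qpcr_config"))
  withr::with_seed(cfg$seed, {
    entities <- rep(names(cfg$entity_counts), cfg$entity_counts)
    n <- length(entities)
    sample_ids <- sprintf("q%03d", seq_len(n))
    loading <- stats::rnorm(n, 0, cfg$loading_sd)       # log2 scale
    rows <- purrr::map_dfr(seq_len(nrow(cfg$assays)), function(a) {
      asy <- cfg$assays[a, ]
      log2q <- if (asy$role == "target") {
        loading + stats::rnorm(n, 0, cfg$target_sd) +
          cfg$target_effect * (entities == "PTC")
      } else {
        loading + stats::rnorm(n, 0, asy$stability_sd)
      }
      purrr::map_dfr(seq_len(cfg$n_replicates), function(r) {
        tibble::tibble(
          sample_id = sample_ids, entity = entities, assay = asy$assay,
          replicate = r,
          ct = asy$base_ct - log2q + stats::rnorm(n, 0, cfg$replicate_sd)
        )
      })
    })
    dplyr::arrange(rows, .data$sample_id, .data$assay, .data$replicate)
  })
}
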