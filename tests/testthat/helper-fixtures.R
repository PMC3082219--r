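# Shared fixture builders. Everything is generated in code; nothing on disk.

# tiny hand-specified study: 4 probes, 4 samples, two probes share a key
toy_study <- function(id = "toy") {
  vals <- rbind(
    p1 = c(1.0, 2.0, 3.0, 4.0),
    p2 = c(5.0, 6.0, 7.0, 8.0),
    p3 = c(2.0, 1.0, 0.0, 3.0),
    p4 = c(9.0, 9.5, 8.5, 9.0)
  )
  colnames(vals) <- paste0(id, "_s", 1:4)
  ann <- list(p1 = c("NM_A"), p2 = c("NM_A"),
              p3 = c("NM_B", "NM_C"), p4 = c("NM_D"))
  study_matrix(id, vals, ann, c("PTC", "PTC", "benign", "benign"))
}

# small two-study configuration used across tests (fast, strong structure)
small_sim <- function(seed = 1, ...) {
  sim_config(n_studies = 2, n_ptc = c(8, 9), n_benign = c(8, 9),
             n_genes = 200, platform_coverage = 0.9,
             seed = seed, ...)
}

# simulate -> collapse -> intersect -> merge -> quantile normalize
prep_merged <- function(cfg) {
  studies <- simulate_studies(cfg)
  mapped <- suppressMessages(lapply(studies, collapse_probes))
  if (length(mapped) > 1) mapped <- intersect_features(mapped)
  quantile_normalize(merge_studies(mapped))
}

# feature key of a simulated gene id (annotations are seed-deterministic)
sim_gene_key <- function(cfg, gene) {
  st <- simulate_studies(cfg, classifier_bound = FALSE)[[1]]
  keys <- vapply(st$annotations, feature_key, "")
  pat <- sprintf("NM_%06d", 100000L + match(gene, cfg$genes))
  unname(unique(keys[grep(pat, keys, fixed = TRUE)]))[1]
}

# random class-labelled matrix with optional planted mean shift
random_labelled_matrix <- function(n_genes, n_per_class, shift_gene = NULL,
                                   shift = 0, sd = 1, seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    x <- matrix(rnorm(n_genes * n, sd = sd), nrow = n_genes,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("s%03d", seq_len(n))))
    labels <- rep(c("PTC", "benign"), each = n_per_class)
    if (!is.null(shift_gene)) x[shift_gene, labels == "PTC"] <-
        x[shift_gene, labels == "PTC"] + shift
    list(x = x, labels = labels)
  })
}
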