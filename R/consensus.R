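#' Pool HOX gene-body probes across cohorts
#'
#' Subsets each cohort's beta matrix to gene-body probes of HOX-locus
#' genes, intersects the probe sets across cohorts, and stacks the samples
#' with a batch label per source matrix.
#'
#' @param matrices list of samples x probes beta matrices (one per cohort).
#' @param manifests list of probe manifests (probe_id, gene, region, ...)
#'   matching `matrices`; a single manifest is recycled.
#' @param hox_gene_list character vector of HOX genes; defaults to the 39
#'   genes of the HOXA-HOXD loci.
#' @return list of class `hox_pool`: `beta` (pooled matrix), `manifest`
#'   (probe annotation with locus), `batch` (character vector per sample).
#' @export
pool_hox_body_probes <- function(matrices, manifests,
                                 hox_gene_list = unlist(hox_genes(),
                                                        use.names = FALSE)) {
  if (!length(matrices)) abort("need at least one matrix.")
  if (!is.list(manifests) || is.data.frame(manifests)) {
    manifests <- list(manifests)
  }
  if (length(manifests) == 1) {
    manifests <- rep(manifests, length(matrices))
  }
  keep_sets <- purrr::map2(matrices, manifests, function(m, man) {
    hx <- man$probe_id[man$region == "Body" & man$gene %in% hox_gene_list]
    intersect(colnames(m), hx)
  })
  common <- Reduce(intersect, keep_sets)
  if (!length(common)) abort("no HOX gene-body probes shared by all cohorts.")
  beta <- do.call(rbind, lapply(matrices, function(m) m[, common, drop = FALSE]))
  batch <- rep(paste0("batch", seq_along(matrices)),
               vapply(matrices, nrow, integer(1)))
  man <- manifests[[1]]
  man <- man[match(common, man$probe_id), ]
  if (!"locus" %in% names(man)) {
    man$locus <- sub("^(HOX[A-D]).*$", "\\1", man$gene)
  }
  structure(list(beta = beta, manifest = as_tibble(man), batch = batch),
            class = "hox_pool")
}

#' @export
print.hox_pool <- function(x, ...) {
  cat("<hox_pool> ", nrow(x$beta), " samples x ", ncol(x$beta),
      " probes, ", length(unique(x$batch)), " batch(es)\n", sep = "")
  invisible(x)
}

#' Batch-adjust pooled beta values
#'
#' Empirical-Bayes location/scale batch adjustment applied per probe on the
#' logit(beta) scale, then mapped back to (0, 1). With a single batch the
#' input is returned unchanged up to the logit round trip. Batches with a
#' single sample are an error.
#'
#' @param beta samples x probes beta matrix.
#' @param batch batch label per sample.
#' @return adjusted beta matrix of the same shape.
#' @export
batch_adjust <- function(beta, batch) {
  check_beta_matrix(beta)
  if (length(batch) != nrow(beta)) {
    abort("`batch` must have one label per sample (row).")
  }
  if (any(table(batch) < 2)) {
    abort("every batch needs at least 2 samples for adjustment.")
  }
  x <- logit_beta(beta)
  if (length(unique(batch)) == 1) {
    return(expit_beta(x))
  }
  adj <- sva::ComBat(dat = t(x), batch = factor(batch))
  out <- expit_beta(t(adj))
  dimnames(out) <- dimnames(beta)
  out
}

#' Align a two-cluster labeling with a reference
#'
#' Of the two possible mappings of one binary labeling onto another,
#' returns the one maximizing agreement with the reference.
#'
#' @param labels integer/character vector of 2 cluster labels.
#' @param reference labeling over the same samples, also 2 clusters.
#' @return `labels` re-coded into the reference's label set.
#' @export
align_labels <- function(labels, reference) {
  if (length(labels) != length(reference)) {
    abort("`labels` and `reference` must cover the same samples.")
  }
  ul <- sort(unique(labels)); ur <- sort(unique(reference))
  if (length(ul) > 2 || length(ur) > 2) {
    abort("label alignment is defined for at most 2 clusters.")
  }
  if (length(ul) == 1) {
    agree <- vapply(ur, function(r) sum(reference == r), numeric(1))
    return(rep(ur[which.max(agree)], length(labels)))
  }
  map1 <- setNames(ur, ul)
  map2 <- setNames(rev(ur), ul)
  a1 <- sum(map1[as.character(labels)] == reference)
  a2 <- sum(map2[as.character(labels)] == reference)
  best <- if (a1 >= a2) map1 else map2
  unname(best[as.character(labels)])
}

#' Consensus clustering of repeated stochastic embeddings
#'
#' Runs `n_runs` independently seeded 2-D UMAP embeddings of the beta
#' matrix, partitions each embedding into two clusters with k-means
#' (10 restarts), aligns every run's labels to the first run, and derives
#' per-sample majority labels and switch frequencies. The switch frequency
#' is the fraction of runs disagreeing with the sample's majority label, so
#' it lies in `[0, 0.5]` and does not depend on which run is the reference.
#' Samples switching in more than `max_switch` of runs (strictly) are
#' flagged not retained. Cluster orientation is fixed by the data: HOX-high
#' is the majority group with the greater overall mean beta.
#'
#' @param beta samples x probes beta matrix (batch-adjusted if pooled).
#' @param n_runs number of embedding runs (default 1000).
#' @param seed base seed; run r uses `seed + r - 1`.
#' @param n_neighbors,min_dist UMAP hyperparameters.
#' @param max_switch stability-filter cutoff on the switch frequency.
#' @return object of class `hox_consensus`: list with `samples` (tibble:
#'   sample_id, majority_label, switch_freq, retained), `runs` (samples x
#'   runs matrix of aligned labels), `embedding` (last run's 2-D
#'   coordinates), `params`.
#' @export
consensus_cluster <- function(beta, n_runs = 1000, seed = 1,
                              n_neighbors = 15, min_dist = 0.1,
                              max_switch = 0.10) {
  check_beta_matrix(beta)
  n <- nrow(beta)
  if (n < 4) abort("need at least 4 samples.")
  if (n_runs < 1) abort("`n_runs` must be >= 1.")
  nb <- min(n_neighbors, n - 1)
  labels <- matrix(NA_integer_, n, n_runs,
                   dimnames = list(rownames(beta), NULL))
  emb <- NULL
  for (r in seq_len(n_runs)) {
    withr::with_seed(seed + r - 1, {
      emb <- uwot::umap(beta, n_neighbors = nb, min_dist = min_dist,
                        init = "random", n_threads = 1, n_sgd_threads = 0)
      km <- kmeans(emb, centers = 2, nstart = 10)
    })
    lab <- km$cluster
    labels[, r] <- if (r == 1) lab else align_labels(lab, labels[, 1])
  }
  frac1 <- rowMeans(labels == 1)
  majority <- ifelse(frac1 >= 0.5, 1L, 2L)
  switch_freq <- rowMeans(labels != majority)
  # orient: HOX-high = majority group with greater overall mean beta
  m1 <- mean(beta[majority == 1L, , drop = FALSE])
  m2 <- mean(beta[majority == 2L, , drop = FALSE])
  high_cluster <- if (isTRUE(m2 > m1)) 2L else 1L
  lab_chr <- ifelse(majority == high_cluster, "HOX-high", "HOX-low")
  samples <- tibble(
    sample_id = rownames(beta),
    majority_label = lab_chr,
    switch_freq = switch_freq,
    retained = switch_freq <= max_switch
  )
  structure(list(samples = samples, runs = labels, embedding = emb,
                 params = list(n_runs = n_runs, seed = seed,
                               n_neighbors = nb, min_dist = min_dist,
                               max_switch = max_switch)),
            class = "hox_consensus")
}

#' @export
print.hox_consensus <- function(x, ...) {
  cat("<hox_consensus> ", nrow(x$samples), " samples, ",
      x$params$n_runs, " runs; excluded: ",
      sum(!x$samples$retained), "\n", sep = "")
  invisible(x)
}

#' Apply the switch-frequency stability filter
#'
#' Excludes samples whose switch frequency strictly exceeds the cutoff
#' (default 10%); a sample switching in exactly 10% of runs is retained.
#'
#' @param consensus a `hox_consensus` or its `samples` tibble.
#' @param max_switch cutoff (default 0.10).
#' @return tibble of retained samples.
#' @export
apply_stability_filter <- function(consensus, max_switch = 0.10) {
  tbl <- if (inherits(consensus, "hox_consensus")) consensus$samples
         else as_tibble(consensus)
  tbl |>
    mutate(retained = .data$switch_freq <= max_switch) |>
    filter(.data$retained)
}

#' Differential methylation between consensus clusters
#'
#' Welch t-test per probe on logit(beta); the effect is the HOX-high minus
#' HOX-low mean difference on the logit scale (the methylation analogue of
#' a log fold change), with BH-FDR across probes. Per-gene and per-locus
#' effects are arithmetic means of their member probes' effects.
#'
#' @param beta samples x probes matrix.
#' @param membership cluster label per sample ("HOX-high"/"HOX-low").
#' @param manifest probe manifest with gene and locus columns.
#' @return list of class `hox_diffmeth` with tibbles `probes`, `genes`,
#'   `loci`. Effects are logit-scale mean differences.
#' @export
differential_methylation <- function(beta, membership, manifest = NULL) {
  check_beta_matrix(beta)
  hi <- membership == "HOX-high"
  lo <- membership == "HOX-low"
  if (sum(hi) < 2 || sum(lo) < 2) {
    abort("both clusters need >= 2 samples.")
  }
  x <- logit_beta(beta)
  probes <- purrr::map_dfr(colnames(x), function(p) {
    a <- x[hi, p]; b <- x[lo, p]
    if (sd(a) == 0 && sd(b) == 0) {
      return(tibble(probe_id = p, effect = mean(a) - mean(b),
                    p = NA_real_, status = "degenerate"))
    }
    tt <- stats::t.test(a, b)
    tibble(probe_id = p, effect = unname(diff(rev(tt$estimate))),
           p = tt$p.value, status = "ok")
  })
  probes$fdr <- p.adjust(probes$p, method = "BH")
  genes <- loci <- NULL
  if (!is.null(manifest)) {
    ann <- manifest[match(probes$probe_id, manifest$probe_id), ]
    probes$gene <- ann$gene
    probes$locus <- if ("locus" %in% names(ann)) ann$locus else
      sub("^(HOX[A-D]).*$", "\\1", ann$gene)
    genes <- probes |>
      group_by(.data$gene) |>
      summarise(effect = mean(.data$effect), n_probes = n(),
                .groups = "drop")
    loci <- probes |>
      group_by(.data$locus) |>
      summarise(effect = mean(.data$effect), n_probes = n(),
                .groups = "drop")
  }
  structure(list(probes = probes, genes = genes, loci = loci),
            class = "hox_diffmeth")
}

#' @export
print.hox_diffmeth <- function(x, ...) {
  cat("<hox_diffmeth> ", nrow(x$probes), " probes (effect = logit-scale",
      " mean difference)\n", sep = "")
  invisible(x)
}
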