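#' Infer arm-level relative dosage from single-nucleus expression
#'
#' A simplified inferred-SCNA procedure over meta-cells. Nuclei within each
#' cluster are pooled into meta-cells of about `k_metacell` nuclei (counts
#' summed, then log-normalized), expression of each gene is compared to the
#' mean over reference meta-cells, the per-gene log2 ratios are clipped,
#' median-centered per meta-cell, smoothed along genomic order with a
#' centered moving average of `window` genes within each arm (the window
#' shrinks, flagged, on arms with fewer genes), and averaged per arm; arm
#' scores are finally re-centered at each meta-cell's median arm score, so
#' the profile is relative to the typical (assumed neutral) arm. An
#' arm is called `loss` when its score falls below `-tau`, `gain` above
#' `+tau`, otherwise `intact`. A meta-cell shows the codeletion pattern
#' when 1p and 19q are lost while 1q and 19p are intact; each cluster's
#' `codeletion_fraction` is the fraction of its meta-cells with that
#' pattern.
#'
#' When `reference_clusters` is `NULL` the first pass uses all meta-cells
#' as reference. With `update_reference = TRUE` (default) exactly one
#' update round is performed: clusters showing no codeletion evidence in
#' the first pass become the reference and the profile is recomputed.
#'
#' @param counts genes x nuclei count matrix.
#' @param clusters cluster label per nucleus (vector or `sn_clusters`).
#' @param features feature table with gene, arm, start (genomic order).
#' @param reference_clusters labels of clusters to use as the initial
#'   reference; `NULL` = all.
#' @param k_metacell nuclei per meta-cell (default 25).
#' @param window moving-average window in genes (default 51).
#' @param tau symmetric call threshold on the arm score (default 0.15).
#' @param u universality level used when updating the reference and by
#'   [call_compartments()] (default 0.95).
#' @param min_ref_mean genes whose reference mean raw count per nucleus is
#'   below this are excluded from the profile (default 0.1).
#' @param clip per-gene log2-ratio clip (default 3).
#' @param update_reference run one reference-update round (default TRUE).
#' @return object of class `arm_dosage`: tibbles `metacells` (metacell,
#'   cluster, arm, score, call, codeleted), `cluster_arms` (cluster, arm,
#'   score, call), `clusters` (cluster, n_metacells, codeletion_fraction),
#'   plus `params` and `reference_used`.
#' @export
infer_arm_dosage <- function(counts, clusters, features,
                             reference_clusters = NULL,
                             k_metacell = 25, window = 51, tau = 0.15,
                             u = 0.95, min_ref_mean = 0.1, clip = 3,
                             update_reference = TRUE) {
  if (inherits(clusters, "sn_clusters")) {
    clusters <- setNames(as.character(clusters$nuclei$cluster),
                         clusters$nuclei$barcode)[colnames(counts)]
  }
  clusters <- as.character(clusters)
  stopifnot(length(clusters) == ncol(counts))
  feats <- features[features$gene %in% rownames(counts), ]
  feats <- feats[order(feats$arm, feats$start), ]
  counts <- counts[feats$gene, , drop = FALSE]

  # pool nuclei (fixed barcode order) into meta-cells of ~k nuclei
  mc_id <- character(ncol(counts))
  for (cl in unique(clusters)) {
    idx <- which(clusters == cl)
    ng <- max(1L, floor(length(idx) / k_metacell))
    grp <- pmin(ceiling(seq_along(idx) / (length(idx) / ng)), ng)
    mc_id[idx] <- paste0(cl, ".", grp)
  }
  pooled <- t(rowsum(t(as.matrix(counts)), mc_id))
  mc_cluster <- sub("\\.[0-9]+$", "", colnames(pooled))
  mc_n <- as.vector(table(mc_id)[colnames(pooled)])

  run_pass <- function(ref_clusters) {
    ref_cols <- if (is.null(ref_clusters)) rep(TRUE, ncol(pooled)) else
      mc_cluster %in% ref_clusters
    if (!any(ref_cols)) abort("reference clusters contain no meta-cells.")
    ref_mean_raw <- rowSums(pooled[, ref_cols, drop = FALSE]) /
      sum(mc_n[ref_cols])
    keep <- ref_mean_raw >= min_ref_mean
    lx <- logcounts(pooled[keep, , drop = FALSE])
    ref <- rowMeans(lx[, ref_cols, drop = FALSE])
    rel <- lx - ref
    rel <- pmin(pmax(rel, -clip), clip)
    # median-center each meta-cell so depth composition cancels
    rel <- sweep(rel, 2, apply(rel, 2, median))
    arm_f <- feats$arm[keep]
    shrunk <- character(0)
    for (a in unique(arm_f)) {
      ii <- which(arm_f == a)
      if (length(ii) < window) shrunk <- c(shrunk, a)
      rel[ii, ] <- apply(rel[ii, , drop = FALSE], 2, running_mean,
                         w = min(window, length(ii)))
    }
    score <- t(rowsum(rel, arm_f) / as.vector(table(arm_f)))
    # re-center on the typical arm: relative dosage is defined against the
    # per-meta-cell median arm score (assumes most arms are neutral)
    score <- score - apply(score, 1, median)
    list(score = score, shrunk = shrunk)   # metacells x arms
  }

  pass1 <- run_pass(reference_clusters)
  codel_frac <- function(score_mat) {
    call_mat <- ifelse(score_mat < -tau, "loss",
                       ifelse(score_mat > tau, "gain", "intact"))
    codel <- call_mat[, "1p"] == "loss" & call_mat[, "19q"] == "loss" &
      call_mat[, "1q"] == "intact" & call_mat[, "19p"] == "intact"
    tapply(codel, mc_cluster, mean)
  }
  ref_used <- reference_clusters %||% "all"
  score <- pass1$score
  shrunk <- pass1$shrunk
  if (update_reference) {
    cf <- codel_frac(pass1$score)
    clean <- names(cf)[cf <= 1 - u]
    if (length(clean)) {
      pass2 <- run_pass(clean)
      score <- pass2$score
      shrunk <- pass2$shrunk
      ref_used <- clean
    }
  }
  call_mat <- ifelse(score < -tau, "loss",
                     ifelse(score > tau, "gain", "intact"))
  codel <- call_mat[, "1p"] == "loss" & call_mat[, "19q"] == "loss" &
    call_mat[, "1q"] == "intact" & call_mat[, "19p"] == "intact"

  metacells <- tibble(
    metacell = rep(rownames(score), ncol(score)),
    cluster = rep(mc_cluster, ncol(score)),
    arm = rep(colnames(score), each = nrow(score)),
    score = as.vector(score),
    call = as.vector(call_mat)
  )
  cluster_arms <- metacells |>
    group_by(.data$cluster, .data$arm) |>
    summarise(score = mean(.data$score), .groups = "drop") |>
    mutate(call = ifelse(.data$score < -tau, "loss",
                         ifelse(.data$score > tau, "gain", "intact")))
  clusters_tbl <- tibble(cluster = mc_cluster, codeleted = codel) |>
    group_by(.data$cluster) |>
    summarise(n_metacells = n(),
              codeletion_fraction = mean(.data$codeleted),
              .groups = "drop")
  structure(list(metacells = metacells, cluster_arms = cluster_arms,
                 clusters = clusters_tbl,
                 reference_used = ref_used,
                 params = list(k_metacell = k_metacell, window = window,
                               tau = tau, u = u, clip = clip,
                               min_ref_mean = min_ref_mean,
                               shrunk_arms = unique(shrunk))),
            class = "arm_dosage")
}

#' @export
print.arm_dosage <- function(x, ...) {
  cat("<arm_dosage> ", nrow(x$clusters), " clusters, tau = ",
      x$params$tau, "\n", sep = "")
  print(x$clusters)
  invisible(x)
}

#' Call cluster compartments from codeletion universality
#'
#' A cluster is neoplastic when its codeletion fraction is at least `u`
#' (universal 1p/19q codeletion), non-neoplastic when at most `1 - u`, and
#' excluded otherwise (codeletion evidence not universal).
#'
#' @param profile an `arm_dosage` object or its `clusters` tibble.
#' @param u universality level (default 0.95).
#' @return tibble with cluster, codeletion_fraction, compartment.
#' @export
call_compartments <- function(profile, u = 0.95) {
  tbl <- if (inherits(profile, "arm_dosage")) profile$clusters
         else as_tibble(profile)
  tbl |>
    mutate(compartment = ifelse(.data$codeletion_fraction >= u, "neoplastic",
                         ifelse(.data$codeletion_fraction <= 1 - u,
                                "non-neoplastic", "excluded"))) |>
    select("cluster", "codeletion_fraction", "compartment")
}
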