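#' Log-normalize single-nucleus counts
#'
#' Library-size normalization to counts per million followed by
#' `log2(1 + cpm)`. Returns a dense genes x nuclei matrix.
#'
#' @param counts genes x nuclei count matrix (sparse or dense).
#' @param scale library-size scale factor (default 1e6).
#' @return dense numeric matrix.
#' @export
logcounts <- function(counts, scale = 1e6) {
  totals <- Matrix::colSums(counts)
  totals[totals == 0] <- 1
  x <- as.matrix(counts)
  log2(1 + sweep(x, 2, scale / totals, "*"))
}

#' Cluster nuclei from a count matrix
#'
#' Standard pipeline: drop all-zero nuclei (reported), log-normalize, PCA
#' (default 30 components, truncated SVD), shared-nearest-neighbor graph
#' from the `k` nearest neighbors in PC space (Jaccard weights), Louvain
#' community detection, and a seeded 2-D UMAP of the PCs for display.
#'
#' @param counts genes x nuclei count matrix.
#' @param n_pcs number of principal components.
#' @param k neighbors for the SNN graph.
#' @param seed integer seed (fixes PCA initialization, Louvain, UMAP).
#' @return object of class `sn_clusters`: tibble `nuclei` (barcode,
#'   cluster), `embedding` (2-D matrix), `dropped` (barcodes of all-zero
#'   nuclei), `pcs`.
#' @export
cluster_nuclei <- function(counts, n_pcs = 30, k = 10, seed = 1) {
  if (ncol(counts) < 50) abort("need at least 50 nuclei.")
  zero <- Matrix::colSums(counts) == 0
  dropped <- colnames(counts)[zero]
  if (length(dropped)) {
    message(length(dropped), " all-zero nuclei dropped before clustering.")
    counts <- counts[, !zero, drop = FALSE]
  }
  x <- logcounts(counts)
  # scale genes, cap extremes as usual
  x <- x - rowMeans(x)
  sds <- sqrt(rowSums(x^2) / (ncol(x) - 1))
  keep <- sds > 0
  x <- x[keep, , drop = FALSE] / sds[keep]
  x[x > 10] <- 10; x[x < -10] <- -10

  withr::with_seed(seed, {
    n_pcs <- min(n_pcs, nrow(x) - 1, ncol(x) - 1)
    sv <- irlba::irlba(t(x), nv = n_pcs)
    pcs <- sv$u %*% diag(sv$d, n_pcs, n_pcs)
    rownames(pcs) <- colnames(x)

    knn <- FNN::get.knn(pcs, k = k)$nn.index
    n <- nrow(pcs)
    nbr <- cbind(seq_len(n), knn)        # include self for Jaccard
    edges <- do.call(rbind, lapply(seq_len(n), function(i) {
      cbind(i, knn[i, ])
    }))
    # Jaccard similarity of neighbor sets for each kNN edge
    nbr_list <- lapply(seq_len(n), function(i) nbr[i, ])
    w <- vapply(seq_len(nrow(edges)), function(e) {
      a <- nbr_list[[edges[e, 1]]]; b <- nbr_list[[edges[e, 2]]]
      it <- length(intersect(a, b))
      it / (length(a) + length(b) - it)
    }, numeric(1))
    keep_e <- w > 1 / 15
    g <- igraph::graph_from_data_frame(
      data.frame(from = edges[keep_e, 1], to = edges[keep_e, 2],
                 weight = w[keep_e]),
      directed = FALSE,
      vertices = data.frame(name = seq_len(n)))
    g <- igraph::simplify(g, edge.attr.comb = "max")
    comm <- igraph::cluster_louvain(g)
    cl <- igraph::membership(comm)

    emb <- uwot::umap(pcs, n_neighbors = min(15, n - 1), min_dist = 0.3,
                      n_threads = 1, n_sgd_threads = 0)
    rownames(emb) <- rownames(pcs)
  })
  structure(list(
    nuclei = tibble(barcode = rownames(pcs),
                    cluster = factor(paste0("C", unname(cl)))),
    embedding = emb, dropped = dropped, pcs = pcs
  ), class = "sn_clusters")
}

#' @export
print.sn_clusters <- function(x, ...) {
  cat("<sn_clusters> ", nrow(x$nuclei), " nuclei in ",
      nlevels(x$nuclei$cluster), " clusters",
      if (length(x$dropped)) paste0(" (", length(x$dropped), " dropped)"),
      "\n", sep = "")
  invisible(x)
}

#' Assign cell types to clusters from marker panels
#'
#' For each cluster, the mean z-scored expression of every marker panel is
#' computed; the cluster gets the top panel's type if that panel beats the
#' runner-up by at least `margin` (in panel-score standard deviations
#' across clusters), otherwise "unassigned". Markers absent from the
#' feature space are reported, not fatal; all panels absent is an error.
#'
#' @param counts genes x nuclei count matrix.
#' @param clusters cluster label per nucleus (vector or `sn_clusters`).
#' @param which_clusters optional subset of cluster labels to type.
#' @param marker_sets named list of marker panels (see
#'   [default_marker_sets()]).
#' @param margin required lead of the top panel (default 0.25 sd).
#' @return tibble with cluster, cell_type, top score, runner-up score.
#' @export
assign_cell_types <- function(counts, clusters, which_clusters = NULL,
                              marker_sets = default_marker_sets(),
                              margin = 0.25) {
  if (inherits(clusters, "sn_clusters")) {
    clusters <- setNames(as.character(clusters$nuclei$cluster),
                         clusters$nuclei$barcode)[colnames(counts)]
  }
  clusters <- as.character(clusters)
  present <- lapply(marker_sets, function(g) intersect(g, rownames(counts)))
  absent <- unlist(purrr::map2(marker_sets, present, setdiff))
  if (length(absent)) {
    message("markers absent from features: ", paste(absent, collapse = ", "))
  }
  if (all(lengths(present) == 0)) abort("no marker panel present in features.")
  marker_sets <- present[lengths(present) > 0]

  x <- logcounts(counts)
  cl_levels <- unique(clusters)
  cl_means <- vapply(cl_levels, function(cl) {
    rowMeans(x[, clusters == cl, drop = FALSE])
  }, numeric(nrow(x)))
  # z-score genes across clusters so panels are comparable
  mu <- rowMeans(cl_means); s <- apply(cl_means, 1, sd)
  s[s == 0] <- 1
  z <- (cl_means - mu) / s
  panel <- vapply(marker_sets, function(g) {
    colMeans(z[g, , drop = FALSE])
  }, numeric(length(cl_levels)))
  if (is.null(dim(panel))) panel <- matrix(panel, nrow = 1,
                                           dimnames = list(cl_levels,
                                                           names(marker_sets)))
  keep <- which_clusters %||% cl_levels
  purrr::map_dfr(intersect(cl_levels, keep), function(cl) {
    sc <- panel[cl, ]
    ord <- order(sc, decreasing = TRUE)
    top <- sc[ord[1]]
    second <- if (length(sc) > 1) sc[ord[2]] else -Inf
    type <- if (top - second >= margin) names(sc)[ord[1]] else "unassigned"
    tibble(cluster = cl, cell_type = type,
           top_score = unname(top), runner_up = unname(second))
  })
}
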