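#' Planted truth for a multi-batch pan-HOX methylation matrix
#'
#' Describes the generator behind [gen_panhox()]: gene-body probes spread
#' over the four HOX loci, two planted methylation clusters separated on
#' the logit-beta scale (the shift concentrated on, but not exclusive to,
#' HOXD probes), per-batch additive offsets on the logit scale, and a
#' fraction of ambiguous samples interpolated midway between the clusters.
#'
#' Defaults emulate the pooled cohort the consensus analysis was designed
#' for: three batches of 171, 170 and 24 samples sharing 422 HOX gene-body
#' probes, with roughly 5% ambiguous samples.
#'
#' @param n_per_batch integer vector of samples per batch.
#' @param n_probes number of shared HOX gene-body probes (default 422).
#' @param cluster_shift mean logit-scale beta offset of the HOX-high
#'   cluster on HOXD probes; other loci receive 35% of it.
#' @param high_fraction fraction of non-ambiguous samples planted in the
#'   HOX-high cluster.
#' @param batch_offsets per-batch additive logit-scale shifts; `NULL` picks
#'   a moderate default pattern matched to the number of batches.
#' @param ambiguous_fraction fraction of samples placed midway between the
#'   two planted clusters; must lie in `[0, 1)`.
#' @param noise_sd logit-scale residual standard deviation.
#' @param seed integer seed.
#' @return an object of class `panhox_truth`.
#' @export
panhox_truth <- function(n_per_batch = c(171, 170, 24),
                         n_probes = 422,
                         cluster_shift = 1.5,
                         high_fraction = 0.4,
                         batch_offsets = NULL,
                         ambiguous_fraction = 0.05,
                         noise_sd = 0.35,
                         seed = 1L) {
  if (is.null(batch_offsets)) {
    batch_offsets <- rep(c(0, 0.6, -0.4, 0.3, -0.2),
                         length.out = length(n_per_batch))
  }
  if (length(batch_offsets) != length(n_per_batch)) {
    abort("`batch_offsets` must match `n_per_batch` in length.")
  }
  if (ambiguous_fraction < 0 || ambiguous_fraction >= 1) {
    abort("`ambiguous_fraction` must lie in [0, 1).")
  }
  check_prob(high_fraction, "high_fraction")
  structure(
    list(n_per_batch = as.integer(n_per_batch), n_probes = as.integer(n_probes),
         cluster_shift = cluster_shift, high_fraction = high_fraction,
         batch_offsets = batch_offsets, ambiguous_fraction = ambiguous_fraction,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "panhox_truth"
  )
}

# the 39 protein-coding HOX genes of the four loci
hox_genes <- function() {
  list(
    HOXA = paste0("HOXA", c(1:7, 9:11, 13)),
    HOXB = paste0("HOXB", c(1:9, 13)),
    HOXC = paste0("HOXC", c(4:6, 8:13)),
    HOXD = paste0("HOXD", c(1, 3, 4, 8:13))
  )
}

# HOXA on 7p15, HOXB on 17q21, HOXC on 12q13, HOXD on 2q31
.HOX_LOCUS_ARMS <- c(HOXA = "7p", HOXB = "17q", HOXC = "12q", HOXD = "2q")
.HOX_LOCUS_START <- c(HOXA = 27100000L, HOXB = 48500000L,
                      HOXC = 54300000L, HOXD = 176900000L)

#' Manifest of synthetic HOX gene-body probes
#'
#' Assigns `n_probes` gene-body probes round-robin to the 39 HOX genes,
#' so every probe maps to exactly one gene and one locus.
#'
#' @param n_probes number of probes.
#' @return tibble with probe_id, gene, locus, region, chrom_arm, pos.
#' @export
hox_probe_manifest <- function(n_probes = 422) {
  genes <- hox_genes()
  gene_vec <- unlist(genes, use.names = FALSE)
  locus_vec <- rep(names(genes), lengths(genes))
  idx <- rep(seq_along(gene_vec), length.out = n_probes)
  idx <- sort(idx)
  tibble(
    probe_id = sprintf("cgH%07d", seq_len(n_probes)),
    gene = gene_vec[idx],
    locus = locus_vec[idx],
    region = "Body",
    chrom_arm = unname(.HOX_LOCUS_ARMS[locus_vec[idx]]),
    pos = unname(.HOX_LOCUS_START[locus_vec[idx]]) +
      3000L * idx + 40L * seq_len(n_probes)
  )
}

#' Generate a multi-batch pan-HOX beta matrix with planted clusters
#'
#' @param truth a [panhox_truth()].
#' @return list of class `panhox_sim`: `beta` (samples x probes matrix),
#'   `manifest` (probe annotation with locus and gene), `samples` (tibble:
#'   sample_id, batch, true_label, ambiguous).
#' @export
#' @examples
#' sim <- gen_panhox(panhox_truth(n_per_batch = c(30, 30), seed = 2))
#' table(sim$samples$true_label)
gen_panhox <- function(truth) {
  stopifnot(inherits(truth, "panhox_truth"))
  manifest <- hox_probe_manifest(truth$n_probes)
  n <- sum(truth$n_per_batch)
  withr::with_seed(truth$seed, {
    batch <- rep(paste0("batch", seq_along(truth$n_per_batch)),
                 truth$n_per_batch)
    ids <- sprintf("P%04d", seq_len(n))

    n_amb <- floor(truth$ambiguous_fraction * n)
    amb <- rep(FALSE, n)
    if (n_amb > 0) amb[sample.int(n, n_amb)] <- TRUE
    lab <- ifelse(rbinom(n, 1, truth$high_fraction) == 1, "HOX-high", "HOX-low")

    base <- qlogis(runif(truth$n_probes, 0.2, 0.5))
    probe_w <- ifelse(manifest$locus == "HOXD", 1, 0.35)
    delta <- truth$cluster_shift * probe_w

    memb <- ifelse(amb, 0.5, ifelse(lab == "HOX-high", 1, 0))
    shift_mat <- outer(memb, delta)                      # n x p
    logit_val <- sweep(shift_mat, 2, base, "+") +
      truth$batch_offsets[match(batch, unique(batch))] +
      matrix(rnorm(n * truth$n_probes, 0, truth$noise_sd), n)
    beta <- expit_beta(logit_val)
    dimnames(beta) <- list(ids, manifest$probe_id)

    structure(list(
      beta = beta, manifest = manifest,
      samples = tibble(sample_id = ids, batch = batch,
                       true_label = lab, ambiguous = amb)
    ), class = "panhox_sim")
  })
}

#' @export
print.panhox_sim <- function(x, ...) {
  cat("<panhox_sim> ", nrow(x$beta), " samples x ", ncol(x$beta),
      " probes, ", length(unique(x$samples$batch)), " batches\n", sep = "")
  invisible(x)
}
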