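#' Default marker panels for non-neoplastic brain cell types
#'
#' The marker genes used for first-pass cell typing: RBFOX3 for neurons;
#' MBP, MOG and CNP for oligodendrocytes; SLC1A2, GFAP, AQP4 and ALDH1L1
#' for astrocytes; PTPRC, CD163 and CD14 for microglia.
#'
#' @return named list of character vectors.
#' @export
default_marker_sets <- function() {
  list(
    neuron = "RBFOX3",
    oligodendrocyte = c("MBP", "MOG", "CNP"),
    astrocyte = c("SLC1A2", "GFAP", "AQP4", "ALDH1L1"),
    microglia = c("PTPRC", "CD163", "CD14")
  )
}

#' Default synthetic cell-state program gene sets
#'
#' Synthetic-truth gene programs for the four neoplastic cell states
#' (OPC-like, Astro-like, Cycling, RE). These are generator-defined sets,
#' not published signatures; swap in real programs for real data.
#'
#' @param n_genes genes per program.
#' @return named list of character vectors.
#' @export
default_state_programs <- function(n_genes = 40) {
  states <- c("OPC-like", "Astro-like", "Cycling", "RE")
  tags <- c("OPC", "AST", "CYC", "RE")
  setNames(lapply(tags, function(t) sprintf("PRG%s%03d", t, seq_len(n_genes))),
           states)
}

#' Default synthetic lineage and stemness gene sets
#'
#' Synthetic-truth sets for oligodendrocytic (OC) and astrocytic (AC)
#' lineage scores and for the stemness score.
#'
#' @param n_genes genes per set.
#' @return named list with elements OC, AC, stemness.
#' @export
default_lineage_sets <- function(n_genes = 30) {
  list(
    OC = sprintf("LINOC%03d", seq_len(n_genes)),
    AC = sprintf("LINAC%03d", seq_len(n_genes)),
    stemness = sprintf("STEM%03d", seq_len(n_genes))
  )
}

#' Planted truth for a synthetic single-nucleus experiment
#'
#' Describes the generator behind [gen_snseq()]: a mixture of neoplastic
#' nuclei and four non-neoplastic cell types; arm-level dosage loss of
#' 1p and 19q (with 1q and 19p intact) in neoplastic nuclei only; cell-type
#' marker programs; cell-state gene programs within the neoplastic
#' compartment; lineage/stemness programs; and a sparse marker gene
#' (HOXD12 stand-in) whose per-nucleus activation probability depends on
#' compartment and state, highest in Cycling then OPC-like nuclei.
#'
#' Counts are negative binomial (dispersion 0.5) around a log-normal
#' per-gene base profile scaled by per-nucleus depth.
#'
#' @param n_nuclei number of nuclei.
#' @param type_proportions named proportions over neoplastic,
#'   oligodendrocyte, astrocyte, neuron, microglia; must sum to 1.
#' @param state_proportions named proportions over OPC-like, Astro-like,
#'   Cycling, RE, gradient within the neoplastic compartment; must sum to 1.
#' @param deleted_arm_dosage multiplicative expression factor applied to
#'   genes on 1p and 19q in neoplastic nuclei; in (0, 1].
#' @param genes_per_arm background genes simulated per chromosome arm.
#' @param arms chromosome arms carried by the feature table; must include
#'   1p, 1q, 19p and 19q.
#' @param marker_fc,program_fc,lineage_fc,type_program_fc fold changes
#'   applied to marker, state-program, lineage and cell-type program genes
#'   in the nuclei that express them. Each non-neoplastic type carries a
#'   broad 40-gene program besides its canonical markers, as real cell
#'   types do; neoplastic nuclei carry a shared neoplastic program.
#' @param sparse_marker name of the sparse marker gene.
#' @param sparse_marker_prob named activation probabilities for the sparse
#'   marker: one entry per cell state plus `non_neoplastic`.
#' @param mean_depth expected total counts per nucleus.
#' @param dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param seed integer seed.
#' @return object of class `sn_truth`.
#' @export
sn_truth <- function(n_nuclei = 3000,
                     type_proportions = c(neoplastic = 0.55,
                                          oligodendrocyte = 0.18,
                                          astrocyte = 0.10,
                                          neuron = 0.09,
                                          microglia = 0.08),
                     state_proportions = c("OPC-like" = 0.30,
                                           "Astro-like" = 0.30,
                                           "Cycling" = 0.15,
                                           "RE" = 0.05,
                                           "gradient" = 0.20),
                     deleted_arm_dosage = 0.5,
                     genes_per_arm = 300,
                     arms = c("1p", "1q", "19p", "19q",
                              "2q", "7p", "10q", "17q"),
                     marker_fc = 8,
                     program_fc = 4,
                     lineage_fc = 3,
                     type_program_fc = 4,
                     sparse_marker = "HOXD12",
                     sparse_marker_prob = c("Cycling" = 0.15,
                                            "OPC-like" = 0.08,
                                            "Astro-like" = 0.02,
                                            "RE" = 0.02,
                                            "gradient" = 0.02,
                                            "non_neoplastic" = 0.005),
                     mean_depth = 4000,
                     dispersion = 0.5,
                     seed = 1L) {
  if (abs(sum(type_proportions) - 1) > 1e-8) {
    abort("`type_proportions` must sum to 1.")
  }
  if (abs(sum(state_proportions) - 1) > 1e-8) {
    abort("`state_proportions` must sum to 1.")
  }
  if (deleted_arm_dosage <= 0 || deleted_arm_dosage > 1) {
    abort("`deleted_arm_dosage` must lie in (0, 1].")
  }
  if (!all(c("1p", "1q", "19p", "19q") %in% arms)) {
    abort("`arms` must include 1p, 1q, 19p and 19q.")
  }
  programs <- default_state_programs()
  markers <- default_marker_sets()
  lineage <- default_lineage_sets()
  types <- c(names(type_proportions))
  tags <- toupper(substr(types, 1, 3))
  type_programs <- setNames(
    lapply(tags, function(t) sprintf("TYP%s%03d", t, 1:40)), types)
  if (sparse_marker %in% c(unlist(programs), unlist(markers),
                           unlist(lineage))) {
    abort("the sparse marker must be disjoint from program and marker sets.")
  }
  structure(
    list(n_nuclei = as.integer(n_nuclei),
         type_proportions = type_proportions,
         state_proportions = state_proportions,
         deleted_arm_dosage = deleted_arm_dosage,
         genes_per_arm = as.integer(genes_per_arm), arms = arms,
         marker_fc = marker_fc, program_fc = program_fc,
         lineage_fc = lineage_fc, type_program_fc = type_program_fc,
         type_programs = type_programs,
         sparse_marker = sparse_marker,
         sparse_marker_prob = sparse_marker_prob,
         mean_depth = mean_depth, dispersion = dispersion,
         programs = programs, markers = markers, lineage = lineage,
         seed = as.integer(seed)),
    class = "sn_truth"
  )
}

# feature table: background genes fill each arm; named marker/program/
# lineage genes and the sparse marker live on neutral arms so they cannot
# masquerade as dosage signal
sn_feature_table <- function(truth) {
  bg <- purrr::map_dfr(truth$arms, function(a) {
    tibble(
      gene = sprintf("BG%s_%03d", gsub("[^0-9pq]", "", a),
                     seq_len(truth$genes_per_arm)),
      chrom = paste0("chr", sub("[pq]$", "", a)),
      arm = a
    )
  })
  named <- unique(c(unlist(truth$markers, use.names = FALSE),
                    unlist(truth$programs, use.names = FALSE),
                    unlist(truth$lineage, use.names = FALSE),
                    unlist(truth$type_programs, use.names = FALSE)))
  neutral <- setdiff(truth$arms, c("1p", "1q", "19p", "19q"))
  named_tbl <- tibble(
    gene = named,
    arm = rep(neutral, length.out = length(named)),
    chrom = paste0("chr", sub("[pq]$", "", arm))
  )
  marker_tbl <- tibble(gene = truth$sparse_marker, chrom = "chr2", arm = "2q")
  feats <- bind_rows(bg, named_tbl, marker_tbl)
  feats |>
    group_by(.data$arm) |>
    mutate(ord = seq_len(dplyr::n())) |>
    ungroup() |>
    mutate(start = 1000000L + .data$ord * 30000L,
           end = .data$start + 2000L) |>
    select("gene", "chrom", "start", "end", "arm") |>
    arrange(.data$chrom, .data$arm, .data$start)
}

#' Generate synthetic single-nucleus counts with planted truth
#'
#' Emits a sparse gene-by-nucleus count matrix, a feature table with
#' genomic coordinates, barcodes, and the planted per-nucleus truth
#' (compartment, cell type, state, sparse-marker activity). Neoplastic
#' nuclei carry the 1p/19q dosage loss; program and marker genes are
#' upregulated in their state/type; the sparse marker is Bernoulli-active
#' with state-specific probability.
#'
#' @param truth an [sn_truth()].
#' @return list of class `sn_sim`: `counts` (dgCMatrix, genes x nuclei),
#'   `features` (tibble: gene, chrom, start, end, arm), `barcodes`
#'   (character), `truth_table` (tibble: barcode, compartment, cell_type,
#'   state, marker_active), `truth`.
#' @export
#' @examples
#' sim <- gen_snseq(sn_truth(n_nuclei = 200, genes_per_arm = 60, seed = 3))
#' Matrix::dim(sim$counts)
gen_snseq <- function(truth) {
  stopifnot(inherits(truth, "sn_truth"))
  feats <- sn_feature_table(truth)
  missing <- setdiff(unlist(truth$programs, use.names = FALSE), feats$gene)
  if (length(missing)) {
    abort(sprintf("program genes absent from features: %s",
                  paste(missing, collapse = ", ")))
  }
  n <- truth$n_nuclei
  g <- nrow(feats)
  withr::with_seed(truth$seed, {
    barcodes <- sprintf("BC%05d", seq_len(n))
    type <- sample(names(truth$type_proportions), n, replace = TRUE,
                   prob = truth$type_proportions)
    state <- rep(NA_character_, n)
    neo <- type == "neoplastic"
    state[neo] <- sample(names(truth$state_proportions), sum(neo),
                         replace = TRUE, prob = truth$state_proportions)

    base <- rlnorm(g, meanlog = log(0.3), sdlog = 1)
    base <- base / sum(base) * truth$mean_depth
    names(base) <- feats$gene

    depth <- rlnorm(n, meanlog = 0, sdlog = 0.25)
    on_del <- feats$arm %in% c("1p", "19q")
    size <- 1 / truth$dispersion

    counts <- matrix(0L, g, n, dimnames = list(feats$gene, barcodes))
    gene_idx <- seq_len(g)
    for (i in seq_len(n)) {
      mu <- base
      tp <- truth$type_programs[[type[i]]]
      mu[tp] <- mu[tp] * truth$type_program_fc
      if (neo[i]) {
        mu[on_del] <- mu[on_del] * truth$deleted_arm_dosage
        st <- state[i]
        if (st %in% names(truth$programs)) {
          mu[truth$programs[[st]]] <- mu[truth$programs[[st]]] *
            truth$program_fc
        }
        if (st == "OPC-like") {
          mu[truth$lineage$OC] <- mu[truth$lineage$OC] * truth$lineage_fc
          mu[truth$lineage$stemness] <- mu[truth$lineage$stemness] *
            truth$lineage_fc
        } else if (st == "Astro-like") {
          mu[truth$lineage$AC] <- mu[truth$lineage$AC] * truth$lineage_fc
        } else if (st == "Cycling") {
          mu[truth$lineage$stemness] <- mu[truth$lineage$stemness] *
            truth$lineage_fc
        }
      } else {
        mk <- truth$markers[[type[i]]]
        mu[mk] <- mu[mk] * truth$marker_fc
      }
      mu[truth$sparse_marker] <- 0
      counts[, i] <- rnbinom(g, mu = mu * depth[i], size = size)
    }

    p_act <- ifelse(neo, truth$sparse_marker_prob[state],
                    truth$sparse_marker_prob[["non_neoplastic"]])
    active <- rbinom(n, 1, p_act) == 1
    counts[truth$sparse_marker, ] <- ifelse(active, 1L + rpois(n, 0.4), 0L)

    truth_table <- tibble(
      barcode = barcodes,
      compartment = ifelse(neo, "neoplastic", "non-neoplastic"),
      cell_type = ifelse(neo, NA_character_, type),
      state = state,
      marker_active = active
    )
    structure(list(
      counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
      features = feats, barcodes = barcodes,
      truth_table = truth_table, truth = truth
    ), class = "sn_sim")
  })
}

#' @export
print.sn_sim <- function(x, ...) {
  cat("<sn_sim> ", ncol(x$counts), " nuclei x ", nrow(x$counts),
      " genes\n", sep = "")
  invisible(x)
}

#' Write / read a single-nucleus simulation in MatrixMarket layout
#'
#' Writes `matrix.mtx`, `features.tsv` (gene, chrom, start, end, arm) and
#' `barcodes.tsv` under `dir`; `read_snseq()` reads them back.
#'
#' @param sim an `sn_sim` (or any list with counts/features/barcodes).
#' @param dir output directory, created if needed.
#' @return `write_snseq()` returns `dir` invisibly; `read_snseq()` a list
#'   with `counts`, `features`, `barcodes`.
#' @export
write_snseq <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(sim$counts, file.path(dir, "matrix.mtx"))
  utils::write.table(sim$features, file.path(dir, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(colnames(sim$counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' @rdname write_snseq
#' @export
read_snseq <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  features <- as_tibble(utils::read.delim(file.path(dir, "features.tsv")))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  dimnames(counts) <- list(features$gene, barcodes)
  list(counts = counts, features = features, barcodes = barcodes)
}
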