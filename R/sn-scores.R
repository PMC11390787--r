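#' Bin genes by aggregate expression
#'
#' Genes are ranked by their mean expression across nuclei and cut into
#' `bins` equal-size bins; used to draw expression-matched control genes.
#'
#' @param expr genes x nuclei log-normalized matrix.
#' @param bins number of bins (default 25).
#' @return integer vector of bin ids, named by gene.
#' @keywords internal
expression_bins <- function(expr, bins = 25) {
  agg <- rowMeans(expr)
  bin <- ceiling(rank(agg, ties.method = "first") / length(agg) * bins)
  setNames(as.integer(bin), rownames(expr))
}

#' Relative program score with bin-matched controls
#'
#' The score of a nucleus for a gene program is the mean centered
#' expression of the program genes minus the mean centered expression of a
#' control set drawn from the same expression bins: for each program gene,
#' `n_ctrl` genes are sampled from its bin (`n_ctrl = Inf` uses the whole
#' bin, the deterministic limit used by the permutation test). Centered
#' expression is the gene's log-normalized expression minus its mean
#' across nuclei, so scores are relative, unitless, and centered near zero
#' for unstructured programs.
#'
#' @param expr genes x nuclei log-normalized matrix (see [logcounts()]).
#' @param gene_set character vector of program genes.
#' @param bins number of expression bins (default 25).
#' @param n_ctrl control genes sampled per program gene (default 100);
#'   `Inf` for full-bin controls.
#' @param seed seed for the control draw.
#' @return named numeric vector of per-nucleus scores.
#' @export
relative_program_score <- function(expr, gene_set, bins = 25,
                                   n_ctrl = 100, seed = 1) {
  genes <- intersect(gene_set, rownames(expr))
  if (!length(genes)) abort("gene set has no genes in the expression matrix.")
  centered <- expr - rowMeans(expr)
  bin <- expression_bins(expr, bins)
  prog <- colMeans(centered[genes, , drop = FALSE])
  if (is.infinite(n_ctrl)) {
    ctrl <- bin_control_means(centered, bin, bin[genes])
  } else {
    ctrl_genes <- withr::with_seed(seed, unlist(lapply(genes, function(g) {
      pool <- names(bin)[bin == bin[[g]]]
      sample(pool, min(n_ctrl, length(pool)))
    })))
    ctrl <- colMeans(centered[ctrl_genes, , drop = FALSE])
  }
  prog - ctrl
}

# expected control signal: bin-composition-weighted mean of per-bin
# average centered expression
bin_control_means <- function(centered, bin, program_bins) {
  bin_means <- rowsum(centered, bin) / as.vector(table(bin))
  comp <- table(factor(program_bins, levels = rownames(bin_means)))
  as.vector(crossprod(bin_means, as.vector(comp) / sum(comp)))
}

#' Permutation test for cell-state program scores
#'
#' For each state program, observed per-nucleus scores are compared with
#' the scores of `n_perm` random gene sets matched in size and expression-
#' bin composition. Both observed and null scores use the deterministic
#' full-bin control term, so the test is exchangeable by construction. The
#' p-value uses the add-one correction,
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`, so its attainable floor
#' is `1/(n_perm + 1)` (about 1e-5 at the default 100,000 permutations).
#' FDRs are Benjamini-Hochberg across the full nucleus-by-state grid.
#'
#' @param expr genes x nuclei log-normalized matrix.
#' @param programs named list of state gene sets
#'   (see [default_state_programs()]).
#' @param n_perm number of permutations (default 1e5).
#' @param bins number of expression bins.
#' @param seed integer seed.
#' @param block permutations computed per block (memory control).
#' @return object of class `state_test`: tibble with barcode, state, score,
#'   p, fdr.
#' @export
permutation_state_test <- function(expr, programs, n_perm = 1e5,
                                   bins = 25, seed = 1, block = 2000) {
  if (n_perm < 1) abort("`n_perm` must be >= 1.")
  centered <- expr - rowMeans(expr)
  bin <- expression_bins(expr, bins)
  bin_index <- split(seq_len(nrow(expr)), bin)

  res <- purrr::imap(programs, function(genes, state) {
    genes <- intersect(genes, rownames(expr))
    if (!length(genes)) {
      abort(sprintf("program '%s' has no genes in the matrix.", state))
    }
    ctrl <- bin_control_means(centered, bin, bin[genes])
    obs <- colMeans(centered[genes, , drop = FALSE]) - ctrl
    comp <- table(bin[genes])
    exceed <- numeric(ncol(expr))
    withr::with_seed(seed + match(state, names(programs)), {
      done <- 0
      while (done < n_perm) {
        b <- min(block, n_perm - done)
        # size/bin-matched random sets, one column per permutation
        ii <- integer(0); jj <- integer(0)
        for (bn in names(comp)) {
          pool <- bin_index[[bn]]
          m <- comp[[bn]]
          draws <- replicate(b, pool[sample.int(length(pool), m)])
          ii <- c(ii, as.vector(draws))
          jj <- c(jj, rep(seq_len(b), each = m))
        }
        S <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                                  dims = c(nrow(expr), b))
        null <- as.matrix(Matrix::crossprod(S, centered)) / length(genes)
        null <- sweep(null, 2, ctrl)
        exceed <- exceed + colSums(null >= rep(obs, each = b))
        done <- done + b
      }
    })
    tibble(barcode = colnames(expr), state = state, score = unname(obs),
           p = unname((1 + exceed) / (1 + n_perm)))
  })
  out <- bind_rows(res)
  out$fdr <- p.adjust(out$p, method = "BH")
  structure(out, class = c("state_test", class(out)))
}

#' Assign cell states from the FDR grid
#'
#' Each nucleus gets the state with the lowest FDR when that FDR is
#' strictly below `alpha` (default 0.0125, i.e. 0.05 divided by the four
#' states); otherwise the state is "gradient". Ties are broken by the
#' larger observed score, then by the fixed order of `state_order`.
#'
#' @param state_test a `state_test` tibble (barcode, state, score, fdr).
#' @param alpha FDR threshold (default 0.0125).
#' @param state_order tie-break order of states.
#' @return tibble with barcode, state, min_fdr.
#' @export
assign_state <- function(state_test, alpha = 0.0125,
                         state_order = c("OPC-like", "Astro-like",
                                         "Cycling", "RE")) {
  st <- as_tibble(state_test)
  st$state_rank <- match(st$state, state_order)
  st |>
    arrange(.data$barcode, .data$fdr, dplyr::desc(.data$score),
            .data$state_rank) |>
    group_by(.data$barcode) |>
    summarise(state = ifelse(.data$fdr[1] < alpha, .data$state[1],
                             "gradient"),
              min_fdr = .data$fdr[1], .groups = "drop")
}

#' Stemness and lineage scores
#'
#' Computes the oligodendrocytic (OC) and astrocytic (AC) lineage scores
#' and the stemness score as relative program scores, plus the lineage
#' differential `OC - AC`.
#'
#' @param expr genes x nuclei log-normalized matrix.
#' @param sets named list with OC, AC and stemness gene sets
#'   (see [default_lineage_sets()]).
#' @param bins,n_ctrl,seed passed to [relative_program_score()].
#' @return tibble with barcode, oc_score, ac_score, stemness_score,
#'   lineage_diff.
#' @export
stemness_lineage_scores <- function(expr, sets = default_lineage_sets(),
                                    bins = 25, n_ctrl = 100, seed = 1) {
  oc <- relative_program_score(expr, sets$OC, bins, n_ctrl, seed)
  ac <- relative_program_score(expr, sets$AC, bins, n_ctrl, seed + 1)
  stem <- relative_program_score(expr, sets$stemness, bins, n_ctrl, seed + 2)
  tibble(barcode = colnames(expr), oc_score = oc, ac_score = ac,
         stemness_score = stem, lineage_diff = oc - ac)
}

#' Compare sparse-marker prevalence and scores across groups
#'
#' Pairwise contrasts of marker prevalence (fraction of nuclei with
#' nonzero marker signal) between groups, each tested with Fisher's exact
#' test; empty groups are skipped with a message. An all-zero contrast is
#' reported with p = 1.
#'
#' @param data data frame with one row per nucleus.
#' @param active name of the logical marker-activity column.
#' @param group name of the grouping column.
#' @return tibble with group1, group2, n1, n2, prev1, prev2, p.
#' @export
compare_marker_prevalence <- function(data, active = "marker_active",
                                      group = "group") {
  a <- data[[active]]; g <- as.character(data[[group]])
  keep <- !is.na(a) & !is.na(g)
  a <- a[keep]; g <- g[keep]
  levels <- unique(g)
  if (length(levels) < 2) abort("grouping is degenerate: < 2 groups.")
  pairs <- utils::combn(levels, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    i1 <- g == pr[1]; i2 <- g == pr[2]
    if (!any(i1) || !any(i2)) {
      message("empty group in contrast ", pr[1], " vs ", pr[2], "; skipped.")
      return(NULL)
    }
    tab <- matrix(c(sum(a[i1]), sum(!a[i1]), sum(a[i2]), sum(!a[i2])),
                  2, byrow = TRUE)
    p <- stats::fisher.test(tab)$p.value
    tibble(group1 = pr[1], group2 = pr[2],
           n1 = sum(i1), n2 = sum(i2),
           prev1 = mean(a[i1]), prev2 = mean(a[i2]), p = p)
  })
}

#' Compare a continuous score across two groups (Student's t)
#'
#' @param data data frame with one row per nucleus.
#' @param score name of the numeric score column.
#' @param group name of a two-level grouping column.
#' @return tibble with group means, t statistic and p value.
#' @export
compare_scores <- function(data, score, group) {
  s <- data[[score]]; g <- as.character(data[[group]])
  levels <- unique(g[!is.na(g)])
  if (length(levels) != 2) abort("`group` must have exactly 2 levels.")
  tt <- stats::t.test(s[g == levels[1]], s[g == levels[2]], var.equal = TRUE)
  tibble(group1 = levels[1], group2 = levels[2],
         mean1 = unname(tt$estimate[1]), mean2 = unname(tt$estimate[2]),
         t = unname(tt$statistic), p = tt$p.value)
}
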