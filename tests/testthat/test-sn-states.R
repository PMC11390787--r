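# one moderate simulation shared across blocks in this file
sim <- gen_snseq(sn_truth(n_nuclei = 1200, genes_per_arm = 250, seed = 4))
truth_tbl <- sim$truth_table
cl <- cluster_nuclei(sim$counts, seed = 1)
planted <- ifelse(truth_tbl$compartment == "neoplastic", "neoplastic",
                  truth_tbl$cell_type)

test_that("clustering separates the planted populations", {
  tab <- table(cl$nuclei$cluster, planted)
  purity <- apply(tab, 1, max) / rowSums(tab)
  expect_gte(nlevels(cl$nuclei$cluster), 5)
  expect_true(all(purity > 0.9))
})

test_that("all-zero nuclei are dropped with a report", {
  cts <- sim$counts[, 1:100]
  cts[, 3] <- 0
  expect_message(out <- cluster_nuclei(cts, seed = 1), "all-zero")
  expect_equal(out$dropped, colnames(cts)[3])
  expect_equal(nrow(out$nuclei), 99)
})

test_that("duplicating every nucleus preserves the clustering", {
  idx <- 1:400
  cts <- sim$counts[, idx]
  dup <- cbind(cts, cts)
  colnames(dup) <- c(colnames(cts), paste0(colnames(cts), "_d"))
  out <- cluster_nuclei(dup, seed = 1)
  a <- out$nuclei$cluster[1:400]
  b <- out$nuclei$cluster[401:800]
  expect_gt(mean(a == b), 0.95)
})

test_that("arm dosage recovers the planted 1p/19q loss", {
  dos <- infer_arm_dosage(sim$counts, cl, sim$features)
  arms <- tidy(dos)
  cmp <- call_compartments(dos)
  neo_truth <- table(cl$nuclei$cluster, truth_tbl$compartment)
  planted_neo <- rownames(neo_truth)[
    neo_truth[, "neoplastic"] / rowSums(neo_truth) > 0.5]
  called_neo <- cmp$cluster[cmp$compartment == "neoplastic"]
  expect_setequal(called_neo, planted_neo)
  # estimated arm log2-ratio within +-0.1 of log2(planted dosage)
  del <- arms[arms$cluster %in% planted_neo & arms$arm %in% c("1p", "19q"), ]
  expect_true(all(abs(del$score - log2(0.5)) < 0.1))
  expect_true(all(del$call == "loss"))
  intact <- arms[arms$cluster %in% planted_neo &
                   arms$arm %in% c("1q", "19p"), ]
  expect_true(all(intact$call == "intact"))
  # non-neoplastic clusters carry no loss calls on 1p/19q
  other <- arms[!(arms$cluster %in% planted_neo) &
                  arms$arm %in% c("1p", "19q"), ]
  expect_true(all(other$call == "intact"))
})

test_that("dosage 1.0 produces no codeletion calls anywhere", {
  s0 <- gen_snseq(sn_truth(n_nuclei = 400, genes_per_arm = 150,
                           deleted_arm_dosage = 1, seed = 9))
  c0 <- cluster_nuclei(s0$counts, seed = 2)
  d0 <- infer_arm_dosage(s0$counts, c0, s0$features)
  expect_true(all(d0$clusters$codeletion_fraction < 0.5))
  cmp0 <- call_compartments(d0)
  expect_false(any(cmp0$compartment == "neoplastic"))
})

test_that("a reference cluster scores near zero against itself", {
  nn <- names(which.max(table(cl$nuclei$cluster[planted != "neoplastic"])))
  dos <- infer_arm_dosage(sim$counts, cl, sim$features,
                          reference_clusters = nn,
                          update_reference = FALSE)
  self <- tidy(dos)
  self <- self[self$cluster == nn, ]
  expect_true(all(abs(self$score) < 0.02))
})

test_that("compartment calls follow the universality rule and ignore ids", {
  prof <- tibble::tibble(cluster = c("A", "B", "C"),
                         codeletion_fraction = c(1, 0, 0.5))
  cmp <- call_compartments(prof)
  expect_equal(cmp$compartment,
               c("neoplastic", "non-neoplastic", "excluded"))
  # invariant to relabeling cluster ids
  prof2 <- prof; prof2$cluster <- c("Z9", "K2", "Q1")
  expect_equal(call_compartments(prof2)$compartment, cmp$compartment)
  # boundary: exactly u is neoplastic, exactly 1-u non-neoplastic
  prof3 <- tibble::tibble(cluster = "x", codeletion_fraction = 0.95)
  expect_equal(call_compartments(prof3)$compartment, "neoplastic")
})

test_that("marker panels assign the planted cell types", {
  cmp <- call_compartments(infer_arm_dosage(sim$counts, cl, sim$features))
  nn <- cmp$cluster[cmp$compartment == "non-neoplastic"]
  types <- assign_cell_types(sim$counts, cl, which_clusters = nn)
  tab <- table(cl$nuclei$cluster, planted)
  for (i in seq_len(nrow(types))) {
    truth_type <- colnames(tab)[which.max(tab[types$cluster[i], ])]
    expect_equal(types$cell_type[i], truth_type)
  }
  # flat expression across panels gives unassigned
  flat <- matrix(5, nrow = length(unlist(default_marker_sets())), ncol = 60,
                 dimnames = list(unlist(default_marker_sets()),
                                 paste0("n", 1:60)))
  ty <- assign_cell_types(flat, rep(c("c1", "c2"), each = 30))
  expect_true(all(ty$cell_type == "unassigned"))
})

test_that("program scores behave like Tirosh-style relative scores", {
  # identical expression everywhere: program minus control is exactly 0
  flat <- matrix(3, 20, 10, dimnames = list(paste0("g", 1:20),
                                            paste0("n", 1:10)))
  expect_equal(unname(relative_program_score(flat, c("g1", "g2"))),
               rep(0, 10))
  # worked 3-gene example on a single-bin toy profile, hand-computed
  toy <- matrix(seq_len(50), 10, 5,
                dimnames = list(paste0("g", 1:10), paste0("n", 1:5)))
  prog <- c("g1", "g2", "g3")
  centered <- toy - rowMeans(toy)
  hand <- colMeans(centered[prog, ]) - colMeans(centered)
  got <- relative_program_score(toy, prog, bins = 1, n_ctrl = Inf)
  expect_equal(got, hand)
  # random gene sets score near zero on average
  expr <- logcounts(sim$counts[, truth_tbl$compartment == "neoplastic"][, 1:200])
  draws <- vapply(1:300, function(s) {
    gs <- withr::with_seed(s, sample(rownames(expr), 30))
    mean(relative_program_score(expr, gs, seed = s))
  }, numeric(1))
  expect_lt(abs(mean(draws)), 0.02)
})

test_that("permutation p-values respect the add-one floor", {
  expr <- logcounts(sim$counts[, 1:60])
  st <- permutation_state_test(expr, default_state_programs()[1],
                               n_perm = 499, seed = 2)
  expect_true(all(st$p >= 1 / 500))
  expect_true(all(st$p > 0 & st$p <= 1))
  expect_error(permutation_state_test(expr, default_state_programs()[1],
                                      n_perm = 0), "n_perm")
})

test_that("planted states are recovered with FDR-gated assignment", {
  neo <- truth_tbl$compartment == "neoplastic"
  expr <- logcounts(sim$counts[, neo])
  st <- permutation_state_test(expr, default_state_programs(),
                               n_perm = 2000, seed = 9)
  asg <- assign_state(st)
  truth_states <- truth_tbl$state[neo][match(asg$barcode,
                                             truth_tbl$barcode[neo])]
  non_grad <- truth_states != "gradient"
  acc <- mean(asg$state[non_grad] == truth_states[non_grad])
  expect_gte(acc, 0.85)
  # planted gradient nuclei mostly stay gradient
  expect_gte(mean(asg$state[!non_grad] == "gradient"), 0.9)
})

test_that("state assignment follows the lowest-FDR rule with tie-breaks", {
  grid <- tibble::tibble(
    barcode = rep(c("b1", "b2", "b3"), each = 4),
    state = rep(c("OPC-like", "Astro-like", "Cycling", "RE"), 3),
    score = c(1, 0, 0, 0,  0, 0, 0, 0,  1, 2, 0, 0),
    fdr = c(0.001, 0.2, 0.9, 1,  0.2, 0.3, 0.4, 0.5,  0.005, 0.005, 0.9, 1))
  asg <- assign_state(grid)
  expect_equal(asg$state[asg$barcode == "b1"], "OPC-like")
  expect_equal(asg$state[asg$barcode == "b2"], "gradient")
  # tie on FDR broken by the larger score
  expect_equal(asg$state[asg$barcode == "b3"], "Astro-like")
})

test_that("stemness and lineage scores track the planted phenotypes", {
  neo <- truth_tbl$compartment == "neoplastic"
  expr <- logcounts(sim$counts[, neo])
  sc <- stemness_lineage_scores(expr)
  states <- truth_tbl$state[neo]
  expect_gt(mean(sc$oc_score[states == "OPC-like"]),
            mean(sc$ac_score[states == "OPC-like"]))
  expect_gt(mean(sc$ac_score[states == "Astro-like"]),
            mean(sc$oc_score[states == "Astro-like"]))
  stem_hi <- states %in% c("OPC-like", "Cycling")
  tt <- t.test(sc$stemness_score[stem_hi], sc$stemness_score[!stem_hi])
  expect_gt(unname(tt$statistic), 0)
  expect_lt(tt$p.value, 0.01)
})

test_that("sparse-marker prevalence contrasts recover the planted ordering", {
  ann <- tibble::tibble(
    barcode = truth_tbl$barcode,
    marker_active = truth_tbl$marker_active,
    group = dplyr::case_when(
      truth_tbl$compartment != "neoplastic" ~ "non-neoplastic",
      truth_tbl$state == "Cycling" ~ "cycling",
      TRUE ~ "other-neoplastic"))
  res <- compare_marker_prevalence(ann, group = "group")
  cyc <- res[res$group1 == "cycling" | res$group2 == "cycling", ]
  expect_true(all(cyc$p < 0.05))
  # agreement with the hypergeometric enumeration oracle
  r1 <- res[1, ]
  tab <- matrix(c(round(r1$prev1 * r1$n1), r1$n1 - round(r1$prev1 * r1$n1),
                  round(r1$prev2 * r1$n2), r1$n2 - round(r1$prev2 * r1$n2)),
                2, byrow = TRUE)
  expect_equal(r1$p, fisher_oracle(tab), tolerance = 1e-8)
  # all-zero marker: p = 1, not significant
  ann0 <- ann; ann0$marker_active <- FALSE
  res0 <- compare_marker_prevalence(ann0, group = "group")
  expect_true(all(res0$p == 1))
})
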