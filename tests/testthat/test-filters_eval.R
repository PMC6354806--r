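# Gene-list and differential-expression filters, sensitivity / FPR
# arithmetic, the consensus-threshold ROC and the seed-size sweep.

# fold changes as printed for the 14 RydC candidates chosen for testing
# (treatment/control ratios from the pulse-expression experiment)
rydc_fold_changes <- c(31.00, 0.32, 0.63, 0.67, 0.30, 0.67, 0.30, 1.00,
                       0.30, 0.59, 3.49, 0.75, 0.91, 1.17)

small_report <- function() {
  tabs <- list(
    rbind(mk_pred("T", "g1", -50, -35), mk_pred("T", "g2", 10, 25),
          mk_pred("T", "g3", -20, -5)),
    rbind(mk_pred("S", "g1", -45, -30), mk_pred("S", "g2", 12, 27)),
    rbind(mk_pred("I", "g4", 30, 45))
  )
  collate(tabs)
}

test_that("gene-list filtering is exact set intersection, ranks untouched", {
  rep0 <- small_report()
  all_genes <- unique(rep0$entries$gene)
  expect_identical(apply_gene_filter(rep0, all_genes)$entries, rep0$entries)
  expect_identical(nrow(apply_gene_filter(rep0, character())$entries), 0L)
  withr::local_seed(3)
  for (i in 1:10) {
    keep <- sample(c(all_genes, "ghost"), sample(1:4, 1))
    got <- apply_gene_filter(rep0, keep)
    expect_identical(sort(unique(got$entries$gene)),
                     sort(intersect(all_genes, keep)))
    expect_identical(got$entries,
                     rep0$entries[rep0$entries$gene %in% keep, ],
                     ignore_attr = TRUE)
  }
})

test_that("the DE filter keeps strong responders and drops flat genes", {
  rep0 <- small_report()
  de <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                   fold_change = c(31.00, 1.00, 0.30, 2.0),
                   q_value = c(0.001, 0.001, 0.002, 0.5))
  got <- apply_de_filter(rep0, de, filter_spec())
  # 31.00 up and 0.30 down pass; 1.00 is flat; g4 fails the q cutoff
  expect_identical(sort(unique(got$entries$gene)), c("g1", "g3"))
  # genes absent from the DE table are dropped
  got2 <- apply_de_filter(rep0, de[de$gene == "g1", , drop = FALSE], filter_spec())
  expect_identical(unique(got2$entries$gene), "g1")
  # inclusive bounds keep a gene sitting exactly on 1.5 / 0.5
  de_edge <- data.frame(gene = c("g1", "g2"), fold_change = c(1.5, 0.5),
                        q_value = c(0.001, 0.001))
  expect_identical(sort(unique(apply_de_filter(rep0, de_edge)$entries$gene)),
                   c("g1", "g2"))
  expect_identical(nrow(apply_de_filter(
    rep0, de_edge, filter_spec(inclusive = FALSE))$entries), 0L)
})

test_that("the printed fold-change column retains exactly six genes", {
  de <- data.frame(gene = sprintf("t%02d", seq_along(rydc_fold_changes)),
                   fold_change = rydc_fold_changes,
                   q_value = 0.001)
  spec <- filter_spec()
  kept <- de$fold_change[de$fold_change >= spec$fc_up |
                           de$fold_change <= spec$fc_down]
  expect_identical(sort(kept), sort(c(31.00, 0.32, 0.30, 0.30, 0.30, 3.49)))
  expect_identical(length(srnacons:::de_passing_genes(de, spec)), 6L)
})

test_that("a degenerate filter spec is the identity on genes in the DE table", {
  rep0 <- small_report()
  genes <- unique(rep0$entries$gene)
  de <- data.frame(gene = genes, fold_change = runif(length(genes), 0.2, 5),
                   q_value = runif(length(genes)))
  got <- apply_de_filter(rep0, de, filter_spec(fc_up = 1, fc_down = 1, q_max = 1))
  expect_identical(got$entries, rep0$entries)
})

test_that("sensitivity and FPR reproduce the printed percent arithmetic", {
  expect_equal(sensitivity_pct(10, 18), 55.6, tolerance = 1e-3)
  expect_identical(percent_display(sensitivity_pct(10, 18)), 56L)
  expect_identical(percent_display(sensitivity_pct(3, 8)), 38L)
  expect_identical(percent_display(sensitivity_pct(17, 18)), 94L)
  expect_equal(sensitivity_pct(8, 8), 100)
  expect_equal(sensitivity_pct(0, 5), 0)
  expect_equal(false_positive_rate_pct(0, 12), 0)
  expect_equal(false_positive_rate_pct(6, 12), 50)
  expect_equal(false_positive_rate_pct(12, 12), 100)
  expect_error(sensitivity_pct(1, 0), "n_known")
  expect_error(false_positive_rate_pct(0, 0), "n_nontargets")
  expect_error(sensitivity_pct(9, 8), "n_correct")
  # scale-free
  withr::local_seed(12)
  for (i in 1:10) {
    b <- sample(1:50, 1); a <- sample(0:b, 1)
    expect_equal(sensitivity_pct(a, b), sensitivity_pct(10 * a, 10 * b))
    expect_equal(false_positive_rate_pct(a, b),
                 false_positive_rate_pct(10 * a, 10 * b))
  }
})

roc_fixture <- function() {
  known <- data.frame(gene = c("k1", "k2"), mrna_start = -60L, mrna_end = -41L,
                      srna_start = NA, srna_end = NA, source = "assay")
  tabs <- list(
    rbind(mk_pred("T", "k1", -55, -40), mk_pred("T", "k2", -60, -45),
          mk_pred("T", "n1", 10, 25)),
    rbind(mk_pred("S", "k1", -58, -42), mk_pred("S", "k2", -59, -44)),
    rbind(mk_pred("I", "k1", -50, -38))
  )
  collate(tabs, known_sites = known)
}

test_that("consensus ROC hits the ideal corner on a clean fixture and is monotone", {
  rep0 <- roc_fixture()
  ev <- consensus_roc(rep0, known_targets = c("k1", "k2"),
                      nontargets = c("n1", "n2", "n3"))
  expect_equal(unname(ev$tpr_by_k[["2"]]), 100)
  expect_equal(unname(ev$fpr_by_k[["2"]]), 0)
  # n1 has a single-channel call: FPR at k=1 only
  expect_equal(unname(ev$fpr_by_k[["1"]]), 100 / 3)
  # k=1 dominates k=4 in both coordinates
  expect_gte(ev$tpr_by_k[["1"]], ev$tpr_by_k[["4"]])
  expect_gte(ev$fpr_by_k[["1"]], ev$fpr_by_k[["4"]])
  expect_true(all(diff(ev$points$tpr) <= 0))
  expect_true(all(diff(ev$points$fpr) <= 0))
  expect_error(consensus_roc(rep0, c("k1"), c("k1", "n1")), "overlap")
})

test_that("ROC points equal an exhaustive per-gene recount on random designs", {
  withr::local_seed(44)
  for (rep in 1:15) {
    design <- random_fixture_design(n_genes = 10, rng_seed = sample.int(1e6, 1))
    if (nrow(design) == 0) next
    mock <- synth_prediction_tables(design, rng_seed = sample.int(1e6, 1))
    rep0 <- collate(mock$tables, known_sites = mock$known_sites)
    known <- unique(mock$known_sites$gene)
    nontargets <- setdiff(unique(design$gene), known)
    if (length(known) == 0 || length(nontargets) == 0) next
    ev <- consensus_roc(rep0, known, nontargets)
    e <- rep0$entries
    for (k in 1:4) {
      tpr_naive <- 100 * sum(vapply(known, function(g) {
        any(e$gene == g & e$classification == "correct" & e$agreement >= k)
      }, logical(1))) / length(known)
      fpr_naive <- 100 * sum(vapply(nontargets, function(g) {
        any(e$gene == g & e$agreement >= k)
      }, logical(1))) / length(nontargets)
      expect_equal(unname(ev$tpr_by_k[[as.character(k)]]), tpr_naive)
      expect_equal(unname(ev$fpr_by_k[[as.character(k)]]), fpr_naive)
    }
    expect_true(all(diff(ev$points$tpr) <= 0))
    expect_true(all(diff(ev$points$fpr) <= 0))
  }
})

test_that("seed sweeps lose a capped site exactly past its run length", {
  pl <- data.frame(gene_index = c(1, 3, 5), rel_start = c(-40, -30, 15),
                   len = c(18, 13, 16), srna_start = c(3, 22, 40),
                   max_run = c(NA, 6, NA))
  fix <- synth_genome(fixture_spec(n_genes = 6, planted = pl, rng_seed = 77))
  known <- truth_as_known_sites(fix$truth)
  sweep <- seed_sweep(fix$srna, fix$ann, known, seeds = 5:8,
                      params = scan_params("relaxed", p_threshold = "unfiltered",
                                           n_shuffles = 30))
  expect_identical(sweep$seed, 5:8)
  expect_true(all(diff(sweep$sensitivity) <= 0))
  # all three found up to seed 6; the 6-run site lost at seed 7
  expect_equal(sweep$sensitivity[sweep$seed == 5], 100)
  expect_equal(sweep$sensitivity[sweep$seed == 6], 100)
  expect_equal(sweep$n_correct[sweep$seed == 7], 2L)
  expect_equal(sweep$n_correct[sweep$seed == 8], 2L)
  expect_error(seed_sweep(fix$srna, fix$ann, known[0, ]), "n_known")
})
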