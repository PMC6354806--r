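# Cross-channel collation: interval overlap, classification, single-linkage
# agreement, rank assignment, report collation and recollation.

test_that("prediction tables round-trip and reject convention violations", {
  dir <- withr::local_tempdir()
  tab <- rbind(mk_pred("T", "cfa", -110, -98), mk_pred("S", "cfa", -110, -98),
               mk_pred("I", "grpE", 16, 29), mk_pred("C", "moaB", 27, 42),
               mk_pred("T", "araH", 9, 25))
  p <- file.path(dir, "t.tsv")
  write_prediction_table(tab, p)
  re <- read_prediction_table(p)
  expect_equal(re, tab[names(re)], ignore_attr = TRUE)
  expect_identical(nrow(re), 5L)
  # channel override
  re2 <- read_prediction_table(p, channel_label = "X")
  expect_identical(unique(re2$channel), "X")
  # interval containing 0 is rejected with its line number
  bad <- tab; bad$mrna_start[2] <- 0
  pb <- file.path(dir, "bad.tsv")
  write_prediction_table(bad, pb)
  expect_error(read_prediction_table(pb), "row 2.*position 0")
  # unknown columns are rejected
  writeLines(c("channel\tgene\tfoo", "T\tg\t1"), file.path(dir, "cols.tsv"))
  expect_error(read_prediction_table(file.path(dir, "cols.tsv")), "unknown column")
})

test_that("interval overlap follows the no-zero convention", {
  expect_true(intervals_overlap(c(-110, -98), c(-110, -98)))
  expect_true(intervals_overlap(c(-110, -98), c(-98, -80)))   # share -98
  expect_false(intervals_overlap(c(-24, -10), c(12, 22)))
  expect_identical(rel_span(-3, 2), 5L)                        # -3..+2 skips 0
  expect_identical(rel_span(4, 11), 8L)
  # min_overlap counts shared positions across the origin correctly
  expect_true(intervals_overlap(c(-3, 2), c(-1, 5), min_overlap = 3L))
  expect_false(intervals_overlap(c(-3, 2), c(1, 5), min_overlap = 3L))
  expect_error(intervals_overlap(c(0, 5), c(1, 2)), "position 0")
})

test_that("predictions classify as correct, inconsistent or novel", {
  known <- data.frame(gene = "cfa", mrna_start = -110L, mrna_end = -98L,
                      srna_start = 2L, srna_end = 14L, source = "assay")
  expect_identical(classify_prediction(mk_pred("T", "cfa", -110, -98), known),
                   "correct")
  expect_identical(classify_prediction(mk_pred("T", "cfa", -200, -150), known),
                   "inconsistent")
  expect_identical(classify_prediction(mk_pred("T", "yigL", -110, -98), known),
                   "novel")
  expect_identical(classify_prediction(mk_pred("T", "cfa", -110, -98), NULL),
                   "novel")
})

test_that("agreement clustering is single linkage over interval overlap", {
  two <- rbind(mk_pred("T", "g", -50, -31), mk_pred("S", "g", -50, -31))
  expect_identical(agreement_clusters(two), c(1L, 1L))
  three <- rbind(mk_pred("T", "g", 1, 10), mk_pred("S", "g", 30, 40),
                 mk_pred("I", "g", 60, 70))
  expect_identical(agreement_clusters(three), 1:3)
  # chain: A overlaps B, B overlaps C, A does not overlap C -> one cluster
  chain <- rbind(mk_pred("T", "g", 1, 15), mk_pred("S", "g", 10, 25),
                 mk_pred("I", "g", 20, 35))
  expect_identical(agreement_clusters(chain), c(1L, 1L, 1L))
  expect_error(agreement_clusters(rbind(mk_pred("T", "a", 1, 5),
                                        mk_pred("T", "b", 1, 5))),
               "single gene")
  # random interval sets match the transitive-closure oracle
  withr::local_seed(606)
  for (rep in 1:40) {
    n <- sample(2:8, 1)
    starts <- sample(c(-80:-1, 1:80), n)
    ends <- starts + sample(5:25, n, TRUE)
    ends <- ifelse(ends == 0L, 1L, ends)   # endpoints never sit on 0
    preds <- do.call(rbind, lapply(seq_len(n), function(i) {
      mk_pred(LETTERS[i], "g", starts[i], ends[i])
    }))
    expect_identical(agreement_clusters(preds),
                     oracle_clusters(starts, ends))
  }
})

test_that("rank tiers follow the 1-7 prioritisation with best tier winning", {
  # known site, correct from 3 channels, 1 inconsistent channel -> rank 1
  expect_identical(assign_rank(c("correct", "correct", "correct", "inconsistent"),
                               c("S", "I", "C", "T"), c(1L, 1L, 1L, 2L), TRUE), 1L)
  # known site, single correct channel -> rank 2
  expect_identical(assign_rank(c("correct", "inconsistent"), c("I", "T"),
                               c(1L, 2L), TRUE), 2L)
  # known site, nothing correct -> rank 3
  expect_identical(assign_rank("inconsistent", "T", 1L, TRUE), 3L)
  # no known site, two channels agreeing -> rank 4
  expect_identical(assign_rank(c("novel", "novel"), c("T", "I"), c(1L, 1L), FALSE), 4L)
  # single-channel novel: C -> 5, T or S -> 6, I -> 7
  expect_identical(assign_rank("novel", "C", 1L, FALSE), 5L)
  expect_identical(assign_rank("novel", "T", 1L, FALSE), 6L)
  expect_identical(assign_rank("novel", "S", 1L, FALSE), 6L)
  expect_identical(assign_rank("novel", "I", 1L, FALSE), 7L)
  # disjoint novel predictions from several channels: best channel tier
  expect_identical(assign_rank(c("novel", "novel"), c("C", "I"), c(1L, 2L), FALSE), 5L)
  expect_error(assign_rank(character(), character(), integer(), FALSE),
               "zero retained predictions")
})

test_that("collation merges channels, ranks genes and is deterministic", {
  tabs <- list(mk_pred("T", "gA", -50, -35, sig = 0.02),
               mk_pred("S", "gA", -45, -30, sig = 0.01),
               mk_pred("I", "gA", -48, -33, sig = 0.3))
  rep1 <- collate(tabs)
  expect_identical(unique(rep1$entries$gene), "gA")
  expect_identical(unique(rep1$entries$rank), 4L)
  expect_identical(unique(rep1$entries$agreement), 3L)
  # rank is the last column
  expect_identical(names(rep1$entries)[ncol(rep1$entries)], "rank")
  # byte-identical reports for identical inputs
  dir <- withr::local_tempdir()
  write_report(rep1, file.path(dir, "a"))
  write_report(collate(tabs), file.path(dir, "b"))
  expect_identical(readLines(file.path(dir, "a.tsv")),
                   readLines(file.path(dir, "b.tsv")))
  expect_error(collate(list()), "no channel data")
})

test_that("collation reproduces the naive answer key over random designs", {
  withr::local_seed(99)
  for (rep in 1:60) {
    design <- random_fixture_design(n_genes = 8, rng_seed = sample.int(1e6, 1))
    if (nrow(design) == 0) next
    mock <- synth_prediction_tables(design, rng_seed = sample.int(1e6, 1))
    got <- collate(mock$tables, known_sites = mock$known_sites)
    e <- got$entries
    key <- mock$key
    for (g in unique(key$gene)) {
      eg <- e[e$gene == g, ]
      kg <- key[key$gene == g, ]
      eg <- eg[order(eg$channel, eg$mrna_start), ]
      kg <- kg[order(kg$channel, kg$mrna_start), ]
      expect_identical(unique(eg$rank), unique(kg$expected_rank))
      expect_identical(eg$classification, kg$expected_class)
      expect_identical(as.integer(eg$agreement), as.integer(kg$expected_agreement))
    }
  }
})

test_that("recollation reproduces collation without re-running channels", {
  design <- random_fixture_design(n_genes = 10, rng_seed = 21)
  mock <- synth_prediction_tables(design, rng_seed = 22)
  dir <- withr::local_tempdir()
  save_raw_results(mock$tables, dir, known_sites = mock$known_sites)
  direct <- collate(mock$tables, known_sites = mock$known_sites)
  re <- recollate(dir)
  expect_equal(re$entries, direct$entries, tolerance = 1e-9)
  # unchanged filters -> identical report files
  d2 <- withr::local_tempdir()
  write_report(direct, file.path(d2, "direct"))
  write_report(re, file.path(d2, "re"))
  expect_identical(readLines(file.path(d2, "re.tsv")),
                   readLines(file.path(d2, "direct.tsv")))
  # gene-list narrowing: subset with unchanged ranks
  keep <- unique(direct$entries$gene)[1:3]
  sub <- recollate(dir, filters = filter_spec(gene_list = keep))
  expect_identical(sort(unique(sub$entries$gene)), sort(keep))
  merged <- merge(sub$entries[c("gene", "channel", "mrna_start", "rank")],
                  direct$entries[c("gene", "channel", "mrna_start", "rank")],
                  by = c("gene", "channel", "mrna_start"))
  expect_identical(merged$rank.x, merged$rank.y)
  # widening filters is monotone in membership
  wide <- recollate(dir, filters = filter_spec(gene_list = unique(direct$entries$gene)))
  expect_true(all(sub$entries$gene %in% wide$entries$gene))
  expect_gte(nrow(wide$entries), nrow(sub$entries))
  expect_error(recollate(file.path(dir, "nope")), "no saved raw results")
})
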