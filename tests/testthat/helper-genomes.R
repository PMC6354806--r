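# Hand-built miniature genomes used across test files.

# A two-gene annotation constructed directly (no file round trip).
tiny_ann <- function(sequence = NULL) {
  # positions:        1         11        21        31        41        51
  #                   |         |         |         |         |         |
  seq0 <- sequence %||% "ACGTACGTACATGGCTAAATTTGCCGGGTACCCATTTTGACGTACGTACGTA"
  genes <- data.frame(
    locus_tag = c("g1", "g2"),
    gene_name = c("alpha", "beta"),
    strand = c("+", "-"),
    cds_start = c(11L, 31L),
    cds_end = c(22L, 42L),
    product = c("forward test gene", "reverse test gene"),
    stringsAsFactors = FALSE
  )
  structure(list(sequence = seq0, genes = genes, genome_id = "mini"),
            class = "genome_annotation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tiny_fixture_files <- function(dir, ann = tiny_ann()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(dir, "mini.fna"), ptt = file.path(dir, "mini.ptt"))
  write_genome(ann, paths["fasta"], paths["ptt"])
  paths
}

to_rna_str <- function(x) chartr("T", "U", toupper(x))

# canonical one-row prediction table
mk_pred <- function(channel, gene, ms, me, ss = 5L, se = 20L,
                    score = -20, sig = 0.01) {
  data.frame(channel = channel, gene = gene, mrna_start = ms, mrna_end = me,
             srna_start = ss, srna_end = se, score = score, significance = sig,
             passed_threshold = TRUE, stringsAsFactors = FALSE)
}
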