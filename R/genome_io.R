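# Genome + annotation ingestion and start-codon window extraction.
#
# A genome_annotation holds one replicon's sequence (DNA alphabet internally)
# and a gene table in NCBI PTT column order. All genomic coordinates are
# 1-based inclusive; the translation anchor (+1) is the leftmost CDS base for
# plus-strand genes and the rightmost for minus-strand genes.

#' Load a genome and its annotation
#'
#' Reads a single-replicon FASTA and an NCBI PTT gene table into a validated
#' `genome_annotation` object. U is normalised to T internally; windows are
#' emitted in the RNA alphabet by [extract_window()].
#'
#' @param sequence_path path to a FASTA file holding one replicon.
#' @param annotation_path path to a tab-delimited PTT table (columns
#'   Location, Strand, Length, PID, Gene, Synonym, Code, COG, Product; the
#'   Synonym column is the locus tag).
#' @return a `genome_annotation`: list with `sequence` (character string),
#'   `genes` (data.frame with locus_tag, gene_name, strand, cds_start,
#'   cds_end, product) and `genome_id`.
#' @export
load_genome <- function(sequence_path, annotation_path) {
  if (!file.exists(sequence_path)) stop("genome FASTA not found: ", sequence_path)
  if (!file.exists(annotation_path)) stop("annotation not found: ", annotation_path)
  ss <- Biostrings::readBStringSet(sequence_path)
  if (length(ss) == 0L) stop("no sequence in FASTA: ", sequence_path)
  if (length(ss) > 1L) stop("multi-replicon FASTA not supported (", length(ss), " records)")
  sequence <- to_dna(as.character(ss[[1L]]))
  if (grepl("[^ACGTN]", sequence)) stop("genome sequence contains non-ACGTUN characters")
  genome_id <- sub("\\s.*$", "", names(ss)[1L])
  genes <- read_ptt(annotation_path)
  validate_genes(genes, nchar(sequence))
  structure(
    list(sequence = sequence, genes = genes, genome_id = genome_id),
    class = "genome_annotation"
  )
}

ptt_columns <- c("Location", "Strand", "Length", "PID", "Gene", "Synonym",
                 "Code", "COG", "Product")

# PTT layout: free-text title line, "<n> proteins" line, header line, rows.
read_ptt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- which(startsWith(lines, "Location"))[1L]
  if (is.na(hdr)) stop("no PTT header line (starting with 'Location') in ", path)
  body <- lines[seq.int(hdr + 1L, length.out = max(0L, length(lines) - hdr))]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) {
    return(data.frame(locus_tag = character(), gene_name = character(),
                      strand = character(), cds_start = integer(),
                      cds_end = integer(), product = character()))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 9L)
  if (length(bad)) {
    stop("malformed PTT row(s) at line ", paste(hdr + bad, collapse = ", "),
         " of ", path, " (expected 9 tab-separated columns)")
  }
  tab <- do.call(rbind, lapply(fields, function(f) f[1:9]))
  loc <- regmatches(tab[, 1L], regexec("^(\\d+)\\.\\.(\\d+)$", tab[, 1L]))
  badloc <- which(lengths(loc) != 3L)
  if (length(badloc)) {
    stop("unparseable Location '", tab[badloc[1L], 1L], "' at line ",
         hdr + badloc[1L], " of ", path)
  }
  starts <- as.integer(vapply(loc, `[`, "", 2L))
  ends <- as.integer(vapply(loc, `[`, "", 3L))
  if (any(tab[, 2L] != "+" & tab[, 2L] != "-")) {
    i <- which(tab[, 2L] != "+" & tab[, 2L] != "-")[1L]
    stop("invalid strand '", tab[i, 2L], "' at line ", hdr + i, " of ", path)
  }
  data.frame(
    locus_tag = tab[, 6L],
    gene_name = ifelse(tab[, 5L] == "-", NA_character_, tab[, 5L]),
    strand = tab[, 2L],
    cds_start = starts,
    cds_end = ends,
    product = tab[, 9L],
    stringsAsFactors = FALSE
  )
}

validate_genes <- function(genes, seq_len) {
  if (any(genes$cds_end < genes$cds_start)) {
    i <- which(genes$cds_end < genes$cds_start)[1L]
    stop("gene ", genes$locus_tag[i], ": end (", genes$cds_end[i],
         ") < start (", genes$cds_start[i], ")")
  }
  if (any(genes$cds_start < 1L) || any(genes$cds_end > seq_len)) {
    i <- which(genes$cds_start < 1L | genes$cds_end > seq_len)[1L]
    stop("gene ", genes$locus_tag[i], ": coordinates ", genes$cds_start[i],
         "..", genes$cds_end[i], " outside sequence of length ", seq_len)
  }
  dup <- genes$locus_tag[duplicated(genes$locus_tag)]
  if (length(dup)) stop("duplicate locus_tag: ", paste(unique(dup), collapse = ", "))
  invisible(TRUE)
}

#' Write a genome annotation back to FASTA + PTT files
#'
#' Inverse of [load_genome()]; reloading the written files reproduces
#' identical gene records and sequence.
#'
#' @param ann a `genome_annotation`.
#' @param sequence_path,annotation_path output paths.
#' @return invisibly, the two paths.
#' @export
write_genome <- function(ann, sequence_path, annotation_path) {
  stopifnot(inherits(ann, "genome_annotation"))
  ss <- Biostrings::DNAStringSet(ann$sequence)
  names(ss) <- ann$genome_id
  Biostrings::writeXStringSet(ss, sequence_path, width = 70L)
  g <- ann$genes
  rows <- paste(
    paste0(g$cds_start, "..", g$cds_end), g$strand,
    g$cds_end - g$cds_start + 1L, "-",
    ifelse(is.na(g$gene_name), "-", g$gene_name),
    g$locus_tag, "-", "-", g$product,
    sep = "\t"
  )
  writeLines(c(
    paste0(ann$genome_id, " - 1..", nchar(ann$sequence)),
    paste0(nrow(g), " proteins"),
    paste(ptt_columns, collapse = "\t"),
    rows
  ), annotation_path)
  invisible(c(sequence_path, annotation_path))
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation '", x$genome_id, "': ", nchar(x$sequence), " nt, ",
      nrow(x$genes), " genes\n", sep = "")
  invisible(x)
}

# Map translation-relative positions to genomic coordinates for one gene row.
rel_to_genomic <- function(gene, rel) {
  if (gene$strand == "+") {
    ifelse(rel > 0, gene$cds_start + rel - 1L, gene$cds_start + rel)
  } else {
    ifelse(rel > 0, gene$cds_end - rel + 1L, gene$cds_end - rel)
  }
}

#' Extract the search window around a gene's start codon
#'
#' Returns the coding-strand-oriented RNA window covering translation-relative
#' positions -up..+down (position 0 does not exist: -1 abuts +1, and +1 is the
#' first base of the start codon). Windows running off the replicon end are
#' clipped silently, with the clipped base counts recorded; the replicon is
#' treated as linear.
#'
#' @param ann a `genome_annotation`.
#' @param gene locus tag of the gene.
#' @param up,down non-negative nucleotide counts upstream/downstream of the
#'   translation start (e.g. 80/20 stringent, 150/100 relaxed).
#' @return a `window_sequence`: list with `gene` (one-row gene record), `seq`
#'   (RNA string 5'->3' on the coding strand), `rel_coords` (integer vector,
#'   one translation-relative position per base), `clipped_up`, `clipped_down`.
#' @export
extract_window <- function(ann, gene, up, down) {
  stopifnot(inherits(ann, "genome_annotation"))
  if (up < 0 || down < 0) stop("up and down must be >= 0")
  if (up == 0 && down == 0) stop("empty window: up = down = 0")
  i <- match(gene, ann$genes$locus_tag)
  if (is.na(i)) stop("unknown gene: ", gene)
  g <- ann$genes[i, , drop = FALSE]
  L <- nchar(ann$sequence)
  rel <- rel_seq(if (up > 0) -up else 1L, if (down > 0) down else -1L)
  gpos <- rel_to_genomic(g, rel)
  inside <- gpos >= 1L & gpos <= L
  clipped_up <- sum(!inside & rel < 0)
  clipped_down <- sum(!inside & rel > 0)
  rel <- rel[inside]
  gpos <- gpos[inside]
  if (length(gpos) == 0L) stop("window for gene ", gene, " lies entirely off the replicon")
  if (g$strand == "+") {
    s <- substr(ann$sequence, gpos[1L], gpos[length(gpos)])
  } else {
    s <- revcomp(substr(ann$sequence, gpos[length(gpos)], gpos[1L]))
  }
  structure(
    list(gene = g, seq = to_rna(s), rel_coords = as.integer(rel),
         clipped_up = as.integer(clipped_up), clipped_down = as.integer(clipped_down)),
    class = "window_sequence"
  )
}

#' @export
print.window_sequence <- function(x, ...) {
  cat("window_sequence for ", x$gene$locus_tag, " (", x$gene$strand, "): ",
      nchar(x$seq), " nt, rel ", x$rel_coords[1L], "..",
      x$rel_coords[length(x$rel_coords)],
      if (x$clipped_up || x$clipped_down)
        paste0(" (clipped ", x$clipped_up, "/", x$clipped_down, ")") else "",
      "\n", sep = "")
  invisible(x)
}

#' Build a swapped annotation for reverse-mode searches
#'
#' Reverse mode queries an mRNA 5' UTR against a catalogue of sRNAs: each sRNA
#' becomes a pseudo-gene whose translation anchor (+1) is its 5' end, so every
#' downstream operation (window extraction, scanning, collation) works
#' unchanged with sRNAs as the "targets".
#'
#' @param srnas data.frame with columns `id`, `start`, `end`, `strand`
#'   (BED-like 4-column catalogue; 1-based inclusive genomic coordinates).
#' @param ann the `genome_annotation` supplying the sequence.
#' @return a `genome_annotation` whose genes are the sRNAs.
#' @export
build_reverse_annotation <- function(srnas, ann) {
  stopifnot(inherits(ann, "genome_annotation"))
  need <- c("id", "start", "end", "strand")
  if (!all(need %in% names(srnas))) {
    stop("sRNA catalogue needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(srnas) == 0L) stop("empty sRNA catalogue")
  dup <- srnas$id[duplicated(srnas$id)]
  if (length(dup)) stop("duplicate sRNA identifier: ", paste(unique(dup), collapse = ", "))
  genes <- data.frame(
    locus_tag = as.character(srnas$id),
    gene_name = as.character(srnas$id),
    strand = as.character(srnas$strand),
    cds_start = as.integer(srnas$start),
    cds_end = as.integer(srnas$end),
    product = "sRNA (reverse-mode pseudo-gene)",
    stringsAsFactors = FALSE
  )
  validate_genes(genes, nchar(ann$sequence))
  structure(
    list(sequence = ann$sequence, genes = genes,
         genome_id = paste0(ann$genome_id, "|srna-catalogue")),
    class = "genome_annotation"
  )
}

#' Read an sRNA catalogue from a BED-like 4-column tab file
#'
#' Columns: id, start, end, strand (1-based inclusive, no header).
#'
#' @param path file path.
#' @return data.frame with columns id, start, end, strand.
#' @export
read_srna_catalogue <- function(path) {
  if (!file.exists(path)) stop("sRNA catalogue not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("id", "start", "end", "strand"),
                           colClasses = c("character", "integer", "integer", "character"))
  tab
}
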