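# Cross-channel collation: binding-site agreement, classification against
# known sites, rank 1-7 assignment, report writing and recollation.
#
# Canonical prediction table columns (tab-delimited, one row per prediction):
#   channel  gene  mrna_start  mrna_end  srna_start  srna_end  score  significance
# Intervals are translation-relative, ascending, and never contain 0.

prediction_columns <- c("channel", "gene", "mrna_start", "mrna_end",
                        "srna_start", "srna_end", "score", "significance")

#' Read a canonical prediction table
#'
#' @param path tab-delimited file with header columns channel, gene,
#'   mrna_start, mrna_end, srna_start, srna_end, score, significance.
#' @param channel_label optional label overriding the file's channel column.
#' @return validated data.frame of prediction records.
#' @export
read_prediction_table <- function(path, channel_label = NULL) {
  if (!file.exists(path)) stop("prediction table not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c(channel = "character", gene = "character"),
                           stringsAsFactors = FALSE)
  unknown <- setdiff(names(tab), c(prediction_columns, "passed_threshold"))
  if (length(unknown)) stop("unknown column(s) in ", path, ": ",
                            paste(unknown, collapse = ", "))
  missing <- setdiff(prediction_columns, names(tab))
  if (length(missing)) stop("missing column(s) in ", path, ": ",
                            paste(missing, collapse = ", "))
  tab <- tab[prediction_columns]
  if (!is.null(channel_label)) tab$channel <- channel_label
  validate_predictions(tab, path)
  tab
}

validate_predictions <- function(tab, what = "prediction table") {
  bad_line <- function(i, msg) {
    stop(what, ", row ", i, " (line ", i + 1L, "): ", msg, call. = FALSE)
  }
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    if (!nzchar(r$channel)) bad_line(i, "empty channel label")
    if (r$mrna_start == 0 || r$mrna_end == 0 || r$srna_start == 0 || r$srna_end == 0) {
      bad_line(i, "interval contains position 0 (no-zero convention)")
    }
    if (r$mrna_end < r$mrna_start) bad_line(i, "mRNA interval end < start")
    if (r$srna_end < r$srna_start) bad_line(i, "sRNA interval end < start")
  }
  invisible(TRUE)
}

#' Write a canonical prediction table
#' @param preds prediction data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_prediction_table <- function(preds, path) {
  utils::write.table(format_doubles(preds[prediction_columns]), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# %.10g survives a write -> read -> write cycle byte-identically (10 decimal
# digits map injectively into doubles), keeping reports reproducible.
format_doubles <- function(df) {
  for (col in names(df)) {
    if (is.double(df[[col]])) df[[col]] <- sprintf("%.10g", df[[col]])
  }
  df
}

#' Do two translation-relative intervals overlap?
#'
#' True iff the intervals share at least `min_overlap` positions under the
#' no-zero convention. Symmetric and (for min_overlap = 1) reflexive.
#'
#' @param a,b length-2 ascending intervals (no endpoint 0).
#' @param min_overlap minimum number of shared positions (default 1).
#' @return logical.
#' @export
intervals_overlap <- function(a, b, min_overlap = 1L) {
  check_rel_interval(a[1L], a[2L])
  check_rel_interval(b[1L], b[2L])
  lo <- max(a[1L], b[1L])
  hi <- min(a[2L], b[2L])
  if (hi < lo) return(FALSE)
  rel_span(lo, hi) >= min_overlap
}

#' Read a known-sites table
#'
#' Tab-delimited with header gene, mrna_start, mrna_end, srna_start,
#' srna_end, source (sRNA columns and source may be NA).
#'
#' @param path file path.
#' @return data.frame of known sites.
#' @export
read_known_sites <- function(path) {
  if (!file.exists(path)) stop("known-sites table not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c(gene = "character"),
                           stringsAsFactors = FALSE)
  need <- c("gene", "mrna_start", "mrna_end")
  missing <- setdiff(need, names(tab))
  if (length(missing)) stop("missing column(s) in ", path, ": ",
                            paste(missing, collapse = ", "))
  for (col in c("srna_start", "srna_end", "source")) {
    if (!col %in% names(tab)) tab[[col]] <- NA
  }
  if (anyDuplicated(tab[c("gene", "mrna_start", "mrna_end")])) {
    stop("duplicate (gene, mRNA interval) in known-sites table ", path)
  }
  tab
}

#' Classify one prediction against the known sites of its gene
#'
#' "correct" when the gene has a known site whose mRNA interval overlaps the
#' prediction's; "inconsistent" when the gene has known sites but none
#' overlap; "novel" when the gene has no known site. Classification uses the
#' mRNA (target) interval only.
#'
#' @param pred one prediction record (one-row data.frame or list with gene,
#'   mrna_start, mrna_end).
#' @param known known-sites data.frame (may be NULL or empty).
#' @param min_overlap minimum shared positions for "same site".
#' @return "correct", "inconsistent" or "novel".
#' @export
classify_prediction <- function(pred, known, min_overlap = 1L) {
  if (is.null(known) || nrow(known) == 0L) return("novel")
  ks <- known[known$gene == pred$gene, , drop = FALSE]
  if (nrow(ks) == 0L) return("novel")
  for (j in seq_len(nrow(ks))) {
    if (intervals_overlap(c(pred$mrna_start, pred$mrna_end),
                          c(ks$mrna_start[j], ks$mrna_end[j]), min_overlap)) {
      return("correct")
    }
  }
  "inconsistent"
}

#' Single-linkage agreement clusters for one gene's predictions
#'
#' Groups predictions whose target (mRNA) intervals overlap pairwise, closed
#' transitively (single linkage): two channels "agree" when their predicted
#' sites overlap by at least `min_overlap` positions, directly or through a
#' chain of overlapping predictions.
#'
#' @param preds predictions of a single gene.
#' @param min_overlap minimum shared positions.
#' @return integer vector of cluster ids (1-based, in order of first member).
#' @export
agreement_clusters <- function(preds, min_overlap = 1L) {
  n <- nrow(preds)
  if (n == 0L) return(integer())
  if (length(unique(preds$gene)) > 1L) {
    stop("agreement_clusters expects predictions of a single gene")
  }
  id <- seq_len(n)
  find <- function(i) { while (id[i] != i) i <- id[i] <<- id[id[i]]; i }
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (intervals_overlap(c(preds$mrna_start[i], preds$mrna_end[i]),
                          c(preds$mrna_start[j], preds$mrna_end[j]),
                          min_overlap)) {
      id[find(j)] <- find(i)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

default_precedence <- function() list("C", c("T", "S"), "I")

#' Assign the prioritisation rank (1-7) for one gene's evidence
#'
#' Tiers, best first: (1) known site correctly predicted by >= 2 channels;
#' (2) known site correctly predicted by 1 channel; (3) predictions
#' inconsistent with the gene's known sites; (4) >= 2 channels agreeing on
#' the same (novel) site; (5)-(7) single-channel novel predictions ordered by
#' channel precedence (default C, then T or S, then I). A gene matching
#' several tiers takes the best one.
#'
#' @param classifications character vector (one per prediction): "correct",
#'   "inconsistent" or "novel".
#' @param channels channel label per prediction.
#' @param cluster_ids cluster id per prediction from [agreement_clusters()].
#' @param has_known_site does the gene have any known site?
#' @param precedence list of channel-label groups mapping to tiers 5, 6, ...;
#'   channels absent from the list fall in the last tier.
#' @return integer rank in 1..(4 + length(precedence)).
#' @export
assign_rank <- function(classifications, channels, cluster_ids,
                        has_known_site, precedence = default_precedence()) {
  n <- length(classifications)
  if (n == 0L) stop("cannot rank a gene with zero retained predictions")
  if (has_known_site) {
    n_correct <- length(unique(channels[classifications == "correct"]))
    if (n_correct >= 2L) return(1L)
    if (n_correct == 1L) return(2L)
    return(3L)
  }
  sizes <- tapply(channels, cluster_ids, function(ch) length(unique(ch)))
  if (any(sizes >= 2L)) return(4L)
  tier_of <- function(ch) {
    for (t in seq_along(precedence)) if (ch %in% precedence[[t]]) return(t)
    length(precedence)
  }
  4L + min(vapply(unique(channels), tier_of, integer(1)))
}

#' Collate channel predictions into a ranked report
#'
#' Merges any number of labelled prediction tables, clusters overlapping
#' sites per gene, classifies each prediction against the known sites,
#' assigns each gene its rank, applies membership filters (gene list,
#' differential expression), and orders entries by (rank, best significance,
#' gene). Ranks are computed before filtering, so filtering changes
#' membership only, never a rank.
#'
#' @param channel_tables a single prediction data.frame or a list of them
#'   (each with its channel column set, e.g. from [read_prediction_table()]
#'   or [scan_srna_vs_annotation()]).
#' @param known_sites optional known-sites data.frame.
#' @param filters optional [filter_spec()].
#' @param min_overlap minimum shared positions defining "same site".
#' @param precedence channel precedence for single-channel tiers.
#' @param provenance optional named list recorded in the report.
#' @return a `collated_report`: list with `entries` (data.frame, one row per
#'   prediction, rank in the last column), `params_echo`, `provenance`.
#' @export
collate <- function(channel_tables, known_sites = NULL, filters = NULL,
                    min_overlap = 1L, precedence = default_precedence(),
                    provenance = list()) {
  if (is.data.frame(channel_tables)) channel_tables <- list(channel_tables)
  if (length(channel_tables) == 0L) stop("no channel data supplied")
  preds <- do.call(rbind, lapply(channel_tables, function(t) t[prediction_columns]))
  if (nrow(preds) == 0L) stop("no channel data supplied (all tables empty)")
  validate_predictions(preds, "collate input")

  entries <- lapply(split(preds, preds$gene), function(g) {
    g <- g[order(g$channel, g$mrna_start, g$mrna_end, g$srna_start), , drop = FALSE]
    cl <- agreement_clusters(g, min_overlap)
    cls <- vapply(seq_len(nrow(g)), function(i) {
      classify_prediction(g[i, ], known_sites, min_overlap)
    }, character(1))
    has_known <- !is.null(known_sites) && any(known_sites$gene == g$gene[1L])
    sizes <- tapply(g$channel, cl, function(ch) length(unique(ch)))
    g$classification <- cls
    g$cluster <- cl
    g$agreement <- as.integer(sizes[as.character(cl)])
    g$rank <- assign_rank(cls, g$channel, cl, has_known, precedence)
    g
  })
  entries <- do.call(rbind, entries)
  rownames(entries) <- NULL

  # membership filters: never change a rank, only which genes appear
  keep_genes <- unique(entries$gene)
  if (!is.null(filters)) {
    if (!is.null(filters$gene_list)) {
      keep_genes <- intersect(keep_genes, filters$gene_list)
    }
    if (!is.null(filters$de_table)) {
      keep_genes <- intersect(keep_genes, de_passing_genes(filters$de_table, filters))
    }
  }
  entries <- entries[entries$gene %in% keep_genes, , drop = FALSE]

  best_sig <- if (nrow(entries)) {
    stats::aggregate(significance ~ gene, entries, min)
  } else data.frame(gene = character(), significance = numeric())
  sig_of <- stats::setNames(best_sig$significance, best_sig$gene)
  ord <- order(entries$rank, sig_of[entries$gene], entries$gene,
               entries$channel, entries$mrna_start)
  entries <- entries[ord, , drop = FALSE]
  rownames(entries) <- NULL
  # rank in the last column on write
  entries <- entries[c(setdiff(names(entries), "rank"), "rank")]

  structure(
    list(entries = entries,
         params_echo = list(min_overlap = as.integer(min_overlap),
                            precedence = precedence,
                            filters = filter_echo(filters)),
         provenance = provenance),
    class = "collated_report"
  )
}

filter_echo <- function(filters) {
  if (is.null(filters)) return(NULL)
  list(gene_list = filters$gene_list,
       n_de_records = if (is.null(filters$de_table)) NULL else nrow(filters$de_table),
       fc_up = filters$fc_up, fc_down = filters$fc_down, q_max = filters$q_max,
       has_known_sites = !is.null(filters$known_sites))
}

#' @export
print.collated_report <- function(x, ...) {
  e <- x$entries
  cat("collated_report: ", length(unique(e$gene)), " genes, ", nrow(e),
      " predictions from ", length(unique(e$channel)), " channel(s)\n", sep = "")
  if (nrow(e)) {
    cat("rank distribution (genes):\n")
    print(table(rank = e$rank[!duplicated(e$gene)]))
  }
  invisible(x)
}

#' Write a collated report (tab-delimited and/or CSV) with provenance sidecar
#'
#' @param report a `collated_report`.
#' @param path output path; ".tsv" and ".csv" variants are written when
#'   `formats` includes them, plus a `<path>.json` provenance/params sidecar.
#' @param formats subset of c("tsv", "csv").
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, path, formats = c("tsv", "csv")) {
  stopifnot(inherits(report, "collated_report"))
  base <- sub("\\.(tsv|csv)$", "", path)
  written <- character()
  entries <- format_doubles(report$entries)
  if ("tsv" %in% formats) {
    utils::write.table(entries, paste0(base, ".tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    written <- c(written, paste0(base, ".tsv"))
  }
  if ("csv" %in% formats) {
    utils::write.csv(entries, paste0(base, ".csv"), row.names = FALSE,
                     quote = FALSE)
    written <- c(written, paste0(base, ".csv"))
  }
  sidecar <- paste0(base, ".json")
  jsonlite::write_json(list(params = report$params_echo,
                            provenance = report$provenance),
                       sidecar, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(c(written, sidecar))
}

#' Recollate saved raw channel results under new filters
#'
#' Re-runs collation from the raw per-channel tables saved by a previous
#' [run_predict()] (or [save_raw_results()]) without re-running any channel.
#'
#' @param results_dir directory holding `raw/` channel tables and
#'   (optionally) `known_sites.tsv` from a previous run.
#' @param filters new [filter_spec()] (NULL keeps everything).
#' @param min_overlap,precedence as in [collate()].
#' @return a `collated_report`.
#' @export
recollate <- function(results_dir, filters = NULL, min_overlap = 1L,
                      precedence = default_precedence()) {
  raw_dir <- file.path(results_dir, "raw")
  if (!dir.exists(raw_dir)) stop("no saved raw results under ", results_dir)
  files <- sort(list.files(raw_dir, pattern = "\\.tsv$", full.names = TRUE))
  if (length(files) == 0L) stop("no raw channel tables under ", raw_dir)
  tables <- lapply(files, read_prediction_table)
  ks_path <- file.path(results_dir, "known_sites.tsv")
  known <- if (file.exists(ks_path)) read_known_sites(ks_path) else NULL
  collate(tables, known_sites = known, filters = filters,
          min_overlap = min_overlap, precedence = precedence,
          provenance = list(recollated_from = normalizePath(results_dir),
                            channel_files = basename(files)))
}

#' Save raw channel tables (and known sites) for later recollation
#'
#' @param channel_tables list of prediction data.frames (named by channel
#'   when the channel column is not already set).
#' @param results_dir output directory (created).
#' @param known_sites optional known-sites data.frame, saved alongside.
#' @return invisibly, `results_dir`.
#' @export
save_raw_results <- function(channel_tables, results_dir, known_sites = NULL) {
  if (is.data.frame(channel_tables)) channel_tables <- list(channel_tables)
  dir.create(file.path(results_dir, "raw"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(channel_tables)) {
    tab <- channel_tables[[i]]
    label <- if (nrow(tab)) tab$channel[1L] else names(channel_tables)[i] %||% as.character(i)
    write_prediction_table(tab, file.path(results_dir, "raw",
                                          paste0("channel_", label, ".tsv")))
  }
  if (!is.null(known_sites)) {
    utils::write.table(known_sites, file.path(results_dir, "known_sites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(results_dir)
}
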