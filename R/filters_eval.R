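# Results filters (gene lists, differential-expression evidence) and the
# evaluation harness: sensitivity, false-positive rate, consensus-threshold
# ROC, and seed-size sweeps.

#' Results-filter specification
#'
#' Membership filters applied during collation. Fold-change bounds are
#' inclusive by default (keep fold change >= `fc_up` or <= `fc_down`) and a
#' q-value cutoff of `q_max` applies on top; genes absent from a supplied DE
#' table are dropped (the filter is an evidence requirement).
#'
#' @param gene_list optional character vector of locus tags to keep.
#' @param known_sites optional known-sites data.frame (carried for
#'   provenance; classification uses the `known_sites` argument of
#'   [collate()]).
#' @param de_table optional data.frame with columns gene, fold_change,
#'   q_value.
#' @param fc_up,fc_down fold-change bounds (defaults 1.5 and 0.5;
#'   `fc_down < 1 < fc_up` required).
#' @param q_max q-value cutoff (default 0.005).
#' @param inclusive use `>=`/`<=` on the fold-change bounds (default TRUE);
#'   FALSE uses strict inequalities.
#' @return a `filter_spec` list.
#' @export
filter_spec <- function(gene_list = NULL, known_sites = NULL, de_table = NULL,
                        fc_up = 1.5, fc_down = 0.5, q_max = 0.005,
                        inclusive = TRUE) {
  if (!(fc_down <= 1 && 1 <= fc_up)) stop("need fc_down <= 1 <= fc_up")
  if (q_max < 0 || q_max > 1) stop("q_max must be in [0, 1]")
  if (!is.null(de_table)) validate_de_table(de_table)
  structure(
    list(gene_list = gene_list, known_sites = known_sites, de_table = de_table,
         fc_up = fc_up, fc_down = fc_down, q_max = q_max,
         inclusive = isTRUE(inclusive)),
    class = "filter_spec"
  )
}

validate_de_table <- function(de) {
  need <- c("gene", "fold_change", "q_value")
  missing <- setdiff(need, names(de))
  if (length(missing)) stop("DE table missing column(s): ",
                            paste(missing, collapse = ", "))
  if (any(de$fold_change <= 0)) stop("DE fold_change must be > 0")
  if (any(de$q_value < 0 | de$q_value > 1)) stop("DE q_value must be in [0, 1]")
  invisible(TRUE)
}

#' Read a differential-expression table
#'
#' Tab-delimited with header gene, fold_change, q_value (the fold change is
#' treatment/control; q_value is FDR-adjusted).
#'
#' @param path file path.
#' @return data.frame with gene, fold_change, q_value.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stop("DE table not found: ", path)
  de <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(gene = "character"),
                          stringsAsFactors = FALSE)
  validate_de_table(de)
  de
}

# Genes passing the DE criteria of a filter_spec.
de_passing_genes <- function(de, spec) {
  pass_fc <- if (isTRUE(spec$inclusive)) {
    de$fold_change >= spec$fc_up | de$fold_change <= spec$fc_down
  } else {
    de$fold_change > spec$fc_up | de$fold_change < spec$fc_down
  }
  unique(de$gene[pass_fc & de$q_value <= spec$q_max])
}

#' Restrict a collated report to a gene list
#'
#' Keeps entries of listed genes only; order and ranks are untouched.
#'
#' @param report a `collated_report`.
#' @param genes character vector of locus tags.
#' @return filtered `collated_report`.
#' @export
apply_gene_filter <- function(report, genes) {
  stopifnot(inherits(report, "collated_report"))
  report$entries <- report$entries[report$entries$gene %in% genes, , drop = FALSE]
  rownames(report$entries) <- NULL
  report
}

#' Restrict a collated report by differential-expression evidence
#'
#' Keeps entries whose gene has a DE record passing the fold-change bounds
#' and q-value cutoff of `spec`; genes absent from the DE table are dropped.
#'
#' @param report a `collated_report`.
#' @param de DE data.frame (gene, fold_change, q_value).
#' @param spec a [filter_spec()] providing the bounds.
#' @return filtered `collated_report`.
#' @export
apply_de_filter <- function(report, de, spec = filter_spec()) {
  stopifnot(inherits(report, "collated_report"))
  validate_de_table(de)
  apply_gene_filter(report, de_passing_genes(de, spec))
}

#' Sensitivity (true-positive rate) as a percentage
#'
#' Correctly predicted known targets over total known targets, times 100.
#' Use [percent_display()] for the integer display convention (half away
#' from zero, so 10/18 -> 55.6 -> 56).
#'
#' @param n_correct correctly predicted known targets.
#' @param n_known total known targets (>= 1).
#' @return percentage in [0, 100].
#' @export
sensitivity_pct <- function(n_correct, n_known) {
  if (n_known == 0) stop("n_known must be >= 1")
  if (n_correct < 0 || n_correct > n_known) stop("need 0 <= n_correct <= n_known")
  100 * n_correct / n_known
}

#' False-positive rate as a percentage
#'
#' Validated non-targets that are nonetheless called, over all validated
#' non-targets, times 100. The denominator is always the supplied non-target
#' list, never the whole genome.
#'
#' @param n_called validated non-targets with a prediction.
#' @param n_nontargets total validated non-targets (>= 1).
#' @return percentage in [0, 100].
#' @export
false_positive_rate_pct <- function(n_called, n_nontargets) {
  if (n_nontargets == 0) stop("n_nontargets must be >= 1")
  if (n_called < 0 || n_called > n_nontargets) {
    stop("need 0 <= n_called <= n_nontargets")
  }
  100 * n_called / n_nontargets
}

#' Integer percent display (round half away from zero)
#' @param pct numeric percentage.
#' @return integer percentage; 55.5 displays as 56.
#' @export
percent_display <- function(pct) as.integer(round_half_away(pct))

#' Consensus-threshold ROC points
#'
#' For each consensus threshold k, computes the true-positive rate over the
#' known-target genes (a hit requires a correctly classified prediction lying
#' in an agreement cluster of >= k distinct channels; an inconsistent-only
#' gene is a miss) and the false-positive rate over the validated non-target
#' genes (called when any >= k-channel cluster exists, regardless of
#' classification).
#'
#' @param report a `collated_report` built with the known sites of the
#'   true-positive set.
#' @param known_targets character vector of true-positive target genes.
#' @param nontargets character vector of validated non-target genes
#'   (disjoint from `known_targets`).
#' @param k_values consensus thresholds (default 1:4).
#' @return an `eval_summary`: list with `n_known`, `n_nontargets`,
#'   `tpr_by_k`, `fpr_by_k` (named numeric percentages) and `points`
#'   (data.frame k, tpr, fpr).
#' @export
consensus_roc <- function(report, known_targets, nontargets, k_values = 1:4) {
  stopifnot(inherits(report, "collated_report"))
  if (length(intersect(known_targets, nontargets))) {
    stop("known_targets and nontargets overlap: ",
         paste(intersect(known_targets, nontargets), collapse = ", "))
  }
  if (length(known_targets) == 0L) stop("empty known-target list")
  if (length(nontargets) == 0L) stop("empty non-target list")
  e <- report$entries
  tpr <- fpr <- stats::setNames(numeric(length(k_values)), k_values)
  for (k in k_values) {
    hit <- vapply(known_targets, function(g) {
      rows <- e[e$gene == g & e$classification == "correct" & e$agreement >= k, ,
                drop = FALSE]
      nrow(rows) > 0L
    }, logical(1))
    called <- vapply(nontargets, function(g) {
      any(e$gene == g & e$agreement >= k)
    }, logical(1))
    tpr[as.character(k)] <- sensitivity_pct(sum(hit), length(known_targets))
    fpr[as.character(k)] <- false_positive_rate_pct(sum(called), length(nontargets))
  }
  structure(
    list(n_known = length(known_targets), n_nontargets = length(nontargets),
         tpr_by_k = tpr, fpr_by_k = fpr,
         points = data.frame(k = k_values, tpr = unname(tpr), fpr = unname(fpr))),
    class = "eval_summary"
  )
}

#' @export
print.eval_summary <- function(x, ...) {
  cat("eval_summary: ", x$n_known, " known targets, ", x$n_nontargets,
      " validated non-targets\n", sep = "")
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Seed-size sensitivity sweep for the built-in scanner
#'
#' Runs the baseline channel at each seed size and scores sensitivity
#' against the known sites: a known-target gene counts as correct when the
#' reported duplex overlaps a known site of that gene. The prediction set
#' shrinks as the seed grows, so sensitivity is non-increasing.
#'
#' @param query sRNA sequence (RNA string).
#' @param ann a `genome_annotation`.
#' @param known_sites known-sites data.frame (must be non-empty).
#' @param seeds integer vector of seed sizes (default 5:8).
#' @param params base [scan_params()]; its seed_size is overridden per sweep
#'   point.
#' @return data.frame with columns seed, n_correct, n_known, sensitivity.
#' @export
seed_sweep <- function(query, ann, known_sites, seeds = 5:8,
                       params = scan_params("relaxed", p_threshold = "unfiltered")) {
  if (is.null(known_sites) || nrow(known_sites) == 0L) {
    stop("n_known must be >= 1")
  }
  known_genes <- unique(known_sites$gene)
  out <- lapply(seeds, function(s) {
    p <- params
    p$seed_size <- as.integer(s)
    preds <- scan_srna_vs_annotation(query, ann, p)
    n_correct <- sum(vapply(known_genes, function(g) {
      rows <- preds[preds$gene == g, , drop = FALSE]
      nrow(rows) > 0L && any(vapply(seq_len(nrow(rows)), function(i) {
        classify_prediction(rows[i, ], known_sites) == "correct"
      }, logical(1)))
    }, logical(1)))
    data.frame(seed = as.integer(s), n_correct = n_correct,
               n_known = length(known_genes),
               sensitivity = sensitivity_pct(n_correct, length(known_genes)))
  })
  do.call(rbind, out)
}
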