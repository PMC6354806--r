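# Built-in baseline prediction channel: ungapped seed-and-extend RNA-RNA
# duplex search over start-codon windows, scored with additive pair weights
# and assessed against a mononucleotide-shuffle null.

#' Scanner parameters
#'
#' Parameters for the built-in duplex scanner. The two presets mirror the
#' stringent / relaxed regimes used for channel comparison: stringent searches
#' 80 nt upstream / 20 nt downstream of each start codon with a tight
#' significance cutoff, relaxed searches 150/100 with a loose cutoff.
#'
#' @param preset "stringent" (window 80/20, p <= 0.05), "relaxed" (window
#'   150/100, p <= 0.5) or "custom" (no preset values; give windows yourself).
#' @param seed_size minimum number of contiguous base pairs required to
#'   nominate an interaction (default 6).
#' @param window_up,window_down nt searched upstream/downstream of the
#'   translation start; override the preset when supplied.
#' @param p_threshold empirical p-value cutoff, or "unfiltered" to retain all
#'   best-per-gene duplexes.
#' @param allow_GU permit G:U wobble pairs (default TRUE).
#' @param pair_weights named energy weights (arbitrary units, all <= 0);
#'   defaults GC -3, AU -2, GU -1.
#' @param n_shuffles size of the mononucleotide-shuffle null (>= 19).
#' @param rng_seed seed for the shuffle RNG; identical inputs and seed give
#'   byte-identical output.
#' @param top_n optional rank-based cutoff: keep only the best `top_n` records
#'   genome-wide (by p-value, then energy), applied after `p_threshold`.
#' @return a `scan_params` list.
#' @export
scan_params <- function(preset = c("stringent", "relaxed", "custom"),
                        seed_size = 6L,
                        window_up = NULL, window_down = NULL,
                        p_threshold = NULL,
                        allow_GU = TRUE,
                        pair_weights = c(GC = -3, AU = -2, GU = -1),
                        n_shuffles = 200L,
                        rng_seed = 42L,
                        top_n = NULL) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    stringent = list(up = 80L, down = 20L, p = 0.05),
    relaxed   = list(up = 150L, down = 100L, p = 0.5),
    custom    = list(up = NULL, down = NULL, p = "unfiltered")
  )
  window_up <- as.integer(window_up %||% defaults$up)
  window_down <- as.integer(window_down %||% defaults$down)
  p_threshold <- p_threshold %||% defaults$p
  if (length(window_up) == 0L || length(window_down) == 0L ||
      is.na(window_up) || is.na(window_down)) {
    stop("preset 'custom' requires explicit window_up and window_down")
  }
  if (seed_size < 1L) stop("seed_size must be >= 1")
  if (n_shuffles < 19L) stop("n_shuffles must be >= 19")
  if (!all(c("GC", "AU", "GU") %in% names(pair_weights))) {
    stop("pair_weights must name GC, AU and GU")
  }
  if (any(pair_weights > 0)) stop("pair_weights must be <= 0")
  if (!identical(p_threshold, "unfiltered") &&
      (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold > 1)) {
    stop("p_threshold must be in (0, 1] or \"unfiltered\"")
  }
  structure(
    list(preset = preset, seed_size = as.integer(seed_size),
         window_up = window_up, window_down = window_down,
         p_threshold = p_threshold, allow_GU = isTRUE(allow_GU),
         pair_weights = pair_weights[c("GC", "AU", "GU")],
         n_shuffles = as.integer(n_shuffles), rng_seed = as.integer(rng_seed),
         top_n = if (is.null(top_n)) NULL else as.integer(top_n)),
    class = "scan_params"
  )
}

# kernel weight order: GU, AU, GC
kernel_weights <- function(params) {
  as.numeric(params$pair_weights[c("GU", "AU", "GC")])
}

#' Classify a base pair
#'
#' @param b1,b2 single RNA bases (A, C, G, U; T accepted as U).
#' @param allow_GU permit the G:U wobble class.
#' @return "GC", "AU", "GU", or `NA` when the bases do not pair. Symmetric in
#'   its arguments.
#' @export
complementary <- function(b1, b2, allow_GU = TRUE) {
  pair <- paste0(to_rna(b1), to_rna(b2))
  if (!grepl("^[ACGU][ACGU]$", pair)) {
    stop("non-nucleotide base in pair: ", b1, "/", b2)
  }
  if (pair %in% c("GC", "CG")) return("GC")
  if (pair %in% c("AU", "UA")) return("AU")
  if (allow_GU && pair %in% c("GU", "UG")) return("GU")
  NA_character_
}

#' Find seed anchors between an sRNA query and a target window
#'
#' Enumerates every maximal antiparallel run of at least `seed_size`
#' contiguous base pairs between the query (5'->3') and the window sequence.
#' Each maximal run is reported once.
#'
#' @param query RNA string (sRNA, 5'->3'; position +1 is the 5' end).
#' @param window a `window_sequence` from [extract_window()], or a plain RNA
#'   string (then window indices double as relative coordinates 1..n).
#' @param seed_size minimum run length.
#' @param allow_GU permit G:U wobble pairs.
#' @param pair_weights energy weights as in [scan_params()].
#' @return data.frame with one row per maximal run: `q_start`, `q_end`
#'   (query positions), `w_lo`, `w_hi` (window indices; the query 5' side
#'   pairs with `w_hi`, antiparallel), `len`, `energy`.
#' @export
find_seed_matches <- function(query, window, seed_size,
                              allow_GU = TRUE,
                              pair_weights = c(GC = -3, AU = -2, GU = -1)) {
  wseq <- if (inherits(window, "window_sequence")) window$seq else window
  if (seed_size > nchar(query)) stop("seed_size exceeds query length")
  qi <- encode_bases(query)
  wi <- encode_bases(wseq)
  if (any(qi == 0L)) stop("query contains non-ACGU characters")
  runs <- duplex_runs_cpp(qi, wi, as.integer(seed_size),
                          as.numeric(pair_weights[c("GU", "AU", "GC")]),
                          isTRUE(allow_GU))
  out <- data.frame(
    q_start = as.integer(runs$q_start),
    q_end = as.integer(runs$q_start + runs$len - 1L),
    w_lo = as.integer(runs$w_hi - runs$len + 1L),
    w_hi = as.integer(runs$w_hi),
    len = as.integer(runs$len),
    energy = as.numeric(runs$energy)
  )
  out[order(out$w_lo, out$q_start), , drop = FALSE]
}

#' Extend a seed anchor and score the resulting duplex
#'
#' Extends an anchor outward in both directions while bases continue to pair
#' (ungapped; extension stops at the first non-pair or a sequence end) and
#' sums the pair weights. Anchors from [find_seed_matches()] are already
#' maximal, so for them extension is a fixed point.
#'
#' @param anchor one-row data.frame (or list) with `q_start`, `w_hi`, `len`
#'   as produced by [find_seed_matches()].
#' @param query RNA string.
#' @param window a `window_sequence` (or plain RNA string).
#' @param params a `scan_params` (pair weights and GU policy are used).
#' @return a `duplex`: list with `srna_interval` (ascending query positions,
#'   +1 = 5' end), `mrna_interval` (ascending translation-relative target
#'   positions), `n_pairs`, `energy`, and `pairs` (data.frame srna_pos,
#'   mrna_pos, class).
#' @export
extend_and_score <- function(anchor, query, window, params = scan_params()) {
  wseq <- if (inherits(window, "window_sequence")) window$seq else window
  rel <- if (inherits(window, "window_sequence")) window$rel_coords
         else seq_len(nchar(wseq))
  q <- seq_chars(to_rna(query))
  w <- seq_chars(to_rna(wseq))
  i0 <- anchor$q_start[1L]
  j0 <- anchor$w_hi[1L]               # pairs with q_start, antiparallel
  len <- anchor$len[1L]
  cls <- function(a, b) complementary(a, b, params$allow_GU)
  # extend 5' side of the query (towards larger window index)
  while (i0 > 1L && j0 < length(w) && !is.na(cls(q[i0 - 1L], w[j0 + 1L]))) {
    i0 <- i0 - 1L; j0 <- j0 + 1L; len <- len + 1L
  }
  # extend 3' side of the query (towards smaller window index)
  i1 <- i0 + len - 1L
  j1 <- j0 - len + 1L
  while (i1 < length(q) && j1 > 1L && !is.na(cls(q[i1 + 1L], w[j1 - 1L]))) {
    i1 <- i1 + 1L; j1 <- j1 - 1L; len <- len + 1L
  }
  qpos <- seq.int(i0, i1)
  wpos <- seq.int(j0, j1)              # descending
  classes <- mapply(cls, q[qpos], w[wpos], USE.NAMES = FALSE)
  if (anyNA(classes)) stop("anchor does not describe a paired run")
  wts <- params$pair_weights
  structure(
    list(
      srna_interval = c(i0, i1),
      mrna_interval = c(rel[j1], rel[j0]),
      n_pairs = len,
      energy = sum(wts[classes]),
      pairs = data.frame(srna_pos = qpos, mrna_pos = rel[wpos],
                         class = classes, stringsAsFactors = FALSE)
    ),
    class = "duplex"
  )
}

#' Null distribution of best duplex energies on shuffled windows
#'
#' Draws `n_shuffles` mononucleotide shuffles of the window (composition
#' preserved) and records, for each, the best (minimum) duplex energy against
#' the query; `Inf` when no run reaches `seed_size`. Fully determined by
#' `params$rng_seed`.
#'
#' @param window a `window_sequence` or RNA string.
#' @param query RNA string.
#' @param params a `scan_params`.
#' @param seed_offset added to `params$rng_seed` (used to decorrelate genes
#'   while keeping the whole scan reproducible).
#' @return numeric vector of length `n_shuffles`.
#' @export
shuffle_null <- function(window, query, params = scan_params(), seed_offset = 0L) {
  wseq <- if (inherits(window, "window_sequence")) window$seq else window
  qi <- encode_bases(query)
  wi <- encode_bases(wseq)
  wts <- kernel_weights(params)
  n <- length(wi)
  with_seed(params$rng_seed + as.integer(seed_offset), {
    vapply(seq_len(params$n_shuffles), function(s) {
      best_duplex_energy_cpp(qi, wi[sample.int(n)], params$seed_size,
                             wts, params$allow_GU)
    }, numeric(1))
  })
}

#' Empirical p-value of an observed duplex energy
#'
#' Add-one empirical tail probability: `(1 + #{null <= observed}) / (1 + n)`.
#' Lower energies are better, ties count toward the numerator, and the result
#' can never be 0 (minimum `1/(n+1)`).
#'
#' @param observed_energy observed best duplex energy.
#' @param null_energies numeric vector from [shuffle_null()].
#' @return p-value in `[1/(n+1), 1]`.
#' @export
empirical_pvalue <- function(observed_energy, null_energies) {
  if (length(null_energies) == 0L) stop("empty null distribution")
  (1 + sum(null_energies <= observed_energy)) / (1 + length(null_energies))
}

#' Scan an sRNA query against every gene of an annotation
#'
#' For each annotated gene, extracts the start-codon window, finds the
#' best-energy duplex with at least `seed_size` contiguous pairs (ties broken
#' by most-upstream target position, then longest duplex), attaches its
#' shuffle-null empirical p-value, and keeps records passing `p_threshold`
#' ("unfiltered" keeps all). One record per gene at most.
#'
#' @param query sRNA sequence (RNA string).
#' @param ann a `genome_annotation`.
#' @param params a `scan_params`.
#' @param channel channel label recorded on the output (default "B",
#'   the built-in baseline).
#' @return prediction table: data.frame with columns channel, gene,
#'   mrna_start, mrna_end, srna_start, srna_end, score, significance,
#'   passed_threshold.
#' @export
scan_srna_vs_annotation <- function(query, ann, params = scan_params(),
                                    channel = "B") {
  stopifnot(inherits(ann, "genome_annotation"))
  query <- to_rna(query)
  if (!nzchar(channel)) stop("channel label must be nonempty")
  qi <- encode_bases(query)
  if (any(qi == 0L)) stop("query contains non-ACGU characters")
  wts <- kernel_weights(params)
  rows <- vector("list", nrow(ann$genes))
  for (i in seq_len(nrow(ann$genes))) {
    tag <- ann$genes$locus_tag[i]
    w <- extract_window(ann, tag, params$window_up, params$window_down)
    wi <- encode_bases(w$seq)
    runs <- duplex_runs_cpp(qi, wi, params$seed_size, wts, params$allow_GU)
    if (length(runs$len) == 0L) next
    rel <- w$rel_coords
    w_lo <- runs$w_hi - runs$len + 1L
    mrna_lo <- rel[w_lo]
    # best energy; ties -> most upstream target position, then longest duplex
    ord <- order(runs$energy, mrna_lo, -runs$len, runs$q_start)
    b <- ord[1L]
    nulls <- shuffle_null(w, query, params, seed_offset = i)
    p <- empirical_pvalue(runs$energy[b], nulls)
    keep <- identical(params$p_threshold, "unfiltered") || p <= params$p_threshold
    if (!keep) next
    rows[[i]] <- data.frame(
      channel = channel, gene = tag,
      mrna_start = mrna_lo[b], mrna_end = rel[runs$w_hi[b]],
      srna_start = as.integer(runs$q_start[b]),
      srna_end = as.integer(runs$q_start[b] + runs$len[b] - 1L),
      score = runs$energy[b], significance = p,
      passed_threshold = TRUE,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- empty_prediction_table()
  if (!is.null(params$top_n) && nrow(out) > params$top_n) {
    ord <- order(out$significance, out$score, out$gene)
    out <- out[sort(ord[seq_len(params$top_n)]), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

empty_prediction_table <- function() {
  data.frame(channel = character(), gene = character(),
             mrna_start = integer(), mrna_end = integer(),
             srna_start = integer(), srna_end = integer(),
             score = numeric(), significance = numeric(),
             passed_threshold = logical(), stringsAsFactors = FALSE)
}

#' Read the first record of a FASTA file as an RNA string
#'
#' @param path FASTA path.
#' @return named character: the sequence (T normalised to U), named by its id.
#' @export
read_rna_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no sequence in FASTA: ", path)
  s <- to_rna(as.character(ss[[1L]]))
  names(s) <- sub("\\s.*$", "", names(ss)[1L])
  s
}
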