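# Synthetic-data generator: genomes with planted sRNA binding sites, mock
# channel prediction tables with a configurable agreement/correctness
# structure (plus an independently derived answer key), and DE tables.
#
# Planted sites are guaranteed recoverable at exact coordinates: the reverse
# complement of the designated sRNA stretch is embedded at the stated
# translation-relative position, its flanks are forced non-pairing so
# seed-and-extend stops exactly at the planted boundary, and every competing
# background run of >= sanitize_min_run pairs inside the declared search
# window of a planted gene is broken by a deterministic point mutation.

#' Specification for a synthetic genome fixture
#'
#' @param n_genes number of genes (alternating strands).
#' @param gene_length,intergenic_length nt per CDS and between CDSs; the
#'   intergenic default, `2 * window_up + 10`, keeps the search windows of
#'   adjacent genes disjoint so window sanitisation is conflict-free.
#' @param window_up,window_down the declared search window; planted-gene
#'   windows of this size are sanitised so the planted duplex is the only
#'   run of `sanitize_min_run`+ pairs.
#' @param srna_length length of the generated sRNA query.
#' @param gc background GC fraction (default 0.5).
#' @param planted data.frame with columns `gene_index`, `rel_start`
#'   (translation-relative start of the target interval, no 0), `len`
#'   (duplex length), `srna_start` (5' position of the pairing stretch on
#'   the sRNA) and optionally `max_run` (cap the longest contiguous run by
#'   interior mismatches; NA = perfect site).
#' @param sanitize_min_run background runs of at least this many pairs are
#'   broken inside planted-gene windows (default 5).
#' @param rng_seed mandatory seed; same spec + seed give identical bytes.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_genes = 10L, gene_length = 60L,
                         intergenic_length = NULL,
                         window_up = 150L, window_down = 100L,
                         srna_length = 60L, gc = 0.5,
                         planted = NULL, sanitize_min_run = 5L,
                         rng_seed) {
  if (missing(rng_seed)) stop("rng_seed is mandatory for fixtures")
  intergenic_length <- intergenic_length %||% (2L * as.integer(window_up) + 10L)
  if (!is.null(planted)) {
    need <- c("gene_index", "rel_start", "len", "srna_start")
    if (!all(need %in% names(planted))) {
      stop("planted needs columns: ", paste(need, collapse = ", "))
    }
    if (!"max_run" %in% names(planted)) planted$max_run <- NA_integer_
    if (any(planted$rel_start == 0)) stop("planted rel_start cannot be 0")
    if (any(planted$gene_index < 1 | planted$gene_index > n_genes)) {
      stop("planted gene_index out of range")
    }
    if (any(planted$srna_start < 1 |
            planted$srna_start + planted$len - 1L > srna_length)) {
      stop("planted sRNA stretch outside the sRNA")
    }
  }
  structure(
    list(n_genes = as.integer(n_genes), gene_length = as.integer(gene_length),
         intergenic_length = as.integer(intergenic_length),
         window_up = as.integer(window_up), window_down = as.integer(window_down),
         srna_length = as.integer(srna_length), gc = gc, planted = planted,
         sanitize_min_run = as.integer(sanitize_min_run),
         rng_seed = as.integer(rng_seed)),
    class = "fixture_spec"
  )
}

# Advance a no-zero relative position by k steps (k >= 0).
rel_advance <- function(a, k) {
  p <- a + k
  if (a < 0 && p >= 0) p <- p + 1L
  as.integer(p)
}

# A base guaranteed not to pair (even G:U) with the given RNA base.
nonpairing_base <- function(b) c(A = "C", C = "A", G = "A", U = "C")[[b]]

# All bases that cannot pair (even G:U) with the given RNA base.
nonpairing_choices <- function(b) {
  list(A = c("A", "C", "G"), C = c("A", "C", "U"),
       G = c("A", "G"), U = c("C", "U"))[[b]]
}

#' Generate a synthetic genome with planted sRNA binding sites
#'
#' Builds a random genome with genes on alternating strands, a random sRNA,
#' and embeds the reverse complement of designated sRNA stretches at the
#' stated translation-relative positions (see [fixture_spec()]). The truth
#' table records the exact intervals a scanner should report.
#'
#' @param spec a [fixture_spec()].
#' @return list with `ann` (a `genome_annotation`), `srna` (named RNA
#'   string), `truth` (data.frame gene, mrna_start, mrna_end, srna_start,
#'   srna_end, len, max_run, recoverable) and `spec`.
#' @export
synth_genome <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$rng_seed, {
    pad <- spec$window_up + spec$window_down + 10L
    step <- spec$gene_length + spec$intergenic_length
    L <- 2L * pad + spec$n_genes * step
    probs <- c(A = (1 - spec$gc) / 2, C = spec$gc / 2,
               G = spec$gc / 2, T = (1 - spec$gc) / 2)
    genome <- sample(names(probs), L, replace = TRUE, prob = probs)
    srna <- paste(sample(c("A", "C", "G", "U"), spec$srna_length,
                         replace = TRUE,
                         prob = probs[c("A", "C", "G", "T")]),
                  collapse = "")
    genes <- data.frame(
      locus_tag = sprintf("SYN_%03d", seq_len(spec$n_genes)),
      gene_name = sprintf("syg%03d", seq_len(spec$n_genes)),
      strand = rep_len(c("+", "-"), spec$n_genes),
      cds_start = pad + (seq_len(spec$n_genes) - 1L) * step + 1L,
      cds_end = pad + (seq_len(spec$n_genes) - 1L) * step + spec$gene_length,
      product = "synthetic gene",
      stringsAsFactors = FALSE
    )

    # write an RNA base into a gene's coding-strand window position
    set_window_base <- function(gi, rel, base_rna) {
      g <- genes[gi, ]
      pos <- rel_to_genomic(g, rel)
      b <- to_dna(base_rna)
      genome[pos] <<- if (g$strand == "+") b else chartr("ACGT", "TGCA", b)
    }
    set_genomic <- function(pos, dna_base) genome[pos] <<- dna_base

    truth <- NULL
    protected <- integer()  # genomic positions that sanitisation must not touch
    site_body <- integer()  # genomic positions occupied by planted duplexes
    pl <- spec$planted
    if (!is.null(pl) && nrow(pl)) {
      sch <- seq_chars(srna)
      for (r in seq_len(nrow(pl))) {
        gi <- pl$gene_index[r]
        len <- pl$len[r]
        a <- pl$srna_start[r]
        rel0 <- pl$rel_start[r]
        rels <- vapply(0:(len - 1L), function(k) rel_advance(rel0, k), integer(1))
        g <- genes[gi, ]
        gpos <- vapply(rels, function(rv) rel_to_genomic(g, rv), integer(1))
        if (length(intersect(gpos, site_body))) {
          stop("planted site on gene ", g$locus_tag,
               " overlaps another planted site")
        }
        site_body <- c(site_body, gpos)
        # sRNA 5' side pairs the 3' (higher) end of the target interval:
        # window content at rels (ascending) = revcomp of the sRNA stretch
        sub <- sch[a:(a + len - 1L)]
        embed <- seq_chars(revcomp(paste(sub, collapse = "")))
        for (k in seq_len(len)) set_window_base(gi, rels[k], embed[k])
        # interior mismatches capping the longest contiguous run
        mr <- pl$max_run[r]
        mm_rels <- integer()
        if (!is.na(mr) && mr < len) {
          at <- seq.int(mr + 1L, len, by = mr + 1L)
          for (k in at) {
            # window base at rels[k] pairs sRNA base a + (len - k)
            sb <- sch[a + len - k]
            set_window_base(gi, rels[k], nonpairing_base(sb))
            mm_rels <- c(mm_rels, rels[k])
          }
        }
        # guard flanks: stop extension exactly at the planted boundary
        flank_rels <- integer()
        if (a > 1L) {
          fr <- rel_advance(rels[len], 1L)
          set_window_base(gi, fr, nonpairing_base(sch[a - 1L]))
          flank_rels <- c(flank_rels, fr)
        }
        if (a + len - 1L < length(sch)) {
          fr <- as.integer(rel_advance(rels[1L], -1L))
          if (rels[1L] > 0 && fr == 0L) fr <- -1L
          set_window_base(gi, fr, nonpairing_base(sch[a + len]))
          flank_rels <- c(flank_rels, fr)
        }
        protected <- c(protected, gpos,
                       vapply(c(mm_rels, flank_rels),
                              function(rv) rel_to_genomic(g, rv), integer(1)))
        eff_run <- if (is.na(mr)) len else min(mr, len)
        truth <- rbind(truth, data.frame(
          gene = g$locus_tag, strand = g$strand,
          mrna_start = as.integer(rels[1L]), mrna_end = as.integer(rels[len]),
          srna_start = as.integer(a), srna_end = as.integer(a + len - 1L),
          len = as.integer(len), max_run = as.integer(eff_run),
          recoverable = rels[1L] >= -spec$window_up & rels[len] <= spec$window_down,
          stringsAsFactors = FALSE
        ))
      }

      # sanitise planted-gene search windows: walk each window along the
      # query-pairing direction, tracking for every query position the
      # length of the contiguous pair run ending at the current window
      # base; whenever the current (unprotected) base would let any run
      # reach sanitize_min_run, it is replaced by a base that keeps every
      # run shorter. This constructs, in one O(window x query) pass, a
      # background in which the planted duplex is the only run of
      # sanitize_min_run or more pairs (runs threaded entirely through
      # protected planted bases are tolerated: they lie on a shifted
      # diagonal inside the planted region and cannot outscore it).
      planted_genes <- unique(pl$gene_index)
      bases4 <- c("A", "C", "G", "U")
      # pairs_with[q_base, w_base]: Watson-Crick or G:U wobble
      pairs_with <- matrix(FALSE, 4, 4, dimnames = list(bases4, bases4))
      pairs_with["A", "U"] <- pairs_with["U", "A"] <- TRUE
      pairs_with["C", "G"] <- pairs_with["G", "C"] <- TRUE
      pairs_with["G", "U"] <- pairs_with["U", "G"] <- TRUE
      m <- length(sch)

      sanitize_window <- function(gi) {
        g <- genes[gi, ]
        ann_tmp <- structure(list(sequence = paste(genome, collapse = ""),
                                  genes = genes, genome_id = "tmp"),
                             class = "genome_annotation")
        w <- extract_window(ann_tmp, g$locus_tag, spec$window_up, spec$window_down)
        wch <- seq_chars(w$seq)
        n <- length(wch)
        rl <- integer(m)   # run length ending at the previous step, per query pos
        mutated <- FALSE
        # the query runs 5'->3' against the window 3'->5': walk window
        # indices descending so runs extend diagonally step by step
        for (widx in seq.int(n, 1L)) {
          rv <- w$rel_coords[widx]
          gp <- rel_to_genomic(g, rv)
          run_after <- function(b) {
            paired <- pairs_with[, b][sch]
            as.integer(paired) * (c(0L, rl[-m]) + 1L)
          }
          if (gp %in% protected) {
            rl <- run_after(wch[widx])
            next
          }
          cand <- c(wch[widx], sample(setdiff(bases4, wch[widx])))
          new_rls <- lapply(cand, run_after)
          n_viol <- vapply(new_rls, function(x) sum(x >= spec$sanitize_min_run),
                           integer(1))
          pick <- if (n_viol[1L] == 0L) 1L else which.min(n_viol)
          if (pick != 1L) {
            set_window_base(gi, rv, cand[pick])
            wch[widx] <- cand[pick]
            mutated <- TRUE
          }
          rl <- new_rls[[pick]]
        }
        mutated
      }

      # a mutation for one gene can fall inside an overlapping window of
      # another planted gene, so sweep until a full pass changes nothing
      for (round in seq_len(10L)) {
        any_mut <- FALSE
        for (gi in planted_genes) any_mut <- sanitize_window(gi) || any_mut
        if (!any_mut) break
        if (round == 10L) stop("fixture sanitisation did not converge")
      }
    }

    ann <- structure(
      list(sequence = paste(genome, collapse = ""), genes = genes,
           genome_id = sprintf("synthetic_genome_seed%d", spec$rng_seed)),
      class = "genome_annotation"
    )
    names(srna) <- "synthetic_sRNA"
    if (is.null(truth)) {
      truth <- data.frame(gene = character(), strand = character(),
                          mrna_start = integer(), mrna_end = integer(),
                          srna_start = integer(), srna_end = integer(),
                          len = integer(), max_run = integer(),
                          recoverable = logical(), stringsAsFactors = FALSE)
    }
    list(ann = ann, srna = srna, truth = truth, spec = spec)
  })
}

#' Write a synthetic fixture to FASTA + PTT + truth table files
#'
#' @param fix result of [synth_genome()].
#' @param dir output directory (created).
#' @return invisibly, the paths written.
#' @export
write_fixture <- function(fix, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    fasta = file.path(dir, "genome.fna"),
    ptt = file.path(dir, "genome.ptt"),
    srna = file.path(dir, "srna.fa"),
    truth = file.path(dir, "truth.tsv")
  )
  write_genome(fix$ann, paths["fasta"], paths["ptt"])
  writeLines(c(paste0(">", names(fix$srna)), to_dna(fix$srna)), paths["srna"])
  utils::write.table(fix$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Truth table as a known-sites table
#' @param truth truth data.frame from [synth_genome()].
#' @return known-sites data.frame (gene, mrna_start, mrna_end, srna_start,
#'   srna_end, source).
#' @export
truth_as_known_sites <- function(truth) {
  data.frame(gene = truth$gene, mrna_start = truth$mrna_start,
             mrna_end = truth$mrna_end, srna_start = truth$srna_start,
             srna_end = truth$srna_end, source = "planted",
             stringsAsFactors = FALSE)
}

#' Random channel design for mock prediction tables
#'
#' Draws, per gene, whether it owns a known site, and per channel a mode:
#' "correct" / "inconsistent" (known-site genes) or "novel" (others), with a
#' site group controlling which predictions overlap. Within a group,
#' intervals form an overlap chain (adjacent members overlap, distant ones
#' need not), exercising single-linkage clustering.
#'
#' @param n_genes number of genes.
#' @param channels channel labels (default c("T", "S", "I", "C")).
#' @param p_known probability a gene owns a known site.
#' @param p_predict probability a channel emits a record for a gene.
#' @param p_correct probability a known-site gene's record is correct.
#' @param rng_seed mandatory seed.
#' @return data.frame with columns gene, channel, mode, site_group.
#' @export
random_fixture_design <- function(n_genes = 12L, channels = c("T", "S", "I", "C"),
                                  p_known = 0.5, p_predict = 0.6,
                                  p_correct = 0.6, rng_seed) {
  if (missing(rng_seed)) stop("rng_seed is mandatory for fixtures")
  with_seed(rng_seed, {
    rows <- list()
    for (i in seq_len(n_genes)) {
      gene <- sprintf("SYN_%03d", i)
      known <- stats::runif(1) < p_known
      for (ch in channels) {
        if (stats::runif(1) >= p_predict) next
        if (known) {
          mode <- if (stats::runif(1) < p_correct) "correct" else "inconsistent"
        } else {
          mode <- "novel"
        }
        grp <- sample.int(3L, 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = gene, channel = ch, mode = mode, site_group = grp,
          stringsAsFactors = FALSE
        )
      }
    }
    if (length(rows) == 0L) {
      return(data.frame(gene = character(), channel = character(),
                        mode = character(), site_group = integer(),
                        stringsAsFactors = FALSE))
    }
    do.call(rbind, rows)
  })
}

# Known-site interval used for designed fixtures (negative side, away from
# the positive-side group intervals).
design_known_interval <- c(-60L, -41L)

#' Mock per-channel prediction tables plus an independent answer key
#'
#' Emits canonical prediction tables realising a [random_fixture_design()]
#' (or any design data.frame with gene, channel, mode, site_group): correct
#' records overlap the gene's known site, inconsistent and novel records sit
#' at positive-side intervals determined by their site group, with a chain
#' layout inside each group. The answer key (expected classification,
#' cluster, agreement and rank) is derived by a naive independent
#' re-implementation of the collation rules (pairwise-overlap transitive
#' closure and literal tier rules), so it can serve as an oracle for
#' [collate()].
#'
#' @param design design data.frame.
#' @param rng_seed mandatory seed (scores, significances, jitter).
#' @param precedence channel precedence for single-channel tiers.
#' @return list with `tables` (list of per-channel prediction data.frames),
#'   `known_sites`, and `key` (data.frame gene, channel, mrna_start,
#'   mrna_end, expected_class, expected_cluster, expected_agreement,
#'   expected_rank).
#' @export
synth_prediction_tables <- function(design, rng_seed,
                                    precedence = default_precedence()) {
  if (missing(rng_seed)) stop("rng_seed is mandatory for fixtures")
  with_seed(rng_seed, {
    known_genes <- sort(unique(design$gene[design$mode %in%
                                             c("correct", "inconsistent")]))
    known_sites <- if (length(known_genes)) {
      data.frame(
        gene = known_genes,
        mrna_start = design_known_interval[1L],
        mrna_end = design_known_interval[2L],
        srna_start = 5L, srna_end = 24L, source = "designed",
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(gene = character(), mrna_start = integer(),
                 mrna_end = integer(), srna_start = integer(),
                 srna_end = integer(), source = character(),
                 stringsAsFactors = FALSE)
    }
    design <- design[order(design$gene, design$channel), , drop = FALSE]
    design$chain <- 0L
    # chain index within (gene, site group): members of a group form an
    # overlap chain, offset 10 nt apart with 16 nt intervals
    rows <- list()
    for (g in unique(design$gene)) {
      dg <- design[design$gene == g, , drop = FALSE]
      for (grp in unique(dg$site_group[dg$mode != "correct"])) {
        sel <- which(dg$mode != "correct" & dg$site_group == grp)
        for (jj in seq_along(sel)) dg$chain[sel[jj]] <- jj - 1L
      }
      rows[[g]] <- dg
    }
    design <- do.call(rbind, rows)
    n <- nrow(design)
    jit <- if (n) sample.int(21L, n, replace = TRUE) - 11L else integer()  # -10..10
    starts <- ends <- integer(n)
    for (i in seq_len(n)) {
      if (design$mode[i] == "correct") {
        starts[i] <- design_known_interval[1L] + jit[i]
        ends[i] <- starts[i] + 19L
      } else {
        starts[i] <- 100L * design$site_group[i] + 1L + 10L * design$chain[i]
        ends[i] <- starts[i] + 15L
      }
    }
    preds <- data.frame(
      channel = design$channel, gene = design$gene,
      mrna_start = starts, mrna_end = ends,
      srna_start = 5L, srna_end = 24L,
      score = -round(stats::runif(n, 8, 40), 1),
      significance = round(stats::runif(n, 1e-4, 0.5), 4),
      stringsAsFactors = FALSE
    )
    preds$passed_threshold <- TRUE
    key <- naive_answer_key(preds, known_sites, precedence)
    tables <- lapply(split(preds, preds$channel), function(t) {
      t <- t[order(t$gene), , drop = FALSE]
      rownames(t) <- NULL
      t
    })
    list(tables = tables, known_sites = known_sites, key = key)
  })
}

# Naive, independent re-derivation of classification, clustering and rank:
# literal tier rules and repeated-sweep transitive closure, O(n^2) per gene.
# Serves as the oracle the optimised collation path is checked against.
naive_answer_key <- function(preds, known_sites, precedence = default_precedence()) {
  ov <- function(a1, a2, b1, b2) max(a1, b1) <= min(a2, b2)
  out <- list()
  for (g in sort(unique(preds$gene))) {
    p <- preds[preds$gene == g, , drop = FALSE]
    p <- p[order(p$channel, p$mrna_start, p$mrna_end, p$srna_start), , drop = FALSE]
    ks <- known_sites[known_sites$gene == g, , drop = FALSE]
    m <- nrow(p)
    cls <- character(m)
    for (i in seq_len(m)) {
      if (nrow(ks) == 0L) cls[i] <- "novel"
      else {
        hit <- FALSE
        for (j in seq_len(nrow(ks))) {
          if (ov(p$mrna_start[i], p$mrna_end[i], ks$mrna_start[j], ks$mrna_end[j]))
            hit <- TRUE
        }
        cls[i] <- if (hit) "correct" else "inconsistent"
      }
    }
    # transitive closure by repeated sweeps
    cl <- seq_len(m)
    repeat {
      changed <- FALSE
      for (i in seq_len(m)) for (j in seq_len(m)) {
        if (cl[i] != cl[j] &&
            ov(p$mrna_start[i], p$mrna_end[i], p$mrna_start[j], p$mrna_end[j])) {
          new <- min(cl[i], cl[j]); cl[cl == cl[i] | cl == cl[j]] <- new
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    cl <- match(cl, unique(cl))
    agree <- vapply(cl, function(c0) length(unique(p$channel[cl == c0])), integer(1))
    # literal tier rules
    if (nrow(ks) > 0L) {
      ncch <- length(unique(p$channel[cls == "correct"]))
      rank <- if (ncch >= 2L) 1L else if (ncch == 1L) 2L else 3L
    } else if (any(agree >= 2L)) {
      rank <- 4L
    } else {
      tiers <- vapply(unique(p$channel), function(ch) {
        for (t in seq_along(precedence)) if (ch %in% precedence[[t]]) return(t)
        length(precedence)
      }, integer(1))
      rank <- 4L + min(tiers)
    }
    out[[g]] <- data.frame(
      gene = g, channel = p$channel,
      mrna_start = p$mrna_start, mrna_end = p$mrna_end,
      expected_class = cls, expected_cluster = cl,
      expected_agreement = agree, expected_rank = rank,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Synthetic differential-expression table with designed pass/fail flags
#'
#' @param genes locus tags.
#' @param pass logical vector (recycled): should the gene pass the DE filter
#'   in `spec`? Failing genes get either a fold change strictly inside the
#'   bounds or a q-value above the cutoff.
#' @param spec a [filter_spec()] supplying fc_up, fc_down, q_max.
#' @param rng_seed mandatory seed.
#' @return data.frame gene, fold_change, q_value, designed_pass.
#' @export
synth_de_table <- function(genes, pass, spec = filter_spec(), rng_seed) {
  if (missing(rng_seed)) stop("rng_seed is mandatory for fixtures")
  pass <- rep_len(pass, length(genes))
  with_seed(rng_seed, {
    n <- length(genes)
    fc <- q <- numeric(n)
    for (i in seq_len(n)) {
      if (pass[i]) {
        up <- stats::runif(1) < 0.5
        fc[i] <- if (up) round(exp(stats::runif(1, log(spec$fc_up), log(32))), 2)
                 else round(exp(stats::runif(1, log(0.05), log(spec$fc_down))), 2)
        # rounding must not cross the bound
        if (up) fc[i] <- max(fc[i], spec$fc_up) else fc[i] <- min(fc[i], spec$fc_down)
        q[i] <- signif(stats::runif(1, 0, spec$q_max), 3)
      } else if (stats::runif(1) < 0.5) {
        fc[i] <- round(stats::runif(1, spec$fc_down + 0.05, spec$fc_up - 0.05), 2)
        q[i] <- signif(stats::runif(1, 0, spec$q_max), 3)
      } else {
        fc[i] <- round(exp(stats::runif(1, log(0.05), log(32))), 2)
        q[i] <- signif(stats::runif(1, min(spec$q_max * 2, 1), 1), 3)
      }
    }
    data.frame(gene = genes, fold_change = fc, q_value = q,
               designed_pass = pass, stringsAsFactors = FALSE)
  })
}
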