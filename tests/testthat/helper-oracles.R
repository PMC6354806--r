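# Independent brute-force oracles. These deliberately share no code with the
# package internals: pairing is looked up in an explicit table, duplexes are
# enumerated over every (query, window) position pair, and clustering is a
# repeated-sweep transitive closure.

oracle_pair_table <- list(
  AU = -2, UA = -2, GC = -3, CG = -3, GU = -1, UG = -1
)

oracle_pair_weight <- function(qb, wb, allow_gu = TRUE) {
  key <- paste0(qb, wb)
  w <- oracle_pair_table[[key]]
  if (is.null(w)) return(NA_real_)
  if (!allow_gu && key %in% c("GU", "UG")) return(NA_real_)
  w
}

# All maximal antiparallel ungapped runs of >= min_len pairs between query
# q (5'->3') and window w (5'->3'), by exhaustive enumeration of start cells.
# Returns data.frame(q_start, q_end, w_lo, w_hi, len, energy).
oracle_runs <- function(query, window, min_len, allow_gu = TRUE) {
  q <- strsplit(chartr("T", "U", toupper(query)), "")[[1]]
  w <- strsplit(chartr("T", "U", toupper(window)), "")[[1]]
  m <- length(q); n <- length(w)
  out <- list()
  for (i in seq_len(m)) for (j in seq_len(n)) {
    # start of a maximal run: (i, j) pairs but (i-1, j+1) does not
    if (is.na(oracle_pair_weight(q[i], w[j], allow_gu))) next
    if (i > 1 && j < n && !is.na(oracle_pair_weight(q[i - 1], w[j + 1], allow_gu))) next
    len <- 0L; e <- 0
    while (i + len <= m && j - len >= 1) {
      pw <- oracle_pair_weight(q[i + len], w[j - len], allow_gu)
      if (is.na(pw)) break
      e <- e + pw; len <- len + 1L
    }
    if (len >= min_len) {
      out[[length(out) + 1L]] <- data.frame(
        q_start = i, q_end = i + len - 1L, w_lo = j - len + 1L, w_hi = j,
        len = len, energy = e
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(q_start = integer(), q_end = integer(), w_lo = integer(),
                      w_hi = integer(), len = integer(), energy = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$w_lo, res$q_start), , drop = FALSE]
}

# Best (minimum) duplex energy by brute force; Inf when nothing reaches min_len.
oracle_best_energy <- function(query, window, min_len, allow_gu = TRUE) {
  r <- oracle_runs(query, window, min_len, allow_gu)
  if (nrow(r) == 0L) Inf else min(r$energy)
}

# Single-linkage clusters of intervals by repeated-sweep transitive closure.
oracle_clusters <- function(starts, ends) {
  n <- length(starts)
  cl <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (cl[i] != cl[j] && max(starts[i], starts[j]) <= min(ends[i], ends[j])) {
        new <- min(cl[i], cl[j])
        cl[cl == cl[i] | cl == cl[j]] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(cl, unique(cl))
}

# Random RNA string
random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE), collapse = "")
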