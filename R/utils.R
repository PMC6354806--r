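# Internal helpers: translation-relative coordinates, RNA alphabet, seeded RNG.

# Translation-relative coordinates have no position 0: -1 abuts +1, with +1 the
# first base of the start codon. An interval is stored as an ascending pair of
# such positions; because 0 is never an endpoint, ordinary numeric interval
# arithmetic is valid except for span length, which must discount the missing 0.

#' Number of positions spanned by a translation-relative interval
#'
#' Interval endpoints use the no-zero convention (-1 abuts +1), so an interval
#' crossing the start codon spans one position fewer than its numeric width.
#'
#' @param start,end interval endpoints, `start <= end`, neither equal to 0.
#' @return integer count of positions covered.
#' @examples
#' rel_span(-3, 2)   # 5 positions: -3 -2 -1 +1 +2
#' rel_span(4, 11)   # 8
#' @export
rel_span <- function(start, end) {
  check_rel_interval(start, end)
  as.integer(end - start + 1L - (start < 0 & end > 0))
}

check_rel_interval <- function(start, end, what = "interval") {
  if (any(start == 0) || any(end == 0)) {
    stop(what, " uses translation-relative coordinates without position 0", call. = FALSE)
  }
  if (any(end < start)) {
    stop(what, " has end < start", call. = FALSE)
  }
  invisible(TRUE)
}

# Sequence of relative positions from a to b (ascending), skipping 0.
rel_seq <- function(a, b) {
  v <- seq.int(a, b)
  v[v != 0L]
}

# Normalize a nucleotide string to RNA / DNA (uppercase).
to_rna <- function(x) chartr("T", "U", toupper(x))
to_dna <- function(x) chartr("U", "T", toupper(x))

# Split a sequence string into single characters.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Reverse complement of a DNA/RNA string (pure string version; Biostrings is
# used at file-format boundaries, this keeps hot paths light).
revcomp <- function(x) {
  rna <- grepl("U", x <- toupper(x), fixed = TRUE)
  comp <- chartr("ACGTUN", "TGCAAN", x)
  if (rna) comp <- chartr("T", "U", comp)
  paste(rev(seq_chars(comp)), collapse = "")
}

# Integer encoding for the duplex kernel: A=1, C=2, G=3, U/T=4, other=0.
encode_bases <- function(x) {
  m <- match(seq_chars(to_rna(x)), c("A", "C", "G", "U"))
  m[is.na(m)] <- 0L
  as.integer(m)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Round half away from zero for integer percent display (so 55.5 -> 56).
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
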