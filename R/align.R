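#' Pairwise protein alignment with free end gaps
#'
#' Aligns two protein sequences globally with affine gap costs while leaving
#' terminal overhangs unpenalised and unaligned (the "overlap" flavour of
#' Needleman-Wunsch). Scoring uses BLOSUM62 with a gap of length `k` costing
#' `gap_open + k * gap_ext`. Identity is computed over aligned columns only,
#' so terminal gaps never enter the denominator; internal gap columns do.
#'
#' This deterministic aligner backs every homology computation in the
#' package: reciprocal-best-hit tables, donor-identity scans for horizontal
#' transfer, phage gene role calls, fusion detection and the outgroup filter
#' for phylogeny loci.
#'
#' @param a,b Protein sequences as single character strings (or length-1
#'   `Biostrings::AAStringSet`).
#' @param gap_open,gap_ext Affine gap parameters (defaults 11 and 1).
#' @param keep_alignment If `TRUE`, include the aligned strings in the result.
#' @return A one-row tibble with columns `score`, `identity` (percent over
#'   aligned columns), `coverage_query`, `coverage_subject` (aligned span /
#'   sequence length), `matches`, `columns`, and the 1-based aligned spans
#'   `q_start`, `q_end`, `s_start`, `s_end`. With `keep_alignment = TRUE`,
#'   also `aln_q` and `aln_s`.
#' @examples
#' align_pair("HEAGAWGHEE", "PAWHEAE")
#' align_pair("MKV", "MKV")$identity # 100
#' @export
align_pair <- function(a, b, gap_open = 11, gap_ext = 1, keep_alignment = FALSE) {
  a <- as.character(a)
  b <- as.character(b)
  .assert(length(a) == 1 && length(b) == 1, "align_pair() aligns one pair; see align_batch()")
  .assert(nzchar(a) && nzchar(b), "sequences must be non-empty")
  align_batch(a, b, gap_open = gap_open, gap_ext = gap_ext,
              keep_alignment = keep_alignment)
}

#' Batch pairwise alignment
#'
#' Vectorised form of [align_pair()]: aligns `q[i]` against `s[i]` for every
#' `i`. Used internally wherever many candidate pairs must be scored.
#'
#' @param q,s Character vectors of protein sequences, equal length.
#' @inheritParams align_pair
#' @return A tibble with one row per pair; columns as in [align_pair()].
#' @export
align_batch <- function(q, s, gap_open = 11, gap_ext = 1, keep_alignment = FALSE) {
  q <- as.character(q)
  s <- as.character(s)
  .assert(length(q) == length(s), "q and s must have equal length")
  if (length(q) == 0) {
    return(tibble(score = numeric(), identity = numeric(),
                  coverage_query = numeric(), coverage_subject = numeric(),
                  matches = integer(), columns = integer(),
                  q_start = integer(), q_end = integer(),
                  s_start = integer(), s_end = integer()))
  }
  .assert(all(nzchar(q)) && all(nzchar(s)), "sequences must be non-empty")
  res <- .aln_batch_cpp(q, s, .blosum62(), gap_open, gap_ext, keep_alignment)
  out <- tibble(
    score = res$score,
    identity = ifelse(res$columns > 0, 100 * res$matches / res$columns, 0),
    coverage_query = pmax(res$q_end - res$q_start + 1L, 0L) / nchar(q),
    coverage_subject = pmax(res$s_end - res$s_start + 1L, 0L) / nchar(s),
    matches = res$matches,
    columns = res$columns,
    q_start = res$q_start, q_end = res$q_end,
    s_start = res$s_start, s_end = res$s_end
  )
  if (keep_alignment) {
    out$aln_q <- res$aln_q
    out$aln_s <- res$aln_s
  }
  out
}

# BLOSUM62 scoring matrix (cached from Biostrings' copy)
.blosum_env <- new.env(parent = emptyenv())
.blosum62 <- function() {
  if (is.null(.blosum_env$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum_env$m <- e$BLOSUM62
  }
  .blosum_env$m
}
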