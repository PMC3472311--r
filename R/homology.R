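# Proteome-vs-proteome homology search: the sequence-similarity half of
# orthology assignment. A shared-k-mer prefilter keeps the number of exact
# alignments tractable; it can only skip pairs, never alter a score.

.as_protvec <- function(x, arg = "proteome") {
  if (methods::is(x, "XStringSet")) x <- setNames(as.character(x), names(x))
  .assert(is.character(x) && length(x) > 0, paste0(arg, " must be a non-empty named character vector or AAStringSet"))
  .assert(!is.null(names(x)) && all(nzchar(names(x))) && !anyDuplicated(names(x)),
          paste0(arg, " must have unique non-empty names"))
  x
}

# candidate (query index, subject index) pairs sharing >= min_shared k-mers;
# precomputed k-mer tables may be passed to amortise work over many calls
.candidate_pairs <- function(a, b, k = 5L, min_shared = 2L,
                             ka = NULL, kb = NULL) {
  if (is.null(ka)) ka <- .protein_kmers(a, k)
  if (is.null(kb)) kb <- .protein_kmers(b, k)
  da <- data.table::as.data.table(ka)
  db <- data.table::as.data.table(kb)
  data.table::setnames(da, c("idx_q", "kmer"))
  data.table::setnames(db, c("idx_s", "kmer"))
  j <- da[db, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  cnt <- j[, list(n = .N), by = c("idx_q", "idx_s")]
  cnt <- cnt[cnt$n >= min_shared, ]
  as_tibble(cnt[, c("idx_q", "idx_s")])
}

# all hits between two proteomes that pass identity/coverage thresholds
.hit_table <- function(a, b, min_identity = 40, min_coverage = 0.5,
                       kmer_prefilter = TRUE, k = 5L, min_shared = 2L,
                       gap_open = 11, gap_ext = 1, ka = NULL, kb = NULL) {
  a <- .as_protvec(a, "A")
  b <- .as_protvec(b, "B")
  cand <- if (kmer_prefilter) {
    .candidate_pairs(a, b, k = k, min_shared = min_shared, ka = ka, kb = kb)
  } else {
    tidyr::expand_grid(idx_q = seq_along(a), idx_s = seq_along(b))
  }
  if (nrow(cand) == 0) {
    return(tibble(query = character(), subject = character(),
                  identity = numeric(), coverage_query = numeric(),
                  coverage_subject = numeric(), score = numeric()))
  }
  aln <- align_batch(unname(a[cand$idx_q]), unname(b[cand$idx_s]),
                     gap_open = gap_open, gap_ext = gap_ext)
  tibble(
    query = names(a)[cand$idx_q],
    subject = names(b)[cand$idx_s],
    identity = aln$identity,
    coverage_query = aln$coverage_query,
    coverage_subject = aln$coverage_subject,
    score = aln$score
  ) |>
    filter(.data$identity >= min_identity,
           .data$coverage_query >= min_coverage,
           .data$coverage_subject >= min_coverage)
}

.top_per_query <- function(hits) {
  hits |>
    arrange(.data$query, desc(.data$score), .data$subject) |>
    distinct(.data$query, .keep_all = TRUE)
}

#' Best protein hits between two proteomes
#'
#' For every query protein, reports the top-scoring subject that passes the
#' identity and coverage thresholds. Alignment is the package's deterministic
#' BLOSUM62 overlap aligner ([align_pair()]); a shared-5-mer prefilter skips
#' pairs that share fewer than `min_shared` 5-mers, which never changes any
#' computed score, only avoids computing hopeless ones. Score ties resolve
#' to the lexicographically smallest subject id, so results are reproducible.
#'
#' @param a,b Proteomes: named character vectors or `AAStringSet`s.
#' @param min_identity Minimum percent identity over aligned columns
#'   (default 40).
#' @param min_coverage Minimum aligned fraction of both query and subject
#'   (default 0.5).
#' @param kmer_prefilter Use the shared-5-mer prefilter (default `TRUE`).
#' @param k,min_shared Prefilter word size and minimum shared word count.
#' @param gap_open,gap_ext Affine gap parameters passed to the aligner.
#' @return Tibble with columns `query`, `subject`, `identity`,
#'   `coverage_query`, `coverage_subject`, `score`; one row per query with a
#'   passing hit.
#' @export
best_hits <- function(a, b, min_identity = 40, min_coverage = 0.5,
                      kmer_prefilter = TRUE, k = 5L, min_shared = 2L,
                      gap_open = 11, gap_ext = 1) {
  hits <- .hit_table(a, b, min_identity, min_coverage, kmer_prefilter,
                     k, min_shared, gap_open, gap_ext)
  .top_per_query(hits)
}

#' Reciprocal best hits between two proteomes
#'
#' Pairs of proteins that are each other's top-scoring cross-proteome match
#' under the thresholds of [best_hits()]. Because the aligner's score is
#' symmetric, each candidate pair is aligned once and both directions are
#' derived from it. Ties resolve deterministically (lexicographic id), so
#' `reciprocal_best_hits(A, B)` is the exact transpose of
#' `reciprocal_best_hits(B, A)`, and a duplicated gene can contribute at most
#' one pair.
#'
#' @inheritParams best_hits
#' @param kmer_tables Optional list with precomputed k-mer tables for `a`
#'   and `b` (as built by the pan-genome driver), purely a speed aid.
#' @return Tibble with columns `a`, `b` (protein ids), `identity`,
#'   `coverage_a`, `coverage_b`, `score`, sorted by `a`.
#' @export
reciprocal_best_hits <- function(a, b, min_identity = 40, min_coverage = 0.5,
                                 kmer_prefilter = TRUE, k = 5L, min_shared = 2L,
                                 gap_open = 11, gap_ext = 1, kmer_tables = NULL) {
  hits_ab <- .hit_table(a, b, min_identity, min_coverage, kmer_prefilter,
                        k, min_shared, gap_open, gap_ext,
                        ka = kmer_tables$a, kb = kmer_tables$b)
  hits_ba <- hits_ab |>
    rename(query = "subject", subject = "query",
           coverage_query = "coverage_subject",
           coverage_subject = "coverage_query")
  top_ab <- .top_per_query(hits_ab)
  top_ba <- .top_per_query(hits_ba)
  rbh <- inner_join(
    top_ab |> select(a = "query", b = "subject", "identity",
                     coverage_a = "coverage_query",
                     coverage_b = "coverage_subject", "score"),
    top_ba |> select(b = "query", a = "subject"),
    by = c("a", "b")
  )
  arrange(rbh, .data$a)
}
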