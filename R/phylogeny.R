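# Core single-copy ortholog selection, family alignment and concatenation,
# distance matrices and neighbor-joining trees with bootstrap support.

# score of a protein aligned to itself (sum of diagonal BLOSUM62 entries)
.self_scores <- function(prots) {
  B <- .blosum62()
  diagv <- setNames(diag(B), rownames(B))
  vapply(strsplit(unname(prots), ""), function(v) {
    v[!v %in% names(diagv)] <- "X"
    sum(diagv[v])
  }, 1)
}

#' Select core single-copy loci for phylogeny
#'
#' Filters pan loci down to those safe for a concatenated phylogeny: intact
#' in every strain with exactly one member per strain; no member with a
#' within-proteome paralog (another protein in the same strain scoring at
#' least `paralog_guard` of the member's self-alignment score); and, when
#' an outgroup proteome is given, a representative aligning to some
#' outgroup protein at or above `min_outgroup_identity` percent identity.
#'
#' @param pan A `panoen_pan`.
#' @param pam A `panoen_pam` over the same loci.
#' @param strains Named list of `panoen_strain` objects.
#' @param outgroup Optional outgroup proteome (named character vector or
#'   `AAStringSet`); when absent the identity filter is skipped.
#' @param min_outgroup_identity Outgroup identity threshold in percent
#'   (default 60).
#' @param paralog_guard Fraction of the self-score above which a second
#'   within-strain hit marks a paralog (default 0.7).
#' @param paralog_min_shared Shared-5-mer prefilter count for the
#'   within-proteome paralog search (default 6; pairs anywhere near the
#'   guard threshold share far more).
#' @return Integer vector of selected pan ids, sorted.
#' @export
select_core_single_copy <- function(pan, pam, strains, outgroup = NULL,
                                    min_outgroup_identity = 60,
                                    paralog_guard = 0.7,
                                    paralog_min_shared = 6L) {
  S <- length(pan$strains)
  counts <- pan$loci |> count(.data$pan_id, .data$strain)
  bad_multi <- unique(counts$pan_id[counts$n > 1L])
  core <- as.integer(rownames(pam$m)[rowSums(pam$m == 2L) == S])
  sel <- setdiff(core, bad_multi)

  # within-proteome paralog guard
  flagged <- character(0)
  for (st in names(strains)) {
    prot <- strains[[st]]$proteome
    cand <- .candidate_pairs(prot, prot, min_shared = paralog_min_shared)
    cand <- cand |> filter(.data$idx_q < .data$idx_s)
    if (nrow(cand) == 0) next
    aln <- align_batch(unname(prot[cand$idx_q]), unname(prot[cand$idx_s]))
    selfsc <- .self_scores(prot)
    hit <- aln$score >= paralog_guard * pmin(selfsc[cand$idx_q], selfsc[cand$idx_s])
    flagged <- c(flagged, names(prot)[cand$idx_q[hit]], names(prot)[cand$idx_s[hit]])
  }
  if (length(flagged) > 0) {
    bad_par <- unique(pan$loci$pan_id[pan$loci$feature_id %in% flagged])
    sel <- setdiff(sel, bad_par)
  }

  if (!is.null(outgroup) && length(sel) > 0) {
    reps <- pan$representatives
    rid <- as.integer(sub("\\|.*$", "", names(reps)))
    reps <- setNames(unname(reps[rid %in% sel]),
                     paste0("p", rid[rid %in% sel]))
    hits <- .hit_table(reps, .as_protvec(outgroup, "outgroup"),
                       min_identity = min_outgroup_identity,
                       min_coverage = 0.5)
    keep <- as.integer(sub("^p", "", unique(hits$query)))
    sel <- intersect(sel, keep)
  }
  sort(sel)
}

#' Align the members of one gene family
#'
#' Deterministic center-star progressive alignment: members are aligned
#' pairwise to the longest member (ties by name) and merged on its
#' coordinates. Families whose members all share one length (the common
#' case for substitution-only evolution) are stacked without gaps, which
#' is exact.
#'
#' @param seqs Named character vector of member protein (or CDS)
#'   sequences, length >= 2.
#' @return Named character vector of aligned sequences (equal lengths,
#'   gaps as `-`).
#' @export
align_family <- function(seqs) {
  seqs <- .as_protvec(seqs, "seqs")
  .assert(length(seqs) >= 2, "need at least two sequences")
  if (length(unique(nchar(seqs))) == 1L) return(seqs)
  center <- names(seqs)[order(-nchar(seqs), names(seqs))][1]
  others <- setdiff(names(seqs), center)
  L <- nchar(seqs[[center]])
  # pairwise alignments to the center, with end-gap-penalised behaviour
  # emulated by padding unaligned overhangs explicitly
  pieces <- list()
  ins <- integer(L + 1L) # max insertions after center position i (0..L)
  for (nm in others) {
    a <- align_batch(seqs[[center]], seqs[[nm]], keep_alignment = TRUE)
    co <- strsplit(a$aln_q, "")[[1]]
    so <- strsplit(a$aln_s, "")[[1]]
    # rebuild full-length rows: center overhangs, then aligned core
    pre_c <- a$q_start - 1L; post_c <- L - a$q_end
    pre_s <- a$s_start - 1L; post_s <- nchar(seqs[[nm]]) - a$s_end
    cpos <- 0L
    run <- integer(L + 1L) # insertions relative to center in this pair
    run[1] <- pre_s
    srow <- vector("list", L + 1L)
    srow[[1]] <- if (pre_s > 0) substring(seqs[[nm]], 1, pre_s) else ""
    aligned_s <- character(L)
    k <- 1L
    pend <- ""
    for (col in seq_along(co)) {
      if (co[col] != "-") {
        cpos <- cpos + 1L
        aligned_s[pre_c + cpos] <- so[col]
      } else {
        p <- pre_c + cpos
        run[p + 1L] <- run[p + 1L] + 1L
        srow[[p + 1L]] <- paste0(if (is.null(srow[[p + 1L]])) "" else srow[[p + 1L]],
                                 so[col])
      }
    }
    if (post_s > 0) {
      run[L + 1L] <- run[L + 1L] + post_s
      srow[[L + 1L]] <- paste0(if (is.null(srow[[L + 1L]])) "" else srow[[L + 1L]],
                               substring(seqs[[nm]], a$s_end + 1L))
    }
    if (pre_c > 0) aligned_s[seq_len(pre_c)] <- "-"
    if (post_c > 0) aligned_s[(L - post_c + 1L):L] <- "-"
    aligned_s[aligned_s == "" | is.na(aligned_s)] <- "-"
    ins <- pmax(ins, run)
    pieces[[nm]] <- list(run = run, srow = srow, aligned = aligned_s)
  }
  pad <- function(s, w) paste0(s, strrep("-", w - nchar(s)))
  build <- function(run, srow, aligned) {
    outp <- character(0)
    for (i in 0:L) {
      if (ins[i + 1L] > 0) {
        blk <- if (is.null(srow[[i + 1L]])) "" else srow[[i + 1L]]
        outp <- c(outp, pad(blk, ins[i + 1L]))
      }
      if (i < L) outp <- c(outp, aligned[i + 1L])
    }
    paste(outp, collapse = "")
  }
  center_row <- {
    cchars <- strsplit(seqs[[center]], "")[[1]]
    outp <- character(0)
    for (i in 0:L) {
      if (ins[i + 1L] > 0) outp <- c(outp, strrep("-", ins[i + 1L]))
      if (i < L) outp <- c(outp, cchars[i + 1L])
    }
    paste(outp, collapse = "")
  }
  res <- setNames(vector("character", length(seqs)), names(seqs))
  res[center] <- center_row
  for (nm in others) {
    res[nm] <- build(pieces[[nm]]$run, pieces[[nm]]$srow, pieces[[nm]]$aligned)
  }
  res
}

#' Concatenate per-locus alignments
#'
#' Joins per-locus alignments into one long alignment per taxon, loci
#' ordered by pan id, recording the column range of every locus.
#'
#' @param alignments Named list (names = pan ids) of per-locus alignments:
#'   each a named character vector over the same taxa.
#' @param taxa Character vector of taxon labels; every alignment must
#'   cover every taxon.
#' @param molecule `"aa"` or `"nt"`.
#' @return A `panoen_concat` object: `seqs` (named character vector),
#'   `partitions` (tibble `locus`, `start`, `end`, 0-based half-open),
#'   `molecule`.
#' @export
concatenate <- function(alignments, taxa, molecule = c("aa", "nt")) {
  molecule <- match.arg(molecule)
  .assert(length(alignments) > 0, "no alignments to concatenate")
  ord <- order(as.numeric(names(alignments)))
  alignments <- alignments[ord]
  for (nm in names(alignments)) {
    .assert(all(taxa %in% names(alignments[[nm]])),
            paste0("alignment ", nm, " is missing a taxon"))
  }
  widths <- vapply(alignments, function(a) nchar(a[[1]]), 1)
  ends <- cumsum(widths)
  starts <- c(0, head(ends, -1))
  seqs <- vapply(taxa, function(tx) {
    paste(vapply(alignments, function(a) a[[tx]], ""), collapse = "")
  }, "")
  structure(list(
    seqs = setNames(seqs, taxa),
    partitions = tibble(locus = names(alignments),
                        start = as.integer(starts), end = as.integer(ends)),
    molecule = molecule
  ), class = "panoen_concat")
}

#' @export
print.panoen_concat <- function(x, ...) {
  cat("<panoen_concat> ", length(x$seqs), " taxa x ", nchar(x$seqs[[1]]),
      " columns (", nrow(x$partitions), " loci, ", x$molecule, ")\n", sep = "")
  invisible(x)
}

#' Pairwise distance matrix from an alignment
#'
#' p-distances over shared non-gap columns, optionally corrected:
#' Jukes-Cantor (`-3/4 log(1 - 4p/3)`) for nucleotide data or Poisson
#' (`-log(1 - p)`) for amino acid data.
#'
#' @param x A `panoen_concat`, or a named character vector of equal-length
#'   aligned sequences.
#' @param correction `"none"`, `"jc"` (nt only) or `"poisson"` (aa only).
#' @param molecule Molecule type when `x` is a bare vector.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(x, correction = c("none", "poisson", "jc"),
                            molecule = NULL) {
  correction <- match.arg(correction)
  if (inherits(x, "panoen_concat")) {
    seqs <- x$seqs
    molecule <- x$molecule
  } else {
    seqs <- x
    if (is.null(molecule)) molecule <- "aa"
  }
  .assert(length(seqs) >= 2, "need at least two taxa")
  .assert(length(unique(nchar(seqs))) == 1L, "sequences must be aligned")
  if (correction == "jc") .assert(molecule == "nt", "Jukes-Cantor applies to nucleotide data")
  if (correction == "poisson") .assert(molecule == "aa", "Poisson correction applies to amino acid data")
  n <- length(seqs)
  pr <- t(combn(n, 2))
  mm <- .mismatch_pairs_cpp(unname(seqs), pr[, 1], pr[, 2])
  p <- ifelse(mm$shared > 0, mm$mismatch / mm$shared, 0)
  d <- switch(correction,
    none = p,
    jc = -0.75 * log(pmax(1e-12, 1 - 4 * p / 3)),
    poisson = -log(pmax(1e-12, 1 - p))
  )
  out <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  out[pr] <- d
  out[pr[, c(2, 1), drop = FALSE]] <- d
  out
}

# canonical neighbor joining; Q ties break to the lexicographically
# smallest (minimum original taxon label) pair
.nj_raw <- function(d) {
  labs <- rownames(d)
  n <- length(labs)
  if (n == 1) return(paste0(labs, ";"))
  if (n == 2) {
    return(sprintf("(%s:%.10g,%s:%.10g);", labs[1], d[1, 2] / 2,
                   labs[2], d[1, 2] / 2))
  }
  node_str <- labs         # newick fragment per active node
  node_min <- labs         # smallest taxon label under each active node
  D <- d
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-9, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- vapply(seq_len(nrow(cand)), function(k) {
      pairlab <- sort(c(node_min[cand[k, 1]], node_min[cand[k, 2]]))
      paste(pairlab, collapse = "\r")
    }, "")
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    new_str <- sprintf("(%s:%.10g,%s:%.10g)", node_str[i], li, node_str[j], lj)
    new_min <- min(node_min[i], node_min[j])
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    node_str <- c(node_str[keep], new_str)
    node_min <- c(node_min[keep], new_min)
    rownames(D2) <- colnames(D2) <- node_min
    D <- D2
  }
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
          node_str[1], la, node_str[2], lb, node_str[3], lc)
}

#' Neighbor-joining tree with optional bootstrap support
#'
#' Canonical neighbor joining on a symmetric distance matrix, with
#' deterministic tie-breaking (ties in the Q criterion resolve to the pair
#' containing the lexicographically smallest taxa). On an exactly additive
#' matrix the generating tree and its branch lengths are recovered
#' exactly. When an alignment is supplied, bootstrap resamples its columns
#' with replacement, rebuilds the distance matrix and tree `n_reps` times,
#' and reports the fraction of replicates supporting each internal
#' bipartition as node labels.
#'
#' @param d Symmetric distance matrix with taxa dimnames.
#' @param aln Optional `panoen_concat` (or named aligned vector) for
#'   bootstrap.
#' @param n_reps Bootstrap replicates (default 100; 0 disables).
#' @param seed Seed for bootstrap resampling.
#' @param correction Distance correction passed to [distance_matrix()] for
#'   the replicates.
#' @return An `ape::phylo` (unrooted for >= 3 taxa); with bootstrap,
#'   `node.label` holds support fractions in `[0, 1]`.
#' @export
nj_tree <- function(d, aln = NULL, n_reps = 100L, seed = 1L,
                    correction = c("none", "poisson", "jc")) {
  correction <- match.arg(correction)
  .assert(isTRUE(all.equal(d, t(d))), "distance matrix must be symmetric")
  .assert(all(d >= 0), "distance matrix must be non-negative")
  tree <- ape::read.tree(text = .nj_raw(d))
  if (is.null(aln) || n_reps <= 0 || length(tree$tip.label) < 4) return(tree)

  seqs <- if (inherits(aln, "panoen_concat")) aln$seqs else aln
  molecule <- if (inherits(aln, "panoen_concat")) aln$molecule else "aa"
  taxa <- rownames(d)
  .assert(all(taxa %in% names(seqs)), "alignment must cover all taxa")
  seqs <- seqs[taxa]
  # site-pattern compression: bootstrap = multinomial reweighting
  chs <- strsplit(unname(seqs), "")
  ncol_ <- length(chs[[1]])
  colstr <- do.call(paste0, chs)  # per-column pattern strings
  patt <- match(colstr, unique(colstr))
  upat <- unique(colstr)
  counts <- tabulate(patt, nbins = length(upat))
  pm <- do.call(rbind, strsplit(upat, "")) # patterns x taxa
  pairs <- t(combn(length(taxa), 2))
  np <- nrow(pairs)
  mm <- matrix(0L, nrow = length(upat), ncol = np)
  sh <- matrix(0L, nrow = length(upat), ncol = np)
  for (k in seq_len(np)) {
    a <- pm[, pairs[k, 1]]; b <- pm[, pairs[k, 2]]
    ok <- a != "-" & b != "-"
    sh[, k] <- as.integer(ok)
    mm[, k] <- as.integer(ok & a != b)
  }
  set.seed(.child_seed(seed, "nj_bootstrap"))
  boots <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    w <- as.numeric(stats::rmultinom(1, ncol_, counts))
    mmw <- as.numeric(w %*% mm)
    shw <- as.numeric(w %*% sh)
    p <- ifelse(shw > 0, mmw / shw, 0)
    dv <- switch(correction,
      none = p,
      jc = -0.75 * log(pmax(1e-12, 1 - 4 * p / 3)),
      poisson = -log(pmax(1e-12, 1 - p))
    )
    db <- matrix(0, length(taxa), length(taxa), dimnames = list(taxa, taxa))
    db[pairs] <- dv
    db[pairs[, c(2, 1), drop = FALSE]] <- dv
    boots[[r]] <- ape::read.tree(text = .nj_raw(db))
  }
  cnt <- ape::prop.clades(tree, boots, rooted = FALSE)
  cnt[is.na(cnt)] <- 0
  tree$node.label <- cnt / n_reps
  tree
}
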