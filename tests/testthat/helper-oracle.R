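# Independent reference implementations used as oracles. These are written
# against the declared scoring contracts, not against the package internals.

# Reference affine-gap overlap aligner: plain-R dynamic programme over the
# three-state recurrence, free end gaps, gap run of length k costing
# open + k * ext. Returns the optimal score and the set of
# (matches, columns) pairs attainable along optimal paths (enumerated
# exhaustively; tractable at toy scale).
oracle_align <- function(q, s, sub, open = 11, ext = 1, max_paths = 20000) {
  qv <- strsplit(q, "")[[1]]
  sv <- strsplit(s, "")[[1]]
  n <- length(qv); m <- length(sv)
  NEG <- -1e18
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  gop <- open + ext
  for (i in 1:n) {
    for (j in 1:m) {
      prev <- if (i == 1 || j == 1) 0 else max(M[i, j], X[i, j], Y[i, j])
      # note: matrices are 1-indexed at (i, j) for sequence position i-1,j-1
      M[i + 1, j + 1] <- prev + sub[qv[i], sv[j]]
      X[i + 1, j + 1] <- max(M[i, j + 1] - gop, X[i, j + 1] - ext, Y[i, j + 1] - gop)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gop, Y[i + 1, j] - ext, X[i + 1, j] - gop)
    }
  }
  ends <- rbind(
    cbind(n + 1, 1:m + 1),
    cbind(1:n + 1, m + 1)
  )
  allv <- pmax(M[ends], X[ends], Y[ends])
  best <- max(allv)

  # enumerate optimal paths backwards to collect (matches, columns) pairs
  hits <- new.env(parent = emptyenv())
  count <- 0
  walk <- function(i, j, state, matches, cols) {
    if (count > max_paths) return()
    v <- switch(state, M = M[i + 1, j + 1], X = X[i + 1, j + 1], Y = Y[i + 1, j + 1])
    if (state == "M") {
      mm <- matches + (qv[i] == sv[j])
      sc <- sub[qv[i], sv[j]]
      if ((i == 1 || j == 1) && abs(v - sc) < 1e-9) {
        hits[[paste(mm, cols + 1)]] <- TRUE
        count <<- count + 1
      }
      if (i > 1 && j > 1) {
        if (abs(M[i, j] + sc - v) < 1e-9) walk(i - 1, j - 1, "M", mm, cols + 1)
        if (abs(X[i, j] + sc - v) < 1e-9) walk(i - 1, j - 1, "X", mm, cols + 1)
        if (abs(Y[i, j] + sc - v) < 1e-9) walk(i - 1, j - 1, "Y", mm, cols + 1)
      }
    } else if (state == "X") {
      if (abs(M[i, j + 1] - gop - v) < 1e-9) walk(i - 1, j, "M", matches, cols + 1)
      if (abs(X[i, j + 1] - ext - v) < 1e-9) walk(i - 1, j, "X", matches, cols + 1)
      if (abs(Y[i, j + 1] - gop - v) < 1e-9) walk(i - 1, j, "Y", matches, cols + 1)
    } else {
      if (abs(M[i + 1, j] - gop - v) < 1e-9) walk(i, j - 1, "M", matches, cols + 1)
      if (abs(Y[i + 1, j] - ext - v) < 1e-9) walk(i, j - 1, "Y", matches, cols + 1)
      if (abs(X[i + 1, j] - gop - v) < 1e-9) walk(i, j - 1, "X", matches, cols + 1)
    }
  }
  for (r in seq_len(nrow(ends))) {
    i <- ends[r, 1] - 1; j <- ends[r, 2] - 1
    for (st in c("M", "X", "Y")) {
      v <- switch(st, M = M[i + 1, j + 1], X = X[i + 1, j + 1], Y = Y[i + 1, j + 1])
      if (abs(v - best) < 1e-9) walk(i, j, st, 0, 0)
    }
  }
  pairs <- do.call(rbind, lapply(ls(hits), function(k)
    as.integer(strsplit(k, " ")[[1]])))
  list(score = best, match_cols = pairs, exhausted = count <= max_paths)
}

# brute-force core/pan over every subset of strains of a tri-state matrix
oracle_rarefaction <- function(m, x) {
  S <- ncol(m)
  subs <- combn(S, x)
  core <- pan <- numeric(ncol(subs))
  for (k in seq_len(ncol(subs))) {
    cols <- m[, subs[, k], drop = FALSE]
    core[k] <- sum(apply(cols, 1, function(r) all(r == 2)))
    pan[k] <- sum(apply(cols, 1, function(r) any(r >= 1)))
  }
  list(core = core, pan = pan)
}

# random additive distance matrix from a random tree; returns both
random_additive <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa, br = function(k) runif(k, 0.05, 1))
  tr <- ape::unroot(tr)
  d <- ape::cophenetic.phylo(tr)
  d <- d[sort(rownames(d)), sort(colnames(d))]
  list(tree = tr, d = d)
}

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

random_peptide <- function(len) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"), len, replace = TRUE),
        collapse = "")
}
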