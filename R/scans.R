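# Locus-level screens: donor-identity windows for horizontal gene transfer,
# prophage elements at tRNA attachment sites, cassette-locus genotypes,
# role-set completeness, and fusion ORFs.

#' Parameters for the HGT identity scan
#'
#' @param window Loci per sliding window for the reported window means
#'   (default 10).
#' @param min_run Minimum number of consecutive qualifying loci for a
#'   region to be flagged (default 5).
#' @param min_identity Per-locus donor identity threshold in percent
#'   (default 90).
#' @return A validated `panoen_scan_params` list.
#' @export
scan_params <- function(window = 10L, min_run = 5L, min_identity = 90) {
  .assert(window >= min_run && min_run >= 1, "need window >= min_run >= 1")
  .assert(min_identity > 0 && min_identity <= 100, "identity must lie in (0, 100]")
  structure(list(window = as.integer(window), min_run = as.integer(min_run),
                 min_identity = min_identity), class = "panoen_scan_params")
}

#' Flag maximal runs of high-identity loci
#'
#' Given per-locus identities in genome order, returns the maximal runs of
#' at least `min_run` consecutive loci whose identity is at least
#' `min_identity`. The run definition is conjunctive: every locus in a
#' flagged run individually passes the threshold; window means play no part
#' in flagging.
#'
#' @param identity Numeric vector of per-locus identities in genome order.
#' @param min_identity Threshold in percent.
#' @param min_run Minimum run length.
#' @return Tibble `start`, `end` (1-based inclusive indices), `n_loci`.
#' @export
flag_identity_runs <- function(identity, min_identity = 90, min_run = 5L) {
  r <- rle(identity >= min_identity)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  tibble(start = starts[keep], end = ends[keep], n_loci = r$lengths[keep])
}

#' Sliding-window donor identity scan for horizontal gene transfer
#'
#' For one strain, computes the best donor-proteome identity of every locus
#' in genome order (0 when no donor hit passes coverage 0.5), the mean
#' identity over every contiguous `window`-locus window within a replicon
#' (reported for plotting, never used for flagging), and the maximal runs
#' of at least `min_run` consecutive loci with identity at least
#' `min_identity` — the regions predicted to result from horizontal
#' transfer.
#'
#' @param pan A `panoen_pan`.
#' @param strain A `panoen_strain` (one of the collection).
#' @param donors Named list of donor proteomes (named character vectors or
#'   `AAStringSet`s); must be non-empty.
#' @param params A `panoen_scan_params` from [scan_params()].
#' @return A `panoen_hgt_scan` object: `per_locus` (tibble `order`,
#'   `pan_id`, `feature_id`, `replicon`, `identity`, `donor`), `windows`
#'   (tibble `replicon`, `start_order`, `mean_identity`), `regions`
#'   (tibble `replicon`, `start_order`, `end_order`, `start`, `end`,
#'   `n_loci`), `strain`, `params`.
#' @export
hgt_window_scan <- function(pan, strain, donors, params = scan_params()) {
  .assert(length(donors) > 0, "donor proteome set must be non-empty")
  loci <- pan$loci |>
    filter(.data$strain == !!strain$strain_id) |>
    arrange(.data$replicon, .data$cds_order)
  donor_all <- unlist(lapply(donors, .as_protvec))
  donor_src <- rep(names(donors), vapply(donors, length, 1L))
  names(donor_src) <- names(donor_all) <- sub("^[^.]*\\.", "", names(donor_all))

  hits <- .hit_table(strain$proteome, donor_all,
                     min_identity = 0, min_coverage = 0.5) |>
    .top_per_query()
  idmap <- setNames(hits$identity, hits$query)
  dmap <- setNames(hits$subject, hits$query)
  per_locus <- loci |>
    mutate(identity = unname(ifelse(is.na(idmap[.data$feature_id]), 0,
                                    idmap[.data$feature_id])),
           donor = unname(donor_src[dmap[.data$feature_id]])) |>
    group_by(.data$replicon) |>
    mutate(order = row_number()) |>
    ungroup() |>
    select("order", "pan_id", "feature_id", "replicon", "start", "end",
           "identity", "donor")

  w <- params$window
  win <- per_locus |>
    group_by(.data$replicon) |>
    group_modify(function(df, key) {
      n <- nrow(df)
      if (n < w) return(tibble(start_order = integer(), mean_identity = numeric()))
      cs <- c(0, cumsum(df$identity))
      tibble(start_order = seq_len(n - w + 1L),
             mean_identity = (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w)
    }) |>
    ungroup()

  regions <- per_locus |>
    group_by(.data$replicon) |>
    group_modify(function(df, key) {
      runs <- flag_identity_runs(df$identity, params$min_identity, params$min_run)
      if (nrow(runs) == 0) {
        return(tibble(start_order = integer(), end_order = integer(),
                      start = integer(), end = integer(), n_loci = integer()))
      }
      tibble(start_order = runs$start, end_order = runs$end,
             start = df$start[runs$start], end = df$end[runs$end],
             n_loci = runs$n_loci)
    }) |>
    ungroup()

  structure(list(per_locus = per_locus, windows = win, regions = regions,
                 strain = strain$strain_id, params = params),
            class = "panoen_hgt_scan")
}

#' @export
print.panoen_hgt_scan <- function(x, ...) {
  cat("<panoen_hgt_scan> ", x$strain, ": ", nrow(x$per_locus), " loci, ",
      nrow(x$regions), " flagged region(s)\n", sep = "")
  invisible(x)
}

#' @rdname hgt_window_scan
#' @param x A `panoen_hgt_scan` object.
#' @param ... Unused.
#' @export
tidy.panoen_hgt_scan <- function(x, ...) x$per_locus

#' Detect prophage elements at tRNA attachment sites
#'
#' For each tRNA, searches up to `max_len` bases downstream of its 3' end
#' for direct repeats of the tRNA 3' core (the attachment-site signature:
#' the final `core_len` bases, matched at >= 90 percent identity). Each
#' inter-repeat segment is one element copy; genes within the element span
#' are assigned phage roles by alignment against integrase (*int*) and
#' endolysin (*lys*) reference proteins at >= `role_min_identity` percent
#' identity. An element with both *int* and *lys* is classed `full`, with
#' *int* only `fragment`; spans lacking *int* are not reported. Adjacent
#' copies sharing internal att repeats are merged with their copy number.
#'
#' @param strain A `panoen_strain`.
#' @param role_refs List with components `int` and `lys`: named reference
#'   protein vectors.
#' @param trna_ids Feature ids of tRNAs to scan (default: all tRNAs).
#'   Ids absent from the annotation are skipped with a warning.
#' @param max_len Maximum search distance downstream of the tRNA (default
#'   60000).
#' @param core_len Length of the tRNA 3' core used as the att probe
#'   (default 20; at 90 percent identity this allows 2 mismatches).
#' @param role_min_identity Identity threshold for role assignment
#'   (default 40).
#' @return Tibble `strain`, `trna_feature`, `trna_name`, `replicon`,
#'   `start`, `end`, `class`, `copy_number`, `n_genes`, one row per
#'   detected element.
#' @export
detect_phage_elements <- function(strain, role_refs, trna_ids = NULL,
                                  max_len = 60000L, core_len = 20L,
                                  role_min_identity = 40) {
  .assert(length(role_refs$int) > 0, "role_refs$int must be non-empty")
  tr <- strain$features |> filter(.data$kind == "tRNA")
  if (!is.null(trna_ids)) {
    missing <- setdiff(trna_ids, tr$feature_id)
    if (length(missing) > 0) {
      warn(paste("tRNA(s) absent from annotation, skipped:",
                 paste(missing, collapse = ", ")))
    }
    tr <- tr |> filter(.data$feature_id %in% trna_ids)
  }
  cds <- strain$features |> filter(.data$kind == "CDS")
  out <- list()
  for (i in seq_len(nrow(tr))) {
    repl <- tr$replicon[i]
    gseq <- strain$genome[[repl]]
    glen <- length(gseq)
    fwd <- tr$strand[i] != "-"
    if (fwd) {
      core <- Biostrings::subseq(gseq, tr$end[i] - core_len + 1L, tr$end[i])
      wend <- min(glen, tr$end[i] + max_len)
      if (tr$end[i] + 1L > wend) next
      win <- Biostrings::subseq(gseq, tr$end[i] + 1L, wend)
      origin <- tr$end[i] # 0-based position of tRNA 3' end
    } else {
      core <- Biostrings::reverseComplement(
        Biostrings::subseq(gseq, tr$start[i] + 1L, tr$start[i] + core_len))
      wstart <- max(1L, tr$start[i] - max_len + 1L)
      if (wstart > tr$start[i]) next
      win <- Biostrings::reverseComplement(
        Biostrings::subseq(gseq, wstart, tr$start[i]))
      origin <- tr$start[i]
    }
    mm <- floor(core_len * 0.1)
    hits <- Biostrings::matchPattern(core, win, max.mismatch = mm)
    if (length(hits) == 0) next
    att_end <- sort(Biostrings::end(hits)) # distance from origin
    # segment k spans (bound[k], bound[k+1]] downstream of the tRNA
    bounds <- c(0L, att_end)
    seg_genes <- list()
    for (k in seq_len(length(bounds) - 1L)) {
      if (fwd) {
        s0 <- origin + bounds[k]; s1 <- origin + bounds[k + 1L]
        g <- cds |> filter(.data$replicon == repl, .data$start >= s0,
                           .data$end <= s1)
      } else {
        s1 <- origin - bounds[k]; s0 <- origin - bounds[k + 1L]
        g <- cds |> filter(.data$replicon == repl, .data$start >= s0,
                           .data$end <= s1)
      }
      seg_genes[[k]] <- g$feature_id
    }
    all_genes <- unique(unlist(seg_genes))
    if (length(all_genes) == 0) next
    role <- .assign_roles(strain$proteome[all_genes], role_refs,
                          role_min_identity)
    has_int_seg <- vapply(seg_genes, function(g) any(role[g] == "int", na.rm = TRUE), TRUE)
    # copies: maximal prefix of segments carrying an integrase
    k <- 0L
    while (k < length(has_int_seg) && has_int_seg[k + 1L]) k <- k + 1L
    if (k == 0L) next
    genes_in <- unique(unlist(seg_genes[seq_len(k)]))
    has_lys <- any(role[genes_in] == "lys", na.rm = TRUE)
    span_end <- bounds[k + 1L]
    out[[length(out) + 1]] <- tibble(
      strain = strain$strain_id,
      trna_feature = tr$feature_id[i],
      trna_name = tr$product[i],
      replicon = repl,
      start = if (fwd) origin else origin - span_end,
      end = if (fwd) origin + span_end else origin,
      class = if (has_lys) "full" else "fragment",
      copy_number = k,
      n_genes = length(genes_in)
    )
  }
  if (length(out) == 0) {
    return(tibble(strain = character(), trna_feature = character(),
                  trna_name = character(), replicon = character(),
                  start = integer(), end = integer(), class = character(),
                  copy_number = integer(), n_genes = integer()))
  }
  bind_rows(out)
}

# role of each protein: best-identity match among int/lys reference sets
.assign_roles <- function(prots, role_refs, min_identity) {
  out <- setNames(rep(NA_character_, length(prots)), names(prots))
  for (rl in c("int", "lys")) {
    refs <- role_refs[[rl]]
    if (length(refs) == 0) next
    h <- .hit_table(prots, refs, min_identity = min_identity,
                    min_coverage = 0.5)
    if (nrow(h) == 0) next
    top <- .top_per_query(h)
    out[top$query] <- ifelse(is.na(out[top$query]), rl, out[top$query])
  }
  out
}

#' Genotype a variable cassette locus
#'
#' Given two core anchor loci, extracts for every strain the ordered pan
#' ids strictly between the anchors along the genome and groups identical
#' ordered contents into variants. Content is orientation-normalized so
#' the upstream anchor always comes first; a strain whose region is
#' inverted relative to the reference orientation matches the un-inverted
#' variant and is flagged. Variant labels are ordered by frequency, then
#' signature. A strain missing either anchor is labeled unresolved.
#'
#' @param pan A `panoen_pan`.
#' @param anchors Length-2 integer vector: upstream and downstream anchor
#'   pan ids (core intact loci).
#' @return A `panoen_cassette` object: `genotypes` (tibble `strain`,
#'   `variant`, `signature`, `inverted`, `n_genes`), `variants` (tibble
#'   `variant`, `signature`, `n_strains`), `anchors`.
#' @export
genotype_cassette_locus <- function(pan, anchors) {
  .assert(length(anchors) == 2, "anchors must contain two pan ids")
  loci <- pan$loci
  rows <- list()
  for (st in pan$strains) {
    sub <- loci |> filter(.data$strain == st)
    a1 <- sub |> filter(.data$pan_id == anchors[1])
    a2 <- sub |> filter(.data$pan_id == anchors[2])
    if (nrow(a1) == 0 || nrow(a2) == 0 ||
        a1$replicon[1] != a2$replicon[1]) {
      rows[[st]] <- tibble(strain = st, signature = NA_character_,
                           inverted = NA, n_genes = NA_integer_)
      next
    }
    o1 <- a1$cds_order[1]; o2 <- a2$cds_order[1]
    inverted <- o1 > o2
    lo <- min(o1, o2); hi <- max(o1, o2)
    between <- sub |>
      filter(.data$replicon == a1$replicon[1],
             .data$cds_order > lo, .data$cds_order < hi) |>
      arrange(.data$cds_order)
    ids <- between$pan_id
    if (inverted) ids <- rev(ids)
    rows[[st]] <- tibble(strain = st,
                         signature = paste(ids, collapse = ","),
                         inverted = inverted,
                         n_genes = length(ids))
  }
  g <- bind_rows(rows)
  sigs <- g |>
    filter(!is.na(.data$signature)) |>
    count(.data$signature, name = "n_strains") |>
    arrange(desc(.data$n_strains), .data$signature) |>
    mutate(variant = paste0("v", row_number()))
  g <- g |>
    left_join(sigs |> select("signature", "variant"), by = "signature") |>
    mutate(variant = ifelse(is.na(.data$signature), "unresolved", .data$variant)) |>
    select("strain", "variant", "signature", "inverted", "n_genes")
  structure(list(genotypes = g,
                 variants = sigs |> select("variant", "signature", "n_strains"),
                 anchors = anchors),
            class = "panoen_cassette")
}

#' @export
print.panoen_cassette <- function(x, ...) {
  cat("<panoen_cassette> anchors ", x$anchors[1], "-", x$anchors[2], ": ",
      nrow(x$variants), " variant(s) across ",
      sum(!is.na(x$genotypes$signature)), " strains\n", sep = "")
  invisible(x)
}

#' @rdname genotype_cassette_locus
#' @param x A `panoen_cassette` object.
#' @param ... Unused.
#' @export
tidy.panoen_cassette <- function(x, ...) x$genotypes

#' Pathway / complex completeness per strain
#'
#' For each strain and each role group (for example the enzymes of a
#' pathway or the IIA/IIB/IIC subunits of a PTS transporter complex),
#' reports whether every required role is represented by at least one
#' intact locus, and otherwise lists the blocking roles with the nature of
#' each block: `pseudogenization` (only pseudogene copies present) or
#' `absence` (no copy at all).
#'
#' @param pam A `panoen_pam`.
#' @param role_map Tibble with columns `pan_id`, `role` assigning role
#'   labels to loci (role labels are inputs, not inferred).
#' @param groups Named list: group name -> character vector of required
#'   roles. Every required role must appear in `role_map`.
#' @return Tibble `strain`, `group`, `complete`, `n_blocked`,
#'   `blocked_roles` (list-column of tibbles `role`, `reason`).
#' @export
role_completeness <- function(pam, role_map, groups) {
  .assert(is.list(groups) && length(groups) > 0 && !is.null(names(groups)),
          "groups must be a non-empty named list of role vectors")
  req <- unique(unlist(groups))
  missing <- setdiff(req, role_map$role)
  .assert(length(missing) == 0,
          paste("required role(s) absent from role_map:",
                paste(missing, collapse = ", ")))
  m <- pam$m
  rows <- list()
  for (st in pam$strains) {
    col <- m[, st]
    names(col) <- rownames(m)
    for (gname in names(groups)) {
      roles <- groups[[gname]]
      status <- vapply(roles, function(r) {
        ids <- as.character(role_map$pan_id[role_map$role == r])
        ids <- intersect(ids, names(col))
        if (any(col[ids] == 2L)) "intact"
        else if (any(col[ids] == 1L)) "pseudogenization"
        else "absence"
      }, "")
      blocked <- tibble(role = unname(roles[status != "intact"]),
                        reason = unname(status[status != "intact"]))
      rows[[length(rows) + 1]] <- tibble(
        strain = st, group = gname,
        complete = nrow(blocked) == 0L,
        n_blocked = nrow(blocked),
        blocked_roles = list(blocked))
    }
  }
  bind_rows(rows)
}

#' Detect candidate fusion ORFs
#'
#' Flags a protein as a candidate fusion when no single family
#' representative covers at least `min_single_cov` of its length, but two
#' representatives from different families cover at least `min_part_cov`
#' each with mutual overlap of at most `max_overlap` of the protein —
#' the signature of significant matches to the amino- and carboxyl-
#' sections in isolation without any full-length single match. The
#' breakpoint estimate is the midpoint between the two matched spans.
#'
#' @param proteome Named character vector (or `AAStringSet`) of query
#'   proteins.
#' @param representatives Named protein vector of family representatives
#'   (names are family labels; at least two families).
#' @param min_identity Identity threshold for counting a hit (default 40).
#' @param min_single_cov Single-hit coverage above which a protein is not
#'   a fusion candidate (default 0.8).
#' @param min_part_cov Minimum coverage of each partner hit (default 0.3).
#' @param max_overlap Maximum mutual overlap of the two partner spans as a
#'   fraction of the protein (default 0.1).
#' @return Tibble `protein`, `family_n`, `family_c`, `breakpoint`,
#'   `cov_n`, `cov_c`, one row per flagged candidate.
#' @export
detect_fusions <- function(proteome, representatives, min_identity = 40,
                           min_single_cov = 0.8, min_part_cov = 0.3,
                           max_overlap = 0.1) {
  proteome <- .as_protvec(proteome, "proteome")
  representatives <- .as_protvec(representatives, "representatives")
  .assert(length(representatives) >= 2, "need representatives from >= 2 families")
  cand <- .candidate_pairs(proteome, representatives)
  if (nrow(cand) == 0) return(.empty_fusions())
  aln <- align_batch(unname(proteome[cand$idx_q]),
                     unname(representatives[cand$idx_s]))
  hits <- tibble(
    protein = names(proteome)[cand$idx_q],
    family = names(representatives)[cand$idx_s],
    identity = aln$identity,
    q_start = aln$q_start, q_end = aln$q_end,
    cov = (aln$q_end - aln$q_start + 1) / nchar(proteome[cand$idx_q])
  ) |>
    filter(.data$identity >= min_identity)
  out <- list()
  for (p in unique(hits$protein)) {
    h <- hits |> filter(.data$protein == p) |> arrange(.data$q_start, .data$family)
    if (any(h$cov >= min_single_cov)) next
    plen <- nchar(proteome[[p]])
    found <- NULL
    for (i in seq_len(nrow(h))) {
      for (j in seq_len(nrow(h))) {
        if (i == j || h$family[i] == h$family[j]) next
        if (h$q_start[i] > h$q_start[j]) next
        if (h$cov[i] < min_part_cov || h$cov[j] < min_part_cov) next
        ov <- max(0, min(h$q_end[i], h$q_end[j]) -
                    max(h$q_start[i], h$q_start[j]) + 1)
        if (ov > max_overlap * plen) next
        sc <- h$cov[i] + h$cov[j]
        if (is.null(found) || sc > found$sc) {
          found <- list(i = i, j = j, sc = sc)
        }
      }
    }
    if (!is.null(found)) {
      i <- found$i; j <- found$j
      bp <- (h$q_end[i] + h$q_start[j]) / 2
      out[[length(out) + 1]] <- tibble(
        protein = p, family_n = h$family[i], family_c = h$family[j],
        breakpoint = bp, cov_n = h$cov[i], cov_c = h$cov[j])
    }
  }
  if (length(out) == 0) return(.empty_fusions())
  bind_rows(out)
}

.empty_fusions <- function() {
  tibble(protein = character(), family_n = character(), family_c = character(),
         breakpoint = numeric(), cov_n = numeric(), cov_c = numeric())
}
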