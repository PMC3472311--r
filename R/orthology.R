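# Pan-genome locus construction: connected components of the all-pairs
# reciprocal-best-hit graph, conflict resolution by long-range genomic
# synteny (neighbor-locus agreement), reference-anchored locus numbering,
# and intact/pseudogene status classification.

# combined CDS table over a strain list, with per-strain genome order
.cds_table <- function(strains) {
  bind_rows(lapply(strains, function(s) {
    s$features |>
      filter(.data$kind == "CDS") |>
      mutate(strain = s$strain_id)
  })) |>
    group_by(.data$strain) |>
    mutate(cds_order = row_number()) |>
    ungroup()
}

#' Synteny contexts: neighbor features within a window
#'
#' For every CDS, the feature ids of up to `window` neighboring CDS on each
#' side along the same replicon, in genome order. These contexts are the
#' "long-range genomic synteny" evidence used to arbitrate ambiguous
#' homology.
#'
#' @param strains Named list of `panoen_strain` objects.
#' @param window Neighbors per side (default 5).
#' @return A named list mapping feature id to a character vector of
#'   neighbor feature ids.
#' @export
build_synteny_context <- function(strains, window = 5L) {
  cds <- .cds_table(strains)
  out <- vector("list", nrow(cds))
  names(out) <- cds$feature_id
  grp <- cds |> group_by(.data$strain, .data$replicon)
  for (g in group_split(grp)) {
    ids <- g$feature_id
    n <- length(ids)
    for (i in seq_len(n)) {
      lo <- max(1L, i - window)
      hi <- min(n, i + window)
      out[[ids[i]]] <- ids[setdiff(lo:hi, i)]
    }
  }
  out
}

#' Cluster reciprocal best hits into provisional ortholog groups
#'
#' Builds the graph whose vertices are all CDS features across strains and
#' whose edges are reciprocal best hits from every strain pair, and returns
#' its connected components. A component containing two members from one
#' strain is marked `conflicted` and passed to synteny resolution; features
#' with no RBH edge become singleton clusters.
#'
#' @param edges Tibble with columns `a`, `b` (feature ids across all strain
#'   pairs), as produced by [reciprocal_best_hits()].
#' @param members Tibble with columns `feature_id`, `strain` covering every
#'   CDS in the collection.
#' @return Tibble `feature_id`, `strain`, `cluster` (integer), `conflicted`
#'   (logical, per cluster).
#' @export
cluster_rbh <- function(edges, members) {
  .assert(all(c("feature_id", "strain") %in% names(members)),
          "members needs feature_id and strain columns")
  g <- igraph::graph_from_data_frame(
    edges[, c("a", "b")], directed = FALSE,
    vertices = data.frame(name = members$feature_id)
  )
  comp <- igraph::components(g)$membership
  out <- members |>
    mutate(cluster = as.integer(comp[.data$feature_id]))
  conf <- out |>
    count(.data$cluster, .data$strain) |>
    group_by(.data$cluster) |>
    summarise(conflicted = any(.data$n > 1L), .groups = "drop")
  left_join(out, conf, by = "cluster")
}

# neighbor agreement of member `fid` against a set of locus members:
# the number of distinct neighbor clusters of fid that are also neighbor
# clusters of at least one existing member
.neighbor_agreement <- function(fid, locus_members, contexts, clu_of) {
  mine <- unique(clu_of[contexts[[fid]]])
  theirs <- unique(clu_of[unlist(contexts[locus_members], use.names = FALSE)])
  sum(!is.na(mine) & mine %in% theirs)
}

#' Resolve conflicted clusters by genomic synteny
#'
#' Splits or re-assigns members of conflicted RBH components so that each
#' strain contributes at most one member per locus (adjacent co-oriented
#' fragments from one strain are retained together as a split gene). Among
#' a strain's competing members, the one agreeing with the locus on the
#' most neighbor loci (window `window`, orientation-insensitive) joins; a
#' member whose agreement is below `min_agreement` founds a new locus
#' instead, preferring paralog splitting over chimeric merging. Leftover
#' members are peeled iteratively into further loci; final leftovers found
#' singleton loci. All tie-breaks are deterministic (higher identity to the
#' locus representative, then coordinate).
#'
#' @param clusters Output of [cluster_rbh()].
#' @param contexts Output of [build_synteny_context()].
#' @param strains Named list of `panoen_strain` objects (for coordinates
#'   and proteins used in tie-breaking).
#' @param window Synteny window (informational; contexts carry the window).
#' @param min_agreement Minimum neighbor agreement to join a locus
#'   (default 2).
#' @return Tibble `feature_id`, `strain`, `locus` (integer) — a partition
#'   of all features.
#' @export
refine_with_synteny <- function(clusters, contexts, strains,
                                window = 5L, min_agreement = 2L) {
  cds <- .cds_table(strains)
  pos <- setNames(cds$cds_order, cds$feature_id)
  strand <- setNames(cds$strand, cds$feature_id)
  prot <- unlist(lapply(strains, function(s) s$proteome))
  names(prot) <- sub("^[^.]*\\.", "", names(prot))
  clu_of <- setNames(clusters$cluster, clusters$feature_id)

  ok <- clusters |> filter(!.data$conflicted)
  res <- list(ok |> select("feature_id", "strain") |>
                mutate(locus_key = paste0("c", ok$cluster)))

  conf_ids <- sort(unique(clusters$cluster[clusters$conflicted]))
  for (ci in conf_ids) {
    mem <- clusters |>
      filter(.data$cluster == ci) |>
      arrange(.data$strain, .data$feature_id)
    pass <- 0L
    while (nrow(mem) > 0) {
      pass <- pass + 1L
      counts <- table(mem$strain)
      solo <- names(counts)[counts == 1L]
      backbone <- mem$feature_id[mem$strain %in% solo]
      if (length(backbone) == 0) {
        backbone <- mem$feature_id[order(mem$feature_id)][1]
      }
      taken <- backbone
      multi <- setdiff(unique(mem$strain), mem$strain[mem$feature_id %in% backbone])
      for (st in sort(multi)) {
        cand <- mem$feature_id[mem$strain == st]
        # split gene: adjacent co-oriented fragments stay together
        if (length(cand) > 1) {
          po <- sort(pos[cand])
          if (all(diff(po) == 1L) && length(unique(strand[cand])) == 1L) {
            taken <- c(taken, cand)
            next
          }
        }
        scores <- vapply(cand, .neighbor_agreement, 0,
                         locus_members = taken, contexts = contexts,
                         clu_of = clu_of)
        best <- max(scores)
        if (best < min_agreement) next
        top <- cand[scores == best]
        if (length(top) > 1) {
          # tie: higher identity to the representative, then coordinate
          rep_id <- taken[order(-nchar(prot[taken]), taken)][1]
          idv <- align_batch(unname(prot[top]),
                             rep(unname(prot[rep_id]), length(top)))$identity
          top <- top[order(-idv, pos[top])]
        }
        taken <- c(taken, top[1])
      }
      res[[length(res) + 1]] <- tibble(
        feature_id = taken,
        strain = mem$strain[match(taken, mem$feature_id)],
        locus_key = paste0("c", ci, "p", pass))
      mem <- mem |> filter(!(.data$feature_id %in% taken))
      if (pass > 1000L) abort("synteny refinement failed to converge")
    }
  }
  out <- bind_rows(res)
  out |>
    mutate(locus = match(.data$locus_key, sort(unique(out$locus_key)))) |>
    select("feature_id", "strain", "locus")
}

#' Number pan-genome loci against a reference strain
#'
#' Loci with a member in the reference strain are numbered by reference
#' gene order; loci absent from the reference are interleaved at the
#' midpoint between their flanking reference-anchored loci, the anchor
#' chosen by majority vote over carrier strains (ties toward the earlier
#' anchor), with the within-gap order given by mean distance from the left
#' anchor. Numbering is deterministic and a bijection onto `1..N`.
#'
#' @param assignment Tibble `feature_id`, `strain`, `locus` from
#'   [refine_with_synteny()].
#' @param strains Named list of `panoen_strain` objects.
#' @param reference Reference strain id.
#' @return Tibble `feature_id`, `strain`, `pan_id`.
#' @export
assign_pan_numbers <- function(assignment, strains, reference) {
  .assert(reference %in% unique(assignment$strain),
          paste0("reference strain '", reference, "' not present"))
  cds <- .cds_table(strains)
  asn <- assignment |>
    left_join(cds |> select("feature_id", "replicon", "start", "cds_order"),
              by = "feature_id")

  ref <- asn |>
    filter(.data$strain == reference) |>
    arrange(.data$replicon, .data$start) |>
    distinct(.data$locus)
  ref_rank <- setNames(seq_len(nrow(ref)), ref$locus)

  # per-strain sweep: nearest preceding/following reference-anchored locus
  asn <- asn |>
    mutate(rank = unname(ref_rank[as.character(.data$locus)])) |>
    group_by(.data$strain, .data$replicon) |>
    arrange(.data$cds_order, .by_group = TRUE) |>
    mutate(
      left_rank = vctrs::vec_fill_missing(.data$rank, direction = "down"),
      gap_pos = row_number() -
        vctrs::vec_fill_missing(ifelse(is.na(.data$rank), NA_integer_,
                                       row_number()), direction = "down")
    ) |>
    ungroup()

  nonref <- asn |>
    filter(is.na(.data$rank)) |>
    group_by(.data$locus) |>
    summarise(
      anchor = {
        lr <- .data$left_rank[!is.na(.data$left_rank)]
        if (length(lr) == 0) 0 else {
          tab <- sort(table(lr), decreasing = TRUE)
          cands <- as.numeric(names(tab)[tab == tab[1]])
          min(cands)
        }
      },
      ordinal = mean(.data$gap_pos, na.rm = TRUE),
      .groups = "drop"
    ) |>
    mutate(ordinal = ifelse(is.nan(.data$ordinal), 0, .data$ordinal))

  key <- bind_rows(
    tibble(locus = as.integer(ref$locus),
           anchor = as.numeric(ref_rank), ordinal = 0),
    nonref |> mutate(locus = as.integer(.data$locus))
  ) |>
    arrange(.data$anchor, .data$ordinal, .data$locus) |>
    mutate(pan_id = row_number())

  assignment |>
    left_join(key |> select("locus", "pan_id"), by = "locus") |>
    select("feature_id", "strain", "pan_id")
}

#' Classify locus members as intact or pseudogene
#'
#' A member is a pseudogene if (a) its translation contains an internal
#' stop, (b) its protein is shorter than `len_frac` times the median length
#' of members not flagged by (a), or (c) it is one of two or more
#' co-oriented adjacent fragments from one strain assigned to the same
#' locus (a split gene). Everything else is intact.
#'
#' @param numbered Tibble `feature_id`, `strain`, `pan_id`.
#' @param strains Named list of `panoen_strain` objects.
#' @param len_frac Truncation threshold relative to the median intact
#'   member length (default 0.8).
#' @return The input with a `status` column (`"intact"`/`"pseudogene"`).
#' @export
classify_member_status <- function(numbered, strains, len_frac = 0.8) {
  prot <- unlist(lapply(strains, function(s) s$proteome))
  names(prot) <- sub("^[^.]*\\.", "", names(prot))
  cds <- .cds_table(strains)
  pos <- setNames(cds$cds_order, cds$feature_id)
  strand <- setNames(cds$strand, cds$feature_id)

  numbered |>
    mutate(
      .prot = unname(prot[.data$feature_id]),
      .len = nchar(.data$.prot),
      .stop = grepl("*", .data$.prot, fixed = TRUE)
    ) |>
    group_by(.data$pan_id) |>
    mutate(
      .med = stats::median(.data$.len[!.data$.stop]),
      .short = !is.na(.data$.med) & .data$.len < len_frac * .data$.med
    ) |>
    group_by(.data$pan_id, .data$strain) |>
    mutate(
      .split = n() > 1L &&
        all(diff(sort(pos[.data$feature_id])) == 1L) &&
        length(unique(strand[.data$feature_id])) == 1L
    ) |>
    ungroup() |>
    mutate(status = ifelse(.data$.stop | .data$.short | .data$.split,
                           "pseudogene", "intact")) |>
    select("feature_id", "strain", "pan_id", "status")
}

#' Build the pan genome of a strain collection
#'
#' End-to-end orthology: all-pairs reciprocal best hits, connected-component
#' clustering, synteny-based conflict resolution, reference-anchored locus
#' numbering, and member status classification. This is the package's
#' analog of homology-plus-synteny orthology mapping for a small strain
#' collection.
#'
#' @param strains Named list of `panoen_strain` objects (>= 2).
#' @param reference Reference strain id for numbering (default first).
#' @param min_identity,min_coverage RBH thresholds (see [best_hits()]).
#' @param window Synteny window per side (default 5).
#' @param min_agreement Minimum neighbor agreement to join a conflicted
#'   locus (default 2).
#' @param rbh_min_shared Shared-5-mer prefilter count for the all-pairs
#'   RBH stage (default 6). Within a strain collection, true ortholog
#'   pairs share hundreds of 5-mers, so this stricter setting only skips
#'   pairs far below the identity threshold while keeping the all-pairs
#'   stage fast; pass 2 to match the [best_hits()] default.
#' @param verbose Print per-pair progress.
#' @return A `panoen_pan` object: list with `loci` (tibble `pan_id`,
#'   `strain`, `feature_id`, `status`, plus coordinates), `representatives`
#'   (named protein vector, longest intact member per locus, ties by id),
#'   `reference`, `strains` (strain ids), `params`.
#' @export
infer_pan_genome <- function(strains, reference = names(strains)[1],
                             min_identity = 40, min_coverage = 0.5,
                             window = 5L, min_agreement = 2L,
                             rbh_min_shared = 6L, verbose = FALSE) {
  .assert(length(strains) >= 2, "need at least two strains")
  .assert(reference %in% names(strains), "reference must be one of the strains")
  ids <- names(strains)
  kt <- lapply(strains, function(s) .protein_kmers(s$proteome))
  edge_list <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      if (verbose) message("RBH ", ids[i], " vs ", ids[j])
      rb <- reciprocal_best_hits(strains[[i]]$proteome, strains[[j]]$proteome,
                                 min_identity = min_identity,
                                 min_coverage = min_coverage,
                                 min_shared = rbh_min_shared,
                                 kmer_tables = list(a = kt[[i]], b = kt[[j]]))
      edge_list[[length(edge_list) + 1]] <- rb |> select("a", "b")
    }
  }
  edges <- bind_rows(edge_list)
  cds <- .cds_table(strains)
  members <- cds |> select("feature_id", "strain")
  clusters <- cluster_rbh(edges, members)
  contexts <- build_synteny_context(strains, window = window)
  refined <- refine_with_synteny(clusters, contexts, strains,
                                 window = window, min_agreement = min_agreement)
  numbered <- assign_pan_numbers(refined, strains, reference)
  status <- classify_member_status(numbered, strains)
  loci <- status |>
    left_join(cds |> select("feature_id", "replicon", "start", "end",
                            "strand", "cds_order"),
              by = "feature_id") |>
    arrange(.data$pan_id, .data$strain)

  prot <- unlist(lapply(strains, function(s) s$proteome))
  names(prot) <- sub("^[^.]*\\.", "", names(prot))
  reps <- loci |>
    mutate(.len = nchar(unname(prot[.data$feature_id]))) |>
    filter(.data$status == "intact") |>
    arrange(.data$pan_id, -.data$.len, .data$feature_id) |>
    distinct(.data$pan_id, .keep_all = TRUE)
  fallback <- loci |>
    filter(!(.data$pan_id %in% reps$pan_id)) |>
    arrange(.data$pan_id, .data$feature_id) |>
    distinct(.data$pan_id, .keep_all = TRUE)
  reps <- bind_rows(reps |> select("pan_id", "feature_id"),
                    fallback |> select("pan_id", "feature_id")) |>
    arrange(.data$pan_id)
  representatives <- setNames(unname(prot[reps$feature_id]),
                              paste0(reps$pan_id, "|", reps$feature_id))

  structure(list(
    loci = loci |> select("pan_id", "strain", "feature_id", "status",
                          "replicon", "start", "end", "strand", "cds_order"),
    representatives = representatives,
    reference = reference,
    strains = ids,
    params = list(min_identity = min_identity, min_coverage = min_coverage,
                  window = window, min_agreement = min_agreement)
  ), class = "panoen_pan")
}

#' @export
print.panoen_pan <- function(x, ...) {
  cat("<panoen_pan> ", max(x$loci$pan_id), " loci across ",
      length(x$strains), " strains (reference ", x$reference, ")\n", sep = "")
  invisible(x)
}

#' @rdname infer_pan_genome
#' @param x A `panoen_pan` object.
#' @param ... Unused.
#' @export
tidy.panoen_pan <- function(x, ...) {
  x$loci
}

#' @rdname infer_pan_genome
#' @export
glance.panoen_pan <- function(x, ...) {
  st <- x$loci |>
    group_by(.data$pan_id) |>
    summarise(
      n_intact = sum(.data$status == "intact"),
      n_present = n_distinct(.data$strain), .groups = "drop")
  tibble(
    n_loci = nrow(st),
    n_core_intact = sum(st$n_intact >= length(x$strains)),
    n_strains = length(x$strains),
    reference = x$reference
  )
}
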