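# Tri-state presence-absence matrix and the statistics built on it:
# core/pan rarefaction over strain combinations, strain-group-specific
# loci, and the non-reference ORF inventory.

#' Build the tri-state presence-absence matrix
#'
#' One row per pan locus, one column per strain, cells coded 0 (absent),
#' 1 (pseudogene) or 2 (intact). With `chromosomal_only = TRUE`, loci whose
#' members all lie on plasmid replicons are excluded, mirroring headline
#' pan/core counts that cover the chromosomal replicon only.
#'
#' @param pan A `panoen_pan` from [infer_pan_genome()].
#' @param strains Named list of `panoen_strain` objects; required when
#'   `chromosomal_only = TRUE` (to know replicon types).
#' @param chromosomal_only Drop plasmid-only loci (default `FALSE`).
#' @return A `panoen_pam` object: list with `m` (integer matrix, rownames =
#'   pan ids), `strains`, `chromosomal_only`.
#' @export
build_matrix <- function(pan, strains = NULL, chromosomal_only = FALSE) {
  loci <- pan$loci
  if (chromosomal_only) {
    .assert(!is.null(strains), "strains required when chromosomal_only = TRUE")
    repl_type <- bind_rows(lapply(strains, function(s) s$replicons)) |>
      distinct(.data$name, .data$type)
    types <- setNames(repl_type$type, repl_type$name)
    plasmid_only <- loci |>
      group_by(.data$pan_id) |>
      summarise(drop = all(types[.data$replicon] == "plasmid"), .groups = "drop")
    loci <- loci |> anti_join(plasmid_only |> filter(.data$drop), by = "pan_id")
  }
  code <- c(intact = 2L, pseudogene = 1L)
  cell <- loci |>
    group_by(.data$pan_id, .data$strain) |>
    summarise(v = max(code[.data$status]), .groups = "drop")
  ids <- sort(unique(cell$pan_id))
  sts <- pan$strains
  m <- matrix(0L, nrow = length(ids), ncol = length(sts),
              dimnames = list(as.character(ids), sts))
  m[cbind(match(cell$pan_id, ids), match(cell$strain, sts))] <- cell$v
  structure(list(m = m, strains = sts, chromosomal_only = chromosomal_only),
            class = "panoen_pam")
}

#' @export
print.panoen_pam <- function(x, ...) {
  core <- sum(rowSums(x$m == 2L) == ncol(x$m))
  cat("<panoen_pam> ", nrow(x$m), " loci x ", ncol(x$m), " strains (",
      core, " intact-core)", if (x$chromosomal_only) ", chromosomal only",
      "\n", sep = "")
  invisible(x)
}

#' @rdname build_matrix
#' @param x A `panoen_pam` object.
#' @param ... Unused.
#' @export
tidy.panoen_pam <- function(x, ...) {
  as_tibble(x$m, rownames = "pan_id") |>
    tidyr::pivot_longer(-"pan_id", names_to = "strain", values_to = "code") |>
    mutate(pan_id = as.integer(.data$pan_id),
           status = c("absent", "pseudogene", "intact")[.data$code + 1L])
}

#' Core/pan rarefaction over strain combinations
#'
#' For every subset size `x` from 1 to the number of strains, computes the
#' core size (loci present in all subset strains) and pan size (loci
#' present in at least one) over strain subsets. All `choose(S, x)` subsets
#' are enumerated exactly whenever their number is at most `exact_limit`
#' (the default keeps a 14-strain collection exact at every `x`, where the
#' largest count is `choose(14, 7) = 3432`); larger strata are sampled
#' uniformly with the given seed. By default a pseudogene counts as absent
#' for the core but present for the pan, reflecting the separation of
#' full-length ORFs from potential pseudogenes; both conventions are
#' configurable.
#'
#' @param pam A `panoen_pam` from [build_matrix()].
#' @param pseudogene_core Count a pseudogene as `"absent"` (default) or
#'   `"present"` when computing the core.
#' @param pseudogene_pan Count a pseudogene as `"present"` (default) or
#'   `"absent"` when computing the pan.
#' @param exact_limit Maximum number of subsets enumerated exhaustively
#'   per `x` (default 10000).
#' @param n_samples Subsets sampled per `x` beyond `exact_limit`.
#' @param seed Seed for the sampled strata.
#' @return A `panoen_rarefaction` object: `curve` (tibble `x`,
#'   `subset`, `core`, `pan`), `summary` (tibble `x`, `mean_core`,
#'   `mean_pan`, `n_subsets`, `mode`), conventions and seed.
#' @export
rarefaction <- function(pam, pseudogene_core = c("absent", "present"),
                        pseudogene_pan = c("present", "absent"),
                        exact_limit = 10000L, n_samples = 200L, seed = 1L) {
  pseudogene_core <- match.arg(pseudogene_core)
  pseudogene_pan <- match.arg(pseudogene_pan)
  m <- pam$m
  S <- ncol(m)
  .assert(S >= 1, "matrix must have at least one strain")
  core_ok <- if (pseudogene_core == "present") m >= 1L else m == 2L
  pan_ok <- if (pseudogene_pan == "present") m >= 1L else m == 2L
  .assert(S <= 30, "rarefaction supports up to 30 strains")
  bit <- 2^(seq_len(S) - 1)
  cpat <- as.integer(core_ok %*% bit)
  ppat <- as.integer(pan_ok %*% bit)
  ct <- table(cpat); pt <- table(ppat)
  cu <- as.integer(names(ct)); cn <- as.integer(ct)
  pu <- as.integer(names(pt)); pn <- as.integer(pt)

  rows <- list(); sums <- list()
  for (x in seq_len(S)) {
    n_total <- choose(S, x)
    if (n_total <= exact_limit) {
      masks <- as.integer(combn(S, x, function(ix) sum(bit[ix])))
      mode <- "exact"
    } else {
      set.seed(.child_seed(seed, paste0("rarefaction_x", x)))
      masks <- vapply(seq_len(n_samples),
                      function(i) as.integer(sum(bit[sample.int(S, x)])), 1L)
      mode <- "sampled"
    }
    core <- vapply(masks, function(M) sum(cn[bitwAnd(cu, M) == M]), 1)
    pan <- vapply(masks, function(M) sum(pn[bitwAnd(pu, M) != 0L]), 1)
    rows[[x]] <- tibble(x = x, subset = seq_along(masks),
                        core = as.integer(core), pan = as.integer(pan))
    sums[[x]] <- tibble(x = x, mean_core = mean(core), mean_pan = mean(pan),
                        n_subsets = length(masks), mode = mode)
  }
  structure(list(curve = bind_rows(rows), summary = bind_rows(sums),
                 pseudogene_core = pseudogene_core,
                 pseudogene_pan = pseudogene_pan, seed = seed),
            class = "panoen_rarefaction")
}

#' @export
print.panoen_rarefaction <- function(x, ...) {
  s <- x$summary
  cat("<panoen_rarefaction> x = 1..", max(s$x),
      "; core ", round(s$mean_core[nrow(s)], 1), " / pan ",
      round(s$mean_pan[nrow(s)], 1), " at x = ", max(s$x), "\n", sep = "")
  invisible(x)
}

#' @rdname rarefaction
#' @param x A `panoen_rarefaction` object.
#' @param ... Unused.
#' @export
tidy.panoen_rarefaction <- function(x, ...) x$curve

#' @rdname rarefaction
#' @export
glance.panoen_rarefaction <- function(x, ...) {
  s <- x$summary
  tibble(n_strains = max(s$x),
         core_final = s$mean_core[nrow(s)],
         pan_final = s$mean_pan[nrow(s)],
         pseudogene_core = x$pseudogene_core,
         pseudogene_pan = x$pseudogene_pan)
}

#' Loci specific to a strain group
#'
#' Loci intact in every member of `group` and absent (not even a
#' pseudogene) in every other strain. With `group` equal to all strains
#' this returns the intact core.
#'
#' @param pam A `panoen_pam`.
#' @param group Character vector of strain ids (non-empty subset).
#' @return Integer vector of pan ids.
#' @export
group_specific_loci <- function(pam, group) {
  .assert(length(group) > 0, "group must be non-empty")
  .assert(all(group %in% pam$strains), "group contains unknown strains")
  m <- pam$m
  ing <- pam$strains %in% group
  hit <- rowSums(m[, ing, drop = FALSE] == 2L) == sum(ing) &
    rowSums(m[, !ing, drop = FALSE] != 0L) == 0L
  as.integer(rownames(m)[hit])
}

#' Partition loci missing from a reference's published annotation
#'
#' Classifies every locus absent from an externally supplied "published"
#' reference annotation id set into exactly one of three classes:
#' `annotation_difference` (this pipeline finds an intact reference
#' member), `reference_pseudogene` (a reference member exists but is a
#' pseudogene), or `strain_specific_insertion` (no reference member at
#' all). Optionally flags loci whose best identity against external
#' (other-genus) proteomes exceeds their best cross-strain identity within
#' the collection, marking candidate recent imports.
#'
#' @param pan A `panoen_pan`.
#' @param pam A `panoen_pam` over the same loci.
#' @param strains Named list of `panoen_strain` objects.
#' @param reference_published_ids Character vector of reference feature ids
#'   making up the published annotation.
#' @param external_proteomes Optional named list of external proteomes.
#' @param reference Reference strain (defaults to the pan object's).
#' @return Tibble `pan_id`, `class`, `closest_external` (logical, `NA`
#'   when no external proteomes given), `external_identity`,
#'   `within_identity`.
#' @export
non_reference_inventory <- function(pan, pam, strains, reference_published_ids,
                                    external_proteomes = list(),
                                    reference = pan$reference) {
  .assert(reference %in% pan$strains, "unknown reference strain")
  loci <- pan$loci |> filter(.data$pan_id %in% as.integer(rownames(pam$m)))
  ref_members <- loci |> filter(.data$strain == reference)
  published <- ref_members |>
    filter(.data$feature_id %in% reference_published_ids) |>
    distinct(.data$pan_id)
  target <- setdiff(unique(loci$pan_id), published$pan_id)
  refstat <- ref_members |>
    group_by(.data$pan_id) |>
    summarise(ref_intact = any(.data$status == "intact"), .groups = "drop")

  res <- tibble(pan_id = sort(target)) |>
    left_join(refstat, by = "pan_id") |>
    mutate(class = case_when(
      !is.na(.data$ref_intact) & .data$ref_intact ~ "annotation_difference",
      !is.na(.data$ref_intact) ~ "reference_pseudogene",
      TRUE ~ "strain_specific_insertion"
    )) |>
    select("pan_id", "class")

  prot <- unlist(lapply(strains, function(s) s$proteome))
  names(prot) <- sub("^[^.]*\\.", "", names(prot))
  rep_map <- tibble(
    pan_id = as.integer(sub("\\|.*$", "", names(pan$representatives))),
    rep_feature = sub("^.*\\|", "", names(pan$representatives)),
    rep_prot = unname(pan$representatives))
  res <- left_join(res, rep_map, by = "pan_id")

  # best within-collection cross-strain identity of the representative
  within <- vapply(seq_len(nrow(res)), function(i) {
    pid <- res$pan_id[i]
    mem <- loci |> filter(.data$pan_id == pid)
    rep_strain <- mem$strain[match(res$rep_feature[i], mem$feature_id)]
    others <- mem$feature_id[mem$strain != rep_strain]
    if (length(others) == 0) return(0)
    max(align_batch(rep(res$rep_prot[i], length(others)),
                    unname(prot[others]))$identity)
  }, 1)

  if (length(external_proteomes) > 0) {
    ext_all <- unlist(unname(external_proteomes))
    reps <- setNames(res$rep_prot, paste0("pan", res$pan_id))
    hits <- best_hits(reps, ext_all, min_identity = 0, min_coverage = 0.5)
    ext <- setNames(hits$identity, hits$query)
    ext_id <- unname(ext[paste0("pan", res$pan_id)])
    ext_id[is.na(ext_id)] <- 0
    res$external_identity <- ext_id
    res$within_identity <- within
    res$closest_external <- ext_id > within
  } else {
    res$external_identity <- NA_real_
    res$within_identity <- within
    res$closest_external <- NA
  }
  res |> select("pan_id", "class", "closest_external",
                "external_identity", "within_identity")
}
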