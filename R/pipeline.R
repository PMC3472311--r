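# End-to-end pipeline driver: chains simulation, orthology, statistics,
# scans and phylogeny with a single seed fanned out to per-stage child
# seeds, writing deterministic TSV/newick outputs plus a run report.

.pipeline_stages <- c("simulate", "orthologs", "stats", "scan", "phage",
                      "cassettes", "completeness", "tree", "report")

#' Run the analysis pipeline
#'
#' Executes pipeline stages in dependency order, writing each stage's
#' outputs under `out_dir`. `steps = "all"` chains every stage; a single
#' stage can be rerun in isolation, in which case its upstream inputs are
#' reloaded from `out_dir` (a missing upstream output raises a
#' stage-dependency error). A single base seed is fanned out to per-stage
#' child seeds by stable hashing of stage names, so reruns with the same
#' configuration and seed are byte-identical (no timestamps are written).
#'
#' @param out_dir Output directory.
#' @param config Either a YAML file path or a nested list. Recognised
#'   sections: `simulate` (fields of [sim_config()]), `orthologs`
#'   (`min_identity`, `min_coverage`, `window`), `scan` (`window`,
#'   `min_run`, `min_identity`), `tree` (`n_reps`,
#'   `min_outgroup_identity`), `completeness` (`role_map` data frame /
#'   file and `groups`), `seed`.
#' @param steps Character vector of stages, or `"all"`.
#' @param seed Base seed; overrides the config seed.
#' @param quiet Suppress progress messages.
#' @return Invisibly, the run report (also written to
#'   `run_report.yaml`).
#' @export
run_pipeline <- function(out_dir, config = NULL, steps = "all",
                         seed = NULL, quiet = FALSE) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  base_seed <- as.integer(seed %||% config$seed %||% 42L)
  if (identical(steps, "all")) steps <- .pipeline_stages
  .assert(all(steps %in% .pipeline_stages),
          paste("unknown stage(s):",
                paste(setdiff(steps, .pipeline_stages), collapse = ", ")))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  state <- new.env(parent = emptyenv())

  need_collection <- function() {
    if (!is.null(state$collection)) return(state$collection)
    cdir <- file.path(out_dir, "collection")
    if (!dir.exists(file.path(cdir, "strains"))) {
      abort("stage dependency error: no collection found; run 'simulate' first")
    }
    state$collection <- .load_collection(cdir)
    state$collection
  }
  need_pan <- function() {
    if (!is.null(state$pan)) return(state$pan)
    f <- file.path(out_dir, "pan_loci.tsv")
    if (!file.exists(f)) {
      abort("stage dependency error: no pan loci found; run 'orthologs' first")
    }
    state$pan <- .load_pan(out_dir)
    state$pan
  }
  need_pam <- function() {
    if (is.null(state$pam)) {
      col <- need_collection()
      state$pam <- build_matrix(need_pan(), col$strains, chromosomal_only = TRUE)
    }
    state$pam
  }
  report <- list(seed = base_seed,
                 version = as.character(utils::packageVersion("panoen")),
                 stages = list())

  for (stage in .pipeline_stages) {
    if (!stage %in% steps && stage != "report") next
    if (stage == "simulate" && "simulate" %in% steps) {
      say("stage: simulate")
      args <- config$simulate %||% list()
      args$seed <- .child_seed(base_seed, "simulate")
      cfg <- do.call(sim_config, args)
      col <- simulate_collection(cfg)
      write_collection(col, file.path(out_dir, "collection"))
      state$collection <- col
      cds <- vapply(col$strains, function(s) sum(s$features$kind == "CDS"), 1L)
      report$stages$simulate <- list(
        n_strains = cfg$n_strains,
        mean_cds_per_strain = round(mean(cds), 1),
        truth_families = length(unique(col$truth$status_map$family)))
    }
    if (stage == "orthologs" && "orthologs" %in% steps) {
      say("stage: orthologs")
      col <- need_collection()
      oc <- config$orthologs %||% list()
      pan <- infer_pan_genome(col$strains,
                              min_identity = oc$min_identity %||% 40,
                              min_coverage = oc$min_coverage %||% 0.5,
                              window = oc$window %||% 5L)
      state$pan <- pan
      readr::write_tsv(pan$loci, file.path(out_dir, "pan_loci.tsv"),
                       progress = FALSE)
      Biostrings::writeXStringSet(
        Biostrings::AAStringSet(pan$representatives),
        file.path(out_dir, "representatives.faa"), width = 80)
      yaml::write_yaml(list(reference = pan$reference, strains = pan$strains,
                            params = pan$params),
                       file.path(out_dir, "pan_meta.yaml"))
      report$stages$orthologs <- list(n_loci = max(pan$loci$pan_id),
                                      reference = pan$reference)
    }
    if (stage == "stats" && "stats" %in% steps) {
      say("stage: stats")
      pam <- need_pam()
      mt <- tidy(pam) |>
        select("pan_id", "strain", "code") |>
        tidyr::pivot_wider(names_from = "strain", values_from = "code")
      readr::write_tsv(mt, file.path(out_dir, "matrix.tsv"), progress = FALSE)
      rf <- rarefaction(pam, seed = .child_seed(base_seed, "stats"))
      readr::write_tsv(rf$curve, file.path(out_dir, "rarefaction.tsv"),
                       progress = FALSE)
      readr::write_tsv(rf$summary, file.path(out_dir, "rarefaction_summary.tsv"),
                       progress = FALSE)
      state$pam <- pam
      core <- sum(rowSums(pam$m == 2L) == ncol(pam$m))
      core_with_pseudo <- sum(rowSums(pam$m >= 1L) == ncol(pam$m))
      report$stages$stats <- list(
        n_pan = nrow(pam$m), n_core_intact = core,
        n_core_with_pseudogenes = core_with_pseudo)
    }
    if (stage == "scan" && "scan" %in% steps) {
      say("stage: scan")
      col <- need_collection()
      if (length(col$donors) == 0) {
        report$stages$scan <- list(skipped = "no donor proteomes")
      } else {
        pan <- need_pan()
        sc <- config$scan %||% list()
        pars <- scan_params(window = sc$window %||% 10L,
                            min_run = sc$min_run %||% 5L,
                            min_identity = sc$min_identity %||% 90)
        alls <- lapply(col$strains, function(s)
          hgt_window_scan(pan, s, col$donors, pars))
        per <- bind_rows(lapply(alls, function(x)
          x$per_locus |> mutate(strain = x$strain)))
        reg <- bind_rows(lapply(alls, function(x)
          x$regions |> mutate(strain = x$strain)))
        readr::write_tsv(per, file.path(out_dir, "hgt_scan.tsv"), progress = FALSE)
        readr::write_tsv(reg, file.path(out_dir, "hgt_regions.tsv"), progress = FALSE)
        report$stages$scan <- list(flagged_regions = nrow(reg))
      }
    }
    if (stage == "phage" && "phage" %in% steps) {
      say("stage: phage")
      col <- need_collection()
      if (length(col$role_refs$int) == 0) {
        report$stages$phage <- list(skipped = "no phage role references")
      } else {
        ph <- bind_rows(lapply(col$strains, detect_phage_elements,
                               role_refs = col$role_refs))
        readr::write_tsv(ph, file.path(out_dir, "phage_elements.tsv"),
                         progress = FALSE)
        report$stages$phage <- list(
          elements = nrow(ph),
          full = sum(ph$class == "full"),
          fragment = sum(ph$class == "fragment"))
      }
    }
    if (stage == "cassettes" && "cassettes" %in% steps) {
      say("stage: cassettes")
      col <- need_collection()
      pan <- need_pan()
      anch <- cassette_anchors(col, pan)
      if (nrow(anch) == 0) {
        report$stages$cassettes <- list(skipped = "no cassette loci")
      } else {
        res <- list()
        for (i in seq_len(nrow(anch))) {
          cg <- genotype_cassette_locus(pan, c(anch$up[i], anch$down[i]))
          res[[i]] <- cg$genotypes |> mutate(locus = anch$locus[i])
        }
        readr::write_tsv(bind_rows(res), file.path(out_dir, "cassettes.tsv"),
                         progress = FALSE)
        report$stages$cassettes <- list(
          loci = nrow(anch),
          variants = vapply(res, function(r)
            length(setdiff(unique(r$variant), "unresolved")), 1L))
      }
    }
    if (stage == "completeness" && "completeness" %in% steps) {
      say("stage: completeness")
      cc <- config$completeness
      if (is.null(cc)) {
        report$stages$completeness <- list(skipped = "no role map configured")
      } else {
        pam <- need_pam()
        role_map <- if (is.character(cc$role_map)) {
          readr::read_tsv(cc$role_map, col_types = "ic", progress = FALSE)
        } else as_tibble(cc$role_map)
        comp <- role_completeness(pam, role_map, cc$groups)
        flat <- comp |>
          mutate(blocked = vapply(.data$blocked_roles, function(b) {
            paste(paste0(b$role, "(", b$reason, ")"), collapse = ";")
          }, "")) |>
          select("strain", "group", "complete", "n_blocked", "blocked")
        readr::write_tsv(flat, file.path(out_dir, "completeness.tsv"),
                         progress = FALSE)
        report$stages$completeness <- list(
          complete = sum(flat$complete), incomplete = sum(!flat$complete))
      }
    }
    if (stage == "tree" && "tree" %in% steps) {
      say("stage: tree")
      col <- need_collection()
      if (length(col$strains) < 3) {
        abort("tree stage needs at least three strains; refusing to run")
      }
      pan <- need_pan()
      pam <- need_pam()
      tc <- config$tree %||% list()
      sel <- select_core_single_copy(
        pan, pam, col$strains, outgroup = col$outgroup,
        min_outgroup_identity = tc$min_outgroup_identity %||% 60)
      phy <- core_gene_tree(pan, col$strains, sel,
                            n_reps = tc$n_reps %||% 100L,
                            seed = .child_seed(base_seed, "tree"))
      ape::write.tree(phy$tree, file.path(out_dir, "tree.nwk"))
      dm <- phy$distances
      readr::write_tsv(as_tibble(dm, rownames = "strain"),
                       file.path(out_dir, "distances.tsv"), progress = FALSE)
      report$stages$tree <- list(
        loci_used = length(sel),
        alignment_columns = nchar(phy$concat$seqs[[1]]))
    }
  }
  # input/output digests for the report
  outs <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                       "run_report.yaml"))
  dig <- tools::md5sum(file.path(out_dir, outs))
  report$digests <- setNames(as.list(unname(dig)), outs)
  yaml::write_yaml(report, file.path(out_dir, "run_report.yaml"))
  invisible(report)
}

#' Cassette anchor loci from simulation truth
#'
#' Maps each simulated cassette locus to the pan ids of its flanking core
#' genes, as required by [genotype_cassette_locus()].
#'
#' @param collection A `panoen_collection` with truth.
#' @param pan A `panoen_pan` inferred from the same collection.
#' @return Tibble `locus`, `up`, `down` (pan ids).
#' @export
cassette_anchors <- function(collection, pan) {
  cfgs <- collection$config$cassette_loci
  if (length(cfgs) == 0) return(tibble(locus = integer(), up = integer(),
                                       down = integer()))
  fam2pan <- collection$truth$ortholog_map |>
    inner_join(pan$loci |> select("feature_id", "pan_id"), by = "feature_id") |>
    count(.data$family, .data$pan_id) |>
    group_by(.data$family) |>
    slice_max(.data$n, n = 1, with_ties = FALSE) |>
    ungroup()
  lookup <- setNames(fam2pan$pan_id, fam2pan$family)
  tibble(
    locus = seq_along(cfgs),
    up = unname(lookup[sprintf("F%04d", vapply(cfgs, function(x) x$anchor, 1))]),
    down = unname(lookup[sprintf("F%04d", vapply(cfgs, function(x) x$anchor + 1, 1))])
  )
}

#' Core-gene concatenated tree
#'
#' Aligns the members of the selected loci (protein sequences), stacks and
#' concatenates them, computes Poisson-corrected distances and builds the
#' neighbor-joining tree with bootstrap support.
#'
#' @param pan A `panoen_pan`.
#' @param strains Named list of `panoen_strain` objects.
#' @param loci Integer vector of pan ids (from
#'   [select_core_single_copy()]).
#' @param n_reps Bootstrap replicates.
#' @param seed Bootstrap seed.
#' @return List with `tree` (`phylo`, node labels = support), `distances`
#'   (matrix), `concat` (`panoen_concat`).
#' @export
core_gene_tree <- function(pan, strains, loci, n_reps = 100L, seed = 1L) {
  .assert(length(loci) > 0, "no loci selected for the tree")
  prot <- unlist(lapply(strains, function(s) s$proteome))
  names(prot) <- sub("^[^.]*\\.", "", names(prot))
  mem <- pan$loci |> filter(.data$pan_id %in% loci)
  alns <- lapply(split(mem, mem$pan_id), function(df) {
    align_family(setNames(unname(prot[df$feature_id]), df$strain))
  })
  cc <- concatenate(alns, taxa = names(strains), molecule = "aa")
  dm <- distance_matrix(cc, correction = "poisson")
  tr <- nj_tree(dm, aln = cc, n_reps = n_reps, seed = seed,
                correction = "poisson")
  list(tree = tr, distances = dm, concat = cc)
}

# reload a written collection (strain files + truth + donors + refs)
.load_collection <- function(dir) {
  sdir <- file.path(dir, "strains")
  fas <- sort(list.files(sdir, pattern = "\\.fna$", full.names = TRUE))
  strains <- list()
  for (f in fas) {
    id <- sub("\\.fna$", "", basename(f))
    strains[[id]] <- load_strain(f, file.path(sdir, paste0(id, ".gff3")), id)
  }
  donors <- list()
  ddir <- file.path(dir, "donors")
  if (dir.exists(ddir)) {
    for (f in sort(list.files(ddir, pattern = "\\.faa$", full.names = TRUE))) {
      aa <- Biostrings::readAAStringSet(f)
      donors[[sub("\\.faa$", "", basename(f))]] <- setNames(as.character(aa), names(aa))
    }
  }
  role_refs <- list(int = character(0), lys = character(0))
  rf <- file.path(dir, "phage_role_refs.faa")
  if (file.exists(rf)) {
    aa <- Biostrings::readAAStringSet(rf)
    v <- setNames(as.character(aa), names(aa))
    role_refs <- list(int = v[grepl("_int$", names(v))],
                      lys = v[grepl("_lys$", names(v))])
  }
  outgroup <- NULL
  ogf <- file.path(dir, "outgroup.faa")
  if (file.exists(ogf)) {
    aa <- Biostrings::readAAStringSet(ogf)
    outgroup <- setNames(as.character(aa), names(aa))
  }
  cfg <- NULL
  cf <- file.path(dir, "config.yaml")
  if (file.exists(cf)) cfg <- yaml::read_yaml(cf)
  truth <- NULL
  if (dir.exists(file.path(dir, "truth"))) truth <- read_truth(file.path(dir, "truth"))
  structure(list(strains = strains, truth = truth, donors = donors,
                 role_refs = role_refs, outgroup = outgroup, config = cfg),
            class = "panoen_collection")
}

# reload a written pan object
.load_pan <- function(out_dir) {
  loci <- readr::read_tsv(file.path(out_dir, "pan_loci.tsv"),
                          col_types = "icccciici", progress = FALSE)
  meta <- yaml::read_yaml(file.path(out_dir, "pan_meta.yaml"))
  aa <- Biostrings::readAAStringSet(file.path(out_dir, "representatives.faa"))
  structure(list(loci = loci,
                 representatives = setNames(as.character(aa), names(aa)),
                 reference = meta$reference,
                 strains = meta$strains,
                 params = meta$params),
            class = "panoen_pan")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
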