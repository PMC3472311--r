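# Shared fixtures, built in code and memoized for the duration of the run.

.fx <- new.env(parent = emptyenv())
fixture <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# a small but fully featured collection exercising every event type
small_cfg <- function(seed = 11) {
  sim_config(
    n_strains = 5, n_core_genes = 150, accessory_pool_size = 40,
    clade_private_genes = 8,
    cassette_loci = list(list(anchor = 40, n_variants = 3, genes_per_variant = 3)),
    n_trna_sites = 2,
    phage_configs = list(
      list(site = 1, strains = 1, class = "full", copy_number = 2),
      list(site = 2, strains = 2, class = "fragment", copy_number = 1)),
    hgt_segments = list(list(donor = "donorA", n_genes = 5, strains = c(1, 2),
                             identity = 95)),
    donor_pool_size = 20, paralog_pairs = 4,
    mean_gene_len = 120, sd_gene_len = 30,
    plasmid_count_probs = c(0.6, 0.4), seed = seed)
}

small_collection <- function() fixture("small_col", function() {
  simulate_collection(small_cfg())
})

small_pan <- function() fixture("small_pan", function() {
  infer_pan_genome(small_collection()$strains)
})

small_pam <- function() fixture("small_pam", function() {
  build_matrix(small_pan(), small_collection()$strains, chromosomal_only = TRUE)
})

# the default-scale study: 14 strains at the full generative defaults.
# Built once; shared by the acceptance tests.
default_study <- function() fixture("default_study", function() {
  col <- simulate_collection(sim_config(seed = 20120803L))
  pan <- infer_pan_genome(col$strains)
  pam <- build_matrix(pan, col$strains, chromosomal_only = TRUE)
  list(col = col, pan = pan, pam = pam)
})

# truth-vs-inferred join for a collection/pan pair
truth_join <- function(col, pan) {
  dplyr::inner_join(col$truth$ortholog_map, pan$loci,
                    by = c("feature_id", "strain"))
}

# cross-strain truth ortholog pair recall
pair_recall <- function(col, pan) {
  j <- truth_join(col, pan)
  tot <- 0L; rec <- 0L
  for (ff in split(j[, c("strain", "pan_id")], j$family)) {
    if (nrow(ff) < 2) next
    prs <- t(combn(nrow(ff), 2))
    prs <- prs[ff$strain[prs[, 1]] != ff$strain[prs[, 2]], , drop = FALSE]
    tot <- tot + nrow(prs)
    rec <- rec + sum(ff$pan_id[prs[, 1]] == ff$pan_id[prs[, 2]])
  }
  rec / tot
}

# random tri-state presence-absence matrix wrapped as a panoen_pam
random_pam <- function(n_loci, n_strains, seed) {
  set.seed(seed)
  repeat {
    m <- matrix(sample(0:2, n_loci * n_strains, replace = TRUE,
                       prob = c(0.25, 0.15, 0.6)),
                nrow = n_loci,
                dimnames = list(as.character(seq_len(n_loci)),
                                sprintf("S%02d", seq_len(n_strains))))
    if (all(rowSums(m) > 0)) break
  }
  structure(list(m = m, strains = colnames(m), chromosomal_only = FALSE),
            class = "panoen_pam")
}

# tiny hand-built strain: one replicon, explicit features
toy_strain <- function(id, seq, feats) {
  genome <- Biostrings::DNAStringSet(setNames(seq, paste0(id, "_chr")))
  feats$replicon <- paste0(id, "_chr")
  feats$product <- feats$product %||% ""
  feats$raw_status <- "called_full"
  structure(list(
    strain_id = id,
    replicons = tibble::tibble(name = paste0(id, "_chr"), length = nchar(seq),
                               circular = FALSE, type = "chromosome"),
    features = feats[, c("feature_id", "replicon", "start", "end", "strand",
                         "kind", "product", "raw_status")],
    genome = genome,
    proteome = panoen:::.translate_features(genome, feats)
  ), class = "panoen_strain")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
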