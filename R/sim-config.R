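#' Configuration for the strain-collection simulator
#'
#' Builds and validates the configuration object consumed by
#' [simulate_collection()]. The defaults emulate a collection of fourteen
#' ~1.8 Mb *Oenococcus oeni*-like genomes with about 1800 full-length genes
#' and ~100 pseudogenes per strain: a large shared core, a strain-variable
#' accessory pool, three variable gene cassettes (7/3/3 variants, echoing
#' exopolysaccharide locus diversity), prophage insertions at six tRNA sites
#' (full elements and fragments, one tandem duplication), one near-identity
#' horizontal-transfer segment from a divergent donor pool, diverged paralog
#' pairs, occasional small plasmids, and a designated divergent basal strain
#' pair carrying private genes.
#'
#' @param n_strains Number of strains (>= 2). Default 14.
#' @param n_core_genes Core gene families present in every strain.
#' @param accessory_pool_size Size of the accessory family pool; each family
#'   is present in each strain independently with
#'   `accessory_presence_prob`.
#' @param accessory_presence_prob Per-strain presence probability of an
#'   accessory family.
#' @param clade_private_genes Families private to the basal strain pair.
#' @param cassette_loci List of cassette locus descriptions, each a list
#'   with `anchor` (core gene index the cassette sits after; the flanking
#'   core genes act as genotyping anchors), `n_variants`, and
#'   `genes_per_variant`.
#' @param mean_gene_len,sd_gene_len,min_gene_len Gene length distribution
#'   in codons.
#' @param substitution_rate_per_branch Expected substitutions per site per
#'   unit branch; branch lengths are drawn as
#'   `rate * (0.3 + Exp(1))` so every branch carries phylogenetic signal.
#' @param basal_branch_factor Length multiplier for the branch separating
#'   the basal pair from the remaining strains.
#' @param pseudogene_rate Probability that a strain's copy of an eligible
#'   gene receives a premature stop codon.
#' @param n_trna_sites Number of tRNA genes placed along the chromosome
#'   (potential phage attachment sites).
#' @param phage_configs List of phage insertion plans: `site` (tRNA index),
#'   `strains` (strain indices), `class` ("full" or "fragment"),
#'   `copy_number` (tandem copies).
#' @param phage_filler_genes Structural genes in a full element besides
#'   *int* and *lys*.
#' @param hgt_segments List of horizontal-transfer plans: `donor` (label),
#'   `n_genes`, `strains` (recipient indices), `identity` (percent amino
#'   acid identity of the transferred copies to the donor proteins).
#' @param donor_pool_size Unrelated background proteins added to each donor
#'   proteome.
#' @param paralog_pairs Number of core families duplicated into a diverged
#'   paralog family.
#' @param paralog_divergence Amino-acid divergence of each paralog copy
#'   from its source family at the ancestor.
#' @param plasmid_count_probs Distribution of plasmid counts per strain:
#'   probabilities for 0, 1, 2, ... plasmids.
#' @param plasmid_genes Genes per plasmid.
#' @param emit_outgroup Emit an outgroup proteome derived from the
#'   ancestral core proteins.
#' @param outgroup_divergence Amino-acid divergence of the outgroup
#'   proteins from the ancestral core proteins.
#' @param seed Integer seed; the seed fully determines every emitted byte.
#' @return A validated `panoen_sim_config` list.
#' @export
sim_config <- function(n_strains = 14,
                       n_core_genes = 1650,
                       accessory_pool_size = 430,
                       accessory_presence_prob = 0.5,
                       clade_private_genes = 25,
                       cassette_loci = list(
                         list(anchor = 200, n_variants = 7, genes_per_variant = 8),
                         list(anchor = 600, n_variants = 3, genes_per_variant = 5),
                         list(anchor = 1000, n_variants = 3, genes_per_variant = 5)
                       ),
                       mean_gene_len = 250,
                       sd_gene_len = 70,
                       min_gene_len = 60,
                       substitution_rate_per_branch = 0.003,
                       basal_branch_factor = 4,
                       pseudogene_rate = 0.05,
                       n_trna_sites = 6,
                       phage_configs = list(
                         list(site = 1, strains = c(1, 2, 3), class = "full", copy_number = 1),
                         list(site = 2, strains = 4, class = "full", copy_number = 2),
                         list(site = 2, strains = 5, class = "full", copy_number = 1),
                         list(site = 3, strains = c(6, 7), class = "full", copy_number = 1),
                         list(site = 4, strains = 8, class = "full", copy_number = 1),
                         list(site = 5, strains = c(9, 10), class = "fragment", copy_number = 1),
                         list(site = 6, strains = 11, class = "fragment", copy_number = 1)
                       ),
                       phage_filler_genes = 8,
                       hgt_segments = list(
                         list(donor = "donorA", n_genes = 8, strains = 1:7, identity = 95)
                       ),
                       donor_pool_size = 150,
                       paralog_pairs = 20,
                       paralog_divergence = 0.35,
                       plasmid_count_probs = c(0.7, 0.3),
                       plasmid_genes = 5,
                       emit_outgroup = TRUE,
                       outgroup_divergence = 0.20,
                       seed = 42L) {
  cfg <- list(
    n_strains = as.integer(n_strains),
    n_core_genes = as.integer(n_core_genes),
    accessory_pool_size = as.integer(accessory_pool_size),
    accessory_presence_prob = accessory_presence_prob,
    clade_private_genes = as.integer(clade_private_genes),
    cassette_loci = cassette_loci,
    mean_gene_len = mean_gene_len,
    sd_gene_len = sd_gene_len,
    min_gene_len = as.integer(min_gene_len),
    substitution_rate_per_branch = substitution_rate_per_branch,
    basal_branch_factor = basal_branch_factor,
    pseudogene_rate = pseudogene_rate,
    n_trna_sites = as.integer(n_trna_sites),
    phage_configs = phage_configs,
    phage_filler_genes = as.integer(phage_filler_genes),
    hgt_segments = hgt_segments,
    donor_pool_size = as.integer(donor_pool_size),
    paralog_pairs = as.integer(paralog_pairs),
    paralog_divergence = paralog_divergence,
    plasmid_count_probs = plasmid_count_probs,
    plasmid_genes = as.integer(plasmid_genes),
    emit_outgroup = isTRUE(emit_outgroup),
    outgroup_divergence = outgroup_divergence,
    seed = as.integer(seed)
  )
  class(cfg) <- "panoen_sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulator configuration
#'
#' Checks rate bounds, strain counts, and that phage/HGT plans reference
#' existing strains and tRNA sites without colliding at one site. Called by
#' [sim_config()]; exported so that configurations read from file can be
#' re-validated.
#'
#' @param cfg A `panoen_sim_config` object (or bare list with its fields).
#' @return `cfg`, invisibly, if valid; otherwise an error.
#' @export
validate_sim_config <- function(cfg) {
  .assert(cfg$n_strains >= 2, "n_strains must be >= 2")
  .assert(cfg$n_core_genes >= 1, "n_core_genes must be >= 1")
  rates <- c(cfg$accessory_presence_prob, cfg$pseudogene_rate,
             cfg$paralog_divergence, cfg$outgroup_divergence)
  .assert(all(rates >= 0 & rates <= 1), "all rates must lie in [0, 1]")
  .assert(cfg$substitution_rate_per_branch >= 0,
          "substitution rate must be non-negative")
  .assert(abs(sum(cfg$plasmid_count_probs) - 1) < 1e-8,
          "plasmid_count_probs must sum to 1")
  .assert(cfg$min_gene_len >= 10, "min_gene_len must be >= 10 codons")
  for (cl in cfg$cassette_loci) {
    .assert(all(c("anchor", "n_variants", "genes_per_variant") %in% names(cl)),
            "cassette locus needs anchor, n_variants, genes_per_variant")
    .assert(cl$anchor >= 2 && cl$anchor < cfg$n_core_genes - 1,
            "cassette anchor out of core range")
    .assert(cl$n_variants >= 1 && cl$n_variants <= cfg$n_strains,
            "cassette n_variants must be between 1 and n_strains")
  }
  anchors <- vapply(cfg$cassette_loci, function(x) x$anchor, numeric(1))
  .assert(!anyDuplicated(anchors), "cassette anchors must be distinct")
  seen <- character()
  for (pc in cfg$phage_configs) {
    .assert(all(pc$strains >= 1 & pc$strains <= cfg$n_strains),
            "phage config references a nonexistent strain")
    .assert(pc$site >= 1 && pc$site <= cfg$n_trna_sites,
            "phage config references a nonexistent tRNA site")
    .assert(pc$class %in% c("full", "fragment"), "phage class must be full or fragment")
    .assert(pc$copy_number >= 1, "phage copy_number must be >= 1")
    key <- paste(pc$site, pc$strains)
    .assert(!any(key %in% seen),
            "overlapping phage insertions configured at one site in one strain")
    seen <- c(seen, key)
  }
  for (hs in cfg$hgt_segments) {
    .assert(all(hs$strains >= 1 & hs$strains <= cfg$n_strains),
            "HGT segment references a nonexistent strain")
    .assert(hs$identity > 0 && hs$identity <= 100,
            "donor identity must lie in (0, 100]")
    .assert(hs$n_genes >= 1, "HGT segment needs at least one gene")
  }
  invisible(cfg)
}
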