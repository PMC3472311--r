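# Simulator: determinism, conservation, pseudogene/stop invariants,
# divergence structure, configuration validation, truth serialization.

test_that("identical configurations give byte-identical output", {
  c1 <- simulate_collection(small_cfg())
  c2 <- simulate_collection(small_cfg())
  expect_identical(lapply(c1$strains, function(s) as.character(s$genome)),
                   lapply(c2$strains, function(s) as.character(s$genome)))
  expect_identical(c1$truth$ortholog_map, c2$truth$ortholog_map)
  expect_identical(ape::write.tree(c1$truth$tree), ape::write.tree(c2$truth$tree))
  expect_identical(c1$donors, c2$donors)
})

test_that("zero substitutions and no events give identical genomes with core = pan", {
  cfg <- sim_config(n_strains = 3, n_core_genes = 100, accessory_pool_size = 0,
                    clade_private_genes = 0, cassette_loci = list(),
                    substitution_rate_per_branch = 0, pseudogene_rate = 0,
                    n_trna_sites = 0, phage_configs = list(),
                    hgt_segments = list(), paralog_pairs = 0,
                    plasmid_count_probs = c(1), emit_outgroup = FALSE, seed = 3)
  col <- simulate_collection(cfg)
  g <- lapply(col$strains, function(s) as.character(s$genome[[1]]))
  expect_identical(g[[1]], g[[2]])
  expect_identical(g[[2]], g[[3]])
  sm <- col$truth$status_map
  expect_true(all(sm$status == "intact"))
  expect_equal(length(unique(sm$family)), 100L)
})

test_that("per-strain CDS counts reconcile with the truth status map", {
  col <- small_collection()
  om <- col$truth$ortholog_map
  sm <- col$truth$status_map
  for (id in names(col$strains)) {
    n_feat <- sum(col$strains[[id]]$features$kind == "CDS")
    expect_equal(nrow(om[om$strain == id, ]), n_feat)
    # distinct families present = status-map non-absent count
    expect_equal(length(unique(om$family[om$strain == id])),
                 sum(sm$strain == id & sm$status != "absent"))
  }
})

test_that("pseudogenes have an internal stop and intact genes none", {
  col <- small_collection()
  om <- col$truth$ortholog_map
  for (id in c("S01", "S04")) {
    prot <- col$strains[[id]]$proteome
    sm <- col$truth$status_map |> dplyr::filter(strain == id)
    fam_status <- setNames(sm$status, sm$family)
    st <- fam_status[om$family[match(names(prot), om$feature_id)]]
    has_stop <- grepl("*", prot, fixed = TRUE)
    expect_true(all(has_stop[st == "pseudogene"]))
    expect_false(any(has_stop[st == "intact"]))
  }
})

test_that("HGT imports translate at the configured donor identity", {
  col <- small_collection() # one 5-gene segment at 95% into S01 and S02
  hgt <- col$truth$hgt
  expect_equal(nrow(hgt), 2L)
  donor <- col$donors$donorA
  for (i in seq_len(nrow(hgt))) {
    st <- col$strains[[hgt$strain[i]]]
    genes <- st$features |>
      dplyr::filter(kind == "CDS", replicon == hgt$replicon[i],
                    start >= hgt$start[i], end <= hgt$end[i])
    expect_equal(nrow(genes), 5L)
    for (fid in genes$feature_id) {
      hits <- best_hits(st$proteome[fid], donor, min_identity = 0)
      expect_gte(hits$identity[1], 93)
      expect_lte(hits$identity[1], 97)
    }
  }
})

test_that("pairwise divergence increases with path length on the strain tree", {
  col <- small_collection()
  tree <- col$truth$tree
  # nucleotide divergence over shared core genes
  core_ids <- col$truth$families$family[col$truth$families$class == "core"]
  seqs <- lapply(col$strains, function(s) {
    cds <- s$features |> dplyr::filter(kind == "CDS")
    om <- col$truth$ortholog_map
    fam <- om$family[match(cds$feature_id, om$feature_id)]
    keep <- cds$feature_id[fam %in% core_ids[1:80]]
    paste(vapply(keep, function(fid) {
      r <- cds[cds$feature_id == fid, ]
      s0 <- as.character(Biostrings::subseq(s$genome[[r$replicon]],
                                            r$start + 1, r$end))
      if (r$strand == "-") s0 <- panoen:::.revcomp(s0)
      s0
    }, ""), collapse = "")
  })
  dv <- c(); pl <- c()
  pd <- ape::cophenetic.phylo(tree)
  ids <- names(col$strains)
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (j <= i) next
    a <- strsplit(seqs[[ids[i]]], "")[[1]]
    b <- strsplit(seqs[[ids[j]]], "")[[1]]
    n <- min(length(a), length(b))
    dv <- c(dv, mean(a[1:n] != b[1:n]))
    pl <- c(pl, pd[ids[i], ids[j]])
  }
  expect_gt(cor(dv, pl, method = "spearman"), 0.9)
})

test_that("misconfigured phage and HGT plans are rejected", {
  expect_error(sim_config(n_strains = 4, phage_configs = list(
    list(site = 1, strains = 9, class = "full", copy_number = 1)),
    cassette_loci = list(), hgt_segments = list()),
    "nonexistent strain")
  expect_error(sim_config(n_strains = 4, n_trna_sites = 2, phage_configs = list(
    list(site = 5, strains = 1, class = "full", copy_number = 1)),
    cassette_loci = list(), hgt_segments = list()),
    "nonexistent tRNA site")
  expect_error(sim_config(n_strains = 4, n_trna_sites = 2, phage_configs = list(
    list(site = 1, strains = 1, class = "full", copy_number = 1),
    list(site = 1, strains = 1, class = "fragment", copy_number = 1)),
    cassette_loci = list(), hgt_segments = list()),
    "overlapping")
  expect_error(sim_config(n_strains = 4, cassette_loci = list(),
    phage_configs = list(),
    hgt_segments = list(list(donor = "d", n_genes = 3, strains = 1,
                             identity = 150))),
    "identity")
  expect_error(sim_config(n_strains = 1), "n_strains")
})

test_that("truth tables round-trip through write_truth/read_truth", {
  col <- small_collection()
  d <- file.path(tempdir(), "truth_rt")
  write_truth(col$truth, d)
  back <- read_truth(d)
  for (nm in c("ortholog_map", "status_map", "hgt", "phage", "cassette",
               "families")) {
    expect_equal(as.data.frame(back[[nm]]), as.data.frame(col$truth[[nm]]),
                 info = nm)
  }
  expect_true(ape::all.equal.phylo(back$tree, col$truth$tree,
                                   use.edge.length = TRUE, tolerance = 1e-8))
  # ortholog map rows equal total emitted CDS
  expect_equal(nrow(back$ortholog_map),
               sum(vapply(col$strains, function(s)
                 sum(s$features$kind == "CDS"), 1L)))
})

test_that("an empty truth serializes to valid header-only files", {
  empty <- structure(list(
    ortholog_map = tibble::tibble(feature_id = character(),
                                  strain = character(), family = character()),
    status_map = tibble::tibble(family = character(), strain = character(),
                                status = character()),
    hgt = tibble::tibble(strain = character(), replicon = character(),
                         start = integer(), end = integer(), donor = character()),
    phage = tibble::tibble(strain = character(), trna = character(),
                           replicon = character(), start = integer(),
                           end = integer(), class = character(),
                           copy_number = integer()),
    cassette = tibble::tibble(locus = integer(), strain = character(),
                              variant = integer()),
    families = tibble::tibble(family = character(), class = character(),
                              len = integer()),
    tree = ape::read.tree(text = "(A:1,B:1);")
  ), class = "panoen_truth")
  d <- file.path(tempdir(), "truth_empty")
  write_truth(empty, d)
  for (f in c("ortholog_map.tsv", "hgt.tsv", "phage.tsv", "cassette.tsv")) {
    expect_equal(length(readLines(file.path(d, f))), 1L, info = f)
  }
})

test_that("default-sized configuration hits the target gene census", {
  # quick structural check on the small fixture; the default-scale census
  # is asserted by the acceptance suite
  col <- small_collection()
  cds <- vapply(col$strains, function(s) sum(s$features$kind == "CDS"), 1L)
  expect_true(all(cds > 150))
  sm <- col$truth$status_map
  pse <- sum(sm$status == "pseudogene") / sum(sm$status != "absent")
  expect_gt(pse, 0.02)
  expect_lt(pse, 0.09)
})
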