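# Presence-absence matrix, rarefaction, group-specific loci, and the
# non-reference inventory.

test_that("the matrix reproduces the truth status map", {
  col <- small_collection()
  pan <- small_pan()
  pam <- build_matrix(pan, col$strains, chromosomal_only = FALSE)
  long <- tidy(pam)
  j <- truth_join(col, pan)
  fam_of <- j |> dplyr::distinct(pan_id, family) |>
    dplyr::count(pan_id, family) |>
    dplyr::group_by(pan_id) |> dplyr::slice_max(n, n = 1, with_ties = FALSE)
  merged <- long |>
    dplyr::inner_join(fam_of |> dplyr::select(pan_id, family), by = "pan_id") |>
    dplyr::inner_join(col$truth$status_map, by = c("family", "strain"),
                      suffix = c("_called", "_truth"))
  # excluding tandem-duplicate extra loci, calls match truth exactly
  dup_loci <- j |> dplyr::count(family, pan_id) |>
    dplyr::group_by(family) |> dplyr::filter(dplyr::n() > 1) |> dplyr::pull(pan_id)
  clean <- merged |> dplyr::filter(!pan_id %in% dup_loci)
  expect_gt(nrow(clean), 0)
  expect_true(all(clean$status_called == clean$status_truth))
})

test_that("the chromosomal-only flag removes exactly the plasmid loci", {
  col <- small_collection()
  pan <- small_pan()
  all_m <- build_matrix(pan, col$strains, chromosomal_only = FALSE)
  chr_m <- build_matrix(pan, col$strains, chromosomal_only = TRUE)
  plasmid_fams <- col$truth$families$family[col$truth$families$class == "plasmid"]
  realized <- intersect(plasmid_fams, col$truth$ortholog_map$family)
  j <- truth_join(col, pan)
  plasmid_loci <- unique(j$pan_id[j$family %in% realized])
  expect_equal(nrow(all_m$m) - nrow(chr_m$m), length(plasmid_loci))
  expect_false(any(as.character(plasmid_loci) %in% rownames(chr_m$m)))
})

test_that("exact rarefaction equals brute-force enumeration on random matrices", {
  for (seed in 1:6) {
    pam <- random_pam(50, 8, seed)
    rf <- rarefaction(pam)
    for (x in c(1, 3, 5, 8)) {
      ora <- oracle_rarefaction(pam$m, x)
      got <- rf$curve |> dplyr::filter(x == !!x)
      expect_equal(sort(got$core), sort(ora$core), info = paste(seed, x))
      expect_equal(sort(got$pan), sort(ora$pan), info = paste(seed, x))
    }
  }
})

test_that("a two-strain hand case gives core 1, pan 2 at x = 2", {
  m <- matrix(c(2L, 2L, 2L, 0L), nrow = 2, byrow = TRUE,
              dimnames = list(c("1", "2"), c("A", "B")))
  pam <- structure(list(m = m, strains = c("A", "B"), chromosomal_only = FALSE),
                   class = "panoen_pam")
  rf <- rarefaction(pam)
  at2 <- rf$curve |> dplyr::filter(x == 2)
  expect_equal(at2$core, 1L)
  expect_equal(at2$pan, 2L)
})

test_that("an all-intact matrix keeps core = pan = loci at every x", {
  m <- matrix(2L, nrow = 10, ncol = 4,
              dimnames = list(as.character(1:10), sprintf("S%d", 1:4)))
  pam <- structure(list(m = m, strains = colnames(m), chromosomal_only = FALSE),
                   class = "panoen_pam")
  rf <- rarefaction(pam)
  expect_true(all(rf$curve$core == 10L))
  expect_true(all(rf$curve$pan == 10L))
})

test_that("rarefaction means are monotone and meet the full-collection values", {
  pam <- small_pam()
  rf <- rarefaction(pam)
  s <- rf$summary
  expect_true(all(diff(s$mean_core) <= 1e-9))
  expect_true(all(diff(s$mean_pan) >= -1e-9))
  S <- ncol(pam$m)
  expect_equal(s$mean_core[S], sum(rowSums(pam$m == 2L) == S))
  expect_equal(s$mean_pan[S], nrow(pam$m))
  # x = 1: core equals pan within each subset under matching conventions
  rf1 <- rarefaction(pam, pseudogene_core = "present")
  one <- rf1$curve |> dplyr::filter(x == 1)
  expect_equal(one$core, one$pan)
})

test_that("sampled rarefaction agrees with exact enumeration within 3 SE", {
  pam <- random_pam(60, 9, 33)
  exact <- rarefaction(pam)
  sampled <- rarefaction(pam, exact_limit = 1L, n_samples = 150L, seed = 4L)
  for (x in c(3, 5, 7)) {
    e <- exact$summary |> dplyr::filter(x == !!x)
    sca <- sampled$curve |> dplyr::filter(x == !!x)
    se <- stats::sd(sca$core) / sqrt(nrow(sca))
    expect_lt(abs(mean(sca$core) - e$mean_core), max(3 * se, 1e-9))
  }
})

test_that("group-specific loci recover clade-private genes and the core", {
  col <- small_collection()
  pan <- small_pan()
  pam <- small_pam()
  # the basal pair carries the clade-private families
  n <- length(col$strains)
  basal <- sprintf("S%02d", c(n - 1, n))
  got <- group_specific_loci(pam, basal)
  j <- truth_join(col, pan)
  priv <- col$truth$families$family[col$truth$families$class == "clade_private"]
  priv_loci <- unique(j$pan_id[j$family %in% priv])
  # private loci that are intact in both carriers must be found
  m <- pam$m[as.character(intersect(priv_loci, as.integer(rownames(pam$m)))), basal,
             drop = FALSE]
  expect_true(all(rownames(m)[rowSums(m == 2L) == 2] %in% as.character(got)))
  # and everything found must be absent outside the group
  others <- setdiff(pam$strains, basal)
  expect_true(all(pam$m[as.character(got), others] == 0L))
  # whole-collection group returns the intact core
  core <- group_specific_loci(pam, pam$strains)
  expect_equal(length(core), sum(rowSums(pam$m == 2L) == ncol(pam$m)))
  expect_error(group_specific_loci(pam, character(0)), "non-empty")
})

test_that("the non-reference inventory partitions withheld loci correctly", {
  col <- small_collection()
  pan <- small_pan()
  pam <- small_pam()
  loci <- pan$loci |> dplyr::filter(pan_id %in% as.integer(rownames(pam$m)))
  ref <- pan$reference
  refm <- loci |> dplyr::filter(strain == ref)
  # construct a published id set that withholds three classes of loci
  intact_ref <- refm |> dplyr::filter(status == "intact") |> dplyr::pull(pan_id)
  pseudo_ref <- refm |> dplyr::filter(status == "pseudogene") |> dplyr::pull(pan_id)
  drop_intact <- head(sort(intact_ref), 10)
  drop_pseudo <- head(sort(pseudo_ref), 4)
  published <- refm |>
    dplyr::filter(!pan_id %in% c(drop_intact, drop_pseudo)) |>
    dplyr::pull(feature_id)
  inv <- non_reference_inventory(pan, pam, col$strains, published)
  expect_equal(sum(inv$class == "annotation_difference"), length(drop_intact))
  expect_equal(sum(inv$class == "reference_pseudogene"), length(drop_pseudo))
  absent_ref <- setdiff(unique(loci$pan_id), refm$pan_id)
  expect_equal(sum(inv$class == "strain_specific_insertion"), length(absent_ref))
  # classes are disjoint and exhaustive over the non-published loci
  expect_equal(sort(inv$pan_id),
               sort(setdiff(unique(loci$pan_id),
                            refm$pan_id[refm$feature_id %in% published])))
  expect_false(any(duplicated(inv$pan_id)))
})

test_that("external proteomes flag closer-than-collection loci", {
  col <- small_collection()
  pan <- small_pan()
  pam <- small_pam()
  # withhold the HGT loci from the published set; the donor proteome is the
  # external set. Their members are identical across carrier strains, so
  # within-identity (100) beats donor identity (95): not flagged.
  j <- truth_join(col, pan)
  hgt_loci <- unique(j$pan_id[grepl("^H\\d", j$family)])
  ref <- pan$reference
  refm <- pan$loci |> dplyr::filter(strain == ref)
  published <- refm$feature_id
  inv <- non_reference_inventory(pan, pam, col$strains, published,
                                 external_proteomes = col$donors)
  hit <- inv |> dplyr::filter(pan_id %in% hgt_loci)
  expect_true(all(hit$external_identity > 90))
  expect_true(all(hit$within_identity == 100))
  expect_false(any(hit$closest_external))
  # a single-strain locus whose best match is external gets flagged
  singles <- inv |> dplyr::filter(within_identity == 0, external_identity > 0)
  if (nrow(singles) > 0) expect_true(all(singles$closest_external))
})
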