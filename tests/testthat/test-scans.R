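# HGT windows, phage elements, cassette genotypes, completeness, fusions.

test_that("run flagging is conjunctive with the >= min_run boundary", {
  id <- rep(0, 30)
  id[10:14] <- 95                      # run of exactly 5
  r5 <- flag_identity_runs(id, 90, 5)
  expect_equal(nrow(r5), 1L)
  expect_equal(c(r5$start, r5$end), c(10L, 14L))
  id4 <- rep(0, 30); id4[10:13] <- 95  # run of 4: below threshold
  expect_equal(nrow(flag_identity_runs(id4, 90, 5)), 0L)
  # a sub-threshold locus splits a long run into two maximal runs
  idg <- rep(0, 30); idg[10:20] <- 95; idg[15] <- 80
  runs <- flag_identity_runs(idg, 90, 5)
  expect_equal(nrow(runs), 2L)
  expect_equal(runs$start, c(10L, 16L))
  expect_equal(runs$end, c(14L, 20L))
  # shortening one side below min_run drops that side only
  idg[14] <- 80
  runs2 <- flag_identity_runs(idg, 90, 5)
  expect_equal(nrow(runs2), 1L)
  expect_equal(c(runs2$start, runs2$end), c(16L, 20L))
})

test_that("the HGT scan flags the implanted donor segment and nothing else", {
  col <- small_collection()  # 5-gene donorA segment at 95% in S01, S02
  pan <- small_pan()
  for (st in c("S01", "S02")) {
    sc <- hgt_window_scan(pan, col$strains[[st]], col$donors)
    expect_equal(nrow(sc$regions), 1L)
    tr <- col$truth$hgt |> dplyr::filter(strain == st)
    expect_equal(sc$regions$start, tr$start)
    expect_equal(sc$regions$end, tr$end)
    expect_equal(sc$regions$n_loci, 5L)
  }
  # a non-recipient strain has no flagged regions
  sc3 <- hgt_window_scan(pan, col$strains$S03, col$donors)
  expect_equal(nrow(sc3$regions), 0L)
  # per-locus identities are zero without donor hits, and window means exist
  expect_true(all(sc3$per_locus$identity < 90))
  expect_gt(nrow(sc3$windows), 0)
})

test_that("an unreachable identity threshold flags nothing", {
  col <- small_collection()
  pan <- small_pan()
  sc <- hgt_window_scan(pan, col$strains$S01, col$donors,
                        scan_params(min_identity = 100))
  expect_equal(nrow(sc$regions), 0L)
})

test_that("an empty donor set is rejected", {
  col <- small_collection()
  pan <- small_pan()
  expect_error(hgt_window_scan(pan, col$strains$S01, list()), "non-empty")
})

test_that("phage detection reproduces class, span and copy number from truth", {
  col <- small_collection()
  ph <- dplyr::bind_rows(lapply(col$strains, detect_phage_elements,
                                role_refs = col$role_refs))
  tr <- col$truth$phage
  expect_equal(nrow(ph), nrow(tr))
  m <- dplyr::inner_join(ph, tr, by = c("strain", "replicon"),
                         suffix = c("_got", "_truth"))
  expect_equal(nrow(m), nrow(tr))
  expect_equal(m$class_got, m$class_truth)
  expect_equal(m$copy_number_got, m$copy_number_truth)
  expect_equal(m$start_got, m$start_truth)
  expect_equal(m$end_got, m$end_truth)
  expect_equal(m$trna_name, m$trna)
})

test_that("a genome without att repeats yields no phage elements", {
  col <- small_collection()
  ph <- detect_phage_elements(col$strains$S05, col$role_refs)
  expect_equal(nrow(ph), 0L)
})

test_that("unknown tRNA ids are skipped with a warning", {
  col <- small_collection()
  expect_warning(
    detect_phage_elements(col$strains$S01, col$role_refs,
                          trna_ids = c("nope_01")),
    "skipped")
})

test_that("cassette genotypes recover the programmed variants and members", {
  col <- small_collection()
  pan <- small_pan()
  anch <- cassette_anchors(col, pan)
  cg <- genotype_cassette_locus(pan, c(anch$up[1], anch$down[1]))
  truth <- col$truth$cassette |> dplyr::filter(locus == 1)
  expect_equal(nrow(cg$variants), length(unique(truth$variant)))
  # detected variant labels partition strains identically to the truth
  j <- dplyr::inner_join(cg$genotypes, truth, by = "strain")
  tab <- table(j$variant.x, j$variant.y)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  expect_false(any(is.na(cg$genotypes$signature)))
})

test_that("identical cassette content collapses to one variant", {
  pan <- small_pan()
  # anchors directly adjacent in every strain: empty content, one variant
  core_all <- pan$loci |> dplyr::count(pan_id) |>
    dplyr::filter(n == length(pan$strains)) |> dplyr::pull(pan_id)
  # find two core loci adjacent in every strain (no content between)
  ord <- pan$loci |>
    dplyr::filter(pan_id %in% core_all) |>
    dplyr::arrange(strain, replicon, cds_order)
  found <- NULL
  cand <- ord |> dplyr::filter(strain == pan$strains[1])
  for (i in seq_len(nrow(cand) - 1)) {
    a <- cand$pan_id[i]; b <- cand$pan_id[i + 1]
    gap <- pan$loci |>
      dplyr::filter(pan_id %in% c(a, b)) |>
      dplyr::group_by(strain) |>
      dplyr::summarise(d = abs(diff(cds_order)))
    if (all(gap$d == 1)) { found <- c(a, b); break }
  }
  expect_false(is.null(found))
  cg <- genotype_cassette_locus(pan, found)
  expect_equal(nrow(cg$variants), 1L)
  expect_equal(cg$genotypes$n_genes, rep(0L, length(pan$strains)))
})

test_that("role completeness reports pseudogenization and absence blocks", {
  m <- matrix(2L, nrow = 3, ncol = 3,
              dimnames = list(c("1", "2", "3"), c("A", "B", "C")))
  m["2", "B"] <- 1L  # enzyme 2 pseudogenized in B
  m["3", "C"] <- 0L  # enzyme 3 absent in C
  pam <- structure(list(m = m, strains = colnames(m), chromosomal_only = FALSE),
                   class = "panoen_pam")
  role_map <- tibble::tibble(pan_id = 1:3, role = c("e1", "e2", "e3"))
  comp <- role_completeness(pam, role_map,
                            groups = list(pathway = c("e1", "e2", "e3")))
  expect_equal(comp$complete, c(TRUE, FALSE, FALSE))
  bB <- comp$blocked_roles[[2]]
  expect_equal(bB$role, "e2")
  expect_equal(bB$reason, "pseudogenization")
  bC <- comp$blocked_roles[[3]]
  expect_equal(bC$role, "e3")
  expect_equal(bC$reason, "absence")
  # a role present only as a pseudogene everywhere blocks every strain
  m2 <- m; m2["1", ] <- 1L
  pam2 <- structure(list(m = m2, strains = colnames(m2),
                         chromosomal_only = FALSE), class = "panoen_pam")
  comp2 <- role_completeness(pam2, role_map,
                             groups = list(pathway = c("e1")))
  expect_false(any(comp2$complete))
  expect_error(role_completeness(pam, role_map,
                                 groups = list(p = c("e1", "zz"))),
               "absent from role_map")
})

test_that("a pathway block in simulated data traces to a truth pseudogene", {
  col <- small_collection()
  pan <- small_pan()
  pam <- small_pam()
  # pick three core families, one pseudogenized in exactly one strain
  j <- truth_join(col, pan)
  sm <- col$truth$status_map
  one_pseudo <- sm |>
    dplyr::filter(status == "pseudogene", grepl("^F", family)) |>
    dplyr::count(family) |> dplyr::filter(n == 1)
  fam_sel <- one_pseudo$family[1]
  blocked_strain <- sm$strain[sm$family == fam_sel & sm$status == "pseudogene"]
  ok_fams <- sm |> dplyr::group_by(family) |>
    dplyr::summarise(allok = all(status == "intact")) |>
    dplyr::filter(allok, grepl("^F", family)) |> dplyr::pull(family)
  fams <- c(fam_sel, ok_fams[1:2])
  ids <- vapply(fams, function(f) {
    unique(j$pan_id[j$family == f])[1]
  }, 1L)
  role_map <- tibble::tibble(pan_id = as.integer(ids),
                             role = c("enzA", "enzB", "enzC"))
  comp <- role_completeness(pam, role_map,
                            groups = list(path = c("enzA", "enzB", "enzC")))
  bad <- comp |> dplyr::filter(!complete)
  expect_equal(bad$strain, blocked_strain)
  expect_equal(bad$blocked_roles[[1]]$reason, "pseudogenization")
})

test_that("fusion detection flags engineered fusions with a sane breakpoint", {
  set.seed(21)
  fa <- random_peptide(120)
  fb <- random_peptide(140)
  reps <- c(famA = fa, famB = fb, famC = random_peptide(100))
  fusion <- paste0(fa, fb)
  res <- detect_fusions(c(fus = fusion, plain = fa,
                          doubled = paste0(fa, fa)), reps)
  expect_true("fus" %in% res$protein)
  r <- res[res$protein == "fus", ]
  expect_setequal(c(r$family_n, r$family_c), c("famA", "famB"))
  expect_lt(abs(r$breakpoint - 120), 0.1 * nchar(fusion) + 1)
  # a full-length single-family protein is not flagged
  expect_false("plain" %in% res$protein)
  # two hits to the same family do not qualify
  expect_false("doubled" %in% res$protein)
})
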