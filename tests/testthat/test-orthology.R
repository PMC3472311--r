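# Ortholog clustering, synteny conflict resolution, locus numbering and
# member status classification.

# build a minimal strain with genes placed in order; proteins supplied
fake_strain <- function(id, genes, proteins) {
  n <- length(genes)
  tibble::tibble(
    feature_id = genes,
    replicon = paste0(id, "_chr"),
    start = (seq_len(n) - 1L) * 1000L,
    end = (seq_len(n) - 1L) * 1000L + 900L,
    strand = "+",
    kind = "CDS",
    product = "",
    raw_status = "called_full"
  ) -> feats
  structure(list(strain_id = id,
                 replicons = tibble::tibble(name = paste0(id, "_chr"),
                                            length = n * 1000L,
                                            circular = FALSE,
                                            type = "chromosome"),
                 features = feats, genome = NULL,
                 proteome = setNames(proteins, genes)),
            class = "panoen_strain")
}

test_that("a perfect RBH triangle yields one cluster per gene, none conflicted", {
  members <- tibble::tibble(
    feature_id = c(paste0("A_", 1:4), paste0("B_", 1:4), paste0("C_", 1:4)),
    strain = rep(c("A", "B", "C"), each = 4))
  edges <- dplyr::bind_rows(lapply(1:4, function(i) tibble::tibble(
    a = c(paste0("A_", i), paste0("A_", i), paste0("B_", i)),
    b = c(paste0("B_", i), paste0("C_", i), paste0("C_", i)))))
  cl <- cluster_rbh(edges, members)
  expect_equal(dplyr::n_distinct(cl$cluster), 4L)
  expect_false(any(cl$conflicted))
})

test_that("a within-strain duplicate marks its component conflicted", {
  members <- tibble::tibble(
    feature_id = c("A_1", "A_1dup", "B_1"),
    strain = c("A", "A", "B"))
  edges <- tibble::tibble(a = c("A_1", "A_1dup"), b = c("B_1", "B_1"))
  cl <- cluster_rbh(edges, members)
  expect_true(all(cl$conflicted))
})

test_that("synteny resolves a tandem duplicate toward the agreeing copy", {
  set.seed(9)
  fams <- replicate(11, random_peptide(40))
  mk <- function(id, extra = FALSE) {
    genes <- sprintf("%s_%02d", id, 1:11)
    prots <- fams
    if (extra) {
      # a second copy of family 6 at the far end, in a private neighborhood
      genes <- c(genes, sprintf("%s_x%02d", id, 1:5), sprintf("%s_dup", id))
      prots <- c(prots, replicate(5, random_peptide(40)), fams[6])
    }
    fake_strain(id, genes, prots)
  }
  strains <- list(A = mk("A", extra = TRUE), B = mk("B"), C = mk("C"))
  members <- panoen:::.cds_table(strains)[, c("feature_id", "strain")]
  edges <- dplyr::bind_rows(lapply(1:11, function(i) tibble::tibble(
    a = c(sprintf("A_%02d", i), sprintf("A_%02d", i), sprintf("B_%02d", i)),
    b = c(sprintf("B_%02d", i), sprintf("C_%02d", i), sprintf("C_%02d", i)))))
  # the duplicate is RBH-tied into the family-6 component
  edges <- dplyr::bind_rows(edges, tibble::tibble(a = "A_dup", b = "B_06"))
  cl <- cluster_rbh(edges, members)
  f6 <- cl$cluster[cl$feature_id == "A_06"]
  expect_true(cl$conflicted[cl$feature_id == "A_06"][1])
  ctx <- build_synteny_context(strains, window = 5)
  ref <- refine_with_synteny(cl, ctx, strains)
  # partition property: every feature exactly once
  expect_equal(sort(ref$feature_id), sort(members$feature_id))
  l_a06 <- ref$locus[ref$feature_id == "A_06"]
  expect_equal(ref$locus[ref$feature_id == "B_06"], l_a06)
  expect_equal(ref$locus[ref$feature_id == "C_06"], l_a06)
  expect_false(ref$locus[ref$feature_id == "A_dup"] == l_a06)
  # each strain contributes at most one member per locus
  per <- ref |> dplyr::count(locus, strain)
  expect_true(all(per$n == 1L))
})

test_that("without conflicts, refinement reproduces the input clusters", {
  col <- small_collection()
  strains <- col$strains[c("S02", "S03")]
  members <- panoen:::.cds_table(strains)[, c("feature_id", "strain")]
  rb <- reciprocal_best_hits(strains$S02$proteome, strains$S03$proteome,
                             min_shared = 6L)
  cl <- cluster_rbh(rb |> dplyr::select(a, b), members)
  ctx <- build_synteny_context(strains)
  ref <- refine_with_synteny(cl, ctx, strains)
  clean <- cl |> dplyr::filter(!conflicted)
  j <- dplyr::inner_join(clean, ref, by = c("feature_id", "strain"))
  # cluster -> locus must be a bijection on unconflicted components
  expect_true(all(tapply(j$locus, j$cluster, dplyr::n_distinct) == 1L))
  expect_true(all(tapply(j$cluster, j$locus, dplyr::n_distinct) == 1L))
})

test_that("every feature belongs to exactly one locus across the collection", {
  col <- small_collection()
  pan <- small_pan()
  n_cds <- sum(vapply(col$strains, function(s) sum(s$features$kind == "CDS"), 1L))
  expect_equal(nrow(pan$loci), n_cds)
  expect_false(any(duplicated(pan$loci$feature_id)))
  expect_setequal(seq_len(max(pan$loci$pan_id)), unique(pan$loci$pan_id))
})

test_that("reference loci are numbered in reference genome order", {
  pan <- small_pan()
  ref <- pan$loci |>
    dplyr::filter(strain == pan$reference) |>
    dplyr::arrange(replicon, start) |>
    dplyr::distinct(pan_id, .keep_all = TRUE)
  chrom <- ref |> dplyr::filter(grepl("_chr$", replicon))
  expect_true(!is.unsorted(chrom$pan_id))
})

test_that("a locus missing from the reference interleaves between its anchors", {
  f <- replicate(5, random_peptide(40))
  x <- random_peptide(40)
  A <- fake_strain("A", sprintf("A_%d", 1:5), f)             # reference
  B <- fake_strain("B", c("B_1", "B_2", "B_x", "B_3", "B_4", "B_5"),
                   c(f[1:2], x, f[3:5]))
  C <- fake_strain("C", c("C_1", "C_2", "C_x", "C_3", "C_4", "C_5"),
                   c(f[1:2], x, f[3:5]))
  strains <- list(A = A, B = B, C = C)
  assignment <- tibble::tibble(
    feature_id = c(sprintf("A_%d", 1:5),
                   "B_1", "B_2", "B_x", "B_3", "B_4", "B_5",
                   "C_1", "C_2", "C_x", "C_3", "C_4", "C_5"),
    strain = rep(c("A", "B", "C"), c(5, 6, 6)),
    locus = c(1:5, 1, 2, 9, 3, 4, 5, 1, 2, 9, 3, 4, 5))
  num <- assign_pan_numbers(assignment, strains, "A")
  pid <- function(fid) num$pan_id[num$feature_id == fid]
  expect_equal(pid("A_1"), 1L)
  expect_equal(pid("A_5"), 6L)
  expect_equal(pid("B_x"), 3L)  # strictly between families 2 and 3
  expect_equal(pid("B_2"), 2L)
  expect_equal(pid("B_3"), 4L)
  # numbering is deterministic
  num2 <- assign_pan_numbers(assignment, strains, "A")
  expect_identical(num, num2)
})

test_that("member status classification follows the stop/length/split rules", {
  base <- random_peptide(60)
  strains <- list(
    A = fake_strain("A", c("A_1", "A_2", "A_3"),
                    c(base, base, base)),
    B = fake_strain("B", c("B_1", "B_2", "B_3"),
                    c(sub("^(.{30})", "\\1*", base),       # internal stop
                      substr(base, 1, 30),                  # truncated < 0.8 median
                      base)),
    C = fake_strain("C", c("C_1", "C_2", "C_3"),
                    c(base, base, base)))
  numbered <- tibble::tibble(
    feature_id = c("A_1", "A_2", "A_3", "B_1", "B_2", "B_3",
                   "C_1", "C_2", "C_3"),
    strain = rep(c("A", "B", "C"), each = 3),
    pan_id = rep(1:3, 3))
  st <- classify_member_status(numbered, strains)
  get <- function(fid) st$status[st$feature_id == fid]
  expect_equal(get("B_1"), "pseudogene") # rule (a)
  expect_equal(get("B_2"), "pseudogene") # rule (b)
  expect_equal(get("B_3"), "intact")
  expect_true(all(st$status[st$strain != "B"] == "intact"))
})

test_that("adjacent co-oriented fragments of one strain are split-gene pseudogenes", {
  base <- random_peptide(80)
  strains <- list(
    A = fake_strain("A", c("A_1", "A_2"), c(base, random_peptide(80))),
    B = fake_strain("B", c("B_1a", "B_1b", "B_2"),
                    c(substr(base, 1, 40), substr(base, 41, 80),
                      random_peptide(80))))
  numbered <- tibble::tibble(
    feature_id = c("A_1", "A_2", "B_1a", "B_1b", "B_2"),
    strain = c("A", "A", "B", "B", "B"),
    pan_id = c(1L, 2L, 1L, 1L, 2L))
  st <- classify_member_status(numbered, strains)
  expect_true(all(st$status[st$feature_id %in% c("B_1a", "B_1b")] == "pseudogene"))
  expect_equal(st$status[st$feature_id == "A_1"], "intact")
})

test_that("refinement matches exhaustive search on tiny conflicted instances", {
  # random instances: 3 strains, one strain with two candidate copies
  for (seed in 1:5) {
    set.seed(seed)
    fams <- replicate(9, random_peptide(30))
    A <- fake_strain("A", c(sprintf("A_%d", 1:9), "A_c1", "A_c2"),
                     c(fams, fams[5], fams[5]))
    B <- fake_strain("B", sprintf("B_%d", 1:9), fams)
    C <- fake_strain("C", sprintf("C_%d", 1:9), fams)
    strains <- list(A = A, B = B, C = C)
    members <- panoen:::.cds_table(strains)[, c("feature_id", "strain")]
    edges <- dplyr::bind_rows(lapply(setdiff(1:9, 5), function(i) tibble::tibble(
      a = c(sprintf("A_%d", i), sprintf("A_%d", i), sprintf("B_%d", i)),
      b = c(sprintf("B_%d", i), sprintf("C_%d", i), sprintf("C_%d", i)))))
    # family 5's component carries three A members (A_5, A_c1, A_c2)
    edges <- dplyr::bind_rows(edges, tibble::tibble(
      a = c("A_5", "A_c1", "A_c2", "B_5"),
      b = c("B_5", "B_5", "C_5", "C_5")))
    cl <- cluster_rbh(edges, members)
    ctx <- build_synteny_context(strains)
    ref <- refine_with_synteny(cl, ctx, strains)
    clu_of <- setNames(cl$cluster, cl$feature_id)
    cands <- c("A_5", "A_c1", "A_c2")
    scores <- vapply(cands, panoen:::.neighbor_agreement, 0,
                     locus_members = c("B_5", "C_5"), contexts = ctx,
                     clu_of = clu_of)
    best <- cands[which.max(scores)]
    locus_b5 <- ref$locus[ref$feature_id == "B_5"]
    expect_equal(ref$feature_id[ref$locus == locus_b5 & ref$strain == "A"],
                 best)
  }
})
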