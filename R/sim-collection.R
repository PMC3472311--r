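# Forward simulation of a bacterial strain collection with exhaustive ground
# truth. An ancestral chromosome (core genes in fixed random orientation,
# separated by intergenic spacers, tRNA genes at fixed sites) is evolved down
# a coalescent-shaped strain tree by per-branch nucleotide substitutions that
# never create in-frame stops; per-strain events then add accessory genes,
# cassette variants, premature-stop pseudogenes, phage insertions at tRNA
# sites delimited by exact att direct repeats, near-identity HGT imports from
# a simulated donor, and small plasmids.

.bases <- c("A", "C", "G", "T")

.nonstop_codons <- local({
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setdiff(codons, c("TAA", "TAG", "TGA"))
})

.aa_alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.syn_codons <- local({
  tab <- NULL # filled lazily; .codon_table exists by load time
  function() {
    if (is.null(tab)) {
      m <- split(names(.codon_table), unname(.codon_table))
      m <- lapply(m, function(x) setdiff(x, c("TAA", "TAG", "TGA")))
      tab <<- m[vapply(m, length, 1L) > 0]
    }
    tab
  }
})

.random_protein <- function(len) {
  paste(c("M", sample(.aa_alphabet, len - 1, replace = TRUE)), collapse = "")
}

# replace a fraction of residues (never position 1) with different ones
.mutate_aa <- function(p, frac) {
  v <- strsplit(p, "")[[1]]
  n <- length(v)
  k <- round(frac * n)
  if (k == 0) return(p)
  pos <- sample(2:n, min(k, n - 1))
  v[pos] <- vapply(v[pos], function(a) sample(setdiff(.aa_alphabet, a), 1), "")
  paste(v, collapse = "")
}

# protein -> CDS with random synonymous codons, ATG start, TAA stop
.back_translate <- function(p) {
  v <- strsplit(p, "")[[1]]
  syn <- .syn_codons()
  cods <- vapply(v, function(a) {
    opts <- syn[[a]]
    if (is.null(opts)) opts <- .nonstop_codons
    if (length(opts) == 1) opts else sample(opts, 1)
  }, "")
  cods[1] <- "ATG"
  paste(c(cods, "TAA"), collapse = "")
}

# rooted strain tree: random coalescent shape on all but the final two
# strains, which form a designated basal cherry on a long branch
.sim_tree <- function(cfg) {
  n <- cfg$n_strains
  strains <- sprintf("S%02d", seq_len(n))
  rate <- cfg$substitution_rate_per_branch
  bl <- function(k) rate * (0.3 + rexp(k))
  fmt <- function(x) sprintf("%.10g", x)
  if (n == 2) {
    txt <- sprintf("(%s:%s,%s:%s);", strains[1], fmt(bl(1)), strains[2], fmt(bl(1)))
    return(ape::read.tree(text = txt))
  }
  basal <- rate * cfg$basal_branch_factor
  cherry <- sprintf("(%s:%s,%s:%s)", strains[n - 1], fmt(bl(1)),
                    strains[n], fmt(bl(1)))
  if (n - 2 == 1) {
    rest <- sprintf("%s:%s", strains[1], fmt(bl(1)))
  } else {
    tr <- ape::rcoal(n - 2, tip.label = strains[seq_len(n - 2)])
    tr$edge.length <- bl(nrow(tr$edge))
    rest <- sub(";$", "", ape::write.tree(tr, digits = 10))
    rest <- sprintf("%s:%s", rest, fmt(basal))
  }
  txt <- sprintf("(%s,%s:%s);", rest, cherry, fmt(basal))
  ape::read.tree(text = txt)
}

#' Simulate a strain collection with ground truth
#'
#' Forward-simulates genomes, annotations and proteomes for a bacterial
#' strain collection under the statistical structure that the pan-genome
#' analysis assumes, and returns machine-readable truth for every event.
#' See [sim_config()] for the generative model and its defaults. The seed in
#' the configuration fully determines every output byte.
#'
#' @param cfg A `panoen_sim_config` from [sim_config()].
#' @return A `panoen_collection`: list with `strains` (named list of
#'   `panoen_strain` objects), `truth` (`panoen_truth`: `ortholog_map`,
#'   `status_map`, `hgt`, `phage`, `cassette`, `families`, `tree`),
#'   `donors` (named list of donor proteomes), `role_refs` (list with `int`
#'   and `lys` reference proteins), `outgroup` (outgroup proteome or
#'   `NULL`), and `config`.
#' @export
simulate_collection <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  n <- cfg$n_strains
  strains <- sprintf("S%02d", seq_len(n))

  tree <- .sim_tree(cfg)

  ## ---- ancestral layout ----------------------------------------------
  rand_len <- function(k) {
    pmax(cfg$min_gene_len,
         as.integer(round(stats::rnorm(k, cfg$mean_gene_len, cfg$sd_gene_len))))
  }

  anchors <- vapply(cfg$cassette_loci, function(x) as.integer(x$anchor), 1L)
  reserved_core <- unique(c(anchors, anchors + 1L))

  # tRNA slots: spread along the chromosome, avoiding cassette anchors
  trna_slots <- integer(0)
  if (cfg$n_trna_sites > 0) {
    cand <- round(seq(0.08, 0.92, length.out = cfg$n_trna_sites) * cfg$n_core_genes)
    for (i in seq_along(cand)) {
      while (cand[i] %in% c(anchors, trna_slots)) cand[i] <- cand[i] + 1L
    }
    trna_slots <- as.integer(cand)
  }

  free_slots <- setdiff(seq_len(cfg$n_core_genes - 1L), c(anchors, trna_slots))
  hgt_slots <- integer(0)
  if (length(cfg$hgt_segments) > 0) {
    hgt_slots <- sample(free_slots, length(cfg$hgt_segments))
    free_slots <- setdiff(free_slots, hgt_slots)
  }

  fam <- list()   # rows: family, class, len, strand, slot, ord, product
  add_fam <- function(family, class, len, slot, ord, product = "") {
    fam[[length(fam) + 1]] <<- list(family = family, class = class,
                                    len = as.integer(len), strand = sample(c("+", "-"), 1),
                                    slot = as.integer(slot), ord = as.integer(ord),
                                    product = product)
  }

  core_fams <- sprintf("F%04d", seq_len(cfg$n_core_genes))
  core_lens <- rand_len(cfg$n_core_genes)
  for (i in seq_len(cfg$n_core_genes)) {
    add_fam(core_fams[i], "core", core_lens[i], i, 0L)
  }

  # cassette variant contents
  for (li in seq_along(cfg$cassette_loci)) {
    cl <- cfg$cassette_loci[[li]]
    for (v in seq_len(cl$n_variants)) {
      for (g in seq_len(cl$genes_per_variant)) {
        add_fam(sprintf("CAS%d_v%d_g%d", li, v, g), "cassette",
                rand_len(1), cl$anchor, 200L + g, product = "EPS biosynthesis protein")
      }
    }
  }

  if (cfg$accessory_pool_size > 0) {
    sl <- sample(free_slots, cfg$accessory_pool_size, replace = TRUE)
    for (i in seq_len(cfg$accessory_pool_size)) {
      add_fam(sprintf("A%04d", i), "accessory", rand_len(1), sl[i], 400L + i)
    }
  }
  if (cfg$clade_private_genes > 0) {
    sl <- sample(free_slots, cfg$clade_private_genes, replace = TRUE)
    for (i in seq_len(cfg$clade_private_genes)) {
      add_fam(sprintf("P%03d", i), "clade_private", rand_len(1), sl[i], 300L + i)
    }
  }

  paralog_src <- character(0)
  if (cfg$paralog_pairs > 0) {
    paralog_src <- sample(core_fams, cfg$paralog_pairs)
    sl <- sample(free_slots, cfg$paralog_pairs, replace = TRUE)
    for (i in seq_len(cfg$paralog_pairs)) {
      add_fam(sprintf("Q%03d", i), "paralog", NA_integer_, sl[i], 500L + i)
    }
  }

  max_plasmids <- length(cfg$plasmid_count_probs) - 1L
  if (max_plasmids > 0 && cfg$plasmid_genes > 0) {
    for (p in seq_len(max_plasmids)) {
      for (g in seq_len(cfg$plasmid_genes)) {
        add_fam(sprintf("PL%d_g%d", p, g), "plasmid", rand_len(1), 0L, 0L,
                product = if (g == 1) "plasmid replication protein" else "plasmid protein")
      }
    }
  }

  fam <- bind_rows(lapply(fam, as_tibble))

  ## ---- ancestral sequences, evolution --------------------------------
  # evolving families: everything except phage and HGT content (inserted
  # identically in carriers, emulating recent events)
  anc_seq <- setNames(vector("list", nrow(fam)), fam$family)
  for (i in seq_len(nrow(fam))) {
    if (fam$class[i] == "paralog") next
    anc_seq[[fam$family[i]]] <- .random_gene(fam$len[i])
  }
  # paralog ancestors: diverged copy of a core family's protein
  if (cfg$paralog_pairs > 0) {
    for (i in seq_len(cfg$paralog_pairs)) {
      src_p <- .translate_cds(anc_seq[[paralog_src[i]]])
      nt <- .back_translate(.mutate_aa(src_p, cfg$paralog_divergence))
      f <- sprintf("Q%03d", i)
      anc_seq[[f]] <- nt
      fam$len[fam$family == f] <- nchar(nt) %/% 3L
    }
  }

  ev_fams <- fam$family
  ev_lens <- nchar(unlist(anc_seq[ev_fams], use.names = FALSE))
  offsets0 <- c(0L, cumsum(ev_lens))[seq_along(ev_fams)]
  big0 <- unlist(strsplit(unlist(anc_seq[ev_fams], use.names = FALSE), ""),
                 use.names = FALSE)
  # mutable positions: exclude each gene's first and last codon
  eligible <- unlist(Map(function(o, L) (o + 4L):(o + L - 3L),
                         offsets0, ev_lens), use.names = FALSE)
  alt_base <- rbind(c("C", "G", "T"), c("A", "G", "T"),
                    c("A", "C", "T"), c("A", "C", "G"))

  mutate_vec <- function(vec, blen) {
    n_mut <- rpois(1, blen * length(eligible))
    if (n_mut == 0) return(vec)
    pos <- unique(eligible[sample.int(length(eligible), n_mut, replace = TRUE)])
    cur <- match(vec[pos], .bases)
    vec[pos] <- alt_base[cbind(cur, sample.int(3L, length(pos), replace = TRUE))]
    gi <- findInterval(pos - 1L, offsets0)
    rel <- pos - offsets0[gi]
    cs <- unique(offsets0[gi] + ((rel - 1L) %/% 3L) * 3L + 1L)
    cod <- paste0(vec[cs], vec[cs + 1L], vec[cs + 2L])
    bad <- which(cod %in% .stop_codons)
    for (b in bad) {
      vec[cs[b]:(cs[b] + 2L)] <- strsplit(sample(.nonstop_codons, 1), "")[[1]]
    }
    vec
  }

  tip_seqs <- setNames(vector("list", n), strains)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  descend <- function(node, vec) {
    for (ei in kids[[as.character(node)]]) {
      child <- tree$edge[ei, 2]
      v2 <- mutate_vec(vec, tree$edge.length[ei])
      if (child <= n) {
        big <- paste(v2, collapse = "")
        s <- substring(big, offsets0 + 1L, offsets0 + ev_lens)
        tip_seqs[[tree$tip.label[child]]] <<- setNames(s, ev_fams)
      } else {
        descend(child, v2)
      }
    }
  }
  descend(length(tree$tip.label) + 1L, big0)

  ## ---- fixed (non-evolving) content: tRNAs, phage, HGT ----------------
  trna_seqs <- if (cfg$n_trna_sites > 0) {
    setNames(vapply(seq_len(cfg$n_trna_sites), function(i) .random_dna(75), ""),
             sprintf("t%d", seq_len(cfg$n_trna_sites)))
  } else character(0)

  phage_sets <- list() # per site: named list of gene nt seqs + strands
  used_sites <- sort(unique(vapply(cfg$phage_configs, function(x) x$site, 1)))
  role_int <- character(0); role_lys <- character(0)
  for (s in used_sites) {
    genes <- list()
    genes[[sprintf("PH%d_int", s)]] <- .random_gene(350)
    genes[[sprintf("PH%d_lys", s)]] <- .random_gene(300)
    for (g in seq_len(cfg$phage_filler_genes)) {
      genes[[sprintf("PH%d_f%d", s, g)]] <- .random_gene(rand_len(1))
    }
    strand <- setNames(sample(c("+", "-"), length(genes), replace = TRUE),
                       names(genes))
    phage_sets[[as.character(s)]] <- list(genes = genes, strand = strand)
    role_int[sprintf("PH%d_int", s)] <- .translate_cds(genes[[sprintf("PH%d_int", s)]])
    role_lys[sprintf("PH%d_lys", s)] <- .translate_cds(genes[[sprintf("PH%d_lys", s)]])
  }

  donors <- list()
  hgt_content <- list() # per segment: families, nt seqs, slot
  for (si in seq_along(cfg$hgt_segments)) {
    hs <- cfg$hgt_segments[[si]]
    dlen <- rand_len(hs$n_genes)
    dprot <- vapply(dlen, function(L) .random_protein(L - 1L), "")
    dnames <- sprintf("%s_seg%02d_g%02d", hs$donor, si, seq_len(hs$n_genes))
    rprot <- vapply(dprot, function(p) .mutate_aa(p, 1 - hs$identity / 100), "")
    rnt <- vapply(rprot, .back_translate, "")
    fams_h <- sprintf("H%02d_g%02d", si, seq_len(hs$n_genes))
    hgt_content[[si]] <- list(families = fams_h, nt = setNames(rnt, fams_h),
                              slot = hgt_slots[si], strains = strains[hs$strains],
                              donor = hs$donor)
    if (is.null(donors[[hs$donor]])) donors[[hs$donor]] <- character(0)
    donors[[hs$donor]] <- c(donors[[hs$donor]], setNames(dprot, dnames))
  }
  for (d in names(donors)) {
    if (cfg$donor_pool_size > 0) {
      bg <- vapply(rand_len(cfg$donor_pool_size), function(L) .random_protein(L - 1L), "")
      donors[[d]] <- c(donors[[d]],
                       setNames(bg, sprintf("%s_bg%04d", d, seq_len(cfg$donor_pool_size))))
    }
  }

  outgroup <- NULL
  if (cfg$emit_outgroup) {
    og <- vapply(core_fams, function(f) {
      .mutate_aa(.translate_cds(anc_seq[[f]]), cfg$outgroup_divergence)
    }, "")
    outgroup <- setNames(og, paste0("OG_", core_fams))
  }

  ## ---- per-strain event draws ----------------------------------------
  acc_fams <- fam$family[fam$class == "accessory"]
  acc_present <- matrix(runif(length(acc_fams) * n) < cfg$accessory_presence_prob,
                        nrow = length(acc_fams), ncol = n,
                        dimnames = list(acc_fams, strains))
  clade_fams <- fam$family[fam$class == "clade_private"]
  par_fams <- fam$family[fam$class == "paralog"]
  par_present <- matrix(runif(length(par_fams) * n) < 0.5,
                        nrow = length(par_fams), ncol = n,
                        dimnames = list(par_fams, strains))
  if (length(par_fams) > 0) par_present[, 1] <- TRUE # keep every family realized

  cass_variant <- list() # locus -> named int vector per strain
  for (li in seq_along(cfg$cassette_loci)) {
    cl <- cfg$cassette_loci[[li]]
    v <- integer(n)
    perm <- sample(seq_len(n))
    v[perm[seq_len(cl$n_variants)]] <- seq_len(cl$n_variants)
    rest <- perm[-seq_len(cl$n_variants)]
    if (length(rest) > 0) v[rest] <- sample(seq_len(cl$n_variants), length(rest), replace = TRUE)
    cass_variant[[li]] <- setNames(v, strains)
  }

  plasmid_count <- sample(seq_along(cfg$plasmid_count_probs) - 1L, n,
                          replace = TRUE, prob = cfg$plasmid_count_probs)
  names(plasmid_count) <- strains

  # pseudogene draws: eligible = core (minus cassette flanks), accessory,
  # clade-private and cassette genes present in the strain
  pseudo <- list() # strain -> tibble(family, codon, stop)
  for (st in strains) {
    elig <- c(setdiff(core_fams, core_fams[reserved_core]),
              acc_fams[acc_present[, st]],
              if (st %in% strains[c(n - 1, n)]) clade_fams else character(0))
    for (li in seq_along(cfg$cassette_loci)) {
      v <- cass_variant[[li]][st]
      elig <- c(elig, fam$family[fam$class == "cassette" &
                                   startsWith(fam$family, sprintf("CAS%d_v%d_", li, v))])
    }
    hit <- elig[runif(length(elig)) < cfg$pseudogene_rate]
    if (length(hit) > 0) {
      lens <- fam$len[match(hit, fam$family)]
      pseudo[[st]] <- tibble(
        family = hit,
        codon = vapply(lens, function(L) sample(2:(L - 2L), 1L), 1L),
        stop = sample(.stop_codons, length(hit), replace = TRUE)
      )
    } else {
      pseudo[[st]] <- tibble(family = character(), codon = integer(), stop = character())
    }
  }

  phage_plan <- list() # strain -> list of (site, class, copies)
  for (pc in cfg$phage_configs) {
    for (sidx in pc$strains) {
      st <- strains[sidx]
      phage_plan[[st]] <- c(phage_plan[[st]],
                            list(list(site = pc$site, class = pc$class,
                                      copies = as.integer(pc$copy_number))))
    }
  }

  ## ---- fixed ancestral spacers ---------------------------------------
  sp_len <- function(k) as.integer(round(runif(k, 50, 400)))
  spacers <- new.env(parent = emptyenv())
  spacer_for <- function(key) {
    if (is.null(spacers[[key]])) spacers[[key]] <- .random_dna(sp_len(1))
    spacers[[key]]
  }
  # pre-draw in a deterministic order so lookup order cannot matter
  for (f in fam$family) invisible(spacer_for(paste0("sp_", f)))
  for (k in names(trna_seqs)) invisible(spacer_for(paste0("sp_trna_", k)))
  for (s in names(phage_sets)) {
    for (g in names(phage_sets[[s]]$genes)) invisible(spacer_for(paste0("sp_", g)))
  }
  for (hc in hgt_content) for (f in hc$families) invisible(spacer_for(paste0("sp_", f)))
  invisible(spacer_for("sp_origin"))

  ## ---- assemble strains ----------------------------------------------
  slot_extra <- fam |>
    filter(.data$class %in% c("accessory", "clade_private", "paralog")) |>
    arrange(.data$slot, .data$ord)

  strain_objs <- setNames(vector("list", n), strains)
  om_rows <- list(); st_rows <- list(); hgt_rows <- list(); ph_rows <- list()
  cass_rows <- list()

  for (st in strains) {
    parts <- character(0)
    cursor <- 0L
    feats <- list()
    push <- function(s) {
      parts[[length(parts) + 1]] <<- s
      cursor <<- cursor + nchar(s)
    }
    status_here <- list()
    emit_cds <- function(family, nt, strand, replicon, product = "",
                         record_status = TRUE) {
      ps <- pseudo[[st]]
      is_pseudo <- family %in% ps$family
      if (is_pseudo) {
        i <- match(family, ps$family)
        p0 <- (ps$codon[i] - 1L) * 3L + 1L
        substr(nt, p0, p0 + 2L) <- ps$stop[i]
      }
      push(spacer_for(paste0("sp_", family)))
      block <- paste0("TAA", nt, "TTA")
      if (strand == "-") block <- .revcomp(block)
      start <- cursor + 3L
      end <- start + nchar(nt)
      push(block)
      feats[[length(feats) + 1]] <<- list(
        family = family, replicon = replicon, start = start, end = end,
        strand = strand, kind = "CDS", product = product,
        status = if (is_pseudo) "pseudogene" else "intact",
        record = record_status)
      c(start = start, end = end)
    }

    ## chromosome
    chrom <- paste0(st, "_chr")
    push(spacer_for("sp_origin"))
    for (i in seq_len(cfg$n_core_genes)) {
      fr <- fam[i, ] # core families occupy the first rows in order
      emit_cds(fr$family, tip_seqs[[st]][[fr$family]], fr$strand, chrom)

      # tRNA site (+ phage insertion) at this slot
      ti <- match(i, trna_slots)
      if (!is.na(ti)) {
        tkey <- sprintf("t%d", ti)
        push(spacer_for(paste0("sp_trna_", tkey)))
        tstart <- cursor
        push(trna_seqs[[tkey]])
        tend <- cursor
        feats[[length(feats) + 1]] <- list(
          family = paste0("tRNA_", tkey), replicon = chrom, start = tstart,
          end = tend, strand = "+", kind = "tRNA", product = tkey,
          status = "intact", record = FALSE)
        att <- substr(trna_seqs[[tkey]], 56, 75)
        for (pl in phage_plan[[st]]) {
          if (pl$site != ti) next
          ps <- phage_sets[[as.character(pl$site)]]
          gene_names <- names(ps$genes)
          if (pl$class == "fragment") gene_names <- gene_names[1]
          span_start <- tend
          for (cp in seq_len(pl$copies)) {
            for (g in gene_names) {
              push(spacer_for(paste0("sp_", g)))
              block <- paste0("TAA", ps$genes[[g]], "TTA")
              strand_g <- ps$strand[[g]]
              if (strand_g == "-") block <- .revcomp(block)
              gstart <- cursor + 3L
              gend <- gstart + nchar(ps$genes[[g]])
              push(block)
              role <- if (grepl("_int$", g)) "phage integrase (int)"
                      else if (grepl("_lys$", g)) "phage endolysin (lys)"
                      else "phage protein"
              feats[[length(feats) + 1]] <- list(
                family = g, replicon = chrom, start = gstart, end = gend,
                strand = strand_g, kind = "CDS", product = role,
                status = "intact", record = (cp == 1))
            }
            push(.random_dna(80L)) # element tail before att
            push(att)
          }
          ph_rows[[length(ph_rows) + 1]] <- tibble(
            strain = st, trna = tkey, replicon = chrom,
            start = span_start, end = cursor, class = pl$class,
            copy_number = pl$copies)
        }
      }

      # cassette at this anchor
      li <- match(i, anchors)
      if (!is.na(li)) {
        v <- cass_variant[[li]][st]
        cl <- cfg$cassette_loci[[li]]
        for (g in seq_len(cl$genes_per_variant)) {
          f <- sprintf("CAS%d_v%d_g%d", li, v, g)
          fr <- fam[fam$family == f, ]
          emit_cds(f, tip_seqs[[st]][[f]], fr$strand, chrom,
                   product = fr$product)
        }
        cass_rows[[length(cass_rows) + 1]] <- tibble(
          locus = li, strain = st, variant = as.integer(v))
      }

      # HGT segment at this slot
      for (hc in hgt_content) {
        if (hc$slot != i || !(st %in% hc$strains)) next
        seg_start <- NA_integer_
        for (f in hc$families) {
          sp <- emit_cds(f, hc$nt[[f]], "+", chrom,
                         product = "horizontally acquired protein")
          if (is.na(seg_start)) seg_start <- sp[["start"]]
          seg_end <- sp[["end"]]
        }
        hgt_rows[[length(hgt_rows) + 1]] <- tibble(
          strain = st, replicon = chrom, start = seg_start, end = seg_end,
          donor = hc$donor)
      }

      # accessory / clade-private / paralog families at this slot
      ex <- slot_extra[slot_extra$slot == i, ]
      for (j in seq_len(nrow(ex))) {
        f <- ex$family[j]
        present <- switch(ex$class[j],
          accessory = acc_present[f, st],
          clade_private = st %in% strains[c(n - 1, n)],
          paralog = par_present[f, st])
        if (!present) next
        emit_cds(f, tip_seqs[[st]][[f]], ex$strand[j], chrom,
                 product = ex$product[j])
      }
    }
    chrom_seq <- paste(parts, collapse = "")

    ## plasmids
    repl_names <- chrom
    repl_seqs <- list(chrom_seq)
    repl_types <- "chromosome"
    repl_circ <- FALSE
    if (plasmid_count[[st]] > 0) {
      for (p in seq_len(plasmid_count[[st]])) {
        parts <- character(0); cursor <- 0L
        pname <- sprintf("%s_p%d", st, p)
        push(spacer_for("sp_origin"))
        for (g in seq_len(cfg$plasmid_genes)) {
          f <- sprintf("PL%d_g%d", p, g)
          fr <- fam[fam$family == f, ]
          emit_cds(f, tip_seqs[[st]][[f]], fr$strand, pname, product = fr$product)
        }
        push(.random_dna(60L))
        repl_names <- c(repl_names, pname)
        repl_seqs <- c(repl_seqs, paste(parts, collapse = ""))
        repl_types <- c(repl_types, "plasmid")
        repl_circ <- c(repl_circ, TRUE)
      }
    }

    ## materialize the strain object
    fdf <- bind_rows(lapply(feats, as_tibble))
    fdf <- fdf |> arrange(match(.data$replicon, repl_names), .data$start)
    fdf$feature_id <- sprintf("%s_%04d", st, seq_len(nrow(fdf)))
    genome <- Biostrings::DNAStringSet(setNames(unlist(repl_seqs), repl_names))
    features <- fdf |>
      mutate(raw_status = "called_full") |>
      select("feature_id", "replicon", "start", "end", "strand", "kind",
             "product", "raw_status")
    proteome <- .translate_features(genome, features)
    strain_objs[[st]] <- structure(
      list(strain_id = st,
           replicons = tibble(name = repl_names,
                              length = nchar(unlist(repl_seqs)),
                              circular = repl_circ, type = repl_types),
           features = features, genome = genome, proteome = proteome),
      class = "panoen_strain")

    cdsf <- fdf |> filter(.data$kind == "CDS")
    om_rows[[length(om_rows) + 1]] <- tibble(
      feature_id = cdsf$feature_id, strain = st, family = cdsf$family)
    st_rows[[length(st_rows) + 1]] <- cdsf |>
      filter(.data$record) |>
      distinct(.data$family, .keep_all = TRUE) |>
      transmute(strain = st, family = .data$family, status = .data$status)
  }

  ## ---- truth ----------------------------------------------------------
  all_fams <- fam$family
  phage_fams <- unlist(lapply(phage_sets, function(x) names(x$genes)))
  hgt_fams <- unlist(lapply(hgt_content, function(x) x$families))
  universe <- c(all_fams, phage_fams, hgt_fams)
  present <- bind_rows(st_rows)
  status_map <- tidyr::expand_grid(family = universe, strain = strains) |>
    left_join(present, by = c("family", "strain")) |>
    mutate(status = ifelse(is.na(.data$status), "absent", .data$status)) |>
    arrange(.data$family, .data$strain)

  fam_meta <- bind_rows(
    fam |> select("family", "class", "len"),
    tibble(family = phage_fams, class = "phage",
           len = vapply(phage_fams, function(f) {
             s <- sub("^PH(\\d+)_.*$", "\\1", f)
             nchar(phage_sets[[s]]$genes[[f]]) %/% 3L
           }, 1L)),
    tibble(family = hgt_fams, class = "hgt",
           len = unlist(lapply(hgt_content,
                               function(x) nchar(x$nt) %/% 3L), use.names = FALSE))
  )

  truth <- structure(list(
    ortholog_map = bind_rows(om_rows) |> arrange(.data$strain, .data$feature_id),
    status_map = status_map,
    hgt = if (length(hgt_rows)) bind_rows(hgt_rows) |> arrange(.data$strain, .data$start)
          else tibble(strain = character(), replicon = character(),
                      start = integer(), end = integer(), donor = character()),
    phage = if (length(ph_rows)) bind_rows(ph_rows) |> arrange(.data$strain, .data$trna)
            else tibble(strain = character(), trna = character(),
                        replicon = character(), start = integer(),
                        end = integer(), class = character(), copy_number = integer()),
    cassette = if (length(cass_rows)) bind_rows(cass_rows) |> arrange(.data$locus, .data$strain)
               else tibble(locus = integer(), strain = character(), variant = integer()),
    families = fam_meta |> arrange(.data$family),
    tree = tree
  ), class = "panoen_truth")

  structure(list(
    strains = strain_objs,
    truth = truth,
    donors = donors,
    role_refs = list(int = role_int, lys = role_lys),
    outgroup = outgroup,
    config = cfg
  ), class = "panoen_collection")
}

#' @export
print.panoen_collection <- function(x, ...) {
  ns <- length(x$strains)
  cds <- vapply(x$strains, function(s) sum(s$features$kind == "CDS"), 1L)
  cat("<panoen_collection> ", ns, " strains, mean ",
      round(mean(cds)), " CDS/strain, ",
      length(unique(x$truth$status_map$family)), " truth families\n", sep = "")
  invisible(x)
}
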