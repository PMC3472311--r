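# Reading and writing strain data: genome FASTA + GFF3 in, translated
# proteome out. Internal coordinates are 0-based half-open throughout; the
# GFF3 1-based inclusive convention is converted at the boundary.

#' Load one strain from genome FASTA and GFF3
#'
#' Reads a genome and its gene annotation into a `panoen_strain` object:
#' replicon table, ordered feature table (CDS and tRNA), and the translated
#' proteome (genetic code table 11; ATG/GTG/TTG accepted as initiators).
#' A CDS whose length is not a multiple of three, or flagged `partial=true`,
#' is tagged `called_partial` rather than rejected. Internal stop codons are
#' translated as `*` so that downstream pseudogene classification can see
#' them.
#'
#' Replicon topology and type are taken from GFF3 `region` features when
#' present (attributes `replicon_type` and `Is_circular`); otherwise every
#' replicon defaults to a linear chromosome.
#'
#' @param genome_fasta Path to the genome FASTA.
#' @param gff3 Path to the GFF3 annotation (version pragma required by the
#'   format; all seqids must exist in the FASTA).
#' @param strain_id Strain label; defaults to the FASTA file name.
#' @return A `panoen_strain` object: list with `strain_id`, `replicons`
#'   (tibble: `name`, `length`, `circular`, `type`), `features` (tibble:
#'   `feature_id`, `replicon`, `start`, `end`, `strand`, `kind`,
#'   `raw_status`, `product`, sorted by replicon then start; 0-based
#'   half-open), `genome` (`DNAStringSet`), `proteome` (named character
#'   vector).
#' @export
load_strain <- function(genome_fasta, gff3, strain_id = NULL) {
  genome <- Biostrings::readDNAStringSet(genome_fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (is.null(strain_id)) {
    strain_id <- sub("\\.(fa|fasta|fna)$", "", basename(genome_fasta))
  }
  gr <- rtracklayer::import(gff3, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  .assert(all(as.character(df$seqnames) %in% names(genome)),
          "GFF3 seqids missing from FASTA")
  attr_or <- function(nm, default) {
    if (nm %in% names(df)) {
      v <- as.character(df[[nm]])
      ifelse(is.na(v), default, v)
    } else rep(default, nrow(df))
  }
  reg <- df |> filter(.data$type %in% c("region"))
  replicons <- tibble(
    name = names(genome),
    length = Biostrings::width(genome)
  )
  if (nrow(reg) > 0) {
    rt <- tibble(
      name = as.character(reg$seqnames),
      circular = tolower(attr_or("Is_circular", "false")[df$type == "region"]) == "true",
      type = attr_or("replicon_type", "chromosome")[df$type == "region"]
    )
    replicons <- left_join(replicons, rt, by = "name")
    replicons$circular[is.na(replicons$circular)] <- FALSE
    replicons$type[is.na(replicons$type)] <- "chromosome"
  } else {
    replicons$circular <- FALSE
    replicons$type <- "chromosome"
  }

  feat <- df |> filter(.data$type %in% c("CDS", "tRNA"))
  ids <- if ("ID" %in% names(feat)) as.character(feat$ID) else rep(NA_character_, nrow(feat))
  if ("locus_tag" %in% names(feat)) {
    lt <- as.character(feat$locus_tag)
    ids <- ifelse(is.na(ids), lt, ids)
  }
  .assert(!any(is.na(ids)), "every CDS/tRNA feature needs an ID or locus_tag")
  features <- tibble(
    feature_id = ids,
    replicon = as.character(feat$seqnames),
    start = feat$start - 1L,      # to 0-based half-open
    end = feat$end,
    strand = as.character(feat$strand),
    kind = as.character(feat$type),
    product = if ("product" %in% names(feat)) {
      ifelse(is.na(as.character(feat$product)), "", as.character(feat$product))
    } else "",
    partial = if ("partial" %in% names(feat)) {
      tolower(as.character(feat$partial)) %in% "true"
    } else FALSE
  )
  rl <- setNames(replicons$length, replicons$name)
  .assert(all(features$start >= 0 & features$end <= rl[features$replicon]),
          "feature coordinates out of replicon range")
  .assert(all(features$start < features$end), "feature start must precede end")
  features <- features |>
    mutate(raw_status = ifelse(.data$kind == "CDS" &
                                 (((.data$end - .data$start) %% 3L) != 0L | .data$partial),
                               "called_partial", "called_full")) |>
    select(-"partial") |>
    arrange(.data$replicon, .data$start)

  proteome <- .translate_features(genome, features)
  structure(
    list(strain_id = strain_id, replicons = replicons, features = features,
         genome = genome, proteome = proteome),
    class = "panoen_strain"
  )
}

#' @export
print.panoen_strain <- function(x, ...) {
  cat("<panoen_strain> ", x$strain_id, "\n", sep = "")
  cat("  replicons: ", nrow(x$replicons), " (",
      sum(x$replicons$length), " bp)\n", sep = "")
  cat("  features:  ", sum(x$features$kind == "CDS"), " CDS, ",
      sum(x$features$kind == "tRNA"), " tRNA\n", sep = "")
  invisible(x)
}

# extract + translate every CDS in a feature table
.translate_features <- function(genome, features) {
  cds <- features |> filter(.data$kind == "CDS")
  if (nrow(cds) == 0) return(setNames(character(), character()))
  seqs <- vapply(seq_len(nrow(cds)), function(i) {
    s <- as.character(Biostrings::subseq(genome[[cds$replicon[i]]],
                                         cds$start[i] + 1L, cds$end[i]))
    if (cds$strand[i] == "-") s <- .revcomp(s)
    s
  }, character(1))
  setNames(.translate_many(seqs), cds$feature_id)
}

#' Write a strain back to FASTA + GFF3 (+ protein FASTA)
#'
#' Inverse of [load_strain()]: emits the genome FASTA, a GFF3 with `region`,
#' `CDS` and `tRNA` features (1-based inclusive coordinates), and the
#' translated proteome as protein FASTA. Loading the files back preserves
#' feature coordinates and attributes exactly.
#'
#' @param ann A `panoen_strain` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_strain <- function(ann, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(dir, ann$strain_id)
  fa <- paste0(base, ".fna")
  gff <- paste0(base, ".gff3")
  faa <- paste0(base, ".faa")
  Biostrings::writeXStringSet(ann$genome, fa, width = 80)

  reg <- GenomicRanges::GRanges(
    seqnames = ann$replicons$name,
    ranges = IRanges::IRanges(1L, ann$replicons$length),
    strand = "*"
  )
  S4Vectors::mcols(reg)$type <- "region"
  S4Vectors::mcols(reg)$ID <- ann$replicons$name
  S4Vectors::mcols(reg)$replicon_type <- ann$replicons$type
  S4Vectors::mcols(reg)$Is_circular <- ifelse(ann$replicons$circular, "true", "false")

  ft <- ann$features
  gr <- GenomicRanges::GRanges(
    seqnames = ft$replicon,
    ranges = IRanges::IRanges(ft$start + 1L, ft$end),
    strand = ft$strand
  )
  S4Vectors::mcols(gr)$type <- ft$kind
  S4Vectors::mcols(gr)$ID <- ft$feature_id
  S4Vectors::mcols(gr)$locus_tag <- ft$feature_id
  S4Vectors::mcols(gr)$product <- ifelse(nzchar(ft$product), ft$product, NA_character_)
  S4Vectors::mcols(gr)$partial <- ifelse(ft$raw_status == "called_partial", "true", NA_character_)
  S4Vectors::mcols(gr)$phase <- ifelse(ft$kind == "CDS", 0L, NA_integer_)

  all <- suppressWarnings(c(reg, gr))
  rtracklayer::export(all, gff, format = "gff3")

  if (length(ann$proteome) > 0) {
    aa <- Biostrings::AAStringSet(ann$proteome)
    Biostrings::writeXStringSet(aa, faa, width = 80)
  } else {
    writeLines(character(), faa)
  }
  invisible(c(fasta = fa, gff3 = gff, protein = faa))
}

#' Naive ORF calling for annotation-free genomes
#'
#' A deliberately simple start-to-stop ORF caller (genetic code table 11,
#' ATG/GTG/TTG starts) for use when no GFF3 annotation is available. Within
#' each strand, overlapping candidate ORFs are resolved greedily by length
#' (ties by coordinate), so the call set is deterministic. This is plumbing,
#' not a gene finder: it has no model of coding statistics.
#'
#' @param genome A `DNAStringSet` or path to a genome FASTA.
#' @param min_len Minimum ORF length in codons, including the stop
#'   (default 30).
#' @return A feature tibble in the same shape as
#'   `load_strain()$features`.
#' @export
naive_orf_call <- function(genome, min_len = 30L) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  out <- purrr::imap(as.list(as.character(genome)), function(seq, rep_name) {
    n <- nchar(seq)
    orfs <- list()
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seq else .revcomp(seq)
      cand <- .orfs_one_strand(s, min_len)
      if (nrow(cand) == 0) next
      if (strand == "-") {
        tmp <- cand
        cand$start <- n - tmp$end
        cand$end <- n - tmp$start
      }
      cand$strand <- strand
      # greedy non-overlap within strand: longest first, then leftmost
      cand <- cand |> arrange(desc(.data$end - .data$start), .data$start)
      keep <- logical(nrow(cand))
      taken <- matrix(numeric(0), ncol = 2)
      for (i in seq_len(nrow(cand))) {
        s0 <- cand$start[i]; e0 <- cand$end[i]
        if (nrow(taken) == 0 || all(e0 <= taken[, 1] | s0 >= taken[, 2])) {
          keep[i] <- TRUE
          taken <- rbind(taken, c(s0, e0))
        }
      }
      orfs[[strand]] <- cand[keep, , drop = FALSE]
    }
    if (length(orfs) == 0) return(NULL)
    bind_rows(orfs) |> mutate(replicon = rep_name)
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble(feature_id = character(), replicon = character(),
                  start = integer(), end = integer(), strand = character(),
                  kind = character(), product = character(),
                  raw_status = character()))
  }
  out <- out |> arrange(.data$replicon, .data$start)
  out |>
    mutate(feature_id = sprintf("orf_%05d", seq_len(nrow(out))),
           kind = "CDS", product = "", raw_status = "called_full") |>
    select("feature_id", "replicon", "start", "end", "strand", "kind",
           "product", "raw_status")
}

# ORFs on the forward strand of s (0-based half-open coords on s)
.orfs_one_strand <- function(s, min_len) {
  n <- nchar(s)
  res <- list()
  for (frame in 0:2) {
    n_cod <- (n - frame) %/% 3
    if (n_cod < min_len) next
    starts <- frame + 3 * (seq_len(n_cod) - 1) + 1 # 1-based codon starts
    codons <- substring(s, starts, starts + 2)
    is_stop <- codons %in% .stop_codons
    is_start <- codons %in% .start_codons
    # segments between stops; each yields at most one ORF (first start -> stop)
    stop_idx <- which(is_stop)
    seg_start <- c(1L, stop_idx + 1L)
    seg_stop <- c(stop_idx, n_cod) # last segment has no stop -> skipped
    for (k in seq_along(seg_start)) {
      a <- seg_start[k]; b <- seg_stop[k]
      if (k > length(stop_idx)) break  # trailing segment without stop codon
      if (a > b) next
      st <- which(is_start[a:b])
      if (length(st) == 0) next
      first_start <- a + st[1] - 1L
      len <- b - first_start + 1L     # codons incl stop
      if (len < min_len) next
      res[[length(res) + 1]] <- c(starts[first_start] - 1L, starts[b] + 2L)
    }
  }
  if (length(res) == 0) return(tibble(start = integer(), end = integer()))
  m <- do.call(rbind, res)
  tibble(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
}
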