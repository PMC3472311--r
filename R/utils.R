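# Internal helpers shared across modules.

# data.table is used internally for the k-mer join
.datatable.aware <- TRUE

# Bacterial genetic code (translation table 11). Stop codons map to "*".
# Alternative initiators (ATG/GTG/TTG) are handled at translation time.
.stop_codons <- c("TAA", "TAG", "TGA")
.start_codons <- c("ATG", "GTG", "TTG")

.codon_table <- local({
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  # codons enumerated with third base fastest
  codons <- sort(codons)
  aa <- vapply(codons, function(cd) {
    as.character(Biostrings::translate(
      Biostrings::DNAString(cd),
      genetic.code = Biostrings::getGeneticCode("11"),
      no.init.codon = TRUE
    ))
  }, character(1))
  setNames(aa, codons)
})

# deterministic child seed from a base seed and a stage label; stays < 2^31
.child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) + (h * 2654435) %% 1000000007) %% 2147483647)
}

.assert <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
}

# reverse complement on a plain character scalar
.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# translate a CDS nucleotide string (in coding orientation) to protein,
# table 11; internal stops become "*"; trailing stop removed; alternative
# start codons become "M".
.translate_cds <- function(nt) {
  n <- nchar(nt)
  n3 <- n - n %% 3
  if (n3 < 3) return("")
  codons <- substring(nt, seq(1, n3 - 2, by = 3), seq(3, n3, by = 3))
  aa <- unname(.codon_table[codons])
  aa[is.na(aa)] <- "X"
  if (length(aa) > 1 && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (codons[1] %in% .start_codons) aa[1] <- "M"
  paste(aa, collapse = "")
}

# vectorised wrapper
.translate_many <- function(nts) vapply(nts, .translate_cds, character(1), USE.NAMES = FALSE)

# random DNA of length n (uniform base composition)
.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random gene of len codons: start codon + internal codons free of stops + stop
.random_gene <- function(len_codons) {
  non_stop <- setdiff(names(.codon_table), .stop_codons)
  body <- sample(non_stop, len_codons - 2, replace = TRUE)
  paste(c("ATG", body, sample(.stop_codons, 1)), collapse = "")
}

# k-mer tibble for a set of protein sequences: one row per distinct
# (sequence, kmer) pair
.protein_kmers <- function(seqs, k = 5L) {
  lens <- nchar(seqs)
  keep <- which(lens >= k)
  if (length(keep) == 0) {
    return(tibble(idx = integer(), kmer = character()))
  }
  out <- lapply(keep, function(i) {
    s <- seqs[[i]]
    unique(substring(s, seq_len(nchar(s) - k + 1L), seq(k, nchar(s))))
  })
  tibble(
    idx = rep(keep, lengths(out)),
    kmer = unlist(out, use.names = FALSE)
  )
}
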