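# Ground-truth serialization: deterministic, sorted TSVs plus a newick tree,
# so that a written truth reloads equal to the original.

#' Write simulation ground truth to a directory
#'
#' Serializes every truth table as a sorted TSV (`ortholog_map.tsv`,
#' `status_map.tsv`, `hgt.tsv`, `phage.tsv`, `cassette.tsv`,
#' `families.tsv`) and the strain tree as newick (`tree.nwk`). Output is
#' deterministic: identical truth produces byte-identical files.
#'
#' @param truth A `panoen_truth` object (see [simulate_collection()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    readr::write_tsv(df, file.path(dir, name), progress = FALSE)
  }
  w(truth$ortholog_map |> arrange(.data$strain, .data$feature_id), "ortholog_map.tsv")
  w(truth$status_map |> arrange(.data$family, .data$strain), "status_map.tsv")
  w(truth$hgt |> arrange(.data$strain, .data$start), "hgt.tsv")
  w(truth$phage |> arrange(.data$strain, .data$trna, .data$start), "phage.tsv")
  w(truth$cassette |> arrange(.data$locus, .data$strain), "cassette.tsv")
  w(truth$families |> arrange(.data$family), "families.tsv")
  ape::write.tree(truth$tree, file.path(dir, "tree.nwk"), digits = 12)
  invisible(dir)
}

#' Read simulation ground truth back from a directory
#'
#' Inverse of [write_truth()].
#'
#' @param dir Directory written by [write_truth()].
#' @return A `panoen_truth` object.
#' @export
read_truth <- function(dir) {
  r <- function(name, types) {
    readr::read_tsv(file.path(dir, name), col_types = types, progress = FALSE)
  }
  structure(list(
    ortholog_map = r("ortholog_map.tsv", "ccc"),
    status_map = r("status_map.tsv", "ccc"),
    hgt = r("hgt.tsv", "cciic"),
    phage = r("phage.tsv", "ccciici") |>
      select("strain", "trna", "replicon", "start", "end", "class", "copy_number"),
    cassette = r("cassette.tsv", "ici"),
    families = r("families.tsv", "cci"),
    tree = ape::read.tree(file.path(dir, "tree.nwk"))
  ), class = "panoen_truth")
}

#' Write a simulated collection to disk
#'
#' Emits per-strain genome FASTA, GFF3 and protein FASTA (via
#' [write_strain()]), donor proteomes, phage role reference proteins, the
#' outgroup proteome when present, the ground truth (via [write_truth()]),
#' and the configuration as YAML.
#'
#' @param collection A `panoen_collection` from [simulate_collection()].
#' @param dir Output directory.
#' @return Invisibly, the directory path.
#' @export
write_collection <- function(collection, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sdir <- file.path(dir, "strains")
  for (st in names(collection$strains)) {
    write_strain(collection$strains[[st]], sdir)
  }
  if (length(collection$donors) > 0) {
    ddir <- file.path(dir, "donors")
    dir.create(ddir, showWarnings = FALSE)
    for (d in names(collection$donors)) {
      Biostrings::writeXStringSet(
        Biostrings::AAStringSet(collection$donors[[d]]),
        file.path(ddir, paste0(d, ".faa")), width = 80)
    }
  }
  refs <- c(collection$role_refs$int, collection$role_refs$lys)
  if (length(refs) > 0) {
    Biostrings::writeXStringSet(Biostrings::AAStringSet(refs),
                                file.path(dir, "phage_role_refs.faa"), width = 80)
  }
  if (!is.null(collection$outgroup)) {
    Biostrings::writeXStringSet(Biostrings::AAStringSet(collection$outgroup),
                                file.path(dir, "outgroup.faa"), width = 80)
  }
  write_truth(collection$truth, file.path(dir, "truth"))
  cfg <- collection$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
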