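#' Sequence-cluster table
#'
#' Maps accessions to UniRef50-style cluster ids (clusters of sequences at
#' >= 50\% identity), used to remove any relatives of the prediction tools'
#' training proteins from the evaluation set.
#'
#' @param accession,cluster_id equal-length character vectors, or a TSV path
#'   for \code{read_cluster_table} (columns \code{accession},
#'   \code{cluster_id}).
#' @return an object of class \code{cluster_table} (named character vector).
#' @export
cluster_table <- function(accession, cluster_id) {
  stopifnot(length(accession) == length(cluster_id))
  structure(setNames(as.character(cluster_id), accession),
            class = "cluster_table")
}

#' @rdname cluster_table
#' @param path TSV path.
#' @export
read_cluster_table <- function(path) {
  df <- read.delim(path, colClasses = "character")
  cluster_table(df$accession, df$cluster_id)
}

cluster_of <- function(clusters, accession) {
  out <- unname(unclass(clusters)[accession])
  out[is.na(out)] <- "unknown"
  out
}

#' Exclude entries related to training proteins
#'
#' The excluded cluster set is the set of cluster ids of the training
#' accessions; an entry is dropped as soon as \emph{any} of its accessions
#' falls in that set (reason \code{training_overlap}).  Accessions with no
#' known cluster are treated conservatively: the entry is dropped and
#' flagged \code{unknown_cluster}, since relatedness cannot be excluded.
#'
#' @param entries list of \code{\link{allosteric_entry}}.
#' @param clusters a \code{\link{cluster_table}}.
#' @param training_accessions character vector of training-set accessions.
#' @return list with \code{kept} and \code{dropped}.
#' @export
exclude_training_clusters <- function(entries, clusters,
                                      training_accessions) {
  stopifnot(inherits(clusters, "cluster_table"))
  excluded <- unique(cluster_of(clusters, training_accessions))
  entries <- lapply(entries, function(e) {
    if (any(cluster_of(clusters, e$accessions) == "unknown"))
      e$flags <- union(e$flags, "unknown_cluster")
    e
  })
  partition_entries(entries, function(e) {
    cl <- cluster_of(clusters, e$accessions)
    !any(cl %in% excluded) && !any(cl == "unknown")
  }, "training_overlap")
}

#' Keep only small-molecule modulated entries
#'
#' The benchmarked predictors are designed for sites occupied by small
#' molecules, so entries with ionic, peptide or unclassified modulators are
#' dropped (reason \code{modulator_class}).  Every allosteric site of a
#' kept entry must be small-molecule modulated.
#'
#' @param entries list of \code{\link{allosteric_entry}}.
#' @return list with \code{kept} and \code{dropped}.
#' @export
filter_modulator_type <- function(entries) {
  partition_entries(entries, function(e)
    length(e$allosteric_sites) > 0L &&
      all(vapply(e$allosteric_sites, function(s)
        s$modulator_class == "small_molecule", logical(1))),
    "modulator_class")
}

#' Drop enormous structures
#'
#' Structures with more than \code{max_residues} observed protein residues
#' are dropped (reason \code{size}); a structure with exactly
#' \code{max_residues} is kept.
#'
#' @param entries list of \code{\link{allosteric_entry}}.
#' @param max_residues residue cap (default 8000).
#' @return list with \code{kept} and \code{dropped}.
#' @export
filter_size <- function(entries, max_residues = 8000) {
  partition_entries(entries, function(e)
    is.na(e$n_protein_residues) || e$n_protein_residues <= max_residues,
    "size")
}

#' Drop structures containing nucleic acids
#'
#' An entry is dropped (reason \code{nucleic}) when any polymer chain of
#' its structure contains nucleotide residues
#' (A/C/G/U/I/DA/DC/DG/DT/DI); a single modified nucleotide bound as a
#' hetero ligand does not trigger the filter.
#'
#' @param entries list of \code{\link{allosteric_entry}}.
#' @return list with \code{kept} and \code{dropped}.
#' @export
filter_nucleic <- function(entries) {
  partition_entries(entries, function(e) !isTRUE(e$has_nucleic), "nucleic")
}

#' Apply all test-set filters in canonical order
#'
#' The kept set is independent of filter order (each filter tests an
#' independent property), but the drop \emph{reason} of an entry failing
#' several filters is attributed to the first filter in the canonical
#' order: training overlap, modulator class, size, nucleic acids.
#'
#' @param entries list of \code{\link{allosteric_entry}}.
#' @param clusters a \code{\link{cluster_table}}.
#' @param training_accessions training-set accessions.
#' @param max_residues residue cap.
#' @return list with \code{kept} and \code{dropped}.
#' @export
apply_testset_filters <- function(entries, clusters, training_accessions,
                                  max_residues = 8000) {
  st1 <- exclude_training_clusters(entries, clusters, training_accessions)
  st2 <- filter_modulator_type(st1$kept)
  st3 <- filter_size(st2$kept, max_residues)
  st4 <- filter_nucleic(st3$kept)
  list(kept = st4$kept,
       dropped = c(st1$dropped, st2$dropped, st3$dropped, st4$dropped))
}

#' Assemble the evaluation subset
#'
#' If at most \code{n} entries survive the filters, all of them form the
#' test set.  Otherwise a seeded uniform sample without replacement is
#' drawn, keeping at most one structure per sequence cluster (entries are
#' visited in the seeded random order and an entry is taken greedily unless
#' its cluster is already represented).  Deterministic for a fixed seed.
#'
#' @param entries list of filtered \code{\link{allosteric_entry}} (with
#'   heteroatoms already stripped from their structures).
#' @param clusters a \code{\link{cluster_table}}.
#' @param n target size (default 100).
#' @param seed integer seed.
#' @param take_all return all survivors regardless of \code{n}.
#' @return list of selected entries.
#' @export
assemble_testset <- function(entries, clusters, n = 100, seed = 1,
                             take_all = FALSE) {
  if (n <= 0) stop("n must be positive")
  if (take_all || length(entries) <= n) return(entries)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  ord <- sample.int(length(entries))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  seen <- character()
  picked <- integer()
  for (i in ord) {
    cl <- unique(cluster_of(clusters, entries[[i]]$accessions))
    if (any(cl %in% seen)) next
    seen <- c(seen, cl)
    picked <- c(picked, i)
    if (length(picked) == n) break
  }
  entries[sort(picked)]
}
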