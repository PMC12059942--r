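#' Generate a self-consistent synthetic annotation corpus
#'
#' Builds \code{n} cross-referenced fixture entries: ASD-like XML documents,
#' PDB-format structures with a planted modulator, identifier-resolver
#' tables, active-site tables (UniProt-style and M-CSA-style), canonical
#' sequences and a sequence-cluster table.  Every entry is clean unless a
#' defect is requested for it; each defect exercises exactly one pipeline
#' rule, so drop tallies are exactly predictable:
#'
#' \describe{
#'   \item{obsolete_pdb}{XML carries a superseded PDB id that resolves to
#'     the current one (entry is kept, id updated).}
#'   \item{pdb_removed}{XML carries an id no longer in the archive
#'     (dropped).}
#'   \item{id_discrepancy}{the structure's chains map to a different
#'     accession (dropped).}
#'   \item{missing_site}{XML lacks the allosteric-site element (dropped as
#'     incomplete annotation).}
#'   \item{low_resolution}{structure resolved at 4.5 A (dropped).}
#'   \item{mmcif_only}{structure available only as mmCIF (dropped).}
#'   \item{offset_numbering}{author numbering shifted +24 against the
#'     canonical sequence (kept; exercises residue synchronization).}
#'   \item{gap}{residues 18--20 unresolved (kept; exercises gap detection
#'     and the modeling hand-off).}
#'   \item{multi_model}{two MODEL blocks (kept; exercises model merging).}
#'   \item{ion_modulator / peptide_modulator}{modulator class knobs for the
#'     test-set filter.}
#' }
#'
#' Default clean-entry conditions: one 30-residue chain, modulator alias
#' \code{LIG} (small molecule) with pocket residues 8--11, active-site
#' canonical positions 3 and 15 (UniProt-style) and 15 and 22 (M-CSA-style),
#' resolution 2.0 A, one accession per entry, one cluster per accession.
#'
#' @param n number of entries.
#' @param defects named list: defect name -> integer entry indices.
#' @param n_residues chain length.
#' @param seed integer seed (generators are deterministic given
#'   \code{(spec, seed)}).
#' @return an object of class \code{allobench_corpus}: list with
#'   \code{xml} (named character), \code{structures} (named character,
#'   PDB/mmCIF text by pdb id), \code{resolver}, \code{uniprot_sites},
#'   \code{mcsa_sites}, \code{canonical_seqs}, \code{clusters} and
#'   \code{expected} (planted ground truth: drop reason and pocket per
#'   entry).
#' @export
make_corpus <- function(n = 10, defects = list(), n_residues = 30, seed = 1) {
  stopifnot(n >= 1)
  has_defect <- function(d, i) i %in% defects[[d]]
  entry_ids <- sprintf("ASD%03d", seq_len(n))
  pdb_ids <- sprintf("9%03d", seq_len(n))
  accessions <- sprintf("P%05d", seq_len(n))
  # pocket size 4: divisible by the denominators of the overlap fractions
  # used with make_mock_predictions, so expected JIs are exact
  pocket_seq <- 8:11
  active_uni <- c(3L, 15L); active_mcsa <- c(15L, 22L)

  xml <- character(); structures <- character()
  pdb_map <- character(); chain_maps <- list()
  expected_reason <- setNames(rep("", n), entry_ids)
  expected_pocket <- list()

  for (i in seq_len(n)) {
    offset <- if (has_defect("offset_numbering", i)) 24L else 0L
    gaps <- if (has_defect("gap", i)) list(c(18L, 20L)) else list()
    n_models <- if (has_defect("multi_model", i)) 2L else 1L
    resolution <- if (has_defect("low_resolution", i)) 4.5 else 2.0
    mclass <- if (has_defect("ion_modulator", i)) "ion"
      else if (has_defect("peptide_modulator", i)) "peptide"
      else "small_molecule"
    pocket_auth <- pocket_seq + offset

    pdb <- make_synthetic_structure(n_chains = 1, n_residues = n_residues,
                                    gap_ranges = gaps, n_models = n_models,
                                    resolution = resolution,
                                    pdb_id = pdb_ids[i],
                                    number_offset = offset, seed = seed + i)
    pdb <- plant_modulator(pdb, pocket_auth, chain = "A", alias = "LIG")
    structures[pdb_ids[i]] <- paste(pdb, collapse = "\n")
    if (has_defect("mmcif_only", i))
      structures[pdb_ids[i]] <- paste0("data_", pdb_ids[i],
        "\nloop_\n_atom_site.group_PDB\n_atom_site.id\nATOM 1\n")

    acc_in_map <- if (has_defect("id_discrepancy", i)) "P99999" else accessions[i]
    chain_maps[[pdb_ids[i]]] <- c(A = acc_in_map)
    xml_pdb_id <- pdb_ids[i]
    if (has_defect("obsolete_pdb", i)) {
      xml_pdb_id <- sprintf("O%03d", i)
      pdb_map[xml_pdb_id] <- pdb_ids[i]
    }
    if (has_defect("pdb_removed", i)) {
      xml_pdb_id <- sprintf("X%03d", i)
      pdb_map[xml_pdb_id] <- NA_character_
    }
    # first-triggered reason under the pipeline's stage order
    expected_reason[i] <-
      if (has_defect("pdb_removed", i)) "pdb_removed"
      else if (has_defect("id_discrepancy", i)) "id_discrepancy"
      else if (has_defect("mmcif_only", i)) "mmcif_only"
      else if (has_defect("missing_site", i)) "incomplete_annotation"
      else if (has_defect("low_resolution", i)) "resolution"
      else ""

    site_el <- if (has_defect("missing_site", i)) "" else
      sprintf('  <allosteric_site residues="%s"/>\n',
              paste(sprintf("A:%d", pocket_auth), collapse = ";"))
    xml[entry_ids[i]] <- paste0(
      '<allosteric_entry id="', entry_ids[i], '">\n',
      "  <pdb_id>", xml_pdb_id, "</pdb_id>\n",
      "  <uniprot><accession>", accessions[i], "</accession></uniprot>\n",
      site_el,
      '  <modulator alias="LIG" class="', mclass, '"/>\n',
      "</allosteric_entry>\n")
    expected_pocket[[entry_ids[i]]] <- sort_res_tokens(res_token("A", pocket_auth))
  }

  base_seq <- paste(rep(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]],
                        length.out = n_residues), collapse = "")
  structure(list(
    xml = xml, structures = structures,
    resolver = fixture_resolver(pdb_map, chain_maps),
    uniprot_sites = data.frame(accession = rep(accessions,
                                               each = length(active_uni)),
                               position = rep(active_uni, n),
                               stringsAsFactors = FALSE),
    mcsa_sites = data.frame(accession = rep(accessions,
                                            each = length(active_mcsa)),
                            position = rep(active_mcsa, n),
                            stringsAsFactors = FALSE),
    canonical_seqs = setNames(rep(base_seq, n), accessions),
    clusters = cluster_table(accessions, sprintf("UR50_C%03d", seq_len(n))),
    expected = list(drop_reason = expected_reason,
                    pocket = expected_pocket)),
    class = "allobench_corpus")
}

#' Write a corpus to disk in the pipeline's input formats
#'
#' Emits \code{xml/<entry>.xml}, \code{structures/<pdb>.pdb} (or
#' \code{.cif}), \code{pdb_map.tsv}, \code{chain_map.tsv},
#' \code{active_sites_uniprot.tsv}, \code{active_sites_mcsa.tsv},
#' \code{clusters.tsv} and \code{sequences.fasta}.
#'
#' @param corpus an \code{allobench_corpus}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "allobench_corpus"))
  dir.create(file.path(dir, "xml"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "structures"), showWarnings = FALSE)
  for (id in names(corpus$xml))
    writeLines(corpus$xml[[id]], file.path(dir, "xml", paste0(id, ".xml")))
  for (pid in names(corpus$structures)) {
    txt <- corpus$structures[[pid]]
    ext <- if (startsWith(txt, "data_")) ".cif" else ".pdb"
    writeLines(txt, file.path(dir, "structures", paste0(pid, ext)))
  }
  pm <- corpus$resolver$pdb_map
  write.table(data.frame(old_id = names(pm),
                         current_id = ifelse(is.na(pm), "", pm)),
              file.path(dir, "pdb_map.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cm <- do.call(rbind, lapply(names(corpus$resolver$chain_maps), function(p)
    data.frame(pdb_id = p, chain = names(corpus$resolver$chain_maps[[p]]),
               accession = unname(corpus$resolver$chain_maps[[p]]))))
  write.table(cm, file.path(dir, "chain_map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(corpus$uniprot_sites,
              file.path(dir, "active_sites_uniprot.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(corpus$mcsa_sites, file.path(dir, "active_sites_mcsa.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(accession = names(unclass(corpus$clusters)),
                         cluster_id = unname(unclass(corpus$clusters))),
              file.path(dir, "clusters.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  fasta <- unlist(lapply(names(corpus$canonical_seqs), function(a)
    c(paste0(">", a), corpus$canonical_seqs[[a]])))
  writeLines(fasta, file.path(dir, "sequences.fasta"))
  invisible(dir)
}

#' Read a corpus directory written by \code{\link{write_corpus}}
#'
#' @param dir corpus directory.
#' @return an \code{allobench_corpus} (without the \code{expected} ground
#'   truth, which only the in-memory generator knows).
#' @export
read_corpus <- function(dir) {
  xml_files <- sort(list.files(file.path(dir, "xml"), pattern = "\\.xml$",
                               full.names = TRUE))
  xml <- setNames(vapply(xml_files, function(f)
    paste(readLines(f, warn = FALSE), collapse = "\n"), character(1)),
    sub("\\.xml$", "", basename(xml_files)))
  st_files <- sort(list.files(file.path(dir, "structures"),
                              pattern = "\\.(pdb|cif)$", full.names = TRUE))
  structures <- setNames(vapply(st_files, function(f)
    paste(readLines(f, warn = FALSE), collapse = "\n"), character(1)),
    sub("\\.(pdb|cif)$", "", basename(st_files)))
  resolver <- read_fixture_resolver(file.path(dir, "pdb_map.tsv"),
                                    file.path(dir, "chain_map.tsv"))
  fasta <- readLines(file.path(dir, "sequences.fasta"), warn = FALSE)
  hdr <- grep("^>", fasta)
  seqs <- setNames(vapply(seq_along(hdr), function(k) {
    to <- if (k < length(hdr)) hdr[k + 1L] - 1L else length(fasta)
    paste(fasta[(hdr[k] + 1L):to], collapse = "")
  }, character(1)), sub("^>", "", fasta[hdr]))
  structure(list(
    xml = xml, structures = structures, resolver = resolver,
    uniprot_sites = read.delim(file.path(dir, "active_sites_uniprot.tsv")),
    mcsa_sites = read.delim(file.path(dir, "active_sites_mcsa.tsv")),
    canonical_seqs = seqs,
    clusters = read_cluster_table(file.path(dir, "clusters.tsv")),
    expected = NULL), class = "allobench_corpus")
}
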