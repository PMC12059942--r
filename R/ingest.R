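#' ASD-like XML schema
#'
#' The curated-annotation XML files are read against a configurable schema
#' (XPath expressions), since element naming varies between database dumps.
#' The default schema matches the fixture corpus shipped with the package:
#'
#' \preformatted{
#' <allosteric_entry id="ASD001">
#'   <pdb_id>1ABC</pdb_id>
#'   <uniprot><accession>P00001</accession></uniprot>
#'   <allosteric_site residues="A:10;A:11"/>
#'   <modulator alias="ATP" class="small_molecule"/>
#' </allosteric_entry>
#' }
#'
#' @param root root element name.
#' @param id_attr attribute of the root carrying the entry id.
#' @param pdb,accession,site,modulator XPaths relative to the root.
#' @param site_attr,alias_attr,class_attr attribute names.
#' @return a named list describing the schema.
#' @export
asd_schema <- function(root = "allosteric_entry", id_attr = "id",
                       pdb = "./pdb_id", accession = ".//uniprot/accession",
                       site = "./allosteric_site", site_attr = "residues",
                       modulator = "./modulator", alias_attr = "alias",
                       class_attr = "class") {
  list(root = root, id_attr = id_attr, pdb = pdb, accession = accession,
       site = site, site_attr = site_attr, modulator = modulator,
       alias_attr = alias_attr, class_attr = class_attr)
}

#' Parse one ASD-style XML entry
#'
#' Extracts the entry id, PDB id, accessions, the raw allosteric-site
#' residue text (retained verbatim for later parsing), and the modulator
#' alias and class.  An entry lacking the allosteric-site element is flagged
#' \code{missing_site}, not dropped here.
#'
#' @param x path to an XML file or an XML string.
#' @param schema element/attribute naming, see \code{\link{asd_schema}}.
#' @return an object of class \code{raw_asd_entry}: a list with
#'   \code{entry_id}, \code{pdb_id}, \code{accessions},
#'   \code{allosteric_residue_text}, \code{modulator_alias},
#'   \code{modulator_class}, \code{flags}, \code{status}, \code{drop_reason}.
#' @export
parse_asd_xml <- function(x, schema = asd_schema()) {
  doc <- tryCatch(xml2::read_xml(x), error = function(e)
    stop("malformed XML (", if (file.exists(x[1])) x else "<string>", "): ",
         conditionMessage(e)))
  root <- xml2::xml_find_first(doc, paste0("//", schema$root))
  if (inherits(root, "xml_missing"))
    stop("XML does not contain a <", schema$root, "> element")
  entry_id <- xml2::xml_attr(root, schema$id_attr)
  pdb_id <- xml2::xml_text(xml2::xml_find_first(root, schema$pdb))
  accessions <- xml2::xml_text(xml2::xml_find_all(root, schema$accession))
  flags <- character()
  site_node <- xml2::xml_find_first(root, schema$site)
  if (inherits(site_node, "xml_missing")) {
    site_text <- ""
    flags <- c(flags, "missing_site")
  } else {
    site_text <- xml2::xml_attr(site_node, schema$site_attr)
    if (is.na(site_text)) site_text <- xml2::xml_text(site_node)
    if (!nzchar(trimws(site_text))) flags <- c(flags, "missing_site")
  }
  mod_node <- xml2::xml_find_first(root, schema$modulator)
  alias <- ""; mclass <- "unknown"
  if (!inherits(mod_node, "xml_missing")) {
    alias <- xml2::xml_attr(mod_node, schema$alias_attr)
    if (is.na(alias)) alias <- ""
    cl <- xml2::xml_attr(mod_node, schema$class_attr)
    if (!is.na(cl) && cl %in% .modulator_classes) mclass <- cl
  }
  structure(list(entry_id = entry_id, pdb_id = toupper(trimws(pdb_id)),
                 accessions = trimws(accessions),
                 allosteric_residue_text = trimws(site_text),
                 modulator_alias = toupper(alias), modulator_class = mclass,
                 flags = flags, status = "kept", drop_reason = ""),
            class = "raw_asd_entry")
}

#' @rdname parse_asd_xml
#' @param paths character vector of XML file paths, or a directory (all
#'   \code{*.xml} files in it are read, sorted).
#' @return \code{parse_asd_batch}: a list of \code{raw_asd_entry}, one per
#'   file; duplicated entry ids are an error.
#' @export
parse_asd_batch <- function(paths, schema = asd_schema()) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- sort(list.files(paths, pattern = "\\.xml$", full.names = TRUE))
  entries <- lapply(paths, parse_asd_xml, schema = schema)
  ids <- vapply(entries, `[[`, character(1), "entry_id")
  if (anyDuplicated(ids))
    stop("duplicate entry id(s) in batch: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  entries
}

#' Identifier resolver with a static fixture backend
#'
#' Abstracts the look-ups needed to reconcile identifiers: superseded PDB id
#' to current id, PDB id to chain-to-accession map, and obsolete accession
#' to current accession.  The fixture backend is built from static tables so
#' every look-up is deterministic and reproducible; a live backend can
#' implement the same three functions against web APIs.
#'
#' Resolution rule for \code{resolve_pdb}: an id present in \code{pdb_map}
#' resolves to its mapped value (\code{NA} meaning removed from the archive);
#' an id with a chain map is current and resolves to itself; anything else
#' is treated as removed.
#'
#' @param pdb_map named character vector old_id -> current_id (value
#'   \code{NA} = removed).
#' @param chain_maps named list: pdb_id -> named character vector
#'   chain -> accession.
#' @param accession_map named character vector old -> current accession.
#' @return an object of class \code{id_resolver}.
#' @export
fixture_resolver <- function(pdb_map = character(), chain_maps = list(),
                             accession_map = character()) {
  structure(list(pdb_map = pdb_map, chain_maps = chain_maps,
                 accession_map = accession_map), class = "id_resolver")
}

#' @rdname fixture_resolver
#' @param resolver an \code{id_resolver}.
#' @param pdb_id a PDB id.
#' @return \code{resolve_pdb}: the current id, or \code{NA} if removed.
#' @export
resolve_pdb <- function(resolver, pdb_id) {
  stopifnot(inherits(resolver, "id_resolver"))
  if (pdb_id %in% names(resolver$pdb_map)) {
    cur <- unname(resolver$pdb_map[[pdb_id]])
    return(if (is.na(cur)) NA_character_ else cur)
  }
  if (pdb_id %in% names(resolver$chain_maps)) return(pdb_id)
  NA_character_
}

#' @rdname fixture_resolver
#' @return \code{chain_map}: named character vector chain -> accession
#'   (empty when unknown).
#' @export
chain_map <- function(resolver, pdb_id) {
  stopifnot(inherits(resolver, "id_resolver"))
  cm <- resolver$chain_maps[[pdb_id]]
  if (is.null(cm)) character() else cm
}

#' @rdname fixture_resolver
#' @param accession a UniProt-style accession.
#' @return \code{resolve_accession}: the current accession (an unknown
#'   accession passes through unchanged).
#' @export
resolve_accession <- function(resolver, accession) {
  stopifnot(inherits(resolver, "id_resolver"))
  if (accession %in% names(resolver$accession_map))
    unname(resolver$accession_map[[accession]])
  else accession
}

#' Read a fixture resolver from TSV tables
#'
#' @param pdb_map_tsv TSV with columns \code{old_id}, \code{current_id}
#'   (empty current_id = removed).
#' @param chain_map_tsv TSV with columns \code{pdb_id}, \code{chain},
#'   \code{accession}.
#' @param accession_map_tsv optional TSV with columns \code{old},
#'   \code{current}.
#' @return an \code{id_resolver}.
#' @export
read_fixture_resolver <- function(pdb_map_tsv, chain_map_tsv,
                                  accession_map_tsv = NULL) {
  pm <- read.delim(pdb_map_tsv, colClasses = "character")
  pdb_map <- setNames(ifelse(nzchar(pm$current_id), pm$current_id, NA),
                      pm$old_id)
  cm <- read.delim(chain_map_tsv, colClasses = "character")
  chain_maps <- lapply(split(cm, cm$pdb_id), function(g)
    setNames(g$accession, g$chain))
  acc_map <- character()
  if (!is.null(accession_map_tsv)) {
    am <- read.delim(accession_map_tsv, colClasses = "character")
    acc_map <- setNames(am$current, am$old)
  }
  fixture_resolver(pdb_map, chain_maps, acc_map)
}

#' Reconcile the identifiers of a raw entry
#'
#' Replaces a superseded PDB id by its current id, drops entries whose
#' structure is no longer in the archive (reason \code{pdb_removed}),
#' updates accessions, and drops entries none of whose accessions occurs in
#' the structure's chain-to-accession map (reason \code{id_discrepancy}).
#' Idempotent for a fixed resolver.
#'
#' @param entry a \code{raw_asd_entry}.
#' @param resolver an \code{id_resolver}.
#' @return the updated \code{raw_asd_entry}, possibly with
#'   \code{status = "dropped"}.
#' @export
reconcile_identifiers <- function(entry, resolver) {
  stopifnot(inherits(entry, "raw_asd_entry"))
  if (entry$status == "dropped") return(entry)
  cur <- resolve_pdb(resolver, entry$pdb_id)
  if (is.na(cur)) {
    entry$status <- "dropped"; entry$drop_reason <- "pdb_removed"
    return(entry)
  }
  if (!identical(cur, entry$pdb_id)) {
    entry$flags <- union(entry$flags, "pdb_id_updated")
    entry$pdb_id <- cur
  }
  entry$accessions <- vapply(entry$accessions, resolve_accession,
                             character(1), resolver = resolver,
                             USE.NAMES = FALSE)
  cm <- chain_map(resolver, entry$pdb_id)
  if (!any(entry$accessions %in% cm)) {
    entry$status <- "dropped"; entry$drop_reason <- "id_discrepancy"
  }
  entry
}

#' Merge active-site annotations from two sources
#'
#' Positions are 1-based positions in the canonical sequence.  The merge is
#' the per-accession set union of both sources (the conservative choice:
#' catalytic-site atlases cover few proteins, so intersection would discard
#' most annotations), with per-position provenance retained.  Commutative
#' and idempotent.
#'
#' @param uniprot_records,mcsa_records data.frames with columns
#'   \code{accession} and \code{position} (an optional \code{source} column
#'   is honoured; otherwise \code{"UniProt"} / \code{"MCSA"} is assumed).
#' @return data.frame with columns \code{accession}, \code{position},
#'   \code{sources} (semicolon-joined, sorted), sorted by accession then
#'   position.
#' @export
merge_active_sites <- function(uniprot_records, mcsa_records) {
  tag <- function(df, default_source) {
    if (is.null(df) || nrow(df) == 0L)
      return(data.frame(accession = character(), position = integer(),
                        source = character(), stringsAsFactors = FALSE))
    stopifnot(all(c("accession", "position") %in% names(df)))
    if (is.null(df$source)) df$source <- default_source
    df[, c("accession", "position", "source")]
  }
  all_rows <- rbind(tag(uniprot_records, "UniProt"), tag(mcsa_records, "MCSA"))
  if (nrow(all_rows) == 0L)
    return(data.frame(accession = character(), position = integer(),
                      sources = character(), stringsAsFactors = FALSE))
  key <- paste(all_rows$accession, all_rows$position, sep = "\r")
  srcs <- vapply(split(all_rows$source, key), function(s)
    paste(sort(unique(s)), collapse = ";"), character(1))
  uniq <- all_rows[!duplicated(key), c("accession", "position")]
  uniq$sources <- unname(srcs[paste(uniq$accession, uniq$position, sep = "\r")])
  uniq <- uniq[order(uniq$accession, uniq$position), , drop = FALSE]
  rownames(uniq) <- NULL
  uniq$position <- as.integer(uniq$position)
  uniq
}

#' @rdname merge_active_sites
#' @param merged output of \code{merge_active_sites}.
#' @param accession accession to query.
#' @return \code{active_site_positions}: sorted integer positions.
#' @export
active_site_positions <- function(merged, accession) {
  sort(merged$position[merged$accession == accession])
}

#' Parse ASD allosteric-site residue text
#'
#' Accepts both the \code{"chain:number"} dialect and bare residue numbers.
#' Bare numbers are assigned to \code{default_chain} when the entry
#' annotates a single chain; with several candidate chains the entry is
#' flagged ambiguous instead of guessing.
#'
#' @param text raw residue text, tokens separated by \code{";"} or
#'   \code{","}.
#' @param default_chain chain for bare-number tokens (character vector of
#'   the entry's annotated chains).
#' @return list with \code{residues} (character tokens) and \code{flags}.
#' @export
parse_site_text <- function(text, default_chain = "A") {
  toks <- trimws(strsplit(text, "[;,]")[[1L]])
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0L) return(list(residues = character(), flags = "empty_site_text"))
  flags <- character()
  bare <- grepl("^-?[0-9]+[A-Za-z]?$", toks)
  if (any(bare)) {
    if (length(default_chain) != 1L) {
      return(list(residues = character(),
                  flags = "ambiguous_chain_assignment"))
    }
    toks[bare] <- paste0(default_chain, ":", toks[bare])
  }
  parsed <- tryCatch(parse_res_tokens(toks), error = function(e) NULL)
  if (is.null(parsed))
    return(list(residues = character(), flags = "unparseable_site_text"))
  list(residues = sort_res_tokens(toks), flags = flags)
}

#' Partition entries by a predicate
#'
#' Shared helper for all filter stages: entries failing the predicate are
#' marked dropped with \code{reason}; the union of \code{kept} and
#' \code{dropped} is always exactly the input (no silent loss).
#'
#' @param entries list of \code{\link{allosteric_entry}}.
#' @param keep_fun predicate taking an entry, returning \code{TRUE} to keep.
#' @param reason drop reason applied to failing entries.
#' @return list with \code{kept} and \code{dropped} entry lists.
#' @export
partition_entries <- function(entries, keep_fun, reason) {
  keep <- vapply(entries, function(e) isTRUE(keep_fun(e)), logical(1))
  list(kept = entries[keep],
       dropped = lapply(entries[!keep], drop_entry, reason = reason))
}

#' Select entries with complete annotation
#'
#' Kept entries carry at least one non-empty allosteric site and at least
#' one non-empty active site mapped onto the structure numbering; the rest
#' are dropped with reason \code{incomplete_annotation}.
#'
#' @param entries list of \code{\link{allosteric_entry}}.
#' @return list with \code{kept} and \code{dropped}.
#' @export
select_complete_entries <- function(entries) {
  partition_entries(entries, function(e) {
    length(e$allosteric_sites) >= 1L && length(e$active_sites) >= 1L &&
      all(vapply(e$allosteric_sites, function(s) length(s$residues) > 0L,
                 logical(1))) &&
      any(vapply(e$active_sites, function(s) length(s$residues) > 0L,
                 logical(1)))
  }, "incomplete_annotation")
}

#' Resolution filter
#'
#' Keeps entries whose structure is resolved strictly better than
#' \code{cutoff} (a structure at exactly the cutoff is dropped).  Structures
#' without a resolution record (e.g. NMR ensembles) are kept and flagged
#' \code{no_resolution}, since "better than" can only exclude structures
#' whose resolution was measured; the flag lets users exclude them.
#'
#' @param entries list of \code{\link{allosteric_entry}}.
#' @param cutoff resolution cutoff in Angstrom (default 4.0).
#' @return list with \code{kept} and \code{dropped} (reason
#'   \code{resolution}).
#' @export
filter_resolution <- function(entries, cutoff = 4.0) {
  entries <- lapply(entries, function(e) {
    if (is.na(e$resolution)) e$flags <- union(e$flags, "no_resolution")
    e
  })
  partition_entries(entries, function(e)
    is.na(e$resolution) || e$resolution < cutoff, "resolution")
}
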