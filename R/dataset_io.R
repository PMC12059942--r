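#' Tabular dataset output
#'
#' The curated dataset is serialized as CSV with one row per
#' (entry, allosteric site): an entry with two allosteric sites occupies two
#' rows whose entry-level columns repeat.  Dropped entries occupy one row
#' with empty site columns and their drop reason.  Residue sets are
#' semicolon-joined \code{"chain:number[icode]"} tokens in canonical sort
#' order; active sites are serialized as \code{"SOURCE=tok;tok"} groups
#' joined by \code{"|"}.  The first line of the file is the schema marker
#' \code{# allobench-dataset-v1}.
#'
#' @param entries list of \code{\link{allosteric_entry}}.
#' @param path output path.
#' @return \code{write_dataset_csv}: the number of data rows written,
#'   invisibly.
#' @seealso \code{\link{read_dataset_csv}}
#' @export
write_dataset_csv <- function(entries, path) {
  for (e in entries) validate_entry(e)
  rows <- lapply(entries, entry_to_rows)
  df <- do.call(rbind, c(rows, list(empty_dataset_rows())))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.dataset_schema_tag, con)
  write.csv(df, con, row.names = FALSE)
  invisible(nrow(df))
}

.dataset_schema_tag <- "# allobench-dataset-v1"

.dataset_columns <- c("entry_id", "pdb_id", "accessions", "site_index",
                      "allosteric_residues", "modulator_alias",
                      "modulator_class", "allosteric_source", "active_sites",
                      "resolution", "method", "oligomeric_state", "status",
                      "drop_reason", "lddt", "n_protein_residues",
                      "has_nucleic", "flags")

empty_dataset_rows <- function() {
  df <- data.frame(entry_id = character(), pdb_id = character(),
                   accessions = character(), site_index = integer(),
                   allosteric_residues = character(),
                   modulator_alias = character(),
                   modulator_class = character(),
                   allosteric_source = character(), active_sites = character(),
                   resolution = numeric(), method = character(),
                   oligomeric_state = character(), status = character(),
                   drop_reason = character(), lddt = numeric(),
                   n_protein_residues = integer(), has_nucleic = logical(),
                   flags = character(), stringsAsFactors = FALSE)
  df[, .dataset_columns]
}

serialize_active_sites <- function(sites) {
  paste(vapply(sites, function(s)
    paste0(s$source, "=", paste(s$residues, collapse = ";")), character(1)),
    collapse = "|")
}

entry_to_rows <- function(e) {
  n_sites <- length(e$allosteric_sites)
  idx <- if (n_sites == 0L) 0L else seq_len(n_sites)
  base <- data.frame(
    entry_id = e$entry_id, pdb_id = e$pdb_id,
    accessions = paste(e$accessions, collapse = ";"),
    site_index = idx,
    allosteric_residues = "", modulator_alias = "",
    modulator_class = "", allosteric_source = "",
    active_sites = serialize_active_sites(e$active_sites),
    resolution = e$resolution, method = e$method,
    oligomeric_state = e$oligomeric_state, status = e$status,
    drop_reason = e$drop_reason, lddt = e$lddt,
    n_protein_residues = e$n_protein_residues,
    has_nucleic = e$has_nucleic,
    flags = paste(e$flags, collapse = "|"),
    stringsAsFactors = FALSE)
  for (k in seq_len(n_sites)) {
    s <- e$allosteric_sites[[k]]
    base$allosteric_residues[k] <- paste(s$residues, collapse = ";")
    base$modulator_alias[k] <- s$modulator_alias
    base$modulator_class[k] <- s$modulator_class
    base$allosteric_source[k] <- s$source
  }
  base
}

#' Read a curated dataset CSV
#'
#' Inverse of \code{\link{write_dataset_csv}}: reconstructs the entry list,
#' validating the schema (an unknown or missing column is an error naming the
#' column) and the entry invariants (a kept row with an empty residue set is
#' an error).
#'
#' @param path path to a file written by \code{\link{write_dataset_csv}} or
#'   matching its documented schema.
#' @return a list of \code{\link{allosteric_entry}}.
#' @export
read_dataset_csv <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!identical(first, .dataset_schema_tag))
    warning("missing schema marker '", .dataset_schema_tag,
            "'; attempting to read anyway")
  df <- read.csv(path, comment.char = "#", colClasses = "character")
  missing <- setdiff(.dataset_columns, names(df))
  if (length(missing))
    stop("dataset schema mismatch: missing column(s) ",
         paste(missing, collapse = ", "))
  if (nrow(df) == 0L) return(list())
  split_semi <- function(x) {
    out <- strsplit(x, ";", fixed = TRUE)[[1L]]
    out[nzchar(out)]
  }
  entries <- lapply(split(df, factor(df$entry_id, levels = unique(df$entry_id))),
                    function(g) {
    first_row <- g[1L, ]
    active <- list()
    if (nzchar(first_row$active_sites)) {
      groups <- strsplit(first_row$active_sites, "|", fixed = TRUE)[[1L]]
      active <- lapply(groups, function(grp) {
        kvp <- strsplit(grp, "=", fixed = TRUE)[[1L]]
        if (length(kvp) != 2L)
          stop("dataset parse error in column active_sites: ", grp)
        site_annotation("active", split_semi(kvp[2L]), source = kvp[1L])
      })
    }
    allo <- list()
    for (k in seq_len(nrow(g))) {
      if (g$site_index[k] == "0") next
      toks <- split_semi(g$allosteric_residues[k])
      if (length(toks) == 0L && g$status[k] == "kept")
        stop("dataset validation error: kept row for entry ", g$entry_id[k],
             " has an empty allosteric_residues cell")
      if (length(toks) == 0L) next
      allo[[length(allo) + 1L]] <- site_annotation(
        "allosteric", toks, modulator_alias = g$modulator_alias[k],
        modulator_class = g$modulator_class[k],
        source = g$allosteric_source[k])
    }
    allosteric_entry(
      entry_id = first_row$entry_id, pdb_id = first_row$pdb_id,
      accessions = split_semi(first_row$accessions),
      allosteric_sites = allo, active_sites = active,
      resolution = as.numeric(first_row$resolution),
      method = first_row$method,
      oligomeric_state = first_row$oligomeric_state,
      status = first_row$status, drop_reason = first_row$drop_reason,
      lddt = as.numeric(first_row$lddt),
      n_protein_residues = as.integer(first_row$n_protein_residues),
      has_nucleic = as.logical(first_row$has_nucleic),
      flags = {
        f <- strsplit(first_row$flags, "|", fixed = TRUE)[[1L]]
        f[nzchar(f)]
      })
  })
  names(entries) <- NULL
  entries
}
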