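#' Residue references and sites
#'
#' A residue in author numbering is identified by the triple
#' (chain, number, insertion code); the 3-letter residue name is advisory and
#' never used for identity.  Residue sets are represented throughout the
#' package as character vectors of canonical tokens
#' \code{"chain:number[icode]"} (e.g. \code{"A:10"}, \code{"B:52A"}), which
#' makes set operations (intersection, union, Jaccard index) plain vector
#' operations and serialization deterministic.
#'
#' @param chain chain identifier(s), non-empty strings.
#' @param number author residue number(s), integer.
#' @param icode insertion code(s), single characters or \code{""}.
#' @return \code{res_token}: a character vector of tokens.
#' @export
#' @examples
#' res_token("A", c(10, 34))
#' parse_res_tokens(c("A:10", "B:52A"))
res_token <- function(chain, number, icode = "") {
  chain <- as.character(chain)
  if (any(!nzchar(chain) | is.na(chain))) stop("chain_id must be non-empty")
  icode <- ifelse(is.na(icode), "", as.character(icode))
  paste0(chain, ":", as.integer(number), icode)
}

#' @rdname res_token
#' @param tokens character vector of \code{"chain:number[icode]"} tokens.
#' @return \code{parse_res_tokens}: a data.frame with columns \code{chain},
#'   \code{number}, \code{icode}.
#' @export
parse_res_tokens <- function(tokens) {
  if (length(tokens) == 0L)
    return(data.frame(chain = character(), number = integer(),
                      icode = character(), stringsAsFactors = FALSE))
  m <- regmatches(tokens, regexec("^(.+):(-?[0-9]+)([A-Za-z]?)$", tokens))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad))
    stop("unparseable residue token(s): ",
         paste(utils::head(tokens[bad], 5), collapse = ", "))
  data.frame(chain = vapply(m, `[`, character(1), 2L),
             number = as.integer(vapply(m, `[`, character(1), 3L)),
             icode = vapply(m, `[`, character(1), 4L),
             stringsAsFactors = FALSE)
}

#' Canonical ordering for residue tokens
#'
#' Tokens are sorted lexicographically (C locale) so that serialized residue
#' sets diff deterministically.
#'
#' @param tokens character vector of residue tokens.
#' @return the sorted, de-duplicated vector.
#' @export
sort_res_tokens <- function(tokens) {
  sort(unique(tokens), method = "radix")
}

.modulator_classes <- c("small_molecule", "ion", "peptide", "other", "unknown")
.site_sources <- c("ASD", "UniProt", "MCSA", "derived_geometric")

#' Site annotations
#'
#' A site annotation is a non-empty set of residues with a kind (allosteric
#' or active), the chemical-component alias and class of the bound modulator
#' (allosteric sites only), and a provenance tag.
#'
#' @param kind \code{"allosteric"} or \code{"active"}.
#' @param residues character vector of residue tokens (see
#'   \code{\link{res_token}}); must be non-empty.
#' @param modulator_alias chemical-component ID of the modulator, or
#'   \code{""}; must be empty for active sites.
#' @param modulator_class one of \code{small_molecule}, \code{ion},
#'   \code{peptide}, \code{other}, \code{unknown}.
#' @param source provenance: \code{ASD}, \code{UniProt}, \code{MCSA} or
#'   \code{derived_geometric}.
#' @return an object of class \code{site_annotation}.
#' @export
site_annotation <- function(kind, residues, modulator_alias = "",
                            modulator_class = "unknown", source = "ASD") {
  kind <- match.arg(kind, c("allosteric", "active"))
  modulator_class <- match.arg(modulator_class, .modulator_classes)
  source <- match.arg(source, .site_sources)
  residues <- sort_res_tokens(residues)
  if (length(residues) == 0L) stop("site has no residues")
  parse_res_tokens(residues)  # validates token syntax
  if (kind == "active" && nzchar(modulator_alias))
    stop("active sites carry no modulator alias")
  structure(list(kind = kind, residues = residues,
                 modulator_alias = modulator_alias,
                 modulator_class = modulator_class, source = source),
            class = "site_annotation")
}

#' Allosteric entries
#'
#' One curated record: an entry identifier, the structure it refers to, its
#' allosteric and active sites, structure metadata, and a keep/drop status
#' with reason.  Kept entries must carry at least one allosteric and one
#' active site; dropped entries must name their reason.
#'
#' @param entry_id unique entry identifier.
#' @param pdb_id 4-character PDB identifier.
#' @param accessions character vector of UniProt-style accessions.
#' @param allosteric_sites,active_sites lists of \code{\link{site_annotation}}.
#' @param resolution resolution in Angstrom, or \code{NA} (e.g. NMR).
#' @param method experimental method string.
#' @param oligomeric_state oligomeric state string.
#' @param status \code{"kept"} or \code{"dropped"}.
#' @param drop_reason reason string; non-empty iff dropped.
#' @param lddt global lDDT of the rebuilt model in [0, 1], or \code{NA} if
#'   the structure was never modeled.
#' @param n_protein_residues observed protein residue count (test-set size
#'   filter input), or \code{NA}.
#' @param has_nucleic whether any polymer chain contains nucleotide residues.
#' @param flags character vector of non-fatal audit flags.
#' @return an object of class \code{allosteric_entry}.
#' @export
allosteric_entry <- function(entry_id, pdb_id, accessions = character(),
                             allosteric_sites = list(), active_sites = list(),
                             resolution = NA_real_, method = "",
                             oligomeric_state = "", status = "kept",
                             drop_reason = "", lddt = NA_real_,
                             n_protein_residues = NA_integer_,
                             has_nucleic = FALSE, flags = character()) {
  status <- match.arg(status, c("kept", "dropped"))
  e <- structure(list(entry_id = entry_id, pdb_id = pdb_id,
                      accessions = as.character(accessions),
                      allosteric_sites = allosteric_sites,
                      active_sites = active_sites,
                      resolution = as.numeric(resolution), method = method,
                      oligomeric_state = oligomeric_state, status = status,
                      drop_reason = drop_reason, lddt = as.numeric(lddt),
                      n_protein_residues = as.integer(n_protein_residues),
                      has_nucleic = isTRUE(has_nucleic),
                      flags = as.character(flags)),
                 class = "allosteric_entry")
  validate_entry(e)
}

# unvalidated construction, for pipeline states upstream of the
# completeness filter (which is what establishes the kept-entry invariant)
new_entry <- function(...) {
  args <- list(...)
  defaults <- list(entry_id = "", pdb_id = "", accessions = character(),
                   allosteric_sites = list(), active_sites = list(),
                   resolution = NA_real_, method = "", oligomeric_state = "",
                   status = "kept", drop_reason = "", lddt = NA_real_,
                   n_protein_residues = NA_integer_, has_nucleic = FALSE,
                   flags = character())
  defaults[names(args)] <- args
  structure(defaults, class = "allosteric_entry")
}

#' @rdname allosteric_entry
#' @param e an \code{allosteric_entry}.
#' @return \code{validate_entry}: \code{e}, invisibly-checked, or an error.
#' @export
validate_entry <- function(e) {
  stopifnot(inherits(e, "allosteric_entry"))
  if ((e$status == "dropped") != nzchar(e$drop_reason))
    stop("entry ", e$entry_id,
         ": status 'dropped' and a non-empty drop_reason must coincide")
  if (e$status == "kept") {
    if (length(e$allosteric_sites) < 1L || length(e$active_sites) < 1L)
      stop("kept entry ", e$entry_id,
           " must have at least one allosteric and one active site")
  }
  ok <- vapply(c(e$allosteric_sites, e$active_sites), inherits, logical(1),
               "site_annotation")
  if (!all(ok)) stop("entry ", e$entry_id, ": sites must be site_annotation")
  if (!is.na(e$lddt) && (e$lddt < 0 || e$lddt > 1))
    stop("entry ", e$entry_id, ": lddt outside [0, 1]")
  e
}

#' Mark an entry as dropped
#'
#' @param e an \code{allosteric_entry}.
#' @param reason non-empty drop reason.
#' @return the dropped entry.
#' @export
drop_entry <- function(e, reason) {
  stopifnot(inherits(e, "allosteric_entry"), nzchar(reason))
  e$status <- "dropped"
  e$drop_reason <- reason
  e
}

#' Prediction records
#'
#' The output of an allosteric-site prediction tool for one protein: an
#' ordered list of predicted sites (highest-confidence first), each a residue
#' set with an optional score.  An empty \code{ranked_sites} list encodes a
#' tool failure and scores a Jaccard index of 0 downstream.
#'
#' @param tool tool name.
#' @param protein_id protein identifier matching the curated dataset.
#' @param ranked_sites list of lists with elements \code{residues} (character
#'   token vector) and optional \code{score}.
#' @return an object of class \code{prediction_record}.
#' @export
prediction_record <- function(tool, protein_id, ranked_sites = list()) {
  ranked_sites <- lapply(ranked_sites, function(s) {
    if (is.character(s)) s <- list(residues = s)
    if (is.null(s$score)) s$score <- NA_real_
    s$residues <- sort_res_tokens(s$residues)
    # tokens are either "chain:number[icode]" or bare numbers (tools that
    # omit chain ids; resolved later by chain inference)
    bare <- grepl("^-?[0-9]+[A-Za-z]?$", s$residues)
    parse_res_tokens(s$residues[!bare])
    s[c("residues", "score")]
  })
  structure(list(tool = tool, protein_id = protein_id,
                 ranked_sites = ranked_sites),
            class = "prediction_record")
}

#' @export
print.allosteric_entry <- function(x, ...) {
  cat(sprintf("<allosteric_entry %s pdb=%s status=%s%s allo=%d active=%d>\n",
              x$entry_id, x$pdb_id, x$status,
              if (nzchar(x$drop_reason)) paste0("(", x$drop_reason, ")") else "",
              length(x$allosteric_sites), length(x$active_sites)))
  invisible(x)
}

#' @export
print.site_annotation <- function(x, ...) {
  cat(sprintf("<site_annotation %s [%s] %d residues: %s>\n", x$kind, x$source,
              length(x$residues),
              paste(utils::head(x$residues, 6), collapse = ";")))
  invisible(x)
}
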