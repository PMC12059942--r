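# residues never accepted as modulators even when aliased: waters and
# common crystallization buffer components
.modulator_blocklist <- c("HOH", "DOD", "WAT", "GOL", "EDO", "PEG", "PG4",
                          "DMS", "SO4", "PO4", "ACT", "CIT", "TRS", "MES",
                          "EPE", "FMT", "MPD")

#' Locate the allosteric modulator in a structure
#'
#' Finds every hetero residue whose chemical-component code equals the
#' entry's modulator alias (case-insensitively).  Multimeric assemblies
#' typically contain one copy per protomer; each copy becomes its own
#' instance.  Waters and common buffer components are never accepted, even
#' if aliased.
#'
#' @param entry an \code{\link{allosteric_entry}} (or anything with a
#'   \code{modulator_alias} usable via \code{alias}).
#' @param s a \code{structure_model} with heteroatoms still present.
#' @param alias chemical-component code; defaults to the alias of the
#'   entry's first allosteric site.
#' @return a list of \code{modulator_instance} objects (possibly empty),
#'   each a list with \code{chem_comp_id}, \code{residue} (token) and
#'   \code{atoms} (data.frame atom, element, x, y, z).
#' @export
resolve_modulator <- function(entry = NULL, s, alias = NULL) {
  stopifnot(inherits(s, "structure_model"))
  if (is.null(alias)) {
    if (length(entry$allosteric_sites))
      alias <- entry$allosteric_sites[[1L]]$modulator_alias
    else alias <- entry$modulator_alias
  }
  if (is.null(alias) || !nzchar(alias)) stop("no_alias: empty modulator alias")
  alias <- toupper(alias)
  if (alias %in% .modulator_blocklist) return(list())
  at <- s$atoms[s$atoms$model == s$atoms$model[1L] & s$atoms$hetero &
                  toupper(s$atoms$resname) == alias, , drop = FALSE]
  if (nrow(at) == 0L) return(list())
  key <- paste(at$chain, at$resno, at$icode, sep = "\r")
  lapply(split(seq_len(nrow(at)), factor(key, levels = unique(key))),
         function(idx) {
    structure(list(chem_comp_id = alias,
                   residue = res_token(at$chain[idx[1L]], at$resno[idx[1L]],
                                       at$icode[idx[1L]]),
                   atoms = at[idx, c("atom", "element", "x", "y", "z"),
                              drop = FALSE]),
              class = "modulator_instance")
  })
}

# squared cross-distances between two coordinate matrices (rows = atoms)
cross_dist2 <- function(a, b) {
  outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
}

#' Extract the allosteric site around a modulator
#'
#' The allosteric site is the set of protein residues having at least one
#' heavy atom within \code{cutoff} (inclusive) of at least one heavy atom of
#' the modulator.  Hydrogens (rarely present in crystal structures) are
#' excluded on both sides; hetero residues and the modulator itself never
#' appear in the output.  Monotone in \code{cutoff}.
#'
#' @param s a \code{structure_model}.
#' @param mod a \code{modulator_instance} from
#'   \code{\link{resolve_modulator}}.
#' @param cutoff contact distance in Angstrom (default 4.0).
#' @return a character vector of residue tokens (canonical order).
#' @export
extract_site <- function(s, mod, cutoff = 4.0) {
  stopifnot(inherits(s, "structure_model"),
            inherits(mod, "modulator_instance"), cutoff >= 0)
  mod_at <- mod$atoms[!mod$atoms$element %in% c("H", "D"), , drop = FALSE]
  if (nrow(mod_at) == 0L) stop("modulator has no heavy atoms")
  poly <- is_polymer_atom(s) & s$atoms$model == s$atoms$model[1L] &
    !s$atoms$element %in% c("H", "D")
  at <- s$atoms[poly, , drop = FALSE]
  if (nrow(at) == 0L) stop("structure contains no protein atoms")
  d2 <- cross_dist2(as.matrix(at[, c("x", "y", "z")]),
                    as.matrix(mod_at[, c("x", "y", "z")]))
  near <- rowSums(d2 <= cutoff^2 + 1e-9) > 0L
  if (!any(near)) return(character())
  hits <- at[near, , drop = FALSE]
  sort_res_tokens(res_token(hits$chain, hits$resno, hits$icode))
}

#' Compare the database-listed site with the geometrically derived site
#'
#' The derived site (residues within the distance cutoff of the modulator)
#' is authoritative for the output dataset; the agreement with the
#' database-listed residue set is recorded for audit as a Jaccard index and
#' a verdict (\code{agree} when JI >= 0.5, else \code{discrepant}).
#'
#' @param asd_site residue tokens listed by the annotation database.
#' @param derived_site residue tokens from \code{\link{extract_site}}.
#' @param agree_ji JI at or above which the sites are deemed to agree.
#' @return list with \code{ji} and \code{verdict}.
#' @export
validate_site_agreement <- function(asd_site, derived_site, agree_ji = 0.5) {
  u <- length(union(asd_site, derived_site))
  ji <- if (u == 0L) 1 else length(intersect(asd_site, derived_site)) / u
  list(ji = ji, verdict = if (ji >= agree_ji) "agree" else "discrepant")
}
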