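#' Local Distance Difference Test (lDDT)
#'
#' Superposition-free model quality score.  All heavy-atom distances between
#' atoms of \emph{different} residues that are shorter than
#' \code{inclusion_radius} in the \emph{reference} define the distance set.
#' A distance is preserved at threshold t when the model contains both atoms
#' and the model distance differs from the reference distance by strictly
#' less than t; an atom absent from the model makes all its distances
#' non-preserved.  Each distance contributes the fraction of thresholds at
#' which it is preserved; a residue's score is the mean over the distances
#' it participates in, and the global score is the mean of per-residue
#' scores over residues with at least one reference distance.
#'
#' Atoms are matched between model and reference by (chain, author number,
#' insertion code, atom name), so no superposition is ever computed and the
#' score is exactly invariant under rigid motions of the model.
#' Stereochemistry checks of the full published protocol are intentionally
#' omitted: as a QC gate for template-copied coordinates, only distance
#' preservation is informative.
#'
#' @param reference,model \code{structure_model}s sharing a residue
#'   correspondence.
#' @param thresholds distance-difference thresholds in Angstrom (default
#'   0.5, 1, 2, 4).
#' @param inclusion_radius only reference distances below this (Angstrom)
#'   are scored (default 15).
#' @return an object of class \code{lddt_result}: list with
#'   \code{global_score}, \code{per_residue} (named numeric, residue
#'   tokens), \code{thresholds}, \code{inclusion_radius}.
#' @export
compute_lddt <- function(reference, model, thresholds = c(0.5, 1, 2, 4),
                         inclusion_radius = 15) {
  stopifnot(inherits(reference, "structure_model"),
            inherits(model, "structure_model"),
            all(thresholds > 0), inclusion_radius > 0)
  ref_at <- lddt_atoms(reference)
  mod_at <- lddt_atoms(model)
  if (nrow(ref_at) == 0L) stop("reference contains no heavy atoms")
  akey <- function(a) paste(a$chain, a$resno, a$icode, a$atom, sep = "\r")
  rkey <- function(a) res_token(a$chain, a$resno, a$icode)
  ref_res <- rkey(ref_at)
  if (!any(akey(ref_at) %in% akey(mod_at)))
    stop("no_correspondence: model and reference share no atoms")

  xyz <- as.matrix(ref_at[, c("x", "y", "z")])
  d_ref <- sqrt(pmax(cross_dist2(xyz, xyz), 0))
  pair <- which(upper.tri(d_ref) & d_ref < inclusion_radius &
                  outer(ref_res, ref_res, "!="), arr.ind = TRUE)
  if (nrow(pair) == 0L) stop("no reference distances within inclusion radius")

  midx <- match(akey(ref_at), akey(mod_at))
  mxyz <- as.matrix(mod_at[, c("x", "y", "z")])
  i <- pair[, 1L]; j <- pair[, 2L]
  both <- !is.na(midx[i]) & !is.na(midx[j])
  frac <- numeric(nrow(pair))
  if (any(both)) {
    dm <- sqrt(rowSums((mxyz[midx[i[both]], , drop = FALSE] -
                          mxyz[midx[j[both]], , drop = FALSE])^2))
    dd <- abs(dm - d_ref[cbind(i[both], j[both])])
    frac[both] <- rowMeans(outer(dd, thresholds, "<"))
  }
  res_ids <- unique(ref_res)
  contrib <- c(frac, frac)
  owner <- c(ref_res[i], ref_res[j])
  per_res <- vapply(split(contrib, factor(owner, levels = res_ids)), mean,
                    numeric(1))
  per_res <- per_res[!is.nan(per_res)]   # residues with no distances
  structure(list(global_score = mean(per_res), per_residue = per_res,
                 thresholds = thresholds,
                 inclusion_radius = inclusion_radius),
            class = "lddt_result")
}

lddt_atoms <- function(s) {
  sel <- is_polymer_atom(s) & s$atoms$model == s$atoms$model[1L] &
    !s$atoms$element %in% c("H", "D")
  s$atoms[sel, , drop = FALSE]
}

#' @export
print.lddt_result <- function(x, ...) {
  cat(sprintf("<lddt_result global=%.4f over %d residues (thresholds %s A, radius %g A)>\n",
              x$global_score, length(x$per_residue),
              paste(x$thresholds, collapse = "/"), x$inclusion_radius))
  invisible(x)
}

#' Write per-residue lDDT scores as TSV
#'
#' @param x an \code{lddt_result}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_lddt_tsv <- function(x, path) {
  df <- data.frame(residue = names(x$per_residue),
                   lddt = unname(x$per_residue))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gate entries on model quality
#'
#' Entries whose structure was rebuilt by the modeling engine (flag
#' \code{"modeled"}) are kept only when their global lDDT is at least
#' \code{min_lddt}; failing entries are dropped with reason
#' \code{low_lddt}.  Entries that were never modeled pass through
#' unchanged.  A modeled entry without a score is an error.
#'
#' @param entries list of \code{\link{allosteric_entry}}.
#' @param min_lddt threshold (default 0.8).
#' @return list with \code{kept} and \code{dropped}.
#' @export
qc_filter <- function(entries, min_lddt = 0.8) {
  for (e in entries)
    if ("modeled" %in% e$flags && is.na(e$lddt))
      stop("modeled entry ", e$entry_id, " carries no lDDT score")
  partition_entries(entries, function(e)
    !("modeled" %in% e$flags) || e$lddt >= min_lddt, "low_lddt")
}
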