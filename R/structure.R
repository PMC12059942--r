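#' Parse a PDB-format structure
#'
#' Reads coordinates (via \pkg{bio3d}), per-chain SEQRES sequences, the
#' crystallographic resolution (REMARK 2) and the model count (MODEL/ENDMDL)
#' into a \code{structure_model}.  HETATM records are flagged
#' \code{hetero}.  Alternate locations are reduced to one conformer per atom:
#' the highest occupancy wins, ties broken by altloc identifier.
#'
#' mmCIF input is not supported: it is detected and signalled as a condition
#' of class \code{allobench_mmcif} so the pipeline can drop the entry with
#' reason \code{"mmcif_only"}.
#'
#' @param x path to a PDB file, or PDB-format text (character vector of
#'   lines or a single string containing newlines).
#' @param pdb_id optional 4-character identifier; taken from the HEADER
#'   record when absent.
#' @param chain_accession optional named character vector mapping chain ids
#'   to UniProt-style accessions.
#' @return an object of class \code{structure_model}: a list with
#'   \code{pdb_id}, \code{resolution} (Angstrom or \code{NA}),
#'   \code{n_models}, \code{atoms} (data.frame: model, chain, resno, icode,
#'   resname, atom, element, x, y, z, occ, hetero), \code{seqres} (named
#'   list chain -> character vector of 3-letter codes) and
#'   \code{chain_accession}.
#' @export
parse_structure <- function(x, pdb_id = NULL, chain_accession = character()) {
  lines <- as_pdb_lines(x)
  if (looks_like_mmcif(lines)) {
    cond <- structure(
      class = c("allobench_mmcif", "error", "condition"),
      list(message = "structure is in mmCIF format (mmcif_only)",
           call = sys.call()))
    stop(cond)
  }
  if (!any(grepl("^(ATOM|HETATM)", lines)))
    stop("no coordinate records found; not a PDB-format structure")

  if (is.null(pdb_id)) {
    hdr <- grep("^HEADER", lines, value = TRUE)
    pdb_id <- if (length(hdr)) trimws(substr(hdr[1L], 63, 66)) else ""
  }
  res_line <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  resolution <- NA_real_
  if (length(res_line)) {
    m <- regmatches(res_line[1L],
                    regexec("RESOLUTION\\.\\s+([0-9.]+)\\s+ANGSTROM", res_line[1L]))[[1L]]
    if (length(m) == 2L) resolution <- as.numeric(m[2L])
  }
  n_models <- sum(grepl("^MODEL ", lines))
  if (n_models == 0L) n_models <- 1L

  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  pdb <- bio3d::read.pdb(tmp, multi = TRUE, rm.alt = FALSE, verbose = FALSE)

  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  keep <- resolve_altloc(at)
  at <- at[keep, , drop = FALSE]
  xyz <- pdb$xyz
  coord_cols <- as.vector(vapply(which(keep), function(k) (k - 1L) * 3L + 1:3,
                                 integer(3)))
  xyz <- xyz[, coord_cols, drop = FALSE]
  n_models_coord <- nrow(xyz)
  if (n_models_coord != n_models) n_models <- n_models_coord

  per_model <- lapply(seq_len(n_models), function(k) {
    co <- matrix(xyz[k, ], ncol = 3L, byrow = TRUE)
    data.frame(model = k, chain = at$chain, resno = at$resno,
               icode = at$insert, resname = at$resid, atom = at$elety,
               element = ifelse(is.na(at$elesy) | !nzchar(at$elesy),
                                guess_element(at$elety), at$elesy),
               x = co[, 1L], y = co[, 2L], z = co[, 3L], occ = at$o,
               hetero = at$type == "HETATM", stringsAsFactors = FALSE)
  })
  atoms <- do.call(rbind, per_model)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates in structure ", pdb_id)

  seqres <- list()
  if (length(pdb$seqres))
    seqres <- split(unname(pdb$seqres), names(pdb$seqres))

  structure(list(pdb_id = pdb_id, resolution = resolution,
                 n_models = n_models, atoms = atoms, seqres = seqres,
                 chain_accession = chain_accession),
            class = "structure_model")
}

as_pdb_lines <- function(x) {
  if (length(x) == 1L && file.exists(x) && !grepl("\n", x))
    return(readLines(x, warn = FALSE))
  if (length(x) == 1L && grepl("\n", x))
    return(strsplit(x, "\n", fixed = TRUE)[[1L]])
  as.character(x)
}

looks_like_mmcif <- function(lines) {
  head_lines <- utils::head(lines[nzchar(trimws(lines))], 50L)
  any(grepl("^data_", head_lines)) || any(grepl("^_atom_site\\.", head_lines)) ||
    any(grepl("^loop_", head_lines))
}

# one conformer per atom: highest occupancy, ties by altloc id
resolve_altloc <- function(at) {
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  keep <- rep(TRUE, nrow(at))
  dup_keys <- unique(key[duplicated(key)])
  for (k in dup_keys) {
    idx <- which(key == k)
    ord <- order(-at$o[idx], at$alt[idx])
    keep[idx[-ord[1L]]] <- FALSE
  }
  keep
}

guess_element <- function(atom_names) {
  e <- gsub("[^A-Za-z]", "", atom_names)
  ifelse(nchar(e) > 0, substr(e, 1L, 1L), "C")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model %s: %d model(s), %d chain(s), %d atoms, resolution %s A>\n",
              x$pdb_id, x$n_models, length(unique(x$atoms$chain)),
              nrow(x$atoms),
              if (is.na(x$resolution)) "NA" else format(x$resolution)))
  invisible(x)
}

# polymer atoms: non-hetero records, plus hetero records of nonstandard
# residues that are part of the chain's SEQRES (e.g. MSE); never waters
is_polymer_atom <- function(s) {
  in_seqres <- rep(FALSE, nrow(s$atoms))
  for (ch in names(s$seqres)) {
    sel <- s$atoms$chain == ch
    in_seqres[sel] <- s$atoms$resname[sel] %in% s$seqres[[ch]]
  }
  (!s$atoms$hetero | in_seqres) & !(s$atoms$resname %in% .water_names)
}

#' Observed residues of a structure
#'
#' The ordered list of polymer residues observed in the coordinates, one row
#' per residue, taken from the first model.  Hetero records whose residue
#' name appears in the chain's SEQRES (modified amino acids such as MSE)
#' count as polymer; waters never do.
#'
#' @param s a \code{structure_model}.
#' @param chain optional chain id to restrict to.
#' @return data.frame with columns \code{chain}, \code{number},
#'   \code{icode}, \code{name}.
#' @export
observed_residues <- function(s, chain = NULL) {
  at <- s$atoms[s$atoms$model == s$atoms$model[1L] & is_polymer_atom(s), ,
                drop = FALSE]
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  key <- !duplicated(paste(at$chain, at$resno, at$icode, sep = "\r"))
  data.frame(chain = at$chain[key], number = at$resno[key],
             icode = at$icode[key], name = at$resname[key],
             stringsAsFactors = FALSE)
}

#' Number of observed protein residues
#'
#' @param s a \code{structure_model}.
#' @return integer count of polymer residues over all chains.
#' @export
n_protein_residues <- function(s) nrow(observed_residues(s))

.nucleotide_names <- c("A", "C", "G", "U", "I", "DA", "DC", "DG", "DT", "DI")

#' Does the structure contain nucleic-acid polymer chains?
#'
#' Checks polymer (non-hetero) residues against the standard nucleotide
#' names; a lone modified nucleotide bound as a hetero ligand does not count.
#'
#' @param s a \code{structure_model}.
#' @return logical.
#' @export
has_nucleic_chains <- function(s) {
  any(observed_residues(s)$name %in% .nucleotide_names)
}

.chain_label_pool <- c(LETTERS,
                       as.vector(t(outer(LETTERS, LETTERS, paste0))))

#' Merge a multi-model structure into a single model
#'
#' Models are processed in file order; the chains of model 1 keep their
#' labels, and every chain of each later model is relabeled (chains in
#' alphabetical order) to the first unused label, drawn from A--Z and then
#' from two-letter codes AA--ZZ.  Per-atom coordinates are preserved
#' exactly, so the merged structure has the same total atom count as the
#' input had across all models.  SEQRES and accession maps are replicated
#' onto the relabeled chains.
#'
#' @param s a \code{structure_model}.
#' @return a \code{structure_model} with \code{n_models == 1}.
#' @export
merge_models <- function(s) {
  stopifnot(inherits(s, "structure_model"))
  if (s$n_models == 1L) return(s)
  used <- sort(unique(s$atoms$chain[s$atoms$model == 1L]))
  atoms_new <- s$atoms[s$atoms$model == 1L, , drop = FALSE]
  seqres_new <- s$seqres
  acc_new <- s$chain_accession
  for (k in 2:s$n_models) {
    blk <- s$atoms[s$atoms$model == k, , drop = FALSE]
    for (ch in sort(unique(blk$chain))) {
      avail <- setdiff(.chain_label_pool, used)
      if (length(avail) == 0L)
        stop("chain label space exhausted (more than ",
             length(.chain_label_pool), " chains)")
      new_lab <- avail[1L]
      used <- c(used, new_lab)
      sel <- blk$chain == ch
      blk$chain[sel] <- new_lab
      if (!is.null(s$seqres[[ch]])) seqres_new[[new_lab]] <- s$seqres[[ch]]
      if (ch %in% names(s$chain_accession))
        acc_new[new_lab] <- s$chain_accession[[ch]]
    }
    blk$model <- 1L
    atoms_new <- rbind(atoms_new, blk)
  }
  s$atoms <- atoms_new
  s$seqres <- seqres_new
  s$chain_accession <- acc_new
  s$n_models <- 1L
  s
}

.water_names <- c("HOH", "DOD", "WAT")

#' Strip heteroatoms from a structure
#'
#' Removes every hetero-flagged atom and all waters, and drops chains left
#' without atoms (e.g. chains consisting only of a ligand).  Nonstandard
#' amino acids that appear in SEQRES are part of the polymer and are kept.
#' Idempotent.
#'
#' @param s a \code{structure_model}.
#' @return a \code{structure_model} containing protein chains only.
#' @export
strip_heteroatoms <- function(s) {
  stopifnot(inherits(s, "structure_model"))
  s$atoms <- s$atoms[is_polymer_atom(s), , drop = FALSE]
  s$atoms$hetero <- FALSE
  left <- unique(s$atoms$chain)
  s$seqres <- s$seqres[names(s$seqres) %in% left]
  s$chain_accession <- s$chain_accession[names(s$chain_accession) %in% left]
  s
}

#' One-letter SEQRES sequence of a chain
#'
#' @param s a \code{structure_model}.
#' @param chain chain id.
#' @return a 1-letter string, or \code{NULL} when the chain has no SEQRES.
#' @export
seqres_sequence <- function(s, chain) {
  sr <- s$seqres[[chain]]
  if (is.null(sr)) return(NULL)
  paste(aa_three_to_one(sr), collapse = "")
}
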