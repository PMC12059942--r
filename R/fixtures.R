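#' Synthetic structure generator
#'
#' Emits a PDB-format structure built from poly-peptide chains laid out on
#' an extended backbone (C-alpha spacing 3.8 A along x, chains stacked 20 A
#' apart along y).  Realistic folds are deliberately not attempted: the
#' point of the fixture is controllable geometry, so that planted pockets,
#' gaps and perturbations have exactly known ground truth.  Each residue has
#' five heavy atoms (N, CA, C, O, CB) within 2 A of its C-alpha.  The
#' default sequence cycles through the 20 standard amino acids so that
#' subsequences are locally unique and sequence alignments are unambiguous.
#'
#' @param n_chains number of chains (labelled A, B, ...).
#' @param n_residues residues per chain (SEQRES length).
#' @param gap_ranges list of \code{c(start, end)} SEQRES ranges whose
#'   residues are omitted from the coordinates (same ranges applied to
#'   every chain), emulating unresolved loops.
#' @param n_models emit this many MODEL blocks; model k is rigidly shifted
#'   by 10(k-1) A along z.
#' @param resolution value for the REMARK 2 record; \code{NA} omits it
#'   (e.g. an NMR-style entry).
#' @param pdb_id 4-character id written to the HEADER record.
#' @param number_offset author residue numbers are
#'   \code{seq + number_offset} (emulates constructs whose numbering is
#'   shifted against the canonical sequence).
#' @param sequences optional named list chain -> 1-letter sequence
#'   overriding the default cyclic sequence.
#' @param jitter_sd Gaussian coordinate noise in Angstrom (0 = none).
#' @param seed seed used when \code{jitter_sd > 0}.
#' @return character vector of PDB lines (class \code{synthetic_pdb}).
#' @export
make_synthetic_structure <- function(n_chains = 1, n_residues = 20,
                                     gap_ranges = list(), n_models = 1,
                                     resolution = 2.0, pdb_id = "SYN1",
                                     number_offset = 0, sequences = NULL,
                                     jitter_sd = 0, seed = 1) {
  stopifnot(n_chains >= 1, n_residues >= 1, n_models >= 1)
  chains <- LETTERS[seq_len(n_chains)]
  base_seq <- paste(rep(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]],
                        length.out = n_residues), collapse = "")
  seqs <- lapply(chains, function(ch) {
    s <- if (!is.null(sequences[[ch]])) sequences[[ch]] else base_seq
    if (nchar(s) != n_residues) stop("sequence length != n_residues")
    s
  })
  names(seqs) <- chains
  missing_pos <- integer()
  for (g in gap_ranges) {
    if (g[1L] < 1 || g[2L] > n_residues || g[1L] > g[2L])
      stop("gap range outside chain")
    missing_pos <- c(missing_pos, g[1L]:g[2L])
  }

  lines <- c(sprintf("HEADER    SYNTHETIC STRUCTURE                     01-JAN-00   %-4s",
                     pdb_id))
  if (!is.na(resolution))
    lines <- c(lines, sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.",
                              resolution))
  for (ch in chains) {
    res3 <- bio3d::aa123(strsplit(seqs[[ch]], "")[[1L]])
    idx <- split(seq_len(n_residues), (seq_len(n_residues) - 1L) %/% 13L)
    for (k in seq_along(idx))
      lines <- c(lines, sprintf("SEQRES %3d %1s %4d  %s", k, ch, n_residues,
                                paste(sprintf("%-3s", res3[idx[[k]]]),
                                      collapse = " ")))
  }

  # per-residue heavy-atom template, offsets from the C-alpha
  template <- data.frame(atom = c("N", "CA", "C", "O", "CB"),
                         dx = c(-1.2, 0, 1.2, 1.9, 0),
                         dy = c(0.8, 0, 0.8, 1.6, -0.8),
                         dz = c(0, 0, 0, 0, 1.1),
                         element = c("N", "C", "C", "O", "C"),
                         stringsAsFactors = FALSE)
  if (jitter_sd > 0) set.seed(seed)
  model_block <- function(zshift) {
    out <- character(); serial <- 0L
    for (ci in seq_along(chains)) {
      ch <- chains[ci]
      res3 <- bio3d::aa123(strsplit(seqs[[ch]], "")[[1L]])
      for (i in seq_len(n_residues)) {
        if (i %in% missing_pos) next
        ca <- c(3.8 * i, 20 * (ci - 1L), zshift)
        for (a in seq_len(nrow(template))) {
          serial <- serial + 1L
          xyz <- ca + c(template$dx[a], template$dy[a], template$dz[a])
          if (jitter_sd > 0) xyz <- xyz + rnorm(3, sd = jitter_sd)
          out <- c(out, sprintf(
            "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, template$atom[a], res3[i], ch, i + number_offset,
            xyz[1L], xyz[2L], xyz[3L], 1, 10, template$element[a]))
        }
      }
      out <- c(out, "TER")
    }
    out
  }
  if (n_models == 1L) {
    lines <- c(lines, model_block(0))
  } else {
    for (k in seq_len(n_models))
      lines <- c(lines, sprintf("MODEL     %4d", k),
                 model_block(10 * (k - 1L)), "ENDMDL")
  }
  structure(c(lines, "END"), class = c("synthetic_pdb", "character"))
}

#' Plant a modulator with an exactly known pocket
#'
#' Appends a hetero group whose heavy atoms sit 3.7 A above the C-beta of
#' each pocket residue, which on the extended-chain geometry puts exactly
#' the pocket residues within the contact cutoff and every other residue
#' outside it.  The placement is verified against an internal brute-force
#' all-pairs distance check before the fixture is emitted; an unsatisfiable
#' request is an error, never a silently wrong fixture.  An empty pocket
#' places the group far from all residues.
#'
#' @param pdb_lines output of \code{\link{make_synthetic_structure}} (or any
#'   PDB lines ending in \code{END}).
#' @param pocket integer vector of author residue numbers to enclose.
#' @param chain chain carrying the pocket (default \code{"A"}).
#' @param cutoff contact cutoff the pocket is planted for (default 4.0).
#' @param alias chemical-component id of the group (default \code{"LIG"}).
#' @param het_resno hetero residue number (increment to plant several
#'   instances).
#' @return the PDB lines with the HETATM group inserted before \code{END}.
#' @export
plant_modulator <- function(pdb_lines, pocket, chain = "A", cutoff = 4.0,
                            alias = "LIG", het_resno = 901) {
  s <- parse_structure(paste(pdb_lines, collapse = "\n"))
  poly <- s$atoms[is_polymer_atom(s) & s$atoms$model == 1L, , drop = FALSE]
  if (length(pocket)) {
    cb <- poly[poly$chain == chain & poly$atom == "CB" &
                 poly$resno %in% pocket, , drop = FALSE]
    if (nrow(cb) != length(unique(pocket)))
      stop("pocket residues without CB atoms (gap or bad numbering?)")
    lig <- cbind(cb$x, cb$y, cb$z + 3.7)
  } else {
    lig <- rbind(c(max(poly$x) + 100, max(poly$y) + 100, max(poly$z) + 100),
                 c(max(poly$x) + 102, max(poly$y) + 100, max(poly$z) + 100))
  }
  # brute-force self-check: which residues have any atom within the cutoff?
  d2 <- cross_dist2(as.matrix(poly[, c("x", "y", "z")]), lig)
  near <- rowSums(d2 <= cutoff^2) > 0L
  got <- sort(unique(poly$resno[near & poly$chain == chain]))
  off_chain <- any(near & poly$chain != chain)
  if (!identical(got, sort(unique(as.integer(pocket)))) || off_chain)
    stop("planted pocket is geometrically unsatisfiable: wanted {",
         paste(pocket, collapse = ","), "}, placement touches {",
         paste(got, collapse = ","), "}")
  het <- vapply(seq_len(nrow(lig)), function(k) sprintf(
    "HETATM%5d  C%-2d %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    het_resno * 10L + k, k, alias, chain, het_resno,
    lig[k, 1L], lig[k, 2L], lig[k, 3L], 1, 10), character(1))
  # multi-model files get the group inside every MODEL block so that all
  # models keep identical atom lists
  anchors <- which(pdb_lines == "ENDMDL")
  if (length(anchors) == 0L) {
    anchors <- which(pdb_lines == "END")
    if (length(anchors) == 0L) anchors <- length(pdb_lines) + 1L
  }
  for (a in rev(anchors))
    pdb_lines <- append(pdb_lines, het, after = a - 1L)
  structure(pdb_lines, class = c("synthetic_pdb", "character"))
}

#' Perturb a structure model
#'
#' Either applies a random rigid motion (rotation + translation, preserving
#' every inter-atomic distance exactly) or adds i.i.d. Gaussian noise to
#' all coordinates.  Deterministic under \code{seed}.
#'
#' @param s a \code{structure_model}.
#' @param sigma coordinate noise standard deviation in Angstrom.
#' @param rigid apply a random rigid motion instead of noise.
#' @param seed integer seed.
#' @return the perturbed \code{structure_model}.
#' @export
perturb_model <- function(s, sigma = 0, rigid = FALSE, seed = 1) {
  stopifnot(inherits(s, "structure_model"))
  set.seed(seed)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  if (rigid) {
    qr_ <- qr(matrix(rnorm(9), 3, 3))
    rot <- qr.Q(qr_)
    if (det(rot) < 0) rot[, 1L] <- -rot[, 1L]
    shift <- runif(3, -20, 20)
    xyz <- sweep(xyz %*% rot, 2L, -shift)
  } else if (sigma > 0) {
    xyz <- xyz + matrix(rnorm(length(xyz), sd = sigma), ncol = 3L)
  }
  s$atoms$x <- xyz[, 1L]; s$atoms$y <- xyz[, 2L]; s$atoms$z <- xyz[, 3L]
  s
}

#' Mock prediction with an exact expected Jaccard index
#'
#' Builds a one-site prediction containing \code{floor(f * |K|)} residues of
#' the known site K plus enough residues from \code{pool} (non-site
#' residues of the same structure) to keep the predicted size equal to
#' |K|.  With equal-size sets and overlap m the Jaccard index is exactly
#' m / (2|K| - m).  Optionally injects spurious residue numbers absent from
#' any structure, for exercising prediction normalization.
#'
#' @param known residue tokens of the known site.
#' @param f overlap fraction in [0, 1].
#' @param pool residue tokens not in \code{known} used as filler.
#' @param n_spurious number of non-existent residues to append.
#' @param tool,protein_id record identifiers.
#' @param seed seed for the choice of overlap and filler residues.
#' @return a \code{\link{prediction_record}} with one ranked site.
#' @export
make_mock_predictions <- function(known, f, pool, n_spurious = 0,
                                  tool = "mock", protein_id = "prot",
                                  seed = 1) {
  stopifnot(f >= 0, f <= 1)
  known <- sort_res_tokens(known)
  pool <- setdiff(sort_res_tokens(pool), known)
  m <- floor(f * length(known))
  n_fill <- length(known) - m
  if (n_fill > length(pool))
    stop("pool too small: need ", n_fill, " filler residues")
  set.seed(seed)
  take <- if (m > 0) sample(known, m) else character()
  fill <- if (n_fill > 0) sample(pool, n_fill) else character()
  spur <- if (n_spurious > 0)
    res_token("A", 99000L + seq_len(n_spurious)) else character()
  prediction_record(tool, protein_id,
                    list(list(residues = c(take, fill, spur))))
}
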