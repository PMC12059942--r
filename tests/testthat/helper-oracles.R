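# Independent brute-force oracles.  These deliberately use different
# formulations from the package code (top-down recursion, explicit loops)
# so that agreement is evidence of correctness, not shared bugs.

# global affine-gap alignment score by memoized top-down recursion over
# (i, j, previous move)
oracle_align_score <- function(a, b, match = 1, mismatch = -1,
                               gap_open = 5, gap_extend = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  memo <- new.env(hash = TRUE)
  rec <- function(i, j, prev) {
    key <- paste(i, j, prev)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- if (i == 0 && j == 0) {
      0
    } else {
      best <- -Inf
      if (i > 0 && j > 0) {
        s <- if (av[i] != "X" && av[i] == bv[j]) match else mismatch
        best <- max(best, rec(i - 1, j - 1, "D") + s)
      }
      if (i > 0) {
        cost <- gap_extend + if (prev == "U") 0 else gap_open
        best <- max(best, rec(i - 1, j, "U") - cost)
      }
      if (j > 0) {
        cost <- gap_extend + if (prev == "L") 0 else gap_open
        best <- max(best, rec(i, j - 1, "L") - cost)
      }
      best
    }
    memo[[key]] <- res
    res
  }
  # prev state refers to the move taken *after* (closer to the ends), so
  # recurse backwards from the alignment end
  rec(length(av), length(bv), "D0")
}

# residues with any heavy atom within the cutoff of any ligand heavy atom,
# by explicit all-pairs loops
oracle_extract_site <- function(atoms, lig_xyz, cutoff) {
  hits <- character()
  for (r in unique(paste(atoms$chain, atoms$resno, atoms$icode, sep = "\r"))) {
    sel <- paste(atoms$chain, atoms$resno, atoms$icode, sep = "\r") == r
    found <- FALSE
    for (i in which(sel)) {
      for (k in seq_len(nrow(lig_xyz))) {
        d <- sqrt((atoms$x[i] - lig_xyz[k, 1])^2 +
                    (atoms$y[i] - lig_xyz[k, 2])^2 +
                    (atoms$z[i] - lig_xyz[k, 3])^2)
        if (d <= cutoff) { found <- TRUE; break }
      }
      if (found) break
    }
    if (found) {
      parts <- strsplit(r, "\r")[[1]]
      icode <- if (length(parts) >= 3) parts[3] else ""
      hits <- c(hits, paste0(parts[1], ":", as.integer(parts[2]), icode))
    }
  }
  sort(unique(hits))
}

# naive lDDT: explicit loop over reference atom pairs
oracle_lddt <- function(ref, model, thresholds = c(0.5, 1, 2, 4),
                        radius = 15) {
  heavy <- function(s) {
    at <- s$atoms[s$atoms$model == s$atoms$model[1] & !s$atoms$hetero &
                    !s$atoms$element %in% c("H", "D"), ]
    at$akey <- paste(at$chain, at$resno, at$icode, at$atom)
    at$rkey <- paste0(at$chain, ":", at$resno, at$icode)
    at
  }
  r <- heavy(ref); m <- heavy(model)
  res_scores <- list()
  n <- nrow(r)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (r$rkey[i] == r$rkey[j]) next
      dr <- sqrt((r$x[i] - r$x[j])^2 + (r$y[i] - r$y[j])^2 +
                   (r$z[i] - r$z[j])^2)
      if (dr >= radius) next
      mi <- match(r$akey[i], m$akey); mj <- match(r$akey[j], m$akey)
      frac <- 0
      if (!is.na(mi) && !is.na(mj)) {
        dm <- sqrt((m$x[mi] - m$x[mj])^2 + (m$y[mi] - m$y[mj])^2 +
                     (m$z[mi] - m$z[mj])^2)
        frac <- mean(abs(dm - dr) < thresholds)
      }
      for (rk in c(r$rkey[i], r$rkey[j]))
        res_scores[[rk]] <- c(res_scores[[rk]], frac)
    }
  }
  mean(vapply(res_scores, mean, numeric(1)))
}

# Jaccard index by element-wise membership loops
oracle_ji <- function(K, P) {
  K <- unique(K); P <- unique(P)
  inter <- 0
  for (k in K) if (any(P == k)) inter <- inter + 1
  uni <- length(K)
  for (p in P) if (!any(K == p)) uni <- uni + 1
  inter / uni
}

# a bare structure_model built directly from coordinate tables (random
# atom clouds for extraction tests)
cloud_structure <- function(n_res, n_lig_atoms, seed,
                            atoms_per_res = 3, box = 20) {
  set.seed(seed)
  n_at <- n_res * atoms_per_res
  atoms <- data.frame(
    model = 1L,
    chain = "A",
    resno = rep(seq_len(n_res), each = atoms_per_res),
    icode = "",
    resname = "ALA",
    atom = rep(paste0("C", seq_len(atoms_per_res)), n_res),
    element = "C",
    x = runif(n_at, 0, box), y = runif(n_at, 0, box), z = runif(n_at, 0, box),
    occ = 1, hetero = FALSE, stringsAsFactors = FALSE)
  lig <- data.frame(
    model = 1L, chain = "L", resno = 900L, icode = "", resname = "LIG",
    atom = paste0("X", seq_len(n_lig_atoms)), element = "C",
    x = runif(n_lig_atoms, 0, box), y = runif(n_lig_atoms, 0, box),
    z = runif(n_lig_atoms, 0, box), occ = 1, hetero = TRUE,
    stringsAsFactors = FALSE)
  s <- structure(list(pdb_id = "CLOD", resolution = 2, n_models = 1L,
                      atoms = rbind(atoms, lig), seqres = list(),
                      chain_accession = character()),
                 class = "structure_model")
  mod <- structure(list(chem_comp_id = "LIG", residue = "L:900",
                        atoms = lig[, c("atom", "element", "x", "y", "z")]),
                   class = "modulator_instance")
  list(s = s, mod = mod, protein_atoms = atoms,
       lig_xyz = as.matrix(lig[, c("x", "y", "z")]))
}

random_seq <- function(len, alphabet = c("A", "C", "D", "E"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

parse_lines <- function(pdb_lines) parse_structure(paste(pdb_lines, collapse = "\n"))
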