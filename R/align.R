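#' Global pairwise sequence alignment
#'
#' Needleman--Wunsch global alignment with affine gaps (Gotoh's algorithm)
#' under identity scoring: match +1, mismatch -1, and a gap of length L costs
#' gap_open + L * gap_extend (default 5 + L).  Identity scoring rather than a
#' substitution matrix is appropriate here because the two sequences are
#' always near-identical variants of the same protein (canonical sequence vs
#' the sequence observed in the coordinates); \code{X} matches nothing and
#' scores as a mismatch.
#'
#' Traceback ties are broken deterministically: a match/mismatch step is
#' preferred, then a gap in \code{b} (consuming a character of \code{a}),
#' then a gap in \code{a}; within a gap state, extending the gap is preferred
#' over opening it.
#'
#' @param a,b non-empty 1-letter sequences (character scalars).
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @return a list with elements \code{a_aln} and \code{b_aln} (equal-length
#'   gapped strings, gap symbol \code{"-"}), \code{score}, and
#'   \code{identity} (identical columns / alignment length).
#' @export
#' @examples
#' align_sequences("MKTAYIAKQR", "MKTAYIAKQR")$score  # 10
align_sequences <- function(a, b, match = 1, mismatch = -1,
                            gap_open = 5, gap_extend = 1) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L,
            length(b) == 1L)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  av <- strsplit(toupper(a), "")[[1L]]
  bv <- strsplit(toupper(b), "")[[1L]]
  n <- length(av); m <- length(bv)
  gopen <- gap_open + gap_extend   # cost of a length-1 gap
  NEG <- -.Machine$double.xmax / 2

  # M: av[i] aligned to bv[j]; X: gap in b (consumes av[i]); Y: gap in a.
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  if (n > 0L) X[2:(n + 1L), 1L] <- -(gap_open + gap_extend * (1:n))
  if (m > 0L) Y[1L, 2:(m + 1L)] <- -(gap_open + gap_extend * (1:m))
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      s <- if (av[i - 1L] != "X" && av[i - 1L] == bv[j - 1L]) match else mismatch
      M[i, j] <- max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                     Y[i - 1L, j - 1L]) + s
      X[i, j] <- max(X[i - 1L, j] - gap_extend,
                     M[i - 1L, j] - gopen, Y[i - 1L, j] - gopen)
      Y[i, j] <- max(Y[i, j - 1L] - gap_extend,
                     M[i, j - 1L] - gopen, X[i, j - 1L] - gopen)
    }
  }
  score <- max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])

  # traceback with the documented tie-breaking (M, then X, then Y)
  i <- n + 1L; j <- m + 1L
  state <- if (M[i, j] >= X[i, j] && M[i, j] >= Y[i, j]) "M"
           else if (X[i, j] >= Y[i, j]) "X" else "Y"
  a_out <- character(0); b_out <- character(0)
  eps <- 1e-9
  while (i > 1L || j > 1L) {
    if (state == "M") {
      a_out <- c(av[i - 1L], a_out); b_out <- c(bv[j - 1L], b_out)
      s <- if (av[i - 1L] != "X" && av[i - 1L] == bv[j - 1L]) match else mismatch
      prev <- M[i, j] - s
      state <- if (i == 2L && j == 2L) "M"
               else if (abs(M[i - 1L, j - 1L] - prev) < eps) "M"
               else if (abs(X[i - 1L, j - 1L] - prev) < eps) "X" else "Y"
      i <- i - 1L; j <- j - 1L
    } else if (state == "X") {
      a_out <- c(av[i - 1L], a_out); b_out <- c("-", b_out)
      cur <- X[i, j]
      state <- if (abs(X[i - 1L, j] - gap_extend - cur) < eps) "X"
               else if (abs(M[i - 1L, j] - gopen - cur) < eps) "M" else "Y"
      i <- i - 1L
    } else {
      a_out <- c("-", a_out); b_out <- c(bv[j - 1L], b_out)
      cur <- Y[i, j]
      state <- if (abs(Y[i, j - 1L] - gap_extend - cur) < eps) "Y"
               else if (abs(M[i, j - 1L] - gopen - cur) < eps) "M" else "X"
      j <- j - 1L
    }
  }
  a_aln <- paste(a_out, collapse = "")
  b_aln <- paste(b_out, collapse = "")
  ident <- mean(a_out == b_out & a_out != "-")
  list(a_aln = a_aln, b_aln = b_aln, score = score, identity = ident)
}

# 3-letter -> 1-letter translation; nonstandard residues present in SEQRES
# are translated where a parent amino acid is known, unknown codes become X.
.aa_extra <- c(MSE = "M", SEC = "U", PYL = "O", HYP = "P", SEP = "S",
               TPO = "T", PTR = "Y", CSO = "C", MLY = "K", M3L = "K",
               CME = "C", KCX = "K", LLP = "K", PCA = "E")

#' Translate 3-letter residue names to 1-letter codes
#'
#' Standard amino acids translate via the usual table; a small documented set
#' of common modified residues translates to its parent amino acid; anything
#' else becomes \code{"X"} (which aligns as a mismatch).
#'
#' @param resnames character vector of 3-letter residue names.
#' @return character vector of 1-letter codes.
#' @export
aa_three_to_one <- function(resnames) {
  resnames <- toupper(resnames)
  out <- suppressWarnings(bio3d::aa321(resnames))
  extra <- resnames %in% names(.aa_extra)
  out[extra] <- .aa_extra[resnames[extra]]
  out[is.na(out) | !nzchar(out)] <- "X"
  out
}

#' Map canonical sequence positions to author-numbered residues
#'
#' Aligns the canonical (UniProt-style) sequence against the sequence of
#' residues observed in the coordinates of one chain and records, for every
#' aligned column, which author-numbered residue realizes which canonical
#' position.  Substitution columns are mapped but logged; alignments whose
#' identity falls below \code{min_identity} are flagged unalignable.
#'
#' @param canonical_seq canonical 1-letter sequence.
#' @param observed data.frame of observed residues with columns \code{chain},
#'   \code{number}, \code{icode}, \code{name} (3-letter), in chain order.
#' @param min_identity identity floor below which the chain is flagged
#'   unalignable (default 0.30).
#' @return an object of class \code{residue_mapping}: a list with
#'   \code{chain} (chain id), \code{pairs} (data.frame canonical_pos, chain,
#'   number, icode, name), \code{coverage} (fraction of canonical positions
#'   mapped), \code{identity}, \code{unalignable} (logical) and
#'   \code{substitutions} (canonical positions mapped across a mismatch).
#' @export
map_residue_numbers <- function(canonical_seq, observed, min_identity = 0.30) {
  stopifnot(is.data.frame(observed),
            all(c("chain", "number", "icode", "name") %in% names(observed)))
  if (nrow(observed) == 0L) stop("no observed residues")
  chain <- unique(observed$chain)
  if (length(chain) != 1L) stop("observed residues span multiple chains")
  obs_seq <- paste(aa_three_to_one(observed$name), collapse = "")
  aln <- align_sequences(canonical_seq, obs_seq)
  ac <- strsplit(aln$a_aln, "")[[1L]]
  bc <- strsplit(aln$b_aln, "")[[1L]]
  ipos <- cumsum(ac != "-")   # canonical position per column
  jpos <- cumsum(bc != "-")   # observed index per column
  both <- ac != "-" & bc != "-"
  pairs <- data.frame(canonical_pos = ipos[both],
                      chain = observed$chain[jpos[both]],
                      number = observed$number[jpos[both]],
                      icode = observed$icode[jpos[both]],
                      name = observed$name[jpos[both]],
                      stringsAsFactors = FALSE)
  subs <- pairs$canonical_pos[ac[both] != bc[both]]
  structure(list(chain = chain, pairs = pairs,
                 coverage = nrow(pairs) / nchar(canonical_seq),
                 identity = aln$identity,
                 unalignable = aln$identity < min_identity,
                 substitutions = subs),
            class = "residue_mapping")
}

#' Remap canonical positions onto author-numbered residues
#'
#' Converts a set of 1-based canonical sequence positions to residue tokens
#' through a \code{\link{map_residue_numbers}} mapping.  Positions that fall
#' in structural gaps (no observed residue) are returned in \code{unmapped},
#' never silently discarded.
#'
#' @param positions integer vector of canonical positions.
#' @param mapping a \code{residue_mapping}.
#' @return list with \code{site} (character residue tokens) and
#'   \code{unmapped} (integer positions with no observed counterpart).
#' @export
remap_site <- function(positions, mapping) {
  stopifnot(inherits(mapping, "residue_mapping"))
  positions <- unique(as.integer(positions))
  hit <- match(positions, mapping$pairs$canonical_pos)
  ok <- !is.na(hit)
  site <- res_token(mapping$pairs$chain[hit[ok]],
                    mapping$pairs$number[hit[ok]],
                    mapping$pairs$icode[hit[ok]])
  list(site = sort_res_tokens(site), unmapped = sort(positions[!ok]))
}

#' @export
print.residue_mapping <- function(x, ...) {
  cat(sprintf("<residue_mapping chain=%s mapped=%d coverage=%.2f identity=%.2f%s>\n",
              x$chain, nrow(x$pairs), x$coverage, x$identity,
              if (x$unalignable) " UNALIGNABLE" else ""))
  invisible(x)
}
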