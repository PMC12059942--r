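#' Detect missing residues
#'
#' Aligns each chain's SEQRES sequence against the sequence of residues
#' observed in the coordinates (\code{\link{align_sequences}}) and reports
#' the SEQRES ranges with no observed counterpart.  Chains without SEQRES
#' are skipped with a warning.  If the observed sequence does not embed into
#' SEQRES cleanly (any column aligns a different residue), the chain is
#' flagged \code{sequence_conflict}.
#'
#' @param s a \code{structure_model}.
#' @return a list of per-chain gap reports, each a list with \code{chain},
#'   \code{gaps} (data.frame: start, end, missing_sequence; 1-based SEQRES
#'   positions, non-overlapping and sorted) and \code{sequence_conflict}
#'   (logical).
#' @export
find_missing_residues <- function(s) {
  stopifnot(inherits(s, "structure_model"))
  obs <- observed_residues(s)
  reports <- list()
  for (ch in sort(unique(obs$chain))) {
    if (any(s$seqres[[ch]] %in% .nucleotide_names)) next  # not a protein chain
    target <- seqres_sequence(s, ch)
    if (is.null(target)) {
      warning("chain ", ch, " has no SEQRES; skipped")
      next
    }
    och <- obs[obs$chain == ch, , drop = FALSE]
    obs_seq <- paste(aa_three_to_one(och$name), collapse = "")
    aln <- align_sequences(target, obs_seq)
    ac <- strsplit(aln$a_aln, "")[[1L]]
    bc <- strsplit(aln$b_aln, "")[[1L]]
    conflict <- any(ac != "-" & bc != "-" & ac != bc) || any(ac == "-")
    miss <- which(ac != "-" & bc == "-")          # SEQRES columns unobserved
    pos <- cumsum(ac != "-")[miss]                # their SEQRES positions
    gaps <- positions_to_ranges(pos)
    tchars <- strsplit(target, "")[[1L]]
    gaps$missing_sequence <- vapply(seq_len(nrow(gaps)), function(i)
      paste(tchars[gaps$start[i]:gaps$end[i]], collapse = ""), character(1))
    reports[[ch]] <- list(chain = ch, gaps = gaps,
                          sequence_conflict = conflict)
  }
  reports
}

positions_to_ranges <- function(pos) {
  if (length(pos) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  pos <- sort(unique(pos))
  brk <- c(0L, which(diff(pos) > 1L), length(pos))
  data.frame(start = pos[utils::head(brk, -1L) + 1L],
             end = pos[brk[-1L]], stringsAsFactors = FALSE)
}

#' Build a target--template alignment for an external modeling engine
#'
#' The full SEQRES sequence of each chain is the target; the template is the
#' same sequence with gap symbols (\code{"-"}) over the ranges reported
#' missing, so the two strings always have equal length and removing the gap
#' symbols from the template reproduces the observed sequence.
#'
#' @param s a \code{structure_model}.
#' @param gap_reports output of \code{\link{find_missing_residues}}.
#' @return an object of class \code{target_template_alignment}: a named list
#'   chain -> list(target, template).
#' @export
build_target_template_alignment <- function(s, gap_reports = find_missing_residues(s)) {
  out <- list()
  for (rep_ in gap_reports) {
    target <- seqres_sequence(s, rep_$chain)
    tchars <- strsplit(target, "")[[1L]]
    for (i in seq_len(nrow(rep_$gaps)))
      tchars[rep_$gaps$start[i]:rep_$gaps$end[i]] <- "-"
    out[[rep_$chain]] <- list(target = target,
                              template = paste(tchars, collapse = ""))
  }
  structure(out, class = "target_template_alignment")
}

#' Write a target--template alignment as JSON
#'
#' One object per chain with \code{target} and \code{template} strings (gap
#' symbol \code{"-"}), the input format expected by modeling engines that
#' accept an explicit alignment.
#'
#' @param aln a \code{target_template_alignment}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_alignment_json <- function(aln, path) {
  jsonlite::write_json(lapply(unclass(aln), function(ch)
    list(target = ch$target, template = ch$template)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.target_template_alignment <- function(x, ...) {
  for (ch in names(x))
    cat(sprintf("chain %s: %d positions, %d missing\n", ch,
                nchar(x[[ch]]$target),
                lengths(regmatches(x[[ch]]$template,
                                   gregexpr("-", x[[ch]]$template, fixed = TRUE)))))
  invisible(x)
}
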