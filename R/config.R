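#' Pipeline configuration
#'
#' All numeric thresholds used by the curation pipeline live in one object so
#' that a run is fully described by its configuration.  Defaults are the
#' values the pipeline was designed around: allosteric-site extraction within
#' 4 A of the modulator, structures kept only when the crystallographic
#' resolution is better than 4 A, rebuilt models kept only at lDDT >= 0.8,
#' test-set structures capped at 8000 observed protein residues, and the
#' classical lDDT settings (thresholds 0.5/1/2/4 A within a 15 A inclusion
#' radius).
#'
#' @param distance_cutoff_A heavy-atom distance (Angstrom) defining the
#'   allosteric site around the modulator.
#' @param max_resolution_A structures must be resolved strictly better than
#'   this to pass the resolution filter.
#' @param min_lddt modeled structures with a global lDDT below this are
#'   dropped.
#' @param max_residues test-set size filter: structures with more than this
#'   many observed protein residues are dropped.
#' @param lddt_thresholds distance-difference thresholds (Angstrom) averaged
#'   by the lDDT score.
#' @param lddt_inclusion_radius_A only reference inter-residue distances
#'   shorter than this are scored.
#' @param min_alignment_identity canonical-vs-observed sequence alignments
#'   with identity below this floor are flagged unalignable.
#' @return an object of class \code{allobench_config} (a named list).
#' @export
#' @examples
#' cfg <- allobench_config()
#' cfg$distance_cutoff_A
allobench_config <- function(distance_cutoff_A = 4.0,
                             max_resolution_A = 4.0,
                             min_lddt = 0.8,
                             max_residues = 8000,
                             lddt_thresholds = c(0.5, 1, 2, 4),
                             lddt_inclusion_radius_A = 15,
                             min_alignment_identity = 0.30) {
  stopifnot(distance_cutoff_A >= 0, max_resolution_A > 0,
            min_lddt >= 0, min_lddt <= 1, max_residues > 0,
            all(lddt_thresholds > 0), lddt_inclusion_radius_A > 0,
            min_alignment_identity >= 0, min_alignment_identity <= 1)
  structure(list(distance_cutoff_A = distance_cutoff_A,
                 max_resolution_A = max_resolution_A,
                 min_lddt = min_lddt,
                 max_residues = max_residues,
                 lddt_thresholds = sort(lddt_thresholds),
                 lddt_inclusion_radius_A = lddt_inclusion_radius_A,
                 min_alignment_identity = min_alignment_identity),
            class = "allobench_config")
}

#' Read a key/value configuration file
#'
#' The file format is one \code{key=value} pair per line; lists (the lDDT
#' thresholds) are comma-separated.  Unknown keys are an error; missing keys
#' keep their defaults.
#'
#' @param path path to the configuration file.
#' @return an \code{allobench_config}.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  defaults <- allobench_config()
  kv <- strsplit(lines, "=", fixed = TRUE)
  args <- list()
  for (pair in kv) {
    if (length(pair) != 2L)
      stop("malformed config line: ", paste(pair, collapse = "="))
    key <- trimws(pair[1L])
    if (!key %in% names(defaults))
      stop("unknown config key: ", key)
    args[[key]] <- as.numeric(strsplit(trimws(pair[2L]), ",")[[1L]])
  }
  do.call(allobench_config, args)
}

#' Write a configuration file
#'
#' @param cfg an \code{allobench_config}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "allobench_config"))
  vals <- vapply(cfg, function(v) paste(format(v, trim = TRUE), collapse = ","),
                 character(1))
  writeLines(paste0(names(cfg), "=", vals), path)
  invisible(path)
}

#' @export
print.allobench_config <- function(x, ...) {
  cat("allobench configuration:\n")
  for (k in names(x))
    cat(sprintf("  %-24s %s\n", k, paste(format(x[[k]]), collapse = ", ")))
  invisible(x)
}
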