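#' Run the full curation pipeline
#'
#' Wires the stages together in fixed order: parse XML, reconcile
#' identifiers, merge active-site sources, parse structures (dropping
#' mmCIF-only entries), merge multi-model files, synchronize residue
#' numbering, select entries with complete annotation, apply the resolution
#' filter, detect missing residues and emit target--template alignments,
#' optionally invoke an external modeling engine and gate its output with
#' lDDT, resolve the modulator and extract the allosteric site
#' geometrically, and write the dataset CSV.  Deterministic given inputs and
#' configuration; every dropped entry carries exactly one reason and the
#' stage counts telescope (the input of each stage is the kept output of the
#' previous one).
#'
#' @param corpus an \code{allobench_corpus} (from \code{\link{make_corpus}}
#'   or \code{\link{read_corpus}}) or a corpus directory path.
#' @param config an \code{\link{allobench_config}}.
#' @param out_csv optional path for the dataset CSV.
#' @param alignments_dir optional directory for per-entry target--template
#'   alignment JSON files.
#' @param modeling_cmd optional shell command template invoked for entries
#'   with missing residues, with three \code{\%s} slots: template PDB path,
#'   alignment JSON path, output model PDB path.  When absent, gapped
#'   entries pass through unmodeled, flagged \code{unmodeled_gaps}.
#' @return list with \code{entries} (kept and dropped, in entry order),
#'   \code{kept}, \code{report} (a \code{pipeline_report}) and
#'   \code{structures} (named list pdb_id -> merged
#'   \code{structure_model} of the kept entries).
#' @export
run_pipeline <- function(corpus, config = allobench_config(),
                         out_csv = NULL, alignments_dir = NULL,
                         modeling_cmd = NULL) {
  if (is.character(corpus) && length(corpus) == 1L && dir.exists(corpus))
    corpus <- read_corpus(corpus)
  stopifnot(inherits(corpus, "allobench_corpus"),
            inherits(config, "allobench_config"))
  stages <- list(); dropped_all <- list(); warnings <- character()
  record <- function(stage, n_in, n_kept)
    stages[[length(stages) + 1L]] <<- data.frame(
      stage = stage, n_in = n_in, n_kept = n_kept,
      n_dropped = n_in - n_kept, stringsAsFactors = FALSE)
  with_stage <- function(stage, id, expr)
    tryCatch(expr, allobench_mmcif = function(c) stop(c), error = function(e)
      stop("pipeline stage '", stage, "' failed for entry ", id, ": ",
           conditionMessage(e), call. = FALSE))

  # 1: parse XML
  states <- lapply(names(corpus$xml), function(id)
    list(raw = with_stage("parse_xml", id, parse_asd_xml(corpus$xml[[id]]))))
  record("parse_xml", length(states), length(states))

  # 2: reconcile identifiers
  n_in <- length(states)
  states <- lapply(states, function(st) {
    st$raw <- with_stage("reconcile_ids", st$raw$entry_id,
                         reconcile_identifiers(st$raw, corpus$resolver))
    st
  })
  is_dropped <- vapply(states, function(st) st$raw$status == "dropped",
                       logical(1))
  dropped_all <- c(dropped_all, lapply(states[is_dropped], raw_to_entry))
  states <- states[!is_dropped]
  record("reconcile_ids", n_in, length(states))

  # 3: merge active-site sources (no entries dropped here)
  active <- merge_active_sites(corpus$uniprot_sites, corpus$mcsa_sites)
  record("merge_active_sites", length(states), length(states))

  # 4: parse structures (mmCIF-only entries dropped)
  n_in <- length(states)
  keep <- logical(length(states))
  for (k in seq_along(states)) {
    st <- states[[k]]
    txt <- corpus$structures[[st$raw$pdb_id]]
    if (is.null(txt))
      stop("pipeline stage 'parse_structures' failed for entry ",
           st$raw$entry_id, ": no structure for ", st$raw$pdb_id)
    s <- tryCatch(parse_structure(txt, pdb_id = st$raw$pdb_id),
                  allobench_mmcif = function(c) NULL,
                  error = function(e)
                    stop("pipeline stage 'parse_structures' failed for entry ",
                         st$raw$entry_id, ": ", conditionMessage(e),
                         call. = FALSE))
    if (is.null(s)) {
      dropped_all <- c(dropped_all,
                       list(raw_to_entry(st, reason = "mmcif_only")))
    } else {
      s$chain_accession <- chain_map(corpus$resolver, st$raw$pdb_id)
      states[[k]]$structure <- s
      keep[k] <- TRUE
    }
  }
  states <- states[keep]
  record("parse_structures", n_in, length(states))

  # 5: merge multi-model files
  states <- lapply(states, function(st) {
    st$structure <- with_stage("merge_models", st$raw$entry_id,
                               merge_models(st$structure))
    st
  })
  record("merge_models", length(states), length(states))

  # 6: residue synchronization -> candidate entries
  n_in <- length(states)
  states <- lapply(states, function(st)
    with_stage("residue_sync", st$raw$entry_id,
               sync_entry(st, active, corpus$canonical_seqs, config)))
  is_dropped <- vapply(states, function(st)
    st$entry$status == "dropped", logical(1))
  dropped_all <- c(dropped_all, lapply(states[is_dropped], `[[`, "entry"))
  states <- states[!is_dropped]
  record("residue_sync", n_in, length(states))

  # 7: completeness
  states <- filter_stage("select_complete", states, function(entries)
    select_complete_entries(entries))
  dropped_all <- c(dropped_all, attr(states, "dropped"))
  record("select_complete", n_in <- attr(states, "n_in"), length(states))

  # 8: resolution
  states <- filter_stage("filter_resolution", states, function(entries)
    filter_resolution(entries, config$max_resolution_A))
  dropped_all <- c(dropped_all, attr(states, "dropped"))
  record("filter_resolution", attr(states, "n_in"), length(states))

  # 9: gap detection and alignment emission
  if (!is.null(alignments_dir))
    dir.create(alignments_dir, recursive = TRUE, showWarnings = FALSE)
  states <- lapply(states, function(st) {
    gr <- with_stage("gap_detection", st$entry$entry_id,
                     find_missing_residues(st$structure))
    n_gaps <- sum(vapply(gr, function(g) nrow(g$gaps), integer(1)))
    if (any(vapply(gr, `[[`, logical(1), "sequence_conflict")))
      st$entry$flags <- union(st$entry$flags, "sequence_conflict")
    if (n_gaps > 0L) {
      st$entry$flags <- union(st$entry$flags, "has_gaps")
      st$alignment <- build_target_template_alignment(st$structure, gr)
      if (!is.null(alignments_dir))
        write_alignment_json(st$alignment,
                             file.path(alignments_dir,
                                       paste0(st$entry$pdb_id, ".json")))
    }
    st
  })
  record("gap_detection", length(states), length(states))

  # 10: external modeling (optional) and lDDT gate
  states <- lapply(states, function(st) {
    if (!("has_gaps" %in% st$entry$flags)) return(st)
    if (is.null(modeling_cmd)) {
      st$entry$flags <- union(st$entry$flags, "unmodeled_gaps")
      return(st)
    }
    with_stage("modeling", st$entry$entry_id, {
      tmpl <- tempfile(fileext = ".pdb"); alnf <- tempfile(fileext = ".json")
      outf <- tempfile(fileext = ".pdb")
      writeLines(structure_to_pdb_lines(st$structure), tmpl)
      write_alignment_json(st$alignment, alnf)
      status <- system(sprintf(modeling_cmd, tmpl, alnf, outf))
      if (status != 0L || !file.exists(outf))
        stop("modeling command failed")
      model <- parse_structure(outf, pdb_id = st$entry$pdb_id)
      st$entry$lddt <- compute_lddt(
        st$structure, model, thresholds = config$lddt_thresholds,
        inclusion_radius = config$lddt_inclusion_radius_A)$global_score
      st$entry$flags <- union(st$entry$flags, "modeled")
      st
    })
  })
  states <- filter_stage("lddt_gate", states, function(entries)
    qc_filter(entries, config$min_lddt))
  dropped_all <- c(dropped_all, attr(states, "dropped"))
  record("lddt_gate", attr(states, "n_in"), length(states))

  # 11: modulator resolution and geometric site extraction
  states <- lapply(states, function(st)
    with_stage("site_extraction", st$entry$entry_id,
               extract_entry_sites(st, config)))
  record("site_extraction", length(states), length(states))

  kept <- lapply(states, function(st) validate_entry(st$entry))
  entries <- c(kept, dropped_all)
  ord <- order(vapply(entries, `[[`, character(1), "entry_id"))
  entries <- entries[ord]
  if (!is.null(out_csv)) write_dataset_csv(entries, out_csv)

  reasons <- vapply(dropped_all, `[[`, character(1), "drop_reason")
  report <- structure(list(stages = do.call(rbind, stages),
                           drop_reasons = table(reasons),
                           warnings = warnings),
                      class = "pipeline_report")
  validate_report(report)
  structures <- lapply(states, `[[`, "structure")
  names(structures) <- vapply(kept, `[[`, character(1), "pdb_id")
  list(entries = entries, kept = kept, report = report,
       structures = structures)
}

# run an entry-level filter over pipeline states, keeping state and entry
# lists in step
filter_stage <- function(stage, states, filter_fun) {
  entries <- lapply(states, `[[`, "entry")
  res <- filter_fun(entries)
  kept_ids <- vapply(res$kept, `[[`, character(1), "entry_id")
  out <- list()
  for (st in states) {
    i <- match(st$entry$entry_id, kept_ids)
    if (!is.na(i)) {
      st$entry <- res$kept[[i]]
      out[[length(out) + 1L]] <- st
    }
  }
  attr(out, "dropped") <- res$dropped
  attr(out, "n_in") <- length(states)
  out
}

raw_to_entry <- function(st, reason = NULL) {
  raw <- if (!is.null(st$raw)) st$raw else st
  new_entry(entry_id = raw$entry_id, pdb_id = raw$pdb_id,
            accessions = raw$accessions,
            status = if (is.null(reason) && raw$status != "dropped")
              "kept" else "dropped",
            drop_reason = if (!is.null(reason)) reason else raw$drop_reason,
            flags = raw$flags)
}

# stage 6 worker: map active sites onto author numbering, parse the
# database-listed allosteric residues, and assemble the candidate entry
sync_entry <- function(st, active, canonical_seqs, config) {
  raw <- st$raw; s <- st$structure
  cm <- s$chain_accession
  active_sites <- list(); mapped_any <- FALSE; unalignable_all <- TRUE
  flags <- raw$flags
  entry_chains <- character()
  for (acc in intersect(raw$accessions, cm)) {
    canon <- canonical_seqs[[acc]]
    if (is.null(canon)) stop("no canonical sequence for ", acc)
    positions <- active$position[active$accession == acc]
    # homomers: the same sites are instantiated on every matching chain
    for (ch in names(cm)[cm == acc]) {
      obs <- observed_residues(s, ch)
      if (nrow(obs) == 0L) next
      mapping <- map_residue_numbers(canon, obs,
                                     min_identity = config$min_alignment_identity)
      if (mapping$unalignable) next
      unalignable_all <- FALSE
      entry_chains <- c(entry_chains, ch)
      if (length(mapping$substitutions))
        flags <- union(flags, "mapped_substitutions")
      if (length(positions) == 0L) next
      rm_ <- remap_site(positions, mapping)
      if (length(rm_$unmapped))
        flags <- union(flags, "active_positions_unmapped")
      if (length(rm_$site)) {
        active_sites[[length(active_sites) + 1L]] <-
          site_annotation("active", rm_$site, source = "UniProt")
        mapped_any <- TRUE
      }
    }
  }
  if (unalignable_all) {
    st$entry <- raw_to_entry(raw, reason = "unalignable")
    return(st)
  }
  allosteric_sites <- list()
  if (nzchar(raw$allosteric_residue_text)) {
    ps <- parse_site_text(raw$allosteric_residue_text,
                          default_chain = entry_chains)
    flags <- union(flags, ps$flags)
    if (length(ps$residues))
      allosteric_sites <- list(site_annotation(
        "allosteric", ps$residues, modulator_alias = raw$modulator_alias,
        modulator_class = raw$modulator_class, source = "ASD"))
  }
  st$entry <- new_entry(entry_id = raw$entry_id, pdb_id = raw$pdb_id,
                        accessions = raw$accessions,
                        allosteric_sites = allosteric_sites,
                        active_sites = active_sites,
                        resolution = s$resolution,
                        n_protein_residues = n_protein_residues(s),
                        has_nucleic = has_nucleic_chains(s),
                        flags = flags)
  st
}

# stage 11 worker: the geometrically derived site is authoritative; the
# database-listed site is kept for the audit trail via agreement flags
extract_entry_sites <- function(st, config) {
  e <- st$entry; s <- st$structure
  alias <- if (length(e$allosteric_sites))
    e$allosteric_sites[[1L]]$modulator_alias else ""
  mclass <- if (length(e$allosteric_sites))
    e$allosteric_sites[[1L]]$modulator_class else "unknown"
  if (!nzchar(alias)) {
    e$flags <- union(e$flags, "modulator_not_found")
    st$entry <- e
    return(st)
  }
  instances <- resolve_modulator(s = s, alias = alias)
  if (length(instances) == 0L) {
    e$flags <- union(e$flags, "modulator_not_found")
    st$entry <- e
    return(st)
  }
  asd_residues <- if (length(e$allosteric_sites))
    e$allosteric_sites[[1L]]$residues else character()
  derived <- list()
  for (inst in instances) {
    site <- extract_site(s, inst, cutoff = config$distance_cutoff_A)
    if (length(site) == 0L) {
      e$flags <- union(e$flags, "empty_derived_site")
      next
    }
    if (length(asd_residues)) {
      agreement <- validate_site_agreement(asd_residues, site)
      if (agreement$verdict == "discrepant")
        e$flags <- union(e$flags, "site_discrepant")
    }
    derived[[length(derived) + 1L]] <- site_annotation(
      "allosteric", site, modulator_alias = alias,
      modulator_class = mclass, source = "derived_geometric")
  }
  if (length(derived)) e$allosteric_sites <- derived
  st$entry <- e
  st
}

# serialize a structure_model back to minimal PDB lines (templates handed
# to the external modeling engine)
structure_to_pdb_lines <- function(s) {
  lines <- character()
  if (!is.na(s$resolution))
    lines <- c(lines, sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.",
                              s$resolution))
  for (ch in names(s$seqres)) {
    res3 <- s$seqres[[ch]]
    idx <- split(seq_along(res3), (seq_along(res3) - 1L) %/% 13L)
    for (k in seq_along(idx))
      lines <- c(lines, sprintf("SEQRES %3d %1s %4d  %s", k, ch,
                                length(res3),
                                paste(sprintf("%-3s", res3[idx[[k]]]),
                                      collapse = " ")))
  }
  at <- s$atoms[s$atoms$model == s$atoms$model[1L], , drop = FALSE]
  rec <- ifelse(at$hetero, "HETATM", "ATOM  ")
  lines <- c(lines, sprintf(
    "%s%5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, seq_len(nrow(at)), at$atom, at$resname, at$chain, at$resno,
    at$x, at$y, at$z, at$occ, 10, at$element), "END")
  lines
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline report\n")
  print(x$stages, row.names = FALSE)
  if (length(x$drop_reasons)) {
    cat("drop reasons:\n")
    for (r in names(x$drop_reasons))
      cat(sprintf("  %-24s %d\n", r, x$drop_reasons[[r]]))
  }
  invisible(x)
}

#' Check the telescoping invariant of a pipeline report
#'
#' The number of entries entering each stage must equal the number kept by
#' the previous stage, and total drops must equal the sum of per-reason
#' tallies.
#'
#' @param report a \code{pipeline_report}.
#' @return \code{TRUE}, or an error.
#' @export
validate_report <- function(report) {
  st <- report$stages
  if (nrow(st) > 1L && !all(st$n_in[-1L] == st$n_kept[-nrow(st)]))
    stop("stage counts do not telescope")
  if (sum(st$n_dropped) != sum(report$drop_reasons))
    stop("drop tallies do not add up")
  TRUE
}

#' Run the benchmark over a curated dataset
#'
#' Scores a directory (or list) of prediction records against the known
#' allosteric sites of the kept entries, then summarizes per tool and
#' computes the accuracy-versus-cutoff curve.  Predictions referencing a
#' protein absent from the dataset are skipped with a warning and counted.
#'
#' @param entries list of \code{\link{allosteric_entry}} or the path to a
#'   dataset CSV.
#' @param predictions list of \code{\link{prediction_record}} or a
#'   directory readable by \code{\link{read_predictions}}.
#' @param structures named list pdb_id -> \code{structure_model} (as
#'   returned by \code{\link{run_pipeline}}), or a directory of PDB files
#'   named \code{<pdb_id>.pdb}.
#' @param cutoffs JI thresholds for the accuracy curve.
#' @param best_of_k score the best-ranked-site JI instead of the topmost.
#' @param out_dir optional directory for results/summary/curve CSVs.
#' @return list with \code{results}, \code{summary}, \code{curve},
#'   \code{n_skipped}.
#' @export
run_benchmark <- function(entries, predictions, structures,
                          cutoffs = seq(0, 0.5, by = 0.1),
                          best_of_k = FALSE, out_dir = NULL) {
  if (is.character(entries)) entries <- read_dataset_csv(entries)
  if (is.character(predictions)) predictions <- read_predictions(predictions)
  if (is.character(structures)) {
    files <- list.files(structures, pattern = "\\.pdb$", full.names = TRUE)
    structures <- setNames(lapply(files, parse_structure),
                           sub("\\.pdb$", "", basename(files)))
  }
  kept <- Filter(function(e) e$status == "kept", entries)
  known <- list()
  for (e in kept)
    known[[e$pdb_id]] <- lapply(e$allosteric_sites, `[[`, "residues")
  results <- score_predictions(predictions, known, structures,
                               best_of_k = best_of_k)
  n_skipped <- attr(results, "n_skipped")
  if (n_skipped > 0L)
    warning(n_skipped, " prediction(s) referenced unknown proteins and were skipped")
  if (length(predictions) == 0L)
    warning("no predictions found")
  summary <- if (nrow(results)) summarize_benchmark(results) else
    data.frame(tool = character(), median_ji = numeric(),
               mean_ji = numeric(), n = integer(), n_failed = integer())
  curve <- if (nrow(results)) accuracy_curve(results, cutoffs) else
    data.frame(tool = character(), cutoff = numeric(),
               percent_above = numeric())
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(results, file.path(out_dir, "benchmark_results.csv"),
              row.names = FALSE)
    write.csv(summary, file.path(out_dir, "benchmark_summary.csv"),
              row.names = FALSE)
    write.csv(curve, file.path(out_dir, "accuracy_curve.csv"),
              row.names = FALSE)
  }
  list(results = results, summary = summary, curve = curve,
       n_skipped = n_skipped)
}
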