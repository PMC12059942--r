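#' Jaccard index of known and predicted residue sets
#'
#' \eqn{JI = |K \cap P| / |K \cup P|} for the known site K and predicted
#' site P, both sets of residue tokens.  The JI is 1 when the sets are
#' identical, 0 when they share no residue, and is pulled down when the
#' prediction contains many residues outside the known site.  An empty
#' prediction scores 0; an empty known site is an error.
#'
#' @param known,predicted character vectors of residue tokens.
#' @return a number in [0, 1].
#' @export
#' @examples
#' jaccard_index(c("A:1", "A:2"), c("A:2", "A:3"))  # 1/3
jaccard_index <- function(known, predicted) {
  known <- unique(known); predicted <- unique(predicted)
  if (length(known) == 0L) stop("empty_known_site")
  if (length(predicted) == 0L) return(0)
  length(intersect(known, predicted)) / length(union(known, predicted))
}

#' Remove spurious residues from a prediction
#'
#' Prediction tools sometimes emit residue identifiers that do not exist in
#' the structure they were given.  These spurious residues are removed while
#' the correct ones are retained; sites emptied entirely are removed from
#' the ranked list, and the removals are recorded.
#'
#' @param pred a \code{\link{prediction_record}}.
#' @param s the \code{structure_model} that was given to the predictor.
#' @return the normalized \code{prediction_record}, with attribute
#'   \code{n_spurious} (count of removed residues).
#' @export
normalize_prediction <- function(pred, s) {
  stopifnot(inherits(pred, "prediction_record"),
            inherits(s, "structure_model"))
  obs <- observed_residues(s)
  valid <- res_token(obs$chain, obs$number, obs$icode)
  n_spurious <- 0L
  cleaned <- list()
  for (site in pred$ranked_sites) {
    keep <- site$residues %in% valid
    n_spurious <- n_spurious + sum(!keep)
    if (any(keep)) {
      site$residues <- site$residues[keep]
      cleaned[[length(cleaned) + 1L]] <- site
    }
  }
  out <- prediction_record(pred$tool, pred$protein_id, cleaned)
  attr(out, "n_spurious") <- n_spurious
  out
}

#' Match the top prediction against all known sites
#'
#' Multimeric proteins carry several known allosteric sites (one per
#' protomer, or several distinct pockets).  The topmost predicted site is
#' compared against every known site and the best Jaccard index is used;
#' ties resolve to the lowest site index.
#'
#' @param topmost character vector of residue tokens (may be empty: JI 0).
#' @param known_sites non-empty list of residue-token vectors.
#' @return list with \code{ji} and \code{index} (1-based index of the
#'   matched known site).
#' @export
best_ji_match <- function(topmost, known_sites) {
  stopifnot(length(known_sites) >= 1L)
  jis <- vapply(known_sites, jaccard_index, numeric(1),
                predicted = topmost)
  best <- which.max(jis)   # first maximum -> lowest index on ties
  list(ji = jis[best], index = best)
}

#' Distance between site centroids
#'
#' Euclidean distance between the unweighted means of the C-alpha
#' coordinates of two residue sets, and its inverse (the proximity measure
#' correlated with the JI).  Coincident centroids flag the inverse as
#' infinite and store it as \code{NA} with \code{coincident = TRUE}.
#'
#' @param site_a,site_b character vectors of residue tokens.
#' @param s a \code{structure_model} providing coordinates.
#' @return list with \code{distance} (Angstrom), \code{inverse} (1/Angstrom
#'   or \code{NA}) and \code{coincident}.
#' @export
centroid_distance <- function(site_a, site_b, s) {
  ca <- site_centroid(site_a, s, "site_a")
  cb <- site_centroid(site_b, s, "site_b")
  d <- sqrt(sum((ca - cb)^2))
  if (d == 0)
    list(distance = 0, inverse = NA_real_, coincident = TRUE)
  else
    list(distance = d, inverse = 1 / d, coincident = FALSE)
}

site_centroid <- function(site, s, label) {
  ref <- parse_res_tokens(site)
  at <- s$atoms[s$atoms$model == s$atoms$model[1L] & s$atoms$atom == "CA" &
                  !s$atoms$hetero, , drop = FALSE]
  key <- paste(at$chain, at$resno, at$icode, sep = "\r")
  idx <- match(paste(ref$chain, ref$number, ref$icode, sep = "\r"), key)
  if (all(is.na(idx)))
    stop("no C-alpha atoms resolvable for ", label)
  idx <- idx[!is.na(idx)]
  colMeans(at[idx, c("x", "y", "z"), drop = FALSE])
}

is_bare_residue <- function(tokens) grepl("^-?[0-9]+[A-Za-z]?$", tokens)

# residue numbers without chain ids: try every chain and keep the
# assignment maximizing the JI against the known sites
infer_chain <- function(residues, known_sites, s) {
  m <- regmatches(residues, regexec("^(-?[0-9]+)([A-Za-z]?)$", residues))
  number <- as.integer(vapply(m, `[`, character(1), 2L))
  icode <- vapply(m, `[`, character(1), 3L)
  chains <- sort(unique(observed_residues(s)$chain))
  best <- NULL
  for (ch in chains) {
    cand <- res_token(ch, number, icode)
    ji <- max(vapply(known_sites, jaccard_index, numeric(1),
                     predicted = cand))
    if (is.null(best) || ji > best$ji) best <- list(ji = ji, residues = cand)
  }
  best$residues
}

#' Score prediction records against known sites
#'
#' For each (protein, tool): normalize the prediction against the structure
#' (\code{\link{normalize_prediction}}), take the topmost ranked site (or
#' the best-scoring site when \code{best_of_k = TRUE}), match it against all
#' known allosteric sites (\code{\link{best_ji_match}}), and report the JI
#' and centroid distance.  Tools that failed (no ranked sites, or all
#' residues spurious) score JI 0 and are included in all summaries.
#' Confidence scores attached to predictions are carried but never used for
#' re-ranking: the tool's own order defines the topmost site.
#'
#' @param predictions list of \code{\link{prediction_record}}.
#' @param known named list: protein_id -> list of known-site residue-token
#'   vectors.
#' @param structures named list: protein_id -> \code{structure_model}.
#' @param best_of_k score every ranked site and keep the best JI instead of
#'   the topmost (default \code{FALSE}).
#' @return a data.frame of class \code{benchmark_results} with columns
#'   \code{protein_id}, \code{tool}, \code{ji}, \code{matched_site},
#'   \code{centroid_distance_A}, \code{inverse_distance_A}, \code{failed},
#'   \code{n_spurious}, \code{chain_inferred}.
#' @export
score_predictions <- function(predictions, known, structures,
                              best_of_k = FALSE) {
  key <- vapply(predictions, function(p) paste(p$protein_id, p$tool),
                character(1))
  if (anyDuplicated(key))
    stop("duplicate (protein, tool) prediction(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  rows <- lapply(predictions, function(p) {
    ks <- known[[p$protein_id]]
    s <- structures[[p$protein_id]]
    if (is.null(ks) || is.null(s))
      return(NULL)  # caller counts skips
    chain_inferred <- FALSE
    p$ranked_sites <- lapply(p$ranked_sites, function(site) {
      if (length(site$residues) && all(is_bare_residue(site$residues))) {
        site$residues <- infer_chain(site$residues, ks, s)
        chain_inferred <<- TRUE
      }
      site
    })
    p_norm <- normalize_prediction(p, s)
    sites <- p_norm$ranked_sites
    if (length(sites) == 0L) {
      m <- list(ji = 0, index = NA_integer_)
      cd <- list(distance = NA_real_, inverse = NA_real_)
    } else {
      use <- if (best_of_k) seq_along(sites) else 1L
      cand <- lapply(use, function(k) {
        resid <- sites[[k]]$residues
        c(list(residues = resid), best_ji_match(resid, ks))
      })
      m <- cand[[which.max(vapply(cand, `[[`, numeric(1), "ji"))]]
      cd <- tryCatch(centroid_distance(m$residues, ks[[m$index]], s),
                     error = function(e)
                       list(distance = NA_real_, inverse = NA_real_))
    }
    data.frame(protein_id = p$protein_id, tool = p$tool, ji = m$ji,
               matched_site = if (is.null(m$index)) NA_integer_ else m$index,
               centroid_distance_A = cd$distance,
               inverse_distance_A = cd$inverse,
               failed = length(sites) == 0L,
               n_spurious = attr(p_norm, "n_spurious"),
               chain_inferred = chain_inferred,
               stringsAsFactors = FALSE)
  })
  skipped <- vapply(rows, is.null, logical(1))
  out <- do.call(rbind, rows[!skipped])
  if (is.null(out))
    out <- data.frame(protein_id = character(), tool = character(),
                      ji = numeric(), matched_site = integer(),
                      centroid_distance_A = numeric(),
                      inverse_distance_A = numeric(), failed = logical(),
                      n_spurious = integer(), chain_inferred = logical())
  attr(out, "n_skipped") <- sum(skipped)
  class(out) <- c("benchmark_results", class(out))
  out
}

#' Accuracy-versus-cutoff curve
#'
#' For every tool and JI cutoff c, the percentage of proteins whose topmost
#' prediction has JI strictly greater than c.  Failed proteins enter with
#' their assigned JI of 0, so the curve is computed over all proteins.
#'
#' @param results a \code{benchmark_results} data.frame (one row per
#'   (protein, tool); duplicates are an error).
#' @param cutoffs ordered JI thresholds (default 0, 0.1, ..., 0.5).
#' @return a data.frame with columns \code{tool}, \code{cutoff},
#'   \code{percent_above}; \code{percent_above} is non-increasing in
#'   \code{cutoff} for every tool.
#' @export
accuracy_curve <- function(results, cutoffs = seq(0, 0.5, by = 0.1)) {
  stopifnot(is.data.frame(results))
  if (anyDuplicated(paste(results$protein_id, results$tool)))
    stop("duplicate (protein, tool) pairs in results")
  cutoffs <- sort(cutoffs)
  out <- do.call(rbind, lapply(split(results, results$tool), function(g)
    data.frame(tool = g$tool[1L], cutoff = cutoffs,
               percent_above = vapply(cutoffs, function(ct)
                 100 * mean(g$ji > ct), numeric(1)),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Per-tool summary of benchmark results
#'
#' The median is reported alongside the mean: JI distributions are highly
#' skewed (many zeros from failed or off-target predictions), so the median
#' is the more robust measure of central tendency.  Assigned zeros from
#' failed predictions are included in both.
#'
#' @param results a \code{benchmark_results} data.frame.
#' @return data.frame with columns \code{tool}, \code{median_ji},
#'   \code{mean_ji}, \code{n}, \code{n_failed}.
#' @export
summarize_benchmark <- function(results) {
  out <- do.call(rbind, lapply(split(results, results$tool), function(g)
    data.frame(tool = g$tool[1L], median_ji = median(g$ji),
               mean_ji = mean(g$ji), n = nrow(g),
               n_failed = sum(g$failed), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Read prediction records from a directory
#'
#' One file per (tool, protein): either JSON
#' (\code{\{"tool": ..., "protein_id": ..., "ranked_sites": [\{"residues":
#' ["A:10", ...], "score": ...\}, ...]\}}) or TSV with columns \code{tool},
#' \code{protein_id}, \code{rank}, \code{residues} (semicolon-joined
#' tokens), optional \code{score}.
#'
#' @param dir directory containing \code{*.json} / \code{*.tsv} files.
#' @return list of \code{\link{prediction_record}}.
#' @export
read_predictions <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(json|tsv)$",
                           full.names = TRUE))
  lapply(files, function(f) {
    if (grepl("\\.json$", f)) {
      j <- jsonlite::read_json(f, simplifyVector = FALSE)
      sites <- lapply(j$ranked_sites, function(s)
        list(residues = unlist(s$residues),
             score = if (is.null(s$score)) NA_real_ else s$score))
      prediction_record(j$tool, j$protein_id, sites)
    } else {
      df <- read.delim(f, colClasses = "character")
      df <- df[order(as.integer(df$rank)), , drop = FALSE]
      sites <- lapply(seq_len(nrow(df)), function(k)
        list(residues = strsplit(df$residues[k], ";", fixed = TRUE)[[1L]],
             score = if ("score" %in% names(df))
               as.numeric(df$score[k]) else NA_real_))
      prediction_record(df$tool[1L], df$protein_id[1L], sites)
    }
  })
}
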