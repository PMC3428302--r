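# ProbeMelt-style probe design: length selection into a melting-point
# window, specificity scoring against non-targets by predicted hybridization
# efficiency, and multi-probe OTU presence calls.

#' Enumerate probe candidates along a target
#'
#' All (start, length) combinations with the site inside the given bounds,
#' with predicted perfect-match free energy and melting point.
#'
#' @param target_seq target gene sequence.
#' @param lengths probe lengths to consider (default 18:26).
#' @param min_pos,max_pos coverage bounds on the target (defaults 50 and the
#'   gene length minus 49).
#' @param params a `thermo_params` object.
#' @param target_id name label (default "T").
#' @return data.frame: `name`, `start`, `end`, `length`, `sequence`, `dg`,
#'   `melting_point`.
#' @export
candidate_probes <- function(target_seq, lengths = 18:26,
                             min_pos = 50L, max_pos = NULL,
                             params = default_params(), target_id = "T") {
  target_seq <- toupper(as.character(target_seq))
  if (is.null(max_pos)) max_pos <- nchar(target_seq) - 49L
  out <- do.call(rbind, lapply(lengths, function(L) {
    if (max_pos - L + 1L < min_pos) return(NULL)
    t <- tile_probes(target_seq, length = L, min_pos = min_pos,
                     max_pos = max_pos, target_id = target_id)
    t$length <- L
    t
  }))
  out$dg <- vapply(out$sequence, dg_perfect, numeric(1), params = params,
                   USE.NAMES = FALSE)
  out$melting_point <- melting_point(out$dg, params)
  out[, c("name", "start", "end", "length", "sequence", "dg", "melting_point")]
}

#' Select probe lengths into a melting-point window
#'
#' For each target site (anchored by its start position), pick the candidate
#' length whose predicted melting point falls inside the window, preferring
#' the one closest to the window center; sites with no admissible length are
#' reported unmet.
#'
#' @param candidates data.frame from [candidate_probes()].
#' @param window numeric `c(low, high)` melting-point window in % formamide
#'   (default `c(18, 22)`).
#' @return data.frame with one row per site: the selected probe columns plus
#'   `met` (logical; for unmet sites the row carries the closest candidate).
#' @export
select_by_melting_window <- function(candidates, window = c(18, 22)) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  center <- mean(window)
  out <- do.call(rbind, lapply(split(candidates, candidates$start), function(d) {
    inside <- d$melting_point >= window[1] & d$melting_point <= window[2]
    if (any(inside)) {
      d <- d[inside, , drop = FALSE]
      sel <- d[which.min(abs(d$melting_point - center)), , drop = FALSE]
      sel$met <- TRUE
    } else {
      sel <- d[which.min(abs(d$melting_point - center)), , drop = FALSE]
      sel$met <- FALSE
    }
    sel
  }))
  rownames(out) <- NULL
  out[order(out$start), , drop = FALSE]
}

#' Specificity score of a probe against non-targets
#'
#' Predicted hybridization efficiency against the best-scoring site of each
#' non-target sequence (located by semi-global alignment); a probe is flagged
#' specific when every non-target efficiency is below the threshold.
#'
#' @param probe_seq probe, 5'->3'.
#' @param nontargets named character vector (or `DNAStringSet`) of non-target
#'   sequences.
#' @param working_fa hybridization formamide concentration, % v/v (default
#'   15).
#' @param params a `thermo_params` object.
#' @param threshold efficiency threshold for the specificity flag (default
#'   0.05).
#' @param min_score alignment floor passed to [conformation_from_pair()].
#' @return list with `table` (data.frame per non-target: `nontarget`, `dg`,
#'   `efficiency`, `n_events`, `extended`) and `specific` (logical flag).
#' @export
specificity_score <- function(probe_seq, nontargets, working_fa = 15,
                              params = default_params(), threshold = 0.05,
                              min_score = NULL) {
  if (working_fa < 0) stop("working_fa must be >= 0", call. = FALSE)
  nontargets <- stats::setNames(as.character(nontargets),
                                names(nontargets) %||%
                                  paste0("nontarget", seq_along(nontargets)))
  rows <- lapply(names(nontargets), function(nm) {
    conf <- conformation_from_pair(probe_seq, nontargets[[nm]], params,
                                   min_score = min_score)
    if (is.null(conf)) {
      return(data.frame(nontarget = nm, dg = NA_real_, efficiency = 0,
                        n_events = NA_integer_, extended = FALSE,
                        stringsAsFactors = FALSE))
    }
    dg <- attr(conf, "dg")
    ev <- conformation_events(conf)
    data.frame(nontarget = nm, dg = dg,
               efficiency = hyb_efficiency(dg, working_fa, params),
               n_events = sum(ev$type != "pair"),
               extended = isTRUE(attr(conf, "extended")),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  list(table = tab, specific = all(tab$efficiency < threshold))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Multi-probe OTU presence call
#'
#' An operational taxonomic unit is called present when the fraction of its
#' panel probes that are bright reaches the rule (e.g. 9 of 10).
#'
#' @param bright logical vector of per-probe bright/dim calls.
#' @param rule minimum bright fraction (default 0.9).
#' @return logical: present.
#' @export
otu_call <- function(bright, rule = 0.9) {
  stopifnot(length(bright) >= 1)
  mean(bright) >= rule
}

#' Design specific probes for a target against non-targets
#'
#' End-to-end workflow: enumerate candidates, select lengths into the
#' melting-point window, score specificity at the working formamide
#' concentration, and report per-candidate results.
#'
#' @param target_seq target gene sequence.
#' @param nontargets named character vector of non-target sequences.
#' @param window melting-point window, % FA (default `c(18, 22)`).
#' @param lengths candidate probe lengths (default 18:26).
#' @param working_fa hybridization formamide (default 15, about 5 points
#'   under the window).
#' @param threshold non-target efficiency threshold (default 0.05).
#' @param params a `thermo_params` object.
#' @param max_candidates cap on the number of window-selected sites scored
#'   for specificity (evenly spaced; `Inf` = all).
#' @return data.frame (a design report): per selected probe, its coordinates,
#'   melting point, target efficiency at the working formamide, worst
#'   non-target efficiency, and specificity flag.
#' @export
design_probes <- function(target_seq, nontargets, window = c(18, 22),
                          lengths = 18:26, working_fa = 15, threshold = 0.05,
                          params = default_params(), max_candidates = Inf) {
  cand <- candidate_probes(target_seq, lengths = lengths, params = params)
  sel <- select_by_melting_window(cand, window)
  sel <- sel[sel$met, , drop = FALSE]
  if (is.finite(max_candidates) && nrow(sel) > max_candidates) {
    sel <- sel[unique(round(seq(1, nrow(sel), length.out = max_candidates))), ,
               drop = FALSE]
  }
  sel$target_efficiency <- hyb_efficiency(sel$dg, working_fa, params)
  spec <- lapply(sel$sequence, specificity_score, nontargets = nontargets,
                 working_fa = working_fa, params = params, threshold = threshold)
  sel$worst_nontarget_efficiency <- vapply(spec, function(s) {
    if (nrow(s$table)) max(s$table$efficiency) else 0
  }, numeric(1))
  sel$specific <- vapply(spec, `[[`, logical(1), "specific")
  rownames(sel) <- NULL
  sel
}
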