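# Duplex free energies from the microarray nearest-neighbor rule system.
#
# A duplex conformation is stored as an explicit column alignment: two
# equal-length character vectors, probe (5'->3', left to right) and target
# (3'->5', left to right, i.e. antiparallel), with "-" marking an unpaired
# position.  The free energy of any conformation is assembled as
#   dG = dG(perfect duplex of the target site) + sum of loop contributions,
# each loop contributing its loop free energy minus the nearest-neighbor
# stacks of the perfect reference that it replaces (deletions replace two
# stacks, insertions one, single mismatches two, tandem mismatches three).

#' Construct a duplex conformation
#'
#' @param probe character vector of probe-strand column bases 5'->3'
#'   (`"-"` = no probe base in that column, i.e. a target bulge).
#' @param target character vector of target-strand column bases, written
#'   3'->5' left-to-right so columns face each other (`"-"` = probe bulge).
#' @param relaxed_left,relaxed_right number of alignment columns left unpaired
#'   at the probe 5' / 3' terminus (relaxed-end conformation).
#' @return object of class `duplex_conformation`.
#' @export
duplex_conformation <- function(probe, target, relaxed_left = 0L, relaxed_right = 0L) {
  probe <- toupper(probe); target <- toupper(target)
  if (length(probe) != length(target)) {
    stop("probe and target columns must have equal length", call. = FALSE)
  }
  ok <- function(x) all(x %in% c(DNA_BASES, "-"))
  if (!ok(probe) || !ok(target)) {
    stop("invalid-sequence error: alphabet is {A,C,G,T,-}", call. = FALSE)
  }
  if (any(probe == "-" & target == "-")) stop("empty alignment column", call. = FALSE)
  relaxed_left <- as.integer(relaxed_left); relaxed_right <- as.integer(relaxed_right)
  if (relaxed_left < 0 || relaxed_right < 0 ||
      relaxed_left + relaxed_right > length(probe)) {
    stop("relaxed counts must be non-negative and non-overlapping", call. = FALSE)
  }
  structure(list(probe = probe, target = target,
                 relaxed_left = relaxed_left, relaxed_right = relaxed_right),
            class = "duplex_conformation")
}

#' @export
print.duplex_conformation <- function(x, ...) {
  cat("<duplex_conformation> (", length(x$probe), " columns, relaxed ",
      x$relaxed_left, "+", x$relaxed_right, ")\n", sep = "")
  cat("  probe  5'-", paste(x$probe, collapse = ""), "-3'\n", sep = "")
  cat("  target 3'-", paste(x$target, collapse = ""), "-5'\n", sep = "")
  invisible(x)
}

#' Pairing events of a conformation
#'
#' Classifies every alignment column as a Watson-Crick pair, single mismatch,
#' probe bulge (unpaired probe base) or target bulge (unpaired target base).
#' @param conf a `duplex_conformation`.
#' @return data.frame with columns `column`, `probe_base`, `target_base`, `type`.
#' @export
conformation_events <- function(conf) {
  p <- conf$probe; t <- conf$target
  type <- ifelse(p == "-", "target_bulge",
          ifelse(t == "-", "probe_bulge",
          ifelse(COMP[p] == t, "pair", "mismatch")))
  data.frame(column = seq_along(p), probe_base = p, target_base = t,
             type = type, stringsAsFactors = FALSE)
}

#' Perfect-match duplex free energy
#'
#' Sum of the nearest-neighbor stack free energies over the L-1 stacks of the
#' probe read 5'->3', plus the initiation penalty. Invariant under strand
#' reversal of the duplex (i.e. under reverse-complementing the probe).
#'
#' @param probe_seq probe DNA sequence, 5'->3' (character scalar, ACGT).
#' @param params a `thermo_params` object.
#' @return free energy in kcal/mol.
#' @examples
#' p <- synthetic_params()
#' dg_perfect("ACGTACGT", p)
#' @export
dg_perfect <- function(probe_seq, params = default_params()) {
  check_dna(probe_seq, "probe sequence")
  b <- strsplit(probe_seq, "")[[1]]
  if (length(b) < 2) stop("probe length must be >= 2", call. = FALSE)
  stacks <- paste0(b[-length(b)], b[-1])
  sum(lookup_nn(params, stacks)) + params$dg_init
}

# two halves of a "PPP/TTT"-style key
.split_key <- function(key) {
  halves <- strsplit(key, "/", fixed = TRUE)[[1]]
  if (length(halves) != 2L) stop("malformed duplex context key: ", key, call. = FALSE)
  list(p = strsplit(halves[1], "")[[1]], t = strsplit(halves[2], "")[[1]])
}

# reference stacks replaced by a loop, from the target side: the perfect
# reference probe is the complement of the target bases, so the stack between
# target columns (i, i+1) has probe-side dinucleotide comp(t_i) comp(t_{i+1}).
.ref_stack <- function(params, t_i, t_j) {
  lookup_nn(params, paste0(COMP[[t_i]], COMP[[t_j]]))
}

#' Single-mismatch destabilization
#'
#' Free-energy change introduced by one internal mismatch: the loop term for
#' the mismatch triplet minus the two replaced nearest-neighbor stacks of the
#' perfect-match reference (the Watson-Crick duplex of the target site).
#'
#' @param triplet_key context key `"PPP/TTT"`: closing pair, mismatch, closing
#'   pair (probe 5'->3' / target 3'->5').
#' @param params a `thermo_params` object.
#' @param mode `"M5_table"` looks the loop up in the calibrated 104-entry
#'   table; `"M4_linear"` maps a supplied solution loop free energy through
#'   the linear calibration `alpha * dG_sln + beta`.
#' @param sln_loop solution loop free energy (kcal/mol), required for
#'   `"M4_linear"`.
#' @return ddG in kcal/mol.
#' @export
ddg_single_mismatch <- function(triplet_key, params = default_params(),
                                mode = c("M5_table", "M4_linear"),
                                sln_loop = NULL) {
  mode <- match.arg(mode)
  # the loss term is computed on the canonical reading of the triplet, so a
  # context and its strand-reversed mate give the identical ddG
  k <- .split_key(canonical_context(triplet_key))
  if (length(k$p) != 3L) stop("triplet key must span 3 columns", call. = FALSE)
  if (COMP[[k$p[2]]] == k$t[2]) {
    stop("invalid-input error: central pair is Watson-Crick, not a mismatch",
         call. = FALSE)
  }
  if (COMP[[k$p[1]]] != k$t[1] || COMP[[k$p[3]]] != k$t[3]) {
    stop("closing pairs must be Watson-Crick", call. = FALSE)
  }
  loop <- if (mode == "M5_table") {
    lookup_sm_loop(params, triplet_key)
  } else {
    if (is.null(sln_loop)) stop("M4_linear requires sln_loop", call. = FALSE)
    params$sm_linear[["alpha"]] * sln_loop + params$sm_linear[["beta"]]
  }
  lost <- .ref_stack(params, k$t[1], k$t[2]) + .ref_stack(params, k$t[2], k$t[3])
  loop - lost
}

#' Bulged-mismatch destabilization
#'
#' A bulge loop (unpaired base between two closing pairs) scored as the
#' solution bulge-loop free energy scaled by the calibrated slope, minus the
#' replaced reference stacks: a deletion (bulged base on the target strand)
#' replaces two nearest neighbors of the target-site reference duplex, an
#' insertion (bulged base on the probe strand) only one.
#'
#' @param context 3-character bulge key: the flanking bases and the bulged
#'   base read 5'->3' on the strand that carries the bulge.
#' @param params a `thermo_params` object.
#' @param kind `"deletion"` (target bulge) or `"insertion"` (probe bulge).
#' @return ddG in kcal/mol.
#' @export
ddg_bulge <- function(context, params = default_params(),
                      kind = c("deletion", "insertion")) {
  kind <- match.arg(kind)
  check_dna(context, "bulge context")
  if (nchar(context) != 3L) stop("bulge context must be 3 bases", call. = FALSE)
  context <- canonical_bulge(context)  # reversal-invariant loss term
  b <- strsplit(context, "")[[1]]
  loop <- params$bulge_alpha * lookup_bulge_sln(params, context)
  lost <- if (kind == "deletion") {
    # bulged strand is the target: reference stacks from the target triplet
    .ref_stack(params, b[1], b[2]) + .ref_stack(params, b[2], b[3])
  } else {
    # bulged strand is the probe: the single reference stack it interrupts,
    # between the flanking probe bases
    lookup_nn(params, paste0(b[1], b[3]))
  }
  loop - lost
}

#' Tandem-mismatch destabilization
#'
#' Two adjacent mismatches flanked by closing pairs (a quadruplet). Under the
#' rule system the quadruplet is split in two halves, each scored by its
#' closing-pair class (AT/GC) and mismatch class (GG, GA, GT, other); the two
#' scores add up to the loop free energy. The loss term covers the three
#' replaced nearest-neighbor stacks.
#'
#' @param quad_key context key `"PPPP/TTTT"`: closing pair, two mismatches,
#'   closing pair.
#' @param params a `thermo_params` object.
#' @param mode `"M9_rules"` (8-rule score system) or `"M8_linear"` (linear map
#'   of a supplied solution loop value).
#' @param sln_loop solution tandem loop free energy for `"M8_linear"`.
#' @return ddG in kcal/mol.
#' @export
ddg_tandem <- function(quad_key, params = default_params(),
                       mode = c("M9_rules", "M8_linear"), sln_loop = NULL) {
  mode <- match.arg(mode)
  k <- .split_key(canonical_context(quad_key))  # reversal-invariant loss term
  if (length(k$p) != 4L) stop("tandem key must span 4 columns", call. = FALSE)
  if (COMP[[k$p[1]]] != k$t[1] || COMP[[k$p[4]]] != k$t[4]) {
    stop("closing pairs must be Watson-Crick", call. = FALSE)
  }
  if (COMP[[k$p[2]]] == k$t[2] || COMP[[k$p[3]]] == k$t[3]) {
    stop("invalid-input error: central pairs must both be mismatches ",
         "(non-adjacent mismatches follow the additive double-mismatch path)",
         call. = FALSE)
  }
  loop <- if (mode == "M9_rules") {
    params$tandem_scores[[tandem_half_class(k$p[1], k$p[2], k$t[2])]] +
      params$tandem_scores[[tandem_half_class(k$p[4], k$p[3], k$t[3])]]
  } else {
    if (is.null(sln_loop)) stop("M8_linear requires sln_loop", call. = FALSE)
    params$tandem_linear[["alpha"]] * sln_loop + params$tandem_linear[["beta"]]
  }
  lost <- .ref_stack(params, k$t[1], k$t[2]) + .ref_stack(params, k$t[2], k$t[3]) +
    .ref_stack(params, k$t[3], k$t[4])
  loop - lost
}

# conservative fallback penalty for loop regions not covered by the derived
# tables: the least destabilizing covered analog sharing the closing pairs,
# scaled by the number of non-Watson-Crick events so larger uncovered loops
# are never rewarded relative to smaller covered ones
.extended_loop <- function(params, region, t_active) {
  # region: data.frame rows of conformation_events inside the loop;
  # t_active: target bases of the flanking closing pairs (NA at an imposed
  # terminus, where only one closer exists)
  left_p <- if (is.na(t_active[1])) NA_character_ else COMP[[t_active[1]]]
  right_p <- if (is.na(t_active[2])) NA_character_ else COMP[[t_active[2]]]
  all_bulge <- all(region$type %in% c("probe_bulge", "target_bulge")) &&
    length(unique(region$type)) == 1L
  if (all_bulge) {
    keys <- names(params$bulge_loops_sln)
    cand <- params$bulge_alpha * params$bulge_loops_sln
    pick <- if (!is.na(left_p) && !is.na(right_p)) {
      f1 <- substr(keys, 1, 1); f3 <- substr(keys, 3, 3)
      (f1 == left_p & f3 == right_p) | (f1 == right_p & f3 == left_p) |
        (f1 == COMP[[left_p]] & f3 == COMP[[right_p]]) |
        (f1 == COMP[[right_p]] & f3 == COMP[[left_p]])
    } else rep(TRUE, length(cand))
    if (!any(pick)) pick <- rep(TRUE, length(cand))
    return(nrow(region) * min(cand[pick]))
  }
  sm <- params$single_mm_loops
  keys <- names(sm)
  closers_of <- function(k) {
    h <- .split_key(k)
    # both strand readings of the stored canonical key
    list(c(h$p[1], h$p[3]), c(h$t[3], h$t[1]))
  }
  pick <- vapply(keys, function(k) {
    any(vapply(closers_of(k), function(cl) {
      (is.na(left_p) || cl[1] == left_p) && (is.na(right_p) || cl[2] == right_p)
    }, logical(1)))
  }, logical(1))
  if (!any(pick)) pick <- rep(TRUE, length(sm))
  n_events <- sum(region$type != "pair")
  max(n_events, 1L) * min(sm[pick])
}

#' Free energy of an arbitrary duplex conformation
#'
#' Assembles the total duplex free energy: the Watson-Crick reference energy
#' of the active (non-relaxed) target site plus one loop contribution per run
#' of non-paired columns. Runs of one mismatch, one bulged base, or two
#' adjacent mismatches use the calibrated single-mismatch, bulge, and tandem
#' rules; separated mismatches are additive; anything else (3+ adjacent
#' mismatches, multi-base bulges, terminal mismatches in the imposed
#' conformation) falls through to the conservative extended rules and flags
#' the result.
#'
#' @param conf a `duplex_conformation`.
#' @param params a `thermo_params` object.
#' @param sm_mode,tandem_mode loop modes, see [ddg_single_mismatch()] and
#'   [ddg_tandem()] (linear modes need loop values in the tables and are only
#'   available through those functions; here the table/rule modes are used).
#' @return numeric free energy (kcal/mol) with attribute `extended` (logical:
#'   TRUE when any loop used the fallback rules).
#' @export
dg_of_conformation <- function(conf, params = default_params(),
                               sm_mode = "M5_table", tandem_mode = "M9_rules") {
  stopifnot(inherits(conf, "duplex_conformation"))
  n <- length(conf$probe)
  keep <- seq_len(n)
  if (conf$relaxed_left > 0) keep <- setdiff(keep, seq_len(conf$relaxed_left))
  if (conf$relaxed_right > 0) keep <- setdiff(keep, (n - conf$relaxed_right + 1L):n)
  p <- conf$probe[keep]; t <- conf$target[keep]
  ev <- conformation_events(duplex_conformation(p, t))
  extended <- FALSE

  # reference perfect duplex over the active target bases
  t_idx <- which(t != "-")
  if (length(t_idx) < 2L) {
    # no duplex core left: initiation penalty only
    res <- params$dg_init
    attr(res, "extended") <- extended
    return(res)
  }
  t_bases <- t[t_idx]
  ref_stacks <- vapply(seq_len(length(t_bases) - 1L), function(i) {
    .ref_stack(params, t_bases[i], t_bases[i + 1L])
  }, numeric(1))
  dg <- sum(ref_stacks) + params$dg_init

  # runs of non-pair columns
  is_loop <- ev$type != "pair"
  r <- rle(is_loop)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (j in which(r$values)) {
    cols <- starts[j]:ends[j]
    region <- ev[cols, , drop = FALSE]
    # target positions (in t_bases indexing) inside and flanking the region
    t_pos <- match(cols, t_idx)            # NA for probe-bulge columns
    inside <- t_pos[!is.na(t_pos)]
    left_t <- if (starts[j] > 1L) t[starts[j] - 1L] else NA_character_
    right_t <- if (ends[j] < length(t)) t[ends[j] + 1L] else NA_character_
    # stacks of the reference disrupted by this region
    touched <- unique(c(inside - 1L, inside))
    if (length(inside) == 0L) {
      # pure probe bulge: interrupts the single stack between flanking targets
      lpos <- match(starts[j] - 1L, t_idx)
      touched <- lpos
    }
    touched <- touched[touched >= 1L & touched <= length(ref_stacks)]
    lost <- sum(ref_stacks[touched])

    at_terminus <- is.na(left_t) || is.na(right_t)
    types <- region$type
    ddg <- NULL
    if (!at_terminus) {
      if (nrow(region) == 1L && types == "mismatch") {
        key <- paste0(COMP[[left_t]], region$probe_base, COMP[[right_t]], "/",
                      left_t, region$target_base, right_t)
        ddg <- ddg_single_mismatch(key, params, mode = sm_mode)
      } else if (nrow(region) == 1L && types == "target_bulge") {
        ddg <- ddg_bulge(paste0(left_t, region$target_base, right_t), params,
                         kind = "deletion")
      } else if (nrow(region) == 1L && types == "probe_bulge") {
        lp <- p[starts[j] - 1L]; rp <- p[ends[j] + 1L]
        ddg <- ddg_bulge(paste0(lp, region$probe_base, rp), params,
                         kind = "insertion")
      } else if (nrow(region) == 2L && all(types == "mismatch")) {
        key <- paste0(COMP[[left_t]], region$probe_base[1], region$probe_base[2],
                      COMP[[right_t]], "/",
                      left_t, region$target_base[1], region$target_base[2], right_t)
        ddg <- ddg_tandem(key, params, mode = tandem_mode)
      }
    }
    if (is.null(ddg)) {
      # uncovered or terminal region: conservative extended rules against the
      # stacks this region actually disrupts
      ddg <- .extended_loop(params, region, c(left_t, right_t)) - lost
      extended <- TRUE
    }
    dg <- dg + ddg
  }
  attr(dg, "extended") <- extended
  dg
}

#' Minimize a conformation over relaxed-end states
#'
#' A mismatch near a probe terminus can lower the total free energy by
#' leaving all bases from the mismatch to that terminus unpaired (the loop
#' penalty is avoided at the cost of the terminal stacks). This enumerates
#' the imposed conformation, every single-event relaxation toward either
#' terminus, and the two-event combinations relaxing opposite ends, and
#' returns the conformation with the most negative free energy.
#'
#' @param conf imposed `duplex_conformation` (no relaxation set).
#' @param params a `thermo_params` object.
#' @return the minimizing `duplex_conformation`, with attributes `dg` (its
#'   free energy) and `extended`.
#' @export
minimize_conformation <- function(conf, params = default_params()) {
  stopifnot(inherits(conf, "duplex_conformation"))
  n <- length(conf$probe)
  ev <- conformation_events(conf)
  loop_cols <- which(ev$type != "pair")
  # candidate (relaxed_left, relaxed_right) pairs
  cands <- list(c(conf$relaxed_left, conf$relaxed_right))
  for (col in loop_cols) {
    cands <- c(cands, list(c(col, 0L)), list(c(0L, n - col + 1L)))
  }
  if (length(loop_cols) >= 2L) {
    for (a in loop_cols) for (b in loop_cols) {
      if (a < b) cands <- c(cands, list(c(a, n - b + 1L)))
    }
  }
  best <- NULL; best_dg <- Inf; best_ext <- FALSE
  for (cr in unique(cands)) {
    if (cr[1] + cr[2] >= n) next
    cand <- duplex_conformation(conf$probe, conf$target, cr[1], cr[2])
    dg <- dg_of_conformation(cand, params)
    if (dg < best_dg - 1e-12) {
      best_dg <- dg; best <- cand; best_ext <- attr(dg, "extended")
    }
  }
  attr(best, "dg") <- as.numeric(best_dg)
  attr(best, "extended") <- best_ext
  best
}

#' Mismatch destabilization of a whole conformation
#'
#' Difference between the (minimized or imposed) conformation free energy and
#' the perfect-match duplex of the same target site.
#' @param conf a `duplex_conformation`.
#' @param params a `thermo_params` object.
#' @param minimize relax terminal mismatches before scoring (default TRUE).
#' @return ddG in kcal/mol (0 for a perfect duplex).
#' @export
ddg_of_conformation <- function(conf, params = default_params(), minimize = TRUE) {
  dg <- if (minimize) {
    attr(minimize_conformation(conf, params), "dg")
  } else {
    as.numeric(dg_of_conformation(conf, params))
  }
  t_bases <- conf$target[conf$target != "-"]
  ref_probe <- paste(COMP[t_bases], collapse = "")
  dg - dg_perfect(ref_probe, params)
}
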