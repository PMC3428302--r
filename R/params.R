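DNA_BASES <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse complement of a plain character sequence
#' @param x character vector of DNA strings (ACGT).
#' @return character vector, reverse complements.
#' @keywords internal
revcomp_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop("invalid ", what, ": characters outside {A,C,G,T} in ",
         paste(x[bad], collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

# ---- canonical context keys --------------------------------------------------
#
# A duplex context is written "PPP/TTT": the probe strand 5'->3' on the left,
# the target strand 3'->5' on the right, so that the i-th characters of both
# halves face each other.  "-" marks an unpaired (bulged) position.  Reading
# the same physical duplex from the other strand reverses both halves and
# swaps them; the canonical form is the lexicographically smaller of the two
# readings.  Nearest-neighbor stacks use the shorthand of just the probe-side
# dinucleotide ("AG" == "AG/TC"), for which strand reversal is the reverse
# complement.

#' Canonical form of a duplex context key
#'
#' Context keys are written `"PROBE/TARGET"` with the probe strand 5'->3' and
#' the target strand 3'->5' (aligned column-wise; `-` marks a bulged/unpaired
#' position). Reading the duplex from the opposite strand swaps and reverses
#' the two halves; the canonical key is the lexicographically smaller reading,
#' so a context and its strand-reversed mate always share one key.
#'
#' @param key character vector of `"PPP/TTT"` context keys.
#' @return character vector of canonical keys.
#' @examples
#' canonical_context("AGA/TGT")  # == canonical_context("TGT/AGA")
#' @export
canonical_context <- function(key) {
  vapply(key, function(k) {
    halves <- strsplit(k, "/", fixed = TRUE)[[1]]
    if (length(halves) != 2L || nchar(halves[1]) != nchar(halves[2])) {
      stop("malformed duplex context key: ", k, call. = FALSE)
    }
    rev_one <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
    alt <- paste0(rev_one(halves[2]), "/", rev_one(halves[1]))
    min(k, alt)
  }, character(1), USE.NAMES = FALSE)
}

#' Canonical nearest-neighbor stack key
#'
#' A stack is two adjacent Watson-Crick base pairs, identified by the
#' probe-side dinucleotide read 5'->3'. Strand reversal maps a dinucleotide to
#' its reverse complement; the canonical key is the smaller of the two.
#'
#' @param dinuc character vector of dinucleotides (e.g. `"AG"`).
#' @return canonical dinucleotide keys.
#' @export
canonical_stack <- function(dinuc) {
  check_dna(dinuc, "stack")
  if (any(nchar(dinuc) != 2L)) stop("stack keys must be dinucleotides", call. = FALSE)
  pmin(dinuc, revcomp_chr(dinuc))
}

#' Canonical bulge context key
#'
#' A bulge context is the unpaired base together with the two flanking
#' Watson-Crick pairs, written as the three consecutive bases on the strand
#' that carries the bulge, 5'->3' (e.g. `"AGT"`: flanks A and T, bulged G).
#' Strand reversal reads the same triplet 3'->5', i.e. reverses the string.
#'
#' @param key character vector of 3-character bulge keys.
#' @return canonical (lexicographically smaller reading) keys.
#' @export
canonical_bulge <- function(key) {
  check_dna(key, "bulge context")
  if (any(nchar(key) != 3L)) stop("bulge keys are 3 bases", call. = FALSE)
  rev_one <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  vapply(key, function(k) min(k, rev_one(k)), character(1), USE.NAMES = FALSE)
}

#' Enumerate canonical nearest-neighbor stacks
#'
#' All 16 probe-side dinucleotides collapse to 10 equivalence classes under
#' strand reversal (4 self-complementary + 6 pairs).
#' @return sorted character vector of 10 canonical stack keys.
#' @export
nn_contexts <- function() {
  all16 <- as.vector(outer(DNA_BASES, DNA_BASES, paste0))
  sort(unique(canonical_stack(all16)))
}

#' Enumerate canonical single-mismatch triplet contexts
#'
#' A triplet is (closing Watson-Crick pair, non-Watson-Crick pair, closing
#' Watson-Crick pair). There are 4 x 12 x 4 = 192 ordered triplets; merging
#' strand-reversed readings leaves 104 classes.
#'
#' @return sorted character vector of 104 canonical `"PPP/TTT"` keys.
#' @export
single_mismatch_contexts <- function() {
  keys <- character(0)
  for (p1 in DNA_BASES) for (pm in DNA_BASES) for (tm in DNA_BASES) {
    if (tm == COMP[[pm]]) next  # Watson-Crick: not a mismatch
    for (p3 in DNA_BASES) {
      keys <- c(keys, paste0(p1, pm, p3, "/", COMP[[p1]], tm, COMP[[p3]]))
    }
  }
  sort(unique(canonical_context(keys)))
}

#' Enumerate bulge-loop contexts
#'
#' All combinations of a bulged base identity and the two flanking
#' Watson-Crick pairs, keyed by the bulge-strand triplet: 4 x 16 = 64 written
#' forms (strand-reversed mates are kept as distinct keys carrying equal
#' values).
#' @return sorted character vector of 64 bulge keys.
#' @export
bulge_contexts <- function() {
  sort(as.vector(outer(DNA_BASES, as.vector(outer(DNA_BASES, DNA_BASES, paste0)),
                       function(a, b) paste0(substr(b, 1, 1), a, substr(b, 2, 2)))))
}

#' Tandem-mismatch rule classes
#'
#' The tandem rule system scores each half of a tandem-mismatch quadruplet by
#' closing-pair class (AT or GC) and mismatch class (GG, GA, GT, or other),
#' giving 2 x 4 = 8 rules.
#' @return character vector of the 8 class labels, e.g. `"GC:GG"`.
#' @export
tandem_rule_classes <- function() {
  as.vector(outer(c("AT", "GC"), c("GG", "GA", "GT", "other"),
                  function(a, b) paste0(a, ":", b)))
}

#' Class label of one tandem-mismatch half
#' @param closing_probe_base probe-side base of the closing Watson-Crick pair.
#' @param mm_probe_base,mm_target_base the two bases of the mismatch.
#' @return one of the 8 labels of [tandem_rule_classes()].
#' @export
tandem_half_class <- function(closing_probe_base, mm_probe_base, mm_target_base) {
  closing <- ifelse(closing_probe_base %in% c("A", "T"), "AT", "GC")
  pair <- paste0(pmin(mm_probe_base, mm_target_base),
                 pmax(mm_probe_base, mm_target_base))
  mm <- ifelse(pair == "GG", "GG",
        ifelse(pair == "AG", "GA",
        ifelse(pair == "GT", "GT", "other")))
  paste0(closing, ":", mm)
}

# ---- parameter container -----------------------------------------------------

#' Construct a thermodynamic parameter set
#'
#' Bundles every calibrated constant of the microarray free-energy model:
#' the 10 nearest-neighbor stack free energies, the duplex initiation penalty,
#' the 104 single-mismatch loop free energies, the bulge slope mapping
#' solution bulge loops to the array together with the 64 solution bulge-loop
#' values, the 8 tandem half-quadruplet scores, the linear solution-to-array
#' mappings for single and tandem mismatch loops, the formamide m-value, the
#' effective probe concentration, and the physical constants. All free
#' energies are kcal/mol at the hybridization temperature.
#'
#' @param nn_free_energies named numeric, canonical stack key -> kcal/mol (10 entries).
#' @param dg_init initiation free energy penalty, kcal/mol.
#' @param single_mm_loops named numeric, canonical triplet key -> kcal/mol (104 entries).
#' @param bulge_alpha dimensionless slope scaling solution bulge loops to array values.
#' @param bulge_loops_sln named numeric, bulge key -> solution kcal/mol (64 entries,
#'   strand-reversed mates present with equal values).
#' @param tandem_scores named numeric, the 8 tandem rule scores (kcal/mol per half).
#' @param sm_linear numeric `c(alpha, beta)` linear map from solution single-mismatch
#'   loop free energy to the array value.
#' @param tandem_linear numeric `c(alpha, beta)` linear map for tandem loops.
#' @param m_value kcal/mol free-energy increase per percent formamide (v/v).
#' @param effective_probe_conc effective probe concentration \{P\}o, molar.
#' @param gas_constant kcal/(mol K).
#' @param temperature hybridization temperature, K.
#' @param meta optional free-form list (provenance).
#' @return object of class `thermo_params`.
#' @export
thermo_params <- function(nn_free_energies, dg_init, single_mm_loops,
                          bulge_alpha, bulge_loops_sln, tandem_scores,
                          sm_linear = c(alpha = 0.354, beta = 0.487),
                          tandem_linear = c(alpha = 0.198, beta = 1.167),
                          m_value = 0.173,
                          effective_probe_conc = 0.010,
                          gas_constant = 0.00199,
                          temperature = 315.15,
                          meta = list()) {
  p <- structure(list(
    nn_free_energies = nn_free_energies,
    dg_init = dg_init,
    single_mm_loops = single_mm_loops,
    bulge_alpha = bulge_alpha,
    bulge_loops_sln = bulge_loops_sln,
    tandem_scores = tandem_scores,
    sm_linear = c(alpha = unname(sm_linear[1]), beta = unname(sm_linear[2])),
    tandem_linear = c(alpha = unname(tandem_linear[1]), beta = unname(tandem_linear[2])),
    m_value = m_value,
    effective_probe_conc = effective_probe_conc,
    gas_constant = gas_constant,
    temperature = temperature,
    meta = meta
  ), class = "thermo_params")
  validate_params(p)
}

#' Validate a thermodynamic parameter set
#'
#' Checks table completeness (10 / 104 / 64 / 8 entries on canonical keys),
#' strand-reversal consistency of the bulge table, and positivity of the
#' physical constants.
#' @param p a `thermo_params` object.
#' @return `p`, invisibly mutated to have sorted tables.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "thermo_params"))
  if (!isTRUE(p$m_value > 0)) stop("m_value must be > 0", call. = FALSE)
  if (!isTRUE(p$temperature > 0)) stop("temperature must be > 0", call. = FALSE)
  if (!isTRUE(p$gas_constant > 0)) stop("gas_constant must be > 0", call. = FALSE)
  if (!isTRUE(p$effective_probe_conc > 0)) {
    stop("effective_probe_conc must be > 0", call. = FALSE)
  }
  nn_want <- nn_contexts()
  if (!setequal(names(p$nn_free_energies), nn_want)) {
    stop("nn_free_energies must have exactly the 10 canonical stack keys; ",
         "missing: ", paste(setdiff(nn_want, names(p$nn_free_energies)), collapse = ","),
         call. = FALSE)
  }
  sm_want <- single_mismatch_contexts()
  if (!setequal(names(p$single_mm_loops), sm_want)) {
    stop("single_mm_loops must have exactly the 104 canonical triplet keys (",
         length(p$single_mm_loops), " given)", call. = FALSE)
  }
  bl_want <- bulge_contexts()
  if (!setequal(names(p$bulge_loops_sln), bl_want)) {
    stop("bulge_loops_sln must have exactly the 64 bulge keys", call. = FALSE)
  }
  rev_one <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  revs <- vapply(names(p$bulge_loops_sln), rev_one, character(1))
  if (any(abs(p$bulge_loops_sln - p$bulge_loops_sln[revs]) > 1e-9)) {
    stop("bulge_loops_sln must assign equal values to strand-reversed mates",
         call. = FALSE)
  }
  if (!setequal(names(p$tandem_scores), tandem_rule_classes())) {
    stop("tandem_scores must have exactly the 8 rule-class keys", call. = FALSE)
  }
  p$nn_free_energies <- p$nn_free_energies[nn_want]
  p$single_mm_loops <- p$single_mm_loops[sm_want]
  p$bulge_loops_sln <- p$bulge_loops_sln[bl_want]
  p$tandem_scores <- p$tandem_scores[tandem_rule_classes()]
  invisible(p)
}

#' @export
print.thermo_params <- function(x, ...) {
  cat("<thermo_params>\n")
  cat(sprintf("  m-value: %.4g kcal/mol/%% FA   T: %.2f K   R: %.5f\n",
              x$m_value, x$temperature, x$gas_constant))
  cat(sprintf("  dG init: %.3g kcal/mol   {P}o: %.4g M (log10 = %.3f)\n",
              x$dg_init, x$effective_probe_conc, log10(x$effective_probe_conc)))
  cat(sprintf("  tables: %d NN stacks, %d single-mismatch loops, %d bulge loops (alpha = %.3f), %d tandem scores\n",
              length(x$nn_free_energies), length(x$single_mm_loops),
              length(x$bulge_loops_sln), x$bulge_alpha, length(x$tandem_scores)))
  invisible(x)
}

# table lookups (canonicalize the query; missing key -> parameter-table error)

lookup_nn <- function(p, dinuc) {
  key <- canonical_stack(dinuc)
  v <- p$nn_free_energies[key]
  if (anyNA(v)) stop("parameter-table error: missing nearest-neighbor key ",
                     paste(key[is.na(v)], collapse = ","), call. = FALSE)
  unname(v)
}

lookup_sm_loop <- function(p, triplet_key) {
  key <- canonical_context(triplet_key)
  v <- p$single_mm_loops[key]
  if (anyNA(v)) stop("parameter-table error: missing single-mismatch loop key ",
                     paste(key[is.na(v)], collapse = ","), call. = FALSE)
  unname(v)
}

lookup_bulge_sln <- function(p, bulge_key) {
  v <- p$bulge_loops_sln[bulge_key]
  if (anyNA(v)) {
    rev_one <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
    v2 <- p$bulge_loops_sln[vapply(bulge_key, rev_one, character(1))]
    v[is.na(v)] <- v2[is.na(v)]
  }
  if (anyNA(v)) stop("parameter-table error: missing bulge loop key ",
                     paste(bulge_key[is.na(v)], collapse = ","), call. = FALSE)
  unname(v)
}

#' Gas-constant times temperature, kcal/mol
#' @param p a `thermo_params` object.
#' @return numeric RT.
#' @keywords internal
rt_of <- function(p) p$gas_constant * p$temperature
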