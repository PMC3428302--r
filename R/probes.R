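# Probe-set construction, the probe naming convention, the poly-T linker
# rule, and probe/target conformations.
#
# Coordinates are 1-based and inclusive on the target gene's sense strand;
# a probe is the reverse complement of its target site.  Names follow
# "<target><start>-<end>[_<annotation>...]", e.g. "E1013-1034_10AC" (A->C
# substitution at probe position 10), "_gap11" (deleted probe base 11),
# "_I11G" (G inserted between probe positions 11 and 12).

#' Tile perfect-match probes along a target gene
#'
#' One probe per start position `s` with `s >= min_pos` and
#' `s + length - 1 <= max_pos`; positions near the gene termini are excluded
#' to avoid unamplified ends.
#'
#' @param target_seq target gene sequence (character scalar, sense strand) or
#'   a [Biostrings::DNAString].
#' @param length probe length in nt (default 22).
#' @param min_pos,max_pos first and last target positions a probe may cover
#'   (defaults 50 and 1450).
#' @param target_id one-letter target label used in probe names (default "E").
#' @return data.frame of probe records: `name`, `target_id`, `start`, `end`,
#'   `sequence`, `annotations` (empty string), `set`.
#' @export
tile_probes <- function(target_seq, length = 22L, min_pos = 50L, max_pos = 1450L,
                        target_id = "E") {
  target_seq <- toupper(as.character(target_seq))
  check_dna(target_seq, "target sequence")
  if (nchar(target_seq) < max_pos) {
    stop("bounds error: target (", nchar(target_seq), " nt) shorter than max_pos = ",
         max_pos, call. = FALSE)
  }
  starts <- seq.int(min_pos, max_pos - length + 1L)
  sites <- substring(target_seq, starts, starts + length - 1L)
  data.frame(
    name = paste0(target_id, starts, "-", starts + length - 1L),
    target_id = target_id,
    start = starts,
    end = starts + length - 1L,
    sequence = revcomp_chr(sites),
    annotations = "",
    set = "Tile",
    stringsAsFactors = FALSE
  )
}

# probe position p corresponds to target position end - p + 1 (the probe is
# the reverse complement of the site)
.apply_sub <- function(seq, pos, new) {
  b <- strsplit(seq, "")[[1]]; b[pos] <- new; paste(b, collapse = "")
}

#' Build mismatch probe sets from perfect-match tiles
#'
#' Constructors for the standard modification sets used in rule calibration:
#' \describe{
#'   \item{OneM}{all 3 substitutions at probe position 11, every tile.}
#'   \item{PosM}{all 3 substitutions at every position, a probe subset.}
#'   \item{Gap}{deletion of probe base 5, 11, 12 or 18 (21-mer probes).}
#'   \item{Insertion}{each of the 4 bases inserted between positions 11 and
#'     12 (23-mer probes).}
#'   \item{TwoM}{3 x 3 substitutions at position pairs (5,11), (11,18), (5,18).}
#'   \item{Tandem}{3 x 3 substitutions at adjacent positions (11,12).}
#' }
#'
#' @param tiles data.frame from [tile_probes()] (22-mers required).
#' @param set one of `"OneM"`, `"PosM"`, `"Gap"`, `"Insertion"`, `"TwoM"`,
#'   `"Tandem"`.
#' @param subset for the sets defined on a probe subset: indices into `tiles`
#'   (default: an evenly spaced sample of 62 probes).
#' @return data.frame of probe records (same columns as [tile_probes()]).
#' @export
make_mismatch_sets <- function(tiles, set = c("OneM", "PosM", "Gap", "Insertion",
                                              "TwoM", "Tandem"),
                               subset = NULL) {
  set <- match.arg(set)
  L <- nchar(tiles$sequence)
  if (any(L != 22L)) {
    stop("invalid-input error: mismatch-set constructors require 22-mer probes",
         call. = FALSE)
  }
  if (set != "OneM") {
    if (is.null(subset)) {
      subset <- unique(round(seq(1, nrow(tiles), length.out = min(62L, nrow(tiles)))))
    }
    tiles <- tiles[subset, , drop = FALSE]
  }
  out <- list()
  for (i in seq_len(nrow(tiles))) {
    seq <- tiles$sequence[i]
    b <- strsplit(seq, "")[[1]]
    stem <- paste0(tiles$target_id[i], tiles$start[i], "-", tiles$end[i])
    add <- function(suffix, newseq) {
      out[[length(out) + 1L]] <<- data.frame(
        name = paste0(stem, suffix), target_id = tiles$target_id[i],
        start = tiles$start[i], end = tiles$end[i], sequence = newseq,
        annotations = sub("^_", "", suffix), set = set, stringsAsFactors = FALSE)
    }
    subs_at <- function(positions) {
      grid <- expand.grid(lapply(positions, function(p) setdiff(DNA_BASES, b[p])),
                          stringsAsFactors = FALSE)
      for (r in seq_len(nrow(grid))) {
        s <- seq; suffix <- ""
        for (j in seq_along(positions)) {
          p <- positions[j]; new <- grid[r, j]
          s <- .apply_sub(s, p, new)
          suffix <- paste0(suffix, "_", p, b[p], new)
        }
        add(suffix, s)
      }
    }
    switch(set,
      OneM = subs_at(11L),
      PosM = for (p in seq_len(22L)) subs_at(p),
      Tandem = subs_at(c(11L, 12L)),
      TwoM = for (pp in list(c(5L, 11L), c(11L, 18L), c(5L, 18L))) subs_at(pp),
      Gap = for (p in c(5L, 11L, 12L, 18L)) {
        add(paste0("_gap", p), paste(b[-p], collapse = ""))
      },
      Insertion = for (ins in DNA_BASES) {
        add(paste0("_I11", ins),
            paste(c(b[1:11], ins, b[12:22]), collapse = ""))
      }
    )
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$name), , drop = FALSE]
}

#' Encode a probe name
#'
#' @param target_id one-letter target label.
#' @param start,end 1-based inclusive target-site coordinates.
#' @param annotations character vector of annotation tokens (may be empty):
#'   substitutions `"<pos><orig><new>"`, deletions `"gap<pos>"`, insertions
#'   `"I<pos><base>"`.
#' @return the probe name, e.g. `"E1013-1034_10AC"`.
#' @export
probe_name <- function(target_id, start, end, annotations = character(0)) {
  paste0(target_id, start, "-", end,
         if (length(annotations)) paste0("_", paste(annotations, collapse = "_")) else "")
}

#' Decode a probe name
#'
#' Inverse of [probe_name()]; also accepts the typographic en-dash between
#' coordinates.
#' @param name probe name.
#' @return list with `target_id`, `start`, `end`, `annotations` (character
#'   vector of tokens) and `events` (data.frame: `type`, `pos`, `orig`, `new`).
#' @export
parse_probe_name <- function(name) {
  nm <- gsub("–", "-", name)
  parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
  m <- regmatches(parts[1], regexec("^([A-Za-z]+)([0-9]+)-([0-9]+)$", parts[1]))[[1]]
  if (length(m) != 4L) {
    stop("parse error in probe name at stem: ", name, call. = FALSE)
  }
  ann <- parts[-1]
  events <- list()
  for (a in ann) {
    if (grepl("^gap[0-9]+$", a)) {
      events[[length(events) + 1L]] <- data.frame(
        type = "gap", pos = as.integer(sub("^gap", "", a)),
        orig = NA_character_, new = NA_character_, stringsAsFactors = FALSE)
    } else if (grepl("^I[0-9]+[ACGT]$", a)) {
      events[[length(events) + 1L]] <- data.frame(
        type = "insertion", pos = as.integer(gsub("^I([0-9]+)[ACGT]$", "\\1", a)),
        orig = NA_character_, new = sub("^I[0-9]+", "", a), stringsAsFactors = FALSE)
    } else if (grepl("^[0-9]+[ACGT][ACGT]$", a)) {
      core <- regmatches(a, regexec("^([0-9]+)([ACGT])([ACGT])$", a))[[1]]
      events[[length(events) + 1L]] <- data.frame(
        type = "substitution", pos = as.integer(core[2]),
        orig = core[3], new = core[4], stringsAsFactors = FALSE)
    } else {
      stop("parse error in probe name annotation '", a, "': ", name, call. = FALSE)
    }
  }
  list(target_id = m[2], start = as.integer(m[3]), end = as.integer(m[4]),
       annotations = ann,
       events = if (length(events)) do.call(rbind, events) else
         data.frame(type = character(0), pos = integer(0),
                    orig = character(0), new = character(0)))
}

#' Adjust the poly-T linker against the target context
#'
#' The 20-base poly-T linker at the probe 3' end faces the three target bases
#' immediately adjacent to the target site. Any of the first three linker Ts
#' that faces an A or G in the target is converted to A (avoiding dT-dA /
#' dT-dG binding); positions 4-20 stay T.
#'
#' @param facing_bases character vector of up to 3 target bases facing linker
#'   positions 1-3 (ordered outward from the probe); `NA` where the gene ends.
#' @param linker_length total linker length (default 20).
#' @return the adjusted linker sequence.
#' @export
adjust_linker <- function(facing_bases, linker_length = 20L) {
  facing_bases <- toupper(facing_bases)
  first3 <- rep("T", 3L)
  n <- min(3L, length(facing_bases))
  conv <- !is.na(facing_bases[seq_len(n)]) & facing_bases[seq_len(n)] %in% c("A", "G")
  first3[seq_len(n)][conv] <- "A"
  paste(c(first3, rep("T", linker_length - 3L)), collapse = "")
}

#' Target bases facing the linker of a probe
#'
#' The probe 3' end pairs with the 5' end of the target site, so the linker
#' extends over target positions `start - 1`, `start - 2`, `start - 3`.
#' @param target_seq target gene sequence.
#' @param start probe target-site start (1-based).
#' @return character vector of 3 bases (NA past the gene 5' end).
#' @export
linker_context <- function(target_seq, start) {
  target_seq <- toupper(as.character(target_seq))
  pos <- start - (1:3)
  ifelse(pos >= 1, substring(target_seq, pos, pos), NA_character_)
}

# ---- conformations from sequences -------------------------------------------

#' Column alignment of a probe against its target site
#'
#' For equal lengths the duplex is formed column-wise; when lengths differ
#' (bulges) a global alignment with single-base gaps places the bulge.
#' @param probe_seq probe, 5'->3'.
#' @param target_site target site, 5'->3' on the gene sense strand.
#' @return a `duplex_conformation` (imposed; no relaxation).
#' @export
align_probe_site <- function(probe_seq, target_site) {
  probe_seq <- toupper(probe_seq); target_site <- toupper(target_site)
  check_dna(probe_seq, "probe"); check_dna(target_site, "target site")
  # target written 3'->5' left-to-right faces the probe 5'->3'
  t_cols_full <- rev(strsplit(target_site, "")[[1]])
  p_cols_full <- strsplit(probe_seq, "")[[1]]
  if (length(p_cols_full) == length(t_cols_full)) {
    return(duplex_conformation(p_cols_full, t_cols_full))
  }
  perfect <- revcomp_chr(target_site)  # reference probe of the site
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(probe_seq, perfect, type = "global",
                                      substitutionMatrix = mat,
                                      gapOpening = 2, gapExtension = 2)
  p_aln <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s_aln <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  t_aln <- ifelse(s_aln == "-", "-", unname(COMP[s_aln]))
  duplex_conformation(p_aln, t_aln)
}

#' Locate and score a probe on a candidate sequence
#'
#' Semi-global alignment of the probe against a candidate (non-)target gene,
#' allowing substitutions and single-base indels; the edit script becomes the
#' pairing events and the conformation is relaxed-end minimized.
#'
#' @param probe_seq probe, 5'->3'.
#' @param candidate_seq candidate gene or site sequence, 5'->3'.
#' @param params a `thermo_params` object.
#' @param min_score alignment score floor (match +1, mismatch -1, gap open
#'   -2.5, gap extend -2.5) below which the probe is declared to have no site;
#'   default `0.5 * nchar(probe_seq)`.
#' @return a minimized `duplex_conformation` with attributes `dg`, `extended`,
#'   `site_start`, `site_end`, `score`; or `NULL` when no site scores above
#'   the floor (treated as zero hybridization efficiency).
#' @export
conformation_from_pair <- function(probe_seq, candidate_seq,
                                   params = default_params(),
                                   min_score = NULL) {
  probe_seq <- toupper(probe_seq); candidate_seq <- toupper(as.character(candidate_seq))
  check_dna(probe_seq, "probe"); check_dna(candidate_seq, "candidate")
  if (is.null(min_score)) min_score <- 0.5 * nchar(probe_seq)
  # the probe reads as the reverse complement of its site, so align it
  # against the reverse complement of the candidate
  rc_cand <- revcomp_chr(candidate_seq)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(probe_seq, rc_cand, type = "global-local",
                                      substitutionMatrix = mat,
                                      gapOpening = 1.5, gapExtension = 1)
  if (Biostrings::score(pa) < min_score) return(NULL)
  p_aln <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s_aln <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  t_aln <- ifelse(s_aln == "-", "-", unname(COMP[s_aln]))
  conf <- duplex_conformation(p_aln, t_aln)
  conf <- minimize_conformation(conf, params)
  sr <- pa@subject@range  # on the reverse complement of the candidate
  n <- nchar(candidate_seq)
  attr(conf, "site_start") <- n - (sr@start + sr@width - 1L) + 1L
  attr(conf, "site_end") <- n - sr@start + 1L
  attr(conf, "score") <- Biostrings::score(pa)
  conf
}

# ---- TSV / FASTA plumbing ----------------------------------------------------

#' Write a probe table as TSV with '#' metadata headers
#' @param probes probe data.frame.
#' @param path output path.
#' @param meta named character vector written as `# key: value` header lines.
#' @return `path`, invisibly.
#' @export
write_probes <- function(probes, path, meta = c()) {
  con <- file(path, "w"); on.exit(close(con))
  for (k in names(meta)) writeLines(paste0("# ", k, ": ", meta[[k]]), con)
  utils::write.table(probes, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe table written by [write_probes()]
#' @param path TSV path.
#' @return data.frame with attribute `meta` (named character vector).
#' @export
read_probes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines)
  meta <- c()
  for (h in hdr) {
    kv <- regmatches(lines[h], regexec("^# ([^:]+): (.*)$", lines[h]))[[1]]
    if (length(kv) == 3L) meta[kv[2]] <- kv[3]
  }
  df <- utils::read.table(text = lines[setdiff(seq_along(lines), hdr)],
                          sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                          colClasses = NA)
  if ("annotations" %in% names(df)) {
    df$annotations <- ifelse(is.na(df$annotations), "", as.character(df$annotations))
  }
  attr(df, "meta") <- meta
  df
}

#' Read target sequences from FASTA
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_targets <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
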