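# Synthetic fixture generator emulating the experimental design: a random
# 16S-sized gene, tiled probe sets, and replicated fluorescence profiles over
# the 8-point formamide series with sigmoidal melting, per-probe brightness
# variation, homoscedastic Gaussian noise on the normalized scale, occasional
# replicate outliers, and soft scanner saturation at the top of the signal
# scale.

#' Synthetic-data generator configuration
#'
#' @param seed integer seed; fixed seed gives byte-identical outputs.
#' @param gene_length target gene length, nt (default 1542).
#' @param fa_series formamide series, % v/v (default the 8-point series).
#' @param noise_sd Gaussian noise SD on the normalized intensity scale
#'   (default 0.078, i.e. variance 0.0061).
#' @param brightness_range per-probe maximum-signal emulation range, a.u.
#'   (default 500-40000, log-uniform).
#' @param saturation_knee signal level where scanner saturation sets in
#'   (default 40000 a.u.).
#' @param saturation_ceiling hard ceiling of the pixel scale (default 65536).
#' @param replicates replicate features per probe (default 3).
#' @param outlier_rate probability that one replicate of a probe/formamide
#'   point is replaced by an outlying value (default 0.01).
#' @param background mean background fluorescence, a.u. (default 50).
#' @param n_probes number of tiled probes to keep (evenly spaced subsample;
#'   default 300).
#' @param probe_length tiled probe length (default 22).
#' @param min_pos,max_pos tiling bounds on the gene (defaults 50, 1450).
#' @param concentration_factor brightness multiplier emulating target
#'   concentration (default 1; 10 emulates the 10x concentration series where
#'   saturation clipping dominates).
#' @param fragment_length_range,fragment_length_mean documented fragment
#'   length distribution of the labeled target (25-150 nt, mean 65); recorded
#'   in the truth table, not used in signal generation.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, gene_length = 1542L,
                         fa_series = fa_series_default(),
                         noise_sd = 0.078,
                         brightness_range = c(500, 40000),
                         saturation_knee = 40000, saturation_ceiling = 65536,
                         replicates = 3L, outlier_rate = 0.01,
                         background = 50,
                         n_probes = 300L, probe_length = 22L,
                         min_pos = 50L, max_pos = 1450L,
                         concentration_factor = 1,
                         fragment_length_range = c(25L, 150L),
                         fragment_length_mean = 65L) {
  stopifnot(noise_sd >= 0, replicates >= 2, gene_length >= max_pos)
  structure(as.list(environment()), class = "synth_config")
}

# soft clip emulating scanner saturation: linear below the knee, exponential
# approach to the ceiling above it
.saturate <- function(x, knee, ceiling) {
  ifelse(x <= knee, x, knee + (ceiling - knee) * (1 - exp(-(x - knee) / (ceiling - knee))))
}

#' Generate a synthetic target, probe set, and intensity profiles
#'
#' @param config a [synth_config()].
#' @param params a `thermo_params` object used as ground truth.
#' @return list with `gene` (named character), `probes` (probe records with
#'   per-probe truth columns `dg`, `melting_point`, `brightness`), `raw`
#'   (long replicate intensity table: `probe`, `fa`, `rep`, `intensity`,
#'   including `Nonsense` control rows), and `truth` (list: the generating
#'   `m`, `log10_po`, per-probe free energies and melting points).
#' @export
synth_generate <- function(config = synth_config(), params = default_params()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  gene <- paste(sample(DNA_BASES, config$gene_length, replace = TRUE), collapse = "")
  tiles <- tile_probes(gene, length = config$probe_length,
                       min_pos = config$min_pos, max_pos = config$max_pos,
                       target_id = "S")
  if (config$n_probes < nrow(tiles)) {
    keep <- unique(round(seq(1, nrow(tiles), length.out = config$n_probes)))
    tiles <- tiles[keep, , drop = FALSE]
  }
  dg <- vapply(tiles$sequence, dg_perfect, numeric(1), params = params,
               USE.NAMES = FALSE)
  names(dg) <- tiles$name
  mp <- stats::setNames(melting_point(dg, params), names(dg))

  # smooth positional brightness field (log scale) emulating amplification
  # and labeling bias along the gene, plus per-probe scatter
  mid <- (tiles$start + tiles$end) / 2
  lo <- log(config$brightness_range[1]); hi <- log(config$brightness_range[2])
  field <- sin(2 * pi * mid / 400) + 0.5 * sin(2 * pi * mid / 97 + 1)
  scatter <- stats::runif(nrow(tiles), -1, 1)
  z <- (field / 1.5 + scatter) / 2          # in ~[-1, 1]
  brightness <- exp((lo + hi) / 2 + z * (hi - lo) / 2) * config$concentration_factor

  tiles$dg <- dg
  tiles$melting_point <- mp
  tiles$brightness <- brightness

  fa <- config$fa_series
  rows <- vector("list", nrow(tiles) + 1L)
  for (i in seq_len(nrow(tiles))) {
    eff <- hyb_efficiency(dg[i], fa, params)
    signal <- brightness[i] * eff
    nrep <- config$replicates
    m <- matrix(rep(signal, each = nrep), nrow = nrep) +
      matrix(stats::rnorm(nrep * length(fa), 0, config$noise_sd * brightness[i]),
             nrow = nrep) +
      config$background
    # occasional replicate outliers
    out_here <- stats::runif(length(fa)) < config$outlier_rate
    for (j in which(out_here)) {
      r <- sample.int(nrep, 1)
      m[r, j] <- m[r, j] * stats::runif(1, 3, 6)
    }
    m <- .saturate(m, config$saturation_knee, config$saturation_ceiling)
    m <- pmin(pmax(m, 0), config$saturation_ceiling)
    rows[[i]] <- data.frame(probe = tiles$name[i],
                            fa = rep(fa, each = nrep),
                            rep = rep(seq_len(nrep), times = length(fa)),
                            intensity = as.vector(m),
                            stringsAsFactors = FALSE)
  }
  # nonsense background controls: replicated noise around the background level
  nrep <- config$replicates
  rows[[length(rows)]] <- data.frame(
    probe = "Nonsense",
    fa = rep(fa, each = nrep),
    rep = rep(seq_len(nrep), times = length(fa)),
    intensity = pmax(0, stats::rnorm(nrep * length(fa), config$background,
                                     config$background / 5)),
    stringsAsFactors = FALSE)
  raw <- do.call(rbind, rows)
  rownames(raw) <- NULL

  list(gene = c(synthetic_gene = gene),
       probes = tiles,
       raw = raw,
       truth = list(m = params$m_value,
                    log10_po = log10(params$effective_probe_conc),
                    dg = dg, melting_point = mp,
                    seed = config$seed))
}

#' Write generator outputs to files
#'
#' Writes the gene as FASTA, the probe table and raw intensities as TSV with
#' `#` metadata headers carrying the seed.
#' @param sim result of [synth_generate()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
synth_write <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "target.fasta")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$gene), fasta)
  probes <- file.path(dir, "probes.tsv")
  write_probes(sim$probes, probes, meta = c(seed = sim$truth$seed))
  raw <- file.path(dir, "intensities.tsv")
  con <- file(raw, "w")
  writeLines(paste0("# seed: ", sim$truth$seed), con)
  utils::write.table(sim$raw, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  truth <- file.path(dir, "truth.tsv")
  write_probes(data.frame(probe = names(sim$truth$dg),
                          dg = sim$truth$dg,
                          melting_point = sim$truth$melting_point,
                          stringsAsFactors = FALSE),
               truth, meta = c(m = sim$truth$m, log10_po = sim$truth$log10_po,
                               seed = sim$truth$seed))
  invisible(c(fasta = fasta, probes = probes, intensities = raw, truth = truth))
}
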