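# Independent oracles used across the suite.  These deliberately take a
# different code path from the package internals: free energies are rebuilt
# event-by-event from the standalone rule operations with hand-constructed
# context keys, and the melting point is found by bisection instead of the
# closed form.

COMP_H <- c(A = "T", C = "G", G = "C", T = "A")

rc_h <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

rc_h_vec <- function(x) vapply(x, rc_h, character(1), USE.NAMES = FALSE)

# brute-force duplex free energy: reference perfect duplex of the target
# site plus one standalone-op ddG per event run, keys built by hand from the
# column strings
oracle_dg <- function(conf, params) {
  p <- conf$probe; t <- conf$target
  n <- length(p)
  keep <- setdiff(seq_len(n), c(seq_len(conf$relaxed_left),
                                if (conf$relaxed_right > 0) (n - conf$relaxed_right + 1L):n))
  p <- p[keep]; t <- t[keep]
  t_bases <- t[t != "-"]
  ref_probe <- paste(COMP_H[t_bases], collapse = "")
  dg <- dg_perfect(ref_probe, params)
  # scan for event runs
  is_pair <- vapply(seq_along(p), function(i) {
    p[i] != "-" && t[i] != "-" && COMP_H[[p[i]]] == t[i]
  }, logical(1))
  r <- rle(!is_pair)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (j in which(r$values)) {
    cols <- starts[j]:ends[j]
    stopifnot(starts[j] > 1L, ends[j] < length(p))  # oracle covers internal events
    lt <- t[starts[j] - 1L]; rt <- t[ends[j] + 1L]
    pp <- p[cols]; tt <- t[cols]
    if (length(cols) == 1L && pp != "-" && tt != "-") {
      key <- paste0(COMP_H[[lt]], pp, COMP_H[[rt]], "/", lt, tt, rt)
      dg <- dg + ddg_single_mismatch(key, params)
    } else if (length(cols) == 1L && pp == "-") {
      dg <- dg + ddg_bulge(paste0(lt, tt, rt), params, kind = "deletion")
    } else if (length(cols) == 1L && tt == "-") {
      lp <- p[starts[j] - 1L]; rp <- p[ends[j] + 1L]
      dg <- dg + ddg_bulge(paste0(lp, pp, rp), params, kind = "insertion")
    } else if (length(cols) == 2L && all(pp != "-") && all(tt != "-")) {
      key <- paste0(COMP_H[[lt]], pp[1], pp[2], COMP_H[[rt]], "/",
                    lt, tt[1], tt[2], rt)
      dg <- dg + ddg_tandem(key, params)
    } else {
      stop("oracle does not cover this region")
    }
  }
  dg
}

# melting point by bisection on [0, 100] to a given interval width
oracle_melting_bisect <- function(dg, params, tol = 1e-9) {
  target <- hyb_efficiency(dg, 0, params) / 2
  f <- function(fa) hyb_efficiency(dg, fa, params) - target
  lo <- 0; hi <- 100
  if (f(hi) > 0) return(NA_real_)  # not melted by 100%
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# random imposed conformation with planted internal events on a short probe;
# returns the conformation (events at least 2 columns from either end and
# non-adjacent so every region is covered by the derived rules)
random_conformation <- function(L = 12L, n_events = 2L) {
  site <- rand_dna(L)
  t_cols <- rev(strsplit(site, "")[[1]])
  p_cols <- COMP_H[t_cols]
  pos_ok <- 3:(L - 2)
  repeat {
    pos <- sort(sample(pos_ok, n_events))
    if (n_events < 2 || diff(pos) >= 3) break
  }
  types <- sample(c("mismatch", "probe_bulge", "target_bulge"), n_events,
                  replace = TRUE, prob = c(0.6, 0.2, 0.2))
  probe <- p_cols; target <- t_cols
  for (k in seq_len(n_events)) {
    i <- pos[k]
    if (types[k] == "mismatch") {
      probe[i] <- sample(setdiff(c("A", "C", "G", "T"), COMP_H[[target[i]]]), 1)
    } else if (types[k] == "probe_bulge") {
      target[i] <- "-"
      probe[i] <- sample(c("A", "C", "G", "T"), 1)
    } else {
      probe[i] <- "-"
    }
  }
  duplex_conformation(unname(probe), unname(target))
}
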