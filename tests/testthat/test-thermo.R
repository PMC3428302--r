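P <- synthetic_params()

test_that("perfect-match free energy is additive and strand-reversal invariant", {
  # 2-mer base case: one stack plus initiation
  expect_equal(dg_perfect("AG", P),
               P$nn_free_energies[[canonical_stack("AG")]] + P$dg_init)
  # reverse complement of the probe reads the same duplex: identical value
  set.seed(11)
  for (i in 1:20) {
    s <- rand_dna(sample(8:25, 1))
    expect_equal(dg_perfect(s, P), dg_perfect(rc_h(s), P))
  }
  # brute-force stack enumeration oracle on a 22-mer (frozen regression case)
  s <- "GATTCGGAACCTTAGACGTCAA"
  b <- strsplit(s, "")[[1]]
  manual <- P$dg_init
  for (i in 1:21) {
    d <- paste0(b[i], b[i + 1])
    key <- min(d, rc_h(d))
    manual <- manual + P$nn_free_energies[[key]]
  }
  expect_equal(dg_perfect(s, P), manual)
  expect_error(dg_perfect("ACGN", P), "invalid")
  expect_error(dg_perfect("A", P), "length")
})

test_that("single-mismatch ddG matches a hand-summed two-lookup oracle", {
  # loop minus the two replaced reference stacks, keys built by hand
  key <- "AGA/TGT"  # A:T closing, G.G mismatch, A:T closing
  loop <- P$single_mm_loops[[canonical_context(key)]]
  lost <- P$nn_free_energies[[canonical_stack("AC")]] +  # comp(T)comp(G)
    P$nn_free_energies[[canonical_stack("CA")]]          # comp(G)comp(T)
  expect_equal(ddg_single_mismatch(key, P), loop - lost)
  # strand-reversed key gives the identical value
  expect_equal(ddg_single_mismatch("TGT/AGA", P), ddg_single_mismatch(key, P))
  # a Watson-Crick "mismatch" is rejected
  expect_error(ddg_single_mismatch("ACA/TGT", P), "Watson-Crick")
  # linear solution-mapping mode
  expect_equal(ddg_single_mismatch(key, P, mode = "M4_linear", sln_loop = 1.0),
               P$sm_linear[["alpha"]] * 1.0 + P$sm_linear[["beta"]] - lost)
})

test_that("bulge ddG follows the deletion/insertion loss-term rule", {
  ctx <- "AGT"  # flanks A,T on the bulged strand; bulged G
  sln <- P$bulge_loops_sln[[ctx]]
  # deletion (target bulge): two reference stacks lost
  del_lost <- P$nn_free_energies[[canonical_stack(paste0("T", "C"))]] +
    P$nn_free_energies[[canonical_stack(paste0("C", "A"))]]
  expect_equal(ddg_bulge(ctx, P, "deletion"), P$bulge_alpha * sln - del_lost)
  # insertion (probe bulge): one stack between the flanking probe bases
  ins_lost <- P$nn_free_energies[[canonical_stack("AT")]]
  expect_equal(ddg_bulge(ctx, P, "insertion"), P$bulge_alpha * sln - ins_lost)
  # deletion and insertion differ by exactly one nearest-neighbor stack
  expect_equal(ddg_bulge(ctx, P, "deletion") - ddg_bulge(ctx, P, "insertion"),
               ins_lost - del_lost)
  # degenerate parameters: zero slope leaves only the loss term
  P0 <- P; P0$bulge_alpha <- 0
  expect_equal(ddg_bulge(ctx, P0, "deletion"), -del_lost)
})

test_that("tandem ddG adds two half-quadruplet scores minus three stacks", {
  # both halves in the same rule cell double that score
  key <- "AGGT/TGGA"  # A:T closers, G.G + G.G mismatches
  cls_l <- tandem_half_class("A", "G", "G")
  cls_r <- tandem_half_class("T", "G", "G")
  expect_identical(cls_l, "AT:GG")
  expect_identical(cls_r, "AT:GG")
  lost <- P$nn_free_energies[[canonical_stack("AC")]] +  # comp(T)comp(G)
    P$nn_free_energies[[canonical_stack("CC")]] +        # comp(G)comp(G)
    P$nn_free_energies[[canonical_stack("CT")]]          # comp(G)comp(A)
  expect_equal(ddg_tandem(key, P), 2 * P$tandem_scores[["AT:GG"]] - lost)
  # end-for-end swap (strand reversal) gives the identical value
  rev_key <- function(k) {
    h <- strsplit(k, "/")[[1]]
    r <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
    paste0(r(h[2]), "/", r(h[1]))
  }
  for (k in c("AGTC/TGGG", "CGAT/GGCA", key)) {
    expect_equal(ddg_tandem(rev_key(k), P), ddg_tandem(k, P))
  }
  # central Watson-Crick pair routes to the separated-mismatch path
  expect_error(ddg_tandem("AGCT/TGGA", P), "additive double-mismatch")
})

test_that("conformation free energy equals the event-sum oracle for all covered cases", {
  # perfect duplex: equals dg_perfect
  set.seed(21)
  site <- rand_dna(12)
  conf <- align_probe_site(rc_h(site), site)
  expect_equal(as.numeric(dg_of_conformation(conf, P)), dg_perfect(rc_h(site), P))
  expect_false(attr(dg_of_conformation(conf, P), "extended"))

  # random conformations with <= 2 internal events on short probes
  for (i in 1:60) {
    conf <- random_conformation(L = 12L, n_events = sample(0:2, 1))
    got <- dg_of_conformation(conf, P)
    expect_false(attr(got, "extended"))
    expect_equal(as.numeric(got), oracle_dg(conf, P), tolerance = 1e-10)
  }
  # tandem mismatches too
  for (i in 1:20) {
    site <- rand_dna(12)
    t_cols <- rev(strsplit(site, "")[[1]])
    probe <- unname(COMP_H[t_cols])
    for (j in 6:7) {
      probe[j] <- sample(setdiff(c("A", "C", "G", "T"), COMP_H[[t_cols[j]]]), 1)
    }
    conf <- duplex_conformation(probe, t_cols)
    expect_equal(as.numeric(dg_of_conformation(conf, P)), oracle_dg(conf, P),
                 tolerance = 1e-10)
  }
})

test_that("two separated mismatches are additive", {
  set.seed(31)
  site <- rand_dna(22)
  t_cols <- rev(strsplit(site, "")[[1]])
  probe <- unname(COMP_H[t_cols])
  mk <- function(pos_set) {
    pr <- probe
    for (j in pos_set) pr[j] <- setdiff(c("A", "C", "G", "T"),
                                        c(COMP_H[[t_cols[j]]], probe[j]))[1]
    duplex_conformation(pr, t_cols)
  }
  dg0 <- dg_perfect(paste(probe, collapse = ""), P)
  d5 <- as.numeric(dg_of_conformation(mk(5), P)) - dg0
  d18 <- as.numeric(dg_of_conformation(mk(18), P)) - dg0
  both <- as.numeric(dg_of_conformation(mk(c(5, 18)), P)) - dg0
  expect_equal(both, d5 + d18, tolerance = 1e-10)
})

test_that("relaxed-end minimization picks the most negative enumerated state", {
  set.seed(41)
  for (i in 1:25) {
    site <- rand_dna(12)
    t_cols <- rev(strsplit(site, "")[[1]])
    probe <- unname(COMP_H[t_cols])
    pos <- sample(2:11, 1)
    probe[pos] <- sample(setdiff(c("A", "C", "G", "T"), COMP_H[[t_cols[pos]]]), 1)
    conf <- duplex_conformation(probe, t_cols)
    mc <- minimize_conformation(conf, P)
    # oracle: imposed + the stated relaxation extents, scored independently
    cands <- c(as.numeric(dg_of_conformation(conf, P)),
               as.numeric(dg_of_conformation(
                 duplex_conformation(probe, t_cols, relaxed_left = pos), P)),
               as.numeric(dg_of_conformation(
                 duplex_conformation(probe, t_cols,
                                     relaxed_right = 12L - pos + 1L), P)))
    expect_equal(attr(mc, "dg"), min(cands), tolerance = 1e-10)
    # minimization never worsens the imposed conformation
    expect_lte(attr(mc, "dg"), cands[1] + 1e-12)
  }
})

test_that("a central mismatch stays imposed; a costly terminal loop relaxes", {
  # central mismatch on a 22-mer: the clamped flanks outweigh the loop
  set.seed(51)
  site <- rand_dna(22)
  t_cols <- rev(strsplit(site, "")[[1]])
  probe <- unname(COMP_H[t_cols])
  probe[11] <- setdiff(c("A", "C", "G", "T"), COMP_H[[t_cols[11]]])[1]
  mc <- minimize_conformation(duplex_conformation(probe, t_cols), P)
  expect_identical(c(mc$relaxed_left, mc$relaxed_right), c(0L, 0L))

  # near-terminal mismatch with an artificially large loop penalty: relaxed
  Pbig <- P
  Pbig$single_mm_loops[] <- 5
  probe2 <- unname(COMP_H[t_cols])
  probe2[2] <- setdiff(c("A", "C", "G", "T"), COMP_H[[t_cols[2]]])[1]
  mc2 <- minimize_conformation(duplex_conformation(probe2, t_cols), Pbig)
  expect_identical(mc2$relaxed_left, 2L)
})

test_that("uncovered conformations fall through to flagged extended rules", {
  set.seed(61)
  site <- rand_dna(14)
  t_cols <- rev(strsplit(site, "")[[1]])
  probe <- unname(COMP_H[t_cols])
  for (j in 6:8) {  # three adjacent mismatches
    probe[j] <- sample(setdiff(c("A", "C", "G", "T"), COMP_H[[t_cols[j]]]), 1)
  }
  dg <- dg_of_conformation(duplex_conformation(probe, t_cols), P)
  expect_true(attr(dg, "extended"))
  expect_true(is.finite(as.numeric(dg)))
})
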