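test_that("tiling yields one probe per admissible start and exact reverse complements", {
  set.seed(81)
  gene <- rand_dna(1542)
  tiles <- tile_probes(gene)
  # enumeration oracle: count of starts s with s >= 50, s + 21 <= 1450
  expect_identical(nrow(tiles), length(seq(50, 1450 - 22 + 1)))
  expect_identical(nrow(tiles), 1380L)
  # every probe is the reverse complement of its site
  idx <- sample(nrow(tiles), 25)
  for (i in idx) {
    site <- substr(gene, tiles$start[i], tiles$end[i])
    expect_identical(tiles$sequence[i], rc_h(site))
  }
  # single-probe edge case
  one <- tile_probes(gene, length = 22, min_pos = 100, max_pos = 121)
  expect_identical(nrow(one), 1L)
  # random valid bounds match the closed-form count
  for (k in 1:10) {
    lo <- sample(1:400, 1); hi <- lo + sample(30:900, 1)
    got <- nrow(tile_probes(gene, length = 22, min_pos = lo, max_pos = hi))
    expect_identical(got, as.integer(hi - 22 + 1 - lo + 1))
  }
  expect_error(tile_probes(substr(gene, 1, 1000)), "bounds error")
})

test_that("mismatch-set constructors produce the per-probe variant counts", {
  set.seed(82)
  gene <- rand_dna(1542)
  tiles <- tile_probes(gene)[1:5, ]
  per_probe <- c(OneM = 3L, PosM = 66L, Gap = 4L, Insertion = 4L,
                 TwoM = 27L, Tandem = 9L)
  for (s in names(per_probe)) {
    made <- make_mismatch_sets(tiles, s, subset = seq_len(5))
    expect_identical(nrow(made), 5L * per_probe[[s]])
    # names parse back to their generating fields
    for (nm in sample(made$name, 3)) {
      f <- parse_probe_name(nm)
      expect_identical(probe_name(f$target_id, f$start, f$end, f$annotations), nm)
    }
  }
  # modified sequences have the right lengths
  expect_true(all(nchar(make_mismatch_sets(tiles, "Gap", subset = 1:2)$sequence) == 21))
  expect_true(all(nchar(make_mismatch_sets(tiles, "Insertion", subset = 1:2)$sequence) == 23))
  expect_true(all(nchar(make_mismatch_sets(tiles, "OneM")$sequence) == 22))
  # substitutions are real mismatches against the unmodified site
  one <- make_mismatch_sets(tiles, "OneM")
  i <- sample(nrow(one), 5)
  for (j in i) {
    site <- substr(gene, one$start[j], one$end[j])
    conf <- align_probe_site(one$sequence[j], site)
    ev <- conformation_events(conf)
    expect_identical(sum(ev$type == "mismatch"), 1L)
    expect_identical(ev$column[ev$type == "mismatch"], 11L)
  }
  expect_error(make_mismatch_sets(data.frame(sequence = "ACGT"), "OneM"),
               "22-mer")
})

test_that("probe names round-trip for random field tuples", {
  set.seed(83)
  for (i in 1:1000) {
    start <- sample(1:1500, 1)
    len <- sample(18:26, 1)
    n_ann <- sample(0:2, 1)
    ann <- character(0)
    if (n_ann > 0) {
      ann <- replicate(n_ann, {
        switch(sample(3, 1),
               paste0(sample(len, 1), paste(sample(c("A", "C", "G", "T"), 2), collapse = "")),
               paste0("gap", sample(len, 1)),
               paste0("I", sample(len, 1), sample(c("A", "C", "G", "T"), 1)))
      })
    }
    nm <- probe_name("E", start, start + len - 1, ann)
    f <- parse_probe_name(nm)
    expect_identical(f$target_id, "E")
    expect_identical(f$start, start)
    expect_identical(f$end, start + len - 1L)
    expect_identical(f$annotations, ann)
  }
  expect_error(parse_probe_name("E10AC"), "parse error")
  expect_error(parse_probe_name("E10-31_XX"), "parse error")
})

test_that("the poly-T linker rule converts only facing A/G positions", {
  expect_identical(adjust_linker(c("C", "T", "C")), strrep("T", 20))
  expect_identical(adjust_linker(c("A", "G", "A")),
                   paste0("AAA", strrep("T", 17)))
  # per-base oracle on random contexts
  set.seed(84)
  for (i in 1:50) {
    ctx <- sample(c("A", "C", "G", "T"), 3, TRUE)
    got <- strsplit(adjust_linker(ctx), "")[[1]]
    want <- c(ifelse(ctx %in% c("A", "G"), "A", "T"), rep("T", 17))
    expect_identical(got, want)
  }
  # linker context reads outward past the 5' end of the site
  gene <- "TTTAGC"
  expect_identical(linker_context(gene, 5), c("A", "T", "T"))
  expect_identical(linker_context(gene, 2), c("T", NA, NA))
})

test_that("alignment recovers planted edits and flags absent sites", {
  set.seed(85)
  P <- synthetic_params()
  gene <- rand_dna(800)
  for (i in 1:15) {
    start <- sample(100:700, 1)
    site <- substr(gene, start, start + 21)
    probe <- rc_h(site)
    n_ed <- sample(1:2, 1)
    b <- strsplit(gene, "")[[1]]
    pos <- sample(seq(start + 4, start + 17), n_ed)
    if (n_ed == 2 && abs(diff(pos)) < 3) next
    for (p0 in pos) b[p0] <- setdiff(c("A", "C", "G", "T"), b[p0])[1]
    mutated <- paste(b, collapse = "")
    conf <- conformation_from_pair(probe, mutated, P)
    expect_false(is.null(conf))
    expect_identical(attr(conf, "site_start"), start)
    ev <- conformation_events(conf)
    got_cols <- ev$column[ev$type == "mismatch"]
    want_cols <- sort(22 - (pos - start))  # probe coordinates of the edits
    expect_identical(sort(got_cols), as.integer(want_cols))
  }
  # the probe's own perfect site has zero events
  site <- substr(gene, 301, 322)
  conf <- conformation_from_pair(rc_h(site), gene, P)
  ev <- conformation_events(conf)
  expect_identical(sum(ev$type != "pair"), 0L)
  # unalignable candidate: no site
  expect_null(conformation_from_pair(rc_h(site), strrep("AC", 60), P))
})

test_that("probe tables round-trip through TSV with metadata", {
  set.seed(86)
  gene <- rand_dna(1542)
  tiles <- tile_probes(gene)[1:10, ]
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_probes(tiles, tmp, meta = c(seed = "86", tool = "formamelt test"))
  back <- read_probes(tmp)
  expect_identical(back$name, tiles$name)
  expect_identical(back$sequence, tiles$sequence)
  expect_identical(attr(back, "meta")[["seed"]], "86")
})
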