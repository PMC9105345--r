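cfg <- scan_config()

test_that("G4 scanner reports consensus matches with substructure", {
  h <- scan_g4(c(s = "GGGAGGGTGGGAGGG"), cfg)
  expect_equal(nrow(h), 1L)
  expect_equal(c(h$start, h$end), c(0L, 15L))
  expect_equal(h$runs, "3,3,3,3")
  expect_equal(h$loops, "1,1,1")

  expect_equal(nrow(scan_g4(c(s = "ATATATAT"), cfg)), 0L)

  h2 <- scan_g4(c(s = "CCCTCCCACCCTCCC"), cfg, both_strands = TRUE)
  expect_equal(nrow(h2), 1L)
  expect_equal(c(h2$start, h2$end, h2$strand), c("0", "15", "-"))
})

test_that("G4 hits obey strand symmetry under reverse complement", {
  set.seed(21)
  for (i in 1:40) {
    s <- rand_seq(150, c(A = .15, C = .2, G = .45, T = .2))
    h <- scan_g4(c(x = s), cfg, both_strands = TRUE)
    hr <- scan_g4(c(x = reverse_complement(s)), cfg, both_strands = TRUE)
    L <- nchar(s)
    mirrored <- data.frame(start = L - hr$end, end = L - hr$start,
                           strand = ifelse(hr$strand == "+", "-", "+"))
    mirrored <- mirrored[order(mirrored$start, mirrored$end, mirrored$strand), ]
    orig <- h[order(h$start, h$end, h$strand), c("start", "end", "strand")]
    expect_equal(unname(as.matrix(mirrored)), unname(as.matrix(orig)))
  }
})

test_that("Z-DNA scanner finds maximal alternating tracts", {
  expect_equal(scan_zdna(c(a = "GCGCGCGCGC"), cfg)[, c("start", "end")],
               data.frame(start = 0L, end = 10L))
  expect_equal(nrow(scan_zdna(c(a = "GCGCGCGCG"), cfg)), 0L)
  h <- scan_zdna(c(a = "ACACACACACAT"), cfg)
  expect_equal(c(h$start, h$end), c(0L, 12L))
  # N breaks a tract
  expect_equal(nrow(scan_zdna(c(a = "GCGCGNGCGCGC"), cfg)), 0L)
  # footprint invariant under reverse complement
  s <- "TTGCGCGCATATATGCAA"
  expect_equal(scan_zdna(c(x = reverse_complement(s)), cfg)$end - 0L,
               nchar(s) - rev(scan_zdna(c(x = s), cfg)$start))
})

test_that("repeat scanners match the worked examples", {
  c42 <- scan_config(rep_arm_len = 4L, rep_max_spacer = 2L)
  ir <- scan_inverted_repeats(c(x = "GGCCATGGCC"), c42)
  expect_equal(ir[, c("start", "end", "arm", "spacer")],
               data.frame(start = c(0L, 1L), end = c(10L, 9L),
                          arm = c(4L, 4L), spacer = c(2L, 0L)))
  expect_equal(nrow(scan_inverted_repeats(c(x = "AAAAAAAAAA"), c42)), 0L)

  c31 <- scan_config(rep_arm_len = 3L, rep_max_spacer = 1L)
  mr <- scan_mirror_repeats(c(x = "ACGTGCA"), c31)
  expect_equal(c(mr$start, mr$end, mr$arm, mr$spacer), c(0L, 7L, 3L, 1L))
  c30 <- scan_config(rep_arm_len = 3L, rep_max_spacer = 0L)
  expect_equal(nrow(scan_mirror_repeats(c(x = "ACGACG"), c30)), 0L)
  # palindromic arm with spacer 0 is a mirror repeat
  expect_equal(nrow(scan_mirror_repeats(c(x = "ATAATA"), c30)), 1L)

  dr <- scan_direct_repeats(c(x = "CATGCATG"), c42)
  expect_equal(c(dr$start[1], dr$end[1], dr$spacer[1]), c(0L, 8L, 0L))
  expect_equal(nrow(scan_direct_repeats(c(x = "AAAAAAAA"), c42)), 0L)
  dr2 <- scan_direct_repeats(c(x = "CATGTTCATG"), c42)
  expect_true(any(dr2$start == 0L & dr2$end == 10L & dr2$spacer == 2L))
})

test_that("merged mode unions same-class footprints", {
  c42 <- scan_config(rep_arm_len = 4L, rep_max_spacer = 2L,
                     report_mode = "merged")
  m <- merge_hits(scan_inverted_repeats(c(x = "GGCCATGGCC"),
                                        scan_config(rep_arm_len = 4L,
                                                    rep_max_spacer = 2L)))
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(0L, 10L))
})

test_that("STR scanner reports canonical maximal arrays", {
  h <- scan_strs(c(x = "CACACACACA"), cfg)
  expect_equal(c(h$start, h$end, h$unit, h$copies), c("0", "10", "AC", "5"))
  expect_equal(nrow(scan_strs(c(x = "CACACA"), cfg)), 0L)
  h2 <- scan_strs(c(x = "AAAAAAAAAA"), cfg)
  expect_equal(c(h2$unit, h2$copies), c("A", "10"))
  # a dinucleotide array is not also reported at larger unit sizes
  h3 <- scan_strs(c(x = "ACACACACACAC"), cfg)
  expect_equal(nrow(h3), 1L)
  expect_equal(h3$unit, "AC")
})

test_that("H-DNA combines mirror symmetry, spacer, and composition rules", {
  s <- paste0("GAAGAGGAAG", "T", "GAAGGAGAAG")
  h <- scan_hdna(c(x = s), cfg)
  expect_equal(nrow(h), 1L)
  expect_equal(c(h$start, h$end), c(0L, 21L))
  expect_equal(h$ag_frac, 20 / 21)
  s8 <- paste0("GAAGAGGAAG", strrep("T", 8), "GAAGGAGAAG")
  expect_equal(nrow(scan_hdna(c(x = s8), cfg)), 0L)
  # the pyrimidine-rich strand qualifies through the TC fraction
  expect_equal(nrow(scan_hdna(setNames(reverse_complement(s), "y"), cfg)), 1L)
})

test_that("exhaustive scans equal brute-force enumeration on random inputs", {
  set.seed(33)
  c52 <- scan_config(rep_arm_len = 5L, rep_max_spacer = 3L)
  for (i in 1:60) {
    s <- rand_seq(120)
    if (i %% 3 == 0) s <- splice(s, 40, plant_z(12))
    if (i %% 4 == 0) s <- splice(s, 70, strrep("TG", 6))
    expect_equal(scan_zdna(c(x = s), cfg)[, c("start", "end")],
                 sort_hits(oracle_zdna(s)), ignore_attr = TRUE)
    for (type in c("IR", "MR", "DR")) {
      got <- switch(type,
                    IR = scan_inverted_repeats(c(x = s), c52),
                    MR = scan_mirror_repeats(c(x = s), c52),
                    DR = scan_direct_repeats(c(x = s), c52))
      want <- oracle_repeat(s, type, 5L, 3L,
                            purity = if (type == "DR") 0.8 else NULL)
      expect_equal(got[, c("start", "end", "arm", "spacer")],
                   sort_hits(want), ignore_attr = TRUE)
    }
    got_str <- scan_strs(c(x = s), cfg)[, c("start", "end", "unit", "copies")]
    want_str <- sort_hits(oracle_str(s))
    expect_equal(got_str, want_str, ignore_attr = TRUE)
  }
})

test_that("scan_all flags planted classes and handles degenerate input", {
  set.seed(9)
  s <- rand_seq(200, c(A = .3, C = .2, G = .2, T = .3))
  s <- splice(s, 30, plant_g4())
  s <- splice(s, 120, plant_z(14))
  hits <- scan_all(c(x = s), scan_config(report_mode = "merged"),
                   both_strands = TRUE)
  flags <- presence_flags(hits, "x")
  expect_true(all(flags[, c("G4", "Z")]))

  nn <- scan_all(c(x = strrep("N", 120)), cfg, both_strands = TRUE)
  expect_equal(nrow(nn), 0L)

  # deterministic ordering
  h1 <- scan_all(c(x = s), cfg, both_strands = TRUE)
  h2 <- scan_all(c(x = s), cfg, both_strands = TRUE)
  expect_identical(h1, h2)
  expect_true(!is.unsorted(order(h1$class, h1$start)))
})

test_that("every reported hit passes the independent validator", {
  set.seed(17)
  c52 <- scan_config(rep_arm_len = 5L, rep_max_spacer = 3L)
  seqs <- setNames(vapply(1:25, function(i) {
    s <- rand_seq(150, c(A = .2, C = .2, G = .35, T = .25))
    if (i %% 2 == 0) splice(s, 50, plant_z(11)) else s
  }, character(1)), paste0("s", 1:25))
  hits <- scan_all(seqs, c52, both_strands = TRUE)
  expect_true(validate_hits(hits, seqs, c52))
})

test_that("orientation assignment follows gene strand and multiplicity", {
  genes <- gene_models(c("gp", "gm"), "chr1", c("+", "-"),
                       c(100L, 150L), c(400L, 420L))
  hit <- hit <- scan_g4(c(chr1 = strrep("A", 10)), cfg)  # empty template
  h <- data.frame(seq_id = "chr1", class = "G4", start = 200L, end = 220L,
                  strand = "+", arm = NA_integer_, spacer = NA_integer_,
                  unit = NA_character_, copies = NA_integer_,
                  runs = NA_character_, loops = NA_character_,
                  ag_frac = NA_real_)
  lab <- assign_orientation(h, genes)
  expect_equal(nrow(lab), 2L)   # one row per overlapped gene
  expect_equal(lab$orientation[lab$gene_id == "gp"], "non_template")
  expect_equal(lab$orientation[lab$gene_id == "gm"], "template")

  h$start <- 500L; h$end <- 520L
  expect_equal(assign_orientation(h, genes)$orientation, "intergenic")
})
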