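test_that("SNP controls draw only from matching trinucleotide sites", {
  # TTACATTACATT: context ACA occurs centered at 0-based 3 and 8
  genome <- c(chr1 = "TTACATTACATT")
  snp <- variant_table("chr1", 3L, "C", "T")
  sims <- simulate_snp_controls(snp, genome, n_reps = 20, seed = 5)
  expect_equal(nrow(sims), 20L)
  expect_true(all(sims$pos == 8L))   # only alternative ACA center

  # a context unique in the window is dropped
  genome2 <- c(chr1 = "TTTTGCATTTTT")
  snp2 <- variant_table("chr1", 5L, "C", "A")
  sims2 <- suppressMessages(
    simulate_snp_controls(snp2, genome2, n_reps = 5, seed = 1))
  expect_equal(nrow(sims2), 0L)
  expect_equal(attr(sims2, "dropped"), 1L)
})

test_that("SNP control constraints hold on a random genome", {
  g <- gen_genome(40000, gc = 0.45, seed = 8)
  set.seed(9)
  snps <- variant_table("chr1", sample(100:39900, 400), "A", "G")
  mask <- genomic_intervals("chr1", 50L, 39950L)
  sims <- simulate_snp_controls(snps, g$genome, mask, window = 2000,
                                n_reps = 3, seed = 10)
  ctx_of <- function(pos) substr(g$genome[[1]], pos, pos + 2L)
  expect_true(all(ctx_of(sims$pos) == ctx_of(snps$pos[sims$source])))
  expect_true(all(abs(sims$pos - snps$pos[sims$source]) <= 2000))
  expect_true(all(sims$pos != snps$pos[sims$source]))
  expect_true(all(sims$pos >= 50L & sims$pos < 39950L))
  # determinism: identical seed gives identical draws
  sims_b <- simulate_snp_controls(snps, g$genome, mask, window = 2000,
                                  n_reps = 3, seed = 10)
  expect_identical(sims, sims_b)
})

test_that("indel controls preserve length and match local GC", {
  g <- gen_genome(30000, gc = 0.5, seed = 12)
  set.seed(13)
  indels <- variant_table("chr1", sample(500:29000, 150),
                          vtype = sample(c("INS", "DEL"), 150, replace = TRUE),
                          length = sample.int(20, 150, replace = TRUE))
  sims <- simulate_indel_controls(indels, g$genome, window = 3000,
                                  n_reps = 2, seed = 14)
  expect_true(all(sims$length == indels$length[sims$source]))
  expect_true(all(sims$vtype == indels$vtype[sims$source]))
  gc_at <- function(pos, vt, len) {
    fl <- ifelse(vt == "DEL", pmax(len, 1L), 1L)
    vapply(seq_along(pos), function(i) {
      left <- substr(g$genome[[1]], max(pos[i] - 100L, 0L) + 1L, pos[i])
      right <- substr(g$genome[[1]], pos[i] + fl[i] + 1L, pos[i] + fl[i] + 100L)
      both <- paste0(left, right)
      nchar(gsub("[^GC]", "", both)) / nchar(both)
    }, numeric(1))
  }
  gs <- gc_at(sims$pos, sims$vtype, sims$length)
  go <- gc_at(indels$pos[sims$source], indels$vtype[sims$source],
              indels$length[sims$source])
  expect_true(all(abs(gs - go) <= 0.025 + 1e-12))
})

test_that("SV breakpoint controls keep class labels and replicate counts", {
  g <- gen_genome(20000, gc = 0.4, seed = 15)
  bp <- variant_table("chr1", c(2000L, 5000L, 9000L), vtype = "SV_BND",
                      sv_class = c("DEL", "INV", "DUP"))
  sims <- simulate_sv_breakpoints(bp, g$genome, n_reps = 10, seed = 16)
  expect_equal(nrow(sims), 30L)
  expect_equal(sims$sv_class, bp$sv_class[sims$source])
  expect_true(all(table(sims$rep) == 3L))
})

test_that("overlap enrichment computes folds, p-values and CIs", {
  motifs <- genomic_intervals("chr1", c(100L, 300L), c(120L, 330L))
  vars <- variant_table("chr1", c(105L, 310L, 150L, 200L))
  sims <- rbind(
    cbind(variant_table("chr1", c(110L, 400L, 500L, 600L)),
          rep = 1L, source = 1:4),
    cbind(variant_table("chr1", c(315L, 410L, 510L, 610L)),
          rep = 2L, source = 1:4),
    cbind(variant_table("chr1", c(111L, 401L, 501L, 601L)),
          rep = 3L, source = 1:4))
  er <- overlap_enrichment(vars, sims, motifs, seed = 1)
  expect_equal(er$observed, 0.5)
  expect_equal(er$sim_fractions, rep(0.25, 3))
  expect_equal(er$fold, 2.0)
  expect_true(er$ci[1] <= er$fold && er$fold <= er$ci[2])

  # identical distance distributions give p near 1
  sims_same <- do.call(rbind, lapply(1:3, function(r) {
    cbind(vars, rep = r, source = 1:4)
  }))
  er2 <- overlap_enrichment(vars, sims_same, motifs, seed = 1)
  expect_gt(er2$p, 0.9)
  expect_equal(er2$fold, 1.0)

  expect_error(overlap_enrichment(vars, sims, motifs[0, ]), "empty motif")
})

test_that("planted overlap fold is recovered by the enrichment estimator", {
  plan <- data.frame(class = "MR", pos = seq(1000, 59000, by = 500),
                     arm = 10L, spacer = 4L)
  g <- gen_genome(60000, gc = 0.5, plan = plan, seed = 20)
  gv <- gen_variants(g$genome, g$truth, fold = 2, n = 3000,
                     type = "SV_BND", seed = 21)
  sims <- simulate_sv_breakpoints(gv$variants, g$genome, window = 5000,
                                  n_reps = 4, seed = 22)
  er <- overlap_enrichment(gv$variants, sims, g$truth, seed = 23)
  expect_lt(abs(er$fold - 2) / 2, 0.25)
  expect_lt(er$p, 0.01)
})

test_that("indel direction split reports per-class INS/DEL fractions", {
  motifs <- data.frame(seq_id = "chr1", class = c("STR", "G4"),
                       start = c(100L, 500L), end = c(150L, 540L))
  ind <- variant_table("chr1", c(110L, 120L, 510L, 700L, 800L),
                       vtype = c("DEL", "DEL", "INS", "INS", "DEL"),
                       length = 2L)
  tab <- indel_direction_split(ind, motifs)
  expect_equal(tab$class, c("G4", "STR"))
  str_row <- tab[tab$class == "STR", ]
  expect_equal(str_row$del_fraction, 2 / 3)
  expect_equal(str_row$ins_fraction, 0)
  expect_true(all(tab$ins_fraction >= 0 & tab$ins_fraction <= 1, na.rm = TRUE))

  all_del <- ind[ind$vtype == "DEL", ]
  tab2 <- indel_direction_split(all_del, motifs)
  expect_true(all(is.na(tab2$ins_fraction)))
  expect_true(all(!is.na(tab2$del_fraction)))
})

test_that("regulatory z-scores follow the sample-sd definition", {
  expect_equal(unname(regulatory_zscore(c(2, 4, 6))), c(-1, 0, 1))
  expect_warning(z <- regulatory_zscore(c(3, 3, 3)), "constant")
  expect_equal(unname(z), c(0, 0, 0))
  set.seed(2)
  d <- runif(6)
  z1 <- regulatory_zscore(d)
  perm <- sample(6)
  expect_equal(sort(regulatory_zscore(d[perm])), sort(z1))
  expect_equal(sum(z1), 0, tolerance = 1e-12)
})
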