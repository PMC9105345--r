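mk_genes <- function(n = 20, strand = NULL, span = 3000L, gap = 5000L) {
  starts <- seq(5000L, by = span + gap, length.out = n)
  gene_models(sprintf("g%02d", 1:n), "chr1",
              strand %||% rep(c("+", "-"), length.out = n),
              starts, starts + span)
}

test_that("TSS metaprofile is flat under uniform placement and spikes when planted", {
  genes <- mk_genes(30)
  set.seed(31)
  L <- max(genes$end) + 10000L
  feats <- genomic_intervals("chr1", p <- sample.int(L, 20000), p + 1L)
  prof <- tss_metaprofile(feats, genes, flank = 1000L, bin = 100L)
  expect_true(all(abs(prof$fold - 1) < 0.35))

  tss <- gene_tss(genes)
  spike_pos <- ifelse(genes$strand == "+", tss - 50L, tss + 50L)
  feats2 <- genomic_intervals("chr1", spike_pos, spike_pos + 1L)
  expect_warning(
    prof2 <- tss_metaprofile(feats2, genes, flank = 1000L, bin = 100L),
    "background")
  nb <- length(prof2$counts)
  hot <- which.max(prof2$counts)
  expect_equal(prof2$edges[hot], -100L)   # the [-100, 0) bin holds offset -50
  expect_equal(prof2$fold[hot], nb)       # all mass in one of nb bins

  # minus-strand gene: a feature 50 bp 5' of the TSS maps to offset -50
  gm <- gene_models("g", "chr1", "-", 1000L, 2000L)
  f <- genomic_intervals("chr1", 2049L, 2050L)  # TSS at 1999, 50 bp right
  expect_warning(p1 <- tss_metaprofile(f, gm, flank = 100L, bin = 10L))
  expect_equal(p1$edges[which.max(p1$counts)], -50L)

  expect_error(tss_metaprofile(feats, genes[0, ], 1000L, 100L), "no genes")
})

test_that("compartment enrichment reproduces exact binomial arithmetic", {
  # one gene whose upstream-1kb covers 10% of a 10 kb genome
  g <- gene_models("g1", "chr1", "+", 1000L, 9000L,
                   cds_start = 2000L, cds_end = 8000L)
  set.seed(5)
  # 50 of 100 features in [0,1000) upstream window, rest downstream-of-gene
  pos <- c(sample(0:999, 50, replace = TRUE),
           sample(9100:9900, 50, replace = TRUE))
  feats <- genomic_intervals("chr1", pos, pos + 1L)
  res <- compartment_enrichment(feats, g, genome_bp = 10000)
  up <- res[res$compartment == "upstream-1kb", ]
  expect_equal(up$count, 50L)
  expect_equal(up$length_share, 0.1)
  expect_equal(up$fold, 5.0)
  lower <- sum(dbinom(0:50, 100, 0.1)); upper <- sum(dbinom(50:100, 100, 0.1))
  expect_equal(up$p_raw, min(1, 2 * min(lower, upper)), tolerance = 1e-12)
  expect_true(all(res$p_adj >= res$p_raw))
  expect_lte(sum(res$length_share), 1)
})

test_that("promoter-proximal ratio matches density arithmetic", {
  genes <- mk_genes(25, strand = rep("+", 25))
  tss <- gene_tss(genes)
  set.seed(41)
  # uniform over [-1000, 0): ratio ~ 1
  off <- -sample.int(1000, 5000, replace = TRUE)
  pos <- rep(tss, length.out = 5000) + off
  r1 <- promoter_proximal_ratio(genomic_intervals("chr1", pos, pos + 1L),
                                genes, seed = 1)
  expect_lt(abs(r1$ratio - 1), 0.1)
  # all features in [-250, 0): ratio exactly 4
  off2 <- -sample.int(250, 2000, replace = TRUE)
  pos2 <- rep(tss, length.out = 2000) + off2
  r2 <- promoter_proximal_ratio(genomic_intervals("chr1", pos2, pos2 + 1L),
                                genes, seed = 1)
  expect_equal(r2$ratio, 4.0)
  # bootstrap SD shrinks with more genes (per-gene placement heterogeneous)
  mk_sd <- function(n) {
    genes_n <- mk_genes(n, strand = rep("+", n))
    tss_n <- gene_tss(genes_n)
    off_n <- ifelse(seq_len(n) %% 2 == 0, 100L, 900L)
    pos_n <- tss_n - off_n
    promoter_proximal_ratio(genomic_intervals("chr1", pos_n, pos_n + 1L),
                            genes_n, seed = 1)$sd
  }
  expect_lt(mk_sd(100), mk_sd(10))
})

test_that("orientation bias fold and p follow the corrected-odds definition", {
  mk_oriented <- function(k_nt_peak, k_t_peak, n_nt, n_t) {
    n <- n_nt + n_t
    starts <- seq(0L, by = 100L, length.out = n)
    ori <- c(rep("non_template", n_nt), rep("template", n_t))
    in_peak <- c(seq_len(k_nt_peak), n_nt + seq_len(k_t_peak))
    h <- data.frame(seq_id = "chr1", class = "G4", start = starts,
                    end = starts + 20L, strand = "+", gene_id = "g",
                    orientation = ori)
    peaks <- genomic_intervals("chr1", starts[in_peak], starts[in_peak] + 20L)
    list(h = h, peaks = peaks)
  }
  # k=30, m=10, pi=0.5 -> fold 3
  d <- mk_oriented(30, 10, 50, 50)
  r <- orientation_bias_test(d$h, d$peaks)
  expect_equal(r$fold, 3.0)
  expect_equal(r$p, binom_test_two_sided(30, 40, 0.5)$p)
  # k=30, m=10, pi=0.75 -> fold exactly 1
  d2 <- mk_oriented(30, 10, 75, 25)
  r2 <- orientation_bias_test(d2$h, d2$peaks)
  expect_equal(r2$fold, 1.0)
  # grid: fold is 1 whenever observed proportions equal the background
  for (pi in c(0.3, 0.5, 0.6, 0.8)) {
    n_nt <- round(100 * pi); n_t <- 100 - n_nt
    dd <- mk_oriented(n_nt %/% 2, n_t %/% 2 + (n_t %% 2) * 0, n_nt, n_t)
    if (n_nt %/% 2 == 0 || n_t %/% 2 == 0) next
    rr <- orientation_bias_test(dd$h, dd$peaks)
    expect_equal(rr$fold, ((n_nt %/% 2) / (n_t %/% 2)) / (n_nt / n_t))
  }
})

test_that("eQTL density profile is flat under uniformity and sees planted folds", {
  set.seed(51)
  motifs <- genomic_intervals("chr1", m <- seq(5000L, 195000L, by = 2000L),
                              m + 30L)
  L <- 200000L
  eq_u <- data.frame(chrom = "chr1", pos = sample.int(L, 20000) - 1L)
  p1 <- eqtl_density_profile(eq_u, motifs, flank = 1000L, bin = 200L,
                             chrom_sizes = c(chr1 = L))
  expect_true(all(abs(p1$fold - 1) < 0.3))

  g <- gen_eqtls(L, motifs, fold = 3, n = 20000, seed = 52)
  p2 <- eqtl_density_profile(g, motifs, flank = 1000L, bin = 200L,
                             chrom_sizes = c(chr1 = L))
  expect_lt(abs(p2$fold[1] - 3) / 3, 0.15)
  expect_lte(p2$frac_motifs_with_eqtl, 1)

  # all eQTLs inside motifs concentrate in bin 0
  eq_in <- data.frame(chrom = "chr1", pos = m + 5L)
  expect_warning(p3 <- eqtl_density_profile(eq_in, motifs, flank = 1000L,
                                            bin = 200L))
  expect_equal(sum(p3$counts[-1]), 0)
  expect_equal(p3$frac_motifs_with_eqtl, 1)
  expect_error(eqtl_density_profile(eq_u, motifs[0, ], 1000L, 200L),
               "empty motif")
})

test_that("element density z-scores center and scale as defined", {
  els <- list(a = genomic_intervals("chr1", 0L, 1000L),
              b = genomic_intervals("chr1", 2000L, 3000L),
              c = genomic_intervals("chr1", 4000L, 5000L))
  # densities 0.1, 0.3, 0.5 by construction
  f <- genomic_intervals("chr1",
                         c(0L, 2000L, 2100L, 2200L, 4000L, 4100L, 4200L,
                           4300L, 4400L),
                         c(100L, 2100L, 2200L, 2300L, 4100L, 4200L, 4300L,
                           4400L, 4500L))
  z <- element_density_zscore(f, els)
  expect_equal(unname(z), c(-1, 0, 1))
  expect_equal(sum(z), 0, tolerance = 1e-12)
  expect_warning(z0 <- element_density_zscore(f[1:3, ],
                                              list(a = els$a, a2 = els$a)),
                 "constant")
  expect_equal(unname(z0), c(0, 0))
})
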