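test_that("activity computation filters barcodes and forms cpm log ratios", {
  counts <- data.frame(
    insert = c(rep("A", 3), "B"), barcode = c("b1", "b2", "b3", "b4"),
    replicate = 1L, dna = c(2, 5, 7, 88), rna = c(4, 10, 14, 76))
  act <- compute_activity(counts)
  # barcode b1 (dna 2 < 3) removed; A sums: dna 12, rna 24; totals 100 each
  a <- act$records$activity[act$records$insert == "A"]
  expect_equal(a, log2((24e4 + 1) / (12e4 + 1)))
  expect_equal(act$records$n_barcodes[act$records$insert == "A"], 2L)

  # RNA identical to DNA gives activity 0 everywhere
  c2 <- data.frame(insert = rep(c("A", "B"), each = 2),
                   barcode = paste0("b", 1:4), replicate = 1L,
                   dna = c(10, 20, 30, 40), rna = c(10, 20, 30, 40))
  expect_true(all(compute_activity(c2)$records$activity == 0))

  # permuting barcode rows leaves activities unchanged
  set.seed(6)
  c3 <- c2[sample(nrow(c2)), ]
  expect_equal(compute_activity(c3)$records, compute_activity(c2)$records)

  expect_error(compute_activity(transform(c2, dna = dna - 50)), "negative")
  expect_error(compute_activity(c2[, -4]), "columns")
})

test_that("replicate correlations are symmetric with unit diagonal", {
  counts <- do.call(rbind, lapply(1:2, function(r) {
    data.frame(insert = paste0("i", 1:50), barcode = paste0("b", 1:50),
               replicate = r, dna = 100,
               rna = round(100 * 2^seq(-1, 1, length.out = 50)))
  }))
  act <- compute_activity(counts)
  m <- replicate_correlation(act)
  expect_equal(m[1, 2], 1.0, tolerance = 1e-12)  # duplicated replicate
  expect_identical(m, t(m))
  expect_equal(diag(m), c(`1` = 1, `2` = 1))

  set.seed(8)
  counts2 <- do.call(rbind, lapply(1:2, function(r) {
    data.frame(insert = paste0("i", 1:1000), barcode = paste0("b", 1:1000),
               replicate = r, dna = 200,
               rna = rpois(1000, 200))
  }))
  m2 <- replicate_correlation(compute_activity(counts2))
  expect_lt(abs(m2[1, 2]), 0.1)
})

test_that("GC correction fits OLS and standardized-residual outliers", {
  rec <- data.frame(activity = c(0.6, 1.0, 1.4), gc = c(0.3, 0.5, 0.7))
  fit <- gc_correct(rec)
  expect_equal(fit$slope, 2.0, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.0, tolerance = 1e-12)
  expect_equal(fit$corrected, rep(0, 3), tolerance = 1e-12)

  set.seed(9)
  rec2 <- data.frame(gc = runif(300, 0.2, 0.8))
  rec2$activity <- 1.5 * rec2$gc + rnorm(300, 0, 0.2)
  f2 <- gc_correct(rec2)
  expect_lt(abs(f2$slope - 1.5), 0.15)
  expect_lt(abs(pearson_r(f2$corrected, rec2$gc)), 1e-10)
  expect_lt(abs(sum(f2$corrected)), 1e-8)

  # adding a constant changes the intercept only
  rec3 <- transform(rec2, activity = activity + 5)
  f3 <- gc_correct(rec3)
  expect_equal(f3$slope, f2$slope, tolerance = 1e-10)
  expect_equal(f3$intercept, f2$intercept + 5, tolerance = 1e-10)
  expect_equal(f3$corrected, f2$corrected, tolerance = 1e-10)

  # a gross outlier is excluded on refit and both fits are reported
  rec4 <- rec2
  rec4$activity[1] <- rec4$activity[1] + 10
  f4 <- gc_correct(rec4, drop_outliers = TRUE)
  expect_true(1L %in% f4$outliers)
  expect_lt(abs(f4$slope - 1.5), 0.15)
  expect_false(is.null(f4$initial_fit))

  expect_error(gc_correct(data.frame(activity = 1:5 / 5, gc = 0.5)),
               "constant GC")
})

test_that("per-gene z-scores standardize within genes", {
  rec <- data.frame(gene_id = rep(c("g1", "g2"), each = 3),
                    activity = c(1, 2, 3, 11, 12, 13))
  z <- zscore_by_gene(rec)
  expect_equal(z[1:3], c(-1, 0, 1))
  expect_equal(z[1:3], z[4:6])   # identical shapes, different baselines
  expect_equal(mean(z), 0, tolerance = 1e-12)
  for (g in c("g1", "g2")) {
    sel <- rec$gene_id == g
    expect_equal(mean(z[sel]), 0, tolerance = 1e-9)
    expect_equal(sd(z[sel]), 1, tolerance = 1e-9)
  }
  rec2 <- rbind(rec, data.frame(gene_id = "g3", activity = 7))
  expect_warning(z2 <- zscore_by_gene(rec2), "g3")
  expect_true(is.na(z2[7]))
})

test_that("motif contrasts recover planted effects and adjust p-values", {
  set.seed(10)
  n <- 1500
  rec <- data.frame(gc = runif(n, .3, .7))
  for (cl in c("G4", "Z", "IR")) rec[[cl]] <- runif(n) < 0.4
  rec$activity <- 1.5 * rec$gc + 0.5 * rec$Z - 0.3 * rec$G4 + rnorm(n, 0, 0.3)
  out <- motif_contrast(rec, classes = c("G4", "Z", "IR"),
                        score = "gc_corrected", test = "mwu", n_boot = 100,
                        seed = 2)
  expect_equal(out$p_adj, pmin(1, out$p_raw * 3))
  zrow <- out[out$feature == "Z", ]
  expect_lt(abs(zrow$median_diff - 0.5), 0.1)
  expect_lt(zrow$p_adj, 0.001)
  expect_lt(out$median_diff[out$feature == "G4"], 0)
  expect_lt(abs(out$median_diff[out$feature == "IR"]), 0.08)

  # identical groups: difference 0, p = 1
  rec0 <- data.frame(activity = rep(c(1, 2, 3, 4), 2), gc = 0.5,
                     FLAG = rep(c(TRUE, FALSE), each = 4))
  out0 <- motif_contrast(rec0, classes = "FLAG", score = "raw", n_boot = 50,
                         seed = 1)
  expect_equal(out0$median_diff, 0)
  expect_equal(out0$p_raw, 1)
})

test_that("orientation contrast is antisymmetric under label flips", {
  set.seed(12)
  n <- 400
  rec <- data.frame(activity = rnorm(n), gc = runif(n, .3, .7),
                    g4_orientation = sample(c("template", "non_template"),
                                            n, replace = TRUE))
  rec$activity <- rec$activity - 0.4 * (rec$g4_orientation == "template")
  r1 <- orientation_contrast(rec, score = "raw", n_boot = 100, seed = 3)
  expect_lt(abs(r1$median_diff + 0.4), 0.15)
  flipped <- rec
  flipped$g4_orientation <- ifelse(rec$g4_orientation == "template",
                                   "non_template", "template")
  r2 <- orientation_contrast(flipped, score = "raw", n_boot = 100, seed = 3)
  expect_equal(r2$median_diff, -r1$median_diff, tolerance = 1e-12)
})

test_that("Z-DNA length trend uses the tie-corrected Kruskal-Wallis H", {
  rec <- data.frame(z_len = rep(c(10, 15, 20), each = 2),
                    activity = c(1, 2, 3, 4, 5, 6), gc = 0.5)
  r <- zdna_length_trend(rec, breaks = c(10, 14, 18, Inf), score = "raw")
  expect_equal(r$H, kw_formula(rec$activity, cut(rec$z_len,
                                                 c(10, 14, 18, Inf),
                                                 right = FALSE)),
               tolerance = 1e-10)
  expect_equal(unname(r$medians), c(1.5, 3.5, 5.5))
  # H invariant under monotone transforms
  rec2 <- transform(rec, activity = exp(activity))
  expect_equal(zdna_length_trend(rec2, score = "raw")$H, r$H,
               tolerance = 1e-10)
  # degenerate: identical values give H = 0, p = 1
  rec3 <- transform(rec, activity = 1)
  r3 <- zdna_length_trend(rec3, score = "raw")
  expect_equal(r3$p, 1)
  expect_error(zdna_length_trend(rec[rec$z_len == 10, ], score = "raw"),
               "2 length bins")
})

test_that("G-run association finds planted monotone trends", {
  set.seed(14)
  n <- 1200
  rec <- data.frame(gc = runif(n, .3, .7),
                    g_runs = sample(0:4, n, replace = TRUE))
  rec$activity <- 1.2 * rec$gc - 0.1 * rec$g_runs + rnorm(n, 0, 0.2)
  r <- g_run_association(rec, n_boot = 100, seed = 4)
  expect_true(all(diff(r$table$mean) < 0.05))
  expect_lt(r$trend$p, 0.001)
  expect_lt(r$trend$z, 0)

  rec$activity <- 1.2 * rec$gc + rnorm(n, 0, 0.2)
  r0 <- g_run_association(rec, n_boot = 100, seed = 4)
  expect_gt(r0$trend$p, 0.01)
})

test_that("TFBS and motif contrasts share one ranked Bonferroni family", {
  set.seed(15)
  n <- 800
  rec <- data.frame(insert = paste0("i", 1:n), gc = runif(n, .3, .7),
                    Z = runif(n) < 0.4, G4 = runif(n) < 0.4)
  tf_present <- runif(n) < 0.4
  rec$activity <- 0.5 * rec$Z + 0.3 * tf_present + rnorm(n, 0, 0.25)
  tfbs <- data.frame(seq_id = rec$insert[tf_present], tf = "TF1")
  out <- tfbs_vs_motif_contrast(rec, tfbs, classes = c("Z", "G4"),
                                score = "raw", n_boot = 100, seed = 5)
  expect_equal(out$feature[1], "Z")   # largest effect ranks first
  expect_true(which(out$feature == "Z") < which(out$feature == "TF1"))
  expect_equal(out$p_adj, pmin(1, out$p_raw * 3))
  expect_lt(abs(out$median_diff[out$feature == "G4"]), 0.1)

  # feature present in all records is skipped
  rec$ALL <- TRUE
  expect_message(
    out2 <- tfbs_vs_motif_contrast(rec, tfbs, classes = c("Z", "ALL"),
                                   score = "raw", n_boot = 50, seed = 5),
    "skipping")
  expect_false("ALL" %in% out2$feature)
})

test_that("record annotation derives GC, motif flags, orientation and G-runs", {
  set.seed(19)
  s1 <- splice(rand_seq(200, c(A = .3, C = .3, G = .1, T = .3)), 50,
               plant_g4())                       # plus-strand G4
  s2 <- splice(rand_seq(200, c(A = .3, C = .3, G = .1, T = .3)), 50,
               reverse_complement(plant_g4()))   # minus-strand G4
  s3 <- splice(rand_seq(200, c(A = .35, C = .3, G = .05, T = .3)), 80,
               plant_z(16))
  design <- data.frame(insert = c("a", "b", "c"),
                       sequence = c(s1, s2, s3),
                       gene_id = "g1")
  counts <- data.frame(insert = rep(c("a", "b", "c"), each = 2),
                       barcode = paste0("bc", 1:6), replicate = 1L,
                       dna = 50, rna = 50)
  rec <- mpra_annotate(compute_activity(counts), design)
  expect_equal(rec$gc, gc_fraction(design$sequence[match(rec$insert,
                                                         design$insert)]))
  expect_true(rec$G4[rec$insert == "a"])
  expect_equal(rec$g4_orientation[rec$insert == "a"], "non_template")
  expect_equal(rec$g4_orientation[rec$insert == "b"], "template")
  expect_true(rec$Z[rec$insert == "c"])
  expect_gte(rec$z_len[rec$insert == "c"], 16L)
  expect_gte(rec$g_runs[rec$insert == "a"], 4L)
  expect_error(mpra_annotate(compute_activity(counts), design[1:2, ]),
               "missing")
})
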