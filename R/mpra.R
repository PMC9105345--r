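#' Compute MPRA activity scores from a barcode count table
#'
#' Barcodes with fewer than `min_barcode_count` reads in either channel are
#' removed. Surviving barcode counts are summed per insert and replicate,
#' each channel is scaled to counts-per-million within its replicate, and the
#' per-replicate activity is `log((RNA_cpm + 1) / (DNA_cpm + 1))` in base
#' `log_base`. The per-insert activity is the mean over replicates. Inserts
#' with no surviving barcode in any replicate are dropped (with a message).
#'
#' @param counts `data.frame` with columns insert, barcode, replicate, dna,
#'   rna (UMI deduplication is assumed upstream).
#' @param min_barcode_count Minimum count per channel for a barcode to
#'   survive.
#' @param log_base Base of the activity log (default 2).
#' @return `list` of class `mpra_activity`: `records` (insert, activity,
#'   n_barcodes) and `rep_activity` (insert x replicate matrix of
#'   per-replicate activities, NA where an insert had no surviving barcode).
#' @export
compute_activity <- function(counts, min_barcode_count = 3L, log_base = 2) {
  need <- c("insert", "barcode", "replicate", "dna", "rna")
  if (!all(need %in% names(counts))) {
    stopf("count table must have columns: %s", paste(need, collapse = ", "))
  }
  if (any(counts$dna < 0) || any(counts$rna < 0)) stopf("negative counts")
  keep <- counts$dna >= min_barcode_count & counts$rna >= min_barcode_count
  surv <- counts[keep, , drop = FALSE]
  inserts <- sort(unique(counts$insert))
  reps <- sort(unique(counts$replicate))
  mat <- matrix(NA_real_, length(inserts), length(reps),
                dimnames = list(inserts, as.character(reps)))
  nbc <- setNames(rep(0L, length(inserts)), inserts)
  for (r in reps) {
    sr <- surv[surv$replicate == r, , drop = FALSE]
    if (nrow(sr) == 0L) next
    dna_sum <- rowsum(sr$dna, sr$insert)
    rna_sum <- rowsum(sr$rna, sr$insert)
    dna_cpm <- dna_sum / sum(dna_sum) * 1e6
    rna_cpm <- rna_sum / sum(rna_sum) * 1e6
    act <- log((rna_cpm + 1) / (dna_cpm + 1), base = log_base)
    mat[rownames(dna_sum), as.character(r)] <- act
    nb <- rowsum(rep(1L, nrow(sr)), sr$insert)
    nbc[rownames(nb)] <- nbc[rownames(nb)] + nb[, 1]
  }
  alive <- rowSums(!is.na(mat)) > 0L
  if (any(!alive)) {
    message("compute_activity: dropped ", sum(!alive),
            " insert(s) with no surviving barcode")
  }
  records <- data.frame(insert = inserts[alive],
                        activity = rowMeans(mat[alive, , drop = FALSE],
                                            na.rm = TRUE),
                        n_barcodes = as.integer(nbc[alive]),
                        stringsAsFactors = FALSE)
  rownames(records) <- NULL
  structure(list(records = records,
                 rep_activity = mat[alive, , drop = FALSE]),
            class = "mpra_activity")
}

#' @export
print.mpra_activity <- function(x, ...) {
  cat(sprintf("MPRA activity: %d inserts, %d replicates\n",
              nrow(x$records), ncol(x$rep_activity)))
  invisible(x)
}

# Longest chain of consecutive G-runs (runs of >= g_run_min G separated by
# gaps of g4_loop_min..g4_loop_max nt); 0 when the sequence has no G-run.
count_g_runs <- function(seqs, cfg = scan_config()) {
  vapply(seqs, function(s) {
    r <- rle(strsplit(s, NULL)[[1]] == "G")
    ends <- cumsum(r$lengths)
    runs <- which(r$values & r$lengths >= cfg$g_run_min)
    if (!length(runs)) return(0L)
    starts <- ends - r$lengths + 1L
    rs <- starts[runs]; re <- ends[runs]
    best <- 1L; cur <- 1L
    if (length(runs) > 1L) {
      for (i in 2:length(runs)) {
        gap <- rs[i] - re[i - 1L] - 1L
        if (gap >= cfg$g4_loop_min && gap <= cfg$g4_loop_max) {
          cur <- cur + 1L
        } else cur <- 1L
        best <- max(best, cur)
      }
    }
    best
  }, integer(1), USE.NAMES = FALSE)
}

#' Annotate MPRA records with sequence covariates and motif content
#'
#' Joins the design table, computes GC fraction, merged-mode motif presence
#' flags for all seven classes (G4 on both strands), the G4 orientation label
#' (a "+" strand hit on a promoter fragment oriented in transcription
#' direction is non-template), the longest Z-DNA tract length, and the
#' longest chain of consecutive G-runs.
#'
#' @param activity An `mpra_activity` object from [compute_activity()].
#' @param design `data.frame` with columns insert, sequence and optionally
#'   gene_id.
#' @param cfg A [scan_config()].
#' @return `data.frame` of annotated records (one row per insert).
#' @export
mpra_annotate <- function(activity, design, cfg = scan_config()) {
  rec <- activity$records
  m <- match(rec$insert, design$insert)
  if (anyNA(m)) stopf("design table is missing %d insert(s)", sum(is.na(m)))
  rec$sequence <- design$sequence[m]
  rec$gene_id <- if ("gene_id" %in% names(design)) design$gene_id[m] else NA
  rec$gc <- gc_fraction(rec$sequence)
  seqs <- setNames(rec$sequence, rec$insert)
  hits <- scan_all(seqs, cfg, both_strands = TRUE)
  flags <- presence_flags(hits, seq_ids = rec$insert)
  for (cl in colnames(flags)) rec[[cl]] <- unname(flags[, cl])
  g4 <- hits[hits$class == "G4", , drop = FALSE]
  ori <- vapply(rec$insert, function(id) {
    st <- unique(g4$strand[g4$seq_id == id])
    if (!length(st)) NA_character_
    else if (all(st == "+")) "non_template"
    else if (all(st == "-")) "template"
    else "both"
  }, character(1), USE.NAMES = FALSE)
  rec$g4_orientation <- ori
  z <- hits[hits$class == "Z", , drop = FALSE]
  zl <- tapply(z$end - z$start, z$seq_id, max)
  rec$z_len <- as.integer(ifelse(rec$insert %in% names(zl),
                                 zl[rec$insert], 0L))
  rec$g_runs <- count_g_runs(rec$sequence, cfg)
  rec
}

#' Pairwise Pearson correlation of replicate activities
#'
#' @param activity An `mpra_activity` object.
#' @return Symmetric correlation matrix (unit diagonal); entries with fewer
#'   than 2 shared inserts are NA.
#' @export
replicate_correlation <- function(activity) {
  m <- activity$rep_activity
  if (ncol(m) < 2L) stopf("need at least 2 replicates")
  r <- ncol(m)
  out <- diag(1, r)
  dimnames(out) <- list(colnames(m), colnames(m))
  for (i in seq_len(r - 1L)) for (j in (i + 1L):r) {
    ok <- stats::complete.cases(m[, c(i, j)])
    out[i, j] <- out[j, i] <-
      if (sum(ok) < 2L) NA_real_ else pearson_r(m[ok, i], m[ok, j])
  }
  out
}

#' GC-content correction of activity scores
#'
#' Ordinary least squares of activity on GC fraction; the corrected activity
#' is the residual. With `drop_outliers`, records with standardized residual
#' magnitude above `z_cut` are excluded and the model is refit once; both
#' fits are reported and the corrected activities come from the final fit
#' (evaluated for every record, including excluded outliers).
#'
#' @param records `data.frame` with `activity` and `gc` columns.
#' @param drop_outliers Refit after removing outliers?
#' @param z_cut Standardized-residual threshold (default 2.5).
#' @return `list` of class `gc_fit`: slope, intercept, r (Pearson correlation
#'   of fitted and observed in the final fit), corrected (residual vector,
#'   all records), outliers (row indices removed), and `initial_fit`
#'   (slope/intercept/r before outlier removal, when it differs).
#' @export
gc_correct <- function(records, drop_outliers = FALSE, z_cut = 2.5) {
  stopifnot(nrow(records) >= 3L)
  if (length(unique(records$gc)) < 2L) {
    stopf("constant GC content: model unidentifiable")
  }
  fit1 <- stats::lm(activity ~ gc, data = records)
  outliers <- integer(0)
  fit <- fit1
  if (drop_outliers) {
    z <- stats::rstandard(fit1)
    outliers <- which(abs(z) > z_cut)
    if (length(outliers)) {
      fit <- stats::lm(activity ~ gc,
                       data = records[-outliers, , drop = FALSE])
    }
  }
  co <- stats::coef(fit)
  corrected <- records$activity - (co[1] + co[2] * records$gc)
  mk <- function(f, d) list(slope = unname(stats::coef(f)[2]),
                            intercept = unname(stats::coef(f)[1]),
                            r = pearson_r(stats::fitted(f), d$activity))
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 r = mk(fit, if (length(outliers))
                   records[-outliers, , drop = FALSE] else records)$r,
                 corrected = as.numeric(corrected),
                 outliers = outliers,
                 initial_fit = mk(fit1, records)),
            class = "gc_fit")
}

#' @export
print.gc_fit <- function(x, ...) {
  cat(sprintf("GC model: activity = %.4f + %.4f * gc (r = %.3f)%s\n",
              x$intercept, x$slope, x$r,
              if (length(x$outliers))
                sprintf("; %d outlier(s) removed", length(x$outliers)) else ""))
  invisible(x)
}

#' Per-gene z-score normalization of activities
#'
#' For each gene, subtracts the mean activity across that gene's sequences
#' and divides by the sample standard deviation. Genes with fewer than 2
#' records or zero within-gene SD are dropped (z = NA) with a warning.
#'
#' @param records `data.frame` with `gene_id` and a score column.
#' @param score Name of the score column (default "activity").
#' @return Numeric vector of z-scores aligned to `records` (NA for dropped
#'   genes), with attribute `dropped_genes`.
#' @export
zscore_by_gene <- function(records, score = "activity") {
  x <- records[[score]]
  g <- records$gene_id
  z <- rep(NA_real_, length(x))
  dropped <- character(0)
  for (gene in unique(g)) {
    sel <- which(g == gene)
    if (length(sel) < 2L || stats::sd(x[sel]) == 0) {
      dropped <- c(dropped, gene)
      next
    }
    z[sel] <- (x[sel] - mean(x[sel])) / stats::sd(x[sel])
  }
  if (length(dropped)) {
    warnf("zscore_by_gene: dropped gene(s) with <2 records or zero SD: %s",
          paste(dropped, collapse = ", "))
  }
  attr(z, "dropped_genes") <- dropped
  z
}

contrast_one <- function(x_with, x_without, label, n_tests, test, n_boot,
                         seed) {
  p <- switch(test, mwu = mwu_test(x_with, x_without)$p,
              t = welch_t_test(x_with, x_without)$p)
  data.frame(feature = label,
             n_with = length(x_with), n_without = length(x_without),
             median_diff = stats::median(x_with) - stats::median(x_without),
             mean_diff = mean(x_with) - mean(x_without),
             boot_sd = boot_median_diff(x_with, x_without, n_boot, seed),
             p_raw = p, p_adj = min(1, p * n_tests),
             stringsAsFactors = FALSE)
}

get_score <- function(records, score) {
  switch(score,
         raw = records$activity,
         gc_corrected = {
           if (!"gc_corrected" %in% names(records)) {
             gc_correct(records)$corrected
           } else records$gc_corrected
         },
         z = {
           if (!"z" %in% names(records)) zscore_by_gene(records)
           else records$z
         },
         stopf("unknown score '%s'", score))
}

#' Motif presence contrasts on MPRA activity
#'
#' For each motif class, compares the chosen score between records with and
#' without the motif: median difference (with minus without) with bootstrap
#' SD, two-sided test p-value, and Bonferroni adjustment over the classes
#' tested in the same call.
#'
#' @param records Annotated record `data.frame` from [mpra_annotate()] (or
#'   any `data.frame` with logical class-flag columns and score columns).
#' @param classes Motif classes to test (flag column names).
#' @param score `"raw"`, `"gc_corrected"` (computed on the fly if absent) or
#'   `"z"`.
#' @param test `"mwu"` (Mann-Whitney U) or `"t"` (Welch).
#' @param n_boot Bootstrap resamples for the median-difference SD.
#' @param seed RNG seed for the bootstrap.
#' @return `data.frame` of class contrasts.
#' @export
motif_contrast <- function(records, classes = c("G4", "Z", "IR", "DR", "MR",
                                                "STR", "H"),
                           score = c("raw", "gc_corrected", "z"),
                           test = c("mwu", "t"), n_boot = 1000L,
                           seed = NULL) {
  score <- match.arg(score); test <- match.arg(test)
  y <- get_score(records, score)
  res <- lapply(classes, function(cl) {
    f <- records[[cl]]
    ok <- !is.na(y)
    if (!any(f & ok) || !any(!f & ok)) {
      stopf("class %s has an empty group", cl)
    }
    contrast_one(y[f & ok], y[!f & ok], cl, length(classes), test, n_boot,
                 seed)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Template versus non-template G4 orientation contrast
#'
#' Compares the chosen score between G4-containing records whose G4 lies on
#' the template strand and those on the non-template strand (difference is
#' template minus non-template).
#'
#' @inheritParams motif_contrast
#' @return One-row contrast `data.frame`.
#' @export
orientation_contrast <- function(records,
                                 score = c("raw", "gc_corrected", "z"),
                                 test = c("mwu", "t"), n_boot = 1000L,
                                 seed = NULL) {
  score <- match.arg(score); test <- match.arg(test)
  y <- get_score(records, score)
  tpl <- which(records$g4_orientation == "template" & !is.na(y))
  ntp <- which(records$g4_orientation == "non_template" & !is.na(y))
  if (!length(tpl) || !length(ntp)) stopf("empty orientation group")
  out <- contrast_one(y[tpl], y[ntp], "template_vs_non_template", 1L, test,
                      n_boot, seed)
  out
}

#' Kruskal-Wallis trend of activity across Z-DNA length bins
#'
#' @param records Annotated record `data.frame` (uses `z_len` and the score).
#' @param breaks Z-DNA length bin edges (left-closed; records with no Z-DNA
#'   are excluded).
#' @param score Score column selector as in [motif_contrast()].
#' @return `list(H, p, medians, n)` with per-bin medians for monotonicity
#'   inspection.
#' @export
zdna_length_trend <- function(records, breaks = c(10, 14, 18, Inf),
                              score = c("raw", "gc_corrected", "z")) {
  score <- match.arg(score)
  y <- get_score(records, score)
  sel <- records$z_len >= breaks[1] & !is.na(y)
  bins <- cut(records$z_len[sel], breaks = breaks, right = FALSE)
  yy <- y[sel]
  tab <- table(bins)
  if (sum(tab > 0L) < 2L) stopf("need records in at least 2 length bins")
  kt <- kw_test(yy, bins)
  med <- tapply(yy, bins, stats::median)
  list(H = kt$statistic, p = kt$p,
       medians = setNames(as.numeric(med), names(med)),
       n = as.integer(tab))
}

# Jonckheere-Terpstra test for an ordered trend across groups (normal
# approximation; ties handled through the Mann-Whitney counting).
jonckheere_test <- function(y, g) {
  lev <- sort(unique(g))
  k <- length(lev)
  J <- 0
  ns <- vapply(lev, function(l) sum(g == l), numeric(1))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    a <- y[g == lev[i]]; b <- y[g == lev[j]]
    J <- J + sum(outer(b, a, ">")) + 0.5 * sum(outer(b, a, "=="))
  }
  n <- sum(ns)
  mu <- (n^2 - sum(ns^2)) / 4
  sig2 <- (n^2 * (2 * n + 3) - sum(ns^2 * (2 * ns + 3))) / 72
  z <- (J - mu) / sqrt(sig2)
  list(J = J, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Association between consecutive G-run count and corrected activity
#'
#' Mean GC-corrected activity per number of consecutive G-runs (counts above
#' `max_runs` pooled), with bootstrap CIs and a Jonckheere-style monotone
#' trend test across run-count groups.
#'
#' @param records Annotated record `data.frame` (uses `g_runs`).
#' @param max_runs Largest run count reported separately.
#' @param n_boot Bootstrap resamples per group.
#' @param seed RNG seed.
#' @return `list(table, trend)`: per-group n/mean/ci and the trend test.
#' @export
g_run_association <- function(records, max_runs = 5L, n_boot = 200L,
                              seed = NULL) {
  y <- get_score(records, "gc_corrected")
  g <- pmin(records$g_runs, max_runs)
  lev <- sort(unique(g))
  tab <- do.call(rbind, lapply(lev, function(l) {
    yy <- y[g == l & !is.na(y)]
    ci <- if (length(yy) >= 2L) {
      boot_stat(yy, mean, n_boot = n_boot, seed = seed)$ci
    } else c(NA_real_, NA_real_)
    data.frame(g_runs = l, n = length(yy), mean = mean(yy),
               ci_lo = ci[1], ci_hi = ci[2])
  }))
  rownames(tab) <- NULL
  list(table = tab, trend = jonckheere_test(y[!is.na(y)], g[!is.na(y)]))
}

#' Joint ranking of motif and TFBS expression contrasts
#'
#' One contrast per feature (each motif class flag plus each transcription
#' factor with hits), on the chosen score; motifs and TFBSs share one
#' Bonferroni family, and the result is ranked by median difference.
#' Features with an empty group are skipped with a message.
#'
#' @param records Annotated record `data.frame`.
#' @param tfbs_hits `data.frame` with columns seq_id (insert) and tf (from
#'   [pwm_scan()]).
#' @param classes Motif flag columns to include.
#' @inheritParams motif_contrast
#' @return Ranked contrast `data.frame` with a `kind` column (motif/tfbs).
#' @export
tfbs_vs_motif_contrast <- function(records, tfbs_hits,
                                   classes = c("G4", "Z", "IR", "DR", "MR",
                                               "STR", "H"),
                                   score = c("raw", "gc_corrected", "z"),
                                   test = c("t", "mwu"), n_boot = 200L,
                                   seed = NULL) {
  score <- match.arg(score); test <- match.arg(test)
  y <- get_score(records, score)
  tfs <- sort(unique(tfbs_hits$tf))
  feats <- c(setNames(as.list(classes), classes),
             setNames(lapply(tfs, function(tf) {
               records$insert %in% tfbs_hits$seq_id[tfbs_hits$tf == tf]
             }), tfs))
  n_tests <- length(feats)
  res <- list()
  for (nm in names(feats)) {
    f <- if (is.character(feats[[nm]])) records[[nm]] else feats[[nm]]
    ok <- !is.na(y)
    if (!any(f & ok) || !any(!f & ok)) {
      message("tfbs_vs_motif_contrast: skipping ", nm, " (empty group)")
      next
    }
    row <- contrast_one(y[f & ok], y[!f & ok], nm, n_tests, test, n_boot,
                        seed)
    row$kind <- if (nm %in% classes) "motif" else "tfbs"
    res[[nm]] <- row
  }
  out <- do.call(rbind, res)
  out <- out[order(-out$median_diff), ]
  rownames(out) <- NULL
  out
}
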