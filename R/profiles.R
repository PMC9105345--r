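#' Interval set algebra
#'
#' `expand_intervals` pads intervals by `by` bp on each side (clipped at 0 and
#' at `chrom_sizes` when given); `subtract_intervals` removes the bp covered
#' by `b` from `a`; `intersect_intervals` keeps the bp covered by both;
#' `total_bp` is the number of bp covered by the (merged) set.
#'
#' @param df,a,b Interval `data.frame`s.
#' @param by Padding in bp.
#' @param chrom_sizes Optional named vector of chromosome lengths.
#' @return An interval `data.frame` (or a scalar for `total_bp`).
#' @export
expand_intervals <- function(df, by, chrom_sizes = NULL) {
  out <- df
  out$start <- pmax(df$start - as.integer(by), 0L)
  out$end <- df$end + as.integer(by)
  if (!is.null(chrom_sizes)) {
    out$end <- pmin(out$end, as.integer(chrom_sizes[out$chrom]))
  }
  merge_intervals(out)
}

#' @rdname expand_intervals
#' @export
subtract_intervals <- function(a, b) {
  a <- merge_intervals(a); b <- merge_intervals(b)
  if (nrow(a) == 0L || nrow(b) == 0L) return(a)
  pieces <- lapply(split(seq_len(nrow(a)), a$chrom), function(idx) {
    ch <- a$chrom[idx[1]]
    bb <- b[b$chrom == ch, , drop = FALSE]
    res_s <- integer(0); res_e <- integer(0)
    for (i in idx) {
      s <- a$start[i]; e <- a$end[i]
      cuts <- bb[bb$start < e & bb$end > s, , drop = FALSE]
      cur <- s
      for (j in seq_len(nrow(cuts))) {
        if (cuts$start[j] > cur) {
          res_s <- c(res_s, cur); res_e <- c(res_e, cuts$start[j])
        }
        cur <- max(cur, cuts$end[j])
      }
      if (cur < e) { res_s <- c(res_s, cur); res_e <- c(res_e, e) }
    }
    if (!length(res_s)) return(NULL)
    data.frame(chrom = ch, start = res_s, end = res_e,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  }
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' @rdname expand_intervals
#' @export
intersect_intervals <- function(a, b) {
  a <- merge_intervals(a)
  subtract_intervals(a, subtract_intervals(a, b))
}

#' @rdname expand_intervals
#' @export
total_bp <- function(df) {
  m <- merge_intervals(df)
  sum(as.numeric(m$end - m$start))
}

profile_bins <- function(flank, bin) {
  stopifnot(flank > 0L, bin > 0L, (2L * flank) %% bin == 0L)
  seq(-flank, flank, by = bin)
}

#' Metaprofile of features around transcription start sites
#'
#' Features are counted (by midpoint, or by bp coverage) into strand-oriented
#' offset bins around each TSS; negative offsets are upstream in transcription
#' direction. Fold is the per-bin density over the mean density of the
#' outermost 20% of bins (the background); if that background is zero the
#' overall mean density is used instead, with a warning.
#'
#' @param features Interval `data.frame`.
#' @param genes Gene model `data.frame`.
#' @param flank Half-width of the profiled window, bp.
#' @param bin Bin width, bp; must divide `2 * flank`.
#' @param mode Count feature midpoints (default) or bp coverage.
#' @return `list` of class `meta_profile`: anchor, edges, counts, density,
#'   fold, background.
#' @export
tss_metaprofile <- function(features, genes, flank = 1000L, bin = 10L,
                            mode = c("midpoint", "coverage")) {
  mode <- match.arg(mode)
  if (nrow(genes) == 0L) stopf("no genes supplied")
  edges <- profile_bins(flank, bin)
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  tss <- gene_tss(genes)
  mid <- (features$start + features$end - 1L) %/% 2L
  for (g in seq_len(nrow(genes))) {
    sel <- which(features$chrom == genes$chrom[g])
    if (!length(sel)) next
    if (mode == "midpoint") {
      off <- if (genes$strand[g] == "+") mid[sel] - tss[g] else tss[g] - mid[sel]
      off <- off[off >= -flank & off < flank]
      if (length(off)) {
        b <- floor((off + flank) / bin) + 1L
        tab <- tabulate(b, nbins = nb)
        counts <- counts + tab
      }
    } else {
      for (i in sel) {
        o1 <- if (genes$strand[g] == "+") features$start[i] - tss[g] else
          tss[g] - features$end[i] + 1L
        o2 <- o1 + (features$end[i] - features$start[i])
        lo <- max(o1, -flank); hi <- min(o2, flank)
        if (lo >= hi) next
        for (p in lo:(hi - 1L)) {
          counts[floor((p + flank) / bin) + 1L] <-
            counts[floor((p + flank) / bin) + 1L] + 1 / bin
        }
      }
    }
  }
  finish_profile("TSS", edges, counts, bp_per_bin = rep(bin, nb))
}

finish_profile <- function(anchor, edges, counts, bp_per_bin,
                           bg_side = c("both", "far")) {
  bg_side <- match.arg(bg_side)
  nb <- length(counts)
  density <- ifelse(bp_per_bin > 0, counts / bp_per_bin, NA_real_)
  bg_bins <- if (bg_side == "both") {
    k <- max(1L, ceiling(0.1 * nb))
    c(seq_len(k), seq(nb - k + 1L, nb))
  } else {
    k <- max(1L, ceiling(0.2 * nb))
    seq(nb - k + 1L, nb)
  }
  background <- mean(density[bg_bins], na.rm = TRUE)
  if (!is.finite(background) || background == 0) {
    warnf("outermost-bin background is zero; using overall mean density")
    background <- mean(density, na.rm = TRUE)
  }
  structure(list(anchor = anchor, edges = edges, counts = counts,
                 density = density, fold = density / background,
                 background = background),
            class = "meta_profile")
}

#' @export
print.meta_profile <- function(x, ...) {
  cat(sprintf("%s metaprofile: %d bins over [%d, %d), background density %.4g\n",
              x$anchor, length(x$counts), min(x$edges), max(x$edges),
              x$background))
  invisible(x)
}

# genic compartments with single-assignment precedence:
# upstream-1kb > 5'UTR > coding exon > 3'UTR > intron > downstream-1kb
gene_compartments <- function(genes, upstream = 1000L, downstream = 1000L,
                              chrom_sizes = NULL) {
  mk <- function(chrom, start, end) {
    keep <- start < end
    data.frame(chrom = chrom[keep], start = start[keep], end = end[keep],
               stringsAsFactors = FALSE)
  }
  plus <- genes$strand == "+"
  up <- mk(genes$chrom,
           ifelse(plus, pmax(genes$start - upstream, 0L), genes$end),
           ifelse(plus, genes$start, genes$end + upstream))
  down <- mk(genes$chrom,
             ifelse(plus, genes$end, pmax(genes$start - downstream, 0L)),
             ifelse(plus, genes$end + downstream, genes$start))
  utr5 <- mk(genes$chrom,
             ifelse(plus, genes$start, genes$cds_end),
             ifelse(plus, genes$cds_start, genes$end))
  utr3 <- mk(genes$chrom,
             ifelse(plus, genes$cds_end, genes$start),
             ifelse(plus, genes$end, genes$cds_start))
  exon_list <- lapply(seq_len(nrow(genes)), function(g) {
    es <- as.integer(strsplit(genes$exon_starts[g], ",")[[1]])
    ee <- as.integer(strsplit(genes$exon_ends[g], ",")[[1]])
    data.frame(chrom = genes$chrom[g], start = es, end = ee,
               stringsAsFactors = FALSE)
  })
  exons <- do.call(rbind, exon_list)
  cds <- mk(genes$chrom, genes$cds_start, genes$cds_end)
  coding <- intersect_intervals(exons, cds)
  body <- mk(genes$chrom, genes$start, genes$end)
  intron <- subtract_intervals(body, exons)
  if (!is.null(chrom_sizes)) {
    clip <- function(d) {
      d$end <- pmin(d$end, as.integer(chrom_sizes[d$chrom])); d[d$start < d$end, ]
    }
    up <- clip(up); down <- clip(down)
  }
  norm <- function(d) d[, c("chrom", "start", "end"), drop = FALSE]
  comp <- list(`upstream-1kb` = norm(merge_intervals(up)),
               `5'UTR` = norm(merge_intervals(utr5)),
               `coding-exon` = norm(coding),
               `3'UTR` = norm(merge_intervals(utr3)),
               intron = norm(intron),
               `downstream-1kb` = norm(merge_intervals(down)))
  comp <- Filter(function(d) nrow(d) > 0L, comp)
  taken <- NULL
  out <- list()
  for (nm in names(comp)) {
    cur <- if (is.null(taken)) comp[[nm]] else
      norm(subtract_intervals(comp[[nm]], taken))
    out[[nm]] <- cur
    taken <- if (is.null(taken)) cur else
      norm(merge_intervals(rbind(taken, cur)))
  }
  out
}

#' Compartment enrichment of features across the gene body
#'
#' Genic compartments (1 kb upstream of the TSS, 5'UTR, coding exons, 3'UTR,
#' introns, 1 kb downstream of the TES) are derived from the gene models with
#' a fixed single-assignment precedence. Fold is the share of features (by
#' midpoint) in the compartment over the compartment's share of the genome;
#' the p-value is an exact binomial tail doubled to two sides and
#' Bonferroni-adjusted over compartments.
#'
#' @param features Interval `data.frame`.
#' @param genes Gene model `data.frame`.
#' @param genome_bp Total genome size in bp.
#' @param chrom_sizes Optional named vector for clipping flanks.
#' @return `data.frame`: compartment, count, bp, length_share, fold, p_raw,
#'   p_adj.
#' @export
compartment_enrichment <- function(features, genes, genome_bp,
                                   chrom_sizes = NULL) {
  comp <- gene_compartments(genes, chrom_sizes = chrom_sizes)
  mid <- (features$start + features$end - 1L) %/% 2L
  n <- nrow(features)
  res <- lapply(names(comp), function(nm) {
    bp <- total_bp(comp[[nm]])
    if (bp == 0) {
      warnf("zero-length compartment %s skipped", nm)
      return(NULL)
    }
    share <- bp / genome_bp
    k <- sum(point_in_index(features$chrom, mid, interval_index(comp[[nm]])))
    fold <- (k / n) / share
    p <- binom_test_two_sided(k, n, share)$p
    data.frame(compartment = nm, count = k, bp = bp, length_share = share,
               fold = fold, p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- pmin(1, out$p_raw * nrow(out))
  rownames(out) <- NULL
  out
}

#' Promoter-proximal density ratio with bootstrap SD
#'
#' Ratio of per-bp feature densities in the near upstream window (default
#' \[-250, 0)) versus the wide window (default \[-1000, 0)), offsets in
#' transcription direction, pooled over genes; the SD comes from a bootstrap
#' over genes.
#'
#' @param features Interval `data.frame` (counted by midpoint).
#' @param genes Gene model `data.frame`.
#' @param near,wide Offset windows `c(lo, hi)` with `near` inside `wide`.
#' @param n_boot Bootstrap resamples over genes.
#' @param seed RNG seed.
#' @return `list(ratio, sd, n_near, n_wide)`; ratio is `NA` with a warning
#'   when the wide window is empty.
#' @export
promoter_proximal_ratio <- function(features, genes, near = c(-250L, 0L),
                                    wide = c(-1000L, 0L), n_boot = 1000L,
                                    seed = NULL) {
  stopifnot(near[1] >= wide[1], near[2] <= wide[2])
  mid <- (features$start + features$end - 1L) %/% 2L
  tss <- gene_tss(genes)
  per_gene <- lapply(seq_len(nrow(genes)), function(g) {
    sel <- which(features$chrom == genes$chrom[g])
    off <- if (genes$strand[g] == "+") mid[sel] - tss[g] else tss[g] - mid[sel]
    c(near = sum(off >= near[1] & off < near[2]),
      wide = sum(off >= wide[1] & off < wide[2]))
  })
  tab <- do.call(rbind, per_gene)
  ratio_of <- function(m) {
    nw <- sum(m[, "wide"])
    if (nw == 0) return(NA_real_)
    (sum(m[, "near"]) / (near[2] - near[1])) / (nw / (wide[2] - wide[1]))
  }
  ratio <- ratio_of(tab)
  if (is.na(ratio)) warnf("no features in the wide window; ratio is NA")
  bs <- boot_stat(as.data.frame(tab), function(d) ratio_of(as.matrix(d)),
                  n_boot = n_boot, seed = seed)
  list(ratio = ratio, sd = bs$sd,
       n_near = sum(tab[, "near"]), n_wide = sum(tab[, "wide"]))
}

#' Orientation bias of genic G4 motifs at peaks, background-corrected
#'
#' Among genic G4 motifs overlapping peaks, counts non-template (k) versus
#' template (m) motifs; the background proportion pi is the non-template
#' share among all genic G4 motifs. Fold is the observed odds over the
#' background odds, and the p-value is an exact two-sided binomial test of k
#' successes in k + m trials at probability pi. The CI transforms the exact
#' binomial CI of k/(k+m) to the fold scale.
#'
#' @param oriented_hits Output of [assign_orientation()] restricted to G4
#'   hits; rows with orientation "intergenic" are ignored.
#' @param peaks Interval `data.frame` of peaks.
#' @return `list(k, m, pi, fold, p, ci)`.
#' @export
orientation_bias_test <- function(oriented_hits, peaks) {
  h <- oriented_hits[oriented_hits$orientation %in%
                       c("template", "non_template"), , drop = FALSE]
  if (nrow(h) == 0L) stopf("no genic oriented hits")
  pi_bg <- mean(h$orientation == "non_template")
  in_peak <- overlaps_any(h$seq_id, h$start, h$end, peaks)
  k <- sum(in_peak & h$orientation == "non_template")
  m <- sum(in_peak & h$orientation == "template")
  if (k + m == 0L) stopf("no oriented hits overlap peaks")
  odds_bg <- pi_bg / (1 - pi_bg)
  fold <- (k / m) / odds_bg
  p <- binom_test_two_sided(k, k + m, pi_bg)$p
  bt <- stats::binom.test(k, k + m)
  ci <- (bt$conf.int / (1 - bt$conf.int)) / odds_bg
  list(k = k, m = m, pi = pi_bg, fold = fold, p = p, ci = as.numeric(ci))
}

#' eQTL density profile centered on motif footprints
#'
#' Bins eQTL points by distance to the nearest motif footprint (bin 0 =
#' inside a motif) and normalizes to per-bp density using the exact number of
#' genome positions at each distance (via interval expansion, clipped at
#' `chrom_sizes` when given). Fold is density over the mean density of the
#' outermost 20% of distance bins. Also reports the fraction of motifs with
#' at least one eQTL inside.
#'
#' @param eqtls `data.frame` with chrom, pos (0-based points).
#' @param motifs Interval `data.frame` (merged internally).
#' @param flank Maximum distance profiled, bp.
#' @param bin Distance bin width, bp.
#' @param chrom_sizes Optional named vector of chromosome lengths.
#' @return `list` of class `meta_profile` with an extra element
#'   `frac_motifs_with_eqtl`.
#' @export
eqtl_density_profile <- function(eqtls, motifs, flank = 1000L, bin = 100L,
                                 chrom_sizes = NULL) {
  motifs <- merge_intervals(as_chrom_intervals(motifs))
  if (nrow(motifs) == 0L) stopf("empty motif set")
  stopifnot(flank %% bin == 0L)
  d <- abs(distance_to_nearest(eqtls$chrom, eqtls$pos, motifs))
  d <- d[!is.na(d)]
  nb <- flank %/% bin + 1L
  counts <- c(sum(d == 0),
              vapply(seq_len(nb - 1L), function(b) {
                sum(d > (b - 1L) * bin & d <= b * bin)
              }, numeric(1)))
  bp <- numeric(nb)
  bp[1] <- total_bp(motifs)
  prev <- bp[1]
  for (b in seq_len(nb - 1L)) {
    cum <- total_bp(expand_intervals(motifs, b * bin, chrom_sizes))
    bp[b + 1L] <- cum - prev
    prev <- cum
  }
  prof <- finish_profile("motif", seq(0L, flank + bin, by = bin) - bin,
                         counts, bp, bg_side = "far")
  with_e <- overlaps_any(motifs$chrom, motifs$start, motifs$end,
                         eqtls_to_points(eqtls))
  prof$frac_motifs_with_eqtl <- mean(with_e)
  prof
}

eqtls_to_points <- function(eqtls) {
  data.frame(chrom = eqtls$chrom, start = eqtls$pos, end = eqtls$pos + 1L,
             stringsAsFactors = FALSE)
}

#' Feature density z-scores across element sets
#'
#' Density is the number of feature bp overlapping the element set per
#' element bp; z-scores are computed across element labels with the sample
#' standard deviation.
#'
#' @param features Interval `data.frame`.
#' @param element_sets Named list of interval `data.frame`s (length >= 2).
#' @return Named numeric vector of z-scores.
#' @export
element_density_zscore <- function(features, element_sets) {
  stopifnot(length(element_sets) >= 2L)
  dens <- vapply(element_sets, function(el) {
    bp <- total_bp(el)
    if (bp == 0) return(NA_real_)
    total_bp(intersect_intervals(features, el)) / bp
  }, numeric(1))
  regulatory_zscore(dens)
}
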