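#' Construct a variant table
#'
#' @param chrom Chromosomes.
#' @param pos 0-based positions (SNP site, indel anchor, or SV breakpoint).
#' @param ref,alt Ref/alt alleles (may be "." for synthetic variants).
#' @param vtype One of SNP, INS, DEL, SV_BND.
#' @param sv_class Optional SV class (DEL/DUP/INS/INV/CTX/CPX).
#' @param length Indel length in bp (0 for SNP/SV_BND unless known).
#' @return Variant `data.frame`.
#' @export
variant_table <- function(chrom, pos, ref = ".", alt = ".",
                          vtype = "SNP", sv_class = NA_character_,
                          length = 0L) {
  stopifnot(all(vtype %in% c("SNP", "INS", "DEL", "SV_BND")))
  n <- max(base::length(chrom), base::length(pos))
  data.frame(chrom = rep_len(as.character(chrom), n),
             pos = as.integer(pos),
             ref = rep_len(ref, n), alt = rep_len(alt, n),
             vtype = rep_len(vtype, n), sv_class = rep_len(sv_class, n),
             length = rep_len(as.integer(length), n),
             stringsAsFactors = FALSE)
}

# footprint of a variant on the forward axis, 0-based half-open
variant_footprint <- function(vars) {
  ref_len <- ifelse(!is.na(vars$ref) & vars$ref != "." & nzchar(vars$ref),
                    nchar(vars$ref), NA_integer_)
  len <- ifelse(vars$vtype == "DEL",
                ifelse(is.na(ref_len), vars$length + 1L, ref_len), 1L)
  data.frame(chrom = vars$chrom, start = vars$pos,
             end = vars$pos + pmax(len, 1L), stringsAsFactors = FALSE)
}

# Per-chromosome index of trinucleotide-context positions inside the mask:
# list[chrom][context] -> sorted 0-based center positions. Contexts containing
# N are excluded.
context_index <- function(genome, mask = NULL, chroms = names(genome)) {
  mask_idx <- if (!is.null(mask)) interval_index(mask) else NULL
  out <- list()
  for (ch in chroms) {
    x <- strsplit(genome[[ch]], NULL)[[1]]
    n <- length(x)
    if (n < 3L) { out[[ch]] <- list(); next }
    i <- 2:(n - 1L)
    ok <- x[i - 1L] != "N" & x[i] != "N" & x[i + 1L] != "N"
    pos0 <- i[ok] - 1L
    if (!is.null(mask_idx)) {
      keep <- point_in_index(rep(ch, length(pos0)), pos0, mask_idx)
      pos0 <- pos0[keep]
    }
    ctx <- paste0(x[pos0], x[pos0 + 1L], x[pos0 + 2L])
    out[[ch]] <- split(pos0, ctx)
  }
  out
}

snp_context <- function(snps, genome) {
  vapply(seq_len(nrow(snps)), function(i) {
    s <- genome[[snps$chrom[i]]]
    p <- snps$pos[i]
    if (p < 1L || p > nchar(s) - 2L) return(NA_character_)
    ctx <- substr(s, p, p + 2L)
    if (grepl("N", ctx)) NA_character_ else ctx
  }, character(1))
}

#' Simulate trinucleotide-matched SNP controls
#'
#' For every source SNP, each replicate draws one position uniformly among all
#' positions within `window` bp of the source whose trinucleotide context
#' (5' base, center, 3' base) is identical to the source's, that lie inside
#' the callable mask, and that differ from the source position. Sources with
#' no eligible position are dropped (and counted).
#'
#' @param snps Variant `data.frame` (vtype SNP).
#' @param genome Named character vector of chromosome sequences.
#' @param mask Optional callable-region interval `data.frame`; `NULL` means
#'   the whole genome is callable.
#' @param window Maximum distance from the source, bp.
#' @param n_reps Number of simulated replicate sets.
#' @param seed RNG seed (replicates use independent draws).
#' @return `data.frame` of simulated variants with columns of the source table
#'   plus `rep` (replicate index) and `source` (row of the source SNP).
#'   Attribute `dropped` holds the row indices of unplaceable sources.
#' @export
simulate_snp_controls <- function(snps, genome, mask = NULL, window = 10000L,
                                  n_reps = 10L, seed = 1L) {
  if (!all(snps$chrom %in% names(genome))) {
    stopf("missing chromosome sequence for: %s",
          paste(setdiff(snps$chrom, names(genome)), collapse = ", "))
  }
  if (!is.null(mask) && nrow(mask) == 0L) stopf("mask is empty")
  idx <- context_index(genome, mask, chroms = unique(snps$chrom))
  ctx <- snp_context(snps, genome)
  out <- vector("list", 0L)
  dropped <- integer(0)
  with_seed(seed, {
    for (ch in unique(snps$chrom)) {
      rows_ch <- which(snps$chrom == ch)
      for (cx in unique(ctx[rows_ch])) {
        rows <- rows_ch[which(ctx[rows_ch] == cx)]
        if (is.na(cx)) { dropped <- c(dropped, rows); next }
        idxv <- idx[[ch]][[cx]]
        if (is.null(idxv)) { dropped <- c(dropped, rows); next }
        p <- snps$pos[rows]
        lo <- findInterval(p - window - 1L, idxv) + 1L
        hi <- findInterval(p + window, idxv)
        si <- findInterval(p, idxv)
        present <- si >= 1L & idxv[pmax(si, 1L)] == p
        m <- hi - lo + 1L - as.integer(present)
        bad <- m <= 0L
        dropped <- c(dropped, rows[bad])
        rows <- rows[!bad]; p <- p[!bad]; lo <- lo[!bad]; si <- si[!bad]
        present <- present[!bad]; m <- m[!bad]
        if (!length(rows)) next
        for (r in seq_len(n_reps)) {
          k <- lo + floor(stats::runif(length(rows)) * m)
          k <- pmin(k, lo + m - 1L)           # guard fp rounding
          k <- k + as.integer(present & k >= si)
          out[[length(out) + 1L]] <- data.frame(
            chrom = ch, pos = idxv[k], ref = snps$ref[rows],
            alt = snps$alt[rows], vtype = "SNP", sv_class = NA_character_,
            length = 0L, rep = r, source = rows, stringsAsFactors = FALSE)
        }
      }
    }
  })
  res <- if (length(out)) do.call(rbind, out) else
    cbind(variant_table(character(0), integer(0)),
          data.frame(rep = integer(0), source = integer(0)))
  res <- res[order(res$rep, res$source), ]
  rownames(res) <- NULL
  if (length(dropped)) {
    message("simulate_snp_controls: dropped ", length(dropped),
            " source SNP(s) with no eligible matched position")
  }
  attr(res, "dropped") <- sort(dropped)
  res
}

# flanking GC (both 100bp-style windows combined, N excluded) around a
# footprint [p, p+L) on cumulative counts; flanks are truncated at the
# sequence ends and a site is usable only if both flanks have >= 1 base
flank_gc <- function(p, L, W, cum_gc, cum_ok, n) {
  a <- pmax(p - W, 0L); b <- p
  cpos <- p + L; d <- pmin(p + L + W, n)
  gc <- (cum_gc[b + 1L] - cum_gc[a + 1L]) + (cum_gc[d + 1L] - cum_gc[cpos + 1L])
  tot <- (cum_ok[b + 1L] - cum_ok[a + 1L]) + (cum_ok[d + 1L] - cum_ok[cpos + 1L])
  left_w <- b - a; right_w <- d - cpos
  ifelse(left_w >= 1L & right_w >= 1L & tot > 0L, gc / tot, NA_real_)
}

simulate_gc_matched <- function(vars, genome, mask, window, gc_window, gc_tol,
                                n_reps, seed, label) {
  if (!all(vars$chrom %in% names(genome))) {
    stopf("missing chromosome sequence for: %s",
          paste(setdiff(vars$chrom, names(genome)), collapse = ", "))
  }
  mask_idx <- if (!is.null(mask)) interval_index(mask) else NULL
  out <- vector("list", 0L)
  dropped <- integer(0)
  with_seed(seed, {
    for (ch in unique(vars$chrom)) {
      x <- strsplit(genome[[ch]], NULL)[[1]]
      n <- length(x)
      cum_gc <- c(0L, cumsum(x %in% c("G", "C")))
      cum_ok <- c(0L, cumsum(x != "N"))
      rows <- which(vars$chrom == ch)
      for (i in rows) {
        L <- if (vars$vtype[i] == "DEL") max(vars$length[i], 1L) else
             if (vars$vtype[i] == "INS") 1L else 0L
        p0 <- vars$pos[i]
        src_gc <- flank_gc(p0, L, gc_window, cum_gc, cum_ok, n)
        if (is.na(src_gc)) { dropped <- c(dropped, i); next }
        cand <- seq.int(max(p0 - window, 1L), min(p0 + window, n - L - 1L))
        cand <- cand[cand != p0]
        if (length(cand)) {
          gc <- flank_gc(cand, L, gc_window, cum_gc, cum_ok, n)
          cand <- cand[!is.na(gc) & abs(gc - src_gc) <= gc_tol]
        }
        if (length(cand) && !is.null(mask_idx)) {
          cand <- cand[point_in_index(rep(ch, length(cand)), cand, mask_idx)]
        }
        if (!length(cand)) { dropped <- c(dropped, i); next }
        pick <- cand[ceiling(stats::runif(n_reps) * length(cand))]
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, pos = pick, ref = vars$ref[i], alt = vars$alt[i],
          vtype = vars$vtype[i], sv_class = vars$sv_class[i],
          length = vars$length[i], rep = seq_len(n_reps), source = i,
          stringsAsFactors = FALSE)
      }
    }
  })
  res <- if (length(out)) do.call(rbind, out) else
    cbind(variant_table(character(0), integer(0)),
          data.frame(rep = integer(0), source = integer(0)))
  res <- res[order(res$rep, res$source), ]
  rownames(res) <- NULL
  if (length(dropped)) {
    message(label, ": dropped ", length(dropped),
            " source variant(s) with no eligible matched position")
  }
  attr(res, "dropped") <- sort(dropped)
  res
}

#' Simulate length- and GC-matched indel controls
#'
#' Each simulated indel keeps the source's exact length and type, lies within
#' `window` bp of the source (but not at it), inside the callable mask, and
#' its local GC content (over `gc_window` bp on each side of the indel
#' footprint, both flanks combined, truncated at sequence ends) differs from
#' the source's by at most `gc_tol` (absolute). Sites with an empty flank are
#' ineligible.
#'
#' @inheritParams simulate_snp_controls
#' @param indels Variant `data.frame` (vtype INS/DEL with `length`).
#' @param gc_window Flank width for local GC, bp.
#' @param gc_tol Maximum absolute GC-fraction difference.
#' @return As [simulate_snp_controls()].
#' @export
simulate_indel_controls <- function(indels, genome, mask = NULL,
                                    window = 10000L, gc_window = 100L,
                                    gc_tol = 0.025, n_reps = 10L, seed = 1L) {
  simulate_gc_matched(indels, genome, mask, window, gc_window, gc_tol,
                      n_reps, seed, "simulate_indel_controls")
}

#' Simulate GC-matched structural-variant breakpoint controls
#'
#' Breakpoints are point events; each simulated breakpoint lies within
#' `window` bp of its source with local GC (over `gc_window` bp each side)
#' within `gc_tol` of the source's, carrying the source's SV class label.
#'
#' @inheritParams simulate_indel_controls
#' @param breakpoints Variant `data.frame` (vtype SV_BND).
#' @return As [simulate_snp_controls()].
#' @export
simulate_sv_breakpoints <- function(breakpoints, genome, mask = NULL,
                                    window = 10000L, gc_window = 100L,
                                    gc_tol = 0.025, n_reps = 10L, seed = 1L) {
  simulate_gc_matched(breakpoints, genome, mask, window, gc_window, gc_tol,
                      n_reps, seed, "simulate_sv_breakpoints")
}

#' Overlap enrichment of variants at motifs against simulated controls
#'
#' The observed overlap fraction is the share of variants whose footprint
#' (deletions: the deleted span; insertions and SNPs: one anchor base;
#' breakpoints: a point) overlaps at least one motif interval. Fold is the
#' observed fraction over the mean of the per-replicate simulated fractions.
#' The p-value comes from a two-sided Mann-Whitney U test comparing the
#' per-variant distances to the nearest motif between observed variants and
#' pooled simulated controls (`test = "distance_mwu"`, the default), or from
#' the position of the observed fraction in the replicate fraction
#' distribution (`test = "fraction"`). The CI is a percentile bootstrap over
#' variants of the fold.
#'
#' @param variants Observed variant `data.frame`.
#' @param sims Simulated controls from one of the `simulate_*` functions.
#' @param motifs Interval `data.frame` of motif footprints (a `seq_id` column
#'   is accepted in place of `chrom`); merged internally.
#' @param test Test mode; see above.
#' @param n_boot Bootstrap resamples for the CI.
#' @param seed RNG seed for the bootstrap.
#' @return `list` of class `enrichment_result`: observed, sim_fractions,
#'   fold, p, ci, n_obs, n_sim, test.
#' @export
overlap_enrichment <- function(variants, sims, motifs,
                               test = c("distance_mwu", "fraction"),
                               n_boot = 1000L, seed = NULL) {
  test <- match.arg(test)
  motifs <- as_chrom_intervals(motifs)
  if (nrow(motifs) == 0L) stopf("empty motif set")
  if (!nrow(sims)) stopf("need at least one simulated replicate")
  fp <- variant_footprint(variants)
  obs_hit <- overlaps_any(fp$chrom, fp$start, fp$end, motifs)
  observed <- mean(obs_hit)
  sfp <- variant_footprint(sims)
  sim_hit <- overlaps_any(sfp$chrom, sfp$start, sfp$end, motifs)
  sim_fractions <- as.numeric(tapply(sim_hit, sims$rep, mean))
  mean_sim <- mean(sim_fractions)
  if (mean_sim == 0 && observed > 0) {
    warnf("no simulated overlap; fold reported as Inf")
    fold <- Inf
  } else {
    fold <- observed / mean_sim
  }
  p <- if (test == "distance_mwu") {
    d_obs <- abs(distance_to_nearest(variants$chrom, variants$pos, motifs))
    d_sim <- abs(distance_to_nearest(sims$chrom, sims$pos, motifs))
    mwu_test(d_obs[!is.na(d_obs)], d_sim[!is.na(d_sim)])$p
  } else {
    R <- length(sim_fractions)
    min(1, 2 * min((1 + sum(sim_fractions >= observed)) / (R + 1),
                   (1 + sum(sim_fractions <= observed)) / (R + 1)))
  }
  bs <- boot_stat(as.numeric(obs_hit),
                  function(z) if (mean_sim > 0) mean(z) / mean_sim else NA_real_,
                  n_boot = n_boot, seed = seed)
  structure(list(observed = observed, sim_fractions = sim_fractions,
                 fold = fold, p = p, ci = bs$ci,
                 n_obs = nrow(variants), n_sim = nrow(sims), test = test),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "overlap enrichment: observed %.4f vs simulated %.4f (fold %.3f), p = %.3g\n",
    x$observed, mean(x$sim_fractions), x$fold, x$p))
  cat(sprintf("  bootstrap 95%% CI [%.3f, %.3f]; n = %d observed, %d simulated (%s)\n",
              x$ci[1], x$ci[2], x$n_obs, x$n_sim, x$test))
  invisible(x)
}

as_chrom_intervals <- function(df) {
  if (!"chrom" %in% names(df) && "seq_id" %in% names(df)) {
    df$chrom <- df$seq_id
  }
  df[, c("chrom", "start", "end")]
}

#' Insertion versus deletion overlap fractions per motif class
#'
#' @param indels Variant `data.frame` with vtype INS/DEL.
#' @param motifs Motif hit `data.frame` with a `class` column.
#' @return `data.frame` per motif class: ins_fraction, del_fraction and their
#'   del/ins ratio; fractions are `NA` when a side has zero indels.
#' @export
indel_direction_split <- function(indels, motifs) {
  classes <- sort(unique(motifs$class))
  res <- lapply(classes, function(cl) {
    sub <- as_chrom_intervals(motifs[motifs$class == cl, , drop = FALSE])
    frac <- function(v) {
      if (nrow(v) == 0L) return(NA_real_)
      fp <- variant_footprint(v)
      mean(overlaps_any(fp$chrom, fp$start, fp$end, sub))
    }
    fi <- frac(indels[indels$vtype == "INS", , drop = FALSE])
    fd <- frac(indels[indels$vtype == "DEL", , drop = FALSE])
    data.frame(class = cl, ins_fraction = fi, del_fraction = fd,
               del_ins_ratio = fd / fi, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Z-scores of mutation density across element classes
#'
#' `z_i = (d_i - mean(d)) / sd(d)` with the sample standard deviation.
#'
#' @param densities Named numeric vector of per-element-class densities
#'   (length >= 2).
#' @return Named numeric vector of z-scores; all zero (with a warning) when
#'   the densities are constant.
#' @export
regulatory_zscore <- function(densities) {
  stopifnot(length(densities) >= 2L)
  s <- stats::sd(densities)
  if (s == 0) {
    warnf("constant densities: z-scores undefined, returning zeros")
    return(setNames(rep(0, length(densities)), names(densities)))
  }
  (densities - mean(densities)) / s
}
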