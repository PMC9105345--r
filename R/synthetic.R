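motif_plan_length <- function(class, params, cfg) {
  switch(class,
    Z = params$length,
    G4 = {
      loops <- params$loops %||% rep(1L, (params$n_runs %||% cfg$g4_min_runs) - 1L)
      run_len <- params$run_len %||% cfg$g_run_min
      (length(loops) + 1L) * run_len + sum(loops)
    },
    IR = , MR = , DR = 2L * (params$arm %||% cfg$rep_arm_len) +
      (params$spacer %||% 0L),
    stopf("unsupported planted class %s", class))
}

#' Generate a synthetic genome with planted non-B DNA motifs
#'
#' Background bases are iid at the requested GC (P(G) = P(C) = gc/2); planted
#' motifs are built by the [introduce_motif()] machinery (validated by
#' rescanning a local window) at the exact planned coordinates.
#'
#' @param length Genome length, bp.
#' @param gc Background GC fraction.
#' @param plan Optional `data.frame` of planted motifs: columns class, pos
#'   (0-based start) and per-class parameters (`length` for Z; `loops` as a
#'   comma string, `run_len` for G4; `arm`, `spacer` for IR/MR/DR).
#'   Placements must not overlap (2 bp guard band).
#' @param seed RNG seed.
#' @param chrom Chromosome name.
#' @return `list(genome, truth)`: named sequence vector and the truth
#'   interval `data.frame` (chrom, start, end, class).
#' @export
gen_genome <- function(length, gc = 0.41, plan = NULL, seed = 1L,
                       chrom = "chr1") {
  cfg <- scan_config()
  with_seed(seed, {
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    s <- paste(sample(names(probs), length, replace = TRUE, prob = probs),
               collapse = "")
    truth <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), class = character(0))
    if (!is.null(plan) && nrow(plan)) {
      params_of <- function(row) {
        list(length = if ("length" %in% names(plan)) row$length else NULL,
             loops = if ("loops" %in% names(plan) && !is.na(row$loops))
               as.integer(strsplit(as.character(row$loops), ",")[[1]]) else NULL,
             run_len = if ("run_len" %in% names(plan)) row$run_len else NULL,
             arm = if ("arm" %in% names(plan)) row$arm else NULL,
             spacer = if ("spacer" %in% names(plan)) row$spacer else NULL)
      }
      lens <- vapply(seq_len(nrow(plan)), function(i) {
        motif_plan_length(as.character(plan$class[i]),
                          params_of(plan[i, ]), cfg)
      }, numeric(1))
      o <- order(plan$pos)
      if (any(plan$pos[o][-1] < (plan$pos[o] + lens[o] + 2L)[-nrow(plan)]) ||
          any(plan$pos < 1L) || any(plan$pos + lens > length - 1L)) {
        stopf("planted placements overlap or exceed bounds")
      }
      for (i in seq_len(nrow(plan))) {
        cl <- as.character(plan$class[i])
        p <- params_of(plan[i, ])
        p <- p[!vapply(p, is.null, logical(1))]
        p <- p[!vapply(p, function(v) all(is.na(v)), logical(1))]
        len <- lens[i]
        lo <- max(plan$pos[i] - 60L, 0L)
        hi <- min(plan$pos[i] + len + 60L, length)
        local <- substr(s, lo + 1L, hi)
        cfg_i <- cfg
        if (cl %in% c("IR", "MR", "DR") && !is.null(p$arm)) {
          cfg_i$rep_arm_len <- as.integer(p$arm)
          cfg_i$rep_max_spacer <- max(cfg$rep_max_spacer,
                                      as.integer(p$spacer %||% 0L))
        }
        edited <- introduce_motif(local, cl, p, plan$pos[i] - lo,
                                  seed = sample.int(2^30, 1L), cfg = cfg_i)
        s <- paste0(substr(s, 1L, lo), edited, substr(s, hi + 1L, length))
        truth <- rbind(truth, data.frame(chrom = chrom, start = plan$pos[i],
                                         end = plan$pos[i] + len, class = cl,
                                         stringsAsFactors = FALSE))
      }
    }
    list(genome = setNames(s, chrom), truth = truth)
  })
}

#' Generate variants with a planted motif-overlap enrichment
#'
#' Variants are placed so that the per-bp rate inside motif footprints is
#' `fold` times the background rate: the in-motif count is the rounded
#' expectation of the mixture and positions are drawn uniformly without
#' replacement within each stratum.
#'
#' @param genome Named character vector (single chromosome).
#' @param motifs Truth interval `data.frame` of motif footprints.
#' @param fold Planted per-bp rate ratio (>= 0).
#' @param n Number of variants.
#' @param type SNP, INS, DEL or SV_BND.
#' @param seed RNG seed.
#' @param gaps Optional interval `data.frame` excluded from the callable
#'   mask (and from placement).
#' @param edge Margin kept variant-free at both sequence ends.
#' @return `list(variants, mask, truth)`; truth records the realized fold.
#' @export
gen_variants <- function(genome, motifs, fold, n,
                         type = c("SNP", "INS", "DEL", "SV_BND"), seed = 1L,
                         gaps = NULL, edge = 300L) {
  type <- match.arg(type)
  chrom <- names(genome)[1]
  L <- nchar(genome[[1]])
  core <- data.frame(chrom = chrom, start = edge, end = L - edge)
  mask <- if (is.null(gaps)) core else subtract_intervals(core, gaps)
  mm <- intersect_intervals(merge_intervals(as_chrom_intervals(motifs)), mask)
  bg <- subtract_intervals(mask, mm)
  m_bp <- total_bp(mm); bg_bp <- total_bp(bg)
  p_in <- fold * m_bp / (fold * m_bp + bg_bp)
  n_in <- round(n * p_in)
  if (n_in > m_bp) stopf("fold too high: %d variants cannot fit %d motif bp",
                         n_in, m_bp)
  pos_pool <- function(iv) {
    unlist(lapply(seq_len(nrow(iv)), function(i) seq.int(iv$start[i],
                                                         iv$end[i] - 1L)))
  }
  with_seed(seed, {
    pin <- sample(pos_pool(mm), n_in)
    pout <- sample(pos_pool(bg), n - n_in)
    pos <- sample(c(pin, pout))       # shuffle strata together
    lens <- if (type %in% c("INS", "DEL")) {
      sample.int(49L, n, replace = TRUE)
    } else rep(0L, n)
    v <- variant_table(chrom, pos, vtype = type,
                       sv_class = if (type == "SV_BND") "DEL" else NA,
                       length = lens)
    realized <- if (m_bp > 0 && n > n_in) {
      (n_in / m_bp) / ((n - n_in) / bg_bp)
    } else NA_real_
    list(variants = v, mask = mask,
         truth = list(fold = fold, realized_fold = realized, n_in = n_in))
  })
}

#' Generate non-overlapping gene models
#'
#' Genes are tiled with random lengths and gaps, random strands, and single
#' full-span exons with a central CDS.
#'
#' @param genome_length Chromosome length, bp.
#' @param n_genes Number of genes.
#' @param seed RNG seed.
#' @param chrom Chromosome name.
#' @param len_range Gene length range, bp.
#' @param gap_range Intergenic gap range, bp.
#' @return Gene model `data.frame` (see [gene_models()]).
#' @export
gen_gene_models <- function(genome_length, n_genes, seed = 1L,
                            chrom = "chr1", len_range = c(2000L, 5000L),
                            gap_range = c(1500L, 4000L)) {
  with_seed(seed, {
    starts <- integer(0); ends <- integer(0)
    cur <- sample.int(gap_range[2], 1L) + 1000L
    for (g in seq_len(n_genes)) {
      len <- sample(len_range[1]:len_range[2], 1L)
      if (cur + len > genome_length - 1000L) break
      starts <- c(starts, cur); ends <- c(ends, cur + len)
      cur <- cur + len + sample(gap_range[1]:gap_range[2], 1L)
    }
    k <- length(starts)
    if (k < n_genes) {
      warnf("gen_gene_models: placed %d of %d genes before running out of space",
            k, n_genes)
    }
    cds_s <- starts + pmax(100L, (ends - starts) %/% 10L)
    cds_e <- ends - pmax(100L, (ends - starts) %/% 10L)
    gene_models(gene_id = sprintf("gene%03d", seq_len(k)),
                chrom = chrom, strand = sample(c("+", "-"), k, replace = TRUE),
                start = starts, end = ends,
                cds_start = cds_s, cds_end = cds_e)
  })
}

#' Generate eQTL points with a planted in-motif density ratio
#'
#' @param genome_length Chromosome length, bp.
#' @param motifs Motif truth intervals.
#' @param fold Planted in-motif per-bp density over background.
#' @param n Number of eQTLs.
#' @param seed RNG seed.
#' @param chrom Chromosome name.
#' @return `data.frame` with chrom, pos.
#' @export
gen_eqtls <- function(genome_length, motifs, fold, n, seed = 1L,
                      chrom = "chr1") {
  mm <- merge_intervals(as_chrom_intervals(motifs))
  m_bp <- total_bp(mm)
  bg_bp <- genome_length - m_bp
  p_in <- fold * m_bp / (fold * m_bp + bg_bp)
  n_in <- round(n * p_in)
  with_seed(seed, {
    pool <- unlist(lapply(seq_len(nrow(mm)), function(i) {
      seq.int(mm$start[i], mm$end[i] - 1L)
    }))
    pin <- sample(pool, n_in, replace = n_in > length(pool))
    pout <- integer(0)
    while (length(pout) < n - n_in) {
      cand <- sample.int(genome_length, n - n_in - length(pout)) - 1L
      cand <- cand[!point_in_index(rep(chrom, length(cand)), cand,
                                   interval_index(mm))]
      pout <- c(pout, cand)
    }
    data.frame(chrom = chrom, pos = sort(c(pin, pout)),
               stringsAsFactors = FALSE)
  })
}

#' Generate peaks with a planted G4 orientation bias
#'
#' Each genic G4 motif is covered by a peak with probability
#' `2 * coverage * pi` (non-template) or `2 * coverage * (1 - pi)`
#' (template), so the non-template:template coverage odds equal
#' `pi / (1 - pi)` times the background orientation odds, i.e. the
#' background-corrected fold of [orientation_bias_test()] is
#' `pi / (1 - pi)` in expectation.
#'
#' @param oriented_hits Output of [assign_orientation()] for G4 hits;
#'   intergenic rows are ignored.
#' @param pi_non_template Target non-template coverage share in (0, 1).
#' @param coverage Overall coverage scale; probabilities are capped at 1
#'   (with `coverage = 1` and `pi = 0.5`, every genic G4 is overlapped).
#' @param seed RNG seed.
#' @param pad Peak half-width added around each covered motif, bp.
#' @return Peak interval `data.frame`.
#' @export
gen_peaks <- function(oriented_hits, pi_non_template, coverage = 0.4,
                      seed = 1L, pad = 20L) {
  stopifnot(pi_non_template > 0, pi_non_template < 1)
  h <- oriented_hits[oriented_hits$orientation %in%
                       c("template", "non_template"), , drop = FALSE]
  q <- ifelse(h$orientation == "non_template",
              pmin(1, 2 * coverage * pi_non_template),
              pmin(1, 2 * coverage * (1 - pi_non_template)))
  with_seed(seed, {
    cov <- stats::runif(nrow(h)) < q
    if (!any(cov)) {
      return(data.frame(chrom = character(0), start = integer(0),
                        end = integer(0)))
    }
    merge_intervals(data.frame(chrom = h$seq_id[cov],
                               start = pmax(h$start[cov] - pad, 0L),
                               end = h$end[cov] + pad,
                               stringsAsFactors = FALSE))
  })
}

#' Generate an MPRA barcode count table with known ground truth
#'
#' True activity is `baseline_gene + beta_gc * gc + sum(beta_class * flag) +
#' N(0, sigma)` (log2 scale); DNA barcode counts are negative binomial with
#' mean proportional to depth and RNA counts with mean proportional to
#' `depth * 2^activity`. A fraction of barcodes is drawn at much lower depth
#' to exercise the minimum-count filter.
#'
#' @param design `data.frame` with insert, gene_id, gc and logical motif-flag
#'   columns (e.g. from [mpra_annotate()] records or built directly).
#' @param params List: `baseline` (named per gene, or single number),
#'   `beta_gc`, `beta` (named per class), `sigma` (activity noise SD),
#'   `dispersion` (NB size), `frac_low` (share of shallow barcodes).
#' @param n_barcodes Barcodes per insert.
#' @param depth Mean DNA count per barcode.
#' @param n_reps Replicates.
#' @param seed RNG seed.
#' @return `list(counts, truth)`: the count table (insert, barcode,
#'   replicate, dna, rna) and the per-insert true activities plus parameters.
#' @export
gen_mpra_counts <- function(design, params, n_barcodes = 10L, depth = 50,
                            n_reps = 3L, seed = 1L) {
  if (depth <= 0) stopf("depth must be positive")
  beta <- params$beta %||% numeric(0)
  sigma <- params$sigma %||% 0.2
  disp <- params$dispersion %||% 10
  frac_low <- params$frac_low %||% 0.1
  baseline <- params$baseline %||% 0
  with_seed(seed, {
    base_g <- if (length(baseline) > 1L || !is.null(names(baseline))) {
      unname(baseline[design$gene_id])
    } else rep(baseline, nrow(design))
    a <- base_g + (params$beta_gc %||% 0) * design$gc
    for (cl in names(beta)) {
      if (cl %in% names(design)) a <- a + beta[[cl]] * design[[cl]]
    }
    a <- a + stats::rnorm(nrow(design), 0, sigma)
    rows <- vector("list", nrow(design))
    for (i in seq_len(nrow(design))) {
      bc <- sprintf("%s_bc%02d", design$insert[i], seq_len(n_barcodes))
      low <- stats::runif(n_barcodes) < frac_low
      mu_dna <- ifelse(low, depth / 20, depth)
      grid <- expand.grid(barcode = bc, replicate = seq_len(n_reps),
                          stringsAsFactors = FALSE)
      mu <- rep(mu_dna, times = n_reps)
      dna <- stats::rnbinom(nrow(grid), mu = mu, size = disp)
      rna <- stats::rnbinom(nrow(grid), mu = mu * 2^a[i], size = disp)
      rows[[i]] <- data.frame(insert = design$insert[i],
                              barcode = grid$barcode,
                              replicate = grid$replicate,
                              dna = dna, rna = rna,
                              stringsAsFactors = FALSE)
    }
    list(counts = do.call(rbind, rows),
         truth = list(activity = setNames(a, design$insert),
                      params = params))
  })
}
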