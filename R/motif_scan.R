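#' Scanner configuration for non-B DNA motif detection
#'
#' Holds every tunable threshold of the seven motif detectors. The defaults
#' are the field-standard definitions: G-quadruplexes as four or more runs of
#' at least three G separated by 1-7 nt loops; Z-DNA as alternating
#' purine-pyrimidine tracts of at least 10 bp; inverted/direct/mirror repeats
#' with 10 bp arms and spacers up to 4 bp; H-DNA as purine-rich mirror repeats
#' (arm >= 10 bp, spacer < 8 bp, A/G or T/C content above 90%); and short
#' tandem repeats with 1-6 bp units, at least 3 copies and at least 10 bp
#' total.
#'
#' @param g_run_min Minimum G-run length (default 3).
#' @param g4_loop_min,g4_loop_max Loop length bounds (1, 7).
#' @param g4_min_runs Minimum number of G-runs (4).
#' @param z_min_len Minimum alternating-tract length in bp (10).
#' @param rep_arm_len Repeat arm length in bp for IR/DR/MR (10).
#' @param rep_max_spacer Maximum spacer for IR/DR/MR (4).
#' @param str_unit_min,str_unit_max STR unit length bounds (1, 6).
#' @param str_min_total Minimum STR array length in bp (10).
#' @param str_min_copies Minimum STR copy number (3).
#' @param dr_str_purity Fraction of the DR arm that may be covered by a short
#'   tandem repeat before the DR call is suppressed as STR territory (0.80).
#' @param h_ag_min_frac Minimum A/G (or T/C) fraction of an H-DNA footprint
#'   (0.90, exclusive).
#' @param h_min_arm Minimum H-DNA arm length (10).
#' @param h_max_spacer Maximum H-DNA spacer, inclusive (7, i.e. spacer < 8).
#' @param report_mode `"exhaustive"` reports every arm/spacer placement;
#'   `"merged"` unions overlapping same-class footprints.
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(g_run_min = 3L, g4_loop_min = 1L, g4_loop_max = 7L,
                        g4_min_runs = 4L, z_min_len = 10L, rep_arm_len = 10L,
                        rep_max_spacer = 4L, str_unit_min = 1L,
                        str_unit_max = 6L, str_min_total = 10L,
                        str_min_copies = 3L, dr_str_purity = 0.80,
                        h_ag_min_frac = 0.90, h_min_arm = 10L,
                        h_max_spacer = 7L,
                        report_mode = c("exhaustive", "merged")) {
  cfg <- list(g_run_min = as.integer(g_run_min),
              g4_loop_min = as.integer(g4_loop_min),
              g4_loop_max = as.integer(g4_loop_max),
              g4_min_runs = as.integer(g4_min_runs),
              z_min_len = as.integer(z_min_len),
              rep_arm_len = as.integer(rep_arm_len),
              rep_max_spacer = as.integer(rep_max_spacer),
              str_unit_min = as.integer(str_unit_min),
              str_unit_max = as.integer(str_unit_max),
              str_min_total = as.integer(str_min_total),
              str_min_copies = as.integer(str_min_copies),
              dr_str_purity = dr_str_purity,
              h_ag_min_frac = h_ag_min_frac,
              h_min_arm = as.integer(h_min_arm),
              h_max_spacer = as.integer(h_max_spacer),
              report_mode = match.arg(report_mode))
  stopifnot(cfg$g_run_min > 0L, cfg$g4_loop_min >= 1L,
            cfg$g4_loop_min <= cfg$g4_loop_max, cfg$g4_min_runs >= 2L,
            cfg$z_min_len > 0L, cfg$rep_arm_len >= 2L,
            cfg$rep_max_spacer >= 0L, cfg$str_unit_min >= 1L,
            cfg$str_unit_max >= cfg$str_unit_min, cfg$str_min_total > 0L,
            cfg$str_min_copies >= 2L,
            cfg$dr_str_purity > 0, cfg$dr_str_purity <= 1,
            cfg$h_ag_min_frac > 0, cfg$h_ag_min_frac <= 1,
            cfg$h_min_arm >= 2L, cfg$h_max_spacer >= 0L)
  class(cfg) <- "scan_config"
  cfg
}

# One row per motif occurrence; all classes share the schema so results rbind.
empty_hits <- function() {
  data.frame(seq_id = character(0), class = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             arm = integer(0), spacer = integer(0),
             unit = character(0), copies = integer(0),
             runs = character(0), loops = character(0),
             ag_frac = numeric(0), stringsAsFactors = FALSE)
}

hit_rows <- function(seq_id, class, start, end, strand = "+",
                     arm = NA_integer_, spacer = NA_integer_,
                     unit = NA_character_, copies = NA_integer_,
                     runs = NA_character_, loops = NA_character_,
                     ag_frac = NA_real_) {
  if (length(start) == 0L) return(empty_hits())
  data.frame(seq_id = seq_id, class = class,
             start = as.integer(start), end = as.integer(end),
             strand = strand, arm = as.integer(arm),
             spacer = as.integer(spacer), unit = unit,
             copies = as.integer(copies), runs = runs, loops = loops,
             ag_frac = ag_frac, stringsAsFactors = FALSE)
}

order_hits <- function(hits) {
  hits <- hits[order(hits$seq_id, hits$class, hits$start, hits$end,
                     hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

g4_regex <- function(cfg) {
  sprintf("(?:[gG]{%d,}\\w{%d,%d}){%d,}[gG]{%d,}",
          cfg$g_run_min, cfg$g4_loop_min, cfg$g4_loop_max,
          cfg$g4_min_runs - 1L, cfg$g_run_min)
}

# Leftmost-longest matches of the G4 consensus regex on one plus-strand
# sequence. A greedy engine finds the leftmost start; the span is then grown
# to the longest end that still matches the anchored pattern (greedy
# backtracking can settle on a shorter span when a loop absorbs G bases).
g4_matches_plus <- function(s, cfg) {
  pat <- g4_regex(cfg)
  anchored <- paste0("^", pat, "$")
  x <- strsplit(s, NULL)[[1]]
  isG <- x == "G" | x == "g"
  n <- length(x)
  out_start <- integer(0); out_end <- integer(0)
  from <- 1L
  while (from <= n) {
    rest <- substr(s, from, n)
    m <- regexpr(pat, rest, perl = TRUE)
    if (m == -1L) break
    st <- from + as.integer(m) - 1L             # 1-based absolute start
    len <- attr(m, "match.length")
    en <- st + len - 1L                         # 1-based inclusive end
    # furthest the match could possibly reach: no valid match contains more
    # than g4_loop_max consecutive non-G bases
    reach <- en
    gap <- 0L
    j <- en + 1L
    while (j <= n) {
      if (isG[j]) gap <- 0L else gap <- gap + 1L
      if (gap > cfg$g4_loop_max) break
      reach <- j
      j <- j + 1L
    }
    if (reach > en) {
      # candidate longer ends must terminate in a full G-run
      for (j in seq.int(en + 1L, reach)) {
        if (!isG[j]) next
        if (j - cfg$g_run_min + 1L < st) next
        if (!all(isG[(j - cfg$g_run_min + 1L):j])) next
        if (grepl(anchored, substr(s, st, j), perl = TRUE)) en <- j
      }
    }
    out_start <- c(out_start, st); out_end <- c(out_end, en)
    from <- en + 1L
  }
  list(start = out_start, end = out_end)
}

g4_substructure <- function(span) {
  # maximal G-run parse of the reported span: runs of G, gaps are loops
  r <- rle(strsplit(span, NULL)[[1]] %in% c("G", "g"))
  runs <- r$lengths[r$values]
  loops <- r$lengths[!r$values]
  list(runs = runs, loops = loops)
}

#' Scan for G-quadruplex motifs
#'
#' Reports the leftmost-longest, non-overlapping matches of the G4 consensus
#' pattern (>= `g4_min_runs` runs of >= `g_run_min` G separated by loops of
#' `g4_loop_min`..`g4_loop_max` nt). With `both_strands`, the reverse
#' complement is scanned as well and hit coordinates are mapped back to the
#' forward axis with strand "-". The substructure columns record the
#' maximal-G-run decomposition of each span (run lengths and loop lengths,
#' comma-separated).
#'
#' @param seqs Named character vector of sequences.
#' @param cfg A [scan_config()].
#' @param both_strands Scan the reverse complement too?
#' @return Motif hit `data.frame` (0-based half-open coordinates).
#' @export
scan_g4 <- function(seqs, cfg = scan_config(), both_strands = FALSE) {
  res <- lapply(seq_along(seqs), function(k) {
    s <- seqs[[k]]
    id <- names(seqs)[k] %||% as.character(k)
    L <- nchar(s)
    m <- g4_matches_plus(s, cfg)
    hits <- mk_g4_rows(id, s, m$start, m$end, "+", L)
    if (both_strands) {
      rc <- reverse_complement(s)
      mr <- g4_matches_plus(rc, cfg)
      hits <- rbind(hits, mk_g4_rows(id, rc, mr$start, mr$end, "-", L))
    }
    hits
  })
  order_hits(do.call(rbind, c(res, list(empty_hits()))))
}

mk_g4_rows <- function(id, s, st, en, strand, L) {
  if (length(st) == 0L) return(empty_hits())
  subs <- lapply(seq_along(st),
                 function(i) g4_substructure(substr(s, st[i], en[i])))
  start0 <- if (strand == "+") st - 1L else L - en
  end0 <- if (strand == "+") en else L - st + 1L
  hit_rows(id, "G4", start0, end0, strand,
           runs = vapply(subs, function(z) paste(z$runs, collapse = ","),
                         character(1)),
           loops = vapply(subs, function(z) paste(z$loops, collapse = ","),
                          character(1)))
}

#' Scan for Z-DNA motifs
#'
#' Maximal strictly alternating purine (A/G) / pyrimidine (C/T) tracts of
#' length >= `z_min_len`. The definition is strand-symmetric, so hits are
#' reported on "+" only. N bases break tracts.
#'
#' @inheritParams scan_g4
#' @return Motif hit `data.frame`.
#' @export
scan_zdna <- function(seqs, cfg = scan_config()) {
  res <- lapply(seq_along(seqs), function(k) {
    x <- strsplit(seqs[[k]], NULL)[[1]]
    id <- names(seqs)[k] %||% as.character(k)
    n <- length(x)
    if (n < cfg$z_min_len) return(empty_hits())
    cls <- ifelse(x %in% c("A", "G"), 1L, ifelse(x %in% c("C", "T"), 2L, 0L))
    ok <- cls[-n] > 0L & cls[-1L] > 0L & cls[-n] != cls[-1L]
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & (r$lengths + 1L) >= cfg$z_min_len
    hit_rows(id, "Z", starts[keep] - 1L, ends[keep] + 1L, "+")
  })
  order_hits(do.call(rbind, c(res, list(empty_hits()))))
}

# Shared IR/DR/MR engine. Exhaustive mode: every (start, spacer) placement at
# arm length exactly cfg$rep_arm_len. N bases never participate in a motif.
scan_repeat <- function(seqs, cfg, type, arm = cfg$rep_arm_len,
                        max_spacer = cfg$rep_max_spacer, min_spacer = 0L,
                        extend_arms = FALSE, class_label = type) {
  res <- lapply(seq_along(seqs), function(k) {
    s <- seqs[[k]]
    id <- names(seqs)[k] %||% as.character(k)
    x <- strsplit(s, NULL)[[1]]
    n <- length(x)
    xc <- chartr("ACGTN", "TGCAN", x)
    cumN <- c(0L, cumsum(x == "N"))
    all_st <- integer(0); all_sp <- integer(0); all_arm <- integer(0)
    for (sp in min_spacer:max_spacer) {
      w <- 2L * arm + sp
      if (w > n) next
      i <- seq_len(n - w + 1L)
      acc <- rep(TRUE, length(i))
      for (j in 0:(arm - 1L)) {
        a1 <- x[i + j]
        a2 <- switch(type,
                     IR = xc[i + w - 1L - j],
                     MR = x[i + w - 1L - j],
                     DR = x[i + arm + sp + j])
        acc <- acc & (a1 == a2)
      }
      acc <- acc & (cumN[i + w] - cumN[i]) == 0L
      st <- i[acc]
      if (type == "DR" && length(st)) {
        arms <- substring(s, st, st + arm - 1L)
        pure <- vapply(arms, function(a) str_purity(a, cfg), numeric(1),
                       USE.NAMES = FALSE)
        st <- st[pure < cfg$dr_str_purity]
      }
      if (length(st)) {
        all_st <- c(all_st, st)
        all_sp <- c(all_sp, rep(sp, length(st)))
        all_arm <- c(all_arm, rep(arm, length(st)))
      }
    }
    if (extend_arms && length(all_st)) {
      ext <- extend_repeat_arms(x, xc, all_st, all_sp, all_arm, type)
      all_st <- ext$start; all_sp <- ext$spacer; all_arm <- ext$arm
      keep <- !duplicated(data.frame(all_st, all_sp, all_arm))
      all_st <- all_st[keep]; all_sp <- all_sp[keep]; all_arm <- all_arm[keep]
    }
    hit_rows(id, class_label, all_st - 1L, all_st - 1L + 2L * all_arm + all_sp,
             "+", arm = all_arm, spacer = all_sp)
  })
  order_hits(do.call(rbind, c(res, list(empty_hits()))))
}

# Grow arms outward (IR/MR: footprint extends on both flanks; DR: arms extend
# with the repeat period) while symmetry holds and no N enters the footprint.
extend_repeat_arms <- function(x, xc, st, sp, arm, type) {
  n <- length(x)
  for (q in seq_along(st)) {
    repeat {
      a <- arm[q]; i <- st[q]; w <- 2L * a + sp[q]
      ok <- FALSE
      if (type %in% c("IR", "MR")) {
        l <- i - 1L; r <- i + w
        if (l >= 1L && r <= n && x[l] != "N" && x[r] != "N") {
          ok <- if (type == "IR") x[l] == xc[r] else x[l] == x[r]
        }
        if (ok) { st[q] <- l; arm[q] <- a + 1L }
      } else {
        # DR: try arm a+1 with the same start and spacer (full re-comparison;
        # arm growth changes the repeat period, so no incremental shortcut)
        a2 <- a + 1L
        if (i + 2L * a2 + sp[q] - 1L <= n) {
          foot <- x[i:(i + 2L * a2 + sp[q] - 1L)]
          j <- 0:(a2 - 1L)
          if (!any(foot == "N") && all(x[i + j] == x[i + a2 + sp[q] + j])) {
            arm[q] <- a2; ok <- TRUE
          }
        }
      }
      if (!ok) break
    }
  }
  list(start = st, spacer = sp, arm = arm)
}

# Largest fraction of an arm covered by a perfect tandem repeat (>= 2 copies)
# of any unit with length in the STR unit range but at most half the arm.
str_purity <- function(armstr, cfg) {
  x <- strsplit(armstr, NULL)[[1]]
  a <- length(x)
  best <- 0
  umax <- min(cfg$str_unit_max, a %/% 2L)
  if (umax < cfg$str_unit_min) return(0)
  for (u in cfg$str_unit_min:umax) {
    per <- x[seq_len(a - u)] == x[seq_len(a - u) + u]
    r <- rle(per)
    m <- if (any(r$values)) max(r$lengths[r$values]) else 0L
    if (m >= u) best <- max(best, (m + u) / a)
  }
  best
}

#' Scan for inverted repeats
#'
#' Exhaustive mode reports every placement of two `rep_arm_len` bp arms where
#' the second arm is the reverse complement of the first, separated by a
#' spacer of 0..`rep_max_spacer` bp.
#'
#' @inheritParams scan_g4
#' @param extend_arms Grow arms maximally outward while symmetry holds and
#'   report the extended arm length (used when arm lengths themselves are the
#'   quantity of interest).
#' @return Motif hit `data.frame` with `arm` and `spacer` columns.
#' @export
scan_inverted_repeats <- function(seqs, cfg = scan_config(),
                                  extend_arms = FALSE) {
  scan_repeat(seqs, cfg, "IR", extend_arms = extend_arms)
}

#' Scan for mirror repeats
#'
#' As [scan_inverted_repeats()] but the second arm is the reverse (not
#' complemented) of the first.
#'
#' @inheritParams scan_inverted_repeats
#' @return Motif hit `data.frame`.
#' @export
scan_mirror_repeats <- function(seqs, cfg = scan_config(),
                                extend_arms = FALSE) {
  scan_repeat(seqs, cfg, "MR", extend_arms = extend_arms)
}

#' Scan for direct repeats
#'
#' As [scan_inverted_repeats()] but the second arm equals the first. A
#' candidate whose arm is at least `dr_str_purity` covered by a short tandem
#' repeat (unit length up to half the arm) is suppressed: such arms are STR
#' territory.
#'
#' @inheritParams scan_inverted_repeats
#' @return Motif hit `data.frame`.
#' @export
scan_direct_repeats <- function(seqs, cfg = scan_config(),
                                extend_arms = FALSE) {
  scan_repeat(seqs, cfg, "DR", extend_arms = extend_arms)
}

#' Scan for short tandem repeats
#'
#' Maximal perfect tandem arrays with unit length `str_unit_min` ..
#' `str_unit_max`, at least `str_min_copies` copies and at least
#' `str_min_total` bp total. The reported unit is the lexicographically
#' smallest rotation; arrays whose minimal period is shorter than the unit are
#' suppressed (a dinucleotide array is not additionally reported as two
#' mononucleotide arrays).
#'
#' @inheritParams scan_g4
#' @return Motif hit `data.frame` with `unit` and `copies` columns.
#' @export
scan_strs <- function(seqs, cfg = scan_config()) {
  res <- lapply(seq_along(seqs), function(k) {
    s <- seqs[[k]]
    id <- names(seqs)[k] %||% as.character(k)
    x <- strsplit(s, NULL)[[1]]
    n <- length(x)
    st0 <- integer(0); en0 <- integer(0); un <- character(0); cp <- integer(0)
    for (u in cfg$str_unit_min:cfg$str_unit_max) {
      if (n < u + 1L) break
      i <- seq_len(n - u)
      per <- x[i] == x[i + u] & x[i] != "N" & x[i + u] != "N"
      r <- rle(per)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (q in which(r$values)) {
        len <- r$lengths[q] + u
        if (len < cfg$str_min_total || len %/% u < cfg$str_min_copies) next
        i0 <- starts[q]
        stretch <- x[i0:(i0 + len - 1L)]
        if (minimal_period(stretch) < u) next
        unit <- paste(stretch[seq_len(u)], collapse = "")
        st0 <- c(st0, i0 - 1L); en0 <- c(en0, i0 - 1L + len)
        un <- c(un, canonical_rotation(unit)); cp <- c(cp, len %/% u)
      }
    }
    hit_rows(id, "STR", st0, en0, "+", unit = un, copies = cp)
  })
  order_hits(do.call(rbind, c(res, list(empty_hits()))))
}

minimal_period <- function(x) {
  n <- length(x)
  for (p in seq_len(n)) {
    if (p == n || all(x[seq_len(n - p)] == x[seq_len(n - p) + p])) return(p)
  }
  n
}

canonical_rotation <- function(unit) {
  x <- strsplit(unit, NULL)[[1]]
  u <- length(x)
  rots <- vapply(seq_len(u), function(i) {
    paste(x[c(seq(i, u), seq_len(i - 1L))[seq_len(u)]], collapse = "")
  }, character(1))
  min(rots)
}

#' Scan for H-DNA motifs
#'
#' H-DNA motifs are mirror repeats with arm length >= `h_min_arm`, spacer
#' <= `h_max_spacer`, and purine (A/G) or pyrimidine (T/C) fraction over the
#' full footprint strictly greater than `h_ag_min_frac` (either strand may be
#' the purine-rich one).
#'
#' @inheritParams scan_inverted_repeats
#' @return Motif hit `data.frame` with an `ag_frac` column holding
#'   `max(AG, TC)` fraction of the footprint.
#' @export
scan_hdna <- function(seqs, cfg = scan_config(), extend_arms = FALSE) {
  mr <- scan_repeat(seqs, cfg, "MR", arm = cfg$h_min_arm,
                    max_spacer = cfg$h_max_spacer, extend_arms = extend_arms,
                    class_label = "H")
  if (nrow(mr) == 0L) return(mr)
  foot <- substring(seqs[mr$seq_id], mr$start + 1L, mr$end)
  len <- mr$end - mr$start
  n_ag <- nchar(gsub("[^AG]", "", foot))
  n_tc <- nchar(gsub("[^TC]", "", foot))
  mr$ag_frac <- pmax(n_ag, n_tc) / len
  out <- mr[mr$ag_frac > cfg$h_ag_min_frac, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a sequence set for all seven non-B DNA motif classes
#'
#' @inheritParams scan_g4
#' @param both_strands Scan G4s on both strands (other classes are
#'   strand-symmetric).
#' @return Motif hit `data.frame` over classes G4, Z, IR, DR, MR, STR, H,
#'   ordered by (seq_id, class, start, end, strand). With
#'   `cfg$report_mode == "merged"`, overlapping same-class (and same-strand)
#'   footprints are unioned and substructure columns are dropped.
#' @export
scan_all <- function(seqs, cfg = scan_config(), both_strands = FALSE) {
  hits <- rbind(scan_g4(seqs, cfg, both_strands = both_strands),
                scan_zdna(seqs, cfg),
                scan_inverted_repeats(seqs, cfg),
                scan_direct_repeats(seqs, cfg),
                scan_mirror_repeats(seqs, cfg),
                scan_strs(seqs, cfg),
                scan_hdna(seqs, cfg))
  hits <- order_hits(hits)
  if (cfg$report_mode == "merged") hits <- merge_hits(hits) else hits
}

#' Union overlapping same-class motif footprints
#'
#' @param hits Motif hit `data.frame`.
#' @return Hit `data.frame` with one row per merged footprint, per
#'   (seq_id, class, strand); substructure columns are NA.
#' @export
merge_hits <- function(hits) {
  if (nrow(hits) == 0L) return(empty_hits())
  key <- paste(hits$seq_id, hits$class, hits$strand, sep = "\r")
  pieces <- lapply(split(seq_len(nrow(hits)), key), function(idx) {
    d <- hits[idx, ]
    m <- merge_intervals(genomic_intervals(d$seq_id, d$start, d$end))
    hit_rows(d$seq_id[1], d$class[1], m$start, m$end, d$strand[1])
  })
  order_hits(do.call(rbind, pieces))
}

#' Presence flags per sequence and motif class
#'
#' @param hits Motif hit `data.frame` (any mode).
#' @param seq_ids Sequence ids to report (defaults to those present in
#'   `hits`).
#' @param classes Motif classes to report.
#' @return Logical matrix, sequences x classes.
#' @export
presence_flags <- function(hits, seq_ids = unique(hits$seq_id),
                           classes = c("G4", "Z", "IR", "DR", "MR", "STR", "H")) {
  m <- matrix(FALSE, length(seq_ids), length(classes),
              dimnames = list(seq_ids, classes))
  if (nrow(hits)) {
    sel <- hits$class %in% classes & hits$seq_id %in% seq_ids
    m[cbind(match(hits$seq_id[sel], seq_ids),
            match(hits$class[sel], classes))] <- TRUE
  }
  m
}

#' Orient motif hits relative to gene direction
#'
#' A stranded motif on the same strand as an overlapping gene lies on the
#' non-template (mRNA-like) strand; on the opposite strand it is on the
#' template strand. A hit overlapping no gene is intergenic. A hit overlapping
#' several genes yields one labeled row per overlapped gene.
#'
#' @param hits Motif hit `data.frame`; `seq_id` is matched against gene
#'   chromosomes.
#' @param genes Gene model `data.frame` from [gene_models()].
#' @return `data.frame`: the hit rows (replicated per overlapped gene) plus
#'   `gene_id` and `orientation` in {template, non_template, intergenic}.
#' @export
assign_orientation <- function(hits, genes) {
  if (nrow(hits) == 0L) {
    return(cbind(hits, data.frame(gene_id = character(0),
                                  orientation = character(0))))
  }
  res <- lapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    g <- genes[genes$chrom == h$seq_id & genes$start < h$end &
                 genes$end > h$start, , drop = FALSE]
    if (nrow(g) == 0L) {
      cbind(h, data.frame(gene_id = NA_character_,
                          orientation = "intergenic"))
    } else {
      cbind(h[rep(1L, nrow(g)), ],
            data.frame(gene_id = g$gene_id,
                       orientation = ifelse(g$strand == h$strand,
                                            "non_template", "template")))
    }
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Re-validate motif hit invariants against their source sequences
#'
#' Checks, per class: G4 run counts and loop bounds, Z alternation and
#' maximality, IR/MR/DR arm identities, STR periodicity and copy counts, and
#' the H-DNA composition rule. Used by the test suite as an independent
#' validator.
#'
#' @param hits Motif hit `data.frame` (exhaustive mode).
#' @param seqs Named character vector the hits were derived from.
#' @param cfg The [scan_config()] used.
#' @return TRUE invisibly; errors on the first violated invariant.
#' @export
validate_hits <- function(hits, seqs, cfg = scan_config()) {
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    s <- seqs[[h$seq_id]]
    foot <- substr(s, h$start + 1L, h$end)
    if (h$strand == "-") foot <- reverse_complement(foot)
    switch(h$class,
      G4 = {
        runs <- as.integer(strsplit(h$runs, ",")[[1]])
        loops <- if (is.na(h$loops) || h$loops == "") integer(0)
                 else as.integer(strsplit(h$loops, ",")[[1]])
        if (sum(runs) + sum(loops) != nchar(foot)) stopf("G4 hit %d: span mismatch", i)
        # loops of the consensus pattern may absorb G runs shorter than
        # g_run_min, so the invariants hold for the qualifying runs: at
        # least g4_min_runs of them, gaps between consecutive qualifying
        # runs within the loop bounds, and the span starts/ends in one
        qual <- runs >= cfg$g_run_min
        if (sum(qual) < cfg$g4_min_runs) stopf("G4 hit %d: too few runs", i)
        if (!qual[1] || !qual[length(qual)]) stopf("G4 hit %d: ragged ends", i)
        x <- strsplit(foot, NULL)[[1]]
        r <- rle(x == "G" | x == "g")
        ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
        qs <- starts[r$values & r$lengths >= cfg$g_run_min]
        qe <- ends[r$values & r$lengths >= cfg$g_run_min]
        if (length(qs) > 1L) {
          gaps <- qs[-1] - qe[-length(qe)] - 1L
          if (any(gaps < cfg$g4_loop_min | gaps > cfg$g4_loop_max)) {
            stopf("G4 hit %d: loop bound violated", i)
          }
        }
      },
      Z = {
        x <- strsplit(foot, NULL)[[1]]
        cls <- ifelse(x %in% c("A", "G"), 1L, ifelse(x %in% c("C", "T"), 2L, 0L))
        if (any(cls == 0L) || any(diff(cls) == 0L)) stopf("Z hit %d: not alternating", i)
        if (length(x) < cfg$z_min_len) stopf("Z hit %d: too short", i)
      },
      IR = , MR = , DR = , H = {
        a <- h$arm; sp <- h$spacer
        if (2L * a + sp != nchar(foot)) stopf("%s hit %d: footprint size", h$class, i)
        arm1 <- substr(foot, 1L, a)
        arm2 <- substr(foot, a + sp + 1L, 2L * a + sp)
        ok <- switch(h$class,
                     IR = arm2 == reverse_complement(arm1),
                     DR = arm2 == arm1,
                     arm2 == paste(rev(strsplit(arm1, NULL)[[1]]), collapse = ""))
        if (!ok) stopf("%s hit %d: arm symmetry violated", h$class, i)
        if (h$class == "H" &&
            !(h$ag_frac > cfg$h_ag_min_frac)) stopf("H hit %d: composition", i)
      },
      STR = {
        u <- nchar(h$unit)
        x <- strsplit(foot, NULL)[[1]]
        if (length(x) > u &&
            !all(x[seq_len(length(x) - u)] == x[seq_len(length(x) - u) + u])) {
          stopf("STR hit %d: not periodic", i)
        }
        if (h$copies != nchar(foot) %/% u) stopf("STR hit %d: copies", i)
      },
      stopf("unknown class %s", h$class))
  }
  invisible(TRUE)
}
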