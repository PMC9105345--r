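replace_window <- function(s, start0, repl) {
  # start0 is 0-based; repl replaces nchar(repl) bases
  paste0(substr(s, 1L, start0), repl,
         substr(s, start0 + nchar(repl) + 1L, nchar(s)))
}

#' Disrupt a G-quadruplex by G-run point mutations
#'
#' Introduces `n_mut_per_run` substitutions (G to `sub_base`) at uniformly
#' chosen positions within each targeted G-run of the hit. When
#' `runs_targeted = "all"`, the edit is redrawn (up to `max_retry` times)
#' until the edited insert carries no G4 hit on the edited strand.
#'
#' @param insert Insert sequence (single string).
#' @param hit One-row G4 hit `data.frame` (plus strand) from [scan_g4()].
#' @param n_mut_per_run Substitutions per targeted run (1-3).
#' @param runs_targeted Number of runs to hit (1, 2, 3) or `"all"`.
#' @param seed RNG seed.
#' @param cfg A [scan_config()].
#' @param sub_base Replacement base (default "T", which cannot seed a G-run).
#' @param max_retry Rescan retry cap for `runs_targeted = "all"`.
#' @param scope For `runs_targeted = "all"`: require the whole edited insert
#'   ("insert", default) or only the edited window ("window") to be free of
#'   G4 hits on the rescan.
#' @return Edited insert string.
#' @export
disrupt_g4 <- function(insert, hit, n_mut_per_run = 1L, runs_targeted = "all",
                       seed = 1L, cfg = scan_config(), sub_base = "T",
                       max_retry = 100L, scope = c("insert", "window")) {
  scope <- match.arg(scope)
  stopifnot(hit$class == "G4", n_mut_per_run >= 1L)
  x <- strsplit(insert, NULL)[[1]]
  span <- seq.int(hit$start + 1L, hit$end)
  isG <- x[span] == "G"
  r <- rle(isG)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  run_pos <- lapply(runs, function(q) span[starts[q]:ends[q]])
  n_runs <- length(run_pos)
  k <- if (identical(runs_targeted, "all")) n_runs else as.integer(runs_targeted)
  stopifnot(k >= 1L, k <= n_runs)
  with_seed(seed, {
    for (attempt in seq_len(max_retry)) {
      target <- if (k == n_runs) seq_len(n_runs) else sort(sample_int(n_runs, k))
      y <- x
      for (q in target) {
        pos <- run_pos[[q]]
        if (length(pos) < n_mut_per_run) {
          stopf("G-run of length %d cannot take %d mutations",
                length(pos), n_mut_per_run)
        }
        mut <- if (length(pos) == 1L) pos else
          sample(pos, n_mut_per_run)
        y[mut] <- sub_base
      }
      edited <- paste(y, collapse = "")
      if (k < n_runs) return(edited)
      gh <- scan_g4(c(e = edited), cfg)
      clear <- if (scope == "insert") nrow(gh) == 0L else
        !any(gh$start < hit$end & gh$end > hit$start)
      if (clear) return(edited)
    }
    stopf("disrupt_g4: no G4-free edit found in %d attempts", max_retry)
  })
}

#' Scramble a Z-DNA tract
#'
#' Uniformly permutes the tract bases (exact composition preserved),
#' redrawing until no Z-DNA hit of at least `z_min_len` bp overlaps the
#' edited window; bases outside the tract are untouched.
#'
#' @param insert Insert sequence.
#' @param hit One-row Z hit `data.frame` from [scan_zdna()].
#' @param seed RNG seed.
#' @param cfg A [scan_config()].
#' @param max_retry Redraw cap.
#' @return Edited insert string.
#' @export
scramble_zdna <- function(insert, hit, seed = 1L, cfg = scan_config(),
                          max_retry = 100L) {
  stopifnot(hit$class == "Z")
  tract <- strsplit(substr(insert, hit$start + 1L, hit$end), NULL)[[1]]
  with_seed(seed, {
    for (attempt in seq_len(max_retry)) {
      perm <- sample(tract)
      edited <- replace_window(insert, hit$start, paste(perm, collapse = ""))
      z <- scan_zdna(c(e = edited), cfg)
      if (nrow(z) == 0L ||
          !any(z$start < hit$end & z$end > hit$start)) {
        return(edited)
      }
    }
    stopf("scramble_zdna: no alternation-free permutation found in %d attempts",
          max_retry)
  })
}

#' Disrupt a Z-DNA tract by purine-to-pyrimidine substitution
#'
#' Replaces `n_sites` uniformly chosen purines within the tract using the
#' transversion map A->C, G->T (which breaks alternation without creating
#' G-runs). The attribute `residual_tract` records the longest alternating
#' run remaining in the edited window.
#'
#' @inheritParams scramble_zdna
#' @param n_sites Number of purines to substitute (0 is the identity).
#' @return Edited insert string with attribute `residual_tract`.
#' @export
purine_to_pyrimidine_disrupt <- function(insert, hit, n_sites, seed = 1L,
                                         cfg = scan_config()) {
  stopifnot(hit$class == "Z", n_sites >= 0L)
  x <- strsplit(insert, NULL)[[1]]
  span <- seq.int(hit$start + 1L, hit$end)
  pur <- span[x[span] %in% c("A", "G")]
  if (n_sites > length(pur)) {
    stopf("tract has %d purines, cannot substitute %d", length(pur), n_sites)
  }
  edited <- with_seed(seed, {
    sel <- if (n_sites == 0L) integer(0) else
      if (length(pur) == 1L) pur else sample(pur, n_sites)
    x[sel] <- chartr("AG", "CT", x[sel])
    paste(x, collapse = "")
  })
  z <- scan_zdna(c(e = edited), scan_config(z_min_len = 2L))
  win <- z[z$start < hit$end & z$end > hit$start, , drop = FALSE]
  attr(edited, "residual_tract") <-
    if (nrow(win)) max(win$end - win$start) else 1L
  edited
}

# build a synthetic motif sequence of the requested class/parameters;
# returns list(seq, left_class, right_class) for boundary bookkeeping
build_motif_seq <- function(class, params, cfg) {
  switch(class,
    Z = {
      L <- params$length
      phase <- params$phase %||% sample(0:1, 1L)
      cls <- rep(c(0L, 1L), length.out = L)
      if (phase == 1L) cls <- 1L - cls
      bases <- ifelse(cls == 0L, sample(c("A", "G"), L, replace = TRUE),
                      sample(c("C", "T"), L, replace = TRUE))
      paste(bases, collapse = "")
    },
    G4 = {
      loops <- params$loops %||% rep(1L, (params$n_runs %||% cfg$g4_min_runs) - 1L)
      run_len <- params$run_len %||% cfg$g_run_min
      n_runs <- length(loops) + 1L
      parts <- character(0)
      for (i in seq_len(n_runs)) {
        parts <- c(parts, strrep("G", run_len))
        if (i < n_runs) {
          parts <- c(parts, paste(sample(c("A", "C", "T"), loops[i],
                                         replace = TRUE), collapse = ""))
        }
      }
      paste(parts, collapse = "")
    },
    IR = , MR = , DR = {
      arm <- params$arm %||% cfg$rep_arm_len
      sp <- params$spacer %||% 0L
      arm1 <- paste(sample(c("A", "C", "G", "T"), arm, replace = TRUE),
                    collapse = "")
      arm2 <- switch(class, IR = reverse_complement(arm1),
                     MR = paste(rev(strsplit(arm1, NULL)[[1]]), collapse = ""),
                     DR = arm1)
      spacer <- if (sp > 0L) paste(sample(c("A", "C", "G", "T"), sp,
                                          replace = TRUE), collapse = "") else ""
      paste0(arm1, spacer, arm2)
    },
    stopf("cannot build motif of class %s", class))
}

# does the edited insert show the intended hit exactly, and no hit of another
# class fully inside the window?
validate_introduction <- function(edited, class, start0, len, params, cfg) {
  all_hits <- scan_all(setNames(edited, "e"), cfg, both_strands = TRUE)
  inside <- all_hits[all_hits$start >= start0 & all_hits$end <= start0 + len &
                       all_hits$class != class, , drop = FALSE]
  if (nrow(inside) > 0L) return(FALSE)
  own <- all_hits[all_hits$class == class & all_hits$start == start0 &
                    all_hits$end == start0 + len, , drop = FALSE]
  if (nrow(own) == 0L) return(FALSE)
  if (class == "G4" && !is.null(params$loops)) {
    # a flipped motif is scanned on the minus strand, where it reads in its
    # built orientation, so the loop order is unchanged
    want <- paste(params$loops, collapse = ",")
    if (!any(own$loops == want, na.rm = TRUE)) return(FALSE)
  }
  if (class %in% c("IR", "MR", "DR") && !is.null(params$arm)) {
    if (!any(own$arm == params$arm & own$spacer == (params$spacer %||% 0L),
             na.rm = TRUE)) return(FALSE)
  }
  TRUE
}

#' Introduce a synthetic non-B DNA motif into an insert
#'
#' Builds a motif to exact parameters (Z tract of a given length; G4 with a
#' given run count and loop-length vector; IR/DR/MR with given arm and
#' spacer), replaces the same-length window at `position`, and rescans to
#' confirm the intended hit with the intended substructure and no motif of
#' another class inside the window, redrawing the random components up to
#' `max_retry` times. When the flank would extend the motif past the intended
#' footprint (a base continuing a terminal G4 run or a Z alternation, or a
#' full flanking G-run within loop range that would chain into the consensus
#' match), the offending flank bases are also substituted.
#'
#' @param insert Insert sequence.
#' @param class Motif class: "Z", "G4", "IR", "MR", "DR".
#' @param params List of parameters: `length` (Z), `loops`/`run_len`/`n_runs`
#'   (G4), `arm`/`spacer` (repeats), optional `orientation_flip` (G4: insert
#'   the reverse complement).
#' @param position 0-based start of the replaced window.
#' @param seed RNG seed.
#' @param cfg A [scan_config()].
#' @param max_retry Redraw cap.
#' @return Edited insert string (attribute `footprint` = c(start, end)).
#' @export
introduce_motif <- function(insert, class, params = list(), position,
                            seed = 1L, cfg = scan_config(),
                            max_retry = 100L) {
  with_seed(seed, {
    for (attempt in seq_len(max_retry)) {
      motif <- build_motif_seq(class, params, cfg)
      if (class == "G4" && isTRUE(params$orientation_flip)) {
        motif <- reverse_complement(motif)
      }
      len <- nchar(motif)
      if (position + len > nchar(insert)) {
        stopf("motif of %d bp does not fit at position %d", len, position)
      }
      edited <- replace_window(insert, position, motif)
      edited <- fix_boundaries(edited, class, position, len, motif, cfg)
      if (validate_introduction(edited, class, position, len, params, cfg)) {
        attr(edited, "footprint") <- c(position, position + len)
        return(edited)
      }
    }
    stopf("introduce_motif: constraints not satisfied in %d attempts",
          max_retry)
  })
}

# substitute the single base adjacent to the window when it would extend the
# introduced motif beyond its intended footprint
fix_boundaries <- function(edited, class, start0, len, motif,
                           cfg = scan_config()) {
  x <- strsplit(edited, NULL)[[1]]
  n <- length(x)
  l <- start0            # 1-based index of left flank base
  r <- start0 + len + 1L # 1-based index of right flank base
  base_class <- function(b) if (b %in% c("A", "G")) 0L else
    if (b %in% c("C", "T")) 1L else NA_integer_
  if (class %in% c("G4", "Z")) {
    mb <- strsplit(motif, NULL)[[1]]
    if (class == "G4") {
      # a boundary base equal to the motif's terminal base would extend the
      # terminal run (G-run, or C-run for a flipped motif); a full run of
      # that base within loop range of the window would chain into the
      # consensus match and shift the reported span, so such runs in the
      # flanking quarantine region are broken as well
      run_min <- cfg$g_run_min
      loop_max <- cfg$g4_loop_max
      # replacement bases are drawn at random (never the run base, never the
      # complementary-run base) so retries explore different flank repairs
      repl_for <- function(b) sample(setdiff(c("A", "T"), b), 1L)
      break_runs <- function(x, idx, b) {
        # idx ordered from the outer edge toward the window
        cnt <- 0L
        for (i in idx) {
          if (x[i] == b) {
            cnt <- cnt + 1L
            if (cnt == run_min) { x[i] <- repl_for(b); cnt <- 0L }
          } else cnt <- 0L
        }
        x
      }
      reach <- loop_max + run_min
      if (mb[1] %in% c("G", "C")) {
        if (l >= 1L && x[l] == mb[1]) x[l] <- repl_for(mb[1])
        if (l >= 1L) {
          x <- break_runs(x, seq.int(max(1L, l - reach + 1L), l), mb[1])
        }
      }
      if (mb[len] %in% c("G", "C")) {
        if (r <= n && x[r] == mb[len]) x[r] <- repl_for(mb[len])
        if (r <= n) {
          x <- break_runs(x, rev(seq.int(r, min(n, r + reach - 1L))),
                          mb[len])
        }
      }
    } else {
      same_class <- function(cls) {
        if (cls == 0L) sample(c("A", "G"), 1L) else sample(c("C", "T"), 1L)
      }
      if (l >= 1L && !is.na(base_class(x[l])) &&
          base_class(x[l]) != base_class(mb[1])) {
        x[l] <- same_class(base_class(mb[1]))
      }
      if (r <= n && !is.na(base_class(x[r])) &&
          base_class(x[r]) != base_class(mb[len])) {
        x[r] <- same_class(base_class(mb[len]))
      }
    }
  }
  paste(x, collapse = "")
}

#' Remove a motif by randomizing its footprint
#'
#' Replaces the hit footprint with random bases until no motif of the hit's
#' class overlaps the window.
#'
#' @param insert Insert sequence.
#' @param hit One-row motif hit `data.frame`.
#' @param seed RNG seed.
#' @param cfg A [scan_config()].
#' @param max_retry Redraw cap.
#' @return Edited insert string.
#' @export
remove_motif <- function(insert, hit, seed = 1L, cfg = scan_config(),
                         max_retry = 100L) {
  len <- hit$end - hit$start
  scan_fun <- switch(hit$class,
                     G4 = function(s) scan_g4(s, cfg, both_strands = TRUE),
                     Z = function(s) scan_zdna(s, cfg),
                     IR = function(s) scan_inverted_repeats(s, cfg),
                     MR = function(s) scan_mirror_repeats(s, cfg),
                     DR = function(s) scan_direct_repeats(s, cfg),
                     STR = function(s) scan_strs(s, cfg),
                     H = function(s) scan_hdna(s, cfg))
  with_seed(seed, {
    for (attempt in seq_len(max_retry)) {
      filler <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                      collapse = "")
      edited <- replace_window(insert, hit$start, filler)
      hh <- scan_fun(c(e = edited))
      if (nrow(hh) == 0L || !any(hh$start < hit$end & hh$end > hit$start)) {
        return(edited)
      }
    }
    stopf("remove_motif: class %s persists after %d attempts", hit$class,
          max_retry)
  })
}

apply_perturbation <- function(insert, spec, cfg, seed) {
  first_hit <- function(class) {
    h <- switch(class,
                G4 = scan_g4(c(i = insert), cfg),
                Z = scan_zdna(c(i = insert), cfg),
                IR = scan_inverted_repeats(c(i = insert), cfg),
                MR = scan_mirror_repeats(c(i = insert), cfg),
                DR = scan_direct_repeats(c(i = insert), cfg),
                STR = scan_strs(c(i = insert), cfg),
                H = scan_hdna(c(i = insert), cfg))
    if (nrow(h) == 0L) stopf("insert has no %s hit to perturb", class)
    h[1L, ]
  }
  num <- function(v) if (is.null(v) || is.na(v)) NULL else v
  loops <- if (!is.null(spec$loops) && !is.na(spec$loops)) {
    as.integer(strsplit(as.character(spec$loops), ",")[[1]])
  } else NULL
  pos <- num(spec$position) %||% 50L
  runs_val <- if (is.null(spec$runs) || is.na(spec$runs)) "all"
              else as.character(spec$runs)
  # library disruptions must clear every hit of the class (random promoter
  # fragments often carry spontaneous tracts beyond the targeted one)
  disrupt_all <- function(cur, class, op) {
    for (round in 1:25) {
      h <- switch(class,
                  G4 = scan_g4(c(i = cur), cfg),
                  Z = scan_zdna(c(i = cur), cfg))
      if (nrow(h) == 0L) return(cur)
      cur <- op(cur, h[1L, ], round)
    }
    stopf("could not clear all %s hits", class)
  }
  switch(as.character(spec$kind),
    g_run_mutation = {
      if (identical(runs_val, "all")) {
        disrupt_all(insert, "G4", function(cur, h, round) {
          disrupt_g4(cur, h, n_mut_per_run = num(spec$n_mut) %||% 1L,
                     runs_targeted = "all", seed = seed + round, cfg = cfg,
                     scope = "window")
        })
      } else {
        disrupt_g4(insert, first_hit("G4"),
                   n_mut_per_run = num(spec$n_mut) %||% 1L,
                   runs_targeted = runs_val, seed = seed, cfg = cfg)
      }
    },
    z_scramble = disrupt_all(insert, "Z", function(cur, h, round) {
      scramble_zdna(cur, h, seed = seed + round, cfg = cfg)
    }),
    z_purine_to_pyrimidine = as.character(
      purine_to_pyrimidine_disrupt(insert, first_hit("Z"),
                                   n_sites = num(spec$n_sites) %||% 3L,
                                   seed = seed, cfg = cfg)),
    z_length = introduce_motif(insert, "Z", list(length = num(spec$length)),
                               pos, seed = seed, cfg = cfg),
    g4_loop_length = introduce_motif(insert, "G4", list(loops = loops),
                                     pos, seed = seed, cfg = cfg),
    g4_orientation_flip = introduce_motif(insert, "G4",
                                          list(loops = loops,
                                               orientation_flip = TRUE),
                                          pos, seed = seed, cfg = cfg),
    arm_length = , spacer_length = , motif_insertion = {
      cfg_i <- cfg
      if (!is.null(num(spec$arm))) {
        cfg_i$rep_arm_len <- as.integer(spec$arm)
        cfg_i$rep_max_spacer <- max(cfg$rep_max_spacer,
                                    num(spec$spacer) %||% 0L)
      }
      introduce_motif(insert, as.character(spec$class),
                      list(arm = num(spec$arm), spacer = num(spec$spacer),
                           length = num(spec$length), loops = loops),
                      pos, seed = seed, cfg = cfg_i)
    },
    motif_removal = remove_motif(insert, first_hit(as.character(spec$class)),
                                 seed = seed, cfg = cfg),
    stopf("unknown edit kind '%s'", spec$kind))
}

#' Assemble a perturbation MPRA oligo library
#'
#' For every grid row, applies the requested edit to its insert and emits a
#' 230-mer oligo (15 bp primer + 200 bp insert + 15 bp primer), plus one
#' unedited oligo per insert. Every oligo is re-validated: exact length,
#' rescan of intended motif presence/absence, and absence of the SbfI
#' (CCTGCAGG) and AgeI (ACCGGT) sites used for cloning (edits touching a site
#' are redrawn with a perturbed seed). Duplicate oligo sequences are removed
#' with a cross-reference log.
#'
#' @param inserts Named character vector of 200 bp inserts.
#' @param grid `data.frame` of perturbation specs: columns insert, kind, and
#'   any of class, n_mut, runs, n_sites, length, loops, arm, spacer,
#'   position.
#' @param primer5,primer3 15 bp primer sequences.
#' @param cfg A [scan_config()].
#' @param seed RNG seed.
#' @param max_retry Redraw cap for the restriction-site constraint.
#' @return `list` of class `oligo_library`: `oligos` (oligo_id, insert, kind,
#'   class, sequence of length 230, insert_seq), `design` (oligo x motif
#'   presence-flag matrix from rescanning), and `duplicates` (dropped
#'   oligo_id -> kept oligo_id map).
#' @export
build_library <- function(inserts, grid, primer5, primer3,
                          cfg = scan_config(), seed = 1L, max_retry = 25L) {
  stopifnot(nchar(primer5) == 15L, nchar(primer3) == 15L,
            all(nchar(inserts) == 200L))
  sites <- c("CCTGCAGG", "ACCGGT")
  has_site <- function(s) any(vapply(sites, function(p) grepl(p, s, fixed = TRUE),
                                     logical(1)))
  bad_orig <- vapply(names(inserts), function(id) {
    has_site(paste0(primer5, inserts[[id]], primer3))
  }, logical(1))
  if (any(bad_orig)) {
    stopf("SbfI/AgeI site in unedited insert(s) %s: redesign these inserts",
          paste(names(inserts)[bad_orig], collapse = ", "))
  }
  rows <- list()
  for (id in names(inserts)) {
    rows[[length(rows) + 1L]] <- data.frame(
      oligo_id = paste0(id, "_original"), insert = id, kind = "original",
      class = NA_character_, insert_seq = inserts[[id]],
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(grid))) {
    spec <- grid[i, ]
    iid <- as.character(spec$insert)
    if (!iid %in% names(inserts)) {
      stopf("grid row %d: unknown insert '%s'", i, iid)
    }
    base <- inserts[[iid]]
    edited <- NULL
    for (attempt in seq_len(max_retry)) {
      cand <- apply_perturbation(base, spec, cfg,
                                 seed = seed + i * 1000L + attempt)
      if (!has_site(paste0(primer5, cand, primer3))) { edited <- cand; break }
    }
    if (is.null(edited)) {
      stopf("grid row %d: could not avoid restriction sites", i)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      oligo_id = paste0(spec$insert, "_", spec$kind, "_", i),
      insert = spec$insert, kind = as.character(spec$kind),
      class = if ("class" %in% names(spec)) as.character(spec$class)
              else NA_character_,
      insert_seq = as.character(edited), stringsAsFactors = FALSE)
  }
  oligos <- do.call(rbind, rows)
  oligos$sequence <- paste0(primer5, oligos$insert_seq, primer3)
  stopifnot(all(nchar(oligos$sequence) == 230L))
  bad <- vapply(oligos$sequence, has_site, logical(1))
  if (any(bad)) stopf("restriction site present in original insert(s): %s",
                      paste(oligos$oligo_id[bad], collapse = ", "))
  dup <- duplicated(oligos$sequence)
  duplicates <- NULL
  if (any(dup)) {
    keep_id <- oligos$oligo_id[match(oligos$sequence[dup], oligos$sequence)]
    duplicates <- data.frame(dropped = oligos$oligo_id[dup], kept = keep_id,
                             stringsAsFactors = FALSE)
    message("build_library: removed ", sum(dup), " duplicate oligo(s)")
    oligos <- oligos[!dup, , drop = FALSE]
  }
  cfg_merged <- cfg
  cfg_merged$report_mode <- "merged"
  hits <- scan_all(setNames(oligos$insert_seq, oligos$oligo_id),
                   cfg_merged, both_strands = TRUE)
  design <- presence_flags(hits, seq_ids = oligos$oligo_id)
  rownames(oligos) <- NULL
  structure(list(oligos = oligos, design = design, duplicates = duplicates),
            class = "oligo_library")
}

#' @export
print.oligo_library <- function(x, ...) {
  cat(sprintf("oligo library: %d oligos (230-mers), %d duplicates removed\n",
              nrow(x$oligos),
              if (is.null(x$duplicates)) 0L else nrow(x$duplicates)))
  invisible(x)
}
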