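# Independent brute-force oracles used to validate the scanners and
# statistical kernels. Deliberately written with naive loops and substr()
# so they share no code path with the package implementations.

rand_seq <- function(n, probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

splice <- function(s, pos0, repl) {
  paste0(substr(s, 1, pos0), repl, substr(s, pos0 + nchar(repl) + 1, nchar(s)))
}

rc_chr <- function(ch) chartr("ACGTN", "TGCAN", ch)

# greedy non-overlapping matches of the G4 consensus by a generic regex engine
oracle_g4_spans <- function(s, engine = c("pcre", "tre")) {
  engine <- match.arg(engine)
  pat <- "([gG]{3,}\\w{1,7}){3,}[gG]{3,}"
  m <- if (engine == "pcre") gregexpr(pat, s, perl = TRUE)[[1]]
       else gregexpr(pat, s)[[1]]
  if (m[1] == -1) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  data.frame(start = as.integer(m) - 1L,
             end = as.integer(m) + attr(m, "match.length") - 1L)
}

# maximal alternating purine/pyrimidine tracts by direct walking
oracle_zdna <- function(s, min_len = 10L) {
  x <- strsplit(s, NULL)[[1]]
  ry <- function(b) if (b %in% c("A", "G")) "R" else
    if (b %in% c("C", "T")) "Y" else NA_character_
  n <- length(x)
  res <- data.frame(start = integer(0), end = integer(0))
  i <- 1L
  while (i <= n) {
    if (is.na(ry(x[i]))) { i <- i + 1L; next }
    j <- i
    while (j < n && !is.na(ry(x[j + 1L])) && ry(x[j + 1L]) != ry(x[j])) {
      j <- j + 1L
    }
    if (j - i + 1L >= min_len) {
      res <- rbind(res, data.frame(start = i - 1L, end = j))
    }
    i <- j + 1L
  }
  res
}

# every (start, spacer) placement of a fixed-arm IR/MR/DR by substring tests
oracle_repeat <- function(s, type, arm, max_spacer, purity = NULL) {
  n <- nchar(s)
  res <- data.frame(start = integer(0), end = integer(0),
                    arm = integer(0), spacer = integer(0))
  for (i in seq_len(n)) {
    for (sp in 0:max_spacer) {
      w <- 2L * arm + sp
      if (i + w - 1L > n) next
      foot <- substr(s, i, i + w - 1L)
      if (grepl("N", foot)) next
      a1 <- substr(foot, 1L, arm)
      a2 <- substr(foot, arm + sp + 1L, w)
      want <- switch(type,
                     IR = paste(rev(strsplit(rc_chr(a1), NULL)[[1]]),
                                collapse = ""),
                     MR = paste(rev(strsplit(a1, NULL)[[1]]), collapse = ""),
                     DR = a1)
      if (a2 != want) next
      if (type == "DR" && !is.null(purity) &&
          oracle_arm_str_cover(a1) >= purity) next
      res <- rbind(res, data.frame(start = i - 1L, end = i - 1L + w,
                                   arm = arm, spacer = sp))
    }
  }
  res
}

# largest fraction of an arm covered by >= 2 tandem copies of a unit of
# length <= floor(arm/2): direct enumeration of (unit length, start, end)
oracle_arm_str_cover <- function(armstr) {
  a <- nchar(armstr)
  best <- 0
  for (u in seq_len(a %/% 2)) {
    for (i in seq_len(a)) {
      if (i + 2L * u - 1L > a) next
      for (j in (i + 2L * u - 1L):a) {
        w <- substr(armstr, i, j)
        unit <- substr(w, 1L, u)
        reps <- strrep(unit, ceiling(nchar(w) / u))
        if (substr(reps, 1L, nchar(w)) == w) {
          best <- max(best, nchar(w) / a)
        }
      }
    }
  }
  best
}

oracle_rotations_min <- function(unit) {
  u <- nchar(unit)
  doubled <- paste0(unit, unit)
  min(vapply(seq_len(u), function(i) substr(doubled, i, i + u - 1L),
             character(1)))
}

# maximal perfect tandem arrays by walking every (start, unit length)
oracle_str <- function(s, unit_min = 1L, unit_max = 6L, min_total = 10L,
                       min_copies = 3L) {
  x <- strsplit(s, NULL)[[1]]
  n <- length(x)
  res <- data.frame(start = integer(0), end = integer(0),
                    unit = character(0), copies = integer(0))
  for (u in unit_min:unit_max) {
    for (i in seq_len(n)) {
      if (i > 1L && i + u - 1L <= n && x[i - 1L] == x[i + u - 1L] &&
          x[i - 1L] != "N") next   # not maximal on the left
      j <- i + u - 1L
      if (j > n) next
      if (any(x[i:j] == "N")) next
      while (j < n && x[j + 1L] == x[j + 1L - u] && x[j + 1L] != "N") {
        j <- j + 1L
      }
      len <- j - i + 1L
      if (len < max(min_total, u + 1L) || len %/% u < min_copies) next
      arr <- paste(x[i:j], collapse = "")
      # primitive unit: no shorter period covers the array
      prim <- TRUE
      for (p in seq_len(u - 1L)) {
        reps <- strrep(substr(arr, 1L, p), ceiling(len / p))
        if (substr(reps, 1L, len) == arr) { prim <- FALSE; break }
      }
      if (!prim) next
      res <- rbind(res, data.frame(start = i - 1L, end = j,
                                   unit = oracle_rotations_min(
                                     substr(arr, 1L, u)),
                                   copies = len %/% u))
    }
  }
  unique(res)
}

oracle_hdna <- function(s, arm = 10L, max_spacer = 7L, min_frac = 0.90) {
  mr <- oracle_repeat(s, "MR", arm, max_spacer)
  if (nrow(mr) == 0L) return(mr)
  keep <- logical(nrow(mr))
  frac <- numeric(nrow(mr))
  for (i in seq_len(nrow(mr))) {
    foot <- strsplit(substr(s, mr$start[i] + 1L, mr$end[i]), NULL)[[1]]
    f <- max(sum(foot %in% c("A", "G")), sum(foot %in% c("T", "C"))) /
      length(foot)
    keep[i] <- f > min_frac
    frac[i] <- f
  }
  mr$ag_frac <- frac
  mr[keep, , drop = FALSE]
}

# all-pairs signed nearest distance with the package's documented convention
oracle_nearest <- function(chrom, pos, subject) {
  out <- rep(NA_real_, length(pos))
  for (q in seq_along(pos)) {
    sub <- subject[subject$chrom == chrom[q], , drop = FALSE]
    if (nrow(sub) == 0L) next
    best <- NA_real_; best_abs <- Inf
    for (j in seq_len(nrow(sub))) {
      p <- pos[q]
      d <- if (p >= sub$start[j] && p < sub$end[j]) 0
           else if (p < sub$start[j]) -(sub$start[j] - p)
           else p - sub$end[j] + 1
      if (abs(d) < best_abs ||
          (abs(d) == best_abs && d > 0 && !is.na(best) && best < 0)) {
        best <- d; best_abs <- abs(d)
      }
    }
    out[q] <- best
  }
  out
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
enum_mwu <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x); N <- length(pooled)
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_of(x, y)
  combs <- utils::combn(N, n)
  us <- apply(combs, 2L, function(idx) u_of(pooled[idx], pooled[-idx]))
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  list(u = u_obs, p = min(1, p))
}

# Kruskal-Wallis H by the rank formula with tie correction
kw_formula <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(z) sum(z)^2 / length(z))) - 3 * (N + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

pearson_formula <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# simple planted motif builders (independent of the package generators)
plant_g4 <- function(runs = 4L, loop = 1L) {
  paste0(paste(rep(paste0(strrep("G", 3L),
                          strrep("A", loop)), runs - 1L), collapse = ""),
         strrep("G", 3L))
}

plant_z <- function(len = 12L) {
  paste(rep_len(c("G", "C"), len), collapse = "")
}

sort_hits <- function(df) {
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}
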