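#' Scan sequences with position weight matrices
#'
#' Scores every position and strand with the log-odds (base 2) of the PFM
#' against a background base distribution, and converts scores to p-values by
#' exact dynamic programming over the integer-rescaled score distribution
#' under the background (the FIMO core). Positions with p-value below
#' `p_threshold` are reported.
#'
#' @param seqs Named character vector of sequences.
#' @param pfms List of PFM records from [read_pfm()].
#' @param background Base probability vector named A, C, G, T (default: the
#'   uniform distribution).
#' @param p_threshold Report hits with p < this value.
#' @param granularity Score rescaling resolution for the exact p-value DP
#'   (scores are rounded to multiples of this; the induced p-value error is
#'   bounded by the probability mass within one granule of the threshold
#'   score).
#' @param both_strands Scan the reverse complement too?
#' @return `data.frame`: seq_id, tf, start, end (0-based half-open, forward
#'   axis), strand, score (log2 odds), p.
#' @export
pwm_scan <- function(seqs, pfms, background = c(A = 0.25, C = 0.25,
                                                G = 0.25, T = 0.25),
                     p_threshold = 1e-6, granularity = 1e-3,
                     both_strands = TRUE) {
  stopifnot(all(c("A", "C", "G", "T") %in% names(background)))
  bg <- background[c("A", "C", "G", "T")] / sum(background)
  out <- list()
  for (pfm in pfms) {
    mat <- pmax(pfm$matrix, 1e-10)  # guard zero cells of un-pseudocounted PFMs
    L <- ncol(mat)
    lo <- log2(sweep(mat, 1L, bg, "/"))
    sc_int <- round(lo / granularity)
    pv <- pwm_score_pvalues(sc_int, bg)
    for (k in seq_along(seqs)) {
      s <- seqs[[k]]
      id <- names(seqs)[k] %||% as.character(k)
      n <- nchar(s)
      if (L > n) next
      strands <- if (both_strands) c("+", "-") else "+"
      for (strand in strands) {
        ss <- if (strand == "+") s else reverse_complement(s)
        x <- strsplit(ss, NULL)[[1]]
        xi <- match(x, c("A", "C", "G", "T"))  # NA for N
        npos <- n - L + 1L
        tot <- rep(0, npos)
        ok <- rep(TRUE, npos)
        for (j in seq_len(L)) {
          b <- xi[j:(j + npos - 1L)]
          ok <- ok & !is.na(b)
          tot <- tot + ifelse(is.na(b), 0, sc_int[cbind(b, j)])
        }
        p <- pv$lookup(tot)
        hit <- which(ok & p < p_threshold)
        if (length(hit)) {
          st <- if (strand == "+") hit - 1L else n - (hit - 1L) - L
          out[[length(out) + 1L]] <- data.frame(
            seq_id = id, tf = pfm$id, start = st, end = st + L,
            strand = strand, score = tot[hit] * granularity, p = p[hit],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(seq_id = character(0), tf = character(0), start = integer(0),
               end = integer(0), strand = character(0), score = numeric(0),
               p = numeric(0))
  res <- res[order(res$seq_id, res$tf, res$start, res$strand), ]
  rownames(res) <- NULL
  res
}

# Exact distribution of the integer-rescaled log-odds score of a random
# background word, by column-wise convolution; returns a tail-probability
# lookup P(S >= s).
pwm_score_pvalues <- function(sc_int, bg) {
  L <- ncol(sc_int)
  lo_min <- sum(apply(sc_int, 2L, min))
  lo_max <- sum(apply(sc_int, 2L, max))
  width <- as.integer(lo_max - lo_min + 1L)
  dist <- numeric(width)
  # probabilities over offsets s - cum_min
  dist[1L] <- 1
  cum_min <- 0
  for (j in seq_len(L)) {
    col <- sc_int[, j]
    cmin <- min(col)
    newd <- numeric(width)
    for (b in 1:4) {
      off <- as.integer(col[b] - cmin)
      idx <- which(dist > 0)
      newd[idx + off] <- newd[idx + off] + dist[idx] * bg[b]
    }
    dist <- newd
    cum_min <- cum_min + cmin
  }
  tail_p <- rev(cumsum(rev(dist)))
  list(
    support_min = cum_min,
    dist = dist,
    lookup = function(s) {
      i <- as.integer(s - cum_min) + 1L
      i <- pmax(i, 1L)
      ifelse(i > length(tail_p), 0, tail_p[i])
    })
}
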