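#' Read a FASTA file
#'
#' Sequences are uppercased on read and restricted to the A/C/G/T/N alphabet.
#' Record ids are the first whitespace-delimited token of each header line.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names are record ids), in file
#'   order. An empty file gives an empty vector.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) return(setNames(character(0), character(0)))
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stopf("duplicate FASTA ids: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stopf("illegal characters in FASTA record(s): %s",
          paste(ids[bad], collapse = ", "))
  }
  setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of A/C/G/T/N sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse complement of DNA sequences
#'
#' Vectorized; N maps to N. `reverse_complement(reverse_complement(x))` is the
#' identity.
#'
#' @param x Character vector over the alphabet A/C/G/T/N.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  if (length(x) == 0L) return(character(0))
  if (any(grepl("[^ACGTN]", x))) stopf("illegal character in sequence")
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, NULL),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' GC fraction of sequences
#'
#' @param x Character vector of sequences. N bases are excluded from both the
#'   numerator and the denominator.
#' @return Numeric vector in \[0, 1\]; `NA` for sequences with no unambiguous
#'   base.
#' @export
gc_fraction <- function(x) {
  n_gc <- nchar(gsub("[^GC]", "", x))
  n_at <- nchar(gsub("[^AT]", "", x))
  tot <- n_gc + n_at
  ifelse(tot == 0L, NA_real_, n_gc / tot)
}

#' Construct a genomic interval table
#'
#' Intervals are 0-based half-open on the forward axis throughout the package;
#' minus-strand features still carry forward-axis coordinates.
#'
#' @param chrom Character chromosome names.
#' @param start,end Integer 0-based half-open coordinates, `0 <= start < end`.
#' @param strand One of "+", "-", "." (recycled).
#' @param name Feature names (recycled).
#' @param score Optional numeric scores.
#' @return A `data.frame` with columns chrom, start, end, name, score, strand.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".", name = ".",
                              score = 0) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   name = as.character(name), score = as.numeric(score),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$start < 0L) || any(df$start >= df$end)) {
    stopf("invalid interval: require 0 <= start < end")
  }
  if ("strand" %in% names(df) && !all(df$strand %in% c("+", "-", "."))) {
    stopf("strand must be one of '+', '-', '.'")
  }
  invisible(df)
}

#' Read a BED file
#'
#' BED3/BED6 plus any extra columns; coordinates are kept 0-based half-open.
#'
#' @param path Path to a tab-delimited BED file (no header, or a header line
#'   starting with `#` which is skipped).
#' @return Interval `data.frame` (see [genomic_intervals()]); extra columns are
#'   appended verbatim.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE, quote = "")
  if (nrow(df) == 0L) return(genomic_intervals(character(0), integer(0), integer(0)))
  base_names <- c("chrom", "start", "end", "name", "score", "strand")
  n <- min(ncol(df), 6L)
  names(df)[seq_len(n)] <- base_names[seq_len(n)]
  if (!"name" %in% names(df)) df$name <- "."
  if (!"score" %in% names(df)) df$score <- 0
  if (!"strand" %in% names(df)) df$strand <- "."
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  validate_intervals(df)
  df
}

#' Write intervals as BED
#'
#' @param df Interval `data.frame`.
#' @param path Output path.
#' @param extra Character vector of extra column names to append after BED6.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path, extra = character(0)) {
  validate_intervals(df)
  out <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                    name = if ("name" %in% names(df)) df$name else ".",
                    score = if ("score" %in% names(df)) df$score else 0,
                    strand = if ("strand" %in% names(df)) df$strand else ".")
  for (cn in extra) out[[cn]] <- df[[cn]]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge overlapping intervals into their union
#'
#' @param df Interval `data.frame`.
#' @param by_strand Merge within strand levels instead of ignoring strand.
#' @return Interval `data.frame` of disjoint, sorted union intervals.
#' @export
merge_intervals <- function(df, by_strand = FALSE) {
  validate_intervals(df)
  if (nrow(df) == 0L) return(df[, c("chrom", "start", "end")])
  keyf <- if (by_strand) paste(df$chrom, df$strand) else df$chrom
  pieces <- lapply(split(seq_len(nrow(df)), keyf), function(idx) {
    d <- df[idx, ]
    o <- order(d$start, d$end)
    s <- d$start[o]; e <- d$end[o]
    grp <- cumsum(c(1L, as.integer(s[-1] > cummax(e)[-length(e)])))
    data.frame(chrom = d$chrom[1],
               start = as.integer(tapply(s, grp, min)),
               end = as.integer(tapply(e, grp, max)),
               strand = if (by_strand) d$strand[1] else ".",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Internal: per-chromosome sorted disjoint interval lookup structure.
interval_index <- function(df) {
  m <- merge_intervals(df)
  split(m[, c("start", "end")], m$chrom)
}

# Does each point (chrom, pos) fall inside any (merged) subject interval?
point_in_index <- function(chrom, pos, index) {
  out <- logical(length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    tab <- index[[ch]]
    if (is.null(tab) || nrow(tab) == 0L) next
    i <- findInterval(pos[sel], tab$start)
    out[sel] <- i >= 1L & pos[sel] < tab$end[pmax(i, 1L)]
  }
  out
}

#' Test overlap of intervals or points with a subject interval set
#'
#' @param chrom,start,end Query footprints (0-based half-open); a point is a
#'   width-1 footprint.
#' @param subject Subject interval `data.frame` (merged internally).
#' @return Logical vector: does each query overlap any subject interval?
#' @export
overlaps_any <- function(chrom, start, end, subject) {
  idx <- interval_index(subject)
  out <- logical(length(start))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    tab <- idx[[ch]]
    if (is.null(tab) || nrow(tab) == 0L) next
    # subjects are merged and disjoint, so the query [s, e) overlaps some
    # subject iff the last subject starting before e extends past s
    i <- findInterval(end[sel] - 1L, tab$start)
    out[sel] <- i >= 1L & tab$end[pmax(i, 1L)] > start[sel]
  }
  out
}

#' Signed distance from query points to the nearest subject interval
#'
#' Zero when the query falls inside a subject interval. Otherwise the gap in
#' bp, negative when the nearest subject lies 3' of the query on the forward
#' axis (query upstream of subject), positive when the subject lies 5' of the
#' query. Ties are broken toward the 5'-most subject.
#'
#' @param chrom,pos Query point coordinates (0-based).
#' @param subject Subject interval `data.frame`.
#' @return Numeric vector of signed distances; `NA` (with a message) for query
#'   chromosomes absent from the subject.
#' @export
distance_to_nearest <- function(chrom, pos, subject) {
  idx <- interval_index(subject)
  out <- rep(NA_real_, length(pos))
  missing_chr <- character(0)
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    tab <- idx[[ch]]
    if (is.null(tab) || nrow(tab) == 0L) {
      missing_chr <- c(missing_chr, ch)
      next
    }
    p <- pos[sel]
    i <- findInterval(p, tab$start)   # last interval with start <= p
    inside <- i >= 1L & p < tab$end[pmax(i, 1L)]
    # gap to the interval at/left of p (subject 5' of query): positive
    dl <- ifelse(i >= 1L, p - tab$end[pmax(i, 1L)] + 1L, Inf)
    # gap to the interval right of p (subject 3' of query): negative
    dr <- ifelse(i < nrow(tab), tab$start[pmin(i + 1L, nrow(tab))] - p, Inf)
    d <- ifelse(inside, 0,
                ifelse(dl <= dr, dl, -dr))  # tie -> 5' subject (positive)
    out[sel] <- d
  }
  if (length(missing_chr)) {
    message("distance_to_nearest: no subject intervals on chromosome(s) ",
            paste(unique(missing_chr), collapse = ", "), "; reported NA")
  }
  out
}

#' Read position frequency matrices (JASPAR or MEME text)
#'
#' JASPAR format (`>ID name` headers followed by four `A [ ... ]` rows) and
#' minimal MEME format (`MOTIF` blocks with a letter-probability matrix) are
#' supported. Counts are converted to per-column probabilities after adding a
#' pseudocount to every cell.
#'
#' @param path Path to the PFM text file.
#' @param pseudocount Added to every cell before normalization (default 0.25,
#'   the JASPAR convention; use 0 to keep already-normalized matrices).
#' @return List of PFM records, each `list(id, matrix)` where `matrix` is a
#'   4 x L probability matrix with rownames A, C, G, T and columns summing to 1.
#' @export
read_pfm <- function(path, pseudocount = 0.25) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  if (any(grepl("^MEME version", lines)) || any(grepl("^letter-probability", lines))) {
    i <- 1L
    while (i <= length(lines)) {
      if (grepl("^MOTIF", lines[i])) {
        id <- strsplit(trimws(lines[i]), "[ \t]+")[[1]][2]
        j <- i + 1L
        while (j <= length(lines) && !grepl("^letter-probability", lines[j])) j <- j + 1L
        if (j > length(lines)) stopf("MEME motif %s has no letter-probability matrix", id)
        k <- j + 1L
        rows <- list()
        while (k <= length(lines) && grepl("^[ \t]*[0-9.eE+-]", lines[k])) {
          rows[[length(rows) + 1L]] <- as.numeric(strsplit(trimws(lines[k]), "[ \t]+")[[1]])
          k <- k + 1L
        }
        if (length(unique(lengths(rows))) != 1L || lengths(rows)[1] != 4L) {
          stopf("ragged matrix for motif %s", id)
        }
        mat <- t(do.call(rbind, rows))
        rownames(mat) <- c("A", "C", "G", "T")
        out[[length(out) + 1L]] <- list(id = id, matrix = normalize_pfm(mat, pseudocount))
        i <- k
      } else i <- i + 1L
    }
    return(out)
  }
  # JASPAR
  i <- 1L
  while (i <= length(lines)) {
    if (startsWith(lines[i], ">")) {
      id <- sub("^>", "", strsplit(trimws(lines[i]), "[ \t]+")[[1]][1])
      rows <- list()
      for (k in seq_len(4L)) {
        ln <- lines[i + k]
        nums <- regmatches(ln, gregexpr("[0-9.eE+-]+", ln))[[1]]
        base <- sub("^([ACGTacgt]).*", "\\1", trimws(ln))
        rows[[toupper(base)]] <- as.numeric(nums)
      }
      if (length(unique(lengths(rows))) != 1L) stopf("ragged matrix for motif %s", id)
      mat <- rbind(A = rows[["A"]], C = rows[["C"]], G = rows[["G"]], T = rows[["T"]])
      out[[length(out) + 1L]] <- list(id = id, matrix = normalize_pfm(mat, pseudocount))
      i <- i + 5L
    } else i <- i + 1L
  }
  out
}

normalize_pfm <- function(mat, pseudocount) {
  mat <- mat + pseudocount
  sweep(mat, 2L, colSums(mat), "/")
}

#' Read a VCF-subset variant table
#'
#' Parses CHROM/POS/REF/ALT/FILTER (plus SVTYPE/SVLEN from INFO when present),
#' keeps only FILTER == PASS records, and converts positions to 0-based.
#'
#' @param path Path to an uncompressed VCF file.
#' @return `data.frame` with columns chrom, pos (0-based), ref, alt, vtype
#'   (SNP/INS/DEL/SV_BND), sv_class, length.
#' @export
read_vcf_subset <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                      alt = character(0), vtype = character(0),
                      sv_class = character(0), length = integer(0)))
  }
  fields <- strsplit(body, "\t")
  chrom <- vapply(fields, `[[`, character(1), 1L)
  pos1 <- as.integer(vapply(fields, `[[`, character(1), 2L))
  ref <- toupper(vapply(fields, `[[`, character(1), 4L))
  alt <- toupper(vapply(fields, `[[`, character(1), 5L))
  filt <- vapply(fields, function(f) if (length(f) >= 7L) f[[7]] else "PASS", character(1))
  info <- vapply(fields, function(f) if (length(f) >= 8L) f[[8]] else "", character(1))
  keep <- filt == "PASS"
  chrom <- chrom[keep]; pos1 <- pos1[keep]; ref <- ref[keep]; alt <- alt[keep]
  info <- info[keep]
  svtype <- ifelse(grepl("SVTYPE=", info),
                   sub(".*SVTYPE=([^;]+).*", "\\1", info), NA_character_)
  svlen <- rep(NA_integer_, length(info))
  has_len <- grepl("SVLEN=", info)
  svlen[has_len] <- abs(as.integer(sub(".*SVLEN=(-?[0-9]+).*", "\\1",
                                       info[has_len])))
  vtype <- ifelse(!is.na(svtype), "SV_BND",
           ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNP",
           ifelse(nchar(alt) > nchar(ref), "INS", "DEL")))
  len <- ifelse(vtype == "SNP", 0L,
         ifelse(vtype == "SV_BND", ifelse(is.na(svlen), 0L, svlen),
                abs(nchar(alt) - nchar(ref))))
  data.frame(chrom = chrom, pos = pos1 - 1L, ref = ref, alt = alt,
             vtype = vtype, sv_class = svtype, length = as.integer(len),
             stringsAsFactors = FALSE)
}

#' Construct a gene model table
#'
#' @param gene_id Gene identifiers.
#' @param chrom Chromosomes.
#' @param strand "+" or "-".
#' @param start,end Genomic span (0-based half-open). The TSS is the 5' end in
#'   transcription direction (`start` on "+", `end` on "-") and the TES the
#'   3' end.
#' @param cds_start,cds_end Coding span (defaults to the full span).
#' @param exon_starts,exon_ends Comma-separated exon coordinates (default: one
#'   exon spanning the gene).
#' @return `data.frame` of gene models.
#' @export
gene_models <- function(gene_id, chrom, strand, start, end,
                        cds_start = start, cds_end = end,
                        exon_starts = as.character(start),
                        exon_ends = as.character(end)) {
  stopifnot(all(strand %in% c("+", "-")), all(start < end))
  data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
             strand = strand, start = as.integer(start), end = as.integer(end),
             cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
             exon_starts = exon_starts, exon_ends = exon_ends,
             stringsAsFactors = FALSE)
}

#' Transcription start / end sites of gene models
#'
#' @param genes Gene model `data.frame` from [gene_models()].
#' @return Integer vector of TSS (or TES) coordinates, 0-based, on the forward
#'   axis: for a "+" gene the TSS is `start`, for a "-" gene `end - 1`.
#' @export
gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end - 1L)
}

#' @rdname gene_tss
#' @export
gene_tes <- function(genes) {
  ifelse(genes$strand == "+", genes$end - 1L, genes$start)
}
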