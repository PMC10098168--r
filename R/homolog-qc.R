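#' Hit-filtering profile
#'
#' Thresholds applied to homology-search hit tables. Identity and coverage
#' are inclusive minima, the E-value cutoff is strict (`E < max_evalue`),
#' and the length window is inclusive on both ends. Named presets bundle the
#' pipeline's curation settings:
#'
#' * `nitrilase-blast`: identity >= 70, coverage >= 95, E < 1e-10,
#'   length 200--500.
#' * `nitrilase-hmm`: E < 1e-10, length 50--500 (no identity/coverage
#'   thresholds; profile-search hits).
#' * `nhase`: identity >= 50, coverage >= 75, E < 1e-10, length 200--300.
#' * `scnase`: identity >= 50, coverage >= 75, E < 1e-10, length 175--300.
#'
#' @param preset one of the preset names, or `NULL` for a fully custom
#'   profile.
#' @param min_identity,min_coverage percent thresholds in \[0, 100\].
#' @param max_evalue strict E-value cutoff (>= 0).
#' @param length_range inclusive `c(lo, hi)` residue window, `lo < hi`.
#' @return object of class `filter_profile`.
#' @export
filter_profile <- function(preset = NULL, min_identity = 0,
                           min_coverage = 0, max_evalue = 1e-10,
                           length_range = c(1, Inf)) {
  if (!is.null(preset)) {
    p <- switch(preset,
      "nitrilase-blast" = list(70, 95, 1e-10, c(200, 500)),
      "nitrilase-hmm"   = list(0, 0, 1e-10, c(50, 500)),
      "nhase"           = list(50, 75, 1e-10, c(200, 300)),
      "scnase"          = list(50, 75, 1e-10, c(175, 300)),
      stop("unknown preset '", preset, "'"))
    min_identity <- p[[1]]; min_coverage <- p[[2]]
    max_evalue <- p[[3]]; length_range <- p[[4]]
  }
  stopifnot(min_identity >= 0, min_identity <= 100,
            min_coverage >= 0, min_coverage <= 100,
            max_evalue >= 0, length_range[1L] < length_range[2L])
  structure(list(preset = preset, min_identity = min_identity,
                 min_coverage = min_coverage, max_evalue = max_evalue,
                 length_range = length_range),
            class = "filter_profile")
}

#' Read a homology-search hit table
#'
#' Tab-separated hits with a header row (BLAST tabular style with identity,
#' coverage, E-value and subject-length columns). `col_map` renames input
#' columns onto the canonical fields `query`, `subject`, `identity`,
#' `coverage`, `evalue`, `length`, plus optional `organism` and `partial`.
#' Rows with unparseable numeric fields raise an error naming the offending
#' line.
#'
#' @param file TSV path.
#' @param col_map named character vector, canonical field -> input column.
#' @return data.frame of hits with canonical column names.
#' @export
read_hits <- function(file,
                      col_map = c(query = "qseqid", subject = "sseqid",
                                  identity = "pident", coverage = "qcovs",
                                  evalue = "evalue", length = "slen",
                                  organism = "organism",
                                  partial = "partial")) {
  raw <- utils::read.delim(file, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("query", "subject", "identity", "coverage", "evalue", "length")
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (f in names(col_map)) {
    src <- col_map[[f]]
    if (src %in% names(raw)) out[[f]] <- raw[[src]]
  }
  miss <- setdiff(need, names(out))
  if (length(miss)) {
    stop("hit table lacks required column(s): ", paste(miss, collapse = ", "))
  }
  for (f in c("identity", "coverage", "evalue", "length")) {
    v <- suppressWarnings(as.numeric(out[[f]]))
    bad <- which(is.na(v) & !is.na(out[[f]]))
    if (length(bad)) {
      stop("malformed ", f, " value at line ", bad[1L] + 1L,
           " of ", file, ": '", out[[f]][bad[1L]], "'")
    }
    out[[f]] <- v
  }
  out$organism <- if ("organism" %in% names(out)) out$organism else
    NA_character_
  out$partial <- if ("partial" %in% names(out)) {
    tolower(out$partial) %in% c("true", "t", "1", "yes")
  } else FALSE
  out
}

#' Filter hits by a profile
#'
#' A hit is retained iff identity >= min, coverage >= min, E-value < max
#' (strictly), length inside the inclusive window, and not flagged partial.
#' Rejections are counted against the first failing rule, in the fixed order
#' identity, coverage, evalue, length, partial. The filter is idempotent and
#' order-invariant.
#'
#' @param hits data.frame as from [read_hits()].
#' @param profile a [filter_profile()].
#' @return list with `retained` (data.frame) and `rejections` (named integer
#'   vector, one count per rule).
#' @export
filter_hits <- function(hits, profile) {
  stopifnot(inherits(profile, "filter_profile"))
  rules <- c("identity", "coverage", "evalue", "length", "partial")
  fail <- cbind(
    identity = hits$identity < profile$min_identity,
    coverage = hits$coverage < profile$min_coverage,
    evalue = !(hits$evalue < profile$max_evalue),
    length = hits$length < profile$length_range[1L] |
      hits$length > profile$length_range[2L],
    partial = hits$partial
  )
  first_fail <- apply(fail, 1L, function(r) {
    w <- which(r)
    if (length(w)) w[1L] else 0L
  })
  if (!nrow(hits)) first_fail <- integer(0)
  rejections <- vapply(seq_along(rules),
                       function(i) sum(first_fail == i), 0L)
  names(rejections) <- rules
  list(retained = hits[first_fail == 0L, , drop = FALSE],
       rejections = rejections)
}

#' Keep one representative per genus
#'
#' The genus is the first whitespace-delimited token of the organism string
#' (a curated override table may replace irregular names first). Within each
#' genus the longest sequence wins; ties break lexicographically by id, so
#' the result does not depend on input order.
#'
#' @param ids sequence/hit identifiers.
#' @param organisms organism strings, parallel to `ids`.
#' @param lengths sequence lengths, parallel to `ids`.
#' @param overrides optional named character vector mapping organism string
#'   to genus.
#' @return character vector of retained ids.
#' @export
subsample_per_genus <- function(ids, organisms, lengths, overrides = NULL) {
  stopifnot(length(ids) == length(organisms),
            length(ids) == length(lengths),
            all(nzchar(organisms)))
  genus <- vapply(strsplit(organisms, "\\s+"), `[[`, "", 1L)
  if (!is.null(overrides)) {
    hit <- organisms %in% names(overrides)
    genus[hit] <- overrides[organisms[hit]]
  }
  keep <- tapply(seq_along(ids), genus, function(i) {
    i[order(-lengths[i], ids[i])][1L]
  })
  sort(ids[unlist(keep)])
}

#' Aligned amino-acid matrix
#'
#' @param seqs named character vector of aligned sequences (equal lengths,
#'   gaps as `-` or `.`), or a `Biostrings::AAStringSet`.
#' @return character matrix (rows = sequences, columns = alignment sites)
#'   of class `alignment_matrix`.
#' @export
alignment_matrix <- function(seqs) {
  if (methods::is(seqs, "XStringSet")) {
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  }
  if (is.matrix(seqs)) {
    m <- seqs
  } else {
    if (length(unique(nchar(seqs))) != 1L) {
      stop("aligned sequences must all have equal length")
    }
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(m) <- names(seqs)
  }
  if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
    stop("sequence ids must be present and unique")
  }
  class(m) <- c("alignment_matrix", class(m))
  m
}

#' @rdname alignment_matrix
#' @param file FASTA path.
#' @export
read_alignment <- function(file) {
  alignment_matrix(Biostrings::readAAStringSet(file))
}

#' @rdname alignment_matrix
#' @param aln an `alignment_matrix`.
#' @export
write_alignment <- function(aln, file) {
  seqs <- apply(unclass(aln), 1L, paste, collapse = "")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), file)
  invisible(file)
}

is_gap <- function(m) m == "-" | m == "."

#' Catalytic-site conservation check
#'
#' Flags sequences with a gap at, or within `adjacency` columns of, any of
#' the given catalytic-site alignment columns (e.g. a nitrilase Glu/Lys/Cys
#' triad). Optionally also flags residue mismatches at the site columns
#' themselves.
#'
#' @param aln an [alignment_matrix()].
#' @param sites 1-based alignment columns of the catalytic residues.
#' @param expected optional character vector parallel to `sites`; each entry
#'   lists the accepted residue letters for that site (e.g. `"E"`, `"KR"`).
#' @param adjacency how many columns on either side of a site a gap is
#'   disqualifying (default 1).
#' @param check_residue flag residue mismatches too (default: only when
#'   `expected` is supplied).
#' @return list with `violators` (ids) and `report` (per-site data.frame:
#'   `site`, `n_gap_at`, `n_gap_adjacent`, `n_mismatch`).
#' @export
check_catalytic_sites <- function(aln, sites, expected = NULL,
                                  adjacency = 1L,
                                  check_residue = !is.null(expected)) {
  m <- unclass(aln)
  w <- ncol(m)
  if (any(sites < 1L | sites > w)) {
    stop("site column out of range 1..", w)
  }
  gaps <- is_gap(m)
  viol <- logical(nrow(m))
  report <- data.frame(site = sites, n_gap_at = 0L, n_gap_adjacent = 0L,
                       n_mismatch = 0L)
  for (i in seq_along(sites)) {
    s <- sites[i]
    win <- max(1L, s - adjacency):min(w, s + adjacency)
    gap_at <- gaps[, s]
    gap_adj <- rowSums(gaps[, win, drop = FALSE]) > 0L
    report$n_gap_at[i] <- sum(gap_at)
    report$n_gap_adjacent[i] <- sum(gap_adj & !gap_at)
    viol <- viol | gap_adj
    if (check_residue && !is.null(expected)) {
      allowed <- strsplit(toupper(expected[i]), "")[[1L]]
      mism <- !gap_at & !(m[, s] %in% allowed)
      report$n_mismatch[i] <- sum(mism)
      viol <- viol | mism
    }
  }
  list(violators = rownames(m)[viol], report = report)
}

#' Detect autapomorphic insertions
#'
#' A sequence is flagged when it holds residues across at least `min_run`
#' consecutive alignment columns in which at least `gap_majority` of all
#' other sequences hold gaps -- the signature of a private (or nearly
#' private) insertion that is likely an alignment artifact.
#'
#' @param aln an [alignment_matrix()].
#' @param min_run minimum insertion length in residues (default 20).
#' @param gap_majority fraction of the other sequences that must be gapped
#'   (default 0.95).
#' @return character vector of flagged sequence ids.
#' @export
detect_autapomorphic_insertions <- function(aln, min_run = 20L,
                                            gap_majority = 0.95) {
  stopifnot(min_run >= 1L)
  m <- unclass(aln)
  n <- nrow(m)
  if (n < 2L) return(character(0))
  gaps <- is_gap(m)
  gap_per_col <- colSums(gaps)
  flagged <- character(0)
  for (i in seq_len(n)) {
    other_gap_frac <- (gap_per_col - gaps[i, ]) / (n - 1L)
    hot <- !gaps[i, ] & other_gap_frac >= gap_majority
    r <- rle(hot)
    if (any(r$values & r$lengths >= min_run)) {
      flagged <- c(flagged, rownames(m)[i])
    }
  }
  flagged
}

#' Trim alignment columns
#'
#' Retains the inclusive column range `first_keep..last_keep` (e.g. dropping
#' gap-rich N- and C-terminal regions).
#'
#' @param aln an [alignment_matrix()].
#' @param first_keep,last_keep 1-based inclusive bounds.
#' @return trimmed `alignment_matrix` of width `last_keep - first_keep + 1`.
#' @export
trim_columns <- function(aln, first_keep, last_keep) {
  w <- ncol(aln)
  if (first_keep < 1L || last_keep > w || first_keep > last_keep) {
    stop("column range ", first_keep, "..", last_keep,
         " invalid for width ", w)
  }
  out <- unclass(aln)[, first_keep:last_keep, drop = FALSE]
  class(out) <- c("alignment_matrix", class(out))
  out
}

#' Sequence-length distribution summary
#'
#' Gaussian kernel density (Silverman's rule-of-thumb bandwidth) over hit
#' lengths, with an advisory window: the smallest contiguous interval
#' containing the main mode over which the density stays above 10% of the
#' peak. Filtering always uses an explicit [filter_profile()]; the window is
#' a suggestion for choosing one.
#'
#' @param lengths numeric vector of sequence lengths (>= 5).
#' @param peak_fraction density cutoff as a fraction of the peak.
#' @return list with `density` (a [stats::density] object or `NULL` for a
#'   degenerate sample) and `window` (`c(lo, hi)`).
#' @export
length_summary <- function(lengths, peak_fraction = 0.1) {
  stopifnot(length(lengths) >= 5L)
  if (stats::var(lengths) == 0) {
    return(list(density = NULL, window = c(lengths[1L], lengths[1L])))
  }
  d <- stats::density(lengths, bw = "nrd0")
  peak <- which.max(d$y)
  thr <- peak_fraction * d$y[peak]
  lo <- peak
  while (lo > 1L && d$y[lo - 1L] >= thr) lo <- lo - 1L
  hi <- peak
  while (hi < length(d$y) && d$y[hi + 1L] >= thr) hi <- hi + 1L
  list(density = d, window = c(d$x[lo], d$x[hi]))
}
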