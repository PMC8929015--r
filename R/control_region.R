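# A+T-rich control-region architecture: tandem-repeat arrays, nonrepeat
# segments, per-segment composition, and poly-nucleotide runs.
#
# The repeat finder is a small self-match detector: for each candidate
# period p it compares the sequence to itself at lag p and seeds an array
# wherever a full period of consecutive matches occurs. The deterministic
# extension rule (shared with the brute-force test oracle) is: extend right
# in whole-unit blocks, accepting a block only when its own lag-p match
# fraction reaches min_identity, then extend right position-wise while
# positions match exactly; the same leftwards. Arrays are then filtered by
# copy number/identity and overlaps resolved by (longer span, then higher
# identity, then smaller unit). Block-local acceptance keeps array
# boundaries from creeping into flanking low-complexity sequence whose
# chance lag-p match rate is high.

#' Find tandem-repeat arrays in a sequence
#'
#' @param seq nucleotide string
#' @param min_unit,max_unit bounds on the repeat unit length (bp)
#' @param min_copies minimum (possibly fractional) copy number
#' @param min_identity minimum fraction of lag-p self-matches over the array
#' @param exclude_homopolymer drop arrays whose consensus unit is a single
#'   repeated base; homopolymer runs are the business of the poly-run
#'   annotation (see [region_architecture()]), not the repeat-array table
#' @return data.frame of class `repeat_arrays`: (start, end, unit_length,
#'   copies, identity, consensus, truncated_final); coordinates are 1-based
#'   within `seq`, copies are reported to one decimal, `truncated_final`
#'   flags a fractional last copy
#' @export
find_tandem_repeats <- function(seq, min_unit = 10L, max_unit = 200L,
                                min_copies = 2, min_identity = 0.85,
                                exclude_homopolymer = TRUE) {
  n <- nchar(seq)
  empty <- data.frame(start = integer(), end = integer(),
                      unit_length = integer(), copies = numeric(),
                      identity = numeric(), consensus = character(),
                      truncated_final = logical(), stringsAsFactors = FALSE)
  class(empty) <- c("repeat_arrays", "data.frame")
  if (n < 2L * min_unit) return(empty)
  ch <- seq_chars(toupper(seq))
  cands <- list()
  for (p in min_unit:min(max_unit, n %/% 2L)) {
    m <- ch[(p + 1L):n] == ch[1L:(n - p)]  # m[j]: position j+p matches j
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    seed_idx <- which(r$values & r$lengths >= p)
    if (!length(seed_idx)) next
    seen <- rep(FALSE, length(m))
    for (si in seed_idx) {
      a <- starts[si]; b <- ends[si]
      if (seen[a]) next
      # array [A, B] in sequence coords is [A, Bm + p] with Bm in m coords;
      # identity over the array is mean(m[A..Bm])
      A <- a; Bm <- b
      # whole-unit block extension, then exact-match tail extension
      while (Bm + p <= length(m) && mean(m[(Bm + 1L):(Bm + p)]) >= min_identity) {
        Bm <- Bm + p
      }
      while (Bm < length(m) && m[Bm + 1L]) Bm <- Bm + 1L
      while (A - p >= 1L && mean(m[(A - p):(A - 1L)]) >= min_identity) {
        A <- A - p
      }
      while (A > 1L && m[A - 1L]) A <- A - 1L
      while (Bm > A && !m[Bm]) Bm <- Bm - 1L
      while (A < Bm && !m[A]) A <- A + 1L
      seen[A:Bm] <- TRUE
      span <- (Bm + p) - A + 1L
      if (span < p * min_copies) next
      idv <- mean(m[A:Bm])
      if (idv < min_identity) next
      cands[[length(cands) + 1L]] <- list(start = A, end = Bm + p,
                                          unit_length = p, span = span,
                                          identity = idv)
    }
  }
  if (!length(cands)) return(empty)
  cd <- do.call(rbind, lapply(cands, as.data.frame))
  cd <- cd[order(-cd$span, -cd$identity, cd$unit_length), , drop = FALSE]
  keep <- logical(nrow(cd))
  for (i in seq_len(nrow(cd))) {
    ok <- TRUE
    for (j in which(keep)) {
      if (cd$start[i] <= cd$end[j] && cd$end[i] >= cd$start[j]) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  cd <- cd[keep, , drop = FALSE]
  cd <- cd[order(cd$start), , drop = FALSE]
  out <- data.frame(
    start = cd$start, end = cd$end, unit_length = cd$unit_length,
    copies = round(cd$span / cd$unit_length, 1L),
    identity = cd$identity,
    consensus = vapply(seq_len(nrow(cd)), function(i) {
      repeat_consensus(ch, cd$start[i], cd$end[i], cd$unit_length[i])
    }, character(1)),
    truncated_final = (cd$span %% cd$unit_length) != 0L,
    stringsAsFactors = FALSE)
  if (exclude_homopolymer && nrow(out)) {
    mono <- vapply(out$consensus, function(u) {
      length(unique(seq_chars(u))) == 1L
    }, logical(1))
    out <- out[!mono, , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("repeat_arrays", "data.frame")
  out
}

repeat_consensus <- function(ch, start, end, p) {
  span <- end - start + 1L
  k <- span %/% p
  if (k < 1L) return(paste(ch[start:min(end, start + p - 1L)], collapse = ""))
  mat <- matrix(ch[start:(start + k * p - 1L)], nrow = p)
  paste(apply(mat, 1L, function(col) names(which.max(table(col)))), collapse = "")
}

#' Architecture of the A+T-rich control region
#'
#' Runs [find_tandem_repeats()] on the control-region sequence (taken in
#' major-strand orientation, i.e. from the 3' flank of srRNA towards trnI),
#' labels the gaps between arrays as nonrepeat segments, and reports
#' per-segment A+T content plus poly-A / poly-T / poly-AT runs.
#'
#' @param rec a [mitogenome()] record with sequence and a control feature
#' @param min_polyrun minimum poly-run length reported (bp)
#' @param ... passed to [find_tandem_repeats()]
#' @return object of class `region_architecture`: list with `segments`
#'   (label/start/end/length/AT), `repeats` (the array table) and `polyruns`
#'   (pattern/start/length), coordinates local to the region
#' @export
region_architecture <- function(rec, min_polyrun = 8L, ...) {
  ctrl <- rec$features[rec$features$ftype == "control", ]
  if (!nrow(ctrl)) stop("record ", rec$record_id, " has no control (A+T-rich) feature")
  if (is.null(rec$sequence)) stop("record ", rec$record_id, " has no sequence")
  s <- substr(rec$sequence, ctrl$start[1], ctrl$end[1])
  reps <- find_tandem_repeats(s, ...)
  n <- nchar(s)
  bounds <- rbind(
    if (nrow(reps)) data.frame(label = "repeat", start = reps$start, end = reps$end),
    NULL)
  segs <- list()
  pos <- 1L
  if (!is.null(bounds)) bounds <- bounds[order(bounds$start), , drop = FALSE]
  for (i in seq_len(NROW(bounds))) {
    if (bounds$start[i] > pos) {
      segs[[length(segs) + 1L]] <- data.frame(label = "nonrepeat", start = pos,
                                              end = bounds$start[i] - 1L)
    }
    segs[[length(segs) + 1L]] <- data.frame(label = "repeat",
                                            start = bounds$start[i],
                                            end = bounds$end[i])
    pos <- bounds$end[i] + 1L
  }
  if (pos <= n) {
    segs[[length(segs) + 1L]] <- data.frame(label = "nonrepeat", start = pos, end = n)
  }
  segments <- do.call(rbind, segs)
  segments$length <- segments$end - segments$start + 1L
  segments$AT <- vapply(seq_len(nrow(segments)), function(i) {
    attr(base_content(substr(s, segments$start[i], segments$end[i])), "AT")
  }, numeric(1))
  polyruns <- find_polyruns(s, min_polyrun)
  structure(list(segments = segments, repeats = reps, polyruns = polyruns,
                 region_length = n, record_id = rec$record_id),
            class = "region_architecture")
}

find_polyruns <- function(s, min_len = 8L) {
  pats <- c(A = sprintf("A{%d,}", min_len),
            T = sprintf("T{%d,}", min_len),
            AT = sprintf("(?:AT|TA){%d,}[AT]?", ceiling(min_len / 2)))
  rows <- list()
  for (pat in names(pats)) {
    g <- gregexpr(pats[[pat]], s, perl = TRUE)[[1]]
    if (g[1] == -1L) next
    len <- attr(g, "match.length")
    keep <- len >= min_len
    if (!any(keep)) next
    rows[[length(rows) + 1L]] <- data.frame(pattern = pat,
                                            start = as.integer(g[keep]),
                                            length = len[keep],
                                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(pattern = character(), start = integer(),
                      length = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

#' @export
print.region_architecture <- function(x, ...) {
  cat("<region_architecture> ", x$record_id, " (", x$region_length, " bp)\n",
      sep = "")
  for (i in seq_len(nrow(x$segments))) {
    cat(sprintf("  %-9s %5d-%5d  %5d bp  AT %.1f%%\n",
                x$segments$label[i], x$segments$start[i], x$segments$end[i],
                x$segments$length[i], x$segments$AT[i]))
  }
  invisible(x)
}

#' Pairwise identity of repeat units
#'
#' Globally aligns every pair of units (Needleman-Wunsch with unit match
#' score, mismatch and gap penalties) and reports the identity matrix,
#' defined as the number of matching positions divided by the longer unit
#' length. The verdict is "alignable" when the mean off-diagonal identity
#' reaches the threshold — random units of this alphabet sit near 0.25-0.4.
#'
#' @param units character vector of at least two unit sequences
#' @param threshold mean-identity threshold for the alignability verdict
#' @return list with `identity` (matrix), `mean_identity`, `alignable`
#' @export
compare_repeat_units <- function(units, threshold = 0.6) {
  if (length(units) < 2L) stop("need at least two repeat units to compare")
  k <- length(units)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = TRUE)
  id <- matrix(1, k, k, dimnames = list(names(units), names(units)))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      aln <- Biostrings::pairwiseAlignment(units[i], units[j],
                                           type = "global",
                                           substitutionMatrix = sm,
                                           gapOpening = 4, gapExtension = 1)
      id[i, j] <- id[j, i] <-
        Biostrings::nmatch(aln) / max(nchar(units[i]), nchar(units[j]))
    }
  }
  mi <- mean(id[upper.tri(id)])
  list(identity = id, mean_identity = mi, alignable = mi >= threshold)
}
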