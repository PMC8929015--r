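# Junction motif scanning: search a window around a named gene junction for
# a short conserved motif (canonically the pentanucleotide TAGTA at the
# ND1/trnS2 junction, a candidate mtTERM binding site) allowing mismatches.

hamming <- function(a, b) {
  sum(seq_chars(a) != seq_chars(b))
}

#' Scan a gene junction for a conserved motif
#'
#' The junction point is the midpoint between the two named features'
#' facing coordinates; every motif-length window whose span lies within
#' `window` bp of that point is scored by Hamming distance on both strands
#' (substitutions only, no indels). Hits are classed by their overlap with
#' the flanking features and sorted by (mismatches, distance to junction).
#'
#' @param rec a [mitogenome()] record with sequence
#' @param upstream,downstream feature names flanking the junction
#' @param motif motif string (default "TAGTA")
#' @param max_mismatch maximum Hamming distance to report (default 1)
#' @param window half-width of the scanned region in bp (default 30; must be
#'   at least the motif length)
#' @return data.frame of class `motif_hits`: (position, strand, mismatches,
#'   location_class, matched_seq) with attribute `junction` giving the
#'   midpoint coordinate
#' @export
scan_junction <- function(rec, upstream, downstream, motif = "TAGTA",
                          max_mismatch = 1L, window = 30L) {
  if (is.null(rec$sequence)) stop("record ", rec$record_id, " has no sequence")
  m <- nchar(motif)
  if (window < m) stop("window (", window, ") must be at least the motif length (", m, ")")
  f <- rec$features
  iu <- which(f$name == upstream)
  idn <- which(f$name == downstream)
  if (!length(iu)) stop("feature '", upstream, "' not annotated")
  if (!length(idn)) stop("feature '", downstream, "' not annotated")
  up <- f[iu[1], ]
  dn <- f[idn[1], ]
  # order the two features along the genome; warn when not adjacent
  left <- if (up$start <= dn$start) up else dn
  right <- if (up$start <= dn$start) dn else up
  ford <- f[order(f$start), ]
  pos_left <- which(ford$name == left$name)
  if (ford$name[min(pos_left + 1L, nrow(ford))] != right$name) {
    warning(upstream, " and ", downstream,
            " are not adjacent in genome order; scanning their ",
            "inter-coordinate interval anyway", call. = FALSE)
  }
  mid <- (left$end + right$start) / 2
  lo <- as.integer(ceiling(mid - window))
  hi <- as.integer(floor(mid + window))
  motif_rc <- revcomp(motif)
  hits <- list()
  for (p in lo:(hi - m + 1L)) {
    s <- circ_substr(rec$sequence, p, p + m - 1L, rec$genome_length)
    for (strand in c("+", "-")) {
      target <- if (strand == "+") motif else motif_rc
      d <- hamming(s, target)
      if (d <= max_mismatch) {
        hits[[length(hits) + 1L]] <- data.frame(
          position = ((p - 1L) %% rec$genome_length) + 1L,
          strand = strand, mismatches = d,
          location_class = classify_hit_location(p, p + m - 1L, up, dn),
          matched_seq = s, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else {
    data.frame(position = integer(), strand = character(),
               mismatches = integer(), location_class = character(),
               matched_seq = character(), stringsAsFactors = FALSE)
  }
  if (nrow(out)) {
    center_dist <- abs((out$position + (m - 1) / 2) - mid)
    out <- out[order(out$mismatches, center_dist), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "junction") <- mid
  class(out) <- c("motif_hits", "data.frame")
  out
}

classify_hit_location <- function(hs, he, up, dn) {
  within <- function(f) hs >= f$start && he <= f$end
  overlaps <- function(f) hs <= f$end && he >= f$start
  if (within(up)) return("within_upstream_3prime")
  if (within(dn)) return("within_downstream_5prime")
  if (!overlaps(up) && !overlaps(dn)) return("within_spacer")
  "spanning"
}
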