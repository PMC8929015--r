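# Intraspecies per-gene divergence: uncorrected pairwise p-distances with
# pairwise deletion, the COI barcode region, and per-gene summaries.

#' Uncorrected p-distance between two aligned sequences
#'
#' 100 x mismatches / comparable positions, where a position is comparable
#' when neither sequence has a gap ('-') or ambiguous base there (pairwise
#' deletion).
#'
#' @param a,b equal-length strings
#' @return percentage; `NA` with a warning when no positions are comparable
#' @export
#' @examples
#' p_distance("A-CT", "AGCT")  # 0 over 3 comparable sites
p_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences must have equal length")
  ca <- seq_chars(toupper(a))
  cb <- seq_chars(toupper(b))
  ok <- ca %in% NUC & cb %in% NUC
  if (!any(ok)) {
    warning("no comparable positions; p-distance undefined", call. = FALSE)
    return(NA_real_)
  }
  100 * sum(ca[ok] != cb[ok]) / sum(ok)
}

#' The COI DNA-barcode region of a record
#'
#' The 5' prefix of COI in reading orientation; 658 bp is the standard
#' animal barcode length.
#'
#' @param rec a [mitogenome()] record with sequence
#' @param length prefix length in bp (truncated when COI is shorter)
#' @return nucleotide string
#' @export
barcode_region <- function(rec, length = 658L) {
  coi <- extract_gene_sequence(rec, "COI")
  substr(coi, 1L, min(length, nchar(coi)))
}

#' Per-gene divergence summaries across conspecific records
#'
#' All pairwise p-distances per gene (plus, optionally, the barcode region),
#' summarised as min/median/mean/max and sorted by median. Genes missing
#' from any record, or with unequal extracted lengths, are skipped with a
#' warning.
#'
#' @param records list of at least two [mitogenome()] records with sequence
#' @param genes gene names to summarise (default: PCGs and rRNAs present in
#'   the first record)
#' @param barcode also include the COI barcode region as its own row
#' @return data.frame of class `divergence_summary`:
#'   (gene, n_pairs, min, median, mean, max), percentages
#' @export
divergence_table <- function(records, genes = NULL, barcode = TRUE) {
  if (length(records) < 2L) stop("need at least two records")
  if (is.null(genes)) {
    f <- records[[1]]$features
    genes <- f$name[f$ftype %in% c("PCG", "rRNA")]
  }
  get_seqs <- function(g) {
    lapply(records, function(r) {
      if (!g %in% r$features$name) return(NULL)
      extract_gene_sequence(r, g)
    })
  }
  summarise <- function(gname, seqs) {
    if (any(vapply(seqs, is.null, logical(1)))) {
      warning("gene ", gname, " missing from some records; skipped",
              call. = FALSE)
      return(NULL)
    }
    lens <- vapply(seqs, nchar, integer(1))
    if (length(unique(lens)) != 1L) {
      warning("gene ", gname, " has unequal lengths across records; ",
              "skipped — align first", call. = FALSE)
      return(NULL)
    }
    k <- length(seqs)
    d <- numeric(0)
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) d <- c(d, p_distance(seqs[[i]], seqs[[j]]))
    }
    data.frame(gene = gname, n_pairs = length(d),
               min = min(d), median = stats::median(d),
               mean = mean(d), max = max(d), stringsAsFactors = FALSE)
  }
  rows <- lapply(genes, function(g) summarise(g, get_seqs(g)))
  if (barcode) {
    bseqs <- lapply(records, function(r) {
      if (!"COI" %in% r$features$name) return(NULL)
      barcode_region(r)
    })
    rows <- c(rows, list(summarise("barcode", bseqs)))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no gene could be summarised")
  out <- out[order(out$median), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("divergence_summary", "data.frame")
  out
}
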