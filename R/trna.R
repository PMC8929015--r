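# Evaluation of annotated tRNA cloverleaf structures. Structures are
# evaluated, not predicted: pairing comes from annotation (dot-bracket plus
# arm spans) or from the synthetic generator. Base pairs are classed
# Watson-Crick, G-U wobble, or mismatch; canonical dimensions are an
# invariant 7-bp acceptor stem, 5-bp anticodon stem and 7-nt anticodon
# loop; a DHU arm with no pairs marks the truncated form typical of trnS1.

ARM_NAMES <- c("acceptor", "DHU", "anticodon", "TPsiC")

#' Construct a cloverleaf annotation
#'
#' @param trna_name tRNA label (e.g. "trnS1")
#' @param sequence the tRNA sequence (DNA alphabet)
#' @param pairing named list of two-column index matrices (columns i < j),
#'   one per arm: acceptor, DHU, anticodon, TPsiC; an arm may be empty
#' @param anticodon_span optional integer length-2 range of the anticodon
#'   within the sequence
#' @return object of class `cloverleaf`
#' @export
cloverleaf <- function(trna_name, sequence, pairing,
                       anticodon_span = NULL) {
  sequence <- toupper(sequence)
  missing_arms <- setdiff(ARM_NAMES, names(pairing))
  for (a in missing_arms) pairing[[a]] <- matrix(integer(0), ncol = 2L)
  pairing <- pairing[ARM_NAMES]
  all_idx <- do.call(rbind, pairing)
  if (NROW(all_idx)) {
    if (any(all_idx < 1L) || any(all_idx > nchar(sequence))) {
      stop("pairing index out of range for ", trna_name)
    }
    if (any(all_idx[, 1] >= all_idx[, 2])) {
      stop("pairing must satisfy i < j for ", trna_name)
    }
    if (anyDuplicated(as.vector(all_idx))) {
      stop("pairing indices must be disjoint for ", trna_name)
    }
  }
  structure(list(trna_name = trna_name, sequence = sequence,
                 pairing = pairing, anticodon_span = anticodon_span),
            class = "cloverleaf")
}

classify_pair <- function(b1, b2) {
  pair <- paste0(b1, b2)
  if (pair %in% c("AT", "TA", "GC", "CG")) return("watson_crick")
  if (pair %in% c("GT", "TG")) return("wobble_GU")
  "mismatch"
}

#' Evaluate a cloverleaf annotation
#'
#' Classifies every annotated base pair per arm and checks canonical
#' dimensions.
#'
#' @param annot a [cloverleaf()] annotation
#' @return object of class `pair_counts`: list with `per_arm` (data.frame
#'   arm/watson_crick/wobble_GU/mismatch/pairs), `dhu_truncated`, `dims_ok`,
#'   `length`
#' @export
evaluate_cloverleaf <- function(annot) {
  ch <- seq_chars(annot$sequence)
  rows <- lapply(ARM_NAMES, function(arm) {
    pr <- annot$pairing[[arm]]
    if (!NROW(pr)) {
      return(data.frame(arm = arm, watson_crick = 0L, wobble_GU = 0L,
                        mismatch = 0L, pairs = 0L, stringsAsFactors = FALSE))
    }
    cls <- vapply(seq_len(nrow(pr)), function(k) {
      classify_pair(ch[pr[k, 1]], ch[pr[k, 2]])
    }, character(1))
    data.frame(arm = arm,
               watson_crick = sum(cls == "watson_crick"),
               wobble_GU = sum(cls == "wobble_GU"),
               mismatch = sum(cls == "mismatch"),
               pairs = length(cls), stringsAsFactors = FALSE)
  })
  per_arm <- do.call(rbind, rows)
  ac <- annot$pairing$anticodon
  ac_loop <- if (NROW(ac)) {
    inner <- which.max(ac[, 1])
    ac[inner, 2] - ac[inner, 1] - 1L
  } else NA_integer_
  dims_ok <- per_arm$pairs[per_arm$arm == "acceptor"] == 7L &&
    per_arm$pairs[per_arm$arm == "anticodon"] == 5L &&
    !is.na(ac_loop) && ac_loop == 7L
  structure(list(per_arm = per_arm,
                 dhu_truncated = per_arm$pairs[per_arm$arm == "DHU"] == 0L,
                 dims_ok = dims_ok,
                 anticodon_loop = ac_loop,
                 trna_name = annot$trna_name,
                 length = nchar(annot$sequence)),
            class = "pair_counts")
}

#' @export
print.pair_counts <- function(x, ...) {
  cat("<pair_counts> ", x$trna_name, " (", x$length, " nt)",
      if (x$dhu_truncated) "  [DHU truncated]",
      if (x$dims_ok) "  [canonical dims]", "\n", sep = "")
  print(x$per_arm, row.names = FALSE)
  invisible(x)
}

#' Parse a dot-bracket structure into pair indices
#'
#' @param db dot-bracket string over '.', '(' and ')'
#' @return two-column integer matrix (i, j), i < j
#' @export
dotbracket_pairs <- function(db) {
  ch <- seq_chars(db)
  stack <- integer(0)
  pairs <- list()
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string")
      pairs[[length(pairs) + 1L]] <- c(stack[length(stack)], i)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket string")
  m <- do.call(rbind, pairs)
  if (is.null(m)) m <- matrix(integer(0), ncol = 2L)
  m[order(m[, 1]), , drop = FALSE]
}

parse_arm_spans <- function(s) {
  # "acceptor=1-7/66-72;DHU=10-13/22-25;anticodon=27-31/39-43;TPsiC=49-53/61-65"
  out <- list()
  for (part in strsplit(s, ";", fixed = TRUE)[[1]]) {
    kv <- strsplit(part, "=", fixed = TRUE)[[1]]
    spans <- lapply(strsplit(kv[2], "/", fixed = TRUE)[[1]], function(r) {
      ab <- as.integer(strsplit(r, "-", fixed = TRUE)[[1]])
      ab[1]:ab[2]
    })
    out[[kv[1]]] <- unlist(spans)
  }
  out
}

#' Read cloverleaf annotations from a TSV
#'
#' Columns: trna, sequence, structure (dot-bracket), arm_spans
#' (`arm=a-b/c-d;...`). A pair is assigned to the arm containing its 5'
#' index.
#'
#' @param path TSV path
#' @return named list of [cloverleaf()] annotations
#' @export
read_cloverleaf_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "#")
  out <- list()
  for (i in seq_len(nrow(tab))) {
    pr <- dotbracket_pairs(tab$structure[i])
    spans <- parse_arm_spans(tab$arm_spans[i])
    pairing <- lapply(ARM_NAMES, function(arm) {
      idx <- spans[[arm]]
      if (is.null(idx)) return(matrix(integer(0), ncol = 2L))
      pr[pr[, 1] %in% idx, , drop = FALSE]
    })
    names(pairing) <- ARM_NAMES
    out[[tab$trna[i]]] <- cloverleaf(tab$trna[i], tab$sequence[i], pairing)
  }
  out
}

#' Genome-level tRNA structure report
#'
#' Per-record, per-tRNA, per-arm pair classification with genome totals and
#' the shortest/longest tRNA.
#'
#' @param recs list of [mitogenome()] records (lengths are taken from the
#'   annotation)
#' @param annots named list (by record id) of named lists (by tRNA) of
#'   [cloverleaf()] annotations
#' @return list with `table` (record/trna/arm rows), `totals` (per-record
#'   mismatch and wobble totals, shortest and longest tRNA), `missing`
#'   (annotations absent)
#' @export
genome_trna_report <- function(recs, annots) {
  rows <- list()
  missing <- character(0)
  for (rec in recs) {
    trnas <- rec$features[rec$features$ftype == "tRNA", ]
    ann <- annots[[rec$record_id]]
    for (i in seq_len(nrow(trnas))) {
      nm <- trnas$name[i]
      len <- trnas$end[i] - trnas$start[i] + 1L
      a <- ann[[nm]]
      if (is.null(a)) {
        missing <- c(missing, paste0(rec$record_id, ":", nm))
        next
      }
      ev <- evaluate_cloverleaf(a)
      pa <- ev$per_arm
      pa$record <- rec$record_id
      pa$trna <- nm
      pa$length <- len
      pa$dhu_truncated <- ev$dhu_truncated
      pa$dims_ok <- ev$dims_ok
      rows[[length(rows) + 1L]] <- pa
    }
  }
  tab <- do.call(rbind, rows)
  totals <- NULL
  if (!is.null(tab)) {
    per_rec <- split(tab, tab$record)
    totals <- do.call(rbind, lapply(per_rec, function(d) {
      one <- d[!duplicated(d$trna), ]
      data.frame(record = d$record[1],
                 mismatches = sum(d$mismatch),
                 wobble_GU = sum(d$wobble_GU),
                 shortest = one$trna[which.min(one$length)],
                 shortest_bp = min(one$length),
                 longest = one$trna[which.max(one$length)],
                 longest_bp = max(one$length),
                 stringsAsFactors = FALSE)
    }))
    rownames(totals) <- NULL
  }
  list(table = tab, totals = totals, missing = missing)
}
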