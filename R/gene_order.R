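# Gene orders as signed circular permutations; rearrangement typing and
# breakpoint distance.
#
# Type A is the ancestral insect arrangement. Type B carries (i) a
# trnC-trnW transposition at the ND2/trnY junction and (ii) the block
# between ND4L and CytB rewritten from trnT,trnP,ND6 to
# ND6(inverted),trnP,trnT. Type B' is B with trnC triplicated; type C is B
# with trnH moved from the ND5/ND4 junction to just upstream of ND6.

.ancestral_names <- c("trnI", "trnQ", "trnM", "ND2", "trnW", "trnC", "trnY",
                      "COI", "trnL2", "COII", "trnK", "trnD", "ATP8", "ATP6",
                      "COIII", "trnG", "ND3", "trnA", "trnR", "trnN", "trnS1",
                      "trnE", "trnF", "ND5", "trnH", "ND4", "ND4L", "trnT",
                      "trnP", "ND6", "CytB", "trnS2", "ND1", "trnL1", "lrRNA",
                      "trnV", "srRNA")
.ancestral_orient <- c("+", "-", "+", "+", "+", "-", "-",
                       "+", "+", "+", "+", "+", "+", "+",
                       "+", "+", "+", "+", "+", "+", "+",
                       "+", "-", "-", "-", "-", "-", "+",
                       "-", "+", "+", "+", "-", "-", "-",
                       "-", "-")

new_gene_order <- function(order, duplications = integer(0)) {
  structure(list(order = order, duplications = duplications),
            class = "gene_order")
}

#' Reference gene order for an arrangement type
#'
#' @param type one of "A", "B", "B'", "C"
#' @return a `gene_order` object (canonical rotation, starting at trnI)
#' @export
reference_gene_order <- function(type = c("A", "B", "B'", "C")) {
  type <- match.arg(type)
  ord <- data.frame(name = .ancestral_names, orient = .ancestral_orient,
                    stringsAsFactors = FALSE)
  dup <- integer(0)
  if (type %in% c("B", "B'", "C")) {
    # trnC-trnW transposition at the ND2/trnY junction (orientations kept)
    i <- match(c("trnW", "trnC"), ord$name)
    ord[i, ] <- ord[rev(i), ]
    # trnT,trnP,ND6 -> ND6(inverted),trnP,trnT between ND4L and CytB
    i <- match(c("trnT", "trnP", "ND6"), ord$name)
    ord[i, ] <- data.frame(name = c("ND6", "trnP", "trnT"),
                           orient = c("-", "-", "+"), stringsAsFactors = FALSE)
  }
  if (type == "B'") dup <- c(trnC = 3L)
  if (type == "C") {
    # trnH leaves the ND5/ND4 junction and lands just upstream of ND6
    ord <- ord[ord$name != "trnH", ]
    i <- match("ND6", ord$name)
    ord <- rbind(ord[seq_len(i - 1L), ],
                 data.frame(name = "trnH", orient = "-", stringsAsFactors = FALSE),
                 ord[i:nrow(ord), ])
    rownames(ord) <- NULL
  }
  new_gene_order(ord, dup)
}

canonicalize_order <- function(ord, duplications = integer(0)) {
  anchor <- match("trnI", ord$name)
  if (is.na(anchor)) {
    trnas <- grep("^trn", ord$name)
    if (!length(trnas)) stop("gene order contains no tRNA to anchor the rotation")
    warning("trnI absent; anchoring rotation at ", ord$name[trnas[1]],
            call. = FALSE)
    anchor <- trnas[1]
  }
  idx <- c(anchor:nrow(ord), if (anchor > 1L) 1:(anchor - 1L))
  ord <- ord[idx, , drop = FALSE]
  rownames(ord) <- NULL
  new_gene_order(ord, duplications)
}

#' Gene-order signature of an annotated record
#'
#' Features sorted by start become a signed circular permutation
#' (orientation `+` for major strand), rotated to start at trnI; the control
#' region is excluded and duplicated labels are collapsed into a copy-count
#' map (first occurrence keeps the position).
#'
#' @param rec a [mitogenome()] record
#' @return object of class `gene_order`: list with `order` (data.frame
#'   name/orient) and `duplications` (named integer)
#' @export
gene_order_signature <- function(rec) {
  f <- rec$features[rec$features$ftype != "control", , drop = FALSE]
  if (!nrow(f)) stop("record ", rec$record_id, " has no gene features")
  f <- f[order(f$start, f$end), ]
  ord <- data.frame(name = f$name,
                    orient = ifelse(f$strand == "major", "+", "-"),
                    stringsAsFactors = FALSE)
  counts <- table(ord$name)
  dup <- counts[counts > 1L]
  duplications <- stats::setNames(as.integer(dup), names(dup))
  ord <- ord[!duplicated(ord$name), , drop = FALSE]
  rownames(ord) <- NULL
  canonicalize_order(ord, duplications)
}

#' @export
print.gene_order <- function(x, n = 10L, ...) {
  s <- paste0(x$order$name, "(", x$order$orient, ")")
  cat("<gene_order> ", length(s), " genes: ",
      paste(utils::head(s, n), collapse = " "),
      if (length(s) > n) " ...", "\n", sep = "")
  if (length(x$duplications)) {
    cat("  duplications: ",
        paste0(names(x$duplications), "x", x$duplications, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Serialize / parse a gene-order signature
#'
#' One-line text form `"trnI,+;trnQ,-;..."`.
#'
#' @param x a `gene_order` object
#' @return character scalar
#' @export
format_gene_order <- function(x) {
  paste(paste(x$order$name, x$order$orient, sep = ","), collapse = ";")
}

#' @rdname format_gene_order
#' @param s serialized signature string
#' @export
parse_gene_order <- function(s) {
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ",", fixed = TRUE)
  ord <- data.frame(name = vapply(parts, `[`, character(1), 1L),
                    orient = vapply(parts, `[`, character(1), 2L),
                    stringsAsFactors = FALSE)
  canonicalize_order(ord)
}

# Signed circular adjacency set. Each edge (a,sa)->(b,sb) is identified with
# its mirror (b,-sb)->(a,-sa); the canonical string form makes the set
# comparable across readings.
adjacency_set <- function(ord) {
  n <- nrow(ord)
  nxt <- c(2:n, 1L)
  flip <- c("+" = "-", "-" = "+")
  vapply(seq_len(n), function(i) {
    a <- paste0(ord$name[i], ord$orient[i], ">", ord$name[nxt[i]], ord$orient[nxt[i]])
    b <- paste0(ord$name[nxt[i]], flip[ord$orient[nxt[i]]], ">",
                ord$name[i], flip[ord$orient[i]])
    min(a, b)
  }, character(1))
}

#' Breakpoint distance between two gene orders
#'
#' The number of signed circular adjacencies of `a` absent from `b`
#' (duplicated copies are collapsed first). Symmetric; zero iff the signed
#' circular permutations coincide up to rotation and full reversal.
#'
#' @param a,b `gene_order` objects over the same label universe
#' @return non-negative integer
#' @export
breakpoint_distance <- function(a, b) {
  la <- a$order$name
  lb <- b$order$name
  only_a <- setdiff(la, lb)
  only_b <- setdiff(lb, la)
  if (length(only_a) || length(only_b)) {
    stop("label universes differ: ",
         if (length(only_a)) paste0("only in a: ", paste(only_a, collapse = ",")),
         if (length(only_a) && length(only_b)) "; ",
         if (length(only_b)) paste0("only in b: ", paste(only_b, collapse = ",")))
  }
  sa <- adjacency_set(a$order)
  sb <- adjacency_set(b$order)
  length(setdiff(sa, sb))
}

orders_match <- function(sig, ref, tolerate_nd6 = FALSE) {
  a <- sig$order
  b <- ref$order
  if (nrow(a) != nrow(b)) return(FALSE)
  if (!identical(a$name, b$name)) return(FALSE)
  same <- a$orient == b$orient
  if (tolerate_nd6) same[a$name == "ND6"] <- TRUE
  all(same)
}

#' Classify a gene-order signature into arrangement types
#'
#' Matches the signature against the A/B/B'/C reference orders. For the
#' derived types the orientation of ND6 is tolerated either way (the
#' inversion status of the translocated ND6 is matched leniently, with a
#' note in the evidence). Anything else is "novel", reported with the
#' nearest type by breakpoint distance and the differing adjacencies.
#'
#' @param sig a `gene_order` signature
#' @return list with `type` ("A", "B", "B'", "C" or "novel"), `nearest`,
#'   `distance`, and `evidence` (character vector)
#' @export
classify_gene_order <- function(sig) {
  sig <- canonicalize_order(sig$order, sig$duplications)
  types <- c("A", "B", "B'", "C")
  refs <- lapply(types, reference_gene_order)
  names(refs) <- types
  trnC_copies <- unname(sig$duplications["trnC"])
  trnC_copies <- if (is.na(trnC_copies) || is.null(trnC_copies)) 1L else trnC_copies
  for (ty in types) {
    tol <- ty != "A"
    if (orders_match(sig, refs[[ty]], tolerate_nd6 = tol)) {
      want3 <- ty == "B'"
      if ((want3 && trnC_copies >= 3L) || (!want3 && trnC_copies == 1L)) {
        evid <- paste0("matches ", ty, "-type junction pattern")
        if (tol && !identical(sig$order$orient[sig$order$name == "ND6"],
                              refs[[ty]]$order$orient[refs[[ty]]$order$name == "ND6"])) {
          evid <- c(evid, "ND6 orientation differs from reference; tolerated")
        }
        return(list(type = ty, nearest = ty, distance = 0L, evidence = evid))
      }
      # order matches B but trnC copy number says B' (or vice versa)
      ty2 <- if (trnC_copies >= 3L) "B'" else ty
      return(list(type = ty2, nearest = ty2, distance = 0L,
                  evidence = paste0("order matches ", ty, "; trnC copies = ",
                                    trnC_copies)))
    }
  }
  d <- vapply(refs, function(r) breakpoint_distance(sig, r), integer(1))
  nearest <- types[which.min(d)]
  diff_adj <- setdiff(adjacency_set(sig$order),
                      adjacency_set(refs[[nearest]]$order))
  list(type = "novel", nearest = nearest, distance = unname(min(d)),
       evidence = paste0("adjacency not in ", nearest, ": ", diff_adj))
}
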