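# Ka/Ks by Nei-Gojobori counting under the invertebrate mitochondrial code
# (translation table 5), with Jukes-Cantor correction.
#
# Site counting: for a sense codon, each of the 9 single-nucleotide changes
# is classified synonymous/nonsynonymous; changes creating a stop codon are
# excluded from the denominator, and S = 3 * syn/(9 - stops), N = 3 - S.
# Differences: all mutational pathways between two codons that avoid stop
# intermediates are enumerated and averaged with equal weight.

NUC <- c("A", "C", "G", "T")

codon_neighbors <- function(codon) {
  ch <- seq_chars(codon)
  out <- character(0)
  for (pos in 1:3) {
    for (b in setdiff(NUC, ch[pos])) {
      x <- ch
      x[pos] <- b
      out <- c(out, paste(x, collapse = ""))
    }
  }
  out
}

#' Synonymous and nonsynonymous site counts of one codon
#'
#' @param codon a sense codon (A/C/G/T triplet) under translation table 5
#' @return named numeric vector c(S, N) with S + N = 3
#' @export
#' @examples
#' ng86_sites("TTT")  # S = 1/3: only TTT->TTC is synonymous under table 5
ng86_sites <- function(codon) {
  codon <- toupper(codon)
  if (!codon %in% names(genetic_code5())) stop("not a codon: ", codon)
  if (codon %in% stop_codons5()) stop("stop codon has no NG86 sites: ", codon)
  aa <- translate_codon5(codon)
  nb <- codon_neighbors(codon)
  nb_aa <- translate_codon5(nb)
  nonstop <- nb_aa != "*"
  syn <- sum(nb_aa[nonstop] == aa)
  S <- 3 * syn / sum(nonstop)
  c(S = S, N = 3 - S)
}

# Cached per-codon site counts and per-codon-pair averaged difference counts.
ng86_tables <- function() {
  if (!is.null(.mc_env$ng86)) return(.mc_env$ng86)
  sense <- sense_codons5()
  sites <- t(vapply(sense, ng86_sites, numeric(2)))
  k <- length(sense)
  Sd <- matrix(0, k, k, dimnames = list(sense, sense))
  Nd <- matrix(0, k, k, dimnames = list(sense, sense))
  ok <- matrix(TRUE, k, k, dimnames = list(sense, sense))
  stops <- stop_codons5()
  gc5 <- genetic_code5()
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      a <- seq_chars(sense[i]); b <- seq_chars(sense[j])
      diff_pos <- which(a != b)
      paths <- perms(diff_pos)
      sd_tot <- 0; nd_tot <- 0; valid <- 0L
      for (p in seq_len(nrow(paths))) {
        cur <- a
        sd <- 0L; nd <- 0L
        blocked <- FALSE
        for (pos in paths[p, ]) {
          nxt <- cur
          nxt[pos] <- b[pos]
          ccur <- paste(cur, collapse = ""); cnxt <- paste(nxt, collapse = "")
          if (cnxt %in% stops) { blocked <- TRUE; break }
          if (gc5[[ccur]] == gc5[[cnxt]]) sd <- sd + 1L else nd <- nd + 1L
          cur <- nxt
        }
        if (!blocked) {
          sd_tot <- sd_tot + sd; nd_tot <- nd_tot + nd; valid <- valid + 1L
        }
      }
      if (valid == 0L) {
        ok[i, j] <- FALSE
      } else {
        Sd[i, j] <- sd_tot / valid
        Nd[i, j] <- nd_tot / valid
      }
    }
  }
  .mc_env$ng86 <- list(sense = sense, sites = sites, Sd = Sd, Nd = Nd, ok = ok)
  .mc_env$ng86
}

perms <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1L))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- perms(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise Ka/Ks for two aligned coding sequences
#'
#' Nei-Gojobori counting with equal-weight pathway averaging and
#' Jukes-Cantor correction. Codon pairs containing a gap ('-') or ambiguous
#' base are skipped pairwise; codon pairs whose every mutational pathway
#' passes through a stop codon are skipped with a counter; a terminal stop
#' codon is trimmed.
#'
#' @param cds1,cds2 equal-length nucleotide strings (in-frame alignment)
#' @return object of class `kaks_result`: list with S, N, Sd, Nd, pS, pN,
#'   Ks, Ka, ratio (NA when Ks is zero or undefined), codons_compared,
#'   codons_skipped
#' @export
pairwise_kaks <- function(cds1, cds2) {
  cds1 <- toupper(cds1); cds2 <- toupper(cds2)
  if (nchar(cds1) != nchar(cds2)) {
    stop("aligned coding sequences must have equal length (",
         nchar(cds1), " vs ", nchar(cds2), ")")
  }
  r <- nchar(cds1) %% 3L
  if (r > 0L) {
    warning("alignment length not a multiple of 3; trailing ", r,
            " nt dropped", call. = FALSE)
    cds1 <- substr(cds1, 1L, nchar(cds1) - r)
    cds2 <- substr(cds2, 1L, nchar(cds2) - r)
  }
  nc <- nchar(cds1) %/% 3L
  c1 <- substring(cds1, 3L * seq_len(nc) - 2L, 3L * seq_len(nc))
  c2 <- substring(cds2, 3L * seq_len(nc) - 2L, 3L * seq_len(nc))
  tb <- ng86_tables()
  stops <- stop_codons5()
  # trim terminal stops (complete stop codons at the end of either sequence)
  while (nc > 0L && (c1[nc] %in% stops || c2[nc] %in% stops)) {
    c1 <- c1[-nc]; c2 <- c2[-nc]; nc <- nc - 1L
  }
  S <- 0; N <- 0; Sd <- 0; Nd <- 0
  used <- 0L; skipped <- 0L
  for (i in seq_len(nc)) {
    a <- c1[i]; b <- c2[i]
    if (grepl("[^ACGT]", a) || grepl("[^ACGT]", b) ||
        a %in% stops || b %in% stops) {
      skipped <- skipped + 1L
      next
    }
    if (a != b && !tb$ok[a, b]) {
      skipped <- skipped + 1L
      next
    }
    S <- S + (tb$sites[a, "S"] + tb$sites[b, "S"]) / 2
    N <- N + (tb$sites[a, "N"] + tb$sites[b, "N"]) / 2
    if (a != b) {
      Sd <- Sd + tb$Sd[a, b]
      Nd <- Nd + tb$Nd[a, b]
    }
    used <- used + 1L
  }
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  Ks <- jc_correct(pS)
  Ka <- jc_correct(pN)
  ratio <- if (!is.na(Ks) && !is.na(Ka) && Ks > 0) Ka / Ks else NA_real_
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 Ks = Ks, Ka = Ka, ratio = ratio,
                 codons_compared = used, codons_skipped = skipped),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("<kaks_result> %d codons (%d skipped)\n",
              x$codons_compared, x$codons_skipped))
  cat(sprintf("  S=%.2f N=%.2f  Sd=%.2f Nd=%.2f\n", x$S, x$N, x$Sd, x$Nd))
  cat(sprintf("  Ks=%s Ka=%s  Ka/Ks=%s\n",
              format(x$Ks, digits = 4), format(x$Ka, digits = 4),
              format(x$ratio, digits = 4)))
  invisible(x)
}

#' Group summaries of Ka/Ks ratios
#'
#' Mean and standard deviation of the defined ratios within each group;
#' undefined ratios are excluded and counted.
#'
#' @param results data.frame with a `ratio` column (e.g. rows built from
#'   [pairwise_kaks()] outputs) and the grouping column
#' @param by name of the grouping column
#' @return data.frame (group, mean_ratio, sd_ratio, n, n_undefined)
#' @export
group_kaks <- function(results, by) {
  if (!by %in% names(results)) stop("grouping column '", by, "' not found")
  if (!"ratio" %in% names(results)) stop("results must have a 'ratio' column")
  groups <- split(results$ratio, results[[by]])
  rows <- lapply(names(groups), function(g) {
    v <- groups[[g]]
    def <- v[!is.na(v)]
    data.frame(group = g,
               mean_ratio = if (length(def)) mean(def) else NA_real_,
               sd_ratio = if (length(def) > 1L) stats::sd(def) else
                 if (length(def) == 1L) 0 else NA_real_,
               n = length(def), n_undefined = sum(is.na(v)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Ka/Ks over genes of two annotated records
#'
#' Extracts each requested PCG from both records in reading orientation
#' (requiring equal lengths: alignment is the caller's job for indel pairs)
#' and runs [pairwise_kaks()].
#'
#' @param rec1,rec2 [mitogenome()] records with sequence
#' @param genes PCG names (default: the 13 canonical PCGs present in both)
#' @return data.frame with one row per gene plus strand class and the
#'   `kaks_result` fields
#' @export
kaks_by_gene <- function(rec1, rec2, genes = NULL) {
  if (is.null(genes)) {
    genes <- intersect(intersect(PCG_NAMES, rec1$features$name),
                       rec2$features$name)
  }
  rows <- lapply(genes, function(g) {
    s1 <- extract_gene_sequence(rec1, g)
    s2 <- extract_gene_sequence(rec2, g)
    if (nchar(s1) != nchar(s2)) {
      warning("gene ", g, " lengths differ (", nchar(s1), " vs ", nchar(s2),
              "); skipped — align first", call. = FALSE)
      return(NULL)
    }
    k <- pairwise_kaks(s1, s2)
    data.frame(gene = g,
               strand_class = if (g %in% MAJOR_PCGS) "major" else "minor",
               S = k$S, N = k$N, Sd = k$Sd, Nd = k$Nd,
               Ka = k$Ka, Ks = k$Ks, ratio = k$ratio,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
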