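# Annotated circular mitogenomes: construction, validation, and I/O.
#
# Coordinates are 1-based inclusive throughout (GenBank convention), on the
# major strand -- the deposited strand, which in these genomes encodes ND2,
# COI-COIII, ATP6/8, ND3, ND6 and CytB. Minor-strand features are flagged,
# never stored reverse-complemented.

TRNA_LETTERS <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "M",
                  "F", "P", "T", "W", "Y", "V", "K",
                  "L1", "L2", "S1", "S2")

#' Canonical mitochondrial gene labels
#'
#' The controlled vocabulary used by every module: 13 protein-coding genes,
#' 22 tRNAs (two each for leucine and serine), two rRNAs, and the A+T-rich
#' control region.
#'
#' @return character vector of 38 labels
#' @export
canonical_gene_set <- function() {
  c("ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6",
    "COI", "COII", "COIII", "ATP6", "ATP8", "CytB",
    paste0("trn", TRNA_LETTERS), "srRNA", "lrRNA", "AT_rich")
}

PCG_NAMES <- c("ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6",
               "COI", "COII", "COIII", "ATP6", "ATP8", "CytB")
MAJOR_PCGS <- c("ND2", "ND3", "ND6", "COI", "COII", "COIII",
                "ATP6", "ATP8", "CytB")
MINOR_PCGS <- c("ND1", "ND4", "ND4L", "ND5")

#' Normalize a GenBank-style gene label to the canonical vocabulary
#'
#' Maps the label chaos found in deposited records (COX1, cob, s-rRNA,
#' trnL(taa), 12S ribosomal RNA, D-loop, ...) onto [canonical_gene_set()].
#' Unrecognized labels are returned unchanged.
#'
#' @param x character vector of raw labels
#' @param quiet suppress the message logging nontrivial mappings
#' @return character vector of normalized labels
#' @export
normalize_gene_name <- function(x, quiet = FALSE) {
  raw <- x
  key <- toupper(gsub("[ _+-]", "", x))
  map <- c(
    COX1 = "COI", CO1 = "COI", COXI = "COI", COI = "COI",
    COX2 = "COII", CO2 = "COII", COXII = "COII", COII = "COII",
    COX3 = "COIII", CO3 = "COIII", COXIII = "COIII", COIII = "COIII",
    COB = "CytB", CYTB = "CytB", CYB = "CytB",
    NAD1 = "ND1", NAD2 = "ND2", NAD3 = "ND3", NAD4 = "ND4",
    NAD4L = "ND4L", NAD5 = "ND5", NAD6 = "ND6",
    ND1 = "ND1", ND2 = "ND2", ND3 = "ND3", ND4 = "ND4",
    ND4L = "ND4L", ND5 = "ND5", ND6 = "ND6",
    ATP6 = "ATP6", ATP8 = "ATP8", ATPASE6 = "ATP6", ATPASE8 = "ATP8",
    SRRNA = "srRNA", RRNS = "srRNA", "12S" = "srRNA", "12SRRNA" = "srRNA",
    "12SRIBOSOMALRNA" = "srRNA", SSURRNA = "srRNA",
    LRRNA = "lrRNA", RRNL = "lrRNA", "16S" = "lrRNA", "16SRRNA" = "lrRNA",
    "16SRIBOSOMALRNA" = "lrRNA", LSURRNA = "lrRNA",
    ATRICH = "AT_rich", ATRICHREGION = "AT_rich", DLOOP = "AT_rich",
    CONTROLREGION = "AT_rich"
  )
  out <- ifelse(key %in% names(map), unname(map[key]), raw)
  # tRNA forms: trnX, trnX(nnn), tRNA-Xxx, trnL1/trnL2/trnS1/trnS2
  trna_aa <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
               Glu = "E", Gln = "Q", Gly = "G", His = "H", Ile = "I",
               Met = "M", Phe = "F", Pro = "P", Thr = "T", Trp = "W",
               Tyr = "Y", Val = "V", Lys = "K", Leu = "L", Ser = "S")
  for (i in seq_along(out)) {
    lab <- out[i]
    m <- regmatches(lab, regexec("^(?:trn|tRNA-?)([A-Za-z]{1,3})([12])?(?:\\(([a-zA-Z]{3})\\))?$",
                                 lab))[[1]]
    if (length(m)) {
      aa <- m[2]
      if (nchar(aa) == 3L) aa <- unname(trna_aa[paste0(toupper(substr(aa, 1, 1)),
                                                       tolower(substr(aa, 2, 3)))])
      if (!is.na(aa) && nzchar(aa)) {
        suffix <- m[3]
        anticodon <- toupper(m[4])
        if (aa %in% c("L", "S") && !nzchar(suffix) && nzchar(anticodon)) {
          # disambiguate leucine/serine isotypes from the anticodon
          suffix <- if (aa == "L") {
            if (anticodon == "TAG") "1" else "2"
          } else {
            if (anticodon == "GCT") "1" else "2"
          }
        }
        cand <- paste0("trn", toupper(aa), suffix)
        if (cand %in% canonical_gene_set()) out[i] <- cand
      }
    }
  }
  changed <- which(out != raw)
  if (length(changed) && !quiet) {
    message("normalized gene labels: ",
            paste0(raw[changed], "->", out[changed], collapse = ", "))
  }
  out
}

validate_features <- function(features, genome_length) {
  req <- c("name", "ftype", "strand", "start", "end")
  missing_cols <- setdiff(req, names(features))
  if (length(missing_cols)) {
    stop("feature table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!all(features$ftype %in% c("PCG", "tRNA", "rRNA", "control"))) {
    stop("unknown ftype values: ",
         paste(unique(setdiff(features$ftype, c("PCG", "tRNA", "rRNA", "control"))),
               collapse = ", "))
  }
  if (!all(features$strand %in% c("major", "minor"))) {
    stop("strand must be 'major' or 'minor'")
  }
  if (any(features$start > features$end)) {
    bad <- features$name[features$start > features$end]
    stop("start > end for feature(s): ", paste(bad, collapse = ", "),
         " (origin-spanning features must use the two-part row convention)")
  }
  if (any(features$start < 1L) || any(features$end > genome_length)) {
    bad <- features$name[features$start < 1L | features$end > genome_length]
    stop("feature coordinates outside [1, genome_length] for: ",
         paste(bad, collapse = ", "))
  }
  if (sum(features$ftype == "control") > 1L) {
    stop("at most one control (A+T-rich) feature is allowed")
  }
  invisible(TRUE)
}

#' Construct an annotated mitogenome record
#'
#' The central container: a circular genome length, an ordered feature table,
#' and optionally the major-strand sequence. Deviations from the canonical
#' 37-gene + control-region content are reported as warnings, not errors, so
#' partial or rearranged genomes remain usable.
#'
#' @param record_id identifier
#' @param genome_length genome size in bp
#' @param features data.frame with columns name, ftype (PCG/tRNA/rRNA/control),
#'   strand (major/minor), start, end and optionally anticodon, start_codon,
#'   stop_codon, part
#' @param sequence optional major-strand nucleotide string (A/C/G/T/N)
#' @param organism optional organism name
#' @param circular logical; mitogenomes are circular
#' @param check_canonical warn when the feature set deviates from the 37+1
#'   canonical complement
#' @return an object of class `mitogenome`
#' @export
mitogenome <- function(record_id, genome_length, features, sequence = NULL,
                       organism = NA_character_, circular = TRUE,
                       check_canonical = TRUE) {
  stopifnot(is.numeric(genome_length), genome_length >= 1)
  genome_length <- as.integer(genome_length)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  for (col in c("anticodon", "start_codon", "stop_codon")) {
    if (is.null(features[[col]])) {
      features[[col]] <- rep(NA_character_, nrow(features))
    }
    features[[col]][!is.na(features[[col]]) & !nzchar(features[[col]])] <- NA_character_
  }
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  validate_features(features, genome_length)
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    if (nchar(sequence) != genome_length) {
      stop("sequence length (", nchar(sequence),
           ") does not equal genome_length (", genome_length, ")")
    }
    if (grepl("[^ACGTN]", sequence)) stop("sequence contains letters outside A/C/G/T/N")
  }
  if (check_canonical) {
    canon <- canonical_gene_set()
    missing <- setdiff(setdiff(canon, "AT_rich"), features$name)
    extra <- setdiff(features$name, canon)
    if (length(missing)) {
      warning("record ", record_id, " lacks canonical feature(s): ",
              paste(missing, collapse = ", "), call. = FALSE)
    }
    if (length(extra)) {
      warning("record ", record_id, " has non-canonical feature label(s): ",
              paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(record_id = as.character(record_id),
         organism = organism,
         genome_length = genome_length,
         circular = isTRUE(circular),
         sequence = sequence,
         features = features[order(features$start, features$end), , drop = FALSE]),
    class = "mitogenome"
  )
}

#' @export
print.mitogenome <- function(x, ...) {
  cat("<mitogenome> ", x$record_id,
      if (!is.na(x$organism)) paste0(" (", x$organism, ")"), "\n", sep = "")
  cat("  length: ", x$genome_length, " bp",
      if (x$circular) ", circular", "\n", sep = "")
  cat("  features: ", nrow(x$features),
      " (", sum(x$features$ftype == "PCG"), " PCG, ",
      sum(x$features$ftype == "tRNA"), " tRNA, ",
      sum(x$features$ftype == "rRNA"), " rRNA, ",
      sum(x$features$ftype == "control"), " control)\n", sep = "")
  cat("  sequence: ", if (is.null(x$sequence)) "absent" else "present", "\n", sep = "")
  invisible(x)
}

#' Read a mitogenome from a feature-table TSV
#'
#' The table format is tab-delimited with `#key=value` header lines
#' (`#genome_length=<N>` at minimum; `record_id`, `organism`, `circular` are
#' honoured) followed by a column-header row and one row per feature. When
#' `#genome_length` is absent it is inferred as `max(end)`.
#'
#' @param tsv path to the feature table
#' @param fasta optional path to a FASTA file holding the major-strand
#'   sequence; its length must agree with the declared genome length
#' @return a [mitogenome()] record
#' @export
read_feature_table <- function(tsv, fasta = NULL) {
  lines <- readLines(tsv, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(.*)$", h))[[1]]
    if (length(kv) == 3L) meta[[kv[2]]] <- trimws(kv[3])
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(body)) stop("feature table ", tsv, " has no data rows")
  tab <- utils::read.table(text = body, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           fill = TRUE, colClasses = "character")
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  tab$strand <- ifelse(tab$strand %in% c("+", "major"), "major",
                       ifelse(tab$strand %in% c("-", "minor"), "minor", tab$strand))
  part <- tab$part %||% rep(NA_character_, nrow(tab))
  dup <- tab$name[duplicated(paste(tab$name, part))]
  if (length(dup)) stop("duplicate feature name(s) without distinct 'part' tag: ",
                        paste(unique(dup), collapse = ", "))
  genome_length <- as.integer(meta$genome_length %||% max(tab$end))
  sequence <- NULL
  if (!is.null(fasta)) {
    ss <- Biostrings::readDNAStringSet(fasta)
    if (length(ss) != 1L) stop("FASTA must contain exactly one sequence")
    sequence <- as.character(ss[[1]])
    if (nchar(sequence) != genome_length) {
      stop("FASTA length (", nchar(sequence),
           ") does not match declared genome_length (", genome_length, ")")
    }
  }
  mitogenome(record_id = meta$record_id %||% basename(tsv),
             organism = meta$organism %||% NA_character_,
             genome_length = genome_length,
             circular = tolower(meta$circular %||% "true") %in% c("true", "yes", "1"),
             features = tab, sequence = sequence)
}

#' Write a mitogenome's annotation to a feature-table TSV
#'
#' Inverse of [read_feature_table()]: field-for-field round trips.
#'
#' @param rec a [mitogenome()] record
#' @param path output path
#' @return `path`, invisibly
#' @export
write_feature_table <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#genome_length=", rec$genome_length),
    paste0("#record_id=", rec$record_id),
    if (!is.na(rec$organism)) paste0("#organism=", rec$organism),
    paste0("#circular=", tolower(as.character(rec$circular)))
  ), con)
  cols <- c("name", "ftype", "strand", "start", "end",
            "anticodon", "start_codon", "stop_codon")
  tab <- rec$features[, cols]
  for (col in c("anticodon", "start_codon", "stop_codon")) {
    tab[[col]][is.na(tab[[col]])] <- ""
  }
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a record's sequence to FASTA
#'
#' @param rec a [mitogenome()] record with sequence
#' @param path output path
#' @return `path`, invisibly
#' @export
write_record_fasta <- function(rec, path) {
  if (is.null(rec$sequence)) stop("record ", rec$record_id, " has no sequence")
  ss <- Biostrings::DNAStringSet(rec$sequence)
  names(ss) <- rec$record_id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# ---- GenBank flat-file parsing -------------------------------------------

parse_gb_location <- function(loc, lineno) {
  loc0 <- loc
  strand <- "major"
  if (grepl("^complement\\(", loc)) {
    strand <- "minor"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  } else {
    parts <- loc
  }
  spans <- lapply(parts, function(p) {
    p <- gsub("[<>]", "", p)
    m <- regmatches(p, regexec("^(\\d+)\\.\\.(\\d+)$", p))[[1]]
    if (length(m) == 3L) return(c(as.integer(m[2]), as.integer(m[3])))
    m1 <- regmatches(p, regexec("^(\\d+)$", p))[[1]]
    if (length(m1) == 2L) return(rep(as.integer(m1[2]), 2L))
    stop("malformed GenBank location '", loc0, "' at line ", lineno)
  })
  list(strand = strand,
       start = min(vapply(spans, `[`, integer(1), 1L)),
       end = max(vapply(spans, `[`, integer(1), 2L)))
}

#' Read an annotated mitogenome from a GenBank flat file
#'
#' A minimal parser for the LOCUS/FEATURES/ORIGIN sections of a GenBank
#' record. CDS, tRNA, rRNA, D-loop and misc_feature entries are mapped to
#' features (bare `gene` entries that duplicate a typed feature are skipped);
#' `complement(...)` locations become minor-strand features; gene labels are
#' passed through [normalize_gene_name()].
#'
#' @param path path to the GenBank file
#' @return a [mitogenome()] record
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (!length(locus_i)) stop("not a GenBank flat file (no LOCUS line): ", path)
  locus <- strsplit(trimws(lines[locus_i[1]]), "\\s+")[[1]]
  record_id <- locus[2]
  genome_length <- suppressWarnings(as.integer(locus[3]))
  if (is.na(genome_length)) stop("malformed LOCUS line at line ", locus_i[1])
  circular <- any(grepl("circular", lines[locus_i[1]], ignore.case = TRUE))
  organism <- NA_character_
  org_i <- grep("^\\s{2}ORGANISM", lines)
  if (length(org_i)) organism <- trimws(sub("^\\s*ORGANISM\\s*", "", lines[org_i[1]]))

  feat_i <- grep("^FEATURES", lines)
  origin_i <- grep("^ORIGIN", lines)
  end_i <- grep("^//", lines)
  feats <- list()
  if (length(feat_i) && min(c(origin_i, end_i, length(lines) + 1L)) > feat_i[1] + 1L) {
    stop_at <- min(c(origin_i, end_i, length(lines) + 1L))
    block <- lines[(feat_i[1] + 1L):(stop_at - 1L)]
    linenos <- (feat_i[1] + 1L):(stop_at - 1L)
    # split into feature entries: a new entry starts with a key in column 6
    starts <- grep("^\\s{5}\\S", block)
    if (length(starts)) {
      bounds <- c(starts, length(block) + 1L)
      for (k in seq_along(starts)) {
        entry <- block[bounds[k]:(bounds[k + 1L] - 1L)]
        first <- strsplit(trimws(entry[1]), "\\s+")[[1]]
        key <- first[1]
        loc <- paste(first[-1], collapse = "")
        # continuation lines before the first qualifier extend the location
        quals_start <- grep("^\\s{21}/", entry)
        loc_cont <- setdiff(seq_along(entry)[-1],
                            if (length(quals_start)) quals_start[1]:length(entry) else integer(0))
        if (length(loc_cont)) loc <- paste0(loc, paste(trimws(entry[loc_cont]), collapse = ""))
        qual_lines <- trimws(entry[grepl("^\\s{21}/", entry)])
        getq <- function(q) {
          hit <- grep(paste0("^/", q, "="), qual_lines, value = TRUE)
          if (!length(hit)) return(NA_character_)
          gsub("\"", "", sub(paste0("^/", q, "="), "", hit[1]))
        }
        if (!key %in% c("CDS", "tRNA", "rRNA", "misc_feature", "D-loop")) next
        locp <- parse_gb_location(loc, linenos[bounds[k]])
        raw_name <- getq("gene")
        if (is.na(raw_name)) raw_name <- getq("product")
        if (is.na(raw_name)) raw_name <- getq("note")
        if (is.na(raw_name) && key == "D-loop") raw_name <- "D-loop"
        if (is.na(raw_name)) next
        ftype <- switch(key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                        misc_feature = "control", `D-loop` = "control")
        if (key == "misc_feature" &&
            !grepl("A\\+?T|control|D-loop", raw_name, ignore.case = TRUE)) next
        feats[[length(feats) + 1L]] <- data.frame(
          name = normalize_gene_name(raw_name, quiet = TRUE),
          ftype = ftype, strand = locp$strand,
          start = locp$start, end = locp$end,
          anticodon = NA_character_,
          start_codon = NA_character_, stop_codon = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(feats)) {
    warning("GenBank record ", record_id, " yielded no features", call. = FALSE)
    features <- data.frame(name = character(), ftype = character(),
                           strand = character(), start = integer(),
                           end = integer(), anticodon = character(),
                           start_codon = character(), stop_codon = character(),
                           stringsAsFactors = FALSE)
  } else {
    features <- do.call(rbind, feats)
  }

  sequence <- NULL
  if (length(origin_i) && (if (length(end_i[end_i > origin_i[1]]))
      min(end_i[end_i > origin_i[1]]) else length(lines) + 1L) > origin_i[1] + 1L) {
    stop_at <- if (length(end_i[end_i > origin_i[1]]))
      min(end_i[end_i > origin_i[1]]) else length(lines) + 1L
    seq_lines <- lines[(origin_i[1] + 1L):(stop_at - 1L)]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    if (!nzchar(sequence)) sequence <- NULL
  }
  if (nrow(features) && any(features$end > genome_length)) {
    bad <- features$name[features$end > genome_length]
    stop("feature(s) beyond declared sequence length: ", paste(bad, collapse = ", "))
  }
  mitogenome(record_id = record_id, organism = organism,
             genome_length = genome_length, circular = circular,
             features = features, sequence = sequence,
             check_canonical = nrow(features) > 0L)
}

#' Extract a gene's sequence in reading orientation
#'
#' Minor-strand features are reverse-complemented so that the returned string
#' reads 5' to 3' in the direction of transcription.
#'
#' @param rec a [mitogenome()] record with sequence
#' @param name a feature name present in the record
#' @return nucleotide string
#' @export
extract_gene_sequence <- function(rec, name) {
  if (is.null(rec$sequence)) stop("record ", rec$record_id, " has no sequence")
  i <- which(rec$features$name == name)
  if (!length(i)) stop("unknown gene '", name, "' in record ", rec$record_id)
  f <- rec$features[i[1], ]
  s <- substr(rec$sequence, f$start, f$end)
  if (f$strand == "minor") s <- revcomp(s)
  s
}

#' Rotate the origin of a circular record
#'
#' Moves the origin so that the old position `offset + 1` becomes position 1.
#' The cut point must not fall inside any feature (origin-spanning features
#' are not produced); the genomes handled here always have intergenic points
#' to cut at.
#'
#' @param rec a [mitogenome()] record
#' @param offset integer in `[0, genome_length)`
#' @return the rotated record
#' @export
rotate_mitogenome <- function(rec, offset) {
  offset <- as.integer(offset) %% rec$genome_length
  if (offset == 0L) return(rec)
  inside <- rec$features$start <= offset & rec$features$end > offset
  if (any(inside)) {
    stop("rotation cut point ", offset, " falls inside feature(s): ",
         paste(rec$features$name[inside], collapse = ", "))
  }
  f <- rec$features
  shift <- function(p) ((p - offset - 1L) %% rec$genome_length) + 1L
  f$start <- shift(f$start)
  f$end <- shift(f$end)
  seq2 <- NULL
  if (!is.null(rec$sequence)) {
    seq2 <- paste0(substr(rec$sequence, offset + 1L, rec$genome_length),
                   substr(rec$sequence, 1L, offset))
  }
  suppressWarnings(
    mitogenome(rec$record_id, rec$genome_length, f, sequence = seq2,
               organism = rec$organism, circular = rec$circular,
               check_canonical = FALSE)
  )
}

#' Packaged example mitogenome annotations
#'
#' Loads one of the three bundled flatid planthopper coordinate tables:
#' *Metcalfa pruinosa* haplotypes H1 and H3 and *Salurnis marginella*
#' (coordinates only; the deposited sequences are not redistributed).
#'
#' @param which one of "Mpruinosa_H1", "Mpruinosa_H3", "Smarginella"
#' @return a [mitogenome()] record without sequence
#' @export
#' @examples
#' h1 <- example_mitogenome("Mpruinosa_H1")
#' h1
example_mitogenome <- function(which = c("Mpruinosa_H1", "Mpruinosa_H3",
                                         "Smarginella")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0(which, ".tsv"), package = "mitocomp",
                      mustWork = TRUE)
  read_feature_table(path)
}

#' Feature lengths of a record
#'
#' @param rec a [mitogenome()] record
#' @return named integer vector of `end - start + 1` per feature
#' @export
feature_lengths <- function(rec) {
  stats::setNames(rec$features$end - rec$features$start + 1L, rec$features$name)
}
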