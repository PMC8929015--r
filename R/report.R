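# Multi-record summaries and manifest-driven orchestration of the analyses.

at_or_na <- function(rec, span_names) {
  if (is.null(rec$sequence)) return(NA_real_)
  f <- rec$features[rec$features$name %in% span_names, , drop = FALSE]
  if (!nrow(f)) return(NA_real_)
  s <- paste(substring(rec$sequence, f$start, f$end), collapse = "")
  attr(base_content(s), "AT")
}

#' Genome-characteristics summary table
#'
#' One row per record: genome size and A+T content, PCG codon count (from
#' coordinates, via [expected_codon_total()]), and per-class sizes and A+T
#' content for srRNA, lrRNA, the tRNA set and the A+T-rich region. A+T
#' columns are `NA` when the record carries no sequence; size columns need
#' coordinates only. Sizes are plain integers (no thousands separators).
#'
#' @param recs list of [mitogenome()] records
#' @return data.frame, empty when `recs` is empty
#' @export
summarize_table1 <- function(recs) {
  cols <- c("taxon", "size_bp", "AT_pct", "pcg_codons",
            "srRNA_bp", "srRNA_AT", "lrRNA_bp", "lrRNA_AT",
            "trna_bp", "trna_AT", "atrich_bp", "atrich_AT")
  if (!length(recs)) {
    out <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
    return(out)
  }
  rows <- lapply(recs, function(rec) {
    f <- rec$features
    len_of <- function(nm) {
      i <- which(f$name == nm)
      if (!length(i)) NA_integer_ else f$end[i[1]] - f$start[i[1]] + 1L
    }
    trna <- f[f$ftype == "tRNA", ]
    ctrl <- f[f$ftype == "control", ]
    data.frame(
      taxon = if (!is.na(rec$organism)) rec$organism else rec$record_id,
      size_bp = rec$genome_length,
      AT_pct = if (is.null(rec$sequence)) NA_real_ else
        attr(base_content(rec$sequence), "AT"),
      pcg_codons = expected_codon_total(rec),
      srRNA_bp = len_of("srRNA"), srRNA_AT = at_or_na(rec, "srRNA"),
      lrRNA_bp = len_of("lrRNA"), lrRNA_AT = at_or_na(rec, "lrRNA"),
      trna_bp = if (nrow(trna)) sum(trna$end - trna$start + 1L) else NA_integer_,
      trna_AT = at_or_na(rec, trna$name),
      atrich_bp = if (nrow(ctrl)) sum(ctrl$end - ctrl$start + 1L) else NA_integer_,
      atrich_AT = at_or_na(rec, ctrl$name),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

write_tsv_report <- function(df, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.known_analyses <- c("composition", "spacers", "order_classify",
                     "motif_scan", "control_region", "summarize")

run_one_analysis <- function(rec, analysis, params) {
  switch(analysis,
    composition = composition_report(rec),
    spacers = {
      rep <- adjacency_report(rec)
      rep$pairs
    },
    order_classify = {
      cl <- classify_gene_order(gene_order_signature(rec))
      data.frame(record = rec$record_id, type = cl$type, nearest = cl$nearest,
                 distance = cl$distance,
                 evidence = paste(cl$evidence, collapse = "; "),
                 stringsAsFactors = FALSE)
    },
    motif_scan = {
      h <- do.call(scan_junction, c(list(rec = rec), params))
      cbind(record = rec$record_id, as.data.frame(h))
    },
    control_region = {
      arch <- region_architecture(rec)
      arch$segments
    },
    summarize = summarize_table1(list(rec)),
    stop("unknown analysis '", analysis, "'"))
}

#' Run a manifest of analyses over a set of records
#'
#' The manifest lists input record paths (feature tables or GenBank files)
#' and an ordered set of analyses with parameters. Every requested analysis
#' is attempted; failures are recorded and the run continues for independent
#' analyses. A `manifest.json` with input/output md5 hashes is written so a
#' rerun is verifiably identical.
#'
#' @param manifest list with `inputs` (character paths), `analyses` (list of
#'   list(name, params)), and optionally `out_dir`
#' @param out_dir output directory (created; overrides `manifest$out_dir`)
#' @return invisibly, list with `outputs`, `errors`, `manifest_path`
#' @export
run_all <- function(manifest, out_dir = manifest$out_dir) {
  if (is.null(out_dir)) stop("manifest must name an output directory")
  nm <- vapply(manifest$analyses, function(a) a$name, character(1))
  bad <- setdiff(nm, .known_analyses)
  if (length(bad)) {
    stop("unknown analysis name(s): ", paste(bad, collapse = ", "),
         " (known: ", paste(.known_analyses, collapse = ", "), ")")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  recs <- lapply(manifest$inputs, function(p) {
    if (grepl("\\.(gb|gbk|genbank)$", p, ignore.case = TRUE)) read_genbank(p)
    else read_feature_table(p)
  })
  outputs <- character(0)
  errors <- list()
  for (rec in recs) {
    for (a in manifest$analyses) {
      out_path <- file.path(out_dir, paste0(rec$record_id, "_", a$name, ".tsv"))
      res <- tryCatch({
        df <- run_one_analysis(rec, a$name, a$params %||% list())
        write_tsv_report(df, out_path,
                         header = c(paste0("record=", rec$record_id),
                                    paste0("analysis=", a$name)))
        outputs <- c(outputs, out_path)
        NULL
      }, error = function(e) conditionMessage(e))
      if (!is.null(res)) {
        message("[run_all] ", rec$record_id, "/", a$name, " failed: ", res)
        errors[[paste0(rec$record_id, "_", a$name)]] <- res
      }
    }
  }
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(
    inputs = manifest$inputs,
    input_md5 = unname(tools::md5sum(manifest$inputs)),
    analyses = manifest$analyses,
    version = as.character(utils::packageVersion("mitocomp")),
    outputs = basename(outputs),
    output_md5 = unname(tools::md5sum(outputs)),
    errors = errors
  ), manifest_path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(list(outputs = outputs, errors = errors,
                 manifest_path = manifest_path))
}
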