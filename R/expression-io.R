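# Tabular IO: expression tables (genes x samples) with a sample sheet
# mapping samples to conditions and knockout annotations.  TSV is
# canonical; CSV accepted on read by extension.  Files may start with a
# "# eesnet-table-format: <version>" comment; readers reject unknown major
# versions and accept files without the marker.

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

read_table_checked <- function(path) {
  first <- readLines(path, n = 1)
  skip <- 0L
  if (startsWith(first, "#")) {
    ver <- sub("^#\\s*eesnet-table-format:\\s*", "", first)
    if (!identical(ver, first)) check_format_version(ver, basename(path))
    skip <- 1L
  }
  df <- utils::read.delim(path, sep = delim_for(path), skip = skip,
                          check.names = FALSE, stringsAsFactors = FALSE)
  df
}

#' Read an expression table and sample sheet into an expression dataset
#'
#' The expression table has a header row of sample ids and a first column
#' of gene ids; the sample sheet has columns `sample`, `condition`, and
#' optionally `knocked_out_genes` (semicolon-separated gene ids for mutant
#' conditions).  Samples are grouped into per-condition replicate matrices;
#' gene identity is by string id and column order is never semantic.
#'
#' @param table_path expression table (TSV canonical, CSV by extension).
#' @param sheet_path sample sheet TSV/CSV.
#' @param wildtype wildtype condition label (default "wildtype").
#' @return an [expression_dataset()].
#' @export
read_expression_table <- function(table_path, sheet_path,
                                  wildtype = "wildtype") {
  tab <- read_table_checked(table_path)
  sheet <- read_table_checked(sheet_path)
  if (!all(c("sample", "condition") %in% names(sheet))) {
    abort_eesnet("sample sheet needs columns 'sample' and 'condition'",
                 "eesnet_parse_error")
  }
  gene_ids <- as.character(tab[[1]])
  if (anyDuplicated(gene_ids)) {
    abort_eesnet("duplicate gene ids in expression table",
                 "eesnet_data_error")
  }
  samples <- names(tab)[-1]
  missing_in_sheet <- setdiff(samples, sheet$sample)
  missing_in_table <- setdiff(sheet$sample, samples)
  if (length(missing_in_sheet) || length(missing_in_table)) {
    abort_eesnet(
      paste0(
        "sample reconciliation failed.",
        if (length(missing_in_sheet)) {
          paste0(" In table only: ", paste(missing_in_sheet, collapse = ", "),
                 ".")
        } else "",
        if (length(missing_in_table)) {
          paste0(" In sheet only: ", paste(missing_in_table, collapse = ", "),
                 ".")
        } else ""
      ),
      "eesnet_reconciliation_error"
    )
  }
  for (s in samples) {
    col <- tab[[s]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1]
      abort_eesnet(
        sprintf("non-numeric cell at row %d, column '%s'", bad, s),
        "eesnet_parse_error"
      )
    }
  }
  conditions <- list()
  annotation <- list()
  for (cond in unique(sheet$condition)) {
    ss <- sheet$sample[sheet$condition == cond]
    mt <- as.matrix(tab[, ss, drop = FALSE])
    rownames(mt) <- gene_ids
    conditions[[cond]] <- mt
    if ("knocked_out_genes" %in% names(sheet)) {
      ko <- sheet$knocked_out_genes[sheet$condition == cond][1]
      if (!is.na(ko) && nzchar(ko)) {
        annotation[[cond]] <- strsplit(ko, ";", fixed = TRUE)[[1]]
      }
    }
  }
  expression_dataset(conditions, wildtype = wildtype,
                     knockout_annotation = annotation)
}

#' @rdname read_expression_table
#' @param data an [expression_dataset()] to write.
#' @export
write_expression_table <- function(data, table_path, sheet_path) {
  stopifnot(inherits(data, "expression_dataset"))
  cols <- list(gene = data$gene_ids)
  sheet_rows <- list()
  i <- 0L
  for (cond in names(data$conditions)) {
    mt <- data$conditions[[cond]]
    for (r in seq_len(ncol(mt))) {
      i <- i + 1L
      sample_id <- sprintf("%s_r%d", cond, r)
      cols[[sample_id]] <- format_num(mt[, r])
      ko <- data$knockout_annotation[[cond]]
      sheet_rows[[i]] <- data.frame(
        sample = sample_id, condition = cond,
        knocked_out_genes = if (is.null(ko)) "" else paste(ko, collapse = ";")
      )
    }
  }
  header <- paste0("# eesnet-table-format: ", FORMAT_VERSION)
  write_with_header <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    utils::write.table(df, con, sep = delim_for(path), quote = FALSE,
                       row.names = FALSE)
  }
  write_with_header(as.data.frame(cols, check.names = FALSE), table_path)
  write_with_header(do.call(rbind, sheet_rows), sheet_path)
  invisible(table_path)
}

#' Read a run configuration from YAML
#'
#' A run config bundles the seed, the network section (forwarded to
#' [network_config()]), the internal gene list (or "auto-candidates"),
#' tolerances, and output settings.  The parsed config is echoed into every
#' artifact the CLI writes.
#'
#' @param path YAML file.
#' @return a list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  tol <- cfg$tolerances %||% list()
  for (nm in names(tol)) {
    if (!is.numeric(tol[[nm]]) || tol[[nm]] <= 0) {
      abort_eesnet(sprintf("tolerance '%s' must be strictly positive", nm),
                   "eesnet_config_error")
    }
  }
  net_args <- cfg$network %||% list()
  net_args$seed <- cfg$seed
  if (!is.null(tol$viability_residual)) {
    net_args$viability_residual_tol <- tol$viability_residual
  }
  cfg$network_config <- do.call(network_config, net_args)
  cfg$internal_genes <- cfg$internal_genes %||% "auto-candidates"
  cfg$output_dir <- cfg$output_dir %||% "."
  structure(cfg, class = "run_config")
}
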