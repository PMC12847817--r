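#' Read a cell-by-feature count matrix
#'
#' Supports Matrix Market triplet format (a \code{.mtx} file with companion
#' \code{features.tsv} and \code{cells.tsv} id files in the same directory)
#' and a dense TSV (first column cell id, remaining columns features).
#'
#' @param path path to the \code{.mtx} file or the dense TSV
#' @param format one of \code{"mtx_triplet"}, \code{"dense_tsv"}
#' @param negprobe_prefix feature-name prefix marking negative probes
#' @param mask_file optional path to a one-column file of feature names that
#'   are negative probes, overriding the prefix rule
#' @return a \code{\link{count_matrix}}
#' @export
read_count_matrix <- function(path, format = c("mtx_triplet", "dense_tsv"),
                              negprobe_prefix = "NegPrb", mask_file = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mtx_triplet") {
    m <- tryCatch(Matrix::readMM(path),
                  error = function(e) stop("parse error in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
    dir <- dirname(path)
    ff <- file.path(dir, "features.tsv")
    cf <- file.path(dir, "cells.tsv")
    if (!file.exists(ff)) stop("companion file missing: ", ff)
    if (!file.exists(cf)) stop("companion file missing: ", cf)
    feats <- readLines(ff)
    cells <- readLines(cf)
    if (nrow(m) != length(cells) || ncol(m) != length(feats))
      stop("dimension mismatch between matrix and companion id files")
    dimnames(m) <- list(cells, feats)
  } else {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
  }
  mask <- NULL
  if (!is.null(mask_file)) {
    negnames <- readLines(mask_file)
    mask <- colnames(m) %in% negnames
  }
  count_matrix(m, negprobe_mask = mask, negprobe_prefix = negprobe_prefix)
}

#' Write a count matrix
#'
#' @param x a \code{\link{count_matrix}}
#' @param path output \code{.mtx} path (mtx_triplet) or TSV path (dense_tsv)
#' @param format output format, as in \code{\link{read_count_matrix}}
#' @return \code{path}, invisibly
#' @export
write_count_matrix <- function(x, path, format = c("mtx_triplet", "dense_tsv")) {
  format <- match.arg(format)
  if (format == "mtx_triplet") {
    Matrix::writeMM(x$counts, path)
    dir <- dirname(path)
    writeLines(rownames(x$counts), file.path(dir, "cells.tsv"))
    writeLines(colnames(x$counts), file.path(dir, "features.tsv"))
  } else {
    df <- data.frame(cell_id = rownames(x$counts),
                     as.matrix(x$counts), check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a per-cell metadata table (CSV or TSV by extension)
#'
#' @param path file path; \code{.tsv}/\code{.txt} read as TSV, otherwise CSV
#' @return validated cell table data.frame (see \code{\link{validate_cell_table}})
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  validate_cell_table(df)
}

#' Write a cell table as TSV
#' @param df cell table
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_cell_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ligand-receptor pair table
#'
#' Two-column TSV (CellTalkDB-style) with columns \code{ligand} and
#' \code{receptor} (header optional). Duplicate pairs are collapsed with a
#' warning.
#'
#' @param path file path
#' @return data.frame with columns ligand, receptor
#' @export
read_lr_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  header <- identical(tolower(first[1:2]), c("ligand", "receptor"))
  df <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  df <- df[, 1:2]
  names(df) <- c("ligand", "receptor")
  if (any(!nzchar(df$ligand)) || any(!nzchar(df$receptor)))
    stop("empty gene symbol in ligand-receptor table")
  dup <- duplicated(df)
  if (any(dup)) {
    warning(sum(dup), " duplicate ligand-receptor rows collapsed")
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description, then member gene symbols, tab-separated.
#'
#' @param path GMT file path
#' @return named list of character vectors; the description is kept in
#'   \code{attr(,"description")}
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t")
  nm <- vapply(parts, `[`, "", 1)
  if (anyDuplicated(nm)) stop("duplicate gene-set names in GMT")
  desc <- vapply(parts, `[`, "", 2)
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  if (any(lengths(sets) == 0)) {
    stop("empty gene set: ", paste(nm[lengths(sets) == 0], collapse = ", "))
  }
  names(sets) <- nm
  attr(sets, "description") <- stats::setNames(desc, nm)
  sets
}

#' Default run configuration with every analysis threshold
#'
#' Collects the QC, statistical and spatial parameter defaults plus pipeline
#' plumbing (seed, paths, output directory) in one auditable list.
#'
#' @return named list
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    simulate = TRUE,
    out_dir = "mucosaSMI_run",
    coords_global = FALSE,
    counts_path = NULL, cells_path = NULL, protein_path = NULL,
    lr_path = NULL, gmt_path = NULL, fluid_path = NULL,
    qc = qc_params(),
    stat = stat_params(),
    spatial = spatial_params(),
    sim = list()
  )
}

#' Read a run configuration (YAML or JSON), filling unspecified keys with
#' package defaults
#'
#' @param path config file; \code{.json} parsed as JSON, otherwise YAML
#' @param quiet suppress the message listing defaulted keys
#' @return full config list
#' @export
read_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  user <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  merge_config(user, quiet = quiet)
}

#' Merge a partial configuration over the package defaults
#' @param user named list of overrides (possibly nested)
#' @param quiet suppress the defaulted-keys message
#' @return full config list
#' @export
merge_config <- function(user = list(), quiet = FALSE) {
  cfg <- default_run_config()
  filled <- character()
  merge1 <- function(base, over, prefix = "") {
    for (k in union(names(base), names(over))) {
      if (!k %in% names(over)) {
        filled <<- c(filled, paste0(prefix, k))
      } else if (is.list(base[[k]]) && is.list(over[[k]])) {
        base[[k]] <- merge1(base[[k]], over[[k]], paste0(prefix, k, "."))
      } else {
        base[[k]] <- over[[k]]
      }
    }
    base
  }
  cfg <- merge1(cfg, user)
  if (!quiet && length(filled))
    message("config keys filled with defaults: ", paste(filled, collapse = ", "))
  cfg
}

#' Write a tabular result as TSV with a YAML sidecar recording config and seed
#'
#' @param df data.frame to write
#' @param path output TSV path; the sidecar is written to \code{<path>.yaml}
#' @param config run configuration to record (may be a sub-list)
#' @param seed seed to record
#' @return \code{path}, invisibly
#' @export
write_result_tsv <- function(df, path, config = NULL, seed = NULL) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(seed = seed, config = config)
  yaml::write_yaml(sidecar, paste0(path, ".yaml"))
  invisible(path)
}
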