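#' Read an expression matrix from disk
#'
#' Supports dense CSV/TSV (cells as rows, first column = cell id, header =
#' gene ids) and MatrixMarket MTX accompanied by one-id-per-line gene and
#' cell files. Inputs stored genes-as-rows can be transposed on read.
#'
#' @param path Matrix file.
#' @param format `"csv"`, `"tsv"` or `"mtx"`; `"auto"` guesses from the
#'   file extension.
#' @param genes_file,cells_file Identifier files (required for MTX): one id
#'   per line, order matching the matrix dimension.
#' @param transpose If `TRUE` the file stores genes x cells and is
#'   transposed to the package's cells x genes orientation.
#' @param cell_metadata Optional TSV path with per-cell metadata; the first
#'   column must be the cell id.
#' @return Validated expression matrix (dense for CSV/TSV, sparse
#'   `dgCMatrix` for MTX), with any metadata attached.
#' @export
read_expression <- function(path, format = c("auto", "csv", "tsv", "mtx"),
                            genes_file = NULL, cells_file = NULL,
                            transpose = FALSE, cell_metadata = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
                     stop("cannot guess format from extension of ", path))
  }
  if (format == "mtx") {
    if (is.null(genes_file) || is.null(cells_file)) {
      stop("MTX input requires genes_file and cells_file")
    }
    m <- Matrix::readMM(path)
    genes <- readLines(genes_file)
    cells <- readLines(cells_file)
    if (transpose) m <- Matrix::t(m)
    if (nrow(m) != length(cells)) {
      stop("matrix has ", nrow(m), " cells but cells_file lists ",
           length(cells))
    }
    if (ncol(m) != length(genes)) {
      stop("matrix has ", ncol(m), " genes but genes_file lists ",
           length(genes))
    }
    dimnames(m) <- list(cells, genes)
    m <- methods::as(m, "CsparseMatrix")
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- read.csv(path, sep = sep, row.names = 1L, check.names = FALSE)
    m <- as.matrix(df)
    storage.mode(m) <- "double"
    if (transpose) m <- t(m)
  }
  meta <- NULL
  if (!is.null(cell_metadata)) {
    meta <- read.delim(cell_metadata, stringsAsFactors = FALSE)
    ord <- match(rownames(m), meta[[1L]])
    if (anyNA(ord)) stop("cell metadata is missing ", sum(is.na(ord)), " cell id(s)")
    meta <- meta[ord, , drop = FALSE]
    rownames(meta) <- NULL
  }
  validate_matrix(m, cell_metadata = meta)
}

#' Write an expression matrix to disk
#'
#' @param x Validated expression matrix (cells x genes).
#' @param path Output file.
#' @param format `"csv"`, `"tsv"` or `"mtx"`.
#' @param genes_file,cells_file Identifier files to write (MTX only).
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, format = c("csv", "tsv", "mtx"),
                             genes_file = NULL, cells_file = NULL) {
  format <- match.arg(format)
  if (format == "mtx") {
    if (is.null(genes_file) || is.null(cells_file)) {
      stop("MTX output requires genes_file and cells_file")
    }
    Matrix::writeMM(methods::as(methods::as(x, "CsparseMatrix"), "generalMatrix"),
                    path)
    writeLines(colnames(x), genes_file)
    writeLines(rownames(x), cells_file)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- as.data.frame(.dense(x))
    utils::write.table(data.frame(cell_id = rownames(x), df,
                                  check.names = FALSE),
                       path, sep = sep, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read gene signatures from a GMT file
#'
#' Standard tab-separated GMT: name, description, then gene ids. Duplicate
#' genes within a line are removed with a warning; order is preserved.
#'
#' @param path GMT file.
#' @return Named list of `gene_signature` objects (empty list, with a
#'   warning, for an empty file).
#' @export
read_signatures_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("GMT file ", path, " is empty")
    return(list())
  }
  out <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop("GMT line ", i, " has fewer than 3 tab-separated fields")
    }
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("GMT line ", i, " ('", fields[1L], "'): duplicated genes removed")
      genes <- genes[!duplicated(genes)]
    }
    out[[fields[1L]]] <- gene_signature(fields[1L], genes)
  }
  out
}

#' Write gene signatures to a GMT file
#' @param signatures Named list of `gene_signature` objects or character
#'   vectors.
#' @param path Output file.
#' @param description Description field (recycled).
#' @return `path`, invisibly.
#' @export
write_signatures_gmt <- function(signatures, path, description = "na") {
  lines <- vapply(seq_along(signatures), function(i) {
    s <- .as_signature(signatures[[i]],
                       if (!is.null(names(signatures))) names(signatures)[i]
                       else paste0("signature_", i))
    paste(c(s$name, description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a score matrix with optional argmax annotation
#'
#' TSV layout: cells as rows, `cell_id` first, one column per signature at
#' full float precision (so downstream argmax is not perturbed by
#' rounding), plus `predicted` / `max_score` / `margin` columns when
#' annotation is requested.
#'
#' @param scores A `score_matrix`.
#' @param path Output TSV.
#' @param annotate Add argmax label, max score and margin columns.
#' @param truth Optional truth labels; when given together with `annotate`,
#'   a metrics JSON (balanced accuracy, weighted F1, confusion) is written
#'   next to `path` with suffix `.metrics.json`.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path, annotate = FALSE, truth = NULL) {
  df <- data.frame(cell_id = rownames(scores),
                   as.data.frame(unclass(scores)), check.names = FALSE)
  if (annotate) {
    pred <- argmax_labels(scores)
    mx <- apply(scores, 1L, max)
    second <- if (ncol(scores) >= 2L) {
      apply(scores, 1L, function(r) sort(r, decreasing = TRUE)[2L])
    } else mx
    df$predicted <- unname(pred)
    df$max_score <- unname(mx)
    df$margin <- unname(mx - second)
    if (!is.null(truth)) {
      res <- evaluate_labels(pred, truth)
      df$truth <- as.character(truth)
      jsonlite::write_json(
        list(balanced_accuracy = res$balanced_accuracy,
             weighted_f1 = res$weighted_f1,
             confusion = as.data.frame.matrix(res$confusion)),
        paste0(path, ".metrics.json"), auto_unbox = TRUE, digits = NA)
    }
  }
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Command-line scoring entry point
#'
#' Thin wrapper over [read_expression()], [read_signatures_gmt()],
#' [score_all()] and [write_scores()] for shell use; see
#' `inst/scripts/score_signatures.R`. Flags: `--matrix`, `--format`,
#' `--genes`, `--cells`, `--metadata`, `--signatures` (GMT),
#' `--method`, `--control-size`, `--n-bins`, `--max-rank`, `--seed`,
#' `--out`, `--annotate`, `--truth-col`, `--drop-overlap`, `--transpose`.
#'
#' @param args Character vector of command-line arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit code, invisibly (0 on success).
#' @export
cli_score <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!requireNamespace("optparse", quietly = TRUE)) {
    stop("the command-line entry point needs the 'optparse' package")
  }
  spec <- list(
    optparse::make_option("--matrix", type = "character"),
    optparse::make_option("--format", type = "character", default = "auto"),
    optparse::make_option("--genes", type = "character", default = NULL),
    optparse::make_option("--cells", type = "character", default = NULL),
    optparse::make_option("--metadata", type = "character", default = NULL),
    optparse::make_option("--signatures", type = "character"),
    optparse::make_option("--method", type = "character", default = "ans"),
    optparse::make_option("--control-size", type = "integer", default = 100L,
                          dest = "control_size"),
    optparse::make_option("--n-bins", type = "integer", default = 25L,
                          dest = "n_bins"),
    optparse::make_option("--max-rank", type = "integer", default = 1500L,
                          dest = "max_rank"),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--out", type = "character"),
    optparse::make_option("--annotate", action = "store_true", default = FALSE),
    optparse::make_option("--truth-col", type = "character", default = NULL,
                          dest = "truth_col"),
    optparse::make_option("--drop-overlap", action = "store_true",
                          default = FALSE, dest = "drop_overlap"),
    optparse::make_option("--transpose", action = "store_true", default = FALSE)
  )
  opt <- optparse::parse_args(optparse::OptionParser(option_list = spec),
                              args = args)
  if (is.null(opt$matrix) || is.null(opt$signatures) || is.null(opt$out)) {
    message("usage: score_signatures.R --matrix FILE --signatures FILE.gmt --out FILE.tsv")
    return(invisible(2L))
  }
  if (!opt$method %in% .SCORING_METHODS) {
    message("unknown method '", opt$method, "'; choose one of: ",
            paste(.SCORING_METHODS, collapse = ", "))
    return(invisible(2L))
  }
  if (opt$method %in% c("ucell", "jasmine_lh", "jasmine_or") &&
      "--control-size" %in% args) {
    warning("--control-size is ignored by method '", opt$method, "'")
  }
  status <- tryCatch({
    x <- read_expression(opt$matrix, format = opt$format,
                         genes_file = opt$genes, cells_file = opt$cells,
                         transpose = opt$transpose,
                         cell_metadata = opt$metadata)
    sigs <- read_signatures_gmt(opt$signatures)
    message("scoring ", length(sigs), " signature(s) on ", nrow(x),
            " cells x ", ncol(x), " genes with method=", opt$method,
            " (c=", opt$control_size, ", bins=", opt$n_bins,
            ", max_rank=", opt$max_rank,
            ", seed=", if (is.null(opt$seed)) "none" else opt$seed, ")")
    scores <- score_all(x, sigs, method = opt$method,
                        control_size = opt$control_size, n_bins = opt$n_bins,
                        max_rank = opt$max_rank, seed = opt$seed,
                        drop_overlap = opt$drop_overlap)
    excl <- attr(scores, "exclusions")
    for (nm in names(excl)) {
      if (nrow(excl[[nm]])) {
        message("signature '", nm, "': excluded ", nrow(excl[[nm]]),
                " top-expressed gene(s)")
      }
    }
    truth <- NULL
    if (!is.null(opt$truth_col)) {
      meta <- attr(x, "cell_metadata")
      if (is.null(meta) || !opt$truth_col %in% colnames(meta)) {
        stop("truth column '", opt$truth_col, "' not found in metadata")
      }
      truth <- meta[[opt$truth_col]]
    }
    write_scores(scores, opt$out, annotate = opt$annotate, truth = truth)
    message("wrote ", opt$out)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
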