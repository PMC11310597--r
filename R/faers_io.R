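## FAERS quarterly ASCII ingestion: "$"-delimited tables with a header row
## (the post-2012 layout). The reader keeps verbatim field values; all
## normalization happens later in assemble_reports().

pv_tables <- c("demo", "drug", "reac", "indi", "outc", "ther")

## columns that must be present for downstream assembly
pv_mandatory_cols <- list(
  demo = c("primaryid", "caseid"),
  drug = c("primaryid", "role_cod", "drugname"),
  reac = c("primaryid", "pt"),
  indi = c("primaryid", "indi_pt"),
  outc = c("primaryid", "outc_cod"),
  ther = "primaryid"
)

## Parse one delimited file tolerantly: lines whose field count does not
## match the header are skipped and counted, never guessed at.
read_faers_file <- function(path, delim = "$") {
  lines <- readLines(path, warn = FALSE)
  lines <- iconv(lines, from = "", to = "UTF-8", sub = "byte")
  if (length(lines) == 0L) stop("empty file: ", path, call. = FALSE)
  fields <- strsplit(lines, delim, fixed = TRUE)
  header <- tolower(trimws(fields[[1L]]))
  body <- fields[-1L]
  ## trailing empty field is dropped by strsplit; pad rows short by one
  nf <- lengths(body)
  pad <- nf == length(header) - 1L
  body[pad] <- lapply(body[pad], function(x) c(x, ""))
  nf[pad] <- length(header)
  ok <- nf == length(header)
  n_skipped <- sum(!ok)
  mat <- if (any(ok)) {
    matrix(unlist(body[ok], use.names = FALSE),
           ncol = length(header), byrow = TRUE)
  } else {
    matrix(character(0), ncol = length(header))
  }
  dt <- data.table::as.data.table(mat)
  data.table::setnames(dt, header)
  list(rows = dt, n_skipped = n_skipped)
}

#' Read one FAERS quarter into a raw row store
#'
#' Reads the quarterly ASCII tables (DEMO, DRUG, REAC, INDI, OUTC,
#' optionally THER) with verbatim field values. Nothing is filtered or
#' joined at this stage: a DRUG row whose `primaryid` has no DEMO row is
#' retained and only flagged later when reports are assembled. Lines whose
#' field count does not match the header are skipped and counted in the
#' returned `log`.
#'
#' @param paths Named character vector or list with elements `demo`,
#'   `drug`, `reac`, and optionally `indi`, `outc`, `ther`, each a file
#'   path; or a single directory containing files whose names start with
#'   those table names (case-insensitive).
#' @param delim Field delimiter, `"$"` in the published ASCII layout.
#' @return An object of class `raw_quarter`: a list with one `data.table`
#'   of character columns per table (missing optional tables are empty),
#'   plus a `log` element with per-file skipped-line counts.
#' @export
#' @examples
#' truth <- synthetic_truth(n_reports = 50, seed = 1)
#' dir <- tempfile(); gen <- generate_faers(truth, dir)
#' rq <- read_quarter(dir)
#' nrow(rq$demo)
read_quarter <- function(paths, delim = "$") {
  if (length(paths) == 1L && is.character(paths) && dir.exists(paths)) {
    files <- list.files(paths, full.names = TRUE)
    paths <- sapply(pv_tables, function(tb) {
      hit <- files[grepl(paste0("^", tb), tolower(basename(files)))]
      if (length(hit)) hit[1L] else NA_character_
    })
    paths <- paths[!is.na(paths)]
  }
  paths <- as.list(paths)
  names(paths) <- tolower(names(paths))
  if (!all(c("demo", "drug", "reac") %in% names(paths))) {
    stop("need at least demo, drug and reac files", call. = FALSE)
  }
  out <- list()
  log <- list()
  for (tb in pv_tables) {
    if (is.null(paths[[tb]])) {
      out[[tb]] <- data.table::data.table()
      next
    }
    if (!file.exists(paths[[tb]])) {
      stop("file not found: ", paths[[tb]], call. = FALSE)
    }
    parsed <- read_faers_file(paths[[tb]], delim = delim)
    missing <- setdiff(pv_mandatory_cols[[tb]], names(parsed$rows))
    if (length(missing)) {
      stop(sprintf("file %s is missing mandatory column(s): %s",
                   paths[[tb]], paste(missing, collapse = ", ")),
           call. = FALSE)
    }
    out[[tb]] <- parsed$rows
    log[[tb]] <- c(n_rows = nrow(parsed$rows), n_skipped = parsed$n_skipped)
  }
  out$log <- log
  structure(out, class = "raw_quarter")
}

#' Read a deleted-case list
#'
#' FAERS publishes lists of case ids whose reports were deleted after
#' submission; [deduplicate()] drops any report whose `caseid` appears in
#' such a list. The file format is one case id per line.
#'
#' @param path Path to a text file, one caseid per line.
#' @return Character vector of case ids (blank lines removed).
#' @export
read_deleted_cases <- function(path) {
  ids <- trimws(readLines(path, warn = FALSE))
  ids[nzchar(ids)]
}

#' @export
print.raw_quarter <- function(x, ...) {
  cat("<raw_quarter>\n")
  for (tb in pv_tables) {
    if (!is.null(x[[tb]]) && nrow(x[[tb]])) {
      cat(sprintf("  %s: %d rows\n", toupper(tb), nrow(x[[tb]])))
    }
  }
  invisible(x)
}

## write one table in the ingest dialect (used by the generator and the
## normalized-store exporter)
write_faers_file <- function(dt, path, delim = "$") {
  data.table::fwrite(dt, path, sep = delim, quote = FALSE, col.names = TRUE)
  invisible(path)
}
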