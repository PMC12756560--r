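# Compound-table loading: validation, label coding, first-match-wins
# spectrum joining.

TOX21_ENDPOINTS <- c("NR-AR", "NR-AR-LBD", "NR-AhR", "NR-Aromatase", "NR-ER",
                     "NR-ER-LBD", "NR-PPAR-gamma", "SR-ARE", "SR-ATAD5",
                     "SR-HSE", "SR-MMP", "SR-p53")
N_TASKS <- 12L

parse_label_cell <- function(x) {
  if (is.na(x)) return(NA_integer_)
  if (is.character(x)) {
    x <- trimws(x)
    if (x == "" || x == "NA") return(NA_integer_)
    x <- suppressWarnings(as.numeric(x))
    if (is.na(x)) return(-99L)  # sentinel: invalid
  }
  if (x == -1) return(NA_integer_)
  if (x %in% c(0, 1)) return(as.integer(x))
  -99L
}

read_peaks_file <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    pk <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    lapply(pk, as.numeric)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("id", "ppm") %in% names(df))) {
      stopf("peaks CSV '%s' must have columns id, ppm", path)
    }
    split(as.numeric(df$ppm), as.character(df$id))
  }
}

#' Load a multimodal compound dataset
#'
#' Reads a compound table (columns `id`, `smiles`, then the endpoint label
#' columns), validates and parses every SMILES (invalid records are dropped
#' and counted, never imputed), decodes labels (`-1`, empty cells and `NA`
#' all mean missing), and joins per-compound carbon-13 peak lists from one or
#' more sources in priority order: once a compound's spectrum is found in one
#' source, later sources are not consulted.
#'
#' @param compound_csv path to the compound CSV.
#' @param peaks_files optional character vector of peak sources (JSON
#'   `{id: [ppm, ...]}` or long CSV `id,ppm`), highest priority first.
#' @param image_dir optional directory of pre-rendered `<id>.png` images.
#' @param endpoints endpoint column names (default: the 12 Tox21 panels,
#'   with `-` optionally written as `.`).
#' @return a `moltitox_dataset`: list of records plus a summary with counts
#'   `n_total`, `n_valid`, `n_dropped`, `n_with_spectrum`.
#' @export
load_dataset <- function(compound_csv, peaks_files = NULL, image_dir = NULL,
                         endpoints = TOX21_ENDPOINTS) {
  df <- utils::read.csv(compound_csv, stringsAsFactors = FALSE,
                        check.names = FALSE)
  if (!all(c("id", "smiles") %in% names(df))) {
    stopf("compound table must have 'id' and 'smiles' columns")
  }
  ep_cols <- endpoints
  if (!all(ep_cols %in% names(df))) {
    alt <- gsub("-", ".", endpoints)
    if (all(alt %in% names(df))) ep_cols <- alt
    else stopf("compound table is missing endpoint columns: %s",
               paste(setdiff(endpoints, names(df)), collapse = ", "))
  }
  ids <- as.character(df$id)
  if (anyDuplicated(ids)) {
    stopf("duplicate compound id(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  peak_sources <- lapply(peaks_files %||% character(0), read_peaks_file)

  records <- vector("list", nrow(df))
  n_valid <- 0L; n_spec <- 0L; dropped <- character(0)
  for (i in seq_len(nrow(df))) {
    labels <- vapply(ep_cols, function(cc) parse_label_cell(df[[cc]][i]), 0L)
    if (any(labels == -99L, na.rm = TRUE)) {
      stopf("record '%s': label outside {0, 1, -1, missing}", ids[i])
    }
    names(labels) <- endpoints
    mol <- parse_and_validate(df$smiles[i])
    if (is.null(mol)) {
      dropped <- c(dropped, ids[i])
      mt_log(sprintf("dropping record '%s': invalid SMILES '%s'",
                     ids[i], df$smiles[i]))
      next
    }
    peaks <- NULL
    for (src in peak_sources) {           # first-match-wins across sources
      p <- src[[ids[i]]]
      if (!is.null(p) && length(p) > 0L) { peaks <- as.numeric(p); break }
    }
    if (!is.null(peaks)) n_spec <- n_spec + 1L
    image_path <- NULL
    if (!is.null(image_dir)) {
      f <- file.path(image_dir, paste0(ids[i], ".png"))
      if (file.exists(f)) image_path <- f
    }
    n_valid <- n_valid + 1L
    records[[i]] <- list(id = ids[i], smiles = df$smiles[i], mol = mol,
                         labels = labels, peaks = peaks,
                         image_path = image_path)
  }
  records <- records[!vapply(records, is.null, TRUE)]
  structure(list(
    records = records,
    endpoints = endpoints,
    summary = list(n_total = nrow(df), n_valid = n_valid,
                   n_dropped = length(dropped), dropped_ids = dropped,
                   n_with_spectrum = n_spec)
  ), class = "moltitox_dataset")
}

#' @export
print.moltitox_dataset <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<moltitox_dataset> %d records (%d read, %d invalid ",
                     "dropped), %d with spectra (%.0f%%)\n"),
              s$n_valid, s$n_total, s$n_dropped, s$n_with_spectrum,
              100 * s$n_with_spectrum / max(1, s$n_valid)))
  invisible(x)
}

dataset_ids <- function(ds) vapply(ds$records, `[[`, "", "id")

dataset_labels <- function(ds) {
  t(vapply(ds$records, `[[`, numeric(N_TASKS), "labels"))
}
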