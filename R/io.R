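#' Read an sgRNA count matrix from TSV
#'
#' Expects a header `GUIDE<TAB>GENE<TAB><sample>...` (case-insensitive for
#' the two id columns) and integer counts. Rows with missing ids or missing
#' counts are dropped with a message; duplicated guide ids and non-integer
#' counts are hard errors. Lines starting with `#` (provenance headers) are
#' skipped.
#'
#' @param path Path to the TSV file.
#' @return Tibble `guide_id`, `gene_id`, one integer column per sample.
#' @export
read_counts <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (ncol(df) < 3) abort("Count file needs GUIDE, GENE and at least one sample column.")
  nm <- names(df)
  if (toupper(nm[1]) != "GUIDE" || toupper(nm[2]) != "GENE") {
    abort("Count file must start with GUIDE and GENE columns.")
  }
  names(df)[1:2] <- c("guide_id", "gene_id")
  bad <- !stats::complete.cases(df)
  if (any(bad)) {
    inform(sprintf("Dropped %d malformed row(s) with missing fields.", sum(bad)))
    df <- df[!bad, ]
  }
  dup <- df$guide_id[duplicated(df$guide_id)]
  if (length(dup) > 0) {
    abort(sprintf("Duplicated guide id(s): %s",
                  paste(unique(dup), collapse = ", ")))
  }
  sample_cols <- names(df)[-(1:2)]
  for (s in sample_cols) {
    x <- df[[s]]
    if (!is.numeric(x) || any(x < 0) || any(x != floor(x))) {
      abort(sprintf("Sample '%s' contains non-integer or negative counts.", s))
    }
    df[[s]] <- as.integer(x)
  }
  tibble::as_tibble(df)
}

# writes `# key: value` provenance lines ahead of a rectangular file
.provenance_header <- function(seed = NULL, extra = list()) {
  kv <- c(list(tool = paste0("acidscreen ", as.character(utils::packageVersion("acidscreen")))),
          if (!is.null(seed)) list(seed = seed), extra)
  sprintf("# %s: %s", names(kv), vapply(kv, as.character, ""))
}

#' Write an sgRNA count matrix as TSV
#'
#' Writes the `GUIDE GENE <sample>...` layout read back by [read_counts()],
#' optionally preceded by `#`-prefixed provenance lines recording the seed.
#'
#' @param counts Count tibble (`guide_id`, `gene_id`, sample columns).
#' @param path Output path.
#' @param seed Seed to record in the provenance header (optional).
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, seed = NULL) {
  out <- counts
  names(out)[1:2] <- c("GUIDE", "GENE")
  readr::write_lines(.provenance_header(seed), path)
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Read / write growth-plate CSV
#'
#' Plate files carry columns `well`, `group`, `phe`, `absorbance`,
#' `replicate`, `batch`; `#` lines are provenance and are skipped on read.
#'
#' @param path File path.
#' @return [read_plate()]: tibble of wells.
#' @export
read_plate <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  need <- c("well", "group", "phe", "absorbance", "replicate")
  if (!all(need %in% names(df))) {
    abort(sprintf("Plate file must carry columns: %s.", paste(need, collapse = ", ")))
  }
  if (any(df$absorbance < 0)) abort("Negative absorbance in plate file.")
  tibble::as_tibble(df)
}

#' @rdname read_plate
#' @param plate Tibble of wells.
#' @param seed Seed recorded in the provenance header (optional).
#' @return [write_plate()]: `path`, invisibly.
#' @export
write_plate <- function(plate, path, seed = NULL) {
  readr::write_lines(.provenance_header(seed), path)
  readr::write_csv(plate, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Read / write gene-score tables
#'
#' Fixed-column TSV of the [gene_scores()] output: `gene`, `n_obs`, `sumZ`,
#' `normZ`, `p_depl`, `fdr_depl`, `p_enr`, `fdr_enr`, `rank`.
#'
#' @param path File path.
#' @return [read_gene_scores()]: gene-score tibble (internal column names).
#' @export
read_gene_scores <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  out_names <- c("gene", "n_obs", "sumZ", "normZ", "p_depl", "fdr_depl",
                 "p_enr", "fdr_enr", "rank")
  if (!identical(names(df), out_names)) {
    abort("Unexpected gene-score columns.")
  }
  names(df) <- c("gene_id", "n_obs", "sumZ", "normZ", "p_depletion",
                 "fdr_depletion", "p_enrichment", "fdr_enrichment", "rank")
  tibble::as_tibble(df)
}

#' @rdname read_gene_scores
#' @param scores Gene-score tibble.
#' @param seed Seed recorded in the provenance header (optional).
#' @return [write_gene_scores()]: `path`, invisibly.
#' @export
write_gene_scores <- function(scores, path, seed = NULL) {
  out <- scores[c("gene_id", "n_obs", "sumZ", "normZ", "p_depletion",
                  "fdr_depletion", "p_enrichment", "fdr_enrichment", "rank")]
  names(out) <- c("gene", "n_obs", "sumZ", "normZ", "p_depl", "fdr_depl",
                  "p_enr", "fdr_enr", "rank")
  readr::write_lines(.provenance_header(seed), path)
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}
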