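#' One-sided Fisher overrepresentation p-value
#'
#' Probability, under the hypergeometric null, of observing at least the
#' given overlap between a hit list and a gene set drawn from a common
#' universe. Exposed so the contingency-table arithmetic can be checked
#' directly against an exhaustive tail sum.
#'
#' @param overlap Hits inside the set.
#' @param set_size Set size (within the universe).
#' @param n_hits Total hits.
#' @param universe Universe size.
#' @return One-sided (greater) Fisher's exact p-value.
#' @export
fisher_overrep_p <- function(overlap, set_size, n_hits, universe) {
  if (overlap > min(set_size, n_hits)) abort("`overlap` exceeds set or hit size.")
  tab <- matrix(c(overlap, n_hits - overlap,
                  set_size - overlap, universe - n_hits - set_size + overlap),
                nrow = 2)
  if (any(tab < 0)) abort("Inconsistent contingency counts.")
  fisher.test(tab, alternative = "greater")$p.value
}

#' Gene-set overrepresentation of a hit list
#'
#' One-sided Fisher's exact test per gene set (is the set overrepresented
#' among the hits relative to the universe?), with Benjamini-Hochberg
#' adjustment across sets. Sets are intersected with the universe first; the
#' hit list must be a subset of the universe.
#'
#' @param hits Character vector of hit gene ids (or a `hit_set`).
#' @param gene_sets Named list of character vectors, or a GMT tibble from
#'   [read_gmt()].
#' @param universe Character vector of all scored genes.
#' @return Tibble: `set_name`, `overlap`, `set_size`, `hits`, `universe`,
#'   `p`, `fdr`, ordered by `p`.
#' @export
overrepresentation <- function(hits, gene_sets, universe) {
  if (inherits(hits, "hit_set")) hits <- hits$genes
  if (length(universe) == 0) abort("Empty universe.")
  if (!all(hits %in% universe)) abort("All hits must be members of the universe.")
  if (is.data.frame(gene_sets)) {
    gene_sets <- setNames(gene_sets$genes, gene_sets$set_name)
  }
  if (is.null(names(gene_sets))) abort("`gene_sets` must be named.")
  hits <- unique(hits)
  universe <- unique(universe)
  n_hits <- length(hits)
  n_universe <- length(universe)
  rows <- purrr::imap(gene_sets, function(members, nm) {
    members <- intersect(unique(members), universe)
    k <- length(intersect(members, hits))
    m <- length(members)
    tibble::tibble(
      set_name = nm, overlap = k, set_size = m,
      hits = n_hits, universe = n_universe,
      p = fisher_overrep_p(k, m, n_hits, n_universe)
    )
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(fdr = p.adjust(.data$p, method = "BH")) |>
    dplyr::arrange(.data$p, .data$set_name)
}

#' Read gene sets in GMT format
#'
#' Tab-separated lines: set name, description, then one gene id per field.
#'
#' @param path Path to a `.gmt` file.
#' @return Tibble with columns `set_name`, `description`, `genes`
#'   (list-column of character vectors).
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) {
    warn(sprintf("%d GMT line(s) with fewer than 3 fields dropped.", sum(bad)))
    parts <- parts[!bad]
  }
  tibble::tibble(
    set_name = purrr::map_chr(parts, 1),
    description = purrr::map_chr(parts, 2),
    genes = purrr::map(parts, function(p) unique(p[-(1:2)]))
  )
}

#' Write gene sets in GMT format
#'
#' @param gene_sets Tibble as returned by [read_gmt()], or a named list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path) {
  if (!is.data.frame(gene_sets)) {
    gene_sets <- tibble::tibble(set_name = names(gene_sets),
                                description = names(gene_sets),
                                genes = unname(gene_sets))
  }
  lines <- purrr::pmap_chr(gene_sets, function(set_name, description, genes) {
    paste(c(set_name, description, genes), collapse = "\t")
  })
  readr::write_lines(lines, path)
  invisible(path)
}
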