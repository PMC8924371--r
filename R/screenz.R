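#' Normalise sgRNA counts to a common sequencing depth
#'
#' Pseudocounted depth normalisation:
#' `norm = (count + pseudocount) * scale / (sample_total + pseudocount * n_guides)`,
#' so per-sample normalised totals equal `scale` exactly and zero counts map
#' to a small positive value (keeping downstream log fold changes finite).
#'
#' @param counts Count tibble with `guide_id`, `gene_id` and one integer
#'   column per sample (as produced by [simulate_screen()] / [read_counts()]).
#' @param pseudocount Pseudocount added to every guide (default 5).
#' @param scale Target per-sample total (default 1e7 reads).
#' @return Tibble of the same shape with normalised (double) sample columns.
#' @export
normalize_counts <- function(counts, pseudocount = 5, scale = 1e7) {
  sample_cols <- setdiff(names(counts), c("guide_id", "gene_id"))
  if (length(sample_cols) == 0) abort("No sample columns found.")
  n_guides <- nrow(counts)
  dplyr::mutate(counts, dplyr::across(
    dplyr::all_of(sample_cols),
    function(x) {
      tot <- sum(x)
      if (tot <= 0) abort("A sample has zero total counts; cannot normalize.")
      (x + pseudocount) * scale / (tot + pseudocount * n_guides)
    }
  ))
}

#' Per-guide log2 fold changes between two samples
#'
#' @param norm Normalised count tibble (see [normalize_counts()]).
#' @param treated_sample,control_sample Sample column names.
#' @return Tibble `guide_id`, `gene_id`, `control_readcount` (normalised
#'   control reads), `fc` (log2 treated/control).
#' @export
guide_fold_changes <- function(norm, treated_sample, control_sample) {
  if (!all(c(treated_sample, control_sample) %in% names(norm))) {
    abort("Treated or control sample column not found.")
  }
  tibble::tibble(
    guide_id = norm$guide_id,
    gene_id = norm$gene_id,
    control_readcount = norm[[control_sample]],
    fc = log2(norm[[treated_sample]] / norm[[control_sample]])
  )
}

#' Empirical-Bayes standard deviation of guide fold changes
#'
#' Estimates the abundance-dependent noise of log2 fold changes. Guides are
#' sorted by descending control read count; the sd of `fc` is computed in a
#' sliding window of `2 * half_window` guides (clipped at the ends) and then
#' forced non-decreasing toward low abundance with a running maximum from the
#' high-abundance end (low-count guides are never assigned less noise than
#' well-measured ones). When there are fewer guides than one window the
#' global sd is used. Zero estimates are floored at a small epsilon with a
#' warning.
#'
#' @param fc Log2 fold changes.
#' @param control_readcount Normalised control reads, same length.
#' @param half_window Half window width in guides (default 500).
#' @return Per-guide sd, in the input order, all > 0.
#' @export
empirical_bayes_sd <- function(fc, control_readcount, half_window = 500) {
  n <- length(fc)
  if (n < 2) abort("At least 2 guides are required.")
  if (length(control_readcount) != n) abort("Input lengths differ.")
  ord <- order(control_readcount, decreasing = TRUE)
  x <- fc[ord]
  if (n <= 2 * half_window) {
    s <- rep(sd(x), n)
  } else {
    idx <- seq_len(n)
    lo <- pmax(1L, idx - half_window)
    hi <- pmin(n, idx + half_window - 1L)
    cs <- c(0, cumsum(x))
    cs2 <- c(0, cumsum(x^2))
    m <- hi - lo + 1
    s1 <- cs[hi + 1] - cs[lo]
    s2 <- cs2[hi + 1] - cs2[lo]
    s <- sqrt(pmax((s2 - s1^2 / m) / (m - 1), 0))
  }
  s <- cummax(s)   # monotone non-decreasing toward low abundance
  if (any(s < .EPS)) {
    warn(sprintf("%d window sd estimate(s) below %g floored (constant fold changes?).",
                 sum(s < .EPS), .EPS))
    s <- pmax(s, .EPS)
  }
  out <- numeric(n)
  out[ord] <- s
  out
}

#' Guide-level statistics for one treated/control sample pair
#'
#' Convenience wrapper chaining [guide_fold_changes()] and
#' [empirical_bayes_sd()] and forming the guide Z score `z = fc / eb_sd`.
#'
#' @inheritParams guide_fold_changes
#' @inheritParams empirical_bayes_sd
#' @return Tibble `guide_id`, `gene_id`, `control_readcount`, `fc`, `eb_sd`, `z`.
#' @export
guide_stats <- function(norm, treated_sample, control_sample, half_window = 500) {
  guide_fold_changes(norm, treated_sample, control_sample) |>
    dplyr::mutate(
      eb_sd = empirical_bayes_sd(.data$fc, .data$control_readcount, half_window),
      z = .data$fc / .data$eb_sd
    )
}

#' Gene-level normZ scores with directional FDR
#'
#' Aggregates guide Z scores (pooled over guide x replicate observations)
#' into gene scores: `sumZ` is the sum of observations, `normZ = sumZ /
#' sqrt(n_obs)` is then robustly standardised across genes (centred at the
#' median, scaled by the MAD-based estimate), and two one-sided normal-tail
#' p-values are formed: depletion (lower tail, knockout disadvantageous in
#' the treated condition) and enrichment (upper tail). Benjamini-Hochberg
#' adjustment is applied separately per direction. Ranks run from the most
#' depleted (rank 1) to the most enriched gene, ties broken by gene id.
#'
#' @param guide_z Tibble with columns `gene_id` and `z`, one row per
#'   guide x replicate observation.
#' @return `GeneScore` tibble: `gene_id`, `n_obs`, `sumZ`, `normZ`,
#'   `p_depletion`, `fdr_depletion`, `p_enrichment`, `fdr_enrichment`, `rank`.
#' @export
gene_scores <- function(guide_z) {
  stopifnot(all(c("gene_id", "z") %in% names(guide_z)))
  drop <- !is.finite(guide_z$z)
  if (any(drop)) {
    warn(sprintf("%d non-finite guide observation(s) excluded.", sum(drop)))
    guide_z <- guide_z[!drop, ]
  }
  if (nrow(guide_z) == 0) abort("No guide observations left to score.")
  scores <- guide_z |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(n_obs = dplyr::n(), sumZ = sum(.data$z), .groups = "drop") |>
    dplyr::mutate(normZ = .data$sumZ / sqrt(.data$n_obs))
  centre <- median(scores$normZ)
  scale <- mad(scores$normZ)
  if (scale < .EPS) scale <- max(sd(scores$normZ), .EPS)
  scores |>
    dplyr::mutate(
      normZ = (.data$normZ - centre) / scale,
      p_depletion = pnorm(.data$normZ),
      p_enrichment = pnorm(.data$normZ, lower.tail = FALSE),
      fdr_depletion = p.adjust(.data$p_depletion, method = "BH"),
      fdr_enrichment = p.adjust(.data$p_enrichment, method = "BH")
    ) |>
    dplyr::arrange(.data$normZ, .data$gene_id) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' Score differential gene essentiality between two pHe conditions
#'
#' End-to-end scoring for a simulated or read screen: normalises counts,
#' computes guide fold changes, empirical-Bayes sds and Z scores for each
#' replicate pair (treated condition vs control condition at the harvest
#' timepoint), pools observations per gene and returns the gene-score table.
#'
#' @param sim A `screen_sim` (or a list with `counts` and `samples` tibbles).
#' @param treated_phe,control_phe pHe condition labels (e.g. `"6.63"`,
#'   `"7.4"`).
#' @param timepoint Harvest timepoint used for the contrast (default the
#'   latest non-T0 timepoint present, i.e. T11 under default configs; T5
#'   samples, if present, are ignored unless requested).
#' @param pseudocount,scale,half_window Scoring parameters (DrugZ-convention
#'   defaults: 5, 1e7, 500).
#' @return A [gene_scores()] tibble.
#' @examples
#' sim <- simulate_screen(screen_sim_config(n_genes = 100, seed = 3))
#' head(score_screen(sim, treated_phe = "6.63", control_phe = "7.4"))
#' @export
score_screen <- function(sim, treated_phe, control_phe = "7.4",
                         timepoint = NULL, pseudocount = 5, scale = 1e7,
                         half_window = 500) {
  counts <- sim$counts
  samples <- sim$samples
  if (is.null(timepoint)) {
    tp <- setdiff(unique(samples$timepoint), "T0")
    timepoint <- tp[order(-as.integer(sub("^T", "", tp)))][1]
  }
  pick <- function(phe_label) {
    dplyr::filter(samples, .data$timepoint == !!timepoint,
                  .data$phe == phe_label) |>
      dplyr::arrange(.data$replicate)
  }
  treated <- pick(treated_phe)
  control <- pick(control_phe)
  if (nrow(treated) == 0 || nrow(control) == 0) {
    abort(sprintf("No %s samples found for the requested conditions.", timepoint))
  }
  if (nrow(treated) != nrow(control)) {
    abort("Treated and control conditions have different replicate counts.")
  }
  norm <- normalize_counts(counts, pseudocount = pseudocount, scale = scale)
  obs <- purrr::map2(treated$sample, control$sample, function(t_s, c_s) {
    guide_stats(norm, t_s, c_s, half_window = half_window)
  }) |>
    dplyr::bind_rows()
  gene_scores(obs[c("gene_id", "z")])
}

#' Call hits at a directional FDR threshold
#'
#' Selects the genes whose Benjamini-Hochberg FDR in the stated direction is
#' below the threshold and reports the boundary normZ — the least extreme
#' normZ among the hits, the analogue of a screen's published Z cutoff.
#'
#' @param scores A [gene_scores()] tibble.
#' @param direction `"depleted"` (knockout drops out in the treated
#'   condition) or `"enriched"`.
#' @param fdr_threshold FDR threshold (default 0.1).
#' @return A list of class `hit_set`: `direction`, `fdr_threshold`, `genes`
#'   (character vector), `boundary_normZ`, `table` (score rows of the hits).
#' @export
call_hits <- function(scores, direction = c("depleted", "enriched"),
                      fdr_threshold = 0.1) {
  direction <- match.arg(direction)
  if (nrow(scores) == 0) abort("Empty score table.")
  fdr_col <- if (direction == "depleted") "fdr_depletion" else "fdr_enrichment"
  hits <- dplyr::filter(scores, .data[[fdr_col]] < fdr_threshold)
  boundary <- if (nrow(hits) == 0) NA_real_
              else if (direction == "depleted") max(hits$normZ) else min(hits$normZ)
  structure(list(direction = direction, fdr_threshold = fdr_threshold,
                 genes = hits$gene_id, boundary_normZ = boundary,
                 table = hits),
            class = "hit_set")
}

#' @export
print.hit_set <- function(x, ...) {
  cat(sprintf("<hit_set> %d %s gene(s) at FDR < %g (boundary normZ %s)\n",
              length(x$genes), x$direction, x$fdr_threshold,
              if (is.na(x$boundary_normZ)) "NA" else sprintf("%.2f", x$boundary_normZ)))
  invisible(x)
}

#' Overlap between two hit sets
#'
#' Venn-style intersection of two hit sets called in the same direction
#' (e.g. genes depleted at mildly vs highly acidic pHe).
#'
#' @param a,b `hit_set` objects with the same direction.
#' @return A list: counts `only_a`, `both`, `only_b` and the corresponding
#'   gene id vectors `genes_only_a`, `genes_both`, `genes_only_b`.
#' @export
set_overlap <- function(a, b) {
  stopifnot(inherits(a, "hit_set"), inherits(b, "hit_set"))
  if (a$direction != b$direction) {
    abort("Hit sets must have the same direction to be overlapped.")
  }
  both <- intersect(a$genes, b$genes)
  only_a <- setdiff(a$genes, b$genes)
  only_b <- setdiff(b$genes, a$genes)
  list(only_a = length(only_a), both = length(both), only_b = length(only_b),
       genes_only_a = only_a, genes_both = both, genes_only_b = only_b)
}
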