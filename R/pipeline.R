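#' End-to-end synthetic demonstration of the screen analysis
#'
#' Runs the whole analysis on synthetic data with one seed: simulates a
#' pooled screen, scores the highly acidic (6.63 vs 7.4) and mildly acidic
#' (6.9 vs 7.4) contrasts, calls depleted and enriched hits at the FDR
#' threshold, computes the depleted-hit overlap between the two contrasts,
#' tests overrepresentation of the planted gene classes among the
#' highly-acidic depleted hits, simulates wild-type and acid-shifted
#' "knockout" growth plates, fits the biphasic model to both and compares
#' pH50. When `out_dir` is given every table is written with a provenance
#' header recording the seed, plus a `provenance.json` (package version,
#' seed, config hash, output digests — no wall-clock timestamps, so re-runs
#' with the same seed are byte-identical).
#'
#' @param screen_config A [screen_sim_config()]; defaults to
#'   `screen_sim_config(seed = seed)`.
#' @param fdr_threshold Hit-calling FDR threshold (default 0.1).
#' @param ko_ph50_shift Acid-limb shift (pH units) applied to the synthetic
#'   knockout plate group (default +0.3, i.e. more acid-sensitive).
#' @param plate_noise_cv Plate noise CV (default 0.05).
#' @param out_dir Optional output directory (created if needed).
#' @param seed Global seed; also used for the plate simulation (offset) and
#'   recorded in provenance.
#' @return A list of class `acid_demo` with elements `sim`, `scores_66`,
#'   `scores_69`, `hits` (list of hit sets), `overlap`, `enrichment`,
#'   `plate`, `fit_wt`, `fit_ko`, `ph50_comparison`, `seed`, and `files`
#'   (written paths, if any).
#' @examples
#' \donttest{
#' demo <- run_demo(screen_sim_config(n_genes = 200, seed = 11), seed = 11)
#' demo$overlap$both
#' }
#' @export
run_demo <- function(screen_config = NULL, fdr_threshold = 0.1,
                     ko_ph50_shift = 0.3, plate_noise_cv = 0.05,
                     out_dir = NULL, seed = 1) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[stage %s] %s", name, conditionMessage(e)))
    })
  }
  if (is.null(screen_config)) screen_config <- screen_sim_config(seed = seed)

  sim <- stage("simulate", simulate_screen(screen_config))
  scores_66 <- stage("score-6.6", score_screen(sim, treated_phe = "6.63"))
  scores_69 <- stage("score-6.9", score_screen(sim, treated_phe = "6.9"))
  hits <- stage("call-hits", list(
    depleted_66 = call_hits(scores_66, "depleted", fdr_threshold),
    enriched_66 = call_hits(scores_66, "enriched", fdr_threshold),
    depleted_69 = call_hits(scores_69, "depleted", fdr_threshold),
    enriched_69 = call_hits(scores_69, "enriched", fdr_threshold)
  ))
  overlap <- stage("overlap", set_overlap(hits$depleted_69, hits$depleted_66))
  class_sets <- split(sim$truth$gene_id, sim$truth$class)
  enrichment <- stage("overrepresentation",
                      overrepresentation(hits$depleted_66, class_sets,
                                         universe = scores_66$gene_id))

  wt <- biphasic_params(g_max = 1, K = 10^-7.8, n_act = 1.5,
                        Q = 10^-6.5, n_inh = 2)
  ko <- biphasic_params(g_max = 0.9, K = wt$K, n_act = wt$n_act,
                        Q = wt$Q * 10^-ko_ph50_shift, n_inh = wt$n_inh)
  ph_levels <- hh_ph(c(2.75, 5.5, 11, 22, 33, 44), 5)
  plate <- stage("simulate-plate",
                 simulate_growth_plate(list(wild_type = wt, knockout = ko),
                                       ph_levels = ph_levels, n_reps = 3,
                                       noise_cv = plate_noise_cv,
                                       seed = seed + 1000L))
  fit_wt <- stage("fit-wt",
                  fit_biphasic(dplyr::filter(plate, .data$group == "wild_type")))
  fit_ko <- stage("fit-ko",
                  fit_biphasic(dplyr::filter(plate, .data$group == "knockout")))
  ph50_cmp <- stage("compare-ph50", compare_ph50(
    dplyr::filter(plate, .data$group == "wild_type"),
    dplyr::filter(plate, .data$group == "knockout"),
    n_boot = 50, seed = seed + 2000L
  ))

  result <- structure(list(
    sim = sim, scores_66 = scores_66, scores_69 = scores_69, hits = hits,
    overlap = overlap, enrichment = enrichment, plate = plate,
    fit_wt = fit_wt, fit_ko = fit_ko, ph50_comparison = ph50_cmp,
    seed = seed, files = character(0)
  ), class = "acid_demo")

  if (!is.null(out_dir)) {
    result$files <- stage("write", write_demo(result, out_dir))
  }
  result
}

#' @export
print.acid_demo <- function(x, ...) {
  cat(sprintf("<acid_demo> seed %d\n", x$seed))
  cat(sprintf("  6.6 vs 7.4: %d depleted / %d enriched at FDR < %g\n",
              length(x$hits$depleted_66$genes), length(x$hits$enriched_66$genes),
              x$hits$depleted_66$fdr_threshold))
  cat(sprintf("  6.9 vs 7.4: %d depleted / %d enriched\n",
              length(x$hits$depleted_69$genes), length(x$hits$enriched_69$genes)))
  cat(sprintf("  depleted overlap: %d both / %d only-6.9 / %d only-6.6\n",
              x$overlap$both, x$overlap$only_a, x$overlap$only_b))
  cat(sprintf("  pH50: wild-type %.3f, knockout %.3f (delta %+.3f)\n",
              x$fit_wt$ph50, x$fit_ko$ph50, x$ph50_comparison$delta_ph50))
  invisible(x)
}

# writes the demo bundle; returns the file paths
write_demo <- function(demo, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  seed <- demo$seed
  write_counts(demo$sim$counts, p("counts.tsv"), seed = seed)
  readr::write_lines(.provenance_header(seed), p("truth.csv"))
  readr::write_csv(demo$sim$truth, p("truth.csv"), append = TRUE,
                   col_names = TRUE, progress = FALSE)
  write_gene_scores(demo$scores_66, p("gene_scores_66_vs_74.tsv"), seed = seed)
  write_gene_scores(demo$scores_69, p("gene_scores_69_vs_74.tsv"), seed = seed)
  readr::write_lines(.provenance_header(seed), p("hits.tsv"))
  purrr::imap(demo$hits, function(h, nm) {
    tibble::tibble(hit_set = nm, direction = h$direction, gene = h$genes)
  }) |>
    dplyr::bind_rows() |>
    readr::write_tsv(p("hits.tsv"), append = TRUE, col_names = TRUE,
                     progress = FALSE)
  readr::write_lines(.provenance_header(seed), p("enrichment.tsv"))
  readr::write_tsv(demo$enrichment, p("enrichment.tsv"), append = TRUE,
                   col_names = TRUE, progress = FALSE)
  write_plate(demo$plate, p("plate.csv"), seed = seed)
  fits <- purrr::map(list(wild_type = demo$fit_wt, knockout = demo$fit_ko),
                     function(f) c(as.list(glance(f)),
                                   list(params = as.list(tidy(f)$estimate |>
                                                           setNames(tidy(f)$term)))))
  jsonlite::write_json(fits, p("fits.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c("counts.tsv", "truth.csv", "gene_scores_66_vs_74.tsv",
             "gene_scores_69_vs_74.tsv", "hits.tsv", "enrichment.tsv",
             "plate.csv", "fits.json")
  prov <- list(
    tool = "acidscreen",
    version = as.character(utils::packageVersion("acidscreen")),
    seed = seed,
    config_digest = rlang::hash(demo$sim$config),
    outputs = purrr::map(setNames(files, files),
                         function(f) rlang::hash_file(p(f)))
  )
  jsonlite::write_json(prov, p("provenance.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  file.path(out_dir, c(files, "provenance.json"))
}

#' Verify writer/reader round trips on in-memory objects
#'
#' Writes a count matrix, plate and gene-score table to a temporary
#' directory, reads each back, and checks equality (exact for integer
#' counts; numeric columns to double round-trip precision).
#'
#' @param sim A `screen_sim` (default: a small fresh simulation).
#' @return A named logical vector (`counts`, `plate`, `gene_scores`), all
#'   `TRUE` on success; mismatches raise an error.
#' @export
verify_roundtrips <- function(sim = NULL) {
  if (is.null(sim)) sim <- simulate_screen(screen_sim_config(n_genes = 50, seed = 1))
  td <- tempfile("roundtrip")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)

  f1 <- file.path(td, "counts.tsv")
  write_counts(sim$counts, f1, seed = sim$config$seed)
  ok_counts <- isTRUE(all.equal(as.data.frame(read_counts(f1)),
                                as.data.frame(sim$counts)))

  plate <- simulate_growth_plate(
    list(wt = biphasic_params(1, K = 10^-7.8, Q = 10^-6.6)),
    ph_levels = seq(6.4, 7.8, 0.28), n_reps = 2, noise_cv = 0.05, seed = 2)
  f2 <- file.path(td, "plate.csv")
  write_plate(plate, f2)
  ok_plate <- isTRUE(all.equal(as.data.frame(read_plate(f2)),
                               as.data.frame(plate)))

  scores <- score_screen(sim, treated_phe = "6.63")
  f3 <- file.path(td, "scores.tsv")
  write_gene_scores(scores, f3)
  ok_scores <- isTRUE(all.equal(as.data.frame(read_gene_scores(f3)),
                                as.data.frame(scores[names(read_gene_scores(f3))])))

  out <- c(counts = ok_counts, plate = ok_plate, gene_scores = ok_scores)
  if (!all(out)) abort(sprintf("Round trip failed for: %s",
                               paste(names(out)[!out], collapse = ", ")))
  out
}
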