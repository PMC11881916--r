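#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run: the input (a dataset bundle
#' path or a simulation config), the printed analysis constants (escape
#' threshold 0.05, CI multiplier 2.575, DE thresholds 0.05 / 0.1, depth
#' percentile 5), the cell-class map, output directory and seed.
#'
#' @param simulation a [sim_config()], used when `bundle` is `NULL`.
#' @param bundle path to an existing dataset bundle
#'   (see [read_allele_dataset()]), overrides `simulation`.
#' @param out_dir output directory.
#' @param target_sum,z,min_escape,depth_prob,bias_scope see [call_escape()].
#' @param de_alpha,de_lfc,de_min_total,de_min_sample see [run_de()].
#' @param cell_class_map see [classify_deg_category()].
#' @param seed integer seed applied to the simulation when used.
#' @param verbose print stage progress to stderr.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = default_sim_config(),
                            bundle = NULL,
                            out_dir = "xciescape_run",
                            target_sum = 1e4, z = 2.575, min_escape = 0.05,
                            depth_prob = 0.05, bias_scope = "global",
                            de_alpha = 0.05, de_lfc = 0.1,
                            de_min_total = 10, de_min_sample = 10,
                            cell_class_map = default_cell_class_map(),
                            seed = NULL, verbose = FALSE) {
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  if (!is.null(seed) && !is.null(cfg$simulation)) cfg$simulation$seed <- as.integer(seed)
  stopifnot(target_sum > 0, z > 0, min_escape > 0, depth_prob > 0,
            de_alpha > 0, de_lfc > 0)
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config ->", x$out_dir, "\n")
  cat("  input:", if (is.null(x$bundle)) "simulation" else x$bundle, "\n")
  cat(sprintf("  escape > %.2f, z = %.3f, depth pct %.0f%% | DE padj < %.2f, |lfc| > %.2f\n",
              x$min_escape, x$z, 100 * x$depth_prob, x$de_alpha, x$de_lfc))
  invisible(x)
}

stage_log <- function(verbose, ...) {
  if (verbose) message("[xciescape] ", ...)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full escape/DE pipeline
#'
#' simulate (or load) -> validate -> escape calls -> transitions, Sankey
#' counts, dot-plot statistics -> allele-level DE per cell type -> X-vs-
#' autosome enrichment. Writes each stage's table as TSV into
#' `config$out_dir` plus a `manifest.yaml` and a human-readable
#' `report.txt`. Identical config and seed produce byte-identical TSVs.
#'
#' @param config a [pipeline_config()].
#' @return List of class `xci_pipeline_result` holding the stage objects and
#'   output paths, invisibly printable.
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 2)
    t0 <<- t1
  }

  stage_log(config$verbose, "stage: input")
  truth <- NULL
  if (!is.null(config$bundle)) {
    ds <- read_allele_dataset(config$bundle)
  } else {
    sim <- simulate_study(config$simulation)
    ds <- sim$dataset
    truth <- sim$truth
    write_truth(truth, out)
  }
  tick("input")

  stage_log(config$verbose, "stage: validate")
  report <- validate_allele_dataset(ds)
  hard <- report[!report$invariant %in% c("no X genes", "no autosomal genes"), ,
                 drop = FALSE]
  if (nrow(hard))
    stop("validation stage: dataset violates invariants: ",
         paste(unique(hard$invariant), collapse = ", "))
  tick("validate")

  stage_log(config$verbose, "stage: escape")
  calls <- call_escape(ds, target_sum = config$target_sum, z = config$z,
                       min_escape = config$min_escape,
                       depth_prob = config$depth_prob,
                       bias_scope = config$bias_scope)
  write_tsv(as.data.frame(calls), file.path(out, "escape_calls.tsv"))
  tick("escape")

  stage_log(config$verbose, "stage: transitions")
  trans <- classify_transitions(calls)
  write_tsv(as.data.frame(trans), file.path(out, "transitions.tsv"))
  sankey <- summarize_sankey(trans)
  write_tsv(sankey$counts, file.path(out, "sankey.tsv"))
  factors <- suppressWarnings(normalize_cells(ds, config$target_sum))
  dots <- xi_dotplot_stats(ds, factors)
  write_tsv(dots, file.path(out, "dotplot_stats.tsv"))
  tick("transitions")

  stage_log(config$verbose, "stage: deg")
  deg <- run_de(ds, min_total = config$de_min_total,
                min_sample = config$de_min_sample,
                alpha = config$de_alpha, lfc = config$de_lfc)
  write_tsv(as.data.frame(deg), file.path(out, "deg.tsv"))
  tick("deg")

  stage_log(config$verbose, "stage: enrichment")
  expressed <- attr(deg, "expressed")
  enr <- lapply(names(expressed), function(ct) {
    d <- deg[deg$cell_type == ct, , drop = FALSE]
    sig <- paste(d$gene_id, d$allele, sep = "::")[d$significant]
    e <- chromosome_enrichment(sig, expressed[[ct]], ds$genes)
    data.frame(cell_type = ct, focal = e$focal, comparison = "autosomes",
               n_sig_focal = e$n_sig_focal,
               n_expressed_focal = e$n_expressed_focal,
               n_sig_comparison = e$n_sig_comparison,
               n_expressed_comparison = e$n_expressed_comparison,
               chi2 = e$chi2, p_value = e$p_value, stringsAsFactors = FALSE)
  })
  enr <- do.call(rbind, enr)
  write_tsv(enr, file.path(out, "enrichment.tsv"))
  tick("enrichment")

  result <- structure(
    list(dataset = ds, truth = truth, escape_calls = calls,
         transitions = trans, sankey = sankey, dotplot = dots,
         deg = deg, enrichment = enr, out_dir = out,
         config = config, timings = timings),
    class = "xci_pipeline_result")

  manifest <- list(
    package_version = as.character(utils::packageVersion("xciescape")),
    seed = if (is.null(config$bundle)) config$simulation$seed else NA,
    input = if (is.null(config$bundle)) "simulation" else config$bundle,
    outputs = c("escape_calls.tsv", "transitions.tsv", "sankey.tsv",
                "dotplot_stats.tsv", "deg.tsv", "enrichment.tsv"),
    stage_timings_s = as.list(timings),
    thresholds = list(min_escape = config$min_escape, z = config$z,
                      depth_prob = config$depth_prob,
                      de_alpha = config$de_alpha, de_lfc = config$de_lfc))
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  writeLines(make_report(result), file.path(out, "report.txt"))
  result
}

#' @export
print.xci_pipeline_result <- function(x, ...) {
  cat(make_report(x), sep = "\n")
  invisible(x)
}

#' Human-readable run summary
#'
#' Counts of detected X genes, escapees per age, transition categories, and
#' the combined-cells enrichment statistic, computed from the stage outputs.
#'
#' @param result an `xci_pipeline_result` from [run_pipeline()].
#' @return Character vector of report lines.
#' @export
make_report <- function(result) {
  calls <- result$escape_calls
  trans <- result$transitions
  lines <- c("xciescape pipeline report",
             "=========================")
  if (is.null(trans) || nrow(trans) == 0) {
    return(c(lines, "zero classified genes"))
  }
  all_lvl <- trans[trans$cell_type == "all", , drop = FALSE]
  lvl <- if (nrow(all_lvl)) all_lvl else trans
  lines <- c(lines,
    sprintf("detected X genes (combined cells): %d", sum(lvl$detected)),
    sprintf("escapees young: %d | old: %d",
            sum(calls$status == "escapee" & calls$age_group == "young" &
                  calls$cell_type == lvl$cell_type[1]),
            sum(calls$status == "escapee" & calls$age_group == "old" &
                  calls$cell_type == lvl$cell_type[1])),
    "transition categories (combined cells):")
  tab <- table(factor(lvl$category, transition_categories))
  lines <- c(lines, paste0("  ", names(tab), ": ", as.integer(tab)))
  if (!is.null(result$enrichment)) {
    ea <- result$enrichment[result$enrichment$cell_type == "all", , drop = FALSE]
    if (nrow(ea))
      lines <- c(lines, sprintf(
        "X vs autosomes DE enrichment (combined): %d/%d vs %d/%d, chi2 = %.3f, p = %.4g",
        ea$n_sig_focal, ea$n_expressed_focal, ea$n_sig_comparison,
        ea$n_expressed_comparison, ea$chi2, ea$p_value))
  }
  lines
}
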