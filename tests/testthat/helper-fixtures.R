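# Small in-code fixtures shared across test files.

# 4 cells (2 cell types x young/old from 2 samples), 3 genes (2 autosomal, 1 X)
# with hand-written counts used as a hand-summed pseudobulk oracle.
tiny_dataset <- function() {
  xa <- Matrix::Matrix(matrix(c(
    4, 0, 2,   # c1  CA1 young_1
    1, 3, 0,   # c2  CA1 old_1
    0, 5, 1,   # c3  Astro young_1
    2, 2, 2    # c4  Astro old_1
  ), nrow = 4, byrow = TRUE), sparse = TRUE)
  xi <- Matrix::Matrix(matrix(c(
    1, 0, 0,
    0, 2, 1,
    3, 0, 0,
    0, 1, 1
  ), nrow = 4, byrow = TRUE), sparse = TRUE)
  cells <- data.frame(
    barcode = paste0("c", 1:4),
    cell_type = c("CA1", "CA1", "Astro", "Astro"),
    sample_id = c("young_1", "old_1", "young_1", "old_1"),
    age_group = c("young", "old", "young", "old"),
    stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = c("gA1", "gA2", "gX1"),
                      chromosome = c("1", "2", "X"),
                      stringsAsFactors = FALSE)
  allele_dataset(xa, xi, cells, genes)
}

# small but statistically nontrivial simulated study for pipeline-level tests
quick_config <- function(seed = 11, ...) {
  sim_config(n_cell_types = 2, cells_per_type_per_sample = 60,
             n_samples_per_age = 3, n_autosomal_genes = 200, n_x_genes = 40,
             xist_like = TRUE,
             aging_effects = list(
               aging_effect("geneX0005", "new_escape", 0.25),
               aging_effect("geneX0001", "lost_escape"),
               aging_effect("geneA0001", "xa_log2fc", 2)),
             seed = seed, ...)
}

# study-scale run shared by the recovery tests; cached per session
study_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- default_sim_config(seed = 42)
      cache <<- run_pipeline(pipeline_config(
        simulation = cfg, out_dir = file.path(tempdir(), "xciescape_study")))
    }
    cache
  }
})
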