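#' Simulation configuration for allele-resolved snRNA-seq counts
#'
#' Builds the parameter set for the synthetic-data generator, which emulates
#' droplet single-nucleus RNA-seq of an F1-hybrid (M. musculus x M. castaneus)
#' female mouse with nonrandom XCI: the inactive X is always the castaneus X,
#' so inactive-X ("xi_strain") reads arise only from XCI escape, while
#' autosomal reads split 50/50 between strains before mapping bias.
#'
#' @param n_cell_types number of cell types (named from a fixed hippocampal
#'   panel: CA1, CA3, DG, GABA, Glut, Astro, MG, Oligo, OPC).
#' @param cells_per_type_per_sample cells simulated per cell type per sample.
#' @param n_samples_per_age biological replicates per age group.
#' @param n_autosomal_genes,n_x_genes gene counts by chromosome class.
#' @param baseline_escape_fraction fraction of X genes escaping XCI in young
#'   animals (the mouse literature estimates 3-7%; default 0.05).
#' @param mapping_bias probability that an alternate-strain (castaneus) read is
#'   misassigned to the reference (musculus) genome. Under this one-directional
#'   flip model the expected autosomal reference share is `(1+b)/2`; the
#'   default 0.12 reproduces the canonical 56/44 autosomal split.
#' @param informative_read_fraction probability that a read overlaps a
#'   strain-distinguishing SNP and is therefore allele-assignable.
#' @param mean_depth_per_cell expected total reads per cell before allele
#'   assignment.
#' @param dispersion negative-binomial dispersion of per-cell gene counts
#'   (variance = mu + dispersion * mu^2).
#' @param library_sdlog sdlog of the per-cell log-normal library size factor.
#' @param sample_sdlog sdlog of per-(sample, gene) log-normal replicate noise.
#' @param rate_sdlog,celltype_sdlog sdlog of the per-gene base expression rate
#'   and of its per-cell-type modulation.
#' @param escape_prob_range range the baseline escapees' escape probabilities
#'   are drawn from (uniform).
#' @param boosted_rate base expression rate assigned to genes carrying planted
#'   aging effects, so planted signals sit at high depth.
#' @param xist_like if `TRUE`, add one highly expressed X gene (`geneXist`)
#'   transcribed almost exclusively from the inactive X, mimicking Xist and
#'   pulling the pooled X-linked strain split toward the observed ~92/8.
#' @param aging_effects list of [aging_effect()] entries planted in old
#'   samples only.
#' @param seed integer seed; a fixed seed yields byte-identical datasets.
#' @return A list of class `sim_config`.
#' @seealso [default_sim_config()], [build_truth()], [simulate_dataset()]
#' @export
sim_config <- function(n_cell_types = 2,
                       cells_per_type_per_sample = 50,
                       n_samples_per_age = 2,
                       n_autosomal_genes = 60,
                       n_x_genes = 20,
                       baseline_escape_fraction = 0.05,
                       mapping_bias = 0.12,
                       informative_read_fraction = 0.3,
                       mean_depth_per_cell = 2000,
                       dispersion = 0.3,
                       library_sdlog = 0.35,
                       sample_sdlog = 0.1,
                       rate_sdlog = 1,
                       celltype_sdlog = 0.5,
                       escape_prob_range = c(0.08, 0.30),
                       boosted_rate = 20,
                       xist_like = FALSE,
                       aging_effects = list(),
                       seed = 20260901L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  viol <- validate_sim_config(cfg)
  if (nrow(viol)) stop("invalid simulation config: ",
                       paste(viol$message, collapse = "; "))
  cfg
}

#' Describe one planted aging effect
#'
#' @param gene gene id the effect applies to.
#' @param kind one of `new_escape` (silent young, escapes old at probability
#'   `magnitude`), `lost_escape` (escapee young, silent old),
#'   `increased_escape` (escapee young, old escape probability raised to
#'   `magnitude`), `xa_log2fc` / `xi_log2fc` (old-age log2 fold change of one
#'   allele's expression rate).
#' @param magnitude effect size (escape probability or log2 fold change;
#'   ignored for `lost_escape`).
#' @param cell_types cell types affected, or `"all"`.
#' @return A named list describing the effect.
#' @export
aging_effect <- function(gene, kind, magnitude = NA_real_, cell_types = "all") {
  kinds <- c("new_escape", "lost_escape", "increased_escape",
             "xa_log2fc", "xi_log2fc")
  kind <- match.arg(kind, kinds)
  list(gene = gene, kind = kind, magnitude = magnitude, cell_types = cell_types)
}

#' Validate a simulation configuration
#'
#' @param cfg a [sim_config()] (checked field by field, report-based).
#' @return A data.frame report (`field`, `message`); zero rows when valid.
#' @export
validate_sim_config <- function(cfg) {
  bad <- list()
  for (f in c("n_cell_types", "cells_per_type_per_sample", "n_samples_per_age",
              "n_autosomal_genes", "n_x_genes"))
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] < 1)
      bad <- c(bad, list(data.frame(field = f, message = paste(f, "must be a positive integer"))))
  for (f in c("baseline_escape_fraction", "mapping_bias",
              "informative_read_fraction"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      bad <- c(bad, list(data.frame(field = f, message = paste(f, "must lie in [0, 1]"))))
  for (f in c("mean_depth_per_cell", "dispersion"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      bad <- c(bad, list(data.frame(field = f, message = paste(f, "must be positive"))))
  if (cfg$n_cell_types > length(celltype_panel))
    bad <- c(bad, list(data.frame(field = "n_cell_types",
      message = paste("at most", length(celltype_panel), "cell types supported"))))
  for (e in cfg$aging_effects)
    if (!is.finite(e$magnitude) && e$kind != "lost_escape")
      bad <- c(bad, list(data.frame(field = "aging_effects",
        message = paste("effect on", e$gene, "has non-finite magnitude"))))
  if (length(bad)) do.call(rbind, bad)
  else data.frame(field = character(), message = character())
}

celltype_panel <- c("CA1", "CA3", "DG", "GABA", "Glut", "Astro", "MG",
                    "Oligo", "OPC")

#' Default cell-type class map (neuronal vs glial)
#'
#' Five neuronal (CA1, CA3, DG, undefined glutamatergic, GABAergic) and four
#' glial (astrocytes, microglia, oligodendrocytes, OPC) hippocampal cell
#' types, the grouping used to classify differentially expressed genes.
#'
#' @return Named character vector mapping cell type to `"neuronal"`/`"glial"`.
#' @export
default_cell_class_map <- function() {
  c(CA1 = "neuronal", CA3 = "neuronal", DG = "neuronal", GABA = "neuronal",
    Glut = "neuronal", Astro = "glial", MG = "glial", Oligo = "glial",
    OPC = "glial")
}

#' Study-scale default simulation configuration
#'
#' The configuration used for calibration and recovery testing: 6 hippocampal
#' cell types, 4 samples per age group, 7920 cells, 1800 autosomal and 200
#' X-linked genes, a 5% baseline escape fraction, mapping bias 0.12 (giving
#' the expected 56/44 autosomal strain split), an Xist-like Xi-dominant gene,
#' and planted aging effects: 8 new-escape genes (escape probability
#' 0.15-0.30), 4 lost-escape and 3 increased-escape genes, 6 autosomal
#' allele-level log2 fold changes of +-2, and 2 Xi-allele fold changes of +2.
#'
#' @param seed integer seed.
#' @return A [sim_config()].
#' @export
default_sim_config <- function(seed = 20260901L) {
  effects <- c(
    lapply(seq_len(8), function(i)
      aging_effect(sprintf("geneX%04d", 10L + i), "new_escape",
                   magnitude = seq(0.15, 0.30, length.out = 8)[i])),
    lapply(1:4, function(i)
      aging_effect(sprintf("geneX%04d", i), "lost_escape")),
    lapply(1:3, function(i)
      aging_effect(sprintf("geneX%04d", 4L + i), "increased_escape",
                   magnitude = c(0.45, 0.50, 0.55)[i])),
    lapply(1:6, function(i)
      aging_effect(sprintf("geneA%04d", i), "xa_log2fc",
                   magnitude = c(2, 2, 2, -2, -2, -2)[i])),
    lapply(1:2, function(i)
      aging_effect(sprintf("geneX%04d", 7L + i), "xi_log2fc", magnitude = 2))
  )
  sim_config(
    n_cell_types = 6,
    cells_per_type_per_sample = 165,
    n_samples_per_age = 4,
    n_autosomal_genes = 1800,
    n_x_genes = 200,
    xist_like = TRUE,
    aging_effects = effects,
    seed = seed
  )
}

#' @export
print.sim_config <- function(x, ...) {
  n_cells <- x$n_cell_types * x$cells_per_type_per_sample *
    x$n_samples_per_age * 2
  cat("sim_config:", x$n_cell_types, "cell types,",
      2 * x$n_samples_per_age, "samples,", n_cells, "cells,",
      x$n_autosomal_genes + x$n_x_genes + isTRUE(x$xist_like), "genes\n")
  cat("  escape fraction", x$baseline_escape_fraction,
      "| mapping bias", x$mapping_bias,
      "| informative fraction", x$informative_read_fraction, "\n")
  cat("  planted aging effects:", length(x$aging_effects),
      "| seed", x$seed, "\n")
  invisible(x)
}

#' Build the ground-truth parameter tables for a simulation
#'
#' Assigns chromosomes, draws per-gene, per-cell-type expression rates,
#' designates `round(baseline_escape_fraction * n_x_genes)` baseline escapees
#' (the first X genes, so configurations can reference them by id) with escape
#' probabilities drawn uniformly from `escape_prob_range`, and applies the
#' configured aging effects to old-age parameters only. Genes carrying a
#' planted effect get `boosted_rate` as base expression so planted signals are
#' deeply covered.
#'
#' @param config a [sim_config()].
#' @return A list of class `sim_truth`: `genes` (gene_id, chromosome),
#'   `params` (long table gene_id, cell_type, age_group, rate_xa, rate_xi,
#'   rate, p_cast — allele rates before mapping bias), and `effects` (planted
#'   effect table).
#' @export
build_truth <- function(config) {
  set.seed(config$seed)
  autos <- sprintf("geneA%04d", seq_len(config$n_autosomal_genes))
  xgen <- sprintf("geneX%04d", seq_len(config$n_x_genes))
  genes <- data.frame(
    gene_id = c(autos, xgen),
    chromosome = c(as.character(rep_len(1:19, length(autos))),
                   rep("X", length(xgen))),
    stringsAsFactors = FALSE)
  if (isTRUE(config$xist_like))
    genes <- rbind(genes, data.frame(gene_id = "geneXist", chromosome = "X"))

  cts <- celltype_panel[seq_len(config$n_cell_types)]
  n_esc <- round(config$baseline_escape_fraction * config$n_x_genes)
  escapees <- xgen[seq_len(n_esc)]
  esc_prob <- stats::setNames(
    stats::runif(n_esc, config$escape_prob_range[1], config$escape_prob_range[2]),
    escapees)

  base_rate <- stats::setNames(stats::rlnorm(nrow(genes), 0, config$rate_sdlog),
                               genes$gene_id)
  eff_genes <- unique(vapply(config$aging_effects, `[[`, "", "gene"))
  unknown <- setdiff(eff_genes, genes$gene_id)
  if (length(unknown))
    stop("aging effect names unknown gene(s): ", paste(unknown, collapse = ", "))
  base_rate[eff_genes] <- config$boosted_rate
  if (isTRUE(config$xist_like)) base_rate["geneXist"] <- 30

  ct_mult <- matrix(stats::rlnorm(nrow(genes) * length(cts), 0,
                                  config$celltype_sdlog),
                    nrow(genes), length(cts),
                    dimnames = list(genes$gene_id, cts))
  ct_mult[eff_genes, ] <- 1  # planted genes covered evenly in every cell type

  grid <- expand.grid(gene_id = genes$gene_id, cell_type = cts,
                      age_group = c("young", "old"),
                      stringsAsFactors = FALSE)
  grid$chromosome <- genes$chromosome[match(grid$gene_id, genes$gene_id)]
  rate <- base_rate[grid$gene_id] * ct_mult[cbind(grid$gene_id, grid$cell_type)]
  p_cast <- ifelse(grid$chromosome == "X", 0, 0.5)
  p_cast[grid$gene_id %in% escapees] <- esc_prob[grid$gene_id[grid$gene_id %in% escapees]]
  if (isTRUE(config$xist_like)) p_cast[grid$gene_id == "geneXist"] <- 0.95

  rate_xi <- rate * p_cast
  rate_xa <- rate * (1 - p_cast)

  eff_rows <- list()
  for (e in config$aging_effects) {
    e_cts <- if (identical(e$cell_types, "all")) cts else e$cell_types
    sel <- grid$age_group == "old" & grid$gene_id == e$gene &
      grid$cell_type %in% e_cts
    if (e$kind %in% c("new_escape", "increased_escape", "lost_escape")) {
      if (grid$chromosome[match(e$gene, grid$gene_id)] != "X")
        stop("escape effect planted on non-X gene: ", e$gene)
      p_new <- if (e$kind == "lost_escape") 0 else e$magnitude
      tot <- rate_xa[sel] + rate_xi[sel]
      rate_xi[sel] <- tot * p_new
      rate_xa[sel] <- tot * (1 - p_new)
    } else if (e$kind == "xa_log2fc") {
      rate_xa[sel] <- rate_xa[sel] * 2^e$magnitude
    } else if (e$kind == "xi_log2fc") {
      rate_xi[sel] <- rate_xi[sel] * 2^e$magnitude
    }
    eff_rows[[length(eff_rows) + 1L]] <- data.frame(
      gene_id = e$gene, kind = e$kind, magnitude = e$magnitude,
      cell_types = paste(e_cts, collapse = ","), stringsAsFactors = FALSE)
  }

  grid$rate_xa <- rate_xa
  grid$rate_xi <- rate_xi
  grid$rate <- rate_xa + rate_xi
  grid$p_cast <- ifelse(grid$rate > 0, rate_xi / grid$rate, 0)

  structure(list(
    genes = genes,
    cell_types = cts,
    escapees = escapees,
    params = grid[c("gene_id", "chromosome", "cell_type", "age_group",
                    "rate_xa", "rate_xi", "rate", "p_cast")],
    effects = if (length(eff_rows)) do.call(rbind, eff_rows)
              else data.frame(gene_id = character(), kind = character(),
                              magnitude = numeric(), cell_types = character())
  ), class = "sim_truth")
}

#' Simulate an allele-resolved dataset from ground truth
#'
#' For each cell and gene, total reads are negative-binomial around the truth
#' rate scaled by a log-normal per-cell library factor and per-(sample, gene)
#' replicate noise; allele-assignable reads are binomially thinned at
#' `informative_read_fraction`; the strain of origin is binomial with the true
#' castaneus probability; mapping bias then flips each castaneus-origin read
#' to the reference strain independently with probability `mapping_bias`.
#' Only allele-assigned reads populate the two matrices.
#'
#' @param truth a [build_truth()] result consistent with `config`.
#' @param config the [sim_config()] used to build `truth`.
#' @return A list: `dataset` (an [allele_dataset()]) and `truth`.
#' @export
simulate_dataset <- function(truth, config) {
  set.seed(config$seed + 1L)
  cts <- truth$cell_types
  samples <- c(paste0("young_", seq_len(config$n_samples_per_age)),
               paste0("old_", seq_len(config$n_samples_per_age)))
  ages <- rep(c("young", "old"), each = config$n_samples_per_age)
  genes <- truth$genes$gene_id
  ng <- length(genes)
  size <- 1 / config$dispersion

  # truth rates indexed [gene, cell_type, age]
  key <- paste(truth$params$gene_id, truth$params$cell_type,
               truth$params$age_group, sep = "\r")
  rate_xa <- stats::setNames(truth$params$rate_xa, key)
  rate_xi <- stats::setNames(truth$params$rate_xi, key)

  # per-(sample, gene) replicate noise, shared across cell types of a sample
  samp_noise <- matrix(stats::rlnorm(length(samples) * ng, 0, config$sample_sdlog),
                       length(samples), ng, dimnames = list(samples, genes))

  trip <- list(); meta <- list(); cell0 <- 0L
  for (si in seq_along(samples)) {
    for (ct in cts) {
      k <- paste(genes, ct, ages[si], sep = "\r")
      r_xa <- rate_xa[k] * samp_noise[si, ]
      r_xi <- rate_xi[k] * samp_noise[si, ]
      r_tot <- r_xa + r_xi
      p_cast <- ifelse(r_tot > 0, r_xi / r_tot, 0)
      share <- r_tot / sum(r_tot)
      nc <- config$cells_per_type_per_sample
      libf <- stats::rlnorm(nc, 0, config$library_sdlog)
      mu <- outer(libf * config$mean_depth_per_cell, share)  # cells x genes
      tot <- matrix(stats::rnbinom(nc * ng, mu = mu, size = size), nc, ng)
      asg <- matrix(stats::rbinom(nc * ng, tot, config$informative_read_fraction),
                    nc, ng)
      xi_org <- matrix(stats::rbinom(nc * ng, asg,
                                     rep(p_cast, each = nc)), nc, ng)
      xi_obs <- matrix(stats::rbinom(nc * ng, xi_org, 1 - config$mapping_bias),
                       nc, ng)
      xa_obs <- asg - xi_org + (xi_org - xi_obs)
      nz_a <- which(xa_obs > 0); nz_i <- which(xi_obs > 0)
      trip[[length(trip) + 1L]] <- list(
        a_i = cell0 + ((nz_a - 1L) %% nc) + 1L,
        a_j = ((nz_a - 1L) %/% nc) + 1L, a_x = xa_obs[nz_a],
        i_i = cell0 + ((nz_i - 1L) %% nc) + 1L,
        i_j = ((nz_i - 1L) %/% nc) + 1L, i_x = xi_obs[nz_i])
      meta[[length(meta) + 1L]] <- data.frame(
        barcode = sprintf("%s_%s_c%03d", samples[si], ct, seq_len(nc)),
        cell_type = ct, sample_id = samples[si], age_group = ages[si],
        stringsAsFactors = FALSE)
      cell0 <- cell0 + nc
    }
  }
  cells <- do.call(rbind, meta)
  xa <- Matrix::sparseMatrix(
    i = unlist(lapply(trip, `[[`, "a_i")),
    j = unlist(lapply(trip, `[[`, "a_j")),
    x = unlist(lapply(trip, `[[`, "a_x")),
    dims = c(cell0, ng))
  xi <- Matrix::sparseMatrix(
    i = unlist(lapply(trip, `[[`, "i_i")),
    j = unlist(lapply(trip, `[[`, "i_j")),
    x = unlist(lapply(trip, `[[`, "i_x")),
    dims = c(cell0, ng))
  list(dataset = allele_dataset(xa, xi, cells, truth$genes), truth = truth)
}

#' Build truth and simulate in one call
#'
#' @param config a [sim_config()].
#' @return As [simulate_dataset()].
#' @export
simulate_study <- function(config) {
  simulate_dataset(build_truth(config), config)
}

#' Write ground-truth tables next to a dataset bundle
#'
#' @param truth a `sim_truth`.
#' @param path directory; writes `truth.tsv` (per gene/cell type/age rates and
#'   castaneus probabilities) and `truth_effects.tsv`.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(truth$params, file.path(path, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$effects, file.path(path, "truth_effects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a simulation configuration as YAML
#'
#' @param cfg a [sim_config()].
#' @param path file path.
#' @return `read_sim_config` returns a [sim_config()]; `write_sim_config`
#'   returns `path` invisibly.
#' @export
write_sim_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$escape_prob_range <- as.numeric(raw$escape_prob_range)
  raw$aging_effects <- lapply(raw$aging_effects, function(e)
    aging_effect(e$gene, e$kind, e$magnitude,
                 if (length(e$cell_types) == 1) e$cell_types else unlist(e$cell_types)))
  do.call(sim_config, raw)
}
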