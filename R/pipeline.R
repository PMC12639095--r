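config_error <- function(...) {
  stop(structure(
    class = c("tagseq3p_config_error", "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}

config_schema <- list(
  seed = NULL, output_dir = NULL,
  simulate = c("n_genes", "genome_length", "gene_length_range", "min_spacing",
               "genotypes", "time_points", "n_replicates", "read_length",
               "polya_fraction", "tail_range", "end_window", "decoys",
               "reads_meanlog", "reads_sdlog", "min_reads"),
  inputs = c("sample_sheet", "annotation"),
  filter = c("min_match_frac", "max_mismatches", "min_score_frac",
             "unique_only"),
  polya = c("min_tail", "min_purity"),
  quantify = c("min_polya_reads", "validation_mode", "gap", "stranded"),
  normalize = c("min_count", "min_samples"),
  de = c("lfc_threshold", "fdr_threshold", "pseudocount", "prior_df"),
  reregulate = NULL
)

#' Validate a pipeline run configuration
#'
#' Checks the configuration (a nested list, or a path to a YAML file) against
#' the documented schema: unknown keys are rejected with the offending key
#' named, and thresholds must lie in their documented ranges.
#'
#' @param config A list or YAML file path.
#' @return The validated configuration list, with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) config_error("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) config_error("config must be a list or a YAML file")
  unknown <- setdiff(names(config), names(config_schema))
  if (length(unknown)) {
    config_error("unknown config key: ", paste(unknown, collapse = ", "))
  }
  for (section in intersect(names(config), names(config_schema))) {
    allowed <- config_schema[[section]]
    if (is.null(allowed)) next
    bad <- setdiff(names(config[[section]]), allowed)
    if (length(bad)) {
      config_error("unknown config key: ", section, ".",
                   paste(bad, collapse = paste0(", ", section, ".")))
    }
  }
  if (is.null(config$output_dir)) config_error("config needs output_dir")
  if (is.null(config$simulate) && is.null(config$inputs)) {
    config_error("config needs either a 'simulate' or an 'inputs' section")
  }
  config$seed <- config$seed %||% 1L
  f <- config$filter %||% list()
  p <- config$polya %||% list()
  q <- config$quantify %||% list()
  nz <- config$normalize %||% list()
  de <- config$de %||% list()
  config$filter <- filter_policy(
    min_match_frac = f$min_match_frac %||% 0.5,
    max_mismatches = f$max_mismatches %||% 4L,
    min_score_frac = f$min_score_frac %||% 0.66,
    unique_only = f$unique_only %||% TRUE
  )
  config$polya <- polya_policy(
    min_tail = p$min_tail %||% 5L,
    min_purity = p$min_purity %||% 0.9
  )
  config$quantify <- list(
    min_polya_reads = q$min_polya_reads %||% 2L,
    validation_mode = q$validation_mode %||% "per_replicate",
    gap = q$gap %||% 0L,
    stranded = q$stranded %||% TRUE
  )
  if (!config$quantify$validation_mode %in% c("per_replicate", "pooled")) {
    config_error("quantify.validation_mode must be per_replicate or pooled")
  }
  config$normalize <- list(
    min_count = nz$min_count %||% 5L,
    min_samples = nz$min_samples %||% 3L
  )
  config$de <- list(
    lfc_threshold = de$lfc_threshold %||% 0.5,
    fdr_threshold = de$fdr_threshold %||% 0.05,
    pseudocount = de$pseudocount %||% 0.5,
    prior_df = de$prior_df %||% 10
  )
  if (config$de$fdr_threshold <= 0 || config$de$fdr_threshold >= 1) {
    config_error("de.fdr_threshold must be in (0, 1)")
  }
  config$reregulate <- config$reregulate %||% TRUE
  config
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline from a configuration
#'
#' Executes simulate (when configured) -> quantify -> normalize -> qc -> de
#' -> reregulate, writing every result as headered tab-delimited text under
#' `output_dir` together with a JSON run manifest (configuration echo,
#' package version, per-stage record counts, seed, and md5 checksums of all
#' outputs). Runs with identical configuration and inputs produce identical
#' outputs.
#'
#' @param config A configuration list or YAML path; see [validate_config()].
#' @return Invisibly, a list with the in-memory results (`quant`, `counts`,
#'   `size_factors`, `vst`, `pca`, `correlation`, `de`, `shared`,
#'   `reregulation`, `manifest`).
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  outputs <- character(0)
  stage_counts <- list()

  # -- inputs (simulated or provided) ---------------------------------------
  if (!is.null(cfg$simulate)) {
    s <- cfg$simulate
    sim_dir <- file.path(cfg$output_dir, "sim")
    genes <- simulate_annotation(
      n_genes = s$n_genes %||% 20,
      genome_length = s$genome_length %||% 200000,
      gene_length_range = unlist(s$gene_length_range %||% c(500, 2000)),
      min_spacing = s$min_spacing %||% 300
    )
    samples <- tidyr::expand_grid(
      genotype = unlist(s$genotypes %||% "G1"),
      time_point = unlist(s$time_points %||% c("R1", "D1", "R2")),
      replicate = seq_len(s$n_replicates %||% 3)
    )
    samples <- dplyr::mutate(
      samples,
      sample_id = paste(.data$genotype, .data$time_point, .data$replicate,
                        sep = "_"),
      .before = 1
    )
    truth <- simulate_truth_counts(
      genes, samples$sample_id,
      meanlog = s$reads_meanlog %||% log(30),
      sdlog = s$reads_sdlog %||% 0.6,
      min_count = s$min_reads %||% 2L
    )
    sim <- simulate_tag_reads(
      genes, truth, sim_dir,
      read_length = s$read_length %||% 75L,
      polya_fraction = s$polya_fraction %||% 1,
      tail_range = unlist(s$tail_range %||% c(6L, 12L)),
      end_window = s$end_window %||% 50L,
      decoys = s$decoys %||% FALSE
    )
    annotation_path <- file.path(sim_dir, "annotation.gff3")
    write_gff3(genes, annotation_path)
    sample_sheet <- dplyr::inner_join(samples, sim$files, by = "sample_id")
    annotation <- genes
    outputs <- c(outputs, write_tsv(truth,
                                    file.path(sim_dir, "truth_counts.tsv")))
    stage_counts$simulate <- list(n_genes = nrow(genes),
                                  n_samples = nrow(samples))
  } else {
    ss_path <- cfg$inputs$sample_sheet
    an_path <- cfg$inputs$annotation
    if (is.null(ss_path) || !file.exists(ss_path)) {
      config_error("inputs.sample_sheet missing or not found")
    }
    if (is.null(an_path) || !file.exists(an_path)) {
      config_error("inputs.annotation missing or not found")
    }
    sample_sheet <- tibble::as_tibble(
      utils::read.delim(ss_path, stringsAsFactors = FALSE)
    )
    annotation <- load_annotation(an_path)
  }

  # -- quantify -------------------------------------------------------------
  quant <- quantify(
    sample_sheet, annotation,
    filter_policy = cfg$filter, polya_policy = cfg$polya,
    min_polya_reads = cfg$quantify$min_polya_reads,
    validation_mode = cfg$quantify$validation_mode,
    gap = cfg$quantify$gap, stranded = cfg$quantify$stranded
  )
  outputs <- c(
    outputs,
    write_tsv(quant$counts, file.path(cfg$output_dir, "counts.tsv")),
    write_tsv(quant$log, file.path(cfg$output_dir, "quantify_log.tsv")),
    write_intergenic_bed(quant$intergenic,
                         file.path(cfg$output_dir, "intergenic.bed"))
  )
  stage_counts$quantify <- list(
    n_records = sum(quant$log$n_records), n_pass = sum(quant$log$n_pass),
    n_clusters = sum(quant$log$n_clusters),
    n_intergenic = nrow(quant$intergenic)
  )

  # -- normalize + qc -------------------------------------------------------
  counts <- filter_low_expression(quant$counts,
                                  min_count = cfg$normalize$min_count,
                                  min_samples = cfg$normalize$min_samples)
  sf <- estimate_size_factors(counts)
  vst <- vst_transform(counts, sf)
  pca <- run_pca(vst, samples = quant$samples)
  corr <- sample_correlation(vst)
  outputs <- c(
    outputs,
    write_tsv(sf, file.path(cfg$output_dir, "size_factors.tsv")),
    write_tsv(vst, file.path(cfg$output_dir, "vst.tsv")),
    write_tsv(tidy(pca), file.path(cfg$output_dir, "pca_scores.tsv")),
    write_tsv(
      tibble::tibble(component = seq_along(pca$var_explained),
                     var_explained = pca$var_explained),
      file.path(cfg$output_dir, "pca_variance.tsv")
    ),
    write_tsv(tidy(corr), file.path(cfg$output_dir, "sample_correlation.tsv"))
  )
  stage_counts$normalize <- list(
    n_genes_kept = nrow(counts),
    n_genes_filtered = nrow(quant$counts) - nrow(counts)
  )

  # -- differential expression per genotype and transition ------------------
  tps <- unique(quant$samples$time_point)
  genotypes <- unique(quant$samples$genotype)
  de_results <- list()
  shared <- list()
  rereg <- NULL
  if (length(tps) >= 2) {
    transitions <- purrr::map(seq_len(length(tps) - 1),
                              ~ c(tps[.x], tps[.x + 1]))
    for (tr in transitions) {
      label <- paste(tr, collapse = "-")
      per_geno <- list()
      for (g in genotypes) {
        grp <- function(tp) quant$samples$sample_id[
          quant$samples$genotype == g & quant$samples$time_point == tp
        ]
        res <- run_de(counts, sf, group_a = grp(tr[1]), group_b = grp(tr[2]),
                      pseudocount = cfg$de$pseudocount,
                      prior_df = cfg$de$prior_df,
                      lfc_threshold = cfg$de$lfc_threshold,
                      fdr_threshold = cfg$de$fdr_threshold,
                      label = paste0(g, ":", label))
        per_geno[[g]] <- res
        outputs <- c(outputs, write_tsv(
          tidy(res),
          file.path(cfg$output_dir, sprintf("de_%s_%s.tsv", g, label))
        ))
      }
      de_results[[label]] <- per_geno
      sig_sets <- purrr::map(per_geno,
                             ~ .x$gene_id[.x$sig_class != "ns"])
      shared[[label]] <- if (length(sig_sets) >= 2) {
        tab <- shared_deg_sets(sig_sets)
        outputs <- c(outputs, write_tsv(
          dplyr::select(tab, -"genes"),
          file.path(cfg$output_dir, sprintf("upset_%s.tsv", label))
        ))
        attr(tab, "shared")
      } else {
        sig_sets[[1]]
      }
    }
    stage_counts$de <- purrr::map(de_results, function(per_geno) {
      purrr::map_int(per_geno, ~ sum(.x$sig_class != "ns"))
    })

    if (isTRUE(cfg$reregulate) && length(transitions) >= 2) {
      l1 <- paste(transitions[[1]], collapse = "-")
      l2 <- paste(transitions[[2]], collapse = "-")
      shared_both <- intersect(shared[[l1]], shared[[l2]])
      rereg <- purrr::map(genotypes, function(g) {
        dplyr::mutate(
          classify_reregulation(de_results[[l1]][[g]],
                                de_results[[l2]][[g]],
                                shared = shared_both),
          genotype = g, .before = 1
        )
      })
      rereg <- dplyr::bind_rows(rereg)
      outputs <- c(outputs, write_tsv(
        rereg, file.path(cfg$output_dir, "reregulation.tsv")
      ))
      stage_counts$reregulate <- list(
        n_shared_both = length(shared_both),
        n_reregulated = sum(rereg$reregulated)
      )
    }
  }

  # -- manifest -------------------------------------------------------------
  manifest <- list(
    package = "tagseq3p",
    version = as.character(utils::packageVersion("tagseq3p")),
    seed = cfg$seed,
    config = config_echo(cfg),
    stage_counts = stage_counts,
    outputs = {
      files <- sort(unique(outputs))
      md5 <- tools::md5sum(files)
      # keyed relative to output_dir so identical runs in different
      # directories produce identical manifests
      rel <- sub(paste0("^", gsub("([][{}()+*^$.|\\\\?])", "\\\\\\1",
                                  cfg$output_dir), "/?"), "", files)
      as.list(stats::setNames(unname(md5), rel))
    }
  )
  manifest_path <- file.path(cfg$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(
    quant = quant, counts = counts, size_factors = sf, vst = vst, pca = pca,
    correlation = corr, de = de_results, shared = shared,
    reregulation = rereg, manifest = manifest
  ))
}

# strip non-serializable classes for the manifest echo
config_echo <- function(cfg) {
  cfg$filter <- unclass(cfg$filter)
  cfg$polya <- unclass(cfg$polya)
  cfg
}
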