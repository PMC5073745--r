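#' Pipeline configuration
#'
#' Validated settings for [runPipeline()]. Thresholds default to the
#' analysis levels used throughout: interaction FDR 0.05 (BH),
#' per-timepoint familywise alpha 0.05 (Bonferroni), enrichment alpha
#' 0.05 (raw hypergeometric).
#'
#' @param matrix_path,design_path input expression + design TSVs; leave
#'   `NULL` to simulate a dataset instead (`simulate = TRUE`)
#' @param annotation_path optional gene-to-bin TSV for enrichment
#' @param out_dir output directory (created if absent)
#' @param interaction_fdr,timepoint_alpha,enrichment_alpha thresholds in
#'   `(0, 1]`
#' @param universe_size background size for overlap statistics
#' @param seed integer seed (simulation and any randomized step)
#' @param linkage clustering linkage method
#' @param simulate generate the input data with [simulateExperiment()]
#' @param n_genes,pi_interaction simulation sizes when `simulate = TRUE`
#' @return a validated `PipelineConfig` list
#' @export
pipelineConfig <- function(matrix_path = NULL, design_path = NULL,
                           annotation_path = NULL, out_dir = "results",
                           interaction_fdr = 0.05, timepoint_alpha = 0.05,
                           enrichment_alpha = 0.05, universe_size = 22089L,
                           seed = 1L, linkage = "average",
                           simulate = is.null(matrix_path),
                           n_genes = 2000L, pi_interaction = 0.1) {
  for (th in c(interaction_fdr, timepoint_alpha, enrichment_alpha))
    if (th <= 0 || th > 1) stop("thresholds must be in (0, 1]")
  if (seed != as.integer(seed)) stop("seed must be an integer")
  if (!simulate && (is.null(matrix_path) || is.null(design_path)))
    stop("matrix_path and design_path required unless simulate = TRUE")
  if (!simulate) for (p in c(matrix_path, design_path, annotation_path))
    if (!file.exists(p)) stop("input file not found: ", p)
  structure(list(matrix_path = matrix_path, design_path = design_path,
                 annotation_path = annotation_path, out_dir = out_dir,
                 interaction_fdr = interaction_fdr,
                 timepoint_alpha = timepoint_alpha,
                 enrichment_alpha = enrichment_alpha,
                 universe_size = as.integer(universe_size),
                 seed = as.integer(seed), linkage = linkage,
                 simulate = simulate, n_genes = as.integer(n_genes),
                 pi_interaction = pi_interaction),
            class = "PipelineConfig")
}

#' Read a pipeline configuration file
#'
#' Plain-text `key: value` file (YAML-compatible); keys are the
#' [pipelineConfig()] arguments.
#'
#' @param path config file path
#' @return a validated `PipelineConfig`
#' @export
readPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(pipelineConfig)))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(pipelineConfig, vals)
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full kinetic differential-expression pipeline
#'
#' Stages, in order: load or simulate the expression data; per-gene
#' additive-vs-interaction model fits with the nested F-test and BH
#' selection; per-timepoint treated-vs-control DEG calling under
#' Bonferroni control; Venn partitioning of the up- and downregulated
#' sets across timepoints with pairwise hypergeometric overlap p-values;
#' hierarchical clustering of the selected genes' per-timepoint ratio
#' profiles (written as Newick); and, when an annotation is supplied,
#' functional-bin enrichment per timepoint and direction. All results are
#' tab-delimited files under `out_dir`, plus a run log accounting for
#' every input gene (analyzed + skipped = input). Identical configuration
#' and seed give byte-identical result files.
#'
#' @param config a `PipelineConfig` from [pipelineConfig()] /
#'   [readPipelineConfig()]
#' @return invisibly, a list with the in-memory results (`experiment`,
#'   `fits`, `selected`, `deg_sets`, `venn`, `overlaps`, `enrichment`,
#'   `log`) and the written file paths
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logLines <- character(0)
  note <- function(stage, msg) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                    stage, msg)
    message(line)
    logLines <<- c(logLines, line)
  }
  paths <- list()

  # -- input ----------------------------------------------------------
  ke <- if (config$simulate) {
    note("input", sprintf("simulating %d genes (pi_interaction = %g, seed = %d)",
                          config$n_genes, config$pi_interaction, config$seed))
    simulateExperiment(simulationParams(n_genes = config$n_genes,
                                        pi_interaction = config$pi_interaction,
                                        seed = config$seed))
  } else {
    note("input", paste("reading", config$matrix_path))
    readExpression(config$matrix_path, config$design_path)
  }
  nInput <- nrow(ke)
  note("input", sprintf("%d genes x %d observations", nInput, ncol(ke)))

  # -- interaction model selection ------------------------------------
  fits <- fitInteractionModels(ke, fdr_threshold = config$interaction_fdr)
  nSkip <- length(attr(fits, "skipped"))
  stopifnot(nrow(fits) + nSkip == nInput)   # gene accounting invariant
  note("anova", sprintf("analyzed %d genes, skipped %d with missing values",
                        nrow(fits), nSkip))
  sel <- selectInteractionGenes(fits, config$interaction_fdr)
  note("anova", sprintf("%d genes with time x treatment interaction (BH < %g)",
                        nrow(sel), config$interaction_fdr))
  paths$anova <- .writeTsv(as.data.frame(fits),
                           file.path(config$out_dir, "interaction_tests.tsv"))
  paths$selected <- .writeTsv(as.data.frame(sel),
                              file.path(config$out_dir, "interaction_selected.tsv"))

  # -- per-timepoint DEG calling --------------------------------------
  degs <- degTimecourse(ke, alpha = config$timepoint_alpha)
  for (tp in names(degs)) {
    d <- degs[[tp]]
    note("degs", sprintf("%s h: %d up, %d down", tp, length(d$up),
                         length(d$down)))
    paths[[paste0("degs_", tp)]] <-
      .writeTsv(d$table, file.path(config$out_dir,
                                   sprintf("degs_t%s.tsv", tp)))
  }

  # -- set statistics -------------------------------------------------
  venn <- list()
  overlaps <- list()
  for (dir in c("up", "down")) {
    sets <- lapply(degs, `[[`, dir)
    names(sets) <- paste0("t", names(degs))
    nonEmpty <- sets[vapply(sets, length, integer(1)) > 0]
    if (length(nonEmpty) >= 2L) {
      venn[[dir]] <- vennPartition(nonEmpty[seq_len(min(5L, length(nonEmpty)))])
      vdf <- data.frame(region = names(venn[[dir]]),
                        count = as.integer(venn[[dir]]))
      paths[[paste0("venn_", dir)]] <-
        .writeTsv(vdf, file.path(config$out_dir,
                                 sprintf("venn_%s.tsv", dir)))
      prs <- combn(names(nonEmpty), 2L)
      overlaps[[dir]] <- do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
        a <- nonEmpty[[prs[1L, i]]]; b <- nonEmpty[[prs[2L, i]]]
        ov <- overlapPvalue(length(a), length(b), length(intersect(a, b)),
                            config$universe_size)
        data.frame(set_a = prs[1L, i], set_b = prs[2L, i], n_a = ov$n_a,
                   n_b = ov$n_b, overlap = ov$k, expected = ov$expected,
                   p_value = ov$p_value)
      }))
      paths[[paste0("overlap_", dir)]] <-
        .writeTsv(overlaps[[dir]],
                  file.path(config$out_dir, sprintf("overlap_%s.tsv", dir)))
    } else {
      note("venn", sprintf("fewer than 2 nonempty %s sets: omitted", dir))
    }
  }

  # -- clustering of selected-gene ratio profiles ---------------------
  if (nrow(sel) >= 2L) {
    prof <- sapply(degs, function(d) {
      v <- d$table$log2_ratio
      names(v) <- d$table$gene_id
      v[sel$gene_id]
    })
    prof <- matrix(prof, nrow = nrow(sel),
                   dimnames = list(sel$gene_id, paste0("t", names(degs))))
    prof <- prof[apply(is.finite(prof), 1L, all), , drop = FALSE]
    if (nrow(prof) >= 2L) {
      tree <- profileHclust(prof, linkage = config$linkage)
      paths$dendrogram <- writeNewick(tree,
                                      file.path(config$out_dir, "profiles.nwk"))
      note("cluster", sprintf("clustered %d selected genes (%s linkage)",
                              nrow(prof), config$linkage))
    }
  } else note("cluster", "fewer than 2 selected genes: omitted")

  # -- enrichment -----------------------------------------------------
  enrichment <- NULL
  if (!is.null(config$annotation_path)) {
    ann <- readAnnotation(config$annotation_path)
    enrichment <- enrichmentTimecourse(degs, ann,
                                       alpha = config$enrichment_alpha)
    paths$enrichment <- .writeTsv(enrichment,
                                  file.path(config$out_dir, "enrichment.tsv"))
    note("enrich", sprintf("%d bin x timepoint rows", nrow(enrichment)))
  }

  writeLines(logLines, file.path(config$out_dir, "run_log.txt"))
  invisible(list(experiment = ke, fits = fits, selected = sel,
                 deg_sets = degs, venn = venn, overlaps = overlaps,
                 enrichment = enrichment, log = logLines, paths = paths))
}
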