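#' @include expression.R motif-enrichment.R
NULL

#' Assemble a pipeline configuration
#'
#' Paths to the study inputs plus the analysis parameters, all defaulting
#' to the thresholds the analyses are defined with: 1 kb upstream bound
#' window, 100 bp binding sites (50 bp for the two-factor comparison),
#' twofold change at FDR < 0.01 in at least two of four tissue contrasts
#' for coexpression, Bonferroni 0.01 for motif enrichment, 1000 random
#' gene sets, 500 bp TSS windows.
#'
#' @param genome,annotation,peaks_rep_a,peaks_rep_b input paths (FASTA,
#'   GFF3, narrowPeak x2).
#' @param counts,groups count matrix and sample-group TSV paths (optional
#'   when `de_tables` is supplied).
#' @param tf_b optional second-factor narrowPeak path.
#' @param gene_set optional path to a curated gene list (one id per line),
#'   e.g. fatty-acid/triacylglycerol biosynthesis genes.
#' @param term_map optional TSV path (`term<TAB>gene`) for term enrichment.
#' @param de_tables optional externally computed DE tables (paths to TSVs
#'   with columns gene_id, log2fc, pvalue, fdr), bypassing the internal DE
#'   engine.
#' @param embryo_groups,seedcoat_groups group labels defining the four
#'   coexpression contrasts.
#' @param upstream_window,site_width,two_tf_site_width,min_fold,coexpress_fdr,de_fdr,min_contrasts,bonferroni_alpha,geneset_n,tss_window
#'   analysis parameters (see description).
#' @param run_geneset_null run the random-gene-set motif null (costly)?
#' @param seed integer seed for every randomized stage.
#' @return A validated configuration list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(genome, annotation, peaks_rep_a, peaks_rep_b,
                           counts = NULL, groups = NULL, tf_b = NULL,
                           gene_set = NULL, term_map = NULL,
                           de_tables = NULL,
                           embryo_groups = tissueGroups()[1:2],
                           seedcoat_groups = tissueGroups()[3:4],
                           upstream_window = 1000L, site_width = 100L,
                           two_tf_site_width = 50L, min_fold = 2,
                           coexpress_fdr = 0.01, de_fdr = 0.05,
                           min_contrasts = 2L, bonferroni_alpha = 0.01,
                           geneset_n = 1000L, tss_window = 500L,
                           run_geneset_null = FALSE, seed = 1L) {
  cfg <- list(genome = genome, annotation = annotation,
              peaks_rep_a = peaks_rep_a, peaks_rep_b = peaks_rep_b,
              counts = counts, groups = groups, tf_b = tf_b,
              gene_set = gene_set, term_map = term_map,
              de_tables = de_tables, embryo_groups = embryo_groups,
              seedcoat_groups = seedcoat_groups,
              upstream_window = as.integer(upstream_window),
              site_width = as.integer(site_width),
              two_tf_site_width = as.integer(two_tf_site_width),
              min_fold = min_fold, coexpress_fdr = coexpress_fdr,
              de_fdr = de_fdr, min_contrasts = as.integer(min_contrasts),
              bonferroni_alpha = bonferroni_alpha,
              geneset_n = as.integer(geneset_n),
              tss_window = as.integer(tss_window),
              run_geneset_null = isTRUE(run_geneset_null),
              seed = as.integer(seed))
  for (p in c("genome", "annotation", "peaks_rep_a", "peaks_rep_b"))
    if (!file.exists(cfg[[p]]))
      stop(sprintf("input '%s' not found: %s", p, cfg[[p]]), call. = FALSE)
  if (is.null(cfg$counts) && is.null(cfg$de_tables))
    stop("either counts/groups or de_tables must be supplied", call. = FALSE)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipelineConfig()]; relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path YAML path.
#' @return A `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  fix <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(file.exists(p), p, file.path(base, p))
  }
  for (k in c("genome", "annotation", "peaks_rep_a", "peaks_rep_b",
              "counts", "groups", "tf_b", "gene_set", "term_map"))
    y[[k]] <- fix(y[[k]])
  if (!is.null(y$de_tables)) y$de_tables <- vapply(y$de_tables, fix, character(1))
  do.call(pipelineConfig, y)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full direct-target pipeline
#'
#' Executes reproducible-peak calling, peak-to-gene assignment,
#' differential expression over the four tissue contrasts (or injected DE
#' tables), coexpression and direct-target calling, gene-set overlap
#' tests, motif enrichment of direct-target binding sites against matched
#' random regions, the peak positional profile, genomic-feature
#' annotation, and (when a second factor's peaks are supplied) the
#' two-factor distance and 50 bp-window motif comparison.  Identical
#' configuration and seed give an identical report.
#'
#' @param config a `PipelineConfig` from [pipelineConfig()] or
#'   [readPipelineConfig()].
#' @param quiet suppress stage messages?
#' @return A [RunReport-class] object.
#' @export
runFullPipeline <- function(config, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  say("stage: load inputs")
  genome <- .stage("load", readFastaGenome(config$genome))
  models <- .stage("load", readGFF3(config$annotation))
  rep_a <- .stage("load", readNarrowPeak(config$peaks_rep_a))
  rep_b <- .stage("load", readNarrowPeak(config$peaks_rep_b))

  say("stage: reproducible peaks")
  repro <- .stage("reproducible_peaks", reproduciblePeaks(rep_a, rep_b))

  say("stage: bound genes")
  assign <- .stage("bound_genes",
                   assignPeaksToGenes(repro, models, config$upstream_window))
  bound <- assign$bound_genes

  say("stage: differential expression / coexpression")
  de_tables <- .stage("differential_expression", {
    if (!is.null(config$de_tables)) {
      lapply(config$de_tables, utils::read.table, sep = "\t", header = TRUE,
             stringsAsFactors = FALSE)
    } else {
      se <- readCountsTSV(config$counts, config$groups)
      lapply(config$embryo_groups, function(em)
        lapply(config$seedcoat_groups, function(sc)
          nbExactTest(se, em, sc))) |> unlist(recursive = FALSE)
    }
  })
  coexpressed <- .stage("coexpression",
    callCoexpressed(de_tables, min_fold = config$min_fold,
                    fdr_max = config$coexpress_fdr,
                    min_contrasts = config$min_contrasts))
  dt <- callDirectTargets(bound, coexpressed)

  say("stage: overlap statistics")
  universe <- geneIds(models)
  overlaps <- list(bound_vs_coexpressed = .stage("overlap",
    hypergeometricOverlap(bound, intersect(coexpressed, universe),
                          universe)))
  curated <- NULL
  if (!is.null(config$gene_set)) {
    curated <- intersect(readLines(config$gene_set), universe)
    overlaps$dt_vs_gene_set <- .stage("overlap",
      hypergeometricOverlap(dt, curated, universe))
  }
  terms_tab <- NULL
  if (!is.null(config$term_map)) {
    tm <- utils::read.table(config$term_map, sep = "\t", header = FALSE,
                            col.names = c("term", "gene"))
    terms_tab <- .stage("term_enrichment",
      termEnrichment(dt, split(tm$gene, tm$term), universe))
  }

  say("stage: motif enrichment")
  links <- assign$links
  dt_links <- links[links$gene_id %in% dt, , drop = FALSE]
  # one link per peak: nearest TSS among its direct-target genes
  dt_links <- dt_links[order(dt_links$peak, abs(dt_links$distance)), ]
  dt_links <- dt_links[!duplicated(dt_links$peak), , drop = FALSE]
  dt_peaks <- repro[match(dt_links$peak, mcols(repro)$name)]
  panel <- motifPanel()
  enrich <- NULL; profile <- NULL
  if (nrow(dt_links)) {
    sites <- bindingSites(dt_peaks, genome, config$site_width)
    bg <- .stage("matched_background",
      sampleMatchedBackground(dt_links$distance, config$site_width, models,
                              genome, seed = config$seed))
    enrich <- .stage("motif_enrichment",
      motifEnrichment(sites$seqs, bg$seqs, panel,
                      alpha = config$bonferroni_alpha))
    profile <- peakPositionProfile(dt_links)
  }
  features <- .stage("feature_annotation",
                     annotatePeakFeatures(repro, models))

  geneset_null <- NULL
  if (config$run_geneset_null && length(dt)) {
    say("stage: gene-set motif null")
    geneset_null <- .stage("geneset_null",
      genesetMotifBackground(dt, models, genome, panel[["AW-Box"]],
                             width = config$tss_window,
                             n_sets = config$geneset_n, seed = config$seed))
    geneset_null$background_fractions <- NULL  # summary only in the report
  }

  two_tf <- NULL
  if (!is.null(config$tf_b)) {
    say("stage: two-factor comparison")
    tf_b <- .stage("load", readNarrowPeak(config$tf_b))
    assign_b <- assignPeaksToGenes(tf_b, models, config$upstream_window)
    dist <- .stage("tf_distance", peakDistanceBetweenTFs(dt_peaks, tf_b))
    both <- dt_links$gene_id %in% assign_b$bound_genes
    sub_enrich <- list()
    for (lbl in c("bound_by_b", "not_bound_by_b")) {
      sel <- if (lbl == "bound_by_b") both else !both
      if (sum(sel) >= 5L) {
        s50 <- bindingSites(dt_peaks[sel], genome, config$two_tf_site_width)
        bg50 <- sampleMatchedBackground(dt_links$distance[sel],
                                        config$two_tf_site_width, models,
                                        genome, seed = config$seed)
        sub_enrich[[lbl]] <- motifEnrichment(s50$seqs, bg50$seqs, panel,
                                             alpha = config$bonferroni_alpha)
      }
    }
    two_tf <- list(n_dt_peaks_with_b = sum(both),
                   distances = list(median = dist$median, min = dist$min,
                                    max = dist$max,
                                    n_excluded = dist$n_excluded),
                   enrichment = sub_enrich)
  }

  counts_vec <- c(peaks_rep_a = length(rep_a), peaks_rep_b = length(rep_b),
                  reproducible_peaks = length(repro),
                  bound_genes = length(bound),
                  coexpressed_genes = length(coexpressed),
                  dt_genes = length(dt),
                  gene_set_dt = if (is.null(curated)) NA_integer_ else
                    length(intersect(curated, dt)))
  ci <- as.integer(counts_vec)
  names(ci) <- names(counts_vec)
  new("RunReport",
      counts = ci,
      sets = list(bound = bound, coexpressed = coexpressed, dt = dt),
      tables = list(overlaps = overlaps, term_enrichment = terms_tab,
                    motif_enrichment = enrich, peak_profile = profile,
                    feature_annotation = features$table,
                    geneset_null = geneset_null, two_tf = two_tf),
      qc = list(),
      provenance = list(seed = config$seed,
                        parameters = config[setdiff(names(config),
                          c("genome", "annotation", "peaks_rep_a",
                            "peaks_rep_b", "counts", "groups", "tf_b",
                            "gene_set", "term_map", "de_tables"))]))
}

#' Write a run report to disk
#'
#' Emits `report.json` plus per-stage TSVs into `dir`; partially written
#' files are removed when any write fails.
#'
#' @param report a [RunReport-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeRunReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  tryCatch({
    p <- file.path(dir, "report.json")
    jsonlite::write_json(reportAsList(report), p, digits = NA, pretty = TRUE,
                         auto_unbox = TRUE)
    written <- c(written, p)
    for (nm in c("motif_enrichment", "peak_profile", "feature_annotation",
                 "term_enrichment")) {
      tab <- report@tables[[nm]]
      if (is.null(tab) || !is.data.frame(tab)) next
      p <- file.path(dir, paste0(nm, ".tsv"))
      utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
      written <- c(written, p)
    }
    for (nm in names(report@sets)) {
      p <- file.path(dir, paste0(nm, "_genes.txt"))
      writeLines(report@sets[[nm]], p)
      written <- c(written, p)
    }
  }, error = function(e) {
    unlink(written)
    stop(e)
  })
  invisible(dir)
}

#' Plain-list view of a run report
#'
#' @param report a [RunReport-class].
#' @return A JSON-serializable list.
#' @export
reportAsList <- function(report) {
  list(counts = as.list(report@counts),
       sets = report@sets,
       tables = report@tables,
       qc = report@qc,
       provenance = report@provenance)
}
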