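#' Default analysis thresholds
#'
#' Every threshold the pipeline applies, at its default: minimum lncRNA
#' length 201 nt (strictly > 200), maximum ORF 100 aa, coding-potential
#' score cutoff 0 (keep < 0), genome placement at identity > 90 and
#' e-value < 1e-10, DE at 4-fold or more with FDR <= 0.001, specificity
#' index threshold 0.7, co-expression mean filter 30 FPKM and r^2 of at
#' least 0.9 with 100 bootstrap runs, miRNA target penalty <= 3.0, eTM
#' pairing ratio of at least 0.7, organelle homology alignment length
#' over 200 nt, run-on window 2,000 nt.
#'
#' @return Named list of thresholds.
#' @export
default_thresholds <- function() {
  list(min_len = 201, max_orf_aa = 100, score_cutoff = 0,
       min_identity = 90, max_evalue = 1e-10, min_fold = 4,
       max_fdr = 0.001, specificity = 0.7, min_mean = 30, r2 = 0.9,
       bootstrap_runs = 100, target_max_score = 3.0, etm_ratio = 0.7,
       organelle_min_align = 200, runon_window = 2000)
}

threshold_domains <- list(
  min_len = c(1, Inf), max_orf_aa = c(1, Inf),
  score_cutoff = c(-Inf, Inf), min_identity = c(0, 100),
  max_evalue = c(0, Inf), min_fold = c(1, Inf), max_fdr = c(0, 1),
  specificity = c(0, 1), min_mean = c(0, Inf), r2 = c(0, 1),
  bootstrap_runs = c(1, Inf), target_max_score = c(0, Inf),
  etm_ratio = c(0, 1), organelle_min_align = c(0, Inf),
  runon_window = c(0, Inf))

#' Build a pipeline configuration
#'
#' @param outdir Output directory for all reports and tables.
#' @param seed Integer seed controlling every source of randomness.
#' @param simulate Generate the synthetic bundle (`TRUE`) or read inputs
#'   from `inputs` paths (`FALSE`).
#' @param sim Named list of [sim_config()] overrides (seed is taken from
#'   `seed`).
#' @param inputs Named list of input paths (used when `simulate =
#'   FALSE`): `transcripts`, `reference_gtf`, `genome`, `genome_hits`,
#'   `expression`, `samples`, and optionally `coding_scores`,
#'   `protein_hits`, `mirna_mature`, `mirna_hairpin`, `cp_cds`, `mt_cds`,
#'   `tf_ids`, `term_table`.
#' @param thresholds Named list of threshold overrides (see
#'   [default_thresholds()]).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, seed = 1L, simulate = TRUE,
                            sim = list(), inputs = list(),
                            thresholds = list()) {
  th <- utils::modifyList(default_thresholds(), thresholds)
  cfg <- structure(list(outdir = outdir, seed = as.integer(seed),
                        simulate = isTRUE(simulate), sim = sim,
                        inputs = inputs, thresholds = th),
                   class = "pipeline_config")
  errs <- config_violations(cfg)
  if (length(errs) > 0L) {
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  }
  cfg
}

config_violations <- function(cfg) {
  errs <- character(0)
  th <- cfg$thresholds
  unknown <- setdiff(names(th), names(threshold_domains))
  if (length(unknown) > 0L) {
    errs <- c(errs, paste0("unknown threshold: ",
                           paste(unknown, collapse = ", ")))
  }
  for (nm in intersect(names(th), names(threshold_domains))) {
    v <- th[[nm]]
    dom <- threshold_domains[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) ||
        v < dom[[1L]] || v > dom[[2L]]) {
      errs <- c(errs, sprintf(
        "threshold %s = %s outside its domain [%s, %s]", nm,
        paste(v, collapse = ","), dom[[1L]], dom[[2L]]))
    }
  }
  if (is.null(cfg$outdir) || !is.character(cfg$outdir)) {
    errs <- c(errs, "outdir must be a path")
  }
  if (!isTRUE(cfg$simulate)) {
    need <- c("transcripts", "reference_gtf", "genome_hits",
              "expression", "samples")
    missing <- setdiff(need, names(cfg$inputs))
    if (length(missing) > 0L) {
      errs <- c(errs, paste0("simulate is FALSE but inputs lack: ",
                             paste(missing, collapse = ", ")))
    }
  }
  errs
}

#' Validate a pipeline configuration file
#'
#' Reads a YAML configuration and reports every violation at once rather
#' than failing on the first.
#'
#' @param path YAML file with optional top-level keys `outdir`, `seed`,
#'   `simulate`, `sim`, `inputs`, `thresholds`.
#' @return On success, a `pipeline_config`; on failure, a character
#'   vector of violations with class `config_errors`.
#' @export
validate_config <- function(path) {
  raw <- yaml::read_yaml(path)
  th <- utils::modifyList(default_thresholds(),
                          as.list(raw$thresholds %||% list()))
  cfg <- structure(list(outdir = raw$outdir %||% "lncvine_out",
                        seed = as.integer(raw$seed %||% 1L),
                        simulate = isTRUE(raw$simulate %||% TRUE),
                        sim = as.list(raw$sim %||% list()),
                        inputs = as.list(raw$inputs %||% list()),
                        thresholds = th),
                   class = "pipeline_config")
  errs <- config_violations(cfg)
  if (length(errs) > 0L) return(structure(errs, class = "config_errors"))
  cfg
}

load_inputs <- function(cfg) {
  ip <- cfg$inputs
  expr <- read_expression(ip$expression, ip$samples)
  list(
    transcripts = read_fasta(ip$transcripts),
    reference_models = read_gtf(ip$reference_gtf),
    genome_records = if (!is.null(ip$genome)) read_fasta(ip$genome),
    genome_hits = read_blast_tab(ip$genome_hits),
    fpkm = expr$fpkm, samples = expr$samples,
    score_table = if (!is.null(ip$coding_scores))
      read_score_table(ip$coding_scores),
    protein_hits = if (!is.null(ip$protein_hits))
      read_blast_tab(ip$protein_hits),
    mirnas = if (!is.null(ip$mirna_mature)) read_fasta(ip$mirna_mature),
    hairpins = if (!is.null(ip$mirna_hairpin))
      read_fasta(ip$mirna_hairpin),
    cp_cds = if (!is.null(ip$cp_cds)) read_fasta(ip$cp_cds),
    mt_cds = if (!is.null(ip$mt_cds)) read_fasta(ip$mt_cds),
    tf_ids = if (!is.null(ip$tf_ids)) read_id_list(ip$tf_ids),
    term_table = if (!is.null(ip$term_table))
      read_term_table(ip$term_table),
    manifest = NULL)
}

#' Run the full lncRNA analysis pipeline
#'
#' Stages, in order: (optional) synthetic-bundle simulation,
#' identification funnel, genomic placement and class-code
#' classification, expression analysis (DE filter, abundance bins,
#' specificity), co-expression with mRNA/TF/organelle partner sets plus
#' organelle homology, miRNA interaction calling, and network assembly.
#' All per-stage counts are collected into a single report written as TSV
#' and a human-readable text file; a stage failure aborts with the stage
#' name and cause. The run is deterministic under a fixed seed.
#'
#' @param cfg A [pipeline_config()] (or the result of
#'   [validate_config()]).
#' @return The report, a named list of per-stage summaries (invisibly);
#'   side effects: `report.tsv`, `report.txt`, result tables and the
#'   network under `cfg$outdir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  th <- cfg$thresholds
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  data <- stage("input", {
    if (cfg$simulate) {
      sim <- do.call(sim_config, utils::modifyList(
        list(seed = cfg$seed), cfg$sim))
      simulate_study(sim, outdir = file.path(cfg$outdir, "bundle"))
    } else {
      load_inputs(cfg)
    }
  })
  report$conditions <- length(unique(data$samples$condition))

  # ---- identification funnel
  ident <- stage("identify", run_identification(
    data$transcripts, min_len = th$min_len, max_aa = th$max_orf_aa,
    score_table = data$score_table, hit_table = data$protein_hits))
  candidates <- ident$candidates
  report$funnel <- ident$report
  write_tsv(ident$report, file.path(cfg$outdir, "funnel.tsv"))

  # ---- genomic context
  ctx <- stage("classify", {
    hits <- data$genome_hits[
      data$genome_hits$query_id %in% candidates$id, , drop = FALSE]
    placement <- assign_chromosome(hits, min_identity = th$min_identity,
                                   max_evalue = th$max_evalue)
    models <- placements_to_models(placement$placed)
    cls <- classify_transcripts(models, data$reference_models,
                                runon_window = th$runon_window)
    dens <- if (!is.null(data$genome_records)) {
      density_and_distribution(
        placement$placed,
        setNames(data$genome_records$length, data$genome_records$id))
    }
    list(placement = placement, classes = cls,
         summary = class_code_summary(cls), density = dens,
         histogram = length_histogram(candidates))
  })
  report$placed <- nrow(ctx$placement$placed)
  report$unplaced <- length(ctx$placement$unplaced)
  report$class_codes <- ctx$summary
  write_tsv(ctx$classes, file.path(cfg$outdir, "class_codes.tsv"))
  write_tsv(ctx$summary, file.path(cfg$outdir, "class_code_summary.tsv"))
  if (!is.null(ctx$density)) {
    write_tsv(ctx$density, file.path(cfg$outdir, "chromosome_density.tsv"))
  }

  # ---- expression
  expr <- stage("express", {
    lnc_fpkm <- data$fpkm[candidates$id, , drop = FALSE]
    cons <- consensus_expression(lnc_fpkm, data$samples)
    de <- de_filter(lnc_fpkm, data$samples, min_fold = th$min_fold,
                    max_fdr = th$max_fdr)
    spec <- specificity_table(cons, threshold = th$specificity)
    bins <- table(condition = rep(colnames(cons), each = nrow(cons)),
                  bin = bin_expression(as.vector(cons)))
    list(consensus = cons, de = de, spec = spec, bins = bins)
  })
  report$de_count <- length(expr$de$de_transcripts)
  report$specific_count <- sum(expr$spec$is_specific)
  write_tsv(expr$de$results, file.path(cfg$outdir, "de_results.tsv"))
  write_tsv(expr$spec, file.path(cfg$outdir, "specificity.tsv"))
  write_tsv(as.data.frame(expr$bins),
            file.path(cfg$outdir, "expression_bins.tsv"))

  # ---- co-expression
  coex <- stage("coexpress", {
    cons_all <- consensus_expression(data$fpkm, data$samples)
    passing <- mean_filter(cons_all, min_mean = th$min_mean)
    lnc_set <- intersect(candidates$id, passing)
    organelle_ids <- c(data$cp_cds$id, data$mt_cds$id)
    mrna_set <- setdiff(intersect(rownames(data$fpkm), passing),
                        c(candidates$id, organelle_ids))
    edges <- pearson_edges(lnc_set, mrna_set, cons_all,
                           r2_threshold = th$r2, partner_kind = "mRNA")
    if (nrow(edges) > 0L) {
      edges <- bootstrap_edges(edges, cons_all,
                               n_runs = th$bootstrap_runs,
                               r2_threshold = th$r2, seed = cfg$seed)
    }
    tf_edges <- edges[edges$partner_id %in% (data$tf_ids %||%
                                               character(0)), ,
                      drop = FALSE]
    if (nrow(tf_edges) > 0L) tf_edges$partner_kind <- "TF"
    cp_edges <- pearson_edges(
      lnc_set, intersect(data$cp_cds$id %||% character(0), passing),
      cons_all, r2_threshold = th$r2, partner_kind = "chloroplast_CDS")
    mt_edges <- pearson_edges(
      lnc_set, intersect(data$mt_cds$id %||% character(0), passing),
      cons_all, r2_threshold = th$r2, partner_kind = "mitochondrial_CDS")
    annot <- if (!is.null(data$term_table)) {
      transfer_annotations(edges, data$term_table)
    }
    org_hom <- if (!is.null(data$cp_cds) || !is.null(data$mt_cds)) {
      organelle_homology(candidates,
                         rbind(data$cp_cds, data$mt_cds),
                         min_align_len = th$organelle_min_align)
    }
    list(filtered = passing, edges = edges, tf_edges = tf_edges,
         cp_edges = cp_edges, mt_edges = mt_edges, annot = annot,
         org_hom = org_hom)
  })
  report$mean_filtered <- length(coex$filtered)
  report$edge_counts <- c(
    mRNA = nrow(coex$edges), TF = nrow(coex$tf_edges),
    chloroplast_CDS = nrow(coex$cp_edges),
    mitochondrial_CDS = nrow(coex$mt_edges))
  report$organelle_homology_hits <-
    if (is.null(coex$org_hom)) 0L else nrow(coex$org_hom)
  write_tsv(rbind(coex$edges,
                  cbind(coex$cp_edges, bootstrap_support = NA),
                  cbind(coex$mt_edges, bootstrap_support = NA)),
            file.path(cfg$outdir, "coexpression_edges.tsv"))
  if (!is.null(coex$org_hom)) {
    write_tsv(coex$org_hom,
              file.path(cfg$outdir, "organelle_homology.tsv"))
  }

  # ---- miRNA interactions
  mir <- stage("mirna", {
    if (is.null(data$mirnas)) {
      return(list(targets = NULL, etms = NULL, precursors = NULL,
                  roles = NULL))
    }
    targets <- list(); etms <- list()
    for (i in seq_len(nrow(data$mirnas))) {
      for (j in seq_len(nrow(candidates))) {
        targets[[length(targets) + 1L]] <- find_target_sites(
          data$mirnas$id[[i]], data$mirnas$seq[[i]],
          candidates$id[[j]], candidates$seq[[j]],
          max_score = th$target_max_score)
        etms[[length(etms) + 1L]] <- find_etm_sites(
          data$mirnas$id[[i]], data$mirnas$seq[[i]],
          candidates$id[[j]], candidates$seq[[j]],
          min_pairing_ratio = th$etm_ratio)
      }
    }
    targets <- do.call(rbind, targets)
    etms <- do.call(rbind, etms)
    # a perfect complementary site is a target, never an eTM: drop eTM
    # calls whose interval is contained in a called target site
    if (nrow(etms) > 0L && nrow(targets) > 0L) {
      drop <- vapply(seq_len(nrow(etms)), function(k) {
        t_k <- targets[targets$mirna_id == etms$mirna_id[[k]] &
                       targets$transcript_id == etms$transcript_id[[k]], ]
        any(t_k$start < etms$end[[k]] & etms$start[[k]] < t_k$end)
      }, logical(1))
      etms <- etms[!drop, , drop = FALSE]
    }
    precursors <- if (!is.null(data$hairpins)) {
      find_precursors(candidates, data$hairpins)
    }
    roles <- classify_interactions(
      targets, etms,
      precursors %||% data.frame(lncRNA_id = character(0)))
    list(targets = targets, etms = etms, precursors = precursors,
         roles = roles)
  })
  if (!is.null(mir$roles)) {
    report$interaction_roles <- c(
      target = sum(mir$roles$roles$target),
      precursor = sum(mir$roles$roles$precursor),
      eTM = sum(mir$roles$roles$eTM))
    report$role_overlaps <- mir$roles$overlaps
    write_tsv(mir$targets, file.path(cfg$outdir, "mirna_targets.tsv"))
    write_tsv(mir$etms, file.path(cfg$outdir, "mirna_etms.tsv"))
    if (!is.null(mir$precursors)) {
      write_tsv(mir$precursors,
                file.path(cfg$outdir, "mirna_precursors.tsv"))
    }
  }

  # ---- network
  net <- stage("network", build_network(
    coexpr_edges = rbind(coex$edges[, c("lncRNA_id", "partner_id",
                                        "partner_kind")],
                         coex$cp_edges[, c("lncRNA_id", "partner_id",
                                           "partner_kind")],
                         coex$mt_edges[, c("lncRNA_id", "partner_id",
                                           "partner_kind")]),
    targets = mir$targets, etms = mir$etms,
    precursors = mir$precursors))
  report$network <- c(nodes = igraph::vcount(net),
                      edges = igraph::ecount(net))
  export_network(net, file.path(cfg$outdir, "network"))

  write_report(report, cfg$outdir)
  invisible(report)
}

write_report <- function(report, outdir) {
  kv <- data.frame(key = character(0), value = character(0))
  add <- function(key, value) {
    kv <<- rbind(kv, data.frame(key = key, value = as.character(value)))
  }
  add("conditions", report$conditions)
  for (i in seq_len(nrow(report$funnel))) {
    r <- report$funnel[i, ]
    add(paste0("funnel.", r$stage, ".input"), r$input)
    add(paste0("funnel.", r$stage, ".removed"), r$removed)
    add(paste0("funnel.", r$stage, ".retained"), r$retained)
  }
  add("placed", report$placed)
  add("unplaced", report$unplaced)
  for (i in seq_len(nrow(report$class_codes))) {
    add(paste0("class_code.", report$class_codes$code[[i]], ".percent"),
        sprintf("%.4f", report$class_codes$percent[[i]]))
  }
  add("de_count", report$de_count)
  add("specific_count", report$specific_count)
  add("mean_filtered", report$mean_filtered)
  for (nm in names(report$edge_counts)) {
    add(paste0("edges.", nm), report$edge_counts[[nm]])
  }
  add("organelle_homology_hits", report$organelle_homology_hits)
  for (nm in names(report$interaction_roles %||% integer(0))) {
    add(paste0("roles.", nm), report$interaction_roles[[nm]])
  }
  for (nm in names(report$role_overlaps %||% integer(0))) {
    add(paste0("overlap.", nm), report$role_overlaps[[nm]])
  }
  add("network.nodes", report$network[["nodes"]])
  add("network.edges", report$network[["edges"]])
  write_tsv(kv, file.path(outdir, "report.tsv"))
  txt <- c("lncRNA analysis report", "======================", "",
           sprintf("%-38s %s", kv$key, kv$value))
  writeLines(txt, file.path(outdir, "report.txt"))
  invisible(kv)
}
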