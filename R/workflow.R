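#' Validate a pipeline run configuration
#'
#' A run configuration is a plain list (or a YAML file path) with optional
#' stage blocks `conservation`, `target_prediction`, `enrichment`, `qpcr`,
#' `metabolites`, plus a `seed`. Validation resolves every cross-reference
#' it can without running the pipeline — referenced files must exist, the
#' qPCR block's reference gene, target genes and calibrator group must be
#' present in the Ct table — and aggregates all problems into one error
#' list instead of failing at the first.
#'
#' @param cfg A list, or path to a YAML config file.
#' @return List with `valid` (logical), `errors` (character vector) and the
#'   parsed `config`.
#' @export
validate_run_config <- function(cfg) {
  if (is.character(cfg) && length(cfg) == 1L) {
    if (!file.exists(cfg)) stop("config file not found: ", cfg)
    cfg <- yaml::read_yaml(cfg)
  }
  stopifnot(is.list(cfg))
  errors <- character(0)
  need_file <- function(block, field, required = TRUE) {
    p <- cfg[[block]][[field]]
    if (is.null(p)) {
      if (required) errors <<- c(errors, sprintf("%s$%s: missing", block, field))
      return(invisible(NULL))
    }
    if (!file.exists(p)) {
      errors <<- c(errors, sprintf("%s$%s: file not found (%s)", block, field, p))
    }
  }
  if (is.null(cfg$seed)) errors <- c(errors, "seed: missing")
  if (!is.null(cfg$conservation)) {
    need_file("conservation", "fasta")
    need_file("conservation", "regions")
  }
  if (!is.null(cfg$target_prediction)) {
    need_file("target_prediction", "utrs")
    need_file("target_prediction", "mirna", required = FALSE)
    need_file("target_prediction", "ortholog_map", required = FALSE)
    need_file("target_prediction", "reference_targets", required = FALSE)
  }
  if (!is.null(cfg$enrichment)) {
    need_file("enrichment", "universe")
    need_file("enrichment", "gmt")
  }
  if (!is.null(cfg$qpcr)) {
    need_file("qpcr", "ct")
    if (is.null(cfg$qpcr$ref_gene)) errors <- c(errors, "qpcr$ref_gene: missing")
    if (is.null(cfg$qpcr$calibrator)) errors <- c(errors, "qpcr$calibrator: missing")
    p <- cfg$qpcr$ct
    if (!is.null(p) && file.exists(p)) {
      ct <- utils::read.delim(p, stringsAsFactors = FALSE)
      genes <- unique(ct$gene)
      for (g in c(cfg$qpcr$ref_gene, cfg$qpcr$target_genes)) {
        if (!is.null(g) && !all(g %in% genes)) {
          errors <- c(errors, sprintf("qpcr: gene '%s' absent from Ct table",
                                      paste(setdiff(g, genes), collapse = ",")))
        }
      }
      if (!is.null(cfg$qpcr$calibrator) &&
          !cfg$qpcr$calibrator %in% unique(ct$group)) {
        errors <- c(errors, sprintf("qpcr: calibrator group '%s' absent from Ct table",
                                    cfg$qpcr$calibrator))
      }
    }
  }
  if (!is.null(cfg$metabolites)) need_file("metabolites", "table")
  list(valid = !length(errors), errors = errors, config = cfg)
}

#' Run the full analysis pipeline from one configuration
#'
#' Executes the configured stages in dependency order — hairpin
#' conservation profiling, UTR seed scanning with ortholog mapping and
#' conserved-fraction scoring, gene-set enrichment, qPCR relative
#' quantification with ANOVA and SNK letters, and metabolite statistics —
#' writing per-stage artifacts plus a single `report.json` into `out_dir`.
#' Reruns with the same inputs and seed are bit-identical (the report
#' carries no timestamps). A stage failure halts the run naming the stage;
#' artifacts of completed stages are preserved.
#'
#' @param cfg A config list or YAML path (see [validate_run_config()]).
#' @param out_dir Output directory, created if needed.
#' @return The report, invisibly.
#' @export
run_all <- function(cfg, out_dir) {
  chk <- validate_run_config(cfg)
  if (!chk$valid) {
    stop("invalid run config:\n  - ", paste(chk$errors, collapse = "\n  - "))
  }
  cfg <- chk$config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = cfg$seed)
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (!is.null(cfg$conservation)) {
    report$conservation <- run_stage("conservation", function() {
      fam <- read_fasta(cfg$conservation$fasta)
      annot <- read_regions(cfg$conservation$regions)
      aln <- progressive_msa(fam)
      prof <- conservation_profile(aln)
      regs <- region_conservation(aln, prof, annot)
      write_fasta(stats::setNames(aln$rows, aln$ids),
                  file.path(out_dir, "aligned.fasta"))
      utils::write.table(prof, file.path(out_dir, "conservation_profile.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      jsonlite::write_json(regs, file.path(out_dir, "region_conservation.json"),
                           dataframe = "rows", digits = NA)
      list(n_sequences = length(fam), n_columns = aln$ncol,
           region_means = stats::setNames(regs$mean_score, regs$region))
    })
  }

  if (!is.null(cfg$target_prediction)) {
    report$target_prediction <- run_stage("target_prediction", function() {
      tp <- cfg$target_prediction
      utrs <- read_fasta(tp$utrs)
      mirna <- if (is.null(tp$mirna)) omy_mir122() else {
        rec <- read_fasta(tp$mirna)[[1]]
        mature_mirna(rec$id, rec)
      }
      site_types <- if (is.null(tp$site_types)) "6mer" else tp$site_types
      ts <- scan_utrs(utrs, mirna, site_types)
      utils::write.table(ts$sites, file.path(out_dir, "sites.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      writeLines(ts$target_ids, file.path(out_dir, "targets.txt"))
      out <- list(scanned = length(ts$scanned_ids),
                  targets = length(ts$target_ids), n_sites = nrow(ts$sites))
      if (!is.null(tp$ortholog_map)) {
        mp <- map_orthologs(ts, read_ortholog_map(tp$ortholog_map))
        out$mapped <- mp$n_mapped
        out$unmapped <- length(mp$unmapped)
      }
      if (!is.null(tp$reference_targets) && length(ts$target_ids)) {
        ref <- readLines(tp$reference_targets, warn = FALSE)
        cf <- conserved_fraction(ts, ref[nzchar(ref)])
        out$conserved_count <- cf$overlap
        out$conserved_pct <- cf$percent_rounded
      }
      jsonlite::write_json(out, file.path(out_dir, "scan_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      out
    })
  }

  if (!is.null(cfg$enrichment)) {
    report$enrichment <- run_stage("enrichment", function() {
      en <- cfg$enrichment
      alpha <- if (is.null(en$alpha)) 0.05 else en$alpha
      mss <- if (is.null(en$min_set_size)) 3L else en$min_set_size
      res <- snea(read_universe(en$universe), read_gmt(en$gmt),
                  alpha = alpha, min_set_size = mss)
      utils::write.table(res$results, file.path(out_dir, "enrichment.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      list(tested = nrow(res$results), excluded = length(res$excluded),
           significant = sum(res$results$significant),
           top_sets = utils::head(res$results$set_id[res$results$significant], 10))
    })
  }

  if (!is.null(cfg$qpcr)) {
    report$qpcr <- run_stage("qpcr", function() {
      qp <- cfg$qpcr
      ct <- utils::read.delim(qp$ct, stringsAsFactors = FALSE)
      eff <- if (is.null(qp$efficiencies)) 2 else if (is.character(qp$efficiencies)) {
        e <- utils::read.delim(qp$efficiencies, stringsAsFactors = FALSE)
        stats::setNames(e$E, e$gene)
      } else qp$efficiencies
      genes <- qp$target_genes
      if (is.null(genes)) genes <- setdiff(unique(ct$gene), qp$ref_gene)
      per_gene <- lapply(genes, function(g) {
        rel <- relative_expression(ct, g, qp$ref_gene, qp$calibrator, eff)
        snk <- snk_posthoc(rel$ratio, rel$group)
        list(rel = rel, snk = snk,
             summary = list(gene = g, F = snk$anova$F, p = snk$anova$p,
                            df_between = snk$anova$df_between,
                            df_within = snk$anova$df_within,
                            letters = stats::setNames(snk$groups$letters,
                                                      snk$groups$group)))
      })
      ratios <- do.call(rbind, lapply(per_gene, function(x) x$rel))
      utils::write.table(ratios, file.path(out_dir, "qpcr_ratios.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      anova_tab <- do.call(rbind, lapply(per_gene, function(x)
        data.frame(gene = x$summary$gene, df_between = x$summary$df_between,
                   df_within = x$summary$df_within, F = x$summary$F,
                   p = x$summary$p)))
      utils::write.table(anova_tab, file.path(out_dir, "qpcr_anova.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      lapply(per_gene, function(x) x$summary)
    })
  }

  if (!is.null(cfg$metabolites)) {
    report$metabolites <- run_stage("metabolites", function() {
      mt <- utils::read.delim(cfg$metabolites$table, stringsAsFactors = FALSE)
      ctrl <- cfg$metabolites$control_group
      lapply(split(mt, mt$analyte), function(d) {
        snk <- snk_posthoc(d$value, d$group)
        out <- list(analyte = d$analyte[1], F = snk$anova$F, p = snk$anova$p,
                    df_between = snk$anova$df_between,
                    df_within = snk$anova$df_within,
                    letters = stats::setNames(snk$groups$letters,
                                              snk$groups$group))
        if (!is.null(ctrl) && ctrl %in% d$group) {
          cm <- mean(d$value[d$group == ctrl])
          gm <- tapply(d$value, d$group, mean)
          out$percent_change <- stats::setNames(
            100 * (gm / cm - 1), names(gm))[setdiff(names(gm), ctrl)]
        }
        out
      })
    })
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
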