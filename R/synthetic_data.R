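# run expr with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

rand_seq <- function(len, comp = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(comp), len, replace = TRUE, prob = comp), collapse = "")
}

#' Simulate a 3'UTR pool with planted seed sites
#'
#' Generates `n_utrs` random UTR sequences in which a configurable fraction
#' carry at least `sites_per_target` planted copies of a site string at
#' recorded positions; all remaining UTRs are rejection-sampled to be free
#' of the site, so planted-site recall and precision are exact rather than
#' probabilistic. A `"natural"` background mode skips the rejection step
#' (random occurrences allowed), which is what the analytic background-rate
#' expectation `(L - k + 1)/4^k` per UTR refers to.
#'
#' Defaults emulate the scale of an annotated trout 3'UTR pool: 1059 UTRs
#' of which 83 (fraction 83/1059) carry a perfect miR-122 seed match.
#'
#' @param n_utrs Number of UTRs, default 1059.
#' @param site_seq DNA site string to plant, default the miR-122 6mer
#'   `"CACTCC"`.
#' @param length_range Uniform length bounds, default `c(200, 1200)`.
#' @param base_comp Named base probabilities, default uniform.
#' @param planted_target_fraction Fraction of UTRs carrying sites, default
#'   `83/1059`.
#' @param sites_per_target Planted copies per target UTR, default 1.
#' @param background `"clean"` (default; non-targets are site-free) or
#'   `"natural"` (no rejection sampling).
#' @param seed RNG seed (required; the simulator is a pure function of its
#'   arguments).
#' @param max_tries Rejection-sampling retry bound per UTR.
#' @return List with `utrs` (named character vector, `utr0001`...) and
#'   `truth`: `target_ids`, `sites` (data frame `utr_id`, `start`), and the
#'   generating `config`.
#' @export
simulate_utrs <- function(n_utrs = 1059L, site_seq = "CACTCC",
                          length_range = c(200L, 1200L),
                          base_comp = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                          planted_target_fraction = 83 / 1059,
                          sites_per_target = 1L,
                          background = c("clean", "natural"),
                          seed, max_tries = 100L) {
  background <- match.arg(background)
  stopifnot(n_utrs >= 1L, planted_target_fraction >= 0,
            planted_target_fraction <= 1, sites_per_target >= 1L,
            length_range[1] >= nchar(site_seq), !missing(seed))
  site_seq <- toupper(site_seq)
  k <- nchar(site_seq)
  with_seed(seed, {
    n_target <- round(planted_target_fraction * n_utrs)
    ids <- sprintf("utr%04d", seq_len(n_utrs))
    target_idx <- sort(sample.int(n_utrs, n_target))
    utrs <- character(n_utrs)
    site_rows <- list()
    for (i in seq_len(n_utrs)) {
      len <- length_range[1] +
        sample.int(length_range[2] - length_range[1] + 1L, 1L) - 1L
      is_target <- i %in% target_idx
      if (background == "natural" && !is_target) {
        utrs[i] <- rand_seq(len, base_comp)
        next
      }
      # site-free backbone (also for targets, so planted positions are exact)
      tries <- 0L
      repeat {
        s <- rand_seq(len, base_comp)
        if (!length(find_all(site_seq, s))) break
        tries <- tries + 1L
        if (tries >= max_tries) {
          stop("rejection sampling failed after ", max_tries,
               " tries (site too probable for length ", len, ")")
        }
      }
      if (is_target) {
        # plant non-overlapping copies at recorded positions
        taken <- integer(0)
        planted <- integer(0)
        for (cc in seq_len(sites_per_target)) {
          ok <- setdiff(seq_len(len - k + 1L),
                        unlist(lapply(taken, function(p) (p - k + 1L):(p + k - 1L))))
          if (!length(ok)) stop("UTR too short to plant ", sites_per_target,
                                " non-overlapping sites")
          pos <- if (length(ok) == 1L) ok else sample(ok, 1L)
          substr(s, pos, pos + k - 1L) <- site_seq
          taken <- c(taken, pos)
          planted <- c(planted, pos)
        }
        site_rows[[length(site_rows) + 1L]] <-
          data.frame(utr_id = ids[i], start = sort(planted),
                     stringsAsFactors = FALSE)
      }
      utrs[i] <- s
    }
    names(utrs) <- ids
    sites <- if (length(site_rows)) do.call(rbind, site_rows) else
      data.frame(utr_id = character(0), start = integer(0))
    list(utrs = utrs,
         truth = list(target_ids = ids[target_idx], sites = sites,
                      config = list(n_utrs = n_utrs, site_seq = site_seq,
                                    length_range = length_range,
                                    planted_target_fraction = planted_target_fraction,
                                    sites_per_target = sites_per_target,
                                    background = background, seed = seed)))
  })
}

#' Default hairpin region layout used by the family simulator
#'
#' A 72-nt precursor: 5' flank 1-4, mature arm 5-26 (22 nt), loop 27-41,
#' star arm 42-63 (22 nt), 3' flank 64-72.
#'
#' @param reference_id Reference row id, default `"sp01"`.
#' @return A [region_annotation()].
#' @export
default_hairpin_annotation <- function(reference_id = "sp01") {
  region_annotation(reference_id, mature = c(5L, 26L), star = c(42L, 63L),
                    loop = c(27L, 41L))
}

#' Simulate a pre-miRNA ortholog family with region-specific divergence
#'
#' Draws a random ancestor hairpin and derives each species independently
#' (star phylogeny) by substituting each position with its region's rate;
#' unannotated flank positions use the loop rate. The default rates encode
#' the conservation gradient of a deeply conserved miRNA: a frozen mature
#' arm, a nearly frozen star arm, and a drifting loop.
#'
#' @param n_species Number of sequences, default 12.
#' @param ancestor_length Hairpin length, default 72 (matches
#'   [default_hairpin_annotation()]).
#' @param annot A [region_annotation()]; default the 72-nt layout.
#' @param rates Named substitution rates per site in `[0, 1)`:
#'   `c(mature = 0, star = 0.05, loop = 0.3)`.
#' @param seed RNG seed (required).
#' @return List with `family` (named character vector, reference first),
#'   `annotation`, and `truth` (`ancestor`, `rates`, `n_substitutions` per
#'   species).
#' @export
simulate_family <- function(n_species = 12L, ancestor_length = 72L,
                            annot = default_hairpin_annotation(),
                            rates = c(mature = 0, star = 0.05, loop = 0.3),
                            seed) {
  stopifnot(n_species >= 2L, all(rates >= 0), all(rates < 1), !missing(seed))
  stopifnot(inherits(annot, "region_annotation"))
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    anc <- rand_seq(ancestor_length)
    rate_at <- rep(rates[["loop"]], ancestor_length)  # flanks drift like loop
    for (nm in names(annot$regions)) {
      r <- annot$regions[[nm]]
      if (r[2] > ancestor_length) stop("annotation outside ancestor length")
      rate_at[r[1]:r[2]] <- rates[[nm]]
    }
    ids <- sprintf("sp%02d", seq_len(n_species))
    fam <- character(n_species)
    nsub <- integer(n_species)
    anc_chars <- strsplit(anc, "")[[1]]
    for (s in seq_len(n_species)) {
      ch <- anc_chars
      hit <- which(stats::runif(ancestor_length) < rate_at)
      for (p in hit) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
      fam[s] <- paste(ch, collapse = "")
      nsub[s] <- length(hit)
    }
    names(fam) <- ids
    annot$reference_id <- ids[1]
    list(family = fam, annotation = annot,
         truth = list(ancestor = anc, rates = rates, n_substitutions = nsub,
                      config = list(n_species = n_species,
                                    ancestor_length = ancestor_length,
                                    seed = seed)))
  })
}

#' Simulate a gene universe and gene-set collection with planted enrichment
#'
#' Per-gene scores are standard normal; members of planted sets are shifted
#' upward by `log2(enrichment_factor)`, so factor 1 is the exact null. Null
#' sets are drawn from non-planted genes only, keeping the type-I
#' calibration clean. A `"binary"` mode instead plants elevated target
#' membership probability (`p0 * factor`, capped at 1).
#'
#' @param n_genes Universe size, default 1000.
#' @param n_sets Number of gene sets, default 50 (0 gives an empty, valid
#'   collection).
#' @param set_size_range Uniform member-count bounds, default `c(10, 40)`.
#' @param n_planted Number of enriched sets, default 5.
#' @param enrichment_factor Effect size >= 1, default 4.
#' @param score_type `"continuous"` (default) or `"binary"`.
#' @param p0 Baseline target-membership probability for binary scores,
#'   default 0.1.
#' @param seed RNG seed (required).
#' @return List with `universe` (data frame `gene_id`, `score`), `sets`
#'   (named list), `truth` (`planted_set_ids`, `shift`).
#' @export
simulate_geneset_universe <- function(n_genes = 1000L, n_sets = 50L,
                                      set_size_range = c(10L, 40L),
                                      n_planted = 5L, enrichment_factor = 4,
                                      score_type = c("continuous", "binary"),
                                      p0 = 0.1, seed) {
  score_type <- match.arg(score_type)
  stopifnot(enrichment_factor >= 1, n_planted <= n_sets, !missing(seed))
  with_seed(seed, {
    genes <- sprintf("g%05d", seq_len(n_genes))
    score <- if (score_type == "continuous") stats::rnorm(n_genes) else
      as.numeric(stats::runif(n_genes) < p0)
    sets <- list()
    planted_ids <- character(0)
    shift <- log2(enrichment_factor)
    pool <- seq_len(n_genes)  # genes not yet claimed by a planted set
    if (n_sets > 0L) {
      sizes <- sample(set_size_range[1]:set_size_range[2], n_sets,
                      replace = TRUE)
      for (i in seq_len(n_sets)) {
        planted <- i <= n_planted
        sid <- sprintf("set%03d%s", i, if (planted) "_planted" else "")
        memb <- sample(pool, sizes[i])
        if (planted) {
          if (score_type == "continuous") {
            score[memb] <- score[memb] + shift
          } else {
            score[memb] <- as.numeric(
              stats::runif(length(memb)) < min(1, p0 * enrichment_factor))
          }
          pool <- setdiff(pool, memb)
          planted_ids <- c(planted_ids, sid)
        }
        sets[[sid]] <- genes[memb]
      }
    }
    list(universe = data.frame(gene_id = genes, score = score,
                               stringsAsFactors = FALSE),
         sets = sets,
         truth = list(planted_set_ids = planted_ids, shift = shift,
                      config = list(n_genes = n_genes, n_sets = n_sets,
                                    n_planted = n_planted,
                                    enrichment_factor = enrichment_factor,
                                    score_type = score_type, seed = seed)))
  })
}

#' Default planted effects for the assay simulator
#'
#' Fold changes and percent changes per treatment group (relative to the
#' saline control) encoding the qualitative and quantitative structure of a
#' miR-122 inhibition experiment: the targeted miRNA isomiRs strongly down
#' in both dose groups, non-targeted miRNAs untouched, de-repressed target
#' mRNAs up, postprandial glucose up (+62%/+67%), triglycerides and free
#' fatty acids down at the high dose (-36%/-46%) and cholesterol mildly
#' down at both doses (-20%).
#'
#' @return List with `gene_fold_changes` and `analyte_effects`, each a
#'   named list of `c(low, high)` vectors, plus `analyte_control_means`.
#' @export
default_assay_effects <- function() {
  list(
    gene_fold_changes = list(
      "omy-miR-122a" = c(low = 0.35, high = 0.30),
      "omy-miR-122b" = c(low = 0.35, high = 0.30),
      "omy-miR-103"  = c(low = 1, high = 1),
      "omy-miR-21"   = c(low = 1, high = 1),
      "omy-miR-33"   = c(low = 1, high = 1),
      "cyp2k5"       = c(low = 1.8, high = 1.8),
      "ptgr1"        = c(low = 1.8, high = 1.8),
      "arcn1"        = c(low = 1.8, high = 1.8)),
    analyte_effects = list(
      glucose          = c(low = 0.62, high = 0.67),
      triglycerides    = c(low = 0, high = -0.36),
      free_fatty_acids = c(low = 0, high = -0.46),
      cholesterol      = c(low = -0.20, high = -0.20)),
    analyte_control_means = c(glucose = 5, triglycerides = 2,
                              free_fatty_acids = 0.5, cholesterol = 4))
}

#' Simulate qPCR Ct and plasma-metabolite tables with planted effects
#'
#' Ct values are normal around a per-gene baseline; a fold change `f` in a
#' treatment group shifts the group Ct by `-log_E(f)`. Reference genes
#' (`u6`, `ef1a`) are effect-free by construction. Technical replicates are
#' drawn independently around the sample value. Metabolites are lognormal
#' around `control_mean * (1 + effect)` with a fixed coefficient of
#' variation.
#'
#' @param groups Group labels, default `c("saline", "low_dose",
#'   "high_dose")`; the first is the control.
#' @param n_per_group Biological samples per group, default 6.
#' @param gene_fold_changes Named list of `c(low, high)` fold changes (>0);
#'   default [default_assay_effects()].
#' @param analyte_effects Named list of `c(low, high)` fractional changes;
#'   default [default_assay_effects()].
#' @param analyte_control_means Named control-group means.
#' @param cv Metabolite coefficient of variation, default 0.10.
#' @param ct_sd Biological Ct standard deviation in cycles, default 0.25.
#' @param rep_sd Technical-replicate Ct standard deviation, default 0.1.
#' @param n_replicates Technical replicates, default 2.
#' @param efficiency Amplification factor used to map folds to Ct shifts,
#'   default 2.
#' @param seed RNG seed (required).
#' @return List with `ct` (data frame `sample_id`, `group`, `gene`,
#'   `replicate`, `ct`), `efficiencies` (named vector), `metabolites`
#'   (data frame `sample_id`, `group`, `analyte`, `value`), `truth`.
#' @export
simulate_assay <- function(groups = c("saline", "low_dose", "high_dose"),
                           n_per_group = 6L,
                           gene_fold_changes = default_assay_effects()$gene_fold_changes,
                           analyte_effects = default_assay_effects()$analyte_effects,
                           analyte_control_means = default_assay_effects()$analyte_control_means,
                           cv = 0.10, ct_sd = 0.25, rep_sd = 0.1,
                           n_replicates = 2L, efficiency = 2, seed) {
  stopifnot(length(groups) >= 2L, n_per_group >= 2L, cv > 0, ct_sd > 0,
            efficiency > 1, !missing(seed))
  if (length(gene_fold_changes)) {
    stopifnot(all(vapply(gene_fold_changes, length, 0L) == length(groups) - 1L))
  }
  if (length(analyte_effects)) {
    stopifnot(all(vapply(analyte_effects, length, 0L) == length(groups) - 1L),
              all(names(analyte_effects) %in% names(analyte_control_means)))
  }
  stopifnot(all(unlist(gene_fold_changes) > 0))
  with_seed(seed, {
    ref_genes <- c("u6", "ef1a")
    genes <- c(names(gene_fold_changes), ref_genes)
    baseline <- stats::setNames(stats::runif(length(genes), 18, 28), genes)
    sample_ids <- paste0(rep(groups, each = n_per_group), "_",
                         rep(seq_len(n_per_group), length(groups)))
    sample_grp <- rep(groups, each = n_per_group)
    ct_rows <- list()
    for (g in genes) {
      folds <- c(1, if (g %in% ref_genes) rep(1, length(groups) - 1L) else
        unname(gene_fold_changes[[g]]))
      names(folds) <- groups
      mu <- baseline[[g]] - log(folds[sample_grp], base = efficiency)
      samp_ct <- stats::rnorm(length(sample_ids), mu, ct_sd)
      for (r in seq_len(n_replicates)) {
        ct_rows[[length(ct_rows) + 1L]] <- data.frame(
          sample_id = sample_ids, group = sample_grp, gene = g,
          replicate = r, ct = stats::rnorm(length(samp_ct), samp_ct, rep_sd),
          stringsAsFactors = FALSE)
      }
    }
    ct <- do.call(rbind, ct_rows)
    ct <- ct[order(match(ct$sample_id, sample_ids), ct$gene, ct$replicate), ]
    rownames(ct) <- NULL
    sdlog <- sqrt(log(1 + cv^2))
    met_rows <- list()
    for (a in names(analyte_effects)) {
      eff <- c(0, unname(analyte_effects[[a]]))
      names(eff) <- groups
      mgroup <- analyte_control_means[[a]] * (1 + eff[sample_grp])
      meanlog <- log(mgroup) - sdlog^2 / 2
      met_rows[[length(met_rows) + 1L]] <- data.frame(
        sample_id = sample_ids, group = sample_grp, analyte = a,
        value = stats::rlnorm(length(sample_ids), meanlog, sdlog),
        stringsAsFactors = FALSE)
    }
    metabolites <- do.call(rbind, met_rows)
    rownames(metabolites) <- NULL
    list(ct = ct,
         efficiencies = stats::setNames(rep(efficiency, length(genes)), genes),
         metabolites = metabolites,
         truth = list(gene_fold_changes = gene_fold_changes,
                      analyte_effects = analyte_effects,
                      analyte_control_means = analyte_control_means,
                      baseline_ct = baseline,
                      config = list(groups = groups, n_per_group = n_per_group,
                                    cv = cv, ct_sd = ct_sd, rep_sd = rep_sd,
                                    n_replicates = n_replicates,
                                    efficiency = efficiency, seed = seed)))
  })
}
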