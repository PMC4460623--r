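## Synthetic matched tumor/normal cohort with planted ground truth: a
## desk-scale analogue of a TCGA-like breast-cancer cohort. Expression is
## a per-module latent-factor model driven by known directed regulatory
## structures (hub TFs feeding target genes); methylation is logit-normal
## with a planted silenced subset mirroring (minus) expression; miRNAs
## carry planted differential shifts; variants sit on a toy genome with
## planted proximity to dysregulated miRNA loci and differentially
## methylated CpGs; prior/target/drug/term tables are consistent with the
## planted truth.

#' Default configuration of the synthetic cohort
#'
#' The defaults mirror the shape of a tumor/normal multi-omics cohort at
#' reduced scale: 20 tumor + 20 normal samples, 600 genes, 120 miRNAs,
#' three 5-Mb chromosomes.
#'
#' @param ... Named overrides of any default field.
#' @return Configuration list.
#' @export
synth_config <- function(...) {
  cfg <- list(
    n_tumor = 20L, n_normal = 20L,
    n_genes = 600L, n_mirnas = 120L,
    chrom_sizes = c(chr1 = 5000000L, chr2 = 5000000L, chr3 = 5000000L),
    n_modules = 4L, module_size = 40L, n_hubs = 3L,
    n_extra_de = 40L,              # DE genes outside any module
    delta_expr = 2,                # tumor/normal mean shift on DE genes
    noise_sd = 0.4,                # child-node residual SD in the DAG model
    measure_sd = 0.2,              # measurement noise on every gene
    edge_weight_range = c(0.9, 1.1),
    n_de_mirnas = 30L, delta_mirna = 2, mirna_sd = 1,
    n_silenced = 20L,              # down-regulated genes mirrored in methylation
    silencing_noise_sd = 0.2,
    n_dm_extra = 30L,              # extra DM genes, planted 2:1 up:down
    meth_logit_mean = -1.5, meth_logit_sd = 0.5, dm_logit_shift = 1.5,
    probes_per_gene = 2L, probe_noise_sd = 0.1,
    n_background_variants = 60L,
    n_planted_mirna_prox = 10L, mirna_prox_max_bp = 25000L,
    n_planted_cpg_prox = 12L, cpg_prox_max_bp = 300L,
    curated_fraction = 0.6,        # fraction of true hub edges in the priors
    targets_per_mirna_de = 10L,    # DE-gene targets of each DE miRNA
    targets_per_mirna_bg = 4L,     # background targets of each DE miRNA
    background_targets = 12L       # targets of each non-DE miRNA
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad) > 0L) stop("unknown config field(s): ",
                             paste(bad, collapse = ", "))
  cfg[names(overrides)] <- overrides
  cfg
}

random_dag <- function(genes, hubs, weight_range) {
  non_hubs <- setdiff(genes, hubs)
  edges <- list()
  # hub chain gives the hubs their own dependency structure
  if (length(hubs) > 1L) {
    for (i in 2:length(hubs)) {
      edges[[length(edges) + 1L]] <-
        data.frame(from = hubs[i - 1L], to = hubs[i],
                   weight = stats::runif(1, weight_range[1], weight_range[2]) *
                     sample(c(-1, 1), 1L), stringsAsFactors = FALSE)
    }
  }
  for (i in seq_along(non_hubs)) {
    # every non-hub gets >= 1 hub parent, so the hubs dominate the module
    n_par <- sample(1:2, 1L, prob = c(0.7, 0.3))
    parents <- c(sample(hubs, 1L),
                 if (n_par == 2L && i > 1L) sample(non_hubs[seq_len(i - 1L)], 1L))
    parents <- unique(parents)
    for (j in seq_along(parents)) {
      # secondary parents contribute half weight so the hub loading
      # stays dominant (keeps modules coherent under soft thresholding)
      w <- stats::runif(1, weight_range[1], weight_range[2]) *
        sample(c(-1, 1), 1L) * if (j == 1L) 1 else 0.5
      edges[[length(edges) + 1L]] <-
        data.frame(from = parents[j], to = non_hubs[i], weight = w,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, edges)
}

simulate_dag_expression <- function(genes, dag, n, noise_sd) {
  x <- matrix(0, length(genes), n, dimnames = list(genes, NULL))
  parents <- split(seq_len(nrow(dag)), dag$to)
  g <- igraph::graph_from_data_frame(dag[, c("from", "to")],
                                     vertices = data.frame(name = genes))
  order <- names(igraph::topo_sort(g))
  for (v in order) {
    rows <- parents[[v]]
    if (is.null(rows)) {
      x[v, ] <- stats::rnorm(n)
    } else {
      mu <- rep(0, n)
      for (r in rows) mu <- mu + dag$weight[r] * x[dag$from[r], ]
      x[v, ] <- mu + stats::rnorm(n, sd = noise_sd)
    }
  }
  x
}

#' Generate the synthetic cohort with planted truth
#'
#' Identical seeds give byte-identical outputs; all randomness flows from
#' deterministically derived sub-seeds of `seed`.
#'
#' @param config From [synth_config()].
#' @param seed Integer master seed.
#' @return List: `cohort` (`OmicsCohort`), `features` (tss, cpg, mirna
#'   tables + chrom_sizes), `meth_probes` (probe matrix + probe-gene map),
#'   `tables` (prior/target/drug/term tables), `truth` (`TruthBundle`).
#' @export
generate_cohort <- function(config = synth_config(), seed = 1L) {
  cfg <- config
  if (cfg$n_modules * cfg$module_size + cfg$n_extra_de > cfg$n_genes) {
    stop("infeasible config: module + extra DE genes exceed gene count")
  }
  if (cfg$n_de_mirnas > cfg$n_mirnas) {
    stop("infeasible config: n_de_mirnas exceeds n_mirnas")
  }
  if (cfg$n_hubs >= cfg$module_size && cfg$n_modules > 0L) {
    stop("infeasible config: n_hubs must be below module_size")
  }
  n <- cfg$n_tumor + cfg$n_normal
  samples <- c(sprintf("T%02d", seq_len(cfg$n_tumor)),
               sprintf("N%02d", seq_len(cfg$n_normal)))
  group <- stats::setNames(rep(c("tumor", "normal"),
                               c(cfg$n_tumor, cfg$n_normal)), samples)
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  mirnas <- sprintf("mir%03d", seq_len(cfg$n_mirnas))

  out <- with_seed(derive_seed(seed, 1L), {
    ## --- module structure and expression -------------------------------
    module_assignment <- stats::setNames(rep(0L, cfg$n_genes), genes)
    dags <- list()
    hubs_per_module <- list()
    expr <- matrix(stats::rnorm(cfg$n_genes * n), cfg$n_genes, n,
                   dimnames = list(genes, samples))
    idx <- 1L
    for (m in seq_len(cfg$n_modules)) {
      mg <- genes[idx:(idx + cfg$module_size - 1L)]
      idx <- idx + cfg$module_size
      module_assignment[mg] <- m
      hubs <- mg[seq_len(cfg$n_hubs)]
      hubs_per_module[[m]] <- hubs
      dag <- random_dag(mg, hubs, cfg$edge_weight_range)
      dags[[m]] <- dag
      sim <- simulate_dag_expression(mg, dag, n, cfg$noise_sd)
      # unit variance per gene keeps effect sizes comparable across depths
      expr[mg, ] <- t(scale(t(sim)))
    }
    extra_de <- if (cfg$n_extra_de > 0L) {
      genes[idx:(idx + cfg$n_extra_de - 1L)]
    } else character(0)
    module_genes <- genes[module_assignment > 0L]
    de_genes <- c(module_genes, extra_de)
    # module genes shift along their loading on the module factor (first
    # hub), so the group shift reinforces within-module correlation
    # instead of coupling modules to each other
    de_direction <- stats::setNames(character(length(de_genes)), de_genes)
    for (m in seq_len(cfg$n_modules)) {
      mg <- genes[module_assignment == m]
      factor_gene <- hubs_per_module[[m]][1L]
      loading <- drop(stats::cor(t(expr[mg, , drop = FALSE]),
                                 expr[factor_gene, ]))
      de_direction[mg] <- ifelse(loading >= 0, "up", "down")
    }
    de_direction[extra_de] <- sample(c("up", "down"), cfg$n_extra_de,
                                     replace = TRUE)
    if (length(de_genes) > 0L) {
      shift <- ifelse(de_direction == "up", cfg$delta_expr, -cfg$delta_expr)
      expr[de_genes, group == "tumor"] <-
        expr[de_genes, group == "tumor"] + shift
    }
    expr <- expr + matrix(stats::rnorm(length(expr), sd = cfg$measure_sd),
                          nrow(expr))
    expr <- expr + 8  # log2-like positive scale

    ## --- methylation ----------------------------------------------------
    down_genes <- names(de_direction)[de_direction == "down"]
    silenced <- sample(down_genes, min(cfg$n_silenced, length(down_genes)))
    non_de <- setdiff(genes, de_genes)
    dm_extra <- sample(non_de, cfg$n_dm_extra)
    n_up <- round(2 / 3 * cfg$n_dm_extra)  # planted 2:1 up:down ratio
    dm_extra_dir <- stats::setNames(
      rep(c("up", "down"), c(n_up, cfg$n_dm_extra - n_up)), dm_extra)
    logit <- matrix(stats::rnorm(cfg$n_genes * n, cfg$meth_logit_mean,
                                 cfg$meth_logit_sd),
                    cfg$n_genes, n, dimnames = list(genes, samples))
    if (length(silenced) > 0L) {
      z <- t(scale(t(expr[silenced, , drop = FALSE])))
      logit[silenced, ] <- -z +
        matrix(stats::rnorm(length(z), sd = cfg$silencing_noise_sd),
               nrow(z), ncol(z))
    }
    sgn <- ifelse(dm_extra_dir == "up", 1, -1)
    logit[dm_extra, group == "tumor"] <-
      logit[dm_extra, group == "tumor"] + sgn * cfg$dm_logit_shift
    meth_gene_true <- stats::plogis(logit)
    dm_genes <- c(silenced, dm_extra)
    dm_direction <- stats::setNames(
      c(rep("up", length(silenced)), unname(dm_extra_dir)), dm_genes)

    ## --- genome features ------------------------------------------------
    chroms <- names(cfg$chrom_sizes)
    tss <- data.frame(
      chrom = chroms[(seq_len(cfg$n_genes) - 1L) %% length(chroms) + 1L],
      start = NA_integer_, end = NA_integer_, id = genes, strand = "+",
      stringsAsFactors = FALSE)
    tss$start <- vapply(tss$chrom, function(ch) {
      sample.int(cfg$chrom_sizes[[ch]] - 20000L, 1L) + 10000L
    }, integer(1L))
    tss$end <- tss$start + 1L
    cpg_rows <- list()
    for (i in seq_len(cfg$n_genes)) {
      offs <- sample(-1800:1800, cfg$probes_per_gene)
      cpg_rows[[i]] <- data.frame(
        chrom = tss$chrom[i], start = tss$start[i] + offs,
        id = sprintf("cg_%s_%d", genes[i], seq_len(cfg$probes_per_gene)),
        gene_id = genes[i], stringsAsFactors = FALSE)
    }
    cpg <- do.call(rbind, cpg_rows)
    cpg$end <- cpg$start + 1L
    cpg$strand <- "."
    cpg <- cpg[, c("chrom", "start", "end", "id", "strand", "gene_id")]
    mirna_feat <- data.frame(
      chrom = chroms[(seq_len(cfg$n_mirnas) - 1L) %% length(chroms) + 1L],
      start = NA_integer_, id = mirnas, strand = "+",
      stringsAsFactors = FALSE)
    mirna_feat$start <- vapply(mirna_feat$chrom, function(ch) {
      sample.int(cfg$chrom_sizes[[ch]] - 20000L, 1L) + 10000L
    }, integer(1L))
    mirna_feat$end <- mirna_feat$start + 80L
    mirna_feat <- mirna_feat[, c("chrom", "start", "end", "id", "strand")]

    ## --- methylation probes --------------------------------------------
    probe_logit <- logit[cpg$gene_id, , drop = FALSE] +
      matrix(stats::rnorm(nrow(cpg) * n, sd = cfg$probe_noise_sd),
             nrow(cpg), n)
    meth_probes <- stats::plogis(probe_logit)
    dimnames(meth_probes) <- list(cpg$id, samples)
    # cohort-level gene methylation = per-gene probe mean (what
    # collapse_probes reproduces from the written fixture)
    meth <- rowsum(meth_probes, cpg$gene_id) /
      as.vector(table(cpg$gene_id)[sort(unique(cpg$gene_id))])
    meth <- meth[genes, , drop = FALSE]

    ## --- miRNA expression ----------------------------------------------
    de_mirnas <- sample(mirnas, cfg$n_de_mirnas)
    mirna_dir <- stats::setNames(sample(c("up", "down"), cfg$n_de_mirnas,
                                        replace = TRUE), de_mirnas)
    mirna_expr <- matrix(stats::rnorm(cfg$n_mirnas * n, 6, cfg$mirna_sd),
                         cfg$n_mirnas, n, dimnames = list(mirnas, samples))
    mshift <- ifelse(mirna_dir == "up", cfg$delta_mirna, -cfg$delta_mirna)
    mirna_expr[de_mirnas, group == "tumor"] <-
      mirna_expr[de_mirnas, group == "tumor"] + mshift

    ## --- somatic variants ----------------------------------------------
    bases <- c("A", "C", "G", "T")
    tumor_samples <- samples[group == "tumor"]
    bg_chrom <- sample(chroms, cfg$n_background_variants, replace = TRUE)
    bg_ref <- sample(bases, cfg$n_background_variants, replace = TRUE)
    bg <- data.frame(
      chrom = bg_chrom,
      pos = vapply(bg_chrom, function(ch) {
        sample.int(cfg$chrom_sizes[[ch]], 1L) - 1L
      }, integer(1L)),
      ref = bg_ref,
      alt = vapply(bg_ref, function(r) sample(setdiff(bases, r), 1L),
                   character(1L)),
      # cycling through tumor samples keeps them all in the alignment
      # whenever there are at least as many variants as tumor samples
      sample_id = sample(rep(tumor_samples,
                             length.out = cfg$n_background_variants)),
      stringsAsFactors = FALSE)
    prox_mirnas <- sample(de_mirnas, cfg$n_planted_mirna_prox, replace = TRUE)
    pm_ref <- sample(bases, cfg$n_planted_mirna_prox, replace = TRUE)
    planted_mirna <- data.frame(
      chrom = mirna_feat$chrom[match(prox_mirnas, mirna_feat$id)],
      pos = vapply(mirna_feat$start[match(prox_mirnas, mirna_feat$id)],
                   function(s) s - sample.int(min(cfg$mirna_prox_max_bp, s), 1L),
                   integer(1L)),
      ref = pm_ref,
      alt = vapply(pm_ref, function(r) sample(setdiff(bases, r), 1L),
                   character(1L)),
      sample_id = sample(tumor_samples, cfg$n_planted_mirna_prox,
                         replace = TRUE),
      stringsAsFactors = FALSE)
    dm_cpgs <- cpg[cpg$gene_id %in% dm_genes, , drop = FALSE]
    prox_cpgs <- dm_cpgs[sample.int(nrow(dm_cpgs),
                                    cfg$n_planted_cpg_prox), , drop = FALSE]
    planted_cpg <- data.frame(
      chrom = prox_cpgs$chrom,
      pos = vapply(prox_cpgs$start,
                   function(s) s - sample.int(min(cfg$cpg_prox_max_bp, s), 1L),
                   integer(1L)),
      ref = "C",
      alt = sample(c("A", "G", "T"), cfg$n_planted_cpg_prox, replace = TRUE),
      sample_id = sample(tumor_samples, cfg$n_planted_cpg_prox,
                         replace = TRUE),
      stringsAsFactors = FALSE)
    variants <- rbind(bg, planted_mirna, planted_cpg)
    variants <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
    rownames(variants) <- NULL
    planted_pairs <- rbind(
      data.frame(chrom = planted_mirna$chrom, pos = planted_mirna$pos,
                 feature_id = prox_mirnas, kind = "mirna",
                 stringsAsFactors = FALSE),
      data.frame(chrom = planted_cpg$chrom, pos = planted_cpg$pos,
                 feature_id = prox_cpgs$id, kind = "cpg",
                 stringsAsFactors = FALSE))

    ## --- prior / target / drug / term tables ----------------------------
    all_hubs <- unlist(hubs_per_module)
    true_edges <- do.call(rbind, lapply(seq_along(dags), function(m) {
      cbind(dags[[m]][, c("from", "to")], module = m)
    }))
    hub_edges <- true_edges[true_edges$from %in% all_hubs, , drop = FALSE]
    if (!is.null(hub_edges) && nrow(hub_edges) > 0L) {
      n_cur <- max(1L, round(cfg$curated_fraction * nrow(hub_edges)))
      cur <- hub_edges[sample.int(nrow(hub_edges), n_cur), , drop = FALSE]
      prior_regulation <- data.frame(tf = cur$from, target = cur$to,
                                     source = "curated_db",
                                     stringsAsFactors = FALSE)
    } else {
      prior_regulation <- data.frame(tf = character(), target = character(),
                                     source = character())
    }
    tf_table <- data.frame(gene = all_hubs, stringsAsFactors = FALSE)
    mt_rows <- lapply(mirnas, function(m) {
      if (m %in% de_mirnas && length(de_genes) >= cfg$targets_per_mirna_de) {
        targs <- c(sample(de_genes, cfg$targets_per_mirna_de),
                   sample(non_de, cfg$targets_per_mirna_bg))
      } else {
        targs <- sample(genes, cfg$background_targets)
      }
      data.frame(regulator_id = m, target_id = targs,
                 kind = "mirna_to_mrna", source = "target_db",
                 stringsAsFactors = FALSE)
    })
    mirna_targets <- do.call(rbind, mt_rows)
    tm_tfs <- if (length(de_mirnas) > 0L) {
      sample(all_hubs, min(6L, length(all_hubs)))
    } else character(0)
    tm_rows <- lapply(tm_tfs, function(t) {
      regulated <- c(sample(de_mirnas, min(5L, length(de_mirnas))),
                     sample(setdiff(mirnas, de_mirnas), 1L))
      data.frame(regulator_id = t, target_id = regulated,
                 kind = "tf_to_mirna", source = "tf_mirna_db",
                 stringsAsFactors = FALSE)
    })
    # background (non-DE) regulators widen the miRNA universe without
    # entering the network themselves
    for (bg_tf in sample(non_de, 20L)) {
      tm_rows[[length(tm_rows) + 1L]] <-
        data.frame(regulator_id = bg_tf,
                   target_id = sample(mirnas, 5L),
                   kind = "tf_to_mirna", source = "tf_mirna_db",
                   stringsAsFactors = FALSE)
    }
    tf_mirna <- do.call(rbind, tm_rows)
    drugged <- if (length(all_hubs) >= 2L) {
      sample(all_hubs, max(2L, length(all_hubs) %/% 3L))
    } else character(0)
    drug_targets <- data.frame(
      gene = drugged,
      drug = sprintf("drug_%02d", seq_along(drugged)),
      source = rep(c("db_a", "db_b"), length.out = length(drugged)),
      stringsAsFactors = FALSE)
    term_rows <- lapply(seq_len(cfg$n_modules), function(m) {
      data.frame(term_id = sprintf("TERM%03d", m),
                 term_name = sprintf("module_%d_process", m),
                 gene = genes[module_assignment == m],
                 stringsAsFactors = FALSE)
    })
    term_rows[[cfg$n_modules + 1L]] <- data.frame(
      term_id = "TERM900", term_name = "background_process",
      gene = sample(genes, 50L), stringsAsFactors = FALSE)
    term_annotations <- do.call(rbind, term_rows)

    planted_mds <- hubs_per_module
    if (length(planted_mds) > 0L) {
      names(planted_mds) <- paste0("module_", seq_along(planted_mds))
    }
    for (m in seq_len(cfg$n_modules)) {
      mg <- genes[module_assignment == m]
      stopifnot(is_dominating(mg, dags[[m]], planted_mds[[m]]))
    }

    list(expr = expr, meth = meth, meth_probes = meth_probes, cpg = cpg,
         tss = tss, mirna_feat = mirna_feat, mirna_expr = mirna_expr,
         variants = variants, group = group, samples = samples,
         truth = list(
           de_genes = de_genes, de_direction = de_direction,
           de_mirnas = de_mirnas, mirna_direction = mirna_dir,
           dm_genes = dm_genes, dm_direction = dm_direction,
           silenced_genes = silenced,
           module_assignment = module_assignment,
           true_dag_per_module = dags,
           planted_mds = planted_mds,
           planted_proximal_pairs = planted_pairs),
         tables = list(
           tf_table = tf_table, prior_regulation = prior_regulation,
           mirna_targets = mirna_targets, tf_mirna = tf_mirna,
           drug_targets = drug_targets,
           term_annotations = term_annotations))
  })

  cohort <- list(expr = out$expr, meth = out$meth, mirna = out$mirna_expr,
                 variants = out$variants, samples = out$samples,
                 group = out$group)
  class(cohort) <- "OmicsCohort"
  list(
    cohort = cohort,
    features = list(tss = out$tss,
                    cpg = out$cpg[, c("chrom", "start", "end", "id",
                                      "strand")],
                    cpg_gene = data.frame(cpg_id = out$cpg$id,
                                          gene_id = out$cpg$gene_id,
                                          stringsAsFactors = FALSE),
                    mirna = out$mirna_feat,
                    chrom_sizes = cfg$chrom_sizes),
    meth_probes = out$meth_probes,
    tables = out$tables,
    truth = out$truth,
    config = cfg,
    seed = seed
  )
}

#' Write the synthetic cohort as on-disk fixture files
#'
#' Emits every external format the readers consume: TSV matrices, BED
#' features, chrom.sizes, a VCF variant file, a sample sheet, the prior /
#' target / drug / term tables, and the truth bundle as JSON. Reading the
#' files back through the io layer reproduces the in-memory matrices
#' exactly (up to the numeric formatting width, 15 significant digits).
#'
#' @param bundle Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  old <- options(digits = 15)
  on.exit(options(old))
  write_matrix(signif(bundle$cohort$expr, 15), p("expr.tsv"), "gene_id")
  write_matrix(signif(bundle$meth_probes, 15), p("meth_probes.tsv"),
               "probe_id")
  write_matrix(signif(bundle$cohort$mirna, 15), p("mirna.tsv"), "mirna_id")
  write_table_tsv(data.frame(sample_id = bundle$cohort$samples,
                             group = unname(bundle$cohort$group)),
                  p("samples.tsv"))
  writeLines(sprintf("%s\t%d", names(bundle$features$chrom_sizes),
                     bundle$features$chrom_sizes), p("genome.chrom.sizes"))
  write_bed(bundle$features$tss, p("tss.bed"))
  write_bed(bundle$features$cpg, p("cpg.bed"))
  write_bed(bundle$features$mirna, p("mirna.bed"))
  write_variants_vcf(bundle$cohort$variants, p("variants.vcf"),
                     bundle$features$chrom_sizes)
  write_table_tsv(bundle$features$cpg_gene, p("cpg_gene.tsv"))
  write_table_tsv(bundle$tables$tf_table, p("tf_table.tsv"))
  write_table_tsv(bundle$tables$prior_regulation, p("prior_regulation.tsv"))
  write_table_tsv(bundle$tables$mirna_targets, p("mirna_targets.tsv"))
  write_table_tsv(bundle$tables$tf_mirna, p("tf_mirna.tsv"))
  write_table_tsv(bundle$tables$drug_targets, p("drug_targets.tsv"))
  write_table_tsv(bundle$tables$term_annotations, p("term_annotations.tsv"))
  truth <- bundle$truth
  truth$module_assignment <- as.list(truth$module_assignment)
  truth$de_direction <- as.list(truth$de_direction)
  truth$dm_direction <- as.list(truth$dm_direction)
  truth$mirna_direction <- as.list(truth$mirna_direction)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
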