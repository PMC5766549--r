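#' Pipeline configuration
#'
#' Collects the parameters of the end-to-end analysis: either a simulation
#' block (a [sim_config()]) or paths to existing inputs, quality-control
#' thresholds, the genome-wide significance threshold, enrichment, AWM, PCIT
#' and permutation parameters, a master seed and an output directory.
#'
#' @param out_dir Output directory.
#' @param simulate A [sim_config()], or `NULL` to read inputs from `paths`.
#' @param paths Named list with `genotypes` (PLINK prefix), `phenotypes`
#'   (TSV), `annotation` (BED), `gene_sets` (GMT), `tf_list` (text); ignored
#'   when `simulate` is given.
#' @param qc A [qc_thresholds()].
#' @param key_trait Key phenotype anchoring the AWM (default `"trait_1"`).
#' @param gwas_threshold Genome-wide significance threshold on `p_gc`
#'   (default 5e-5).
#' @param run_conditional Also run a conditional scan fixing the key trait's
#'   top SNP.
#' @param sig_alpha,flank_bp,min_set,max_set Enrichment parameters: nominal
#'   per-SNP threshold, SNP-to-gene flank, strict category-size bounds.
#' @param p_key,p_other,min_other_traits,gene_dist_bp,awm_rule AWM selection
#'   parameters (see [build_awm()]).
#' @param min_abs_r PCIT edge-magnitude threshold.
#' @param n_permutations Replicates of the variance-explained permutation.
#' @param cluster_k Number of trait clusters to cut.
#' @param seed Master seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            simulate = NULL,
                            paths = NULL,
                            qc = qc_thresholds(),
                            key_trait = "trait_1",
                            gwas_threshold = 5e-5,
                            run_conditional = TRUE,
                            sig_alpha = 0.05,
                            flank_bp = 15000,
                            min_set = 10,
                            max_set = 1000,
                            p_key = 0.05,
                            p_other = 0.05,
                            min_other_traits = 3,
                            gene_dist_bp = 10000,
                            awm_rule = "or",
                            min_abs_r = 0.80,
                            n_permutations = 10000,
                            cluster_k = 3,
                            seed = 1L) {
  if (is.null(simulate)) {
    needed <- c("genotypes", "phenotypes", "annotation", "gene_sets", "tf_list")
    if (is.null(paths) || !all(needed %in% names(paths))) {
      abort(paste0("`paths` must name: ", paste(needed, collapse = ", ")))
    }
  }
  if (gwas_threshold <= 0 || gwas_threshold >= 1) {
    abort("`gwas_threshold` must lie in (0, 1).")
  }
  structure(
    list(out_dir = out_dir, simulate = simulate, paths = paths, qc = qc,
         key_trait = key_trait, gwas_threshold = gwas_threshold,
         run_conditional = isTRUE(run_conditional), sig_alpha = sig_alpha,
         flank_bp = flank_bp, min_set = min_set, max_set = max_set,
         p_key = p_key, p_other = p_other,
         min_other_traits = min_other_traits, gene_dist_bp = gene_dist_bp,
         awm_rule = awm_rule, min_abs_r = min_abs_r,
         n_permutations = n_permutations, cluster_k = cluster_k,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Packaged demo configuration
#'
#' A small synthetic cohort (300 cows, 3,000 SNPs on 10 chromosomes, 6
#' traits in three clusters, a major QTL at 50% of the key trait's additive
#' variance, 500 permutation replicates) sized to complete in a few minutes
#' on one CPU while exercising every stage.
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @return A [pipeline_config()].
#' @export
demo_pipeline_config <- function(out_dir, seed = 1L) {
  sim <- sim_config(
    n_individuals = 300, n_snps = 3000, n_chromosomes = 10,
    maf_range = c(0.05, 0.5), n_traits = 6,
    trait_clusters = c(1, 1, 2, 2, 3, 3), within_cluster_corr = 0.6,
    h2 = c(0.6, 0.5, 0.4, 0.35, 0.3, 0.2),
    qtl = list(list(chr = 3, snp_index = 150, traits = 1:2, var_frac = 0.5)),
    n_herds = 20, parity_classes = 4, dim_classes = 6,
    ld_decay = 0.4, seed = seed
  )
  pipeline_config(out_dir = out_dir, simulate = sim, key_trait = "trait_1",
                  n_permutations = 500, seed = seed)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes (optionally) cohort simulation, file round-trip, marker QC, GRM
#' construction, per-trait REML + GRAMMAR-GC scans, an optional conditional
#' scan on the key trait's top SNP, SNP-to-gene mapping and Fisher gene-set
#' enrichment, AWM construction, trait clustering, the variance-explained
#' permutation test, PCIT network inference, topology metrics, TF trio
#' selection and regulation classification. All tables are TSV, all reports
#' JSON; a manifest with parameter echo, seed and per-file MD5 checksums is
#' written last, enabling byte-identical re-runs.
#'
#' @param config A [pipeline_config()].
#' @return The manifest (list), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$simulate)) {
    data_dir <- file.path(out, "data")
    .stage("simulate", {
      cohort <- simulate_cohort(config$simulate)
      write_cohort(cohort, data_dir)
    })
    paths <- list(
      genotypes = file.path(data_dir, "genotypes"),
      phenotypes = file.path(data_dir, "phenotypes.tsv"),
      annotation = file.path(data_dir, "genes.bed"),
      gene_sets = file.path(data_dir, "gene_sets.gmt"),
      tf_list = file.path(data_dir, "tf_catalog.txt")
    )
  } else {
    paths <- config$paths
    probe <- c(paste0(paths$genotypes, c(".bed", ".bim", ".fam")),
               paths$phenotypes, paths$annotation, paths$gene_sets,
               paths$tf_list)
    missing <- probe[!file.exists(unlist(probe))]
    if (length(missing) > 0) {
      abort(paste0("Missing input file(s): ", paste(missing, collapse = ", ")))
    }
  }

  inputs <- .stage("read", list(
    genotypes = read_plink(paths$genotypes),
    phenotypes = read_phenotypes(paths$phenotypes),
    genes = read_annotation_bed(paths$annotation),
    gene_sets = read_gmt(paths$gene_sets),
    tf_catalog = read_tf_list(paths$tf_list)
  ))

  qc_res <- .stage("qc", apply_qc(inputs$genotypes, config$qc))
  g <- qc_res$genotypes
  .write_tsv(qc_res$report, file.path(out, "qc_report.tsv"))

  grm <- .stage("grm", build_grm(g))
  traits <- grep("^trait_", names(inputs$phenotypes), value = TRUE)
  if (!config$key_trait %in% traits) {
    abort(paste0("Key trait absent from phenotypes: ", config$key_trait))
  }

  assoc <- .stage("gwas", gwas_scan(inputs$phenotypes, g, grm, traits = traits))
  .write_tsv(assoc, file.path(out, "assoc.tsv"))
  vc <- attr(assoc, "variance_components")
  .write_json(vc, file.path(out, "variance_components.json"))

  cond <- NULL
  if (config$run_conditional) {
    cond <- .stage("condition", {
      key_rows <- assoc[assoc$trait == config$key_trait & !is.na(assoc$p_gc), ]
      top <- key_rows$snp[which.min(key_rows$p_gc)]
      conditional_scan(inputs$phenotypes, config$key_trait, g, grm,
                       fixed_snps = top)
    })
    .write_json(as.list(cond$delta), file.path(out, "conditional_delta.json"))
  }

  enr <- .stage("enrich", {
    assignment <- map_snps_to_genes(g$snp_map, inputs$genes,
                                    flank_bp = config$flank_bp)
    sig <- significant_genes(assoc, assignment, alpha = config$sig_alpha)
    universe <- unique(assignment$gene)
    key_sig <- sig$gene[sig$trait == config$key_trait]
    res <- fisher_enrichment(key_sig, universe, inputs$gene_sets,
                             min_size = config$min_set,
                             max_size = config$max_set)
    .write_tsv(sig, file.path(out, "significant_genes.tsv"))
    .write_tsv(res, file.path(out, "enrichment.tsv"))
    res
  })

  awm <- .stage("awm", build_awm(
    assoc, inputs$genes, config$key_trait, p_key = config$p_key,
    p_other = config$p_other, min_other_traits = config$min_other_traits,
    gene_dist_bp = config$gene_dist_bp, rule = config$awm_rule
  ))
  .write_tsv(tidy(awm), file.path(out, "awm.tsv"))
  .write_json(list(key_trait = awm$key_trait, ap = awm$ap,
                   params = awm$params, chosen_snps = awm$info),
              file.path(out, "awm_meta.json"))

  clust <- .stage("cluster", cluster_traits(awm, k = config$cluster_k))
  .write_tsv(clust$clusters, file.path(out, "trait_clusters.tsv"))

  perm <- .stage("permutation", variance_explained_permutation(
    inputs$phenotypes, config$key_trait, g, awm$info$snp,
    n_replicates = config$n_permutations, seed = config$seed
  ))
  .write_json(as.list(glance(perm)), file.path(out, "permutation.json"))

  net <- .stage("network", {
    corr <- pairwise_correlation(awm)
    flags <- pcit(corr)
    filter_edges(corr, flags, min_abs_r = config$min_abs_r,
                 tf_catalog = inputs$tf_catalog)
  })
  write_sif(net, file.path(out, "network.sif"))
  write_graphml(net, file.path(out, "network.graphml"))
  topo <- .stage("topology", topology(net))
  .write_tsv(topo, file.path(out, "node_metrics.tsv"))

  trio_res <- .stage("trio", {
    if (sum(net$nodes$is_tf) >= 3) {
      trio <- best_tf_trio(net)
      reg <- classify_regulation(net, trio)
      list(trio = trio, regulation = reg)
    } else NULL
  })
  if (!is.null(trio_res)) {
    .write_json(list(
      tf_ids = trio_res$trio$tf_ids,
      n_covered = trio_res$trio$score,
      coverage_fraction = trio_res$trio$coverage_fraction,
      regulation = trio_res$regulation
    ), file.path(out, "tf_trio.json"))
  }

  files <- sort(setdiff(list.files(out, recursive = TRUE), "manifest.json"))
  manifest <- list(
    seed = config$seed,
    key_trait = config$key_trait,
    parameters = unclass(config)[setdiff(names(config), c("simulate", "paths", "qc"))],
    qc = unclass(config$qc),
    n_snps_post_qc = ncol(g$dosage),
    n_samples = nrow(g$dosage),
    n_significant = sum(assoc$p_gc < config$gwas_threshold, na.rm = TRUE),
    awm_genes = nrow(awm$matrix),
    network_edges = nrow(net$edges),
    checksums = as.list(setNames(
      unname(tools::md5sum(file.path(out, files))), files
    ))
  )
  .write_json(manifest, file.path(out, "manifest.json"))
  invisible(manifest)
}

.write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.double, logical(1))
  for (cn in names(df)[num]) df[[cn]] <- sprintf("%.10g", df[[cn]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
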