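#' Default pipeline configuration
#'
#' All screening thresholds live here with the study's values as defaults:
#' fold change 1.5, DE p 0.05, GS 0.2, MM 0.6, MAF 0.05, call rates 0.90,
#' eigengene merge height 0.25, minimum module size 50, extreme group size
#' 30. Simulation settings feed [sim_config()] when no input files are
#' given.
#'
#' @param ... Overrides of any default entry (nested lists are merged
#'   shallowly per top-level name).
#' @return Named list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    traits = c("LW", "DW", "EW", "BMW"),
    focal_trait = "EW",
    seed = 1L,
    counts = NULL, pheno = NULL, vcf = NULL,   # input paths; NULL = simulate
    sim = list(),                               # overrides for sim_config()
    en = list(alpha_grid = seq(0.1, 0.9, by = 0.1), k = 10L),
    wgcna = list(min_module_size = 50L, merge_cut = 0.25,
                 gs_min = 0.2, mm_min = 0.6, r2_target = 0.85),
    de = list(n_per_group = 30L, fc_min = 1.5, p_max = 0.05),
    qc = list(maf_min = 0.05, snp_call_min = 0.90, ind_call_min = 0.90),
    genassoc = list(enabled = FALSE, promoter_pad = 2000)
  )
  ov <- list(...)
  for (nm in names(ov)) {
    if (is.list(cfg[[nm]]) && is.list(ov[[nm]]))
      cfg[[nm]] <- modifyList(cfg[[nm]], ov[[nm]])
    else cfg[[nm]] <- ov[[nm]]
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys override [pipeline_config()]
#'   defaults.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the end-to-end candidate-discovery pipeline
#'
#' Executes normalize -> per-trait elastic-net association -> co-expression
#' network -> per-trait differential expression -> three-way intersection,
#' plus (optionally) the genotype arm (QC, eGWAS of the focal gene, per-SNP
#' trait GLM, SNP overlap). Inputs come from the file paths in the config
#' or, when absent, from [simulate_dataset()] under the config's simulation
#' settings, in which case the report also scores the result against the
#' planted truth. Fully deterministic given the seed.
#'
#' @param config A [pipeline_config()] (or path to a YAML file).
#' @param out_dir Optional directory for the JSON report and result tables.
#' @return List of class `"pipeline_result"` with per-stage outputs,
#'   `candidates` (a `"candidate_sets"`), optional `snp_candidates`, and
#'   `report` (the JSON-ready summary).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop("[", name, "] ", conditionMessage(e), call. = FALSE))

  ## inputs
  truth <- NULL
  if (is.null(config$counts)) {
    sim <- stage("simulate", {
      sc <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
      simulate_dataset(sc)
    })
    counts <- sim$counts; pheno <- sim$pheno; geno <- sim$geno
    truth <- sim$truth
  } else {
    counts <- stage("read", read_counts(config$counts))
    pheno <- stage("read", read_phenotypes(config$pheno))
    geno <- if (!is.null(config$vcf)) stage("read", read_vcf(config$vcf)) else NULL
  }

  ## normalize
  norm <- stage("normalize", {
    sf <- size_factors(counts)
    normalize_counts(counts, sf)
  })
  expr_log <- log_transform(norm)
  common <- intersect(colnames(expr_log), pheno$sample_id)
  pheno_al <- pheno[match(common, pheno$sample_id), , drop = FALSE]
  expr_al <- expr_log[, common, drop = FALSE]

  ## per-trait elastic net
  en <- stage("en-assoc", {
    lapply(setNames(config$traits, config$traits), function(tr)
      en_assoc(expr_al, pheno_al[[tr]],
               alpha_grid = config$en$alpha_grid, k = config$en$k,
               seed = config$seed))
  })
  en_sets <- lapply(en, `[[`, "selected_1se")

  ## network stage
  net <- stage("wgcna", run_wgcna(
    expr_al, pheno_al, traits = config$traits,
    min_module_size = config$wgcna$min_module_size,
    merge_cut = config$wgcna$merge_cut, gs_min = config$wgcna$gs_min,
    mm_min = config$wgcna$mm_min, r2_target = config$wgcna$r2_target))
  hub_sets <- lapply(net$hubs, `[[`, "hubs")

  ## differential expression
  de <- stage("de", {
    lapply(setNames(config$traits, config$traits), function(tr) {
      grp <- split_high_low(pheno_al, tr, config$de$n_per_group)
      de_test(norm[, common, drop = FALSE], grp,
              fc_min = config$de$fc_min, p_max = config$de$p_max)
    })
  })
  deg_sets <- lapply(de, function(d) d$gene_id[d$is_deg])

  ## intersection
  candidates <- stage("integrate",
                      intersect_gene_candidates(en_sets, hub_sets, deg_sets))

  ## optional genotype arm
  snp_candidates <- NULL
  egwas <- NULL
  if (isTRUE(config$genassoc$enabled) && !is.null(geno)) {
    gen <- stage("genassoc", {
      g <- qc_filter_genotypes(geno, config$qc$maf_min,
                               config$qc$snp_call_min, config$qc$ind_call_min)
      g_al <- genotype_matrix(g$dosage[match(common, rownames(g$dosage)), ,
                                       drop = FALSE], g$snp_info)
      K <- build_grm(g_al)
      focal <- if (!is.null(truth)) truth$focal_gene else
        candidates$overlap_per_trait[[config$focal_trait]][1L]
      eg <- lmm_assoc(standardize_vector(expr_al[focal, ]), g_al, K)
      eg_hits <- eg$table$snp_id[eg$table$p < eg$thresholds$suggestive]
      region <- if (!is.null(truth)) truth$focal_gene_locus else NULL
      glm_hits <- lapply(setNames(config$traits, config$traits), function(tr) {
        snps <- if (!is.null(region))
          extract_gene_region_snps(g_al, region, config$genassoc$promoter_pad)
        else g_al$snp_info$snp_id
        a <- glm_assoc(pheno_al[[tr]], g_al, snps)
        a$table$snp_id[a$table$p < 0.05]
      })
      list(egwas = eg,
           snps = intersect_snp_candidates(eg_hits, glm_hits))
    })
    egwas <- gen$egwas
    snp_candidates <- gen$snps
  }

  report <- list(
    seed = config$seed,
    n_samples = length(common),
    n_genes = nrow(expr_al),
    stage_n = list(en = vapply(en, `[[`, integer(1) + 0, "n"),
                   wgcna = net$n_used,
                   de = nrow(pheno_al)),
    soft_power = net$power,
    n_modules = length(unique(net$labels[net$labels > 0])),
    en_selected_sizes = vapply(en_sets, length, integer(1)),
    hub_sizes = vapply(hub_sets, length, integer(1)),
    deg_sizes = vapply(deg_sets, length, integer(1)),
    en_all_traits = candidates$en_all_traits,
    overlap_per_trait = candidates$overlap_per_trait,
    venn_per_trait = candidates$venn_per_trait,
    snp_overlap = snp_candidates$overlap,
    thresholds = list(fc_min = config$de$fc_min, p_max = config$de$p_max,
                      gs_min = config$wgcna$gs_min, mm_min = config$wgcna$mm_min,
                      maf_min = config$qc$maf_min,
                      merge_cut = config$wgcna$merge_cut)
  )
  if (!is.null(truth)) {
    report$truth_focal_gene <- truth$focal_gene
    report$headline_hit <- identical(
      candidates$overlap_per_trait[[config$focal_trait]], truth$focal_gene)
  }
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.table(data.frame(gene_id = names(net$labels), module = net$labels),
                file.path(out_dir, "modules.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  structure(list(en = en, net = net, de = de, candidates = candidates,
                 snp_candidates = snp_candidates, egwas = egwas,
                 truth = truth, report = report, config = config),
            class = "pipeline_result")
}
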