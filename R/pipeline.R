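# Pipeline runner: chains rarefaction, diversity, beta diversity, core
# taxa, neutral-model fit, NST, niche breadth and network inference from a
# single config, writing per-stage TSVs and a JSON report.

PIPELINE_STAGES <- c("tables", "diversity", "betadiv", "core", "ncm", "nst",
                     "niche", "network")

#' Run the full community-assembly pipeline
#'
#' Stages run in dependency order: table input (files or a simulated
#' gradient dataset) and rarefaction; alpha diversity; Bray-Curtis
#' PCoA/PERMANOVA/UPGMA; core taxa per group; neutral community model; NST;
#' niche breadth; ensemble network. Failures in stages after the table
#' stage are recorded in the report and do not abort the run. One global
#' seed expands deterministically into per-stage seeds.
#'
#' @param config A named list or path to a YAML file. Recognised keys:
#'   `input` (list: `counts`, `metadata`, optional `taxonomy` file paths) or
#'   `simulate` (list passed to [synthetic_spec()]); `rarefaction_depth`
#'   (`"min"` or an integer; `"none"` to skip); `seed`; `output_dir`;
#'   optional per-stage parameter blocks `diversity`, `betadiv`, `core`,
#'   `nst`, `network`.
#' @return The report list, invisibly; written as `report.json` under
#'   `output_dir` together with per-stage TSVs.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML file path.")
  known <- c("input", "simulate", "rarefaction_depth", "seed", "output_dir",
             "diversity", "betadiv", "core", "nst", "network", "ncm")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  if (is.null(config$output_dir)) abort("config needs `output_dir`.")
  if (is.null(config$input) && is.null(config$simulate)) {
    abort("config needs either `input` file paths or a `simulate` block.")
  }
  if (!is.null(config$input)) {
    for (f in unlist(config$input)) {
      if (!file.exists(f)) abort(sprintf("input file not found: %s", f))
    }
  }
  seed <- check_scalar_int(config$seed %||% 1, "seed", min = 0L)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = seed, stages = list())
  stage_seed <- function(name) derive_seed(seed, paste0("pipeline::", name))

  # --- tables (mandatory) ----------------------------------------------
  taxonomy <- NULL
  if (!is.null(config$input)) {
    counts <- read_count_table(config$input$counts)
    metadata <- read_sample_metadata(config$input$metadata)
    if (!is.null(config$input$taxonomy)) taxonomy <- read_taxonomy(config$input$taxonomy)
  } else {
    spec <- do.call(synthetic_spec, c(config$simulate, list(seed = stage_seed("simulate"))))
    sim <- simulate_gradient_dataset(spec)
    counts <- sim$counts; metadata <- sim$metadata
    jsonlite::write_json(sim$truth, file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  depth_cfg <- config$rarefaction_depth %||% "min"
  totals <- colSums(as_count_matrix(counts))
  if (!identical(depth_cfg, "none")) {
    depth <- if (identical(depth_cfg, "min")) min(totals) else check_scalar_int(depth_cfg, "rarefaction_depth")
    counts <- rarefy(counts, depth, seed = stage_seed("rarefy"))
    metadata <- metadata[metadata$sample_id %in% names(counts)[-1], , drop = FALSE]
  } else {
    depth <- NA
  }
  dropped <- attr(counts, "dropped")
  counts <- counts[rowSums(counts[-1]) > 0, , drop = FALSE] # prune lost taxa
  write_count_table(counts, file.path(out_dir, "counts_rarefied.tsv"))
  report$stages$tables <- list(
    depth = depth, n_taxa = nrow(counts), n_samples = ncol(counts) - 1,
    dropped = dropped %||% character(0),
    seed = stage_seed("rarefy"))

  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) {
      warn(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
      list(error = conditionMessage(e))
    })
    report$stages[[name]] <<- res
  }

  grp <- metadata$group[match(names(counts)[-1], metadata$sample_id)]

  run_stage("diversity", function() {
    base <- config$diversity$base %||% exp(1)
    alpha <- alpha_diversity(counts, base = base)
    readr::write_tsv(alpha, file.path(out_dir, "alpha_diversity.tsv"), progress = FALSE)
    list(base = base, mean_shannon = mean(alpha$shannon),
         mean_goods_coverage = mean(alpha$goods_coverage))
  })

  run_stage("betadiv", function() {
    n_perm <- config$betadiv$n_perm %||% 999
    dm <- bray_curtis(counts)
    ord <- pcoa(dm)
    readr::write_tsv(ord$coordinates, file.path(out_dir, "pcoa.tsv"), progress = FALSE)
    perm <- permanova(dm, grp, n_perm = n_perm, seed = stage_seed("betadiv"))
    tree <- upgma(dm)
    ape::write.tree(tree, file.path(out_dir, "upgma.nwk"))
    list(n_perm = n_perm, seed = stage_seed("betadiv"),
         prop_axis1 = ord$proportion_explained[1],
         prop_axis2 = ord$proportion_explained[2],
         pseudo_f = perm$pseudo_f, r2 = perm$r2, p_value = perm$p_value)
  })

  run_stage("core", function() {
    occ <- config$core$occurrence_min %||% 0.8
    ra <- config$core$mean_ra_min %||% 0.001
    cs <- core_sets(counts, metadata, occurrence_min = occ, mean_ra_min = ra)
    readr::write_tsv(cs, file.path(out_dir, "core_taxa.tsv"), progress = FALSE)
    shared <- if (length(unique(cs$group)) >= 2) shared_core(cs) else character(0)
    writeLines(shared, file.path(out_dir, "shared_core.txt"))
    list(occurrence_min = occ, mean_ra_min = ra,
         n_core = nrow(cs), n_shared = length(shared))
  })

  run_stage("ncm", function() {
    fit <- fit_ncm(counts)
    readr::write_tsv(fit$fits, file.path(out_dir, "ncm_taxa.tsv"), progress = FALSE)
    as.list(glance(fit))
  })

  run_stage("nst", function() {
    n_draws <- config$nst$n_draws %||% 1000
    metric <- config$nst$metric %||% "bray"
    res <- nst(counts, metadata, metric = metric, n_draws = n_draws,
               seed = stage_seed("nst"))
    readr::write_tsv(res, file.path(out_dir, "nst.tsv"), progress = FALSE)
    list(n_draws = n_draws, metric = metric, seed = stage_seed("nst"),
         nst = setNames(as.list(res$nst), res$group))
  })

  run_stage("niche", function() {
    nb <- niche_breadth(counts)
    bc <- community_niche_breadth(counts)
    readr::write_tsv(nb, file.path(out_dir, "niche_breadth.tsv"), progress = FALSE)
    readr::write_tsv(bc, file.path(out_dir, "bcom.tsv"), progress = FALSE)
    gm <- tapply(bc$bcom, grp, mean)
    list(group_mean_bcom = as.list(gm))
  })

  run_stage("network", function() {
    np <- config$network$n_perm %||% 1000
    nb <- config$network$n_boot %||% 100
    qq <- config$network$q %||% 0.05
    tn <- config$network$top_n %||% 100
    net <- build_network(counts, taxonomy = taxonomy, top_n = tn,
                         n_perm = np, n_boot = nb, q = qq,
                         seed = stage_seed("network"))
    readr::write_tsv(net$edges, file.path(out_dir, "network_edges.tsv"), progress = FALSE)
    c(list(n_perm = np, n_boot = nb, q = qq, top_n = tn,
           seed = stage_seed("network")), as.list(net$topology))
  })

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}
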