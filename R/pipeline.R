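#' Run the full river-network analysis pipeline
#'
#' Orchestrates the complete workflow from one configuration: load (or
#' simulate) inputs, preprocess, build one co-occurrence network per
#' reach-by-season group, compute topology, modules and node roles, fit the
#' neutral community model per group, compute the HAILS land-use index,
#' correlate network indices and keystone taxa with environmental
#' variables, and write a deterministic report bundle with a
#' machine-readable manifest of every parameter, seed and output file hash.
#'
#' The configuration is a list (or path to a YAML file) with:
#' \describe{
#'   \item{output_dir}{where the bundle is written.}
#'   \item{seed}{master seed; per-stage seeds are derived from it and
#'     recorded in the manifest.}
#'   \item{simulate}{optional synthetic-study block (see
#'     [demo_config()]); otherwise `inputs` must give `abundance`,
#'     `metadata` and optionally `landuse` paths.}
#'   \item{grouping}{metadata columns defining analysis groups
#'     (default `c("reach", "season")`).}
#'   \item{inference}{arguments for [inference_config()].}
#'   \item{rarefy_depth}{optional even depth for [rarefy()].}
#'   \item{keystone}{`r_min` / `alpha` for [keystone_env_network()].}
#' }
#'
#' Groups with fewer than 4 samples are skipped for network inference with a
#' logged reason. Any stage error aborts the run naming the stage. The log
#' and manifest carry no timestamps, so rerunning an identical configuration
#' yields a byte-identical bundle.
#'
#' @param config List or path to a YAML configuration file.
#' @return Invisibly, a list with the per-group results, the HAILS table,
#'   correlation tables and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$output_dir)) stop("config$output_dir is required")
  out_dir <- config$output_dir
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  grouping <- if (is.null(config$grouping)) c("reach", "season") else config$grouping
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  in_dir <- file.path(out_dir, "inputs")
  net_dir <- file.path(out_dir, "networks")
  tab_dir <- file.path(out_dir, "tables")
  for (d in c(in_dir, net_dir, tab_dir))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  note <- function(level, ...) {
    log_lines <<- c(log_lines, paste0("[", level, "] ", sprintf(...)))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # ---- inputs -------------------------------------------------------------
  if (!is.null(config$simulate)) {
    stage("simulate", {
      sim <- simulate_study(config$simulate, seed = seed)
      write_abundance(sim$matrix, file.path(in_dir, "abundance.tsv"))
      meta <- cbind(sim$matrix$sample_groups, sim$env)
      utils::write.table(data.frame(sample = rownames(meta), meta),
                         file.path(in_dir, "metadata.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      write_landuse(sim$landuse, file.path(in_dir, "landuse.tsv"))
      note("info", "simulated study written to inputs/")
    })
    paths <- list(abundance = file.path(in_dir, "abundance.tsv"),
                  metadata = file.path(in_dir, "metadata.tsv"),
                  landuse = file.path(in_dir, "landuse.tsv"))
  } else {
    paths <- config$inputs
    if (is.null(paths$abundance) || is.null(paths$metadata))
      stop("config$inputs must provide 'abundance' and 'metadata' paths")
  }

  mat <- stage("load", read_abundance(paths$abundance))
  meta <- stage("load", read_metadata(paths$metadata, rownames(mat$counts)))
  missing_cols <- setdiff(grouping, names(meta))
  if (length(missing_cols) > 0)
    stop("grouping column(s) missing from metadata: ",
         paste(missing_cols, collapse = ", "))
  landuse <- if (!is.null(paths$landuse)) stage("load", read_landuse(paths$landuse))

  if (!is.null(config$rarefy_depth))
    mat <- stage("rarefy", rarefy(mat, config$rarefy_depth, seed = seed + 1L))

  env_cols <- setdiff(names(meta)[vapply(meta, is.numeric, logical(1))], grouping)
  group_key <- interaction(meta[rownames(mat$counts), grouping, drop = FALSE],
                           sep = "_", drop = TRUE)

  inf_args <- if (is.null(config$inference)) list() else config$inference
  inf_args$seed <- seed + 2L
  cfg <- do.call(inference_config, inf_args)

  # ---- per-group analysis -------------------------------------------------
  groups <- list()
  for (g in levels(group_key)) {
    samples <- rownames(mat$counts)[group_key == g]
    if (length(samples) < 4) {
      note("warn", "group %s has %d samples (< 4); network inference skipped",
           g, length(samples))
      next
    }
    gmat <- abundance_matrix(mat$counts[samples, , drop = FALSE],
                             taxonomy = mat$taxonomy)
    res <- stage(paste0("network:", g), {
      net <- infer_network(gmat, cfg)
      if (nrow(net$nodes) == 0) {
        note("warn", "group %s: empty network", g)
        list(network = net)
      } else {
        part <- detect_modules(net, seed = seed + 3L)
        roles <- classify_roles(net, part)
        list(network = net, partition = part,
             topology = network_topology(net, part$membership),
             roles = roles, census = role_census(roles),
             profiles = module_profiles(net, part, gmat$taxonomy))
      }
    })
    res$ncm <- stage(paste0("ncm:", g), fit_ncm(gmat))
    res$diversity <- stage(paste0("diversity:", g), alpha_diversity(gmat))
    res$samples <- samples
    groups[[g]] <- res

    write_network(res$network, file.path(net_dir, paste0(g, "_edges.tsv")), "tsv")
    write_network(res$network, file.path(net_dir, paste0(g, ".graphml")), "graphml")
    if (!is.null(res$roles))
      utils::write.table(res$roles, file.path(tab_dir, paste0(g, "_roles.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (length(groups) == 0) stop("no group had enough samples for analysis")

  topo <- do.call(rbind, lapply(names(groups), function(g) {
    t <- groups[[g]]$topology
    if (is.null(t)) return(NULL)
    cbind(data.frame(group = g), as.data.frame(t))
  }))
  utils::write.table(topo, file.path(tab_dir, "topology.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ncm_tab <- compare_ncm_fits(lapply(groups, `[[`, "ncm"))
  utils::write.table(ncm_tab, file.path(tab_dir, "ncm.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  div_tab <- do.call(rbind, lapply(names(groups), function(g)
    cbind(data.frame(group = g), groups[[g]]$diversity)))
  utils::write.table(div_tab, file.path(tab_dir, "diversity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # ---- HAILS --------------------------------------------------------------
  hails <- NULL
  if (!is.null(landuse)) {
    hails <- stage("hails", classify_reaches(compute_hails(landuse)))
    utils::write.table(as.data.frame(hails), file.path(tab_dir, "hails.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # ---- environment correlations ------------------------------------------
  corr <- keystone <- NULL
  if (length(env_cols) > 0) {
    env_num <- meta[, env_cols, drop = FALSE]
    if (!is.null(topo) && nrow(topo) >= 3) {
      env_by_group <- stats::aggregate(env_num, by = list(group = group_key[
        match(rownames(meta), rownames(mat$counts))]), FUN = mean, na.rm = TRUE)
      rownames(env_by_group) <- env_by_group$group
      ti <- topo; rownames(ti) <- ti$group
      corr <- stage("correlate",
                    correlate_tables(ti[, setdiff(names(ti), "group")],
                                     env_by_group[, env_cols, drop = FALSE]))
      utils::write.table(data.frame(index = rownames(corr$r), corr$r,
                                    check.names = FALSE),
                         file.path(tab_dir, "index_env_r.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(data.frame(index = rownames(corr$p), corr$p,
                                    check.names = FALSE),
                         file.path(tab_dir, "index_env_p.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      note("info", "index-environment correlations use %d groups as observations (low power)",
           nrow(topo))
    } else {
      note("warn", "fewer than 3 networks; index-environment correlations skipped")
    }
    ks_args <- if (is.null(config$keystone)) list() else config$keystone
    keystone <- list()
    for (g in names(groups)) {
      if (is.null(groups[[g]]$roles)) next
      gmat <- abundance_matrix(mat$counts[groups[[g]]$samples, , drop = FALSE])
      ke <- stage(paste0("keystone:", g), do.call(keystone_env_network, c(
        list(roles = groups[[g]]$roles, mat = gmat,
             env = meta[groups[[g]]$samples, env_cols, drop = FALSE]), ks_args)))
      keystone[[g]] <- ke
      write_network(ke$network,
                    file.path(net_dir, paste0(g, "_keystone_env.tsv")), "tsv")
    }
  }

  # ---- manifest -----------------------------------------------------------
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        c("manifest.json", "log.txt")))
  hashes <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(hashes) <- files
  manifest <- list(
    package = "rivnet",
    version = as.character(utils::packageVersion("rivnet")),
    master_seed = seed,
    stage_seeds = list(rarefy = seed + 1L, permutations = seed + 2L,
                       modules = seed + 3L),
    grouping = grouping,
    inference = unclass(cfg),
    rarefy_depth = config$rarefy_depth,
    groups = names(groups),
    apd_rule = "connected pairs only",
    files = hashes)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(list(groups = groups, topology = topo, ncm = ncm_tab,
                 hails = hails, correlations = corr, keystone = keystone,
                 manifest = manifest))
}

#' Simulate a complete multi-group study
#'
#' Generates one planted-block count table per reach-by-season group (shared
#' taxon ids, group-specific realizations), environmental variables tied to
#' the first planted block, and a land-use table spanning the requested
#' human-activity gradient.
#'
#' @param sim List with `groups` (each a list of `reach`, `season` and
#'   [planted_design()] arguments), optional `env_strength` (default 0.9)
#'   and `landuse_gradient`.
#' @param seed Master seed.
#' @return List: `matrix` (combined `abundance_matrix` with `sample_groups`),
#'   `env` (data.frame), `landuse` (a `landuse_table`), `group_matrices`.
#' @export
simulate_study <- function(sim, seed = 1) {
  if (is.null(sim$groups) || length(sim$groups) == 0)
    stop("simulate block needs at least one group")
  strength <- if (is.null(sim$env_strength)) 0.9 else sim$env_strength
  counts_list <- env_list <- list()
  sg <- list()
  gmats <- list()
  taxonomy <- NULL
  for (i in seq_along(sim$groups)) {
    grp <- sim$groups[[i]]
    dargs <- grp[setdiff(names(grp), c("reach", "season"))]
    dargs$seed <- seed + 10L * i
    des <- do.call(planted_design, dargs)
    gm <- generate_planted_counts(des)
    gname <- paste(grp$reach, grp$season, sep = "_")
    rownames(gm$counts) <- paste0(gname, "_", rownames(gm$counts))
    env <- generate_env_table(gm, linked_block = 1, strength = strength,
                              seed = seed + 10L * i + 1L)
    rownames(env) <- rownames(gm$counts)
    counts_list[[gname]] <- gm$counts
    env_list[[gname]] <- env
    n_g <- nrow(gm$counts)
    sg[[gname]] <- data.frame(reach = rep(grp$reach, n_g),
                              season = rep(grp$season, n_g),
                              row.names = rownames(gm$counts))
    gmats[[gname]] <- gm
    if (is.null(taxonomy)) taxonomy <- gm$taxonomy
  }
  if (length(unique(vapply(counts_list, ncol, integer(1)))) != 1)
    stop("all simulated groups must share n_taxa")
  counts <- do.call(rbind, counts_list)
  mat <- abundance_matrix(counts, taxonomy = taxonomy,
                          sample_groups = do.call(rbind, unname(sg)))
  n_basins <- if (is.null(sim$landuse_gradient)) 9 else length(sim$landuse_gradient)
  gradient <- if (is.null(sim$landuse_gradient))
    seq(0.05, 0.85, length.out = n_basins) else unlist(sim$landuse_gradient)
  landuse <- generate_landuse_table(n_basins, gradient)
  list(matrix = mat, env = do.call(rbind, unname(env_list)), landuse = landuse,
       group_matrices = gmats)
}

#' Bundled demonstration configuration
#'
#' A small synthetic two-group study (upper vs lower reach, one season each)
#' sized to run end to end in well under five minutes, used by the examples
#' and the end-to-end determinism tests.
#'
#' @param output_dir Where the report bundle should be written.
#' @param seed Master seed.
#' @return A configuration list accepted by [run_pipeline()].
#' @export
demo_config <- function(output_dir = tempfile("rivnet_run_"), seed = 1) {
  list(
    output_dir = output_dir,
    seed = seed,
    grouping = c("reach", "season"),
    simulate = list(
      groups = list(
        list(reach = "upper", season = "wet", n_samples = 24, n_taxa = 40,
             block_sizes = c(8, 8), within_block_corr = 0.9,
             frac_negative = 0.25, depth = 5000),
        list(reach = "lower", season = "wet", n_samples = 24, n_taxa = 40,
             block_sizes = c(8, 8), within_block_corr = 0.9,
             frac_negative = 0.25, depth = 5000)),
      env_strength = 0.9,
      landuse_gradient = c(0.05, 0.1, 0.2, 0.35, 0.5, 0.65, 0.8, 0.9, 0.95)),
    inference = list(n_permutations = 500, min_taxon_total = 30),
    keystone = list(r_min = 0.8, alpha = 0.05))
}
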