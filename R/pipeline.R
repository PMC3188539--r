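# End-to-end orchestration: counts -> divergence -> contact graph ->
# quartet test -> LSC -> parsimony, plus the region-rate analysis. Pure
# orchestration -- every number in the report is the output of one module
# operation on the same inputs.

#' Configure a full scan
#'
#' Inputs may be given as in-memory objects (`aln`, `trees`, `partition`,
#' `coords` or an `lsc_sim` via `sim`) or as file paths (`alignment_path` +
#' `format`, `tree_paths` named by clade, `clade_map_path`,
#' `structure_path` + `chain`).
#'
#' @param ... Configuration fields. Recognised: input objects/paths as above;
#'   `ref_id` (reference row for structure mapping); `atom_mode`;
#'   `threshold` (contact distance, default 4); `cutoff` (type I posterior
#'   cutoff, default 0.9); `model` (`"marginal-ml"`/`"fitch"`); `correction`
#'   (`"poisson-ml"`/`"identity"`); `counts_tsv` (optional precomputed counts
#'   path); `quartet` (list: `clades` = 4 labels, `n` sites/edge, `n_perm`);
#'   `regions` (named list of integer column vectors); `n_perm`; `seed`
#'   (mandatory); `out_dir` (optional).
#' @return A `scan_config` list.
#' @export
scan_config <- function(...) {
  cfg <- list(...)
  defaults <- list(threshold = 4.0, cutoff = 0.90, model = "marginal-ml",
                   correction = "poisson-ml", atom_mode = "CA",
                   n_perm = 1e5, quartet = NULL, regions = NULL,
                   out_dir = NULL)
  cfg <- utils::modifyList(defaults, cfg)
  if (is.null(cfg$seed)) stop("config needs a seed", call. = FALSE)
  if (cfg$cutoff <= 0.5 || cfg$cutoff >= 1) {
    stop("posterior cutoff must be in (0.5, 1)", call. = FALSE)
  }
  structure(cfg, class = "scan_config")
}

load_scan_inputs <- function(cfg) {
  if (!is.null(cfg$sim)) {
    s <- cfg$sim
    return(list(aln = s$aln, trees = s$trees, partition = s$partition,
                structmap = s$structmap))
  }
  if (!is.null(cfg$aln)) {
    structmap <- cfg$structmap
    if (is.null(structmap) && !is.null(cfg$coords)) {
      structmap <- map_alignment_to_structure(cfg$aln, cfg$ref_id,
                                              cfg$coords)
    }
    return(list(aln = cfg$aln, trees = cfg$trees,
                partition = cfg$partition, structmap = structmap))
  }
  aln <- read_alignment(cfg$alignment_path, format = cfg$format %||% "fasta")
  trees <- lapply(cfg$tree_paths, read_tree)
  partition <- read_clade_map(cfg$clade_map_path)
  structmap <- NULL
  if (!is.null(cfg$structure_path)) {
    coords <- read_structure(cfg$structure_path, cfg$chain,
                             atom_mode = cfg$atom_mode)
    ref_id <- cfg$ref_id %||% msa_ids(aln)[1]
    structmap <- map_alignment_to_structure(aln, ref_id, coords)
  }
  list(aln = aln, trees = trees, partition = partition,
       structmap = structmap)
}

#' Run the full divergence / LSC scan
#'
#' Stages: per-site substitution counts for every clade; type I mixture fit,
#' type II classification and site typing for every clade pair; contact
#' graph over typed columns; optional quartet clustering test; LSC
#' extraction, per-clade profiles, character matrix and exhaustive parsimony
#' (3-9 clades); optional region-rate analysis. Deterministic given the
#' config seed. If `out_dir` is set, all result files are written there.
#'
#' @param config A [scan_config()].
#' @return Object of class `scan_report`.
#' @export
run_full_scan <- function(config) {
  stopifnot(inherits(config, "scan_config"))
  set.seed(config$seed)
  inp <- load_scan_inputs(config)
  aln <- inp$aln; trees <- inp$trees; partition <- inp$partition
  clades <- sort(unique(partition$clade))

  stage <- "counts"
  report <- tryCatch({
    counts <- if (!is.null(config$counts_tsv)) {
      read_counts_tsv(config$counts_tsv)
    } else {
      clade_site_counts(aln, trees, partition, model = config$model,
                        correction = config$correction)
    }
    rates <- relative_rates(counts)

    stage <- "divergence"
    anc <- lapply(stats::setNames(clades, clades), function(cl) {
      reconstruct_ancestral_states(aln, trees[[cl]], model = config$model)
    })
    pairs <- utils::combn(clades, 2, simplify = FALSE)
    fits <- list(); posts <- list(); calls_list <- list()
    theta_rows <- list()
    for (pr in pairs) {
      a <- pr[1]; b <- pr[2]
      key <- paste(a, b, sep = "|")
      f1 <- fit_type_I(counts, a, b)
      po <- type_I_posteriors(f1)
      t2 <- classify_type_II(anc[[a]], anc[[b]], counts, a, b)
      calls_list[[key]] <- classify_sites(aln, partition, po, t2, counts,
                                          a, b, cutoff = config$cutoff)
      fits[[key]] <- f1
      posts[[key]] <- po
      theta_rows[[key]] <- tibble::tibble(
        clade_a = a, clade_b = b,
        theta_type1 = f1$theta, se_type1 = f1$standard_error,
        theta_type2 = t2$theta$theta, se_type2 = t2$theta$standard_error)
    }
    site_calls <- dplyr::bind_rows(calls_list)
    theta_table <- dplyr::bind_rows(theta_rows)

    stage <- "contacts"
    graph <- NULL; lscs <- NULL; profiles <- NULL; cm <- NULL; mp <- NULL
    if (!is.null(inp$structmap)) {
      typed <- unique(site_calls$column[site_calls$class != "none"])
      graph <- suppressWarnings(
        build_contact_graph(inp$structmap, typed,
                            threshold = config$threshold))
      stage <- "lsc"
      lscs <- find_lscs(site_calls, graph)
      if (nrow(lscs) > 0L) {
        profiles <- lsc_state_profiles(lscs, aln, partition)
        cm <- character_matrix(profiles)
        if (length(clades) >= 3L && length(clades) <= 9L) {
          stage <- "parsimony"
          mp <- mp_search(cm)
        }
      }
    }

    stage <- "quartet"
    quartet <- NULL
    if (!is.null(config$quartet) && !is.null(graph)) {
      q <- config$quartet
      key1 <- paste(sort(q$clades[1:2]), collapse = "|")
      key2 <- paste(sort(q$clades[3:4]), collapse = "|")
      sel <- select_quartet_sites(posts[[key1]], posts[[key2]],
                                  n = q$n %||% 25L)
      quartet <- list(
        selection = sel,
        test = clustering_permutation_test(
          sel$sites_e1, sel$sites_e2, graph,
          n_perm = q$n_perm %||% config$n_perm, seed = config$seed),
        consecutive = consecutive_statistic(sel$sites_e1, sel$sites_e2,
                                            inp$structmap)
      )
    }

    stage <- "regions"
    regions <- NULL
    if (!is.null(config$regions)) {
      regions <- run_table1_analysis(counts, config$regions,
                                     n_resample = config$n_perm,
                                     seed = config$seed)
    }

    list(counts = counts, rates = rates, theta_table = theta_table,
         site_calls = site_calls, fits = fits, graph = graph,
         quartet = quartet, lscs = lscs, profiles = profiles,
         character_matrix = cm, parsimony = mp, regions = regions)
  }, error = function(e) {
    stop("scan failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  report$provenance <- list(
    package = "lscscan",
    version = as.character(utils::packageVersion("lscscan")),
    seed = config$seed,
    config = config[setdiff(names(config),
                            c("sim", "aln", "trees", "partition", "coords",
                              "structmap", "out_dir"))]
  )
  class(report) <- "scan_report"
  if (!is.null(config$out_dir)) write_scan_report(report, config$out_dir)
  report
}

#' @export
print.scan_report <- function(x, ...) {
  cat("<scan_report>\n")
  cat("  clades:", paste(unique(x$counts$clade), collapse = ", "), "\n")
  cat("  site calls:", sum(x$site_calls$class != "none"), "typed columns\n")
  if (!is.null(x$lscs)) {
    cat("  LSCs:", length(unique(x$lscs$lsc)), "\n")
  }
  if (!is.null(x$quartet)) {
    cat(sprintf("  quartet test: S = %d, p = %.4g\n",
                x$quartet$test$statistic, x$quartet$test$p_value))
  }
  if (!is.null(x$parsimony)) {
    cat("  parsimony best score:", x$parsimony$best_score, "\n")
  }
  invisible(x)
}

#' Region-rate analysis across clades
#'
#' For each clade and each named region: the clade tree length, the mean
#' normalised rate inside and outside the region, and the one-sided
#' location and rank-sum resampling p-values (lower tail: does the region
#' evolve more slowly?). Also runs, per region, the Poisson likelihood-ratio
#' test of rate uniformity across clades on the region's raw substitution
#' totals with clade tree lengths as exposures.
#'
#' @param counts A [clade_site_counts()] table.
#' @param regions Named list of integer column vectors.
#' @param n_resample Resampling draws (default 100000).
#' @param seed Integer seed.
#' @return List with `region_table` (tibble) and `lrt` (tibble, one row per
#'   region).
#' @export
run_table1_analysis <- function(counts, regions, n_resample = 1e5,
                                seed = NULL) {
  if (is.null(names(regions)) || any(names(regions) == "")) {
    stop("regions must be a named list", call. = FALSE)
  }
  all_cols <- sort(unique(counts$column))
  rates <- relative_rates(counts)
  clades <- sort(unique(counts$clade))
  rows <- list(); lrts <- list()
  for (rg in names(regions)) {
    cols <- regions[[rg]]
    if (!all(cols %in% all_cols)) {
      stop("region '", rg, "' is outside the alignment", call. = FALSE)
    }
    if (length(cols) >= length(all_cols)) {
      stop("region '", rg, "' covers every column", call. = FALSE)
    }
    for (cl in clades) {
      dc <- counts[counts$clade == cl, ]
      dc <- dc[order(dc$column), ]
      rc <- rates[rates$clade == cl, ]
      rc <- rc[order(rc$column), ]
      idx <- match(cols, dc$column)
      ploc <- region_location_test(dc$corrected_count, idx,
                                   n_resample = n_resample, seed = seed)
      pdis <- region_distribution_test(dc$corrected_count, idx,
                                       n_resample = n_resample, seed = seed)
      rows[[paste(rg, cl)]] <- tibble::tibble(
        region = rg, clade = cl,
        tree_length = dc$tree_length[1],
        rate_region = mean(rc$rate[idx]),
        rate_remainder = mean(rc$rate[-idx]),
        p_location = ploc$p_value,
        p_distribution = pdis$p_value
      )
    }
    x <- vapply(clades, function(cl) {
      dc <- counts[counts$clade == cl & counts$column %in% cols, ]
      sum(dc$raw_count)
    }, numeric(1))
    t <- vapply(clades, function(cl) {
      counts$tree_length[counts$clade == cl][1]
    }, numeric(1))
    lr <- poisson_lrt(x, t)
    lrts[[rg]] <- tibble::tibble(region = rg, statistic = lr$statistic,
                                 df = lr$df, p_value = lr$p_value)
  }
  list(region_table = dplyr::bind_rows(rows), lrt = dplyr::bind_rows(lrts))
}

#' Write a scan report to files
#'
#' Emits TSVs (counts, theta table, site calls, contact edges, LSC report,
#' character matrix, region tests), Newick (optimal parsimony trees), and
#' JSON (quartet test, LSC summary, provenance). Content is deterministic
#' given the scan seed, so reruns are byte-identical.
#'
#' @param report A `scan_report`.
#' @param dir Output directory.
#' @return Named list of written paths, invisibly.
#' @export
write_scan_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  wtsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(as.data.frame(df), p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths[[name]] <<- p
  }
  write_counts_tsv(report$counts, file.path(dir, "counts.tsv"))
  paths[["counts.tsv"]] <- file.path(dir, "counts.tsv")
  wtsv(report$theta_table, "theta_table.tsv")
  wtsv(report$site_calls, "site_calls.tsv")
  if (!is.null(report$graph)) {
    wtsv(contact_edges(report$graph), "contact_edges.tsv")
  }
  if (!is.null(report$lscs)) {
    wtsv(report$lscs, "lsc_members.tsv")
    if (!is.null(report$profiles)) wtsv(report$profiles, "lsc_profiles.tsv")
    if (!is.null(report$character_matrix)) {
      write_character_matrix(report$character_matrix,
                             file.path(dir, "character_matrix.tsv"))
      paths[["character_matrix.tsv"]] <- file.path(dir,
                                                   "character_matrix.tsv")
    }
    lsc_json <- split(report$lscs[, c("column", "class", "resno")],
                      report$lscs$lsc)
    jsonlite::write_json(lsc_json, file.path(dir, "lsc_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths[["lsc_report.json"]] <- file.path(dir, "lsc_report.json")
  }
  if (!is.null(report$parsimony)) {
    p <- file.path(dir, "mp_trees.nwk")
    ape::write.tree(report$parsimony$trees, file = p)
    paths[["mp_trees.nwk"]] <- p
  }
  if (!is.null(report$quartet)) {
    q <- report$quartet
    jsonlite::write_json(
      list(statistic = q$test$statistic, p_value = q$test$p_value,
           mode = q$test$mode, pool_size = q$test$pool_size,
           per_edge = as.list(q$test$per_edge),
           consecutive_statistic = as.integer(q$consecutive),
           sites_e1 = q$selection$sites_e1,
           sites_e2 = q$selection$sites_e2),
      file.path(dir, "quartet_test.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths[["quartet_test.json"]] <- file.path(dir, "quartet_test.json")
  }
  if (!is.null(report$regions)) {
    wtsv(report$regions$region_table, "region_tests.tsv")
    wtsv(report$regions$lrt, "region_lrt.tsv")
  }
  jsonlite::write_json(report$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  paths[["provenance.json"]] <- file.path(dir, "provenance.json")
  invisible(paths)
}
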