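#' Fit the community assembly process model to a dataset
#'
#' End-to-end null-model analysis of an OTU table, phylogeny and sample
#' metadata: singleton removal, rarefaction to equal depth, table-tree
#' reconciliation, SES.MNTD, betaNTI, RC-bray, five-way process
#' classification (overall and within successional-age and pH categories),
#' abundance-weighted niche optima with a phylogenetic-signal Mantel
#' correlogram, and Mantel / partial Mantel tests of betaNTI against pH and
#' spatial distance.
#'
#' @param table community table (taxa x samples, integer reads).
#' @param tree `ape::phylo` tree whose tips cover the table's taxa.
#' @param meta metadata data frame with `sample_id` and optionally `pH`,
#'   `age`, `lat`, `lon`.
#' @param depth rarefaction depth; default the minimum sample sum after
#'   singleton removal.
#' @param n_iter null-model iterations for every engine (default 999).
#' @param seed master RNG seed; each engine gets a derived stream.
#' @param weighted_bmntd abundance-weight betaMNTD (default `TRUE`).
#' @param weighted_mntd abundance-weight MNTD in SES.MNTD (default `FALSE`).
#' @param remove_singleton drop dataset-wide singleton OTUs first
#'   (default `TRUE`).
#' @param ph_bins,age_bins bin edges for the within-category process
#'   partitions (`NULL` = defaults of [bin_pairs()]).
#' @param hof also fit HOF niche models (default `FALSE`; slower).
#' @param hof_boot bootstrap resamples for HOF model choice.
#' @return object of class `"assembly_process"`; see Details.
#' @details The returned object carries: `table` (analyzed, rarefied),
#'   `tree`, `meta`, `depth`, `ses_mntd` (per-sample data frame), `bnti`
#'   (a [beta_nti()] result), `rc` (RC-bray matrix), `pairs` (long per-pair
#'   data frame with `bmntd`, `bnti`, `rc_bray`, `process`, and group keys),
#'   `fractions` (process partitions: `all`, `by_age`, `by_ph`), `optima`,
#'   `correlogram`, `mantel` (data frame of Mantel/partial-Mantel tests),
#'   and `hof` when requested.
#' @export
assembly_process <- function(table, tree, meta, depth = NULL, n_iter = 999,
                             seed = 1, weighted_bmntd = TRUE,
                             weighted_mntd = FALSE, remove_singleton = TRUE,
                             ph_bins = NULL, age_bins = NULL, hof = FALSE,
                             hof_boot = 0) {
  cl <- match.call()
  table <- as_community_table(table)
  meta <- validate_metadata(meta)
  if (remove_singleton) table <- remove_singletons(table)
  if (is.null(depth)) depth <- min(colSums(table))
  table <- rarefy(table, depth, seed = child_seed(seed, 10L))
  miss_meta <- setdiff(colnames(table), meta$sample_id)
  if (length(miss_meta)) {
    stop("samples missing from metadata: ",
         paste(head(miss_meta, 5), collapse = ", "), call. = FALSE)
  }
  rec <- reconcile(table, tree)
  table <- rec$table
  tree <- rec$tree
  meta <- meta[match(colnames(table), meta$sample_id), , drop = FALSE]
  d <- cophenetic_dist(tree)

  ses <- ses_mntd(table, d, n_iter = n_iter, seed = child_seed(seed, 11L),
                  abundance_weighted = weighted_mntd)
  bnti <- beta_nti(table, d, n_iter = n_iter, seed = child_seed(seed, 12L),
                   abundance_weighted = weighted_bmntd)
  rc <- rc_bray(table, n_iter = n_iter, seed = child_seed(seed, 13L))

  pairs <- pairs_long(bnti$bmntd, "bmntd")
  pairs$bnti <- lower_tri(bnti$bnti)
  pairs$rc_bray <- lower_tri(rc[rownames(bnti$bnti), rownames(bnti$bnti)])
  pairs$process <- classify_pair(pairs$bnti, pairs$rc_bray)
  fractions <- list(all = partition_fractions(pairs$process))
  if ("age" %in% names(meta) && !anyNA(meta$age)) {
    ag <- bin_pairs(meta, "age", edges = age_bins)
    pairs$age_group <- ag$group[match(paste(pairs$sample_i, pairs$sample_j),
                                      paste(ag$sample_i, ag$sample_j))]
    within <- !startsWith(pairs$age_group, "between:")
    if (any(within)) {
      fractions$by_age <- partition_fractions(pairs$process[within],
                                              pairs$age_group[within])
    }
  }
  has_ph <- "pH" %in% names(meta) && !anyNA(meta$pH)
  if (has_ph) {
    pg <- bin_pairs(meta, "pH", edges = ph_bins)
    pairs$ph_group <- pg$group[match(paste(pairs$sample_i, pairs$sample_j),
                                     paste(pg$sample_i, pg$sample_j))]
    within <- !startsWith(pairs$ph_group, "between:")
    if (any(within)) {
      fractions$by_ph <- suppressWarnings(
        partition_fractions(pairs$process[within], pairs$ph_group[within]))
    }
  }

  optima <- NULL
  correlogram <- NULL
  if (has_ph && length(unique(meta$pH)) > 1L) {
    optima <- weighted_mean_optima(table, setNames(meta$pH, meta$sample_id))
    correlogram <- tryCatch(
      mantel_correlogram(optima_distance(optima),
                         d[optima$otu, optima$otu],
                         n_perm = n_iter, seed = child_seed(seed, 14L)),
      error = function(e) {
        warning("correlogram skipped: ", conditionMessage(e), call. = FALSE)
        NULL
      })
  }

  mantel <- run_mantel_suite(bnti$bnti, meta, n_iter, child_seed(seed, 15L))

  hof_res <- NULL
  if (hof && has_ph) {
    hof_res <- hof_optima(table, setNames(meta$pH, meta$sample_id),
                          n_boot = hof_boot, seed = child_seed(seed, 16L))
  }

  structure(list(call = cl, table = table, tree = tree, meta = meta,
                 depth = depth, n_iter = n_iter, seed = seed,
                 ses_mntd = ses, bnti = bnti, rc = rc, pairs = pairs,
                 fractions = fractions, optima = optima,
                 correlogram = correlogram, mantel = mantel, hof = hof_res),
            class = "assembly_process")
}

# Mantel and partial Mantel tests of betaNTI against pH and spatial
# distance; skipped (with an NA row) where a matrix is degenerate.
run_mantel_suite <- function(bnti_mat, meta, n_perm, seed) {
  tests <- list()
  safe <- function(name, expr) {
    r <- tryCatch(expr, error = function(e) NULL)
    if (is.null(r)) {
      data.frame(test = name, r = NA_real_, p = NA_real_, n_perm = n_perm,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(test = name, r = r$r, p = r$p, n_perm = r$n_perm,
                 stringsAsFactors = FALSE)
    }
  }
  has_ph <- "pH" %in% names(meta) && !anyNA(meta$pH)
  has_xy <- all(c("lat", "lon") %in% names(meta)) &&
    !anyNA(meta$lat) && !anyNA(meta$lon)
  dph <- if (has_ph) env_distance(meta, "pH") else NULL
  dxy <- if (has_xy) spatial_distance(meta) else NULL
  k <- 0L
  if (!is.null(dph)) {
    k <- k + 1L
    tests$ph <- safe("bnti_vs_pH",
                     mantel_test(bnti_mat, dph, n_perm, child_seed(seed, k)))
  }
  if (!is.null(dxy)) {
    k <- k + 1L
    tests$xy <- safe("bnti_vs_space",
                     mantel_test(bnti_mat, dxy, n_perm, child_seed(seed, k)))
  }
  if (!is.null(dph) && !is.null(dxy)) {
    k <- k + 1L
    tests$ph_c <- safe("bnti_vs_pH_control_space",
                       partial_mantel(bnti_mat, dph, dxy, n_perm,
                                      child_seed(seed, k)))
    k <- k + 1L
    tests$xy_c <- safe("bnti_vs_space_control_pH",
                       partial_mantel(bnti_mat, dxy, dph, n_perm,
                                      child_seed(seed, k)))
  }
  if (!length(tests)) return(NULL)
  out <- do.call(rbind, tests)
  rownames(out) <- NULL
  out
}

#' @export
print.assembly_process <- function(x, ...) {
  cat("Community assembly process inference\n")
  cat(sprintf("  %d taxa x %d samples, rarefied to %d reads, %d null iterations\n",
              nrow(x$table), ncol(x$table), x$depth, x$n_iter))
  cat(sprintf("  mean SES.MNTD: %.3f\n", mean(x$ses_mntd$ses_mntd, na.rm = TRUE)))
  fr <- x$fractions$all
  pct <- as.numeric(fr[1L, grep("^pct_", names(fr))])
  names(pct) <- sub("^pct_", "", grep("^pct_", names(fr), value = TRUE))
  cat("  process fractions (%):\n")
  for (nm in names(pct)) cat(sprintf("    %-24s %6.1f\n", nm, pct[nm]))
  invisible(x)
}

#' @export
summary.assembly_process <- function(object, ...) {
  structure(list(
    dims = dim(object$table), depth = object$depth, n_iter = object$n_iter,
    ses = summary(object$ses_mntd$ses_mntd),
    mean_ses = mean(object$ses_mntd$ses_mntd, na.rm = TRUE),
    fractions = object$fractions, mantel = object$mantel,
    correlogram = object$correlogram), class = "summary.assembly_process")
}

#' @export
print.summary.assembly_process <- function(x, ...) {
  cat(sprintf("Assembly inference: %d taxa x %d samples (depth %d, %d nulls)\n",
              x$dims[1L], x$dims[2L], x$depth, x$n_iter))
  cat("\nSES.MNTD:\n"); print(x$ses)
  cat("\nProcess fractions (all pairs):\n"); print(x$fractions$all)
  if (!is.null(x$fractions$by_ph)) {
    cat("\nProcess fractions within pH categories:\n")
    print(x$fractions$by_ph)
  }
  if (!is.null(x$mantel)) { cat("\nMantel tests:\n"); print(x$mantel) }
  if (!is.null(x$correlogram)) {
    cat("\nPhylogenetic-signal correlogram (first classes):\n")
    print(head(as.data.frame(x$correlogram), 4))
  }
  invisible(x)
}

#' @export
plot.assembly_process <- function(x, which = c("bnti", "fractions"), ...) {
  which <- match.arg(which)
  if (which == "bnti") {
    if (!"pH" %in% names(x$meta)) stop("no pH in metadata", call. = FALSE)
    dph <- env_distance(x$meta, "pH")
    graphics::plot(lower_tri(dph), lower_tri(x$bnti$bnti),
                   xlab = expression(Delta ~ "pH"), ylab = expression(beta * "NTI"),
                   pch = 19, col = grDevices::adjustcolor("steelblue", 0.6), ...)
    graphics::abline(h = c(-2, 2), lty = 2, col = "grey40")
  } else {
    fr <- x$fractions$all
    pct <- as.numeric(fr[1L, grep("^pct_", names(fr))])
    names(pct) <- sub("^pct_", "", grep("^pct_", names(fr), value = TRUE))
    graphics::barplot(pct, las = 2, ylab = "% of pairwise comparisons",
                      cex.names = 0.7, ...)
  }
  invisible(x)
}

#' Run the full assembly analysis and write tabular outputs
#'
#' Thin orchestration over [assembly_process()]: loads the inputs (or
#' simulates a [scenario()]), fits, and writes stable TSV outputs plus a
#' run log to `out_dir`.
#'
#' @param out_dir output directory (created if absent).
#' @param table_path,tree_path,meta_path input file paths (TSV table,
#'   newick tree, TSV metadata); mutually exclusive with `scenario`.
#' @param scenario a [scenario()] preset name, simulated in place of file
#'   inputs.
#' @param scenario_args list of extra arguments for [scenario()]
#'   (`n_taxa`, `n_samples`, `depth`).
#' @param ... passed to [assembly_process()].
#' @param seed master seed (also used for the scenario simulation).
#' @return (invisibly) the fitted `"assembly_process"` object. Files
#'   written: `ses_mntd.tsv`, `bnti_pairs.tsv`, `process_fractions.tsv`,
#'   `correlogram.tsv`, `mantel_tests.tsv`, `run_log.txt`.
#' @export
run_assembly <- function(out_dir, table_path = NULL, tree_path = NULL,
                         meta_path = NULL, scenario = NULL,
                         scenario_args = list(), seed = 1, ...) {
  from_files <- !is.null(table_path)
  if (from_files == !is.null(scenario)) {
    stop("supply either input file paths or a scenario name", call. = FALSE)
  }
  if (from_files) {
    if (!file.exists(tree_path)) stop("tree not found: ", tree_path, call. = FALSE)
    table <- read_community_table(table_path)
    tree <- ape::read.tree(tree_path)
    meta <- read_sample_metadata(meta_path)
  } else {
    bundle <- do.call(assemblyproc::scenario,
                      c(list(name = scenario, seed = seed), scenario_args))
    table <- bundle$table
    tree <- bundle$tree
    meta <- bundle$meta
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  log_line <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ..., "\n",
        sep = "", file = log_path, append = TRUE)
  }
  cat("", file = log_path)
  log_line("run_assembly start; seed=", seed,
           if (from_files) paste0("; table=", table_path) else
             paste0("; scenario=", scenario))
  fit <- tryCatch(
    assembly_process(table, tree, meta, seed = seed, ...),
    error = function(e) {
      log_line("FAILED: ", conditionMessage(e))
      stop(e)
    })
  tsv <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  tsv(fit$ses_mntd, "ses_mntd.tsv")
  tsv(fit$pairs, "bnti_pairs.tsv")
  frac <- do.call(rbind, lapply(names(fit$fractions), function(n) {
    f <- fit$fractions[[n]]
    cbind(partition = n, f)
  }))
  tsv(frac, "process_fractions.tsv")
  if (!is.null(fit$correlogram)) {
    tsv(as.data.frame(fit$correlogram), "correlogram.tsv")
  }
  if (!is.null(fit$mantel)) tsv(fit$mantel, "mantel_tests.tsv")
  log_line("done; depth=", fit$depth, "; samples=", ncol(fit$table),
           "; taxa=", nrow(fit$table))
  invisible(fit)
}

#' Library-size sensitivity analysis with cross-depth concordance
#'
#' Runs [depth_sensitivity()] and adds a cross-depth concordance summary:
#' Spearman correlation of SES.MNTD over shared samples and the agreement
#' rate of process labels over shared pairs, for every depth pair. Writes
#' per-depth TSVs when `out_dir` is given.
#'
#' @param table,tree,meta inputs as in [assembly_process()].
#' @param depths integer rarefaction depths (>= 2 feasible).
#' @param out_dir optional output directory.
#' @param n_iter,seed null-model settings.
#' @return list: `sensitivity` (a [depth_sensitivity()] result) and
#'   `concordance` data frame.
#' @export
run_sensitivity <- function(table, tree, meta, depths, out_dir = NULL,
                            n_iter = 999, seed = 1) {
  sens <- depth_sensitivity(table, tree, meta, depths, n_iter = n_iter,
                            seed = seed)
  res <- sens$results
  conc <- NULL
  if (length(res) >= 2L) {
    cmb <- utils::combn(names(res), 2L)
    conc <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
      a <- res[[cmb[1L, j]]]; b <- res[[cmb[2L, j]]]
      common <- intersect(a$ses$sample_id, b$ses$sample_id)
      rho <- if (length(common) >= 3L) {
        suppressWarnings(cor(a$ses$ses_mntd[match(common, a$ses$sample_id)],
                             b$ses$ses_mntd[match(common, b$ses$sample_id)],
                             method = "spearman", use = "complete.obs"))
      } else NA_real_
      key_a <- paste(a$pairs$sample_i, a$pairs$sample_j)
      key_b <- paste(b$pairs$sample_i, b$pairs$sample_j)
      shared <- intersect(key_a, key_b)
      agree <- if (length(shared)) {
        mean(as.character(a$pairs$process[match(shared, key_a)]) ==
               as.character(b$pairs$process[match(shared, key_b)]))
      } else NA_real_
      data.frame(depth_a = a$depth, depth_b = b$depth,
                 spearman_ses = rho, process_agreement = agree)
    }))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(res)) {
      write.table(res[[nm]]$ses,
                  file.path(out_dir, paste0("ses_mntd_depth", nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(res[[nm]]$fractions,
                  file.path(out_dir, paste0("fractions_depth", nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(sens$summary)) {
      write.table(sens$summary, file.path(out_dir, "depth_summary.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(conc)) {
      write.table(conc, file.path(out_dir, "depth_concordance.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  list(sensitivity = sens, concordance = conc)
}
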