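process_levels <- c("variable_selection", "homogeneous_selection",
                    "dispersal_limitation", "homogenizing_dispersal",
                    "undominated", "unclassifiable")

#' Classify a pairwise comparison into an assembly process
#'
#' betaNTI > +2: variable selection; betaNTI < -2: homogeneous selection.
#' Otherwise RC-bray discriminates the stochastic outcomes: RC > +0.95
#' dispersal limitation, RC < -0.95 homogenizing dispersal, |RC| <= 0.95
#' undominated. Boundary values |betaNTI| = 2 fall on the stochastic branch
#' and |RC| = 0.95 on undominated, so classification is total on defined
#' inputs. Missing betaNTI, or missing RC where it is needed, yields
#' `unclassifiable` with a warning.
#'
#' @param bnti numeric vector of betaNTI values.
#' @param rc numeric vector of RC-bray values (recycled `NA` when absent).
#' @return factor over the five processes plus `unclassifiable`.
#' @export
classify_pair <- function(bnti, rc = NULL) {
  if (is.null(rc)) rc <- rep(NA_real_, length(bnti))
  if (length(rc) != length(bnti)) stop("length mismatch", call. = FALSE)
  out <- rep(NA_character_, length(bnti))
  out[!is.na(bnti) & bnti > 2] <- "variable_selection"
  out[!is.na(bnti) & bnti < -2] <- "homogeneous_selection"
  mid <- !is.na(bnti) & abs(bnti) <= 2
  out[mid & !is.na(rc) & rc > 0.95] <- "dispersal_limitation"
  out[mid & !is.na(rc) & rc < -0.95] <- "homogenizing_dispersal"
  out[mid & !is.na(rc) & abs(rc) <= 0.95] <- "undominated"
  need_rc <- mid & is.na(rc)
  if (any(need_rc)) {
    warning(sum(need_rc), " pair(s) with |betaNTI| <= 2 but missing RC-bray; ",
            "unclassifiable", call. = FALSE)
  }
  out[is.na(out)] <- "unclassifiable"
  factor(out, levels = process_levels)
}

#' Relative contributions of assembly processes per group
#'
#' Percentage of classified pairs carrying each process label, per group.
#' Unclassifiable pairs are reported in their own column and excluded from
#' the denominator.
#'
#' @param labels factor from [classify_pair()].
#' @param groups per-pair group keys (default a single `"all"` group).
#' @return data frame with one row per group: `n_pairs` (classified),
#'   `n_unclassifiable`, and `pct_*` columns summing to 100 per row.
#' @export
partition_fractions <- function(labels, groups = NULL) {
  labels <- factor(labels, levels = process_levels)
  if (is.null(groups)) groups <- rep("all", length(labels))
  if (length(groups) != length(labels)) stop("length mismatch", call. = FALSE)
  out <- lapply(split(seq_along(labels), groups), function(ix) {
    lab <- labels[ix]
    cls <- lab[lab != "unclassifiable"]
    n <- length(cls)
    if (n == 0L) return(NULL)
    tab <- table(factor(cls, levels = process_levels[1:5]))
    data.frame(group = groups[ix[1L]], n_pairs = n,
               n_unclassifiable = sum(lab == "unclassifiable"),
               as.list(setNames(100 * as.numeric(tab) / n,
                                paste0("pct_", names(tab)))),
               stringsAsFactors = FALSE)
  })
  empty <- vapply(out, is.null, logical(1))
  if (any(empty)) {
    warning("omitting ", sum(empty), " group(s) with no classified pairs",
            call. = FALSE)
  }
  res <- do.call(rbind, out[!empty])
  if (is.null(res)) stop("no classified pairs in any group", call. = FALSE)
  rownames(res) <- NULL
  res
}

#' Assign sample pairs to within- and between-category groups
#'
#' Bins a metadata variable and keys each unordered sample pair: pairs whose
#' members share a bin get that bin's label (within-category comparisons);
#' cross-bin pairs get `"between:<g1>,<g2>"`. Successional ages are naturally
#' discrete, so `edges = NULL` with `variable = "age"` uses each distinct age
#' as its own bin; for pH the default is bins of width 0.5 spanning the
#' observed range.
#'
#' @param meta metadata data frame with `sample_id`.
#' @param variable metadata column to bin (`"pH"` or `"age"` typically).
#' @param edges strictly increasing bin boundaries, or `NULL` for defaults.
#' @return data frame `sample_i`, `sample_j`, `group` over all pairs i < j.
#' @export
bin_pairs <- function(meta, variable = "pH", edges = NULL) {
  meta <- validate_metadata(meta)
  if (!variable %in% names(meta)) {
    stop("missing metadata column: ", variable, call. = FALSE)
  }
  v <- meta[[variable]]
  if (anyNA(v)) stop("missing values in ", variable, call. = FALSE)
  if (is.null(edges) && variable == "age") {
    key <- paste0("age:", v)
  } else {
    if (is.null(edges)) {
      lo <- floor(min(v) / 0.5) * 0.5
      hi <- ceiling(max(v) / 0.5) * 0.5
      if (hi <= lo) hi <- lo + 0.5
      edges <- seq(lo, hi, by = 0.5)
    }
    if (any(diff(edges) <= 0)) stop("edges not strictly increasing", call. = FALSE)
    b <- cut(v, breaks = edges, include.lowest = TRUE, right = FALSE)
    if (anyNA(b)) {
      stop("values outside bin range: ",
           paste(meta$sample_id[is.na(b)], collapse = ", "), call. = FALSE)
    }
    key <- as.character(b)
  }
  n <- nrow(meta)
  ij <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  g1 <- key[ij[, 2L]]
  g2 <- key[ij[, 1L]]
  grp <- ifelse(g1 == g2, g1,
                paste0("between:", pmin(g1, g2), ",", pmax(g1, g2)))
  data.frame(sample_i = meta$sample_id[ij[, 2L]],
             sample_j = meta$sample_id[ij[, 1L]],
             group = grp, stringsAsFactors = FALSE)
}

#' Sensitivity of assembly inference to rarefaction depth
#'
#' Re-runs rarefaction, SES.MNTD, betaNTI, RC-bray and process
#' classification at each requested depth and reports the per-depth
#' summaries side by side, to check that inferences are not artefacts of
#' library size.
#'
#' @param table community table (unrarefied, singleton-filtered or not).
#' @param tree phylogenetic tree of the taxa.
#' @param meta sample metadata (pH used for the Mantel summary if variable).
#' @param depths integer vector of rarefaction depths.
#' @param n_iter null iterations per engine.
#' @param seed RNG seed; each depth gets a derived stream.
#' @return object of class `"depth_sensitivity"`: list of per-depth results
#'   (`depth`, `ses`, `fractions`, `mantel_r_ph`, `pairs`) plus a `summary`
#'   data frame.
#' @export
depth_sensitivity <- function(table, tree, meta, depths, n_iter = 999,
                              seed = NULL) {
  table <- as_community_table(table)
  meta <- validate_metadata(meta)
  depths <- sort(unique(as.integer(depths)))
  res <- list()
  for (k in seq_along(depths)) {
    depth <- depths[k]
    if (!any(colSums(table) >= depth)) {
      warning("depth ", depth, " unreachable by every sample; skipped",
              call. = FALSE)
      next
    }
    fit <- tryCatch(
      assembly_process(table, tree, meta, depth = depth, n_iter = n_iter,
                       seed = child_seed(seed, k), remove_singleton = FALSE,
                       hof = FALSE),
      error = function(e) {
        warning("depth ", depth, " failed: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (is.null(fit)) next
    res[[as.character(depth)]] <- list(
      depth = depth,
      ses = fit$ses_mntd,
      fractions = fit$fractions$all,
      mantel_r_ph = if (!is.null(fit$mantel) &&
                        "bnti_vs_pH" %in% fit$mantel$test)
        fit$mantel$r[fit$mantel$test == "bnti_vs_pH"] else NA_real_,
      pairs = fit$pairs)
  }
  if (!length(res)) {
    warning("no feasible depth", call. = FALSE)
    return(structure(list(results = list(), summary = NULL),
                     class = "depth_sensitivity"))
  }
  summ <- do.call(rbind, lapply(res, function(r) {
    fr <- r$fractions
    pct <- as.numeric(fr[1L, grep("^pct_", names(fr))])
    modal <- process_levels[1:5][which.max(pct)]
    data.frame(depth = r$depth, n_samples = nrow(r$ses),
               mean_ses_mntd = mean(r$ses$ses_mntd, na.rm = TRUE),
               mantel_r_ph = r$mantel_r_ph, modal_process = modal,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(results = res, summary = summ), class = "depth_sensitivity")
}

#' @export
print.depth_sensitivity <- function(x, ...) {
  cat("Rarefaction-depth sensitivity across",
      length(x$results), "depth(s)\n")
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}
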