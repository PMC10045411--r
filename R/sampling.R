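# Characterisation of the feasible steady-state flux space by
# artificial-centering hit-and-run (ACHR) sampling, with downstream
# Kolmogorov-Smirnov detection of differentially active reactions and
# correlated reaction sets (co-sets).

#' Warmup points for flux sampling
#'
#' The FVA extreme points: for every reaction, the flux vectors attaining
#' its minimum and maximum. These span the polytope and seed the ACHR
#' direction set.
#'
#' @param model a `metabolic_model`.
#' @return matrix (2n x n) of feasible flux vectors, columns = reactions.
#' @export
fva_warmup_points <- function(model) {
  split <- split_reversible(model)
  n <- nrow(model$rxns)
  pts <- matrix(NA_real_, 2 * n, n, dimnames = list(NULL, model$rxns$id))
  k <- 0L
  for (j in seq_len(n)) {
    obj <- obj_vector(split, model$rxns$id[j])
    for (mx in c(FALSE, TRUE)) {
      res <- solve_split_lp(split, obj, maximize = mx)
      if (res$status != "optimal")
        abort_rgem(sprintf("warmup LP for '%s' is %s", model$rxns$id[j],
                           res$status), "rgem_sampling_error")
      k <- k + 1L
      pts[k, ] <- split_to_fluxes(split, res$x)
    }
  }
  pts
}

#' Sample the feasible flux polytope
#'
#' Artificial-centering hit-and-run over `{v : S v = 0, lb <= v <= ub}`.
#' Directions run through the FVA warmup vertices, `thinning` chain steps
#' separate consecutive kept points, and the seed makes runs bit-identical.
#' The conventional number of points is 2n for n reactions.
#'
#' @param model a `metabolic_model` (feasible, finite bounds).
#' @param n_points number of samples (default `2 * n_reactions`).
#' @param seed RNG seed (mandatory for reproducibility).
#' @param thinning chain steps per kept point; the default scales with the
#'   number of reactions (`max(100, 25 n)`) because the mixing time of
#'   hit-and-run grows with the polytope dimension, and a fixed short
#'   thinning leaves chain-level autocorrelation that downstream
#'   two-sample tests would mistake for signal.
#' @param warmup optional precomputed [fva_warmup_points()] matrix.
#' @return a `flux_sample_set`: list with `samples` (n_points x n matrix),
#'   `reaction_ids`, `seed`, `n_points`.
#' @export
sample_fluxes <- function(model, n_points = NULL, seed, thinning = NULL,
                          warmup = NULL) {
  if (missing(seed)) abort_rgem("sample_fluxes requires a seed", "rgem_sampling_error")
  n <- nrow(model$rxns)
  n_points <- n_points %||% (2L * n)
  thinning <- thinning %||% max(100L, 25L * n)
  if (is.null(warmup)) warmup <- fva_warmup_points(model)
  stopifnot(ncol(warmup) == n)
  width <- apply(warmup, 2, function(x) diff(range(x)))
  if (all(width < 1e-9)) {
    warn_rgem("flux polytope is numerically a single point; returning it")
    samples <- matrix(rep(warmup[1, ], n_points), n_points, n, byrow = TRUE,
                      dimnames = list(NULL, model$rxns$id))
  } else {
    set.seed(seed)
    samples <- .achr_sample(warmup, model$rxns$lb, model$rxns$ub,
                            as.integer(n_points), as.integer(thinning))
    colnames(samples) <- model$rxns$id
  }
  structure(list(samples = samples, reaction_ids = model$rxns$id,
                 seed = seed, n_points = n_points, model_id = model$id),
            class = "flux_sample_set")
}

#' @export
print.flux_sample_set <- function(x, ...) {
  cat(sprintf("<flux_sample_set> %d points x %d reactions (seed %s)\n",
              nrow(x$samples), ncol(x$samples), format(x$seed)))
  invisible(x)
}

#' Normalize sampled flux states
#'
#' The default scales every sample by its total absolute flux (L1 norm),
#' making flux states comparable between models of different overall
#' activity; all-zero rows are left unchanged.
#'
#' @param set a `flux_sample_set`.
#' @param method `"l1"`, `"zscore"` (per-reaction standardisation) or
#'   `"none"`.
#' @return the normalized `flux_sample_set`.
#' @export
normalize_samples <- function(set, method = c("l1", "zscore", "none")) {
  method <- match.arg(method)
  s <- set$samples
  if (method == "l1") {
    tot <- rowSums(abs(s))
    tot[tot == 0] <- 1
    set$samples <- s / tot
  } else if (method == "zscore") {
    mu <- colMeans(s)
    sdv <- apply(s, 2, sd)
    sdv[sdv == 0] <- 1
    set$samples <- sweep(sweep(s, 2, mu), 2, sdv, "/")
  }
  set$normalization <- method
  set
}

#' Differentially active reactions between two sample sets
#'
#' Two-sample Kolmogorov-Smirnov test per reaction shared between the two
#' sets; reactions below the p threshold are returned sorted by statistic.
#' No multiple-testing correction is applied (the threshold is meant to be
#' stringent, conventionally p < 0.001).
#'
#' @param wt,ko `flux_sample_set` objects, normalized identically.
#' @param p_threshold significance threshold.
#' @param min_samples per-side minimum; reactions with fewer are skipped.
#' @return data.frame `reaction`, `ks_statistic`, `p_value`, `direction`
#'   (+1 when mean KO > mean WT) for reactions with `p < p_threshold`; the
#'   full per-reaction table is attached as attribute `"all_tests"`.
#' @export
differential_reactions <- function(wt, ko, p_threshold = 0.001,
                                   min_samples = 8) {
  shared <- intersect(wt$reaction_ids, ko$reaction_ids)
  out <- data.frame(reaction = shared, ks_statistic = NA_real_,
                    p_value = NA_real_, direction = NA_real_,
                    stringsAsFactors = FALSE)
  keep <- logical(length(shared))
  for (k in seq_along(shared)) {
    a <- wt$samples[, shared[k]]
    b <- ko$samples[, shared[k]]
    if (length(a) < min_samples || length(b) < min_samples) {
      warn_rgem(sprintf("reaction '%s': fewer than %d samples; skipped",
                        shared[k], min_samples))
      next
    }
    keep[k] <- TRUE
    if (max(a) - min(a) < 1e-12 && max(b) - min(b) < 1e-12 &&
        abs(mean(a) - mean(b)) < 1e-12) {
      out$ks_statistic[k] <- 0; out$p_value[k] <- 1; out$direction[k] <- 0
      next
    }
    ks <- suppressWarnings(stats::ks.test(a, b))
    out$ks_statistic[k] <- unname(ks$statistic)
    out$p_value[k] <- ks$p.value
    out$direction[k] <- sign(mean(b) - mean(a))
  }
  all_tests <- out[keep, , drop = FALSE]
  hits <- all_tests[all_tests$p_value < p_threshold, , drop = FALSE]
  hits <- hits[order(-hits$ks_statistic, hits$reaction), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "all_tests") <- all_tests
  hits
}

#' Correlated reaction sets (co-sets)
#'
#' Builds a graph joining reactions whose sampled fluxes have absolute
#' Pearson correlation at or above the cutoff and returns the connected
#' components of size >= 2. Reactions with (numerically) constant flux are
#' excluded beforehand.
#'
#' @param set a `flux_sample_set` with at least `min_samples` points.
#' @param r_cutoff absolute Pearson correlation cutoff (conventionally 0.95).
#' @param min_samples minimum number of sample points required.
#' @param linkage `"components"` (single linkage, default) or `"cliques"`
#'   (maximal cliques, diagnostics only).
#' @return list of character vectors (reaction ids), largest first.
#' @export
compute_cosets <- function(set, r_cutoff = 0.95, min_samples = 10,
                           linkage = c("components", "cliques")) {
  linkage <- match.arg(linkage)
  if (nrow(set$samples) < min_samples)
    abort_rgem(sprintf("need >= %d samples for co-set analysis", min_samples),
               "rgem_sampling_error")
  vars <- apply(set$samples, 2, var)
  keep <- names(vars)[vars > 1e-12]
  if (length(keep) < 2) return(list())
  cc <- abs(suppressWarnings(cor(set$samples[, keep, drop = FALSE])))
  cc[is.na(cc)] <- 0
  adj <- (cc >= r_cutoff)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  groups <- if (linkage == "components") {
    comp <- igraph::components(g)
    split(names(comp$membership), comp$membership)
  } else {
    lapply(igraph::max_cliques(g, min = 2),
           function(vs) igraph::V(g)$name[as.integer(vs)])
  }
  groups <- Filter(function(x) length(x) >= 2, groups)
  groups <- lapply(groups, sort)
  groups[order(-vapply(groups, length, integer(1)),
               vapply(groups, `[`, character(1), 1))]
}

#' Persist a flux sample set as TSV with header metadata
#'
#' Writes `# key: value` header lines (seed, n_points, normalization)
#' followed by the sample matrix; a `.gz` suffix compresses the file.
#'
#' @param set a `flux_sample_set`.
#' @param path output file (`.tsv` or `.tsv.gz`).
#' @return the path, invisibly.
#' @export
write_samples_tsv <- function(set, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# seed: %d", as.integer(set$seed)),
               sprintf("# n_points: %d", as.integer(set$n_points)),
               sprintf("# normalization: %s", set$normalization %||% "none")),
             con)
  utils::write.table(set$samples, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a flux sample set written by [write_samples_tsv()]
#' @param path file path.
#' @return a `flux_sample_set`.
#' @export
read_samples_tsv <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, 1)
    if (!length(line) || !startsWith(line, "#")) break
    hdr <- c(hdr, line)
  }
  meta <- function(key) sub(sprintf("^# %s: ", key), "",
                            grep(sprintf("^# %s:", key), hdr, value = TRUE))
  samples <- as.matrix(utils::read.delim(text = c(line, readLines(con)),
                                         check.names = FALSE))
  structure(list(samples = samples, reaction_ids = colnames(samples),
                 seed = as.integer(meta("seed")),
                 n_points = as.integer(meta("n_points")),
                 normalization = meta("normalization")),
            class = "flux_sample_set")
}
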