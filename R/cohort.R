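## Locate the python interpreter used for the UMAP embedding.
find_python <- function() {
  py <- Sys.getenv("MITOIFC_PYTHON", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py))
    stop("no python interpreter found for UMAP; install python with ",
         "umap-learn or set MITOIFC_PYTHON", call. = FALSE)
  py
}

#' UMAP embedding of donor feature vectors
#'
#' Two-dimensional UMAP of the normalized feature matrix with the study's
#' settings (Euclidean metric, 8 neighbors, minimum distance 0.01).
#' The embedding is computed by the umap-learn reference implementation
#' through a bundled python helper; a fixed \code{random_state} makes it
#' deterministic for a given seed. Several seeds can be requested in one call
#' (one python process), which is much cheaper than repeated calls.
#'
#' @param x numeric matrix or data frame, donors x features; rownames become
#'   donor identifiers.
#' @param n_neighbors,min_dist,metric UMAP parameters (defaults 8, 0.01,
#'   "euclidean").
#' @param seed integer seed, or a vector of seeds.
#' @return for a single seed, a donors x 2 matrix with attribute
#'   \code{"seed"}; for several seeds, a named list of such matrices.
#' @export
embed_umap <- function(x, n_neighbors = 8, min_dist = 0.01,
                       metric = "euclidean", seed = 42) {
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x))
    stop("'x' must be a complete numeric matrix", call. = FALSE)
  check_number(n_neighbors, "n_neighbors", lower = 2, integer = TRUE)
  check_number(min_dist, "min_dist", lower = 0)
  if (nrow(x) < n_neighbors + 1)
    stop(sprintf(paste0("too few donors (%d) for n_neighbors = %d; ",
                        "reduce n_neighbors"), nrow(x), n_neighbors),
         call. = FALSE)
  seeds <- as.integer(seed)
  td <- tempfile("umap")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  in_csv <- file.path(td, "x.csv")
  out_csv <- file.path(td, "emb.csv")
  cfg <- file.path(td, "cfg.json")
  utils::write.table(x, in_csv, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(input_csv = in_csv, output_csv = out_csv,
                            n_neighbors = n_neighbors, min_dist = min_dist,
                            metric = metric, seeds = seeds),
                       cfg, auto_unbox = TRUE, digits = NA)
  script <- system.file("python", "umap_embed.py", package = "mitoifc")
  if (!nzchar(script))
    stop("bundled umap_embed.py not found; is the package installed?",
         call. = FALSE)
  status <- system2(find_python(), c(shQuote(script), shQuote(cfg)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(out_csv))
    stop("UMAP embedding failed (python exit status ", status, ")",
         call. = FALSE)
  emb <- utils::read.csv(out_csv)
  res <- lapply(seeds, function(s) {
    m <- as.matrix(emb[emb$seed == s, c("x", "y")])
    dimnames(m) <- list(rownames(x), c("umap1", "umap2"))
    attr(m, "seed") <- s
    m
  })
  names(res) <- as.character(seeds)
  if (length(res) == 1L) res[[1]] else res
}

#' Ward hierarchical clustering of donors
#'
#' Agglomerative clustering on Euclidean distances with Ward linkage
#' (\code{hclust} method \code{"ward.D2"}, whose merge sequence minimizes the
#' within-cluster variance increase at every step). Clustering always operates
#' on the feature matrix itself; UMAP is visualization only.
#'
#' With \code{k = "auto"} the cut is chosen as the largest relative gap
#' between successive merge heights over k in 2..6 (a reproducible stand-in
#' for visual dendrogram inspection), and the mean silhouette width per
#' candidate k is reported as a diagnostic.
#'
#' @param x numeric matrix/data frame, donors x features.
#' @param k integer number of clusters, or \code{"auto"}.
#' @return object of class \code{"ward_clustering"}: \code{labels} (named
#'   integer vector), \code{k}, \code{hclust}, \code{newick} (dendrogram as a
#'   Newick string) and \code{diagnostics} (per-k height gap and mean
#'   silhouette).
#' @export
cluster_ward <- function(x, k = "auto") {
  x <- as.matrix(x)
  if (anyNA(x)) stop("'x' must be complete; see cohort_matrix()", call. = FALSE)
  n <- nrow(x)
  d <- stats::dist(x)
  hc <- stats::hclust(d, method = "ward.D2")
  ks <- 2:min(6, n - 1)
  heights <- hc$height            # ascending, length n-1
  gap <- vapply(ks, function(kk) {
    ## height of the merge that a k-cut removes, relative to the previous one
    heights[n - kk + 1L] / heights[n - kk]
  }, numeric(1))
  sil <- vapply(ks, function(kk) {
    cl <- stats::cutree(hc, kk)
    mean(cluster::silhouette(cl, d)[, "sil_width"])
  }, numeric(1))
  diagnostics <- data.frame(k = ks, height_gap = gap, mean_silhouette = sil)
  if (identical(k, "auto")) {
    k <- ks[which.max(gap)]
  } else {
    check_number(k, "k", lower = 1, upper = n, integer = TRUE)
    k <- as.integer(k)
  }
  labels <- if (k == n) stats::setNames(seq_len(n), rownames(x))
            else stats::cutree(hc, k)
  if (is.null(names(labels)) && !is.null(rownames(x)))
    names(labels) <- rownames(x)
  newick <- tryCatch(ape::write.tree(ape::as.phylo(hc)),
                     error = function(e) NA_character_)
  structure(list(labels = labels, k = k, hclust = hc, newick = newick,
                 diagnostics = diagnostics),
            class = "ward_clustering")
}

#' @export
print.ward_clustering <- function(x, ...) {
  cat(sprintf("<ward_clustering> k = %d (%s)\n", x$k,
              paste(sprintf("cluster %s: n=%d", names(table(x$labels)),
                            as.integer(table(x$labels))), collapse = ", ")))
  invisible(x)
}

#' Welch tests of features between two clusters
#'
#' Two-sided Welch t test (Satterthwaite degrees of freedom) of every feature
#' column between the two clusters. Raw p values are reported alongside
#' Benjamini-Hochberg adjusted q values; the study reports raw p, the
#' adjustment is provided as a side-by-side diagnostic.
#'
#' @param x numeric matrix/data frame, donors x features.
#' @param labels cluster labels with exactly two distinct values, each with at
#'   least 2 donors.
#' @return data frame: feature, t, df, p, q. Features with degenerate
#'   variance in both groups get missing statistics with a warning.
#' @export
cluster_feature_tests <- function(x, labels) {
  x <- as.data.frame(x)
  lv <- sort(unique(labels))
  if (length(lv) != 2L)
    stop("'labels' must define exactly two clusters", call. = FALSE)
  if (min(table(labels)) < 2L)
    stop("both clusters need at least 2 donors", call. = FALSE)
  rows <- lapply(names(x), function(f) {
    a <- x[[f]][labels == lv[1]]
    b <- x[[f]][labels == lv[2]]
    tt <- tryCatch(stats::t.test(a, b, var.equal = FALSE),
                   error = function(e) NULL)
    if (is.null(tt)) {
      warning(sprintf("feature '%s': degenerate variance, p missing", f),
              call. = FALSE)
      return(data.frame(feature = f, t = NA_real_, df = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    data.frame(feature = f, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

## Mann-Whitney with the study's convention: exact two-sided p for small
## tie-free samples, normal approximation with tie correction otherwise.
mann_whitney <- function(a, b) {
  exact <- (length(a) + length(b)) <= 12 &&
    !any(duplicated(c(a, b)))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' Disease-subgroup tests against the healthy reference
#'
#' For every disease subgroup with at least three patients, each feature's
#' normalized percentages are compared with the reference-control percentages
#' by a two-sided Mann-Whitney U test (exact for combined n <= 12 without
#' ties, normal approximation with tie correction otherwise). Smaller
#' subgroups are reported as untested.
#'
#' @param x numeric matrix/data frame of patient feature percentages.
#' @param subtypes character vector of disease subtypes per patient row.
#' @param reference numeric matrix/data frame of the reference controls'
#'   percentages (same feature columns).
#' @return list with \code{tests} (data frame: subtype, feature, n, U, p,
#'   exact) and \code{untested} (subtypes with n < 3).
#' @export
subgroup_vs_reference <- function(x, subtypes, reference) {
  x <- as.data.frame(x)
  reference <- as.data.frame(reference)
  feats <- intersect(names(x), names(reference))
  if (length(feats) == 0L)
    stop("no shared feature columns between patients and reference",
         call. = FALSE)
  tab <- table(subtypes)
  tested <- names(tab)[tab >= 3]
  untested <- names(tab)[tab < 3]
  rows <- list()
  for (st in tested) {
    idx <- which(subtypes == st)
    for (f in feats) {
      mw <- mann_whitney(x[[f]][idx], reference[[f]])
      rows[[length(rows) + 1L]] <- data.frame(
        subtype = st, feature = f, n = length(idx),
        U = mw$U, p = mw$p, exact = mw$exact, stringsAsFactors = FALSE)
    }
  }
  list(tests = if (length(rows)) do.call(rbind, rows) else
         data.frame(subtype = character(), feature = character(),
                    n = integer(), U = numeric(), p = numeric(),
                    exact = logical()),
       untested = untested)
}

#' Spearman correlation of features with binary clinical phenotypes
#'
#' Binary phenotypes (Yes/No, coded 1/0) are correlated with each feature
#' percentage by Spearman's rank correlation; donors with a missing phenotype
#' are excluded pairwise, and p values use the tie-corrected asymptotic
#' approximation. Phenotypes constant after NA removal give a missing rho.
#'
#' @param x numeric matrix/data frame, donors x features.
#' @param clinical data frame of phenotype columns with values in
#'   \{"Yes", "No", NA\} (or already 0/1); a donor_id column, if present, is
#'   ignored for the arithmetic but must match row order.
#' @return list of matrices \code{rho}, \code{p} and \code{n} (features x
#'   phenotypes).
#' @export
phenotype_correlation <- function(x, clinical) {
  x <- as.data.frame(x)
  clinical <- as.data.frame(clinical)
  clinical <- clinical[, setdiff(names(clinical), "donor_id"), drop = FALSE]
  if (nrow(clinical) != nrow(x))
    stop("'clinical' must have one row per donor row of 'x'", call. = FALSE)
  bin <- lapply(clinical, function(v) {
    if (is.numeric(v)) return(v)
    out <- ifelse(v == "Yes", 1, ifelse(v == "No", 0, NA))
    out[is.na(v) | v == "NA"] <- NA
    out
  })
  feats <- names(x)
  phen <- names(bin)
  rho <- p <- n <- matrix(NA_real_, length(feats), length(phen),
                          dimnames = list(feats, phen))
  for (f in feats) for (ph in phen) {
    ok <- !is.na(x[[f]]) & !is.na(bin[[ph]])
    n[f, ph] <- sum(ok)
    if (sum(ok) < 3 || length(unique(bin[[ph]][ok])) < 2 ||
        length(unique(x[[f]][ok])) < 2)
      next
    ct <- suppressWarnings(stats::cor.test(x[[f]][ok], bin[[ph]][ok],
                                           method = "spearman",
                                           exact = FALSE))
    rho[f, ph] <- unname(ct$estimate)
    p[f, ph] <- ct$p.value
  }
  list(rho = rho, p = p, n = n)
}

#' Fisher's exact test of cluster vs phenotype
#'
#' Two-by-two association between the two clusters and a binary phenotype,
#' with donors whose phenotype was not assessed (NA) excluded. The two-sided
#' exact p comes from the hypergeometric distribution and the reported odds
#' ratio is the conditional maximum-likelihood estimate.
#'
#' @param labels cluster labels (two levels).
#' @param phenotype vector in \{"Yes", "No", NA\} (or 0/1 with NA).
#' @return list: \code{table} (2x2), \code{odds_ratio}, \code{p}.
#' @export
cluster_phenotype_fisher <- function(labels, phenotype) {
  if (length(labels) != length(phenotype))
    stop("'labels' and 'phenotype' must have equal length", call. = FALSE)
  ph <- if (is.numeric(phenotype)) phenotype
        else ifelse(phenotype == "Yes", 1, ifelse(phenotype == "No", 0, NA))
  ph[!is.na(phenotype) & phenotype == "NA"] <- NA
  ok <- !is.na(ph) & !is.na(labels)
  tab <- table(cluster = labels[ok], phenotype = ph[ok])
  if (!all(dim(tab) == c(2L, 2L)) || any(rowSums(tab) == 0) ||
      any(colSums(tab) == 0)) {
    return(list(table = tab, odds_ratio = NA_real_, p = 1))
  }
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(table = tab, odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Assemble a complete cohort feature matrix
#'
#' Extracts the five normalized feature percentages for the patients of a
#' \code{\link{donor_vectors}} table and applies the missing-data policy:
#' donors with any missing feature are dropped (default) or median-imputed.
#'
#' @param vectors a \code{donor_vectors} data frame.
#' @param missing one of \code{"drop"}, \code{"impute"}.
#' @param role_filter roles to keep (default \code{"patient"}).
#' @return numeric matrix (donors x 5) with donor ids as rownames and the
#'   kept metadata (cluster, subtype) as attributes.
#' @export
cohort_matrix <- function(vectors, missing = c("drop", "impute"),
                          role_filter = "patient") {
  missing <- match.arg(missing)
  v <- vectors[vectors$role %in% role_filter, , drop = FALSE]
  feats <- ifc_features_pct()
  m <- as.matrix(v[, feats, drop = FALSE])
  rownames(m) <- v$donor_id
  if (anyNA(m)) {
    if (missing == "drop") {
      keep <- stats::complete.cases(m)
      m <- m[keep, , drop = FALSE]
      v <- v[keep, , drop = FALSE]
    } else {
      for (j in seq_len(ncol(m)))
        m[is.na(m[, j]), j] <- stats::median(m[, j], na.rm = TRUE)
    }
  }
  if (!all(is.finite(m))) stop("non-finite feature percentages", call. = FALSE)
  attr(m, "cluster") <- v$cluster
  attr(m, "subtype") <- v$subtype
  m
}

#' Cohort-level analysis of normalized IFC features
#'
#' The package's model-like core: clusters donors on their five normalized
#' feature percentages (Euclidean distance, Ward linkage), embeds them in two
#' dimensions with UMAP for visualization, tests each feature between the two
#' clusters (Welch), and — when a clinical table is supplied — computes
#' Spearman feature-phenotype correlations and Fisher's exact cluster-
#' phenotype tests.
#'
#' @param vectors a \code{\link{donor_vectors}} table (or a plain numeric
#'   matrix of feature percentages).
#' @param clinical optional clinical phenotype data frame (values Yes/No/NA),
#'   one row per clustered donor.
#' @param k clusters ("auto" or integer).
#' @param seed seed for the UMAP embedding.
#' @param missing missing-feature policy, see \code{\link{cohort_matrix}}.
#' @param umap set \code{FALSE} to skip the embedding (e.g. without python).
#' @return object of class \code{"ifc_cohort"} with elements \code{matrix},
#'   \code{distance}, \code{clustering}, \code{labels}, \code{embedding},
#'   \code{feature_tests}, \code{phenotype} (rho/p/n and per-phenotype Fisher
#'   results) and \code{seed}.
#' @export
cohort_analysis <- function(vectors, clinical = NULL, k = "auto", seed = 42,
                            missing = "drop", umap = TRUE) {
  m <- if (is.matrix(vectors)) vectors else cohort_matrix(vectors, missing)
  cl <- cluster_ward(m, k)
  emb <- if (isTRUE(umap)) embed_umap(m, seed = seed) else NULL
  tests <- if (cl$k == 2L) cluster_feature_tests(m, cl$labels) else NULL
  phen <- NULL
  if (!is.null(clinical)) {
    corr <- phenotype_correlation(m, clinical)
    cols <- setdiff(names(as.data.frame(clinical)), "donor_id")
    fisher <- lapply(cols, function(cn)
      cluster_phenotype_fisher(cl$labels, as.data.frame(clinical)[[cn]]))
    names(fisher) <- cols
    phen <- list(correlation = corr, fisher = fisher)
  }
  structure(list(matrix = m, distance = stats::dist(m), clustering = cl,
                 labels = cl$labels, embedding = emb, feature_tests = tests,
                 phenotype = phen, seed = seed),
            class = "ifc_cohort")
}

#' @export
print.ifc_cohort <- function(x, ...) {
  cat(sprintf("<ifc_cohort> %d donors, %d features, k = %d clusters\n",
              nrow(x$matrix), ncol(x$matrix), x$clustering$k))
  print(x$clustering)
  if (!is.null(x$feature_tests)) {
    cat("Welch tests between clusters:\n")
    print(x$feature_tests, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @export
summary.ifc_cohort <- function(object, ...) {
  cat(sprintf("Cohort of %d donors clustered into %d groups (Ward, Euclidean)\n",
              nrow(object$matrix), object$clustering$k))
  print(object$clustering$diagnostics, row.names = FALSE, digits = 3)
  for (cl in sort(unique(object$labels))) {
    cat(sprintf("\nCluster %s feature means (%% of control):\n", cl))
    print(round(colMeans(object$matrix[object$labels == cl, , drop = FALSE]), 1))
  }
  if (!is.null(object$phenotype)) {
    cat("\nFisher cluster-phenotype p values:\n")
    print(vapply(object$phenotype$fisher, function(f) f$p, numeric(1)),
          digits = 3)
  }
  invisible(object)
}

#' Plot a cohort analysis
#'
#' \code{type = "umap"} draws the 2-D embedding colored by cluster;
#' \code{type = "dendrogram"} the Ward tree; \code{type = "box"} per-feature
#' boxplots split by cluster.
#'
#' @param x an \code{ifc_cohort}.
#' @param type plot type.
#' @param ... ignored.
#' @export
plot.ifc_cohort <- function(x, type = c("umap", "dendrogram", "box"), ...) {
  type <- match.arg(type)
  if (type == "umap") {
    if (is.null(x$embedding)) stop("no embedding stored", call. = FALSE)
    graphics::plot(x$embedding, col = x$labels + 1L, pch = 19,
                   xlab = "UMAP 1", ylab = "UMAP 2",
                   main = "Donor embedding (UMAP)")
    graphics::legend("topright", legend = paste("cluster", sort(unique(x$labels))),
                     col = sort(unique(x$labels)) + 1L, pch = 19, bty = "n")
  } else if (type == "dendrogram") {
    graphics::plot(x$clustering$hclust, main = "Ward clustering",
                   xlab = "", sub = "")
  } else {
    old <- graphics::par(mfrow = c(1, ncol(x$matrix)))
    on.exit(graphics::par(old), add = TRUE)
    for (f in colnames(x$matrix))
      graphics::boxplot(x$matrix[, f] ~ x$labels, xlab = "cluster",
                        ylab = "% of control", main = f)
  }
  invisible(x)
}

#' Radar-plot data and drawing for one donor
#'
#' Draws the five normalized feature percentages of one donor as a radar
#' polygon over the healthy reference band.
#'
#' @param vector one row of a \code{donor_vectors} table.
#' @param ranges an \code{\link{reference_ranges}} object.
#' @param ... passed to \code{graphics::plot.window}.
#' @export
radar_plot <- function(vector, ranges, ...) {
  feats <- ifc_features_pct()
  vals <- as.numeric(vector[1, feats])
  ang <- seq(0, 2 * pi, length.out = length(feats) + 1)[-(length(feats) + 1)] +
    pi / 2
  lim <- max(c(vals, ranges$upper_pct), na.rm = TRUE) * 1.1
  graphics::plot.new()
  graphics::plot.window(c(-lim, lim), c(-lim, lim), asp = 1, ...)
  poly <- function(r, ...)
    graphics::polygon(r * cos(ang), r * sin(ang), ...)
  poly(ranges$upper_pct, col = grDevices::grey(0.9), border = NA)
  poly(ranges$lower_pct, col = "white", border = NA)
  poly(ifelse(is.na(vals), 0, vals), border = "red", lwd = 2)
  graphics::text(1.05 * lim * cos(ang), 1.05 * lim * sin(ang),
                 sub("_pct$", "", feats), cex = 0.7, xpd = NA)
  graphics::title(main = vector$donor_id[1])
  invisible(NULL)
}
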