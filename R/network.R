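#' Absolute Pearson correlation similarity between genes
#'
#' The unsigned co-expression similarity S(k, j) = |cor(k, j)| of the two
#' genes' expression profiles across samples; S(k, k) = 1.
#'
#' @param expr Genes x samples matrix, every gene with nonzero variance,
#'   at least 3 samples.
#' @return Symmetric genes x genes matrix with unit diagonal, entries in
#'   \[0, 1\].
#' @export
pearson_similarity <- function(expr) {
  expr <- as_expression_matrix(expr)
  if (ncol(expr) < 3L) stop("need at least 3 samples to correlate genes", call. = FALSE)
  v <- row_variances(expr)
  if (any(v == 0)) {
    stop("zero-variance gene(s) have undefined correlations: ",
         paste(head(rownames(expr)[v == 0], 5L), collapse = ", "), call. = FALSE)
  }
  s <- abs(cor(t(expr)))
  s[s > 1] <- 1  # guard rounding
  diag(s) <- 1
  s
}

#' Soft-thresholding power adjacency
#'
#' Raises the similarity matrix elementwise to the power `b`, the weighted
#' network's "soft" analogue of hard-thresholding an unweighted graph. The
#' diagonal is set to 0 so that connectivity sums run over j != k.
#'
#' @param S Similarity matrix from [pearson_similarity()].
#' @param power Positive exponent b (conventionally chosen by the scale-free
#'   topology criterion, see [pick_soft_power()]; b = 6 is the usual default).
#' @return Adjacency matrix with zero diagonal and entries in \[0, 1\], with
#'   attribute `power`.
#' @export
soft_power_adjacency <- function(S, power = 6) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  if (power <= 0) stop("power must be positive", call. = FALSE)
  a <- S^power
  diag(a) <- 0
  attr(a, "power") <- power
  a
}

#' Whole-network connectivity
#'
#' C_k = sum over j != k of a(k, j): the total adjacency weight a gene carries
#' to the rest of the network.
#'
#' @param A Adjacency matrix (zero diagonal).
#' @return Named nonnegative vector, one value per gene.
#' @export
node_connectivity <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  A <- zero_diag(A)
  rowSums(A)
}

zero_diag <- function(A) { diag(A) <- 0; A }

#' Choose the soft-thresholding power by the scale-free topology criterion
#'
#' For each candidate power, connectivities are binned (10 equal-width bins),
#' and log10 bin frequency is regressed on log10 mean bin connectivity; a
#' network is near scale-free when this log-log relation is linear. The
#' smallest candidate whose fit reaches `r2_target` is returned. If none
#' qualifies, the conventional default b = 6 is returned with a warning.
#'
#' @param S Similarity matrix.
#' @param candidates Candidate powers (default 1:10).
#' @param r2_target R-squared required of the log-log fit (default 0.8).
#' @param n_bins Number of connectivity bins.
#' @return The chosen power, with attribute `fit_table`, a tibble of
#'   (power, r_squared, slope, mean_connectivity).
#' @export
pick_soft_power <- function(S, candidates = 1:10, r2_target = 0.8, n_bins = 10L) {
  if (length(candidates) == 0L) stop("no candidate powers supplied", call. = FALSE)
  fits <- lapply(candidates, function(b) {
    k <- node_connectivity(soft_power_adjacency(S, b))
    c(scale_free_fit(k, n_bins = n_bins), mean_connectivity = mean(k))
  })
  tab <- tibble::tibble(
    power = as.numeric(candidates),
    r_squared = vapply(fits, `[[`, 0, "r_squared"),
    slope = vapply(fits, `[[`, 0, "slope"),
    mean_connectivity = vapply(fits, `[[`, 0, "mean_connectivity")
  )
  ok <- which(tab$r_squared >= r2_target)
  if (length(ok) > 0L) {
    b <- tab$power[ok[1L]]
  } else {
    warning("no candidate power reached R^2 >= ", r2_target,
            "; falling back to the conventional b = 6", call. = FALSE)
    b <- 6
  }
  structure(b, fit_table = tab)
}

# log10(freq) ~ log10(mean connectivity) over equal-width connectivity bins
scale_free_fit <- function(k, n_bins = 10L) {
  if (diff(range(k)) == 0) stop("degenerate connectivity distribution", call. = FALSE)
  bins <- cut(k, breaks = n_bins, include.lowest = TRUE)
  freq <- tapply(k, bins, length)
  kmean <- tapply(k, bins, mean)
  keep <- !is.na(freq) & freq > 0 & kmean > 0
  if (sum(keep) < 3L) {
    stop("fewer than 3 nonempty connectivity bins; cannot assess scale-free fit", call. = FALSE)
  }
  fit <- lm(log10(as.numeric(freq[keep])) ~ log10(as.numeric(kmean[keep])))
  c(r_squared = summary(fit)$r.squared, slope = unname(coef(fit)[2L]))
}

#' Topological overlap dissimilarity
#'
#' d(k, j) = 1 - w(k, j) with topological overlap
#' w(k, j) = (l(k, j) + a(k, j)) / (min(C_k, C_j) + 1 - a(k, j)), where
#' l(k, j) = sum over u != k, j of a(k, u) a(u, j) counts shared neighbours.
#' Genes whose neighbourhoods coincide get d near 0; genes with no direct
#' connection and no shared neighbours get d = 1.
#'
#' @param A Adjacency matrix (zero diagonal).
#' @return Symmetric dissimilarity matrix in \[0, 1\] with zero diagonal.
#' @export
tom_dissimilarity <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  A <- zero_diag(A)
  C <- rowSums(A)
  L <- A %*% A  # zero diagonal of A removes the u = k and u = j terms
  denom <- outer(C, C, pmin) + 1 - A
  omega <- (L + A) / denom
  omega[denom <= 0] <- 0  # both genes isolated: no overlap, d = 1
  d <- 1 - omega
  d <- (d + t(d)) / 2
  d[d < 0] <- 0
  d[d > 1] <- 1
  diag(d) <- 0
  d
}

#' Detect network modules by cutting the dendrogram
#'
#' Average-linkage hierarchical clustering of the topological overlap
#' dissimilarity, followed by the basic tree-cut rule: cut at `cut_height`
#' times the dendrogram height and call every resulting branch with at least
#' `min_module_size` genes a module. Genes on smaller branches are left
#' unassigned (label 0). Labels 1, 2, ... are ordered by decreasing module
#' size.
#'
#' @param D Symmetric dissimilarity matrix with zero diagonal.
#' @param min_module_size Minimum genes per module (default 20).
#' @param cut_height Cut height as a fraction of the maximum merge height
#'   (default 0.99).
#' @return Integer vector of module labels, named by gene.
#' @export
detect_modules <- function(D, min_module_size = 20L, cut_height = 0.99) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  d <- nrow(D)
  labels <- setNames(integer(d), rownames(D))
  if (min_module_size > d) return(labels)
  tree <- hclust(as.dist(D), method = "average")
  raw <- cutree(tree, h = cut_height * max(tree$height))
  sizes <- table(raw)
  keep <- as.integer(names(sizes)[sizes >= min_module_size])
  if (length(keep) == 0L) return(labels)
  # relabel kept branches 1, 2, ... by decreasing size (first-seen order on ties)
  kept_sizes <- sizes[as.character(keep)]
  ord <- keep[order(-as.integer(kept_sizes), match(keep, unique(raw)))]
  for (i in seq_along(ord)) labels[raw == ord[i]] <- i
  labels
}

#' Intramodular connectivity
#'
#' Like [node_connectivity()] but with the adjacency sum restricted to genes
#' sharing the gene's module; genes in no module (label 0) get 0.
#'
#' @param A Adjacency matrix (zero diagonal).
#' @param labels Integer module labels aligned with the rows of `A`.
#' @return Named nonnegative vector.
#' @export
intramodular_connectivity <- function(A, labels) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A), length(labels) == nrow(A))
  A <- zero_diag(A)
  out <- setNames(numeric(nrow(A)), rownames(A))
  for (m in setdiff(unique(labels), 0L)) {
    idx <- which(labels == m)
    out[idx] <- rowSums(A[idx, idx, drop = FALSE])
  }
  out
}

#' Build the full weighted co-expression network
#'
#' Runs the whole construction: absolute-correlation similarity, soft power
#' adjacency (power fixed or chosen by [pick_soft_power()]), whole-network
#' connectivity, topological overlap dissimilarity, module detection by
#' dynamic tree cut, and intramodular connectivity.
#'
#' @param expr Genes x samples matrix (standardized or not; correlations are
#'   scale-free).
#' @param power Soft power b, or `NULL` to select it by the scale-free
#'   topology criterion.
#' @param candidates Candidate powers when `power` is `NULL`.
#' @param r2_target Scale-free fit target.
#' @param min_module_size,cut_height Module detection controls, see
#'   [detect_modules()].
#' @return A `coexpression_network` object: list with `adjacency`, `power`,
#'   `connectivity`, `tom`, `modules`, `intramodular_connectivity`,
#'   `gene_ids`. Use [tidy()] for the per-gene table.
#' @examples
#' set.seed(1)
#' sim <- simulate_dataset(simulation_scenario(
#'   n_samples = 60, module_sizes = c(30, 30), background_genes = 20))
#' net <- build_network(sim$expr, power = 6)
#' glance(net)
#' @export
build_network <- function(expr, power = NULL, candidates = 1:10,
                          r2_target = 0.8, min_module_size = 20L,
                          cut_height = 0.99) {
  expr <- as_expression_matrix(expr)
  S <- pearson_similarity(expr)
  if (is.null(power)) power <- as.numeric(pick_soft_power(S, candidates, r2_target))
  A <- soft_power_adjacency(S, power)
  conn <- node_connectivity(A)
  D <- tom_dissimilarity(A)
  labels <- detect_modules(D, min_module_size = min_module_size,
                           cut_height = cut_height)
  kin <- intramodular_connectivity(A, labels)
  structure(
    list(adjacency = A, power = power, connectivity = conn, tom = D,
         modules = labels, intramodular_connectivity = kin,
         gene_ids = rownames(expr)),
    class = "coexpression_network"
  )
}

#' @export
print.coexpression_network <- function(x, ...) {
  nm <- sum(unique(x$modules) != 0L)
  cat("Weighted co-expression network\n",
      "  genes: ", length(x$gene_ids), "\n",
      "  soft power b: ", x$power, "\n",
      "  modules: ", nm, " (", sum(x$modules == 0L), " genes unassigned)\n",
      sep = "")
  invisible(x)
}

#' @describeIn build_network per-gene tibble (gene, module, connectivity,
#'   intramodular_connectivity).
#' @param x A `coexpression_network`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
#' @export
tidy.coexpression_network <- function(x, ...) {
  tibble::tibble(
    gene = x$gene_ids,
    module = as.integer(x$modules),
    connectivity = unname(x$connectivity),
    intramodular_connectivity = unname(x$intramodular_connectivity)
  )
}

#' @describeIn build_network one-row summary (n_genes, power, n_modules,
#'   n_unassigned, median_connectivity).
#' @exportS3Method generics::glance
#' @export
glance.coexpression_network <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$gene_ids),
    power = x$power,
    n_modules = length(setdiff(unique(x$modules), 0L)),
    n_unassigned = sum(x$modules == 0L),
    median_connectivity = median(x$connectivity)
  )
}

#' Write the per-gene module table as TSV
#' @param network A `coexpression_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_module_table <- function(network, path) {
  tab <- tidy(network)
  tab$connectivity <- signif(tab$connectivity, 6L)
  tab$intramodular_connectivity <- signif(tab$intramodular_connectivity, 6L)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
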