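#' Inter-animal Pearson correlation matrix for one treatment group
#'
#' Functional connectivity between regions is defined as the Pearson
#' correlation, across the animals of one group, of their c-Fos signal
#' densities. Regions with zero variance across animals yield NA rows/columns.
#'
#' @param x a `density_table` (or [count_table]; Pearson correlation is
#'   invariant to the per-region volume scaling, so both give the same matrix).
#' @param group group label to subset to; NULL uses all animals in `x`.
#' @return object of class `corr_matrix`: a symmetric regions x regions
#'   matrix with unit diagonal, with attributes `group` and `n_animals`.
#' @export
correlation_matrix <- function(x, group = NULL) {
  m <- if (inherits(x, "density_table")) x$values
       else if (inherits(x, "count_table")) x$counts
       else as.matrix(x)
  if (!is.null(group)) {
    labs <- if (inherits(x, "density_table") || inherits(x, "count_table"))
      x$group else rownames(m)
    m <- m[labs == group, , drop = FALSE]
  }
  if (nrow(m) < 3)
    stop("need >= 3 animals to estimate correlations (got ", nrow(m), ")")
  r <- suppressWarnings(stats::cor(m))
  sdv <- apply(m, 2, stats::sd)
  degen <- sdv == 0
  r[degen, ] <- NA_real_
  r[, degen] <- NA_real_
  diag(r)[!degen] <- 1
  structure(r, group = if (is.null(group)) NA_character_ else group,
            n_animals = nrow(m), class = c("corr_matrix", "matrix"))
}

#' Heatmap ordering: anatomical blocks, clustered within block
#'
#' Regions are blocked by their anatomical division (in the order the
#' divisions appear in the region set); within each block the order is the
#' dendrogram leaf order from hierarchically clustering that block's
#' correlation profiles. The ordering derived from one (reference) group's
#' matrix is meant to be applied to every treatment's heatmap.
#'
#' @param corr a [correlation_matrix()] result
#' @param regions a [region_set] with `anatomical_group` for every region
#' @param method linkage criterion passed to [stats::hclust()]
#' @return character vector: region acronyms in heatmap order.
#' @export
anatomical_heatmap_order <- function(corr, regions, method = "complete") {
  acr <- colnames(corr)
  ag <- stats::setNames(regions$anatomical_group, regions$acronym)[acr]
  if (any(is.na(ag)))
    stop("regions without an anatomical group: ",
         paste(acr[is.na(ag)], collapse = ", "))
  blocks <- unique(stats::setNames(regions$anatomical_group, regions$acronym)[
    intersect(regions$acronym, acr)])
  out <- character(0)
  for (b in blocks) {
    members <- acr[ag == b]
    valid <- acr[apply(corr, 2, function(z) any(!is.na(z)))]
    ok <- members[apply(corr[members, valid, drop = FALSE], 1,
                        function(z) !anyNA(z))]
    bad <- setdiff(members, ok)
    ord <- ok
    if (length(ok) >= 3) {
      hc <- stats::hclust(stats::dist(corr[ok, valid, drop = FALSE]), method = method)
      # canonical leaf orientation (weights = mean correlation), so the
      # ordering depends on the data only, not on input column order
      wts <- rowMeans(corr[ok, valid, drop = FALSE], na.rm = TRUE)
      dd <- stats::reorder(stats::as.dendrogram(hc), wts, agglo.FUN = mean)
      ord <- ok[stats::order.dendrogram(dd)]
    } else if (length(ok) == 2) {
      ord <- sort(ok)
    }
    out <- c(out, ord, bad)
  }
  out
}

#' Hierarchical clustering of correlation profiles
#'
#' Two regions are close when their correlation patterns with all other
#' regions are similar: the distance is the Euclidean distance between rows of
#' the correlation matrix. Merge heights are normalised by the maximum height
#' so dendrograms of different groups are comparable on a common 0-1 scale.
#' Regions with any NA correlation are dropped (with a message).
#'
#' @param corr a [correlation_matrix()] result
#' @param method linkage criterion (`"complete"` default; `"single"`,
#'   `"average"`, `"ward.D2"` supported)
#' @return object of class `fos_dendrogram`: list with `hclust`, `leaves`,
#'   `merge_heights`, `heights_norm`, `method`, `group`, `dropped`.
#' @export
cluster_structures <- function(corr, method = "complete") {
  # zero-variance regions first (all-NA rows), then any residual incompleteness
  ok <- apply(corr, 1, function(z) any(!is.na(z)))
  sub <- corr[ok, ok, drop = FALSE]
  ok2 <- apply(sub, 1, function(z) !anyNA(z))
  keep <- rownames(sub)[ok2]
  ok <- rownames(corr) %in% keep
  dropped <- rownames(corr)[!ok]
  if (sum(ok) < 2) stop("need >= 2 regions with complete correlations")
  if (length(dropped))
    message("dropping ", length(dropped), " region(s) with NA correlations: ",
            paste(dropped, collapse = ", "))
  m <- corr[ok, ok, drop = FALSE]
  hc <- stats::hclust(stats::dist(m), method = method)
  h <- hc$height
  structure(list(hclust = hc, leaves = rownames(m),
                 merge_heights = h, heights_norm = h / max(h),
                 method = method, group = attr(corr, "group"),
                 dropped = dropped),
            class = "fos_dendrogram")
}

#' @export
print.fos_dendrogram <- function(x, ...) {
  cat("Correlation-profile dendrogram:", length(x$leaves), "regions,",
      x$method, "linkage")
  if (!is.na(x$group)) cat(" (group ", x$group, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Cut a dendrogram into k modules
#' @param dend a [cluster_structures()] result
#' @param k number of modules
#' @return integer membership vector named by region acronym.
#' @export
cut_modules <- function(dend, k) {
  stopifnot(inherits(dend, "fos_dendrogram"))
  stats::cutree(dend$hclust, k = k)
}

#' Module count as a function of dendrogram cut height
#'
#' Cutting a dendrogram at a fraction h of its total height leaves
#' `leaves - #\{merges with normalised height <= h\}` modules: at h = 0 every
#' region is its own module, at h = 1 a single module remains. The curve is
#' non-increasing in h.
#'
#' @param dend a [cluster_structures()] result
#' @param n_steps number of cut fractions on the 0-1 grid (101 = whole
#'   percentages).
#' @return data frame of class `modularity_curve`: `cut_fraction`, `modules`,
#'   with attribute `n_leaves`.
#' @export
modularity_curve <- function(dend, n_steps = 101) {
  stopifnot(inherits(dend, "fos_dendrogram"), n_steps >= 2)
  fr <- seq(0, 1, length.out = n_steps)
  nl <- length(dend$leaves)
  mods <- vapply(fr, function(h) nl - sum(dend$heights_norm <= h), integer(1))
  structure(data.frame(cut_fraction = fr, modules = mods),
            n_leaves = nl, group = dend$group,
            class = c("modularity_curve", "data.frame"))
}

#' @export
plot.modularity_curve <- function(x, ...) {
  graphics::plot(x$cut_fraction * 100, x$modules, type = "s",
                 xlab = "cut height (% of tree height)",
                 ylab = "number of modules", ...)
  invisible(x)
}

#' Compare two modularity curves with the log-rank (Mantel-Cox) test
#'
#' Each dendrogram's normalised merge heights are treated as uncensored event
#' times: a module-count curve is exactly the "number at risk" profile of
#' those events, so two curves are compared by the standard two-sample
#' log-rank statistic on the merge heights.
#'
#' @param dend_a,dend_b [cluster_structures()] results
#' @return list with `statistic` (chi-square, 1 df), `p_value`, `n_events`.
#' @export
compare_modularity_logrank <- function(dend_a, dend_b) {
  stopifnot(inherits(dend_a, "fos_dendrogram"), inherits(dend_b, "fos_dendrogram"))
  ha <- dend_a$heights_norm; hb <- dend_b$heights_norm
  if (length(ha) < 2 || length(hb) < 2)
    stop("each dendrogram needs >= 2 merges")
  time <- c(ha, hb)
  grp <- rep(c("a", "b"), c(length(ha), length(hb)))
  sd <- survival::survdiff(survival::Surv(time, rep(1L, length(time))) ~ grp)
  list(statistic = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       n_events = c(a = length(ha), b = length(hb)))
}

#' Thresholded functional-network graph
#'
#' Nodes are the regions significant at the (stringent) node threshold on BH
#' q-values; edges join node pairs whose inter-animal correlation exceeds
#' `r_cut` (strictly positive rule: negative correlations never form edges,
#' NAs are ignored). Hubs are nodes ranked by degree.
#'
#' @param diff a [fos_diff] result (or a character vector of node acronyms)
#' @param corr a [correlation_matrix()] result for the treatment group
#' @param p_cut node threshold on q-values (default 0.01)
#' @param r_cut edge threshold on Pearson r (default 0.75)
#' @param family,group optional filters passed to [significant_regions()]
#' @return object of class `functional_graph`: list with `nodes`, `edges`
#'   (data frame `from`, `to`, `r`), `degree` (named integer), `hubs`
#'   (nodes by descending degree) and `graph` (an igraph object).
#' @export
build_graph <- function(diff, corr, p_cut = 0.01, r_cut = 0.75,
                        family = NULL, group = NULL) {
  nodes <- if (is.character(diff)) diff
           else significant_regions(diff, alpha = p_cut, family = family, group = group)
  nodes <- intersect(nodes, colnames(corr))
  if (length(nodes) == 0)
    warning("no regions pass the node threshold; graph is empty")
  edges <- data.frame(from = character(0), to = character(0), r = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(nodes) >= 2) {
    sub <- corr[nodes, nodes, drop = FALSE]
    idx <- which(upper.tri(sub) & !is.na(sub) & sub > r_cut, arr.ind = TRUE)
    if (nrow(idx))
      edges <- data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
                          r = sub[idx], stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  deg <- igraph::degree(g)
  structure(list(nodes = nodes, edges = edges, degree = deg,
                 hubs = names(sort(deg, decreasing = TRUE)),
                 p_cut = p_cut, r_cut = r_cut, graph = g),
            class = "functional_graph")
}

#' @export
print.functional_graph <- function(x, ...) {
  cat("Functional graph:", length(x$nodes), "nodes (q <=", x$p_cut, "),",
      nrow(x$edges), "edges (r >", x$r_cut, ")\n")
  if (length(x$hubs))
    cat("Top hubs:", paste(utils::head(x$hubs, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Export a functional graph for external renderers
#' @param x a [build_graph()] result
#' @param dir output directory; writes `graph.graphml` and `edges.csv`
#' @export
write_graph_files <- function(x, dir) {
  stopifnot(inherits(x, "functional_graph"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  igraph::write_graph(x$graph, file.path(dir, "graph.graphml"), format = "graphml")
  utils::write.csv(x$edges, file.path(dir, "edges.csv"), row.names = FALSE)
  invisible(dir)
}
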