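## all permutations of 1..n as an n! x n matrix (n <= 9; used for the exact
## small-sample Spearman null)
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

spearman_p <- function(rho, n, rx = NULL, ry = NULL) {
  if (is.na(rho)) return(NA_real_)
  if (n < 10L && !is.null(rx)) {
    ## exact permutation null over all n! orderings (mid-rank ties kept)
    P <- permutations(n)
    rxc <- rx - mean(rx)
    perm_r <- as.numeric(matrix(ry[P], nrow(P), n) %*% rxc) /
      sqrt(sum(rxc^2) * sum((ry - mean(ry))^2))
    return(mean(abs(perm_r) >= abs(rho) - 1e-12))
  }
  if (abs(rho) >= 1) return(0)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

#' Spearman rank correlation with significance
#'
#' Mid-rank (average-rank) Spearman correlation of the complete pairs, with a
#' two-sided p-value from the exact permutation null for fewer than 10 pairs
#' and the t approximation on `n - 2` degrees of freedom otherwise.
#'
#' @param x,y numeric vectors (pairwise-complete; >= 4 pairs).
#' @return list with `rho`, `p`, `n` and, when a vector is constant, `rho =
#'   NA` with a `reason`.
#' @export
spearman_assoc <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n,
                reason = "constant input"))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  list(rho = rho, p = spearman_p(rho, n, rx, ry), n = n)
}

#' Pairwise Spearman correlation matrix for one study group
#'
#' Pairwise-complete Spearman correlations over the selected features of the
#' named group only, with per-pair p-values and pair counts.
#'
#' @param dataset a `phenome_dataset`, or a samples-by-features matrix.
#' @param group group label (required for a dataset; must exist).
#' @param features optional character vector restricting/ordering features.
#' @param panels panel kinds to draw features from (dataset input).
#' @return a `corr_matrix`: `rho`, `p`, `n` matrices, `features` data frame
#'   (`name`, `panel`) and the `group` tag.
#' @export
correlation_matrix <- function(dataset, group = NULL, features = NULL,
                               panels = c("metabolite", "lipoprotein",
                                          "cytokine")) {
  if (inherits(dataset, "phenome_dataset")) {
    if (is.null(group)) stop("group label required", call. = FALSE)
    if (!group %in% levels(dataset$samples$group))
      stop("unknown group label: ", group, call. = FALSE)
    X <- combined_panel(dataset, panels)[dataset$samples$group == group, ,
                                         drop = FALSE]
    panel_of <- feature_panels(dataset)
  } else {
    X <- as_feature_matrix(dataset)
    panel_of <- stats::setNames(rep(NA_character_, ncol(X)), colnames(X))
    group <- group %||% "all"
  }
  if (!is.null(features)) {
    missing <- setdiff(features, colnames(X))
    if (length(missing))
      stop("unknown features: ", paste(missing, collapse = ", "),
           call. = FALSE)
    X <- X[, features, drop = FALSE]
  }
  if (nrow(X) < 4L) stop("group has fewer than 4 samples", call. = FALSE)

  rho <- stats::cor(X, method = "spearman", use = "pairwise.complete.obs")
  nm <- crossprod(!is.na(X))
  p <- matrix(NA_real_, ncol(X), ncol(X), dimnames = dimnames(rho))
  for (i in seq_len(ncol(X) - 1L)) for (j in seq.int(i + 1L, ncol(X))) {
    nij <- nm[i, j]
    if (nij < 4L || is.na(rho[i, j])) next
    if (nij < 10L) {
      ok <- !is.na(X[, i]) & !is.na(X[, j])
      p[i, j] <- spearman_p(rho[i, j], nij, rank(X[ok, i]), rank(X[ok, j]))
    } else {
      p[i, j] <- spearman_p(rho[i, j], nij)
    }
    p[j, i] <- p[i, j]
  }
  structure(list(rho = rho, p = p, n = nm,
                 features = data.frame(name = colnames(X),
                                       panel = unname(panel_of[colnames(X)])),
                 group = group),
            class = "corr_matrix")
}

#' @export
print.corr_matrix <- function(x, ...) {
  cat("Spearman correlation matrix (", x$group, "): ", nrow(x$rho),
      " features\n", sep = "")
  invisible(x)
}

#' Build a weighted-node correlation network
#'
#' Nodes are the selected features (e.g. the `q < 0.05` differential set plus
#' forced includes such as IL-6/IL-8); undirected edges connect pairs whose
#' correlation passes the significance criterion (`p < alpha`, or BH q over
#' the candidate edge family when `correction = "fdr"`) and `|rho| >=
#' min_abs_rho`.  Node weight is the degree (count of incident edges).
#'
#' @param corr a `corr_matrix` computed on the intended group.
#' @param alpha edge significance level.
#' @param min_abs_rho minimum absolute correlation for an edge.
#' @param include_features node set (default: all features of `corr`).
#' @param correction `"none"` (raw p, the display convention for these maps)
#'   or `"fdr"` (BH over candidate edges).
#' @return a `corr_network`: `nodes` (`name`, `panel`, `weight`), `edges`
#'   (`from`, `to`, `rho`, `p`, `sign`), `criteria`, `group`.
#' @export
build_network <- function(corr, alpha = 0.05, min_abs_rho = 0,
                          include_features = NULL,
                          correction = c("none", "fdr")) {
  stopifnot(inherits(corr, "corr_matrix"))
  correction <- match.arg(correction)
  nodes <- include_features %||% corr$features$name
  missing <- setdiff(nodes, corr$features$name)
  if (length(missing))
    stop("features absent from correlation matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!length(nodes)) stop("empty node set", call. = FALSE)

  rho <- corr$rho[nodes, nodes, drop = FALSE]
  p <- corr$p[nodes, nodes, drop = FALSE]
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  pv <- p[ut]
  crit_p <- if (correction == "fdr") bh_fdr(pv) else pv
  keep <- !is.na(pv) & crit_p < alpha & abs(rho[ut]) >= min_abs_rho
  edges <- data.frame(from = nodes[ut[keep, 1L]],
                      to = nodes[ut[keep, 2L]],
                      rho = rho[ut][keep],
                      p = pv[keep],
                      sign = ifelse(rho[ut][keep] >= 0, "+", "-"),
                      stringsAsFactors = FALSE)
  degree <- stats::setNames(integer(length(nodes)), nodes)
  if (nrow(edges)) {
    tab <- table(c(edges$from, edges$to))
    degree[names(tab)] <- as.integer(tab)
  }
  node_df <- data.frame(
    name = nodes,
    panel = corr$features$panel[match(nodes, corr$features$name)],
    weight = as.integer(degree), stringsAsFactors = FALSE)
  structure(list(nodes = node_df, edges = edges,
                 criteria = list(alpha = alpha, min_abs_rho = min_abs_rho,
                                 correction = correction),
                 group = corr$group),
            class = "corr_network")
}

#' @export
print.corr_network <- function(x, ...) {
  cat("Correlation network (", x$group, "): ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges (alpha = ", x$criteria$alpha,
      if (x$criteria$correction == "fdr") ", FDR-corrected" else "",
      ", |rho| >= ", x$criteria$min_abs_rho, ")\n", sep = "")
  top <- x$nodes[order(-x$nodes$weight), ][seq_len(min(3L, nrow(x$nodes))), ]
  cat("  top nodes by degree:",
      paste(top$name, " (", top$weight, ")", sep = "", collapse = ", "), "\n")
  invisible(x)
}

edge_keys <- function(net) {
  if (!nrow(net$edges)) return(character(0))
  apply(net$edges[, c("from", "to")], 1L, function(e)
    paste(sort(e), collapse = "||"))
}

#' Differential comparison of two correlation networks
#'
#' Requires the same node universe; reports per-node degrees in each network,
#' the degree difference, the edges unique to each network, total edge
#' counts, and the top-ranked node by degree per network.
#'
#' @param a,b `corr_network` objects over the same node set.
#' @return a `network_comparison` list.
#' @export
compare_networks <- function(a, b) {
  stopifnot(inherits(a, "corr_network"), inherits(b, "corr_network"))
  sym <- c(setdiff(a$nodes$name, b$nodes$name),
           setdiff(b$nodes$name, a$nodes$name))
  if (length(sym))
    stop("node universes differ; symmetric difference: ",
         paste(sym, collapse = ", "), call. = FALSE)
  nodes <- a$nodes$name
  da <- stats::setNames(a$nodes$weight, a$nodes$name)[nodes]
  db <- stats::setNames(b$nodes$weight, b$nodes$name)[nodes]
  ka <- edge_keys(a); kb <- edge_keys(b)
  deg <- data.frame(name = nodes, degree_a = as.integer(da),
                    degree_b = as.integer(db),
                    difference = as.integer(da - db), row.names = NULL)
  structure(list(
    degrees = deg,
    unique_to_a = a$edges[!(ka %in% kb), , drop = FALSE],
    unique_to_b = b$edges[!(kb %in% ka), , drop = FALSE],
    n_edges = c(a = nrow(a$edges), b = nrow(b$edges)),
    top_node = c(a = nodes[which.max(da)], b = nodes[which.max(db)]),
    groups = c(a = a$group, b = b$group)
  ), class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  cat("Network comparison: ", x$groups["a"], " (", x$n_edges["a"],
      " edges) vs ", x$groups["b"], " (", x$n_edges["b"], " edges)\n",
      sep = "")
  cat("  top node by degree:", x$top_node["a"], "vs", x$top_node["b"], "\n")
  invisible(x)
}

net_to_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    if (nrow(net$edges)) net$edges else
      data.frame(from = character(0), to = character(0), rho = numeric(0),
                 p = numeric(0), sign = character(0)),
    directed = FALSE, vertices = net$nodes)
  g <- igraph::set_graph_attr(g, "group", net$group)
  g <- igraph::set_graph_attr(g, "alpha", net$criteria$alpha)
  g <- igraph::set_graph_attr(g, "min_abs_rho", net$criteria$min_abs_rho)
  igraph::set_graph_attr(g, "correction", net$criteria$correction)
}

#' Export / import a correlation network
#'
#' `"edgelist"` writes a CSV with columns `source`, `target`, `rho`, `p`,
#' `sign`, `group`, preceded by comment lines carrying the criteria and the
#' node table (so isolated nodes and degree weights survive the round trip).
#' `"graphml"` writes GraphML via igraph with node attributes (`panel`,
#' `weight`), edge attributes and graph-level criteria.
#'
#' @param net a `corr_network`.
#' @param path output file.
#' @param format `"edgelist"` or `"graphml"`.
#' @return `read_network` returns the reconstructed `corr_network`.
#' @export
export_network <- function(net, path, format = c("edgelist", "graphml")) {
  stopifnot(inherits(net, "corr_network"))
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(net_to_igraph(net), path, format = "graphml")
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# group: %s", net$group), con)
  writeLines(sprintf("# criteria: alpha=%.17g min_abs_rho=%.17g correction=%s",
                     net$criteria$alpha, net$criteria$min_abs_rho,
                     net$criteria$correction), con)
  writeLines(sprintf("# node: %s,%s,%d", net$nodes$name, net$nodes$panel,
                     net$nodes$weight), con)
  writeLines("source,target,rho,p,sign,group", con)
  if (nrow(net$edges))
    writeLines(sprintf("%s,%s,%.17g,%.17g,%s,%s", net$edges$from,
                       net$edges$to, net$edges$rho, net$edges$p,
                       net$edges$sign, net$group), con)
  invisible(path)
}

#' @rdname export_network
#' @export
read_network <- function(path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- data.frame(name = igraph::V(g)$name,
                        panel = igraph::V(g)$panel,
                        weight = as.integer(igraph::V(g)$weight),
                        stringsAsFactors = FALSE)
    el <- igraph::as_data_frame(g, what = "edges")
    edges <- data.frame(from = el$from %||% character(0),
                        to = el$to %||% character(0),
                        rho = as.numeric(el$rho %||% numeric(0)),
                        p = as.numeric(el$p %||% numeric(0)),
                        sign = as.character(el$sign %||% character(0)),
                        stringsAsFactors = FALSE)
    return(structure(list(
      nodes = nodes, edges = edges,
      criteria = list(alpha = igraph::graph_attr(g, "alpha"),
                      min_abs_rho = igraph::graph_attr(g, "min_abs_rho"),
                      correction = igraph::graph_attr(g, "correction")),
      group = igraph::graph_attr(g, "group")), class = "corr_network"))
  }
  lines <- readLines(path)
  grp <- trimws(sub("^#\\s*group:", "", grep("^#\\s*group:", lines,
                                             value = TRUE)[1L]))
  cl <- grep("^#\\s*criteria:", lines, value = TRUE)[1L]
  crit <- strsplit(trimws(sub("^#\\s*criteria:", "", cl)), " ")[[1L]]
  crit <- strsplit(crit, "=", fixed = TRUE)
  criteria <- stats::setNames(lapply(crit, `[`, 2L), vapply(crit, `[`, "", 1L))
  criteria$alpha <- as.numeric(criteria$alpha)
  criteria$min_abs_rho <- as.numeric(criteria$min_abs_rho)
  nl <- sub("^#\\s*node:\\s*", "", grep("^#\\s*node:", lines, value = TRUE))
  nparts <- strsplit(nl, ",", fixed = TRUE)
  nodes <- data.frame(name = vapply(nparts, `[`, "", 1L),
                      panel = vapply(nparts, `[`, "", 2L),
                      weight = as.integer(vapply(nparts, `[`, "", 3L)),
                      stringsAsFactors = FALSE)
  body <- lines[!grepl("^#", lines)]
  edges <- if (length(body) > 1L) {
    parts <- strsplit(body[-1L], ",", fixed = TRUE)
    data.frame(from = vapply(parts, `[`, "", 1L),
               to = vapply(parts, `[`, "", 2L),
               rho = as.numeric(vapply(parts, `[`, "", 3L)),
               p = as.numeric(vapply(parts, `[`, "", 4L)),
               sign = vapply(parts, `[`, "", 5L),
               stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(0), to = character(0), rho = numeric(0),
               p = numeric(0), sign = character(0), stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, criteria = criteria,
                 group = grp), class = "corr_network")
}
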