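# Internal: n_subjects x n_pairs matrix of residual Z-scores.
# Degenerate pairs and pairs with a missing subject value get weight 0.
# For a symmetrized baseline each pair carries the direction with the
# larger absolute Z-score.
.weights_matrix <- function(F, model) {
  pairs <- model$pairs
  k_idx <- match(pairs$feature_k, model$feature_names)
  l_idx <- match(pairs$feature_l, model$feature_names)
  n <- nrow(F)

  one_direction <- function(x_idx, y_idx, alpha, beta, sigma, degen) {
    a <- ifelse(degen, 0, alpha)
    b <- ifelse(degen, 0, beta)
    s <- ifelse(degen, 1, sigma)
    # per-pair constants recycled column-wise over the n x np layout
    W <- (F[, y_idx, drop = FALSE] - rep(a, each = n) -
            F[, x_idx, drop = FALSE] * rep(b, each = n)) / rep(s, each = n)
    if (any(degen)) W[, degen] <- 0
    W
  }

  if (isTRUE(model$symmetrize)) {
    Wf <- one_direction(k_idx, l_idx, pairs$alpha, pairs$beta, pairs$sigma,
                        pairs$degenerate_fwd)
    Wr <- one_direction(l_idx, k_idx, pairs$alpha_rev, pairs$beta_rev,
                        pairs$sigma_rev, pairs$degenerate_rev)
    Wf[!is.finite(Wf)] <- 0
    Wr[!is.finite(Wr)] <- 0
    take_rev <- abs(Wr) > abs(Wf)
    W <- Wf
    W[take_rev] <- Wr[take_rev]
    attr(W, "n_skipped") <- 0L
    return(W)
  }

  W <- one_direction(k_idx, l_idx, pairs$alpha, pairs$beta, pairs$sigma,
                     pairs$degenerate)
  na_skip <- !is.finite(W)
  if (any(na_skip)) W[na_skip] <- 0
  attr(W, "n_skipped") <- sum(na_skip)
  W
}

new_parenclitic_network <- function(subject_id, nodes, k_idx, l_idx, weight,
                                    binary = NULL, threshold = NULL) {
  structure(list(subject_id = subject_id, nodes = nodes,
                 k_idx = k_idx, l_idx = l_idx, weight = weight,
                 binary = binary, threshold = threshold),
            class = "parenclitic_network")
}

#' Build a subject's parenclitic deviation network
#'
#' Compares one subject against the fitted control baselines: for every
#' non-degenerate feature pair \{k, l\} the edge weight is the residual
#' Z-score `w = (f_l - (alpha + beta * f_k)) / sigma`, i.e. the subject's
#' distance from the control relation in units of the control residual
#' spread. Large `|w|`, of either sign, marks an abnormal pair. Degenerate
#' pairs carry weight 0 and never form links; pairs for which the subject is
#' missing a value are skipped with a warning (weight 0).
#'
#' @param subject A named numeric vector, or a one-row data frame whose
#'   feature columns cover the model's features (a `subject_id` column or
#'   name is used as the network's id).
#' @param model A [fit_baseline()] result.
#' @return An object of class `parenclitic_network` holding one weight per
#'   unordered feature pair. Use [binarize()] to threshold it, [tidy()] for
#'   an edge-list tibble, `as.matrix()` for the weighted adjacency matrix.
#' @examples
#' controls <- tibble::tibble(f1 = rnorm(50), f2 = rnorm(50))
#' model <- fit_baseline(controls)
#' net <- compute_network(c(f1 = 1, f2 = -2), model)
#' tidy(net)
#' @export
compute_network <- function(subject, model) {
  stopifnot(inherits(model, "parenclitic_baseline"))
  id <- NA_character_
  if (is.data.frame(subject)) {
    if (nrow(subject) != 1) abort("subject must be a single row")
    if ("subject_id" %in% names(subject)) id <- as.character(subject$subject_id)
    subject_vals <- unlist(subject[, intersect(names(subject), model$feature_names)])
  } else if (is.numeric(subject)) {
    subject_vals <- subject
  } else {
    abort("subject must be a named numeric vector or one-row data frame")
  }
  missing_feats <- setdiff(model$feature_names, names(subject_vals))
  if (length(missing_feats) > 0) {
    abort(paste0("subject lacks model feature(s): ",
                 paste(missing_feats, collapse = ", ")))
  }
  F <- matrix(as.numeric(subject_vals[model$feature_names]), nrow = 1,
              dimnames = list(NULL, model$feature_names))
  W <- .weights_matrix(F, model)
  if (attr(W, "n_skipped") > 0) {
    warn(paste0("subject ", id, ": ", attr(W, "n_skipped"),
                " pair(s) skipped due to missing values (weight 0)"))
  }
  pairs <- model$pairs
  new_parenclitic_network(
    subject_id = id, nodes = model$feature_names,
    k_idx = match(pairs$feature_k, model$feature_names),
    l_idx = match(pairs$feature_l, model$feature_names),
    weight = as.numeric(W))
}

#' Build parenclitic networks for every subject of a cohort
#'
#' @param cohort A cohort table (`subject_id`, label column, features).
#' @param model A [fit_baseline()] result.
#' @param label_col Label column name, ignored as a feature.
#' @param threshold If non-`NULL`, networks are also [binarize()]d at this
#'   threshold.
#' @return A named list of `parenclitic_network` objects (one per subject).
#' @export
compute_networks <- function(cohort, model, label_col = "DEATH",
                             threshold = NULL) {
  stopifnot(inherits(model, "parenclitic_baseline"))
  cohort <- tibble::as_tibble(cohort)
  ids <- if ("subject_id" %in% names(cohort)) {
    as.character(cohort$subject_id)
  } else sprintf("S%05d", seq_len(nrow(cohort)))
  missing_feats <- setdiff(model$feature_names, names(cohort))
  if (length(missing_feats) > 0) {
    abort(paste0("cohort lacks model feature(s): ",
                 paste(missing_feats, collapse = ", ")))
  }
  F <- as.matrix(cohort[, model$feature_names, drop = FALSE])
  W <- .weights_matrix(F, model)
  if (attr(W, "n_skipped") > 0) {
    warn(paste0(attr(W, "n_skipped"),
                " pair value(s) skipped due to missing values (weight 0)"))
  }
  pairs <- model$pairs
  k_idx <- match(pairs$feature_k, model$feature_names)
  l_idx <- match(pairs$feature_l, model$feature_names)
  nets <- lapply(seq_len(nrow(F)), function(i) {
    net <- new_parenclitic_network(ids[i], model$feature_names,
                                   k_idx, l_idx, W[i, ])
    if (!is.null(threshold)) net <- binarize(net, threshold) else net
  })
  names(nets) <- ids
  nets
}

#' Threshold a weighted parenclitic network
#'
#' Keeps a link for each pair whose absolute Z-score weight strictly exceeds
#' `threshold`; weights at or below the threshold are discarded as
#' statistically insignificant. The weighted network is retained alongside
#' the binary adjacency.
#'
#' @param network A `parenclitic_network`.
#' @param threshold Non-negative cutoff on `|w|`; default 0.5.
#' @return The network with its `binary` link vector filled in.
#' @export
binarize <- function(network, threshold = 0.5) {
  stopifnot(inherits(network, "parenclitic_network"))
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0) {
    abort("threshold must be a single non-negative number")
  }
  network$binary <- abs(network$weight) > threshold
  network$threshold <- threshold
  network
}

#' @export
print.parenclitic_network <- function(x, ...) {
  cat("<parenclitic_network> subject ", x$subject_id, "\n", sep = "")
  cat("  nodes: ", length(x$nodes), ", pairs: ", length(x$weight), "\n", sep = "")
  if (!is.null(x$binary)) {
    cat("  links: ", sum(x$binary), " at |w| > ", x$threshold, "\n", sep = "")
  } else {
    cat("  links: not binarized (see binarize())\n")
  }
  invisible(x)
}

#' @rdname compute_network
#' @param x A `parenclitic_network`.
#' @param ... Unused.
#' @export
tidy.parenclitic_network <- function(x, ...) {
  out <- tibble::tibble(source = x$nodes[x$k_idx], target = x$nodes[x$l_idx],
                        weight = x$weight)
  if (!is.null(x$binary)) out$binary <- as.integer(x$binary)
  out
}

#' @export
as.matrix.parenclitic_network <- function(x, ...) {
  n <- length(x$nodes)
  A <- matrix(0, n, n, dimnames = list(x$nodes, x$nodes))
  A[cbind(x$k_idx, x$l_idx)] <- x$weight
  A[cbind(x$l_idx, x$k_idx)] <- x$weight
  A
}

# Binary adjacency (0/1 integer matrix) of a binarized network.
binary_adjacency <- function(network) {
  if (is.null(network$binary)) {
    abort("network is not binarized; call binarize() first")
  }
  n <- length(network$nodes)
  A <- matrix(0L, n, n, dimnames = list(network$nodes, network$nodes))
  on <- network$binary
  A[cbind(network$k_idx[on], network$l_idx[on])] <- 1L
  A[cbind(network$l_idx[on], network$k_idx[on])] <- 1L
  A
}

#' Convert a parenclitic network to an igraph graph
#'
#' @param network A `parenclitic_network`.
#' @param binary_only If `TRUE` (default) and the network is binarized, only
#'   the surviving links become edges (with their weights as attributes);
#'   otherwise every non-zero weight becomes an edge.
#' @return An undirected `igraph` graph with one vertex per feature.
#' @export
as_igraph <- function(network, binary_only = TRUE) {
  stopifnot(inherits(network, "parenclitic_network"))
  keep <- if (binary_only && !is.null(network$binary)) {
    network$binary
  } else {
    network$weight != 0
  }
  g <- igraph::make_empty_graph(n = length(network$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = network$nodes)
  if (any(keep)) {
    edges <- rbind(network$k_idx[keep], network$l_idx[keep])
    g <- igraph::add_edges(g, as.vector(edges),
                           weight = network$weight[keep])
  }
  g
}

#' Write a network as an edge-list CSV or GraphML file
#'
#' The CSV form is `source,target,weight,binary` over all non-degenerate
#' pairs; the GraphML form contains only the binarized links (weights kept
#' as edge attributes) for interoperability with graph tools.
#'
#' @param network A binarized `parenclitic_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_csv <- function(network, path) {
  stopifnot(inherits(network, "parenclitic_network"))
  if (is.null(network$binary)) abort("binarize() the network first")
  readr::write_csv(tidy(network), path)
  invisible(path)
}

#' @rdname write_network_csv
#' @export
write_network_graphml <- function(network, path) {
  stopifnot(inherits(network, "parenclitic_network"))
  if (is.null(network$binary)) abort("binarize() the network first")
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}
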