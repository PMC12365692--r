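CANONICAL_NETWORKS <- c("DMN", "FP", "visual", "DAN", "VAN", "SAL", "AUD",
                        "CON", "SMd", "SMl", "Tpole", "MTL", "PMN", "PON")

#' Binary network-membership template
#'
#' Converts a node-to-network label vector into the node x network 0/1
#' membership matrix used for template matching. Column order defines the
#' canonical tie-breaking order.
#'
#' @param network_labels Character vector assigning each node to a
#'   network.
#' @param networks Network names/order; defaults to the canonical 14
#'   functional networks, restricted to those present.
#' @return Node x network binary matrix of class `network_template`.
#' @export
network_template <- function(network_labels,
                             networks = intersect(CANONICAL_NETWORKS,
                                                  unique(network_labels))) {
  labels <- as.character(network_labels)
  extra <- setdiff(unique(labels), networks)
  networks <- c(networks, sort(extra))
  m <- vapply(networks, function(nw) as.numeric(labels == nw),
              numeric(length(labels)))
  rownames(m) <- names(network_labels)
  structure(m, class = c("network_template", "matrix"))
}

eta_squared_similarity <- function(a, b) {
  m_pair <- (a + b) / 2
  grand <- mean(c(a, b))
  ss_within <- sum((a - m_pair)^2 + (b - m_pair)^2)
  ss_total <- sum((a - grand)^2 + (b - grand)^2)
  if (ss_total == 0) return(NA_real_)
  1 - ss_within / ss_total
}

#' Assign each node to its best-matching functional network
#'
#' Correlates every node's connectivity profile (its FC row with the
#' self-connection removed) against each network's binary membership
#' vector and assigns the argmax network. Ties are broken by the
#' template's column order with a warning; all-constant profiles are left
#' unassigned.
#'
#' @param fc Node x node (Fisher-z) connectivity matrix.
#' @param template A [network_template] over the same node set.
#' @param metric `"pearson"` (default) or `"eta2"` similarity.
#' @return A `network_assignment` data frame (node, network, score).
#' @export
template_match <- function(fc, template, metric = c("pearson", "eta2")) {
  metric <- match.arg(metric)
  fc <- as.matrix(fc)
  if (nrow(fc) != nrow(template))
    stop_invalid("FC and template node sets differ")
  n <- nrow(fc)
  networks <- colnames(template)
  scores <- matrix(NA_real_, n, length(networks),
                   dimnames = list(NULL, networks))
  for (i in seq_len(n)) {
    profile <- fc[i, -i]
    if (stats::sd(profile) == 0) next
    for (k in seq_along(networks)) {
      tvec <- template[-i, k]
      if (stats::sd(tvec) == 0) {
        scores[i, k] <- 0
        next
      }
      scores[i, k] <- if (metric == "pearson")
        stats::cor(profile, tvec) else
          eta_squared_similarity(profile, tvec)
    }
  }
  assigned <- character(n); best <- numeric(n)
  ties <- 0L
  for (i in seq_len(n)) {
    if (all(is.na(scores[i, ]))) {
      assigned[i] <- NA_character_; best[i] <- NA_real_
      next
    }
    top <- which(scores[i, ] == max(scores[i, ], na.rm = TRUE))
    if (length(top) > 1L) ties <- ties + 1L
    assigned[i] <- networks[top[1L]]
    best[i] <- scores[i, top[1L]]
  }
  if (ties > 0L)
    warning(sprintf("%d node(s) tied; first network in template order used",
                    ties), call. = FALSE)
  if (length(networks) == 1L) assigned[!is.na(best)] <- networks
  structure(
    data.frame(node = seq_len(n), network = assigned, score = best,
               stringsAsFactors = FALSE),
    class = c("network_assignment", "data.frame"))
}

#' Group-consensus network map
#'
#' Labels a node with a network iff at least `threshold` of subjects
#' assigned it that network; otherwise the node stays unassigned. The
#' conventional thresholds are 66% and 75%; the looser one can only label
#' more nodes.
#'
#' @param assignments List of `network_assignment`s (>= 2 subjects).
#' @param threshold Agreement fraction required (e.g., 0.66 or 0.75).
#' @return Data frame (node, network, overlap_fraction); `network` is
#'   `NA` where no network reaches the threshold.
#' @export
group_overlap <- function(assignments, threshold = 0.66) {
  stopifnot(length(assignments) >= 2L, threshold > 0, threshold <= 1)
  n <- nrow(assignments[[1L]])
  labels <- vapply(assignments, function(a) a$network, character(n))
  consensus <- character(n); frac <- numeric(n)
  for (i in seq_len(n)) {
    tab <- table(labels[i, ], useNA = "no")
    if (!length(tab)) {
      consensus[i] <- NA_character_; frac[i] <- 0
      next
    }
    top <- which.max(tab)
    frac[i] <- tab[top] / length(assignments)
    consensus[i] <- if (frac[i] >= threshold) names(tab)[top]
      else NA_character_
  }
  data.frame(node = seq_len(n), network = consensus,
             overlap_fraction = frac, stringsAsFactors = FALSE)
}

#' Restrict nodes and networks to the analysis set
#'
#' Drops nodes without a consensus label and networks left with fewer
#' than `min_nodes` labeled nodes (network-level averages need at least
#' two member nodes).
#'
#' @param consensus Data frame from [group_overlap].
#' @param min_nodes Minimum labeled nodes per retained network.
#' @return List: `nodes` (retained node indices), `networks` (retained
#'   network names), `node_networks` (labels for retained nodes),
#'   `dropped_nodes`, `dropped_networks`.
#' @export
filter_networks_for_analysis <- function(consensus, min_nodes = 2L) {
  labeled <- !is.na(consensus$network)
  tab <- table(consensus$network[labeled])
  keep_nets <- names(tab)[tab >= min_nodes]
  keep <- labeled & consensus$network %in% keep_nets
  list(nodes = consensus$node[keep],
       networks = sort(keep_nets),
       node_networks = consensus$network[keep],
       dropped_nodes = consensus$node[!keep],
       dropped_networks = sort(setdiff(names(tab), keep_nets)))
}
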